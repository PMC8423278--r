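#' SEG score (mean Jaccard index over ground-truth masks)
#'
#' A ground-truth mask is matched to the result mask covering more than
#' half of its pixels; matched masks contribute their intersection-over-
#' union, unmatched masks contribute 0.
#'
#' @param gt,res [labeled_sequence]s of equal length and shape.
#' @return numeric in \[0, 1\].
#' @export
seg_score <- function(gt, res) {
  if (length(gt$frames) != length(res$frames) ||
      !identical(gt$dim, res$dim))
    stop("ground truth and result differ in frame count or image shape")
  vals <- c()
  for (t in seq_along(gt$frames)) {
    g <- gt$frames[[t]]; r <- res$frames[[t]]
    for (lb in sort(unique(g[g > 0L]))) {
      gpix <- which(g == lb)
      hit <- r[gpix]
      hit <- hit[hit > 0L]
      j <- 0
      if (length(hit)) {
        tabs <- table(hit)
        best <- as.integer(names(tabs)[which.max(tabs)])
        inter <- max(tabs)
        if (inter > 0.5 * length(gpix)) {
          rsize <- sum(r == best)
          j <- inter / (length(gpix) + rsize - inter)
        }
      }
      vals <- c(vals, j)
    }
  }
  if (!length(vals)) return(0)
  mean(vals)
}

# graph representation for the edit-distance measures: nodes are mask
# instances, edges are temporal links within tracks plus parent links
lineage_graph <- function(seq) {
  nodes <- mask_table(seq)
  nodes$key <- paste(nodes$t, nodes$label)
  edges <- data.frame(t1 = integer(), l1 = integer(), t2 = integer(),
                      l2 = integer(), semantic = character())
  lin <- seq$lineage
  if (nrow(lin)) {
    for (r in seq_len(nrow(lin))) {
      lb <- lin$label[r]
      pres <- sort(nodes$t[nodes$label == lb])
      pres <- pres[pres >= lin$begin[r] & pres <= lin$end[r]]
      if (length(pres) >= 2L)
        edges <- rbind(edges,
                       data.frame(t1 = pres[-length(pres)], l1 = lb,
                                  t2 = pres[-1], l2 = lb,
                                  semantic = "track"))
      if (lin$parent[r] != 0) {
        pr <- lin$parent[r]
        ppres <- sort(nodes$t[nodes$label == pr])
        pp <- match(pr, lin$label)
        ppres <- ppres[ppres >= lin$begin[pp] & ppres <= lin$end[pp]]
        if (length(ppres) && length(pres))
          edges <- rbind(edges,
                         data.frame(t1 = max(ppres), l1 = pr,
                                    t2 = min(pres), l2 = lb,
                                    semantic = "parent"))
      }
    }
  } else {
    # no lineage: treat each label as one track across its present frames
    for (lb in unique(nodes$label)) {
      pres <- sort(nodes$t[nodes$label == lb])
      if (length(pres) >= 2L)
        edges <- rbind(edges,
                       data.frame(t1 = pres[-length(pres)], l1 = lb,
                                  t2 = pres[-1], l2 = lb,
                                  semantic = "track"))
    }
  }
  list(nodes = nodes, edges = edges)
}

# penalty weights of the published AOGM convention: adding a node (FN)
# costs most, then splitting; edge edits are light, DET zeroes them
aogm_weights <- c(NS = 5, FN = 10, FP = 1, ED = 1, EA = 1.5, EC = 1)

#' DET and TRA scores (normalised graph-edit distances)
#'
#' Both measures compare acyclic lineage graphs built from the result and
#' the ground truth: nodes are mask instances (matched by the
#' more-than-half-overlap rule), edges are temporal links within tracks
#' and mother-daughter links. The edit cost to turn the result graph into
#' the ground-truth graph is normalised by the cost of building the
#' ground-truth graph from scratch; DET sets all edge penalties to zero.
#'
#' @param gt,res [labeled_sequence]s (ground truth needs lineage).
#' @return named numeric vector `c(TRA = ..., DET = ...)`.
#' @export
tra_det_scores <- function(gt, res) {
  if (length(gt$frames) != length(res$frames) ||
      !identical(gt$dim, res$dim))
    stop("ground truth and result differ in frame count or image shape")
  G <- lineage_graph(gt)
  R <- lineage_graph(res)
  w <- aogm_weights

  # node matching per frame: GT node -> res label covering > half of it
  match_map <- new.env(parent = emptyenv())     # gt key -> res key
  res_hits <- list()                            # res key -> # gt matched
  n_fn <- 0L
  for (t in sort(unique(G$nodes$t))) {
    g <- gt$frames[[t + 1L]]; r <- res$frames[[t + 1L]]
    for (lb in G$nodes$label[G$nodes$t == t]) {
      gpix <- which(g == lb)
      hit <- r[gpix]; hit <- hit[hit > 0L]
      matched <- FALSE
      if (length(hit)) {
        tabs <- table(hit)
        best <- as.integer(names(tabs)[which.max(tabs)])
        if (max(tabs) > 0.5 * length(gpix)) {
          rk <- paste(t, best)
          assign(paste(t, lb), rk, envir = match_map)
          res_hits[[rk]] <- c(res_hits[[rk]], paste(t, lb))
          matched <- TRUE
        }
      }
      if (!matched) n_fn <- n_fn + 1L
    }
  }
  n_ns <- sum(pmax(0L, lengths(res_hits) - 1L))          # split operations
  n_fp <- sum(!(R$nodes$key %in% names(res_hits)))

  # edge comparison on matched nodes
  res_edge_key <- if (nrow(R$edges))
    paste(R$edges$t1, R$edges$l1, R$edges$t2, R$edges$l2) else character()
  gt_to_res <- function(key)
    if (exists(key, envir = match_map, inherits = FALSE))
      get(key, envir = match_map) else NA_character_
  n_ea <- 0L; n_ec <- 0L
  used_res_edges <- character()
  if (nrow(G$edges)) for (r in seq_len(nrow(G$edges))) {
    k1 <- gt_to_res(paste(G$edges$t1[r], G$edges$l1[r]))
    k2 <- gt_to_res(paste(G$edges$t2[r], G$edges$l2[r]))
    if (is.na(k1) || is.na(k2) || identical(k1, k2)) { n_ea <- n_ea + 1L; next }
    ek <- paste(sub(" ", " ", k1), sub(" ", " ", k2))
    hit <- which(res_edge_key == ek)
    if (!length(hit)) { n_ea <- n_ea + 1L; next }
    used_res_edges <- c(used_res_edges, ek)
    if (!any(R$edges$semantic[hit] == G$edges$semantic[r]))
      n_ec <- n_ec + 1L
  }
  n_ed <- sum(!(res_edge_key %in% used_res_edges))

  n_nodes <- nrow(G$nodes); n_edges <- nrow(G$edges)
  aogm0_tra <- w["FN"] * n_nodes + w["EA"] * n_edges
  aogm0_det <- w["FN"] * n_nodes
  cost_tra <- w["FN"] * n_fn + w["FP"] * n_fp + w["NS"] * n_ns +
    w["EA"] * n_ea + w["ED"] * n_ed + w["EC"] * n_ec
  cost_det <- w["FN"] * n_fn + w["FP"] * n_fp + w["NS"] * n_ns
  tra <- if (aogm0_tra > 0) 1 - min(cost_tra, aogm0_tra) / aogm0_tra else 1
  det <- if (aogm0_det > 0) 1 - min(cost_det, aogm0_det) / aogm0_det else 1
  c(TRA = unname(tra), DET = unname(det))
}

#' Evaluate a tracking result against ground truth
#'
#' @param gt ground-truth [labeled_sequence] (with lineage).
#' @param res result [labeled_sequence] or `tracking_graph`.
#' @return data.frame with columns `SEG`, `DET`, `TRA`.
#' @export
evaluate_tracking <- function(gt, res) {
  if (inherits(res, "tracking_graph"))
    res <- as_labeled_sequence(res, n_frames = length(gt$frames))
  td <- tra_det_scores(gt, res)
  data.frame(SEG = seg_score(gt, res), DET = unname(td["DET"]),
             TRA = unname(td["TRA"]))
}
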