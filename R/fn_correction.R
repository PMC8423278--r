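#' Fill internal track gaps with interpolated masks
#'
#' For every track with missing frames strictly inside its span, the last
#' available mask before the gap is translated to centroid positions
#' linearly interpolated between the two anchor masks (rounded half-up per
#' axis) and inserted at each missing frame. Gaps at a track's start or
#' end (only one anchor) are left unfilled.
#'
#' @param graph a `tracking_graph`.
#' @return the graph with gap masks inserted; `$fn_log` lists insertions.
#' @export
interpolate_masks <- function(graph) {
  dims <- graph$dim
  log <- list()
  for (i in seq_along(graph$tracks)) {
    x <- graph$tracks[[i]]
    o <- order(x$frames)
    fr <- x$frames[o]; masks <- x$masks[o]
    labs <- x$labels[o]
    full <- seq(min(fr), max(fr))
    miss <- setdiff(full, fr)
    if (!length(miss)) next
    for (g in split(miss, cumsum(c(1, diff(miss) != 1)))) {
      a <- max(fr[fr < min(g)])
      b <- min(fr[fr > max(g)])
      ma <- masks[[match(a, fr)]]
      mb <- masks[[match(b, fr)]]
      ca <- colMeans(pix_coords(ma, dims))
      cb <- colMeans(pix_coords(mb, dims))
      coords_a <- pix_coords(ma, dims)
      for (f in g) {
        w <- (f - a) / (b - a)
        target <- ca + w * (cb - ca)
        shift <- floor(target - ca + 0.5)      # round half-up per axis
        newpix <- coords_to_pix(sweep(coords_a, 2, -shift), dims)
        if (!length(newpix)) next
        fr <- c(fr, f); masks <- c(masks, list(sort(newpix)))
        labs <- c(labs, NA_integer_)
        log[[length(log) + 1L]] <- list(track = x$id, frame = f,
                                        centroid = target)
      }
    }
    o <- order(fr)
    graph$tracks[[i]]$frames <- fr[o]
    graph$tracks[[i]]$masks <- masks[o]
    graph$tracks[[i]]$labels <- labs[o]
  }
  graph$fn_log <- c(graph$fn_log, log)
  graph
}

#' Resolve pixel conflicts between overlapping masks
#'
#' After gap interpolation, inserted masks can overlap existing ones.
#' Every pixel claimed by more than one track in a frame is assigned to
#' the mask whose centroid is closest (Euclidean), ties broken by the
#' lower track id. Non-conflicted pixels are never modified.
#'
#' @param graph a `tracking_graph`.
#' @return conflict-free `tracking_graph`.
#' @export
resolve_conflicts <- function(graph) {
  dims <- graph$dim
  tr <- graph$tracks
  if (!length(tr)) return(graph)
  frames_used <- sort(unique(unlist(lapply(tr, function(x) x$frames))))
  for (t in frames_used) {
    claims <- list()
    for (i in seq_along(tr)) {
      j <- match(t, tr[[i]]$frames)
      if (!is.na(j)) claims[[length(claims) + 1L]] <- list(i = i, j = j)
    }
    if (length(claims) < 2L) next
    allpix <- unlist(lapply(claims, function(cl) tr[[cl$i]]$masks[[cl$j]]))
    dup <- unique(allpix[duplicated(allpix)])
    if (!length(dup)) next
    cents <- lapply(claims, function(cl)
      colMeans(pix_coords(tr[[cl$i]]$masks[[cl$j]], dims)))
    ids <- vapply(claims, function(cl) tr[[cl$i]]$id, 1L)
    dupco <- pix_coords(dup, dims)
    for (pidx in seq_along(dup)) {
      px <- dup[pidx]
      holders <- which(vapply(claims, function(cl)
        px %in% tr[[cl$i]]$masks[[cl$j]], TRUE))
      d <- vapply(holders, function(h)
        sqrt(sum((cents[[h]] - dupco[pidx, ])^2)), 1)
      # closest centroid, ties to the lower track id
      best <- holders[order(d, ids[holders])][1]
      for (h in setdiff(holders, best)) {
        cl <- claims[[h]]
        tr[[cl$i]]$masks[[cl$j]] <- setdiff(tr[[cl$i]]$masks[[cl$j]], px)
      }
    }
    # a mask emptied by conflict resolution loses that frame
    for (cl in claims) {
      if (!length(tr[[cl$i]]$masks[[cl$j]])) {
        keep <- setdiff(seq_along(tr[[cl$i]]$frames), cl$j)
        tr[[cl$i]]$frames <- tr[[cl$i]]$frames[keep]
        tr[[cl$i]]$masks <- tr[[cl$i]]$masks[keep]
        tr[[cl$i]]$labels <- tr[[cl$i]]$labels[keep]
      }
    }
  }
  graph$tracks <- tr
  graph
}

#' False-negative correction stage
#'
#' @param graph a `tracking_graph`.
#' @return graph with interpolated gap masks and conflicts resolved.
#' @export
correct_false_negatives <- function(graph) {
  resolve_conflicts(interpolate_masks(graph))
}
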