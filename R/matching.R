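#' Matching-stage configuration
#'
#' @param delta_t maximum time span (frames) over which a track may bridge
#'   missing masks (default 3).
#' @param roi_scale ROI size as a multiple of the mean mask extent.
#' @param window_length frames per optimization window.
#' @param window_overlap frames shared by consecutive windows (at least
#'   `delta_t`; default `delta_t`).
#' @param n_max_pairs cap on coupled mitosis pairs per split node.
#' @param theta_factor the large-cost constant is
#'   `theta = theta_factor * alpha` (default 1000).
#' @return a `matching_config` list.
#' @export
matching_config <- function(delta_t = 3L, roi_scale = 2,
                            window_length = 10L, window_overlap = NULL,
                            n_max_pairs = 10L, theta_factor = 1000) {
  if (is.null(window_overlap)) window_overlap <- delta_t
  stopifnot(delta_t >= 1L, window_overlap >= delta_t,
            window_length > window_overlap)
  structure(list(delta_t = as.integer(delta_t), roi_scale = roi_scale,
                 window_length = as.integer(window_length),
                 window_overlap = as.integer(window_overlap),
                 n_max_pairs = as.integer(n_max_pairs),
                 theta_factor = theta_factor),
            class = "matching_config")
}

node_key <- function(type, label, t, ot = NA)
  paste(type, label, t, ot, sep = ":")

#' Build the typed flow graph for one time window
#'
#' Nodes: source/sink, one object node per segmented object, `delta_t - 1`
#' skip nodes per object (hypothesised missing masks), split nodes
#' (mitosis / over-segmentation), merge nodes (under-segmentation), and
#' per-frame appear/delete nodes. Edges follow the allowed type adjacency
#' and connect only candidate-derived nodes; capacities implement the
#' unit-flow and counting rules of the coupled min-cost flow model.
#'
#' @param features `sequence_features`.
#' @param cand result of [find_candidates].
#' @param cfg [matching_config].
#' @param window integer vector `c(first_frame, last_frame)` (0-based).
#' @param roi from [default_roi_size] (for `alpha`).
#' @return a `flow_graph`: node table, edge table (costs NA until
#'   [compute_costs]), and bookkeeping.
#' @export
build_flow_graph <- function(features, cand, cfg, window,
                             roi = default_roi_size(features, cfg$roi_scale)) {
  t0 <- window[1]; t1 <- window[2]
  stopifnot(t1 >= t0)
  dt <- cfg$delta_t
  frames <- t0:t1
  objs <- features$objects
  nobj <- vapply(frames, function(t) length(objs[[t + 1L]]), 1L)
  names(nobj) <- frames

  cnd <- cand$candidates
  cnd <- cnd[cnd$t >= t0 & cnd$cand_t <= t1, , drop = FALSE]
  # candidate lookup: labels of objects at frame t+k matched to (t, label)
  ckey <- paste(cnd$t, cnd$label, cnd$cand_t, sep = ":")
  cand_of <- function(t, label, t2) {
    sel <- ckey == paste(t, label, t2, sep = ":")
    cnd$cand_label[sel]
  }
  if (any(!is.na(cnd$cand_label))) {
    for (r in seq_len(nrow(cnd))) {
      if (is.null(objs[[cnd$cand_t[r] + 1L]][[as.character(cnd$cand_label[r])]]))
        stop("candidate references unknown object ", cnd$cand_label[r],
             " at frame ", cnd$cand_t[r])
    }
  }

  # node identity: skip and split nodes additionally carry the origin
  # frame `ot` of their object, since raw segmentation labels are only
  # unique within a frame
  nodes <- list()
  add_node <- local({
    n <- 0L
    function(type, label = NA_integer_, t = NA_integer_, ot = NA_integer_) {
      n <<- n + 1L
      nodes[[n]] <<- data.frame(id = n, type = type, label = label, t = t,
                                ot = ot)
      n
    }
  })
  SRC <- add_node("source"); SNK <- add_node("sink")
  id_of <- new.env(parent = emptyenv())
  reg <- function(type, label, t, ot = NA_integer_) {
    id <- add_node(type, label, t, ot)
    assign(node_key(type, label, t, ot), id, envir = id_of)
    id
  }
  get_id <- function(type, label, t, ot = NA_integer_) {
    k <- node_key(type, label, t, ot)
    if (exists(k, envir = id_of, inherits = FALSE))
      get(k, envir = id_of) else NA_integer_
  }

  for (t in frames) for (lb in names(objs[[t + 1L]]))
    reg("o", as.integer(lb), t)
  # skip nodes
  for (t in frames) for (lb in names(objs[[t + 1L]])) {
    for (k in seq_len(dt - 1L)) {
      tt <- t + k
      if (tt > t1) break
      reg("x", as.integer(lb), tt, ot = t)
    }
  }
  for (t in frames[-length(frames)]) reg("a", NA_integer_, t)
  for (t in frames[-1L]) reg("d", NA_integer_, t)

  edges <- list()
  add_edge <- function(from, to, cap, lb = 0) {
    edges[[length(edges) + 1L]] <<-
      data.frame(from = from, to = to, cap = cap, lb = lb, cost = NA_real_)
  }

  # source -> first-frame objects; source -> appear (required flow |O_{t+1}|)
  for (lb in names(objs[[t0 + 1L]]))
    add_edge(SRC, get_id("o", as.integer(lb), t0), 1)
  for (t in frames[-length(frames)]) {
    req <- nobj[as.character(t + 1L)]
    add_edge(SRC, get_id("a", NA, t), req, lb = req)
  }
  # delete -> sink, capacity summed over the skip span
  for (t in frames[-1L]) {
    span <- max(t - dt, t0):t
    add_edge(get_id("d", NA, t), SNK,
             sum(nobj[as.character(intersect(span, frames))]))
  }

  # per-object edges
  for (t in frames) for (lb in names(objs[[t + 1L]])) {
    i <- as.integer(lb)
    oid <- get_id("o", i, t)
    # movement + skip chain + window-end exits
    if (t < t1) {
      for (j in cand_of(t, i, t + 1L))
        add_edge(oid, get_id("o", j, t + 1L), 1)
      xid <- get_id("x", i, t + 1L, ot = t)
      if (!is.na(xid)) add_edge(oid, xid, 1)
      add_edge(oid, get_id("d", NA, t + 1L), 1)         # disappear
    } else {
      add_edge(oid, SNK, 1)
    }
    if (t > t0) add_edge(get_id("a", NA, t - 1L), oid, 1)  # appear
    # skip chain of object i
    for (k in seq_len(dt - 1L)) {
      tt <- t + k
      if (tt > t1) break
      xid <- get_id("x", i, tt, ot = t)
      if (tt < t1) {
        nxt <- get_id("x", i, tt + 1L, ot = t)
        if (!is.na(nxt)) add_edge(xid, nxt, 1)
        for (j in cand_of(t, i, tt + 1L))
          add_edge(xid, get_id("o", j, tt + 1L), 1)
      } else {
        add_edge(xid, SNK, 1)
      }
    }
  }
  edges <- do.call(rbind, edges)
  edges <- unique(edges)

  # split nodes: s_{i,tau} after object/skip node of i at tau-1
  splits <- list()
  for (t in frames) for (lb in names(objs[[t + 1L]])) {
    i <- as.integer(lb)
    for (k in seq_len(dt)) {
      tau <- t + k
      if (tau > t1) break
      src_id <- if (k == 1L) get_id("o", i, t) else
        get_id("x", i, tau - 1L, ot = t)
      if (is.na(src_id)) next
      daughters <- cand_of(t, i, tau)
      if (length(daughters) < 2L) next
      sid <- reg("s", i, tau, ot = t)
      splits[[length(splits) + 1L]] <-
        data.frame(sid = sid, mother_label = i, mother_t = t,
                   step = k, tau = tau, src_id = src_id,
                   daughters = I(list(daughters)))
      edges <- rbind(edges,
                     data.frame(from = src_id, to = sid, cap = 1, lb = 0,
                                cost = 0),
                     data.frame(from = get_id("a", NA, tau - 1L), to = sid,
                                cap = length(daughters), lb = 0, cost = 0))
      for (j in daughters)
        edges <- rbind(edges, data.frame(from = sid,
                                         to = get_id("o", j, tau),
                                         cap = 1, lb = 0, cost = NA_real_))
    }
  }
  # merge nodes: m_{i,tau} in front of object node o_{i,tau+1}
  merges <- list()
  for (t in frames[-1L]) for (lb in names(objs[[t + 1L]])) {
    i <- as.integer(lb)
    oid <- get_id("o", i, t)
    inflow <- edges[edges$to == oid &
                      nodes_type(nodes, edges$from) %in% c("o", "x"), ,
                    drop = FALSE]
    if (nrow(inflow) < 2L) next
    mid <- reg("m", i, t - 1L)
    merges[[length(merges) + 1L]] <-
      data.frame(mid = mid, target_label = i, target_t = t,
                 n_in = nrow(inflow))
    for (v in inflow$from)
      edges <- rbind(edges, data.frame(from = v, to = mid, cap = 1, lb = 0,
                                       cost = NA_real_))
    edges <- rbind(edges,
                   data.frame(from = mid, to = oid, cap = 1, lb = 0, cost = 0),
                   data.frame(from = mid, to = get_id("d", NA, t), cap = nrow(inflow),
                              lb = 0, cost = 0))
  }
  # appear -> delete drains
  for (t in frames[-length(frames)]) {
    add2 <- data.frame(from = get_id("a", NA, t),
                       to = get_id("d", NA, t + 1L),
                       cap = nobj[as.character(t + 1L)], lb = 0, cost = 0)
    edges <- rbind(edges, add2)
  }

  nodes <- do.call(rbind, nodes)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 splits = if (length(splits)) do.call(rbind, splits) else NULL,
                 merges = if (length(merges)) do.call(rbind, merges) else NULL,
                 pairs = NULL,
                 window = c(t0, t1), cfg = cfg, roi = roi,
                 source = SRC, sink = SNK, n_obj = nobj),
            class = "flow_graph")
}

nodes_type <- function(nodes, ids) {
  tp <- vapply(nodes, function(nd) nd$type, "",
               USE.NAMES = FALSE)[ids]
  tp
}

#' Attach the position-based costs to a flow graph
#'
#' Movement cost is the distance between the displaced centroid and the
#' target centroid; skip costs are the displacement magnitude unless the
#' propagated centroid falls inside any bounding box at the target frame
#' (then `theta`); mitosis pair costs combine mother-midpoint distance and
#' the mother-daughter distance asymmetry, gated by the inter-daughter
#' distance; split/merge edges use minimal distances between propagated
#' mask points and centroids gated by bounding-box membership; appearance
#' and disappearance cost the distance to the nearest image border capped
#' at `alpha`. Edges with cost at or above the pruning threshold (default
#' `theta`) are removed where feasibility permits, and mitosis pairs are
#' ranked by cost with at most `n_max_pairs` kept per split node.
#'
#' @param graph a `flow_graph` from [build_flow_graph].
#' @param features `sequence_features`.
#' @param disp displacement table from [propagate_objects].
#' @return the graph with costs, coupled pairs, and pruning applied.
#' @export
compute_costs <- function(graph, features, disp) {
  cfg <- graph$cfg
  alpha <- graph$roi$alpha
  theta <- cfg$theta_factor * alpha
  objs <- features$objects
  dims <- features$dim
  nodes <- graph$nodes
  edges <- graph$edges
  ntype <- nodes$type[edges$from]
  ttype <- nodes$type[edges$to]

  obj_at <- function(label, t) objs[[t + 1L]][[as.character(label)]]
  cum_of <- function(label, t) disp[[t + 1L]][[as.character(label)]]
  phat <- function(label, t, k) {
    o <- obj_at(label, t)
    o$centroid + cum_of(label, t)[k, ]
  }
  border_dist <- function(p) min(pmin(p, (dims - 1) - p))
  any_bbox_contains <- function(p, t) {
    for (o in objs[[t + 1L]])
      if (in_bbox(p, o$bbox_min, o$bbox_max)) return(TRUE)
    FALSE
  }

  # origin (object frame) of each o/x node id involved in an edge
  origin_t <- function(id) nodes$t[id]   # for o nodes: own frame
  lab <- function(id) nodes$label[id]

  x_origin <- function(id) nodes$ot[id]

  cost <- edges$cost
  for (r in seq_len(nrow(edges))) {
    ft <- ntype[r]; tt_ <- ttype[r]
    if (!is.na(cost[r])) next
    f <- edges$from[r]; to <- edges$to[r]
    if (ft == "o" && tt_ == "o") {
      i <- lab(f); t <- origin_t(f); j <- lab(to)
      cost[r] <- sqrt(sum((phat(i, t, 1L) - obj_at(j, t + 1L)$centroid)^2))
    } else if (ft == "o" && tt_ == "x") {
      i <- lab(f); t <- origin_t(f)
      p1 <- phat(i, t, 1L)
      step <- cum_of(i, t)[1L, ]
      cost[r] <- if (!any_bbox_contains(p1, t + 1L))
        sqrt(sum(step^2)) else theta
    } else if (ft == "x" && tt_ == "x") {
      i <- lab(f); t <- x_origin(f)
      k2 <- nodes$t[to] - t
      p2 <- phat(i, t, k2)
      step <- cum_of(i, t)[k2, ] - cum_of(i, t)[k2 - 1L, ]
      cost[r] <- if (!any_bbox_contains(p2, nodes$t[to]))
        sqrt(sum(step^2)) else theta
    } else if (ft == "x" && tt_ == "o") {
      i <- lab(f); t <- x_origin(f)
      k2 <- nodes$t[to] - t
      j <- lab(to)
      cost[r] <- sqrt(sum((phat(i, t, k2) -
                             obj_at(j, nodes$t[to])$centroid)^2))
    } else if (ft == "a" && tt_ == "o") {
      p <- obj_at(lab(to), nodes$t[to])$centroid
      cost[r] <- min(alpha, border_dist(p))
    } else if (ft == "o" && tt_ == "d") {
      p <- obj_at(lab(f), origin_t(f))$centroid
      cost[r] <- min(alpha, border_dist(p))
    } else if (ft == "s" && tt_ == "o") {
      srow <- graph$splits[graph$splits$sid == f, ]
      i <- srow$mother_label; t <- srow$mother_t; k <- srow$step
      o_m <- obj_at(i, t)
      shift <- cum_of(i, t)[k, ]
      j <- lab(to)
      pj <- obj_at(j, nodes$t[to])$centroid
      if (in_bbox(pj, o_m$bbox_min + shift, o_m$bbox_max + shift)) {
        qhat <- sweep(o_m$Q, 2, -shift)
        cost[r] <- sqrt(min(rowSums(sweep(qhat, 2, pj)^2)))
      } else cost[r] <- theta
    } else if (tt_ == "m" && ft %in% c("o", "x")) {
      mrow <- graph$merges[graph$merges$mid == to, ]
      i <- mrow$target_label; t2 <- mrow$target_t
      o_i <- obj_at(i, t2)
      if (ft == "o") { j <- lab(f); tj <- origin_t(f); k <- t2 - tj }
      else { j <- lab(f); tj <- x_origin(f); k <- t2 - tj }
      pj_hat <- phat(j, tj, k)
      if (in_bbox(pj_hat, o_i$bbox_min, o_i$bbox_max)) {
        cost[r] <- sqrt(min(rowSums(sweep(o_i$Q, 2, pj_hat)^2)))
      } else cost[r] <- theta
    } else {
      cost[r] <- 0
    }
  }
  edges$cost <- cost

  # coupled mitosis pairs (before pruning of split edges)
  pairs <- list()
  if (!is.null(graph$splits)) for (srow in seq_len(nrow(graph$splits))) {
    s <- graph$splits[srow, ]
    i <- s$mother_label; t <- s$mother_t
    o_m <- obj_at(i, t)
    ds <- sort(s$daughters[[1]])
    if (length(ds) < 2L) next
    cmb <- utils::combn(ds, 2L)
    pc <- apply(cmb, 2, function(jl) {
      pj <- obj_at(jl[1], s$tau)$centroid
      pl <- obj_at(jl[2], s$tau)$centroid
      c3 <- sqrt(sum((pj - pl)^2))
      if (c3 <= 1.5 * o_m$bbox_diag) {
        c1 <- sqrt(sum((o_m$centroid - (pj + pl) / 2)^2))
        c2 <- abs(sqrt(sum((o_m$centroid - pj)^2)) -
                    sqrt(sum((o_m$centroid - pl)^2)))
        c1 + c2
      } else theta
    })
    keep <- order(pc, cmb[1, ], cmb[2, ])
    keep <- keep[pc[keep] < theta]
    for (k in keep)
      pairs[[length(pairs) + 1L]] <-
        data.frame(sid = s$sid, tau = s$tau,
                   mother_label = i, mother_t = t,
                   j = cmb[1, k], l = cmb[2, k], cost = pc[k])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  if (!is.null(pairs)) {
    # keep the n_max cheapest pairs per segmented object (over all of its
    # split nodes), ranked by mitosis cost, ties by daughter ids
    keep <- unlist(lapply(split(seq_len(nrow(pairs)),
                                paste(pairs$mother_label, pairs$mother_t)),
                          function(ix) {
      o <- ix[order(pairs$cost[ix], pairs$j[ix], pairs$l[ix])]
      head(o, cfg$n_max_pairs)
    }))
    pairs <- pairs[sort(keep), , drop = FALSE]
  }

  # prune expensive non-structural edges; a split->daughter edge carries
  # the over-segmentation role only, so its removal leaves coupled
  # mitosis-pair flow over the same arc intact
  prunable <- (ntype %in% c("o", "x") & ttype %in% c("o", "x")) |
    (ntype == "s" & ttype == "o") | (ttype == "m")
  drop <- prunable & edges$cost >= theta - 1e-9
  edges <- edges[!drop, , drop = FALSE]

  # iteratively drop degenerate split/merge/skip structures
  repeat {
    changed <- FALSE
    # split nodes need a routable flow of two: a mitosis pair or at least
    # two over-segmentation edges
    sids <- nodes$id[nodes$type == "s"]
    for (sid in sids) {
      present <- any(edges$from == sid | edges$to == sid)
      if (!present) next
      nout <- sum(edges$from == sid)
      npair <- if (is.null(pairs)) 0L else sum(pairs$sid == sid)
      has_mother <- any(edges$to == sid &
                          nodes$type[edges$from] %in% c("o", "x"))
      has_appear <- any(edges$to == sid & nodes$type[edges$from] == "a")
      if ((nout < 2L && npair == 0L) || !has_mother || !has_appear) {
        edges <- edges[edges$from != sid & edges$to != sid, , drop = FALSE]
        if (!is.null(pairs)) pairs <- pairs[pairs$sid != sid, , drop = FALSE]
        changed <- TRUE
      }
    }
    # merge nodes need >= 2 inflows from o/x plus both outflows
    mids <- nodes$id[nodes$type == "m"]
    for (mid in mids) {
      present <- any(edges$from == mid | edges$to == mid)
      if (!present) next
      nin <- sum(edges$to == mid)
      has_o <- any(edges$from == mid & nodes$type[edges$to] == "o")
      has_d <- any(edges$from == mid & nodes$type[edges$to] == "d")
      if (nin < 2L || !has_o || !has_d) {
        edges <- edges[edges$from != mid & edges$to != mid, , drop = FALSE]
        changed <- TRUE
      }
    }
    # skip nodes need an inflow and an outflow
    xids <- nodes$id[nodes$type == "x"]
    for (xid in xids) {
      present <- any(edges$from == xid | edges$to == xid)
      if (present &&
          (!any(edges$to == xid) || !any(edges$from == xid))) {
        edges <- edges[edges$from != xid & edges$to != xid, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!is.null(pairs) && nrow(pairs)) {
    # pairs need their split node alive (with its o->s and a->s edges)
    keep <- vapply(seq_len(nrow(pairs)), function(r)
      any(edges$to == pairs$sid[r]), TRUE)
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) pairs <- NULL
  }
  # a->s capacities follow the surviving number of daughters (over edges
  # plus coupled-pair members)
  for (sid in nodes$id[nodes$type == "s"]) {
    e_as <- which(edges$to == sid & nodes$type[edges$from] == "a")
    if (!length(e_as)) next
    dtars <- nodes$label[edges$to[edges$from == sid]]
    if (!is.null(pairs)) {
      pr <- pairs[pairs$sid == sid, , drop = FALSE]
      dtars <- c(dtars, pr$j, pr$l)
    }
    edges$cap[e_as] <- max(1L, length(unique(dtars)))
  }

  rownames(edges) <- NULL
  graph$edges <- edges
  graph$pairs <- pairs
  graph$theta <- theta
  graph
}

#' Assemble the integer program of a costed flow graph
#'
#' Rows: flow conservation on every inner node, unit flow through every
#' object node, the merge and split ordering inequalities that quantise
#' merge/split flow to 0 or at least 2, the one-active-pair rule and the
#' mitosis-XOR-over-segmentation rule. Bounds carry the edge capacities
#' and the appear-node flow requirements.
#'
#' @param graph a costed `flow_graph`.
#' @return list with `obj`, `A`, `dir`, `rhs`, `lb`, `ub`, and the counts
#'   `n_edges`, `n_pairs`, or `NULL` for an edgeless graph.
#' @export
matching_ilp <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges; pairs <- graph$pairs
  nE <- nrow(edges)
  nP <- if (is.null(pairs)) 0L else nrow(pairs)
  nv <- nE + nP
  if (nE == 0L) return(NULL)

  rows <- list(); dirs <- character(); rhs <- numeric()
  add_row <- function(idx, coef, dir, b) {
    rows[[length(rows) + 1L]] <<- list(idx = idx, coef = coef)
    dirs[length(dirs) + 1L] <<- dir
    rhs[length(rhs) + 1L] <<- b
  }

  # pair variable incidence: at split node (outflow 2), at daughters (in 1)
  pair_in_node <- function(id) {
    if (nP == 0L) return(NULL)
    out <- NULL
    sidm <- which(pairs$sid == id)
    if (length(sidm)) out <- rbind(out, cbind(sidm, -2))
    if (nodes$type[id] == "o") {
      dm <- which((pairs$j == nodes$label[id] | pairs$l == nodes$label[id]) &
                    pairs$tau == nodes$t[id])
      if (length(dm)) out <- rbind(out, cbind(dm, 1))
    }
    out
  }

  # conservation on all nodes except source/sink (skip isolated nodes)
  for (id in nodes$id) {
    tp <- nodes$type[id]
    if (tp %in% c("source", "sink")) next
    ein <- which(edges$to == id); eout <- which(edges$from == id)
    pv <- pair_in_node(id)
    if (!length(ein) && !length(eout) && is.null(pv)) next
    idx <- c(ein, eout); coef <- c(rep(1, length(ein)), rep(-1, length(eout)))
    if (!is.null(pv)) { idx <- c(idx, nE + pv[, 1]); coef <- c(coef, pv[, 2]) }
    add_row(idx, coef, "==", 0)
    if (tp == "o") {   # unit inflow
      idx2 <- ein; coef2 <- rep(1, length(ein))
      if (!is.null(pv)) {
        pos <- pv[pv[, 2] > 0, , drop = FALSE]
        if (nrow(pos)) { idx2 <- c(idx2, nE + pos[, 1]); coef2 <- c(coef2, pos[, 2]) }
      }
      add_row(idx2, coef2, "==", 1)
    }
  }

  # merge ordering inequalities (flow 0 or >= 2)
  if (!is.null(graph$merges)) for (mi in seq_len(nrow(graph$merges))) {
    mid <- graph$merges$mid[mi]
    e_mo <- which(edges$from == mid &
                    nodes$type[edges$to] == "o")
    e_md <- which(edges$from == mid & nodes$type[edges$to] == "d")
    e_in <- which(edges$to == mid)
    if (!length(e_in) && !length(e_mo) && !length(e_md)) next
    if (!length(e_mo) || !length(e_md)) {
      # structurally incomplete: forbid any flow through the node
      for (e in c(e_in, e_mo, e_md)) add_row(e, 1, "==", 0)
      next
    }
    add_row(c(e_mo, e_md), c(1, -1), "<=", 0)
    for (e in e_in) add_row(c(e, e_mo), c(1, -1), "<=", 0)
  }
  # split ordering inequalities
  if (!is.null(graph$splits)) for (si in seq_len(nrow(graph$splits))) {
    sid <- graph$splits$sid[si]
    e_as <- which(edges$to == sid & nodes$type[edges$from] == "a")
    e_os <- which(edges$to == sid & nodes$type[edges$from] %in% c("o", "x"))
    e_out <- which(edges$from == sid)
    prs <- if (nP) which(pairs$sid == sid) else integer()
    if (!length(e_as) && !length(e_os) && !length(e_out) && !length(prs)) next
    if (!length(e_as) || !length(e_os)) {
      # structurally incomplete: forbid any flow through the node
      for (e in c(e_as, e_os, e_out)) add_row(e, 1, "==", 0)
      for (p in prs) add_row(nE + p, 1, "==", 0)
      next
    }
    if (!length(e_out) && !length(prs)) next
    add_row(c(e_os, e_as), c(1, -1), "<=", 0)
    # per daughter: total flow to the daughter <= flow o -> s
    dls <- unique(c(nodes$label[edges$to[e_out]],
                    if (length(prs)) c(pairs$j[prs], pairs$l[prs])))
    for (dl in dls) {
      idx <- integer(); coef <- numeric()
      e_d <- e_out[nodes$label[edges$to[e_out]] == dl]
      if (length(e_d)) { idx <- e_d; coef <- rep(1, length(e_d)) }
      pr_d <- prs[pairs$j[prs] == dl | pairs$l[prs] == dl]
      if (length(pr_d)) { idx <- c(idx, nE + pr_d); coef <- c(coef, rep(1, length(pr_d))) }
      add_row(c(idx, e_os), c(coef, -1), "<=", 0)
    }
    if (length(prs)) {
      add_row(nE + prs, rep(1, length(prs)), "<=", 1)  # one pair max
      # a split node models either a mitosis or an over-segmentation;
      # with at most one active pair this aggregates to one row per
      # over-segmentation edge
      for (e in e_out)
        add_row(c(nE + prs, e), c(rep(1, length(prs)), 1), "<=", 1)
    }
  }

  m <- length(rows)
  A <- matrix(0, m, nv)
  for (r in seq_len(m)) A[r, rows[[r]]$idx] <- A[r, rows[[r]]$idx] + rows[[r]]$coef
  obj <- c(edges$cost, if (nP) pairs$cost else numeric(0))
  lb <- c(edges$lb, rep(0, nP))
  ub <- c(edges$cap, rep(1, nP))
  list(obj = obj, A = A, dir = dirs, rhs = rhs, lb = lb, ub = ub,
       n_edges = nE, n_pairs = nP)
}

#' Solve the coupled minimum-cost flow problem of one window
#'
#' Builds the integer program via [matching_ilp] and solves it exactly.
#'
#' @param graph a costed `flow_graph`.
#' @return list with `flows` (edge table + `flow` column), `pair_flows`,
#'   `objective` and `status`.
#' @export
solve_matching <- function(graph) {
  edges <- graph$edges; pairs <- graph$pairs
  ilp <- matching_ilp(graph)
  if (is.null(ilp))
    return(list(flows = cbind(edges, flow = numeric(0)),
                pair_flows = NULL, objective = 0, status = "optimal",
                nodes = graph$nodes, graph = graph))
  sol <- milp_solve(ilp$obj, ilp$A, ilp$dir, ilp$rhs,
                    lb = ilp$lb, ub = ilp$ub, int_vars = TRUE)
  if (sol$status != "optimal")
    stop("matching ILP not solved to optimality: ", sol$status)
  nE <- ilp$n_edges; nP <- ilp$n_pairs
  flows <- cbind(edges, flow = sol$solution[seq_len(nE)])
  pf <- if (nP) cbind(pairs, flow = sol$solution[nE + seq_len(nP)]) else NULL
  list(flows = flows, pair_flows = pf, objective = sol$objective,
       status = sol$status, nodes = graph$nodes, graph = graph)
}

# Extract per-source-object events from one solved window.
window_events <- function(sol) {
  graph <- sol$graph
  nodes <- sol$nodes
  fl <- sol$flows[sol$flows$flow > 0.5, , drop = FALSE]
  pf <- sol$pair_flows
  ev <- list()
  emit <- function(src_t, src_label, dst_t, dst_label, kind)
    ev[[length(ev) + 1L]] <<-
      data.frame(src_t = src_t, src_label = src_label,
                 dst_t = dst_t, dst_label = dst_label, kind = kind)

  out_of <- function(id) fl[fl$from == id, , drop = FALSE]

  resolve_split <- function(sid, src_t, src_label) {
    # active pair?
    if (!is.null(pf)) {
      act <- pf[pf$sid == sid & pf$flow > 0.5, , drop = FALSE]
      if (nrow(act)) {
        tau <- act$tau[1]
        emit(src_t, src_label, tau, act$j[1], "divide")
        emit(src_t, src_label, tau, act$l[1], "divide")
        return(invisible())
      }
    }
    oo <- out_of(sid)
    for (r in seq_len(nrow(oo)))
      emit(src_t, src_label, nodes$t[oo$to[r]], nodes$label[oo$to[r]],
           "split")
  }

  obj_ids <- nodes$id[nodes$type == "o"]
  for (oid in obj_ids) {
    t <- nodes$t[oid]; i <- nodes$label[oid]
    oo <- out_of(oid)
    if (!nrow(oo)) next
    # follow at most one unit (object outflow is 1)
    cur <- oo[1, ]
    repeat {
      tt <- nodes$type[cur$to]
      if (tt == "o") { emit(t, i, nodes$t[cur$to], nodes$label[cur$to],
                            "move"); break }
      if (tt == "d") { emit(t, i, NA, NA, "disappear"); break }
      if (tt == "sink") { emit(t, i, NA, NA, "end_window"); break }
      if (tt == "s") { resolve_split(cur$to, t, i); break }
      if (tt == "m") {
        mrow <- graph$merges[graph$merges$mid == cur$to, ]
        emit(t, i, mrow$target_t, mrow$target_label, "merge"); break
      }
      if (tt == "x") {
        nxt <- out_of(cur$to)
        if (!nrow(nxt)) { emit(t, i, NA, NA, "end_window"); break }
        cur <- nxt[1, ]
        if (nodes$type[cur$to] == "o") {
          emit(t, i, nodes$t[cur$to], nodes$label[cur$to], "skip"); break
        }
        next
      }
      emit(t, i, NA, NA, "end_window"); break
    }
  }
  if (length(ev)) do.call(rbind, ev) else
    data.frame(src_t = integer(), src_label = integer(),
               dst_t = integer(), dst_label = integer(), kind = character())
}

#' Assemble tracks from the solved windows
#'
#' Segmented objects connected by the same flow path become one track;
#' where several paths start or end at a node, new tracks are created and
#' the predecessor/successor links kept. Overlapping windows are stitched
#' by object identity, the earlier window being authoritative up to the
#' overlap midpoint; conflicting inbound links from later windows are
#' dropped and counted.
#'
#' @param events list of per-window event tables (from solved windows).
#' @param owned list of `c(from, to)` frame ranges owned by each window.
#' @param features `sequence_features`.
#' @return a `tracking_graph`.
#' @export
flows_to_tracks <- function(events, owned, features) {
  # combine events by ownership of the source frame
  keep <- list()
  for (w in seq_along(events)) {
    e <- events[[w]]
    if (!nrow(e)) next
    rng <- owned[[w]]
    e <- e[e$src_t >= rng[1] & e$src_t <= rng[2], , drop = FALSE]
    if (nrow(e)) { e$window <- w; keep[[length(keep) + 1L]] <- e }
  }
  ev <- if (length(keep)) do.call(rbind, keep) else
    data.frame(src_t = integer(), src_label = integer(), dst_t = integer(),
               dst_label = integer(), kind = character(), window = integer())

  links <- ev[!is.na(ev$dst_t), , drop = FALSE]
  # resolve cross-window inbound conflicts: earliest window wins
  conflicts <- 0L
  if (nrow(links)) {
    dkey <- paste(links$dst_t, links$dst_label)
    first_w <- tapply(links$window, dkey, min)
    ok <- links$window == first_w[dkey]
    conflicts <- sum(!ok)
    links <- links[ok, , drop = FALSE]
  }

  objs <- features$objects
  nT <- length(objs)
  okey <- function(t, l) paste(t, l)
  out_by <- split(seq_len(nrow(links)), okey(links$src_t, links$src_label))
  in_by <- split(seq_len(nrow(links)), okey(links$dst_t, links$dst_label))

  track_of <- new.env(parent = emptyenv())
  tracks <- list()
  new_track <- function(t, l, preds = integer()) {
    id <- length(tracks) + 1L
    o <- objs[[t + 1L]][[as.character(l)]]
    tracks[[id]] <<- list(id = id, frames = t, labels = l,
                          masks = list(o$pix), preds = preds,
                          succs = integer())
    for (p in preds)
      tracks[[p]]$succs <<- unique(c(tracks[[p]]$succs, id))
    assign(okey(t, l), id, envir = track_of)
    id
  }
  append_to <- function(id, t, l) {
    o <- objs[[t + 1L]][[as.character(l)]]
    tracks[[id]]$frames <<- c(tracks[[id]]$frames, t)
    tracks[[id]]$labels <<- c(tracks[[id]]$labels, l)
    tracks[[id]]$masks[[length(tracks[[id]]$masks) + 1L]] <<- o$pix
    assign(okey(t, l), id, envir = track_of)
  }

  for (t in seq_len(nT) - 1L) {
    for (l in names(objs[[t + 1L]])) {
      k <- okey(t, l)
      inl <- in_by[[k]]
      if (is.null(inl)) { new_track(t, as.integer(l)); next }
      li <- links[inl, , drop = FALSE]
      src_tracks <- unique(vapply(seq_len(nrow(li)), function(r)
        get(okey(li$src_t[r], li$src_label[r]), envir = track_of), 1L))
      simple <- nrow(li) == 1L && li$kind[1] %in% c("move", "skip")
      if (simple) {
        sk <- okey(li$src_t[1], li$src_label[1])
        src_out <- out_by[[sk]]
        if (length(src_out) == 1L) {
          append_to(src_tracks[1], t, as.integer(l))
          next
        }
      }
      new_track(t, as.integer(l), preds = src_tracks)
    }
  }

  structure(list(tracks = tracks, dim = features$dim,
                 n_frames = nT, stitch_conflicts = conflicts),
            class = "tracking_graph")
}

#' @export
print.tracking_graph <- function(x, ...) {
  cat(sprintf("<tracking_graph> %d track(s) over %d frame(s)\n",
              length(x$tracks), x$n_frames))
  invisible(x)
}

#' Run the matching stage over a whole sequence
#'
#' Splits the sequence into overlapping windows, solves the coupled
#' minimum-cost flow problem per window, and stitches the solutions into a
#' preliminary tracking graph (tracks may still have multiple predecessors
#' or more than two successors; see [untangle_tracks]).
#'
#' @param features `sequence_features`.
#' @param raw optional raw frames.
#' @param cfg [matching_config].
#' @return a `tracking_graph`.
#' @export
match_sequence <- function(features, raw = NULL, cfg = matching_config()) {
  nT <- length(features$objects)
  roi <- default_roi_size(features, cfg$roi_scale)
  cand <- find_candidates(features, raw, cfg$delta_t, roi)
  L <- cfg$window_length; ov <- cfg$window_overlap
  if (nT <= L) {
    starts <- 0L
  } else {
    starts <- seq(0L, nT - L, by = L - ov)
    if (tail(starts, 1) + L < nT)
      starts <- c(starts, nT - L)
  }
  wins <- lapply(starts, function(s) c(s, min(s + L - 1L, nT - 1L)))
  # ownership: earlier window authoritative up to the overlap midpoint
  owned <- vector("list", length(wins))
  for (w in seq_along(wins)) {
    from <- if (w == 1L) 0L else owned[[w - 1L]][2] + 1L
    to <- if (w == length(wins)) nT - 1L else {
      s_next <- wins[[w + 1L]][1]
      e_this <- wins[[w]][2]
      floor((s_next + e_this) / 2)
    }
    owned[[w]] <- c(from, to)
  }
  events <- vector("list", length(wins))
  sols <- vector("list", length(wins))
  for (w in seq_along(wins)) {
    win <- wins[[w]]
    n_in_win <- sum(vapply(win[1]:win[2], function(t)
      length(features$objects[[t + 1L]]), 1L))
    if (n_in_win == 0L) {
      events[[w]] <- data.frame(src_t = integer(), src_label = integer(),
                                dst_t = integer(), dst_label = integer(),
                                kind = character())
      next
    }
    g <- build_flow_graph(features, cand, cfg, win, roi)
    g <- compute_costs(g, features, cand$disp)
    sol <- solve_matching(g)
    sols[[w]] <- sol
    events[[w]] <- window_events(sol)
  }
  gr <- flows_to_tracks(events, owned, features)
  gr$windows <- wins
  gr$solutions <- sols
  gr
}
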