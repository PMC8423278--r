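#' Enumerate all candidate sets of mergeable tracks
#'
#' Tracks may be merged when they (a) share identical predecessor and
#' successor sets, (b) share identical successors while predecessor-less
#' members begin after the predecessor-bearing member starts, or (c) share
#' identical predecessors while successor-less members end before the
#' successor-bearing member ends. Conditions are evaluated on maximal
#' groups and every subset of size >= 2 is emitted as a candidate set.
#'
#' @param graph a `tracking_graph`.
#' @param max_group cap on a maximal group's size before only pairs and
#'   the full set are enumerated (guards combinatorial blow-up).
#' @return list of integer vectors (track ids), duplicates removed.
#' @export
enumerate_mergeable_sets <- function(graph, max_group = 8L) {
  tr <- graph$tracks
  ids <- vapply(tr, function(x) x$id, 1L)
  preds <- lapply(tr, function(x) sort(x$preds))
  succs <- lapply(tr, function(x) sort(x$succs))
  begin <- vapply(tr, function(x) min(x$frames), 1L)
  end <- vapply(tr, function(x) max(x$frames), 1L)
  names(preds) <- names(succs) <- names(begin) <- names(end) <- ids

  groups <- list()
  pkey <- vapply(preds, paste, "", collapse = ",")
  skey <- vapply(succs, paste, "", collapse = ",")

  # (a) identical predecessors and successors
  akey <- paste(pkey, "|", skey)
  for (g in split(ids, akey)) if (length(g) >= 2L)
    groups[[length(groups) + 1L]] <- sort(g)

  # (b) identical successors; predecessor-less members begin after the
  #     predecessor-bearing member starts
  for (n in ids[lengths(preds) > 0]) {
    cand <- ids[skey == skey[as.character(n)] & lengths(preds) == 0 &
                  begin > begin[as.character(n)] & ids != n]
    if (length(cand)) groups[[length(groups) + 1L]] <- sort(c(n, cand))
  }
  # (c) identical predecessors; successor-less members end before the
  #     successor-bearing member ends
  for (n in ids[lengths(succs) > 0]) {
    cand <- ids[pkey == pkey[as.character(n)] & lengths(succs) == 0 &
                  end < end[as.character(n)] & ids != n]
    if (length(cand)) groups[[length(groups) + 1L]] <- sort(c(n, cand))
  }

  sets <- list()
  seen <- new.env(parent = emptyenv())
  emit <- function(s) {
    k <- paste(s, collapse = ",")
    if (!exists(k, envir = seen, inherits = FALSE)) {
      assign(k, TRUE, envir = seen)
      sets[[length(sets) + 1L]] <<- s
    }
  }
  for (g in groups) {
    if (length(g) > max_group) {
      for (i in seq_along(g)) for (j in seq_along(g)) if (i < j)
        emit(sort(c(g[i], g[j])))
      emit(sort(g))
    } else {
      for (k in 2:length(g))
        apply(utils::combn(g, k), 2, function(s) emit(sort(s)))
    }
  }
  sets
}

#' Edge-removal cost constant for the untangling problem
#'
#' `gamma = 2 * ceiling(q30(track length) * q99(links per track))`, where
#' the first factor is the 0.3 quantile of temporal track lengths and the
#' second the 0.99 quantile of the number of predecessor/successor links
#' per track.
#'
#' @param graph a `tracking_graph`.
#' @return numeric scalar.
#' @export
untangling_gamma <- function(graph) {
  tr <- graph$tracks
  len <- vapply(tr, function(x) max(x$frames) - min(x$frames) + 1L, 1L)
  links <- vapply(tr, function(x) length(x$preds) + length(x$succs), 1L)
  q_len <- as.numeric(quantile(len, 0.3))
  q_links <- as.numeric(quantile(links, 0.99))
  2 * ceiling(q_len * q_links)
}

#' Build the untangling integer linear program
#'
#' Variables: binary edge removals `z^e_pn`, integer splits `z^s_n` (the
#' number of additional tracks a split creates), binary merges `z^m_r` per
#' candidate set. Each track contributes one predecessor inequality (at
#' most one predecessor after the operations) and one successor inequality
#' (at most two successors), plus the at-most-one-merge-per-track rule and
#' the coupling that merged tracks drop their shared links jointly or not
#' at all. Costs: `gamma` per removed edge, span of the merged track times
#' (set size - 1) per merge, track span per additional split part.
#'
#' @param graph a `tracking_graph`.
#' @param gamma edge-removal cost (default [untangling_gamma]).
#' @return an `untangling_problem` with the constraint system and
#'   variable catalogue.
#' @export
build_untangling_ilp <- function(graph, gamma = untangling_gamma(graph)) {
  tr <- graph$tracks
  ids <- vapply(tr, function(x) x$id, 1L)
  by_id <- setNames(seq_along(tr), ids)
  preds <- setNames(lapply(tr, function(x) sort(x$preds)), ids)
  succs <- setNames(lapply(tr, function(x) sort(x$succs)), ids)
  begin <- setNames(vapply(tr, function(x) min(x$frames), 1L), ids)
  end <- setNames(vapply(tr, function(x) max(x$frames), 1L), ids)
  span <- end - begin + 1L

  msets <- enumerate_mergeable_sets(graph)
  set_key <- vapply(msets, paste, "", collapse = ",")

  # variable catalogue
  evars <- list()   # edges p -> n
  for (n in ids) for (p in preds[[as.character(n)]])
    evars[[length(evars) + 1L]] <- c(p = p, n = n)
  n_e <- length(evars)
  n_s <- length(ids)
  n_m <- length(msets)
  nv <- n_e + n_s + n_m
  e_idx <- function(p, n) {
    for (k in seq_len(n_e))
      if (evars[[k]]["p"] == p && evars[[k]]["n"] == n) return(k)
    NA_integer_
  }
  s_idx <- function(n) n_e + unname(by_id[as.character(n)])
  m_idx <- function(r) n_e + n_s + match(paste(r, collapse = ","), set_key)

  M_n <- lapply(ids, function(n)
    msets[vapply(msets, function(r) n %in% r, TRUE)])
  names(M_n) <- ids
  W_n <- lapply(ids, function(n)
    sort(unique(c(n, unlist(M_n[[as.character(n)]])))))
  names(W_n) <- ids

  rows <- list(); rhs <- numeric(); dirs <- character(); labels <- character()
  add_row <- function(coefs, dir, b, label = "") {
    rows[[length(rows) + 1L]] <<- coefs
    dirs[length(dirs) + 1L] <<- dir
    rhs[length(rhs) + 1L] <<- b
    labels[length(labels) + 1L] <<- label
  }

  pred_rhs <- setNames(numeric(length(ids)), ids)
  succ_rhs <- setNames(numeric(length(ids)), ids)
  pred_coef_list <- list()

  for (n in ids) {
    cn <- as.character(n)
    Pn <- preds[[cn]]; Sn <- succs[[cn]]
    coef <- numeric(nv)
    # merge tracks: sum over r in M_n of (P_{n,r} - 1)
    for (r in M_n[[cn]]) {
      Pnr <- sum(vapply(r, function(m)
        identical(preds[[as.character(m)]], Pn), TRUE))
      coef[m_idx(r)] <- coef[m_idx(r)] + (Pnr - 1)
    }
    # split tracks and remove edges, over W_n
    for (w in W_n[[cn]]) {
      coef[s_idx(w)] <- coef[s_idx(w)] - 1
      for (p in preds[[as.character(w)]])
        coef[e_idx(p, w)] <- coef[e_idx(p, w)] - 1
    }
    # split predecessors
    for (p in Pn) coef[s_idx(p)] <- coef[s_idx(p)] + 1
    # merge predecessors: q in M(P_n)
    for (k in seq_along(msets)) {
      q <- msets[[k]]
      if (!length(intersect(q, Pn))) next
      Sqn <- sum(vapply(q, function(m) n %in% succs[[as.character(m)]], TRUE))
      coef[n_e + n_s + k] <- coef[n_e + n_s + k] + min(0, -Sqn + 1)
    }
    succ_union <- unique(unlist(lapply(Pn, function(p)
      succs[[as.character(p)]])))
    b <- -length(Pn) + max(1, length(succ_union))
    pred_rhs[cn] <- b
    pred_coef_list[[cn]] <- coef
    add_row(coef, "<=", b, paste0("pred_", n))

    # successor inequality
    coef <- numeric(nv)
    for (r in M_n[[cn]]) {
      Snr <- sum(vapply(r, function(m)
        identical(succs[[as.character(m)]], Sn), TRUE))
      coef[m_idx(r)] <- coef[m_idx(r)] + (Snr - 1)
    }
    for (w in W_n[[cn]]) {
      coef[s_idx(w)] <- coef[s_idx(w)] - 1
      for (v in succs[[as.character(w)]])
        coef[e_idx(w, v)] <- coef[e_idx(w, v)] - 1
    }
    for (v in Sn) coef[s_idx(v)] <- coef[s_idx(v)] + 1
    for (k in seq_along(msets)) {
      q <- msets[[k]]
      if (!length(intersect(q, Sn))) next
      Pqn <- sum(vapply(q, function(m) n %in% preds[[as.character(m)]], TRUE))
      coef[n_e + n_s + k] <- coef[n_e + n_s + k] + min(0, -Pqn + 1)
    }
    pred_union <- unique(unlist(lapply(Sn, function(v)
      preds[[as.character(v)]])))
    b <- -length(Sn) + 2 * length(pred_union) + 1
    succ_rhs[cn] <- b
    add_row(coef, "<=", b, paste0("succ_", n))

    # a track can join at most one merge set
    if (length(M_n[[cn]])) {
      coef <- numeric(nv)
      for (r in M_n[[cn]]) coef[m_idx(r)] <- 1
      add_row(coef, "<=", 1, paste0("onemerge_", n))
    }
  }

  # merged tracks drop shared links jointly or not at all
  for (k in seq_along(msets)) {
    r <- msets[[k]]
    for (i in seq_along(r)) for (j in seq_along(r)) {
      if (i >= j) next
      n <- r[i]; v <- r[j]
      for (p in intersect(preds[[as.character(n)]],
                          preds[[as.character(v)]])) {
        coef <- numeric(nv)
        coef[e_idx(p, v)] <- 1; coef[e_idx(p, n)] <- -1
        coef[n_e + n_s + k] <- 1
        add_row(coef, "<=", 1, "couple")
        coef[e_idx(p, v)] <- -1; coef[e_idx(p, n)] <- 1
        add_row(coef, "<=", 1, "couple")
      }
      for (s in intersect(succs[[as.character(n)]],
                          succs[[as.character(v)]])) {
        coef <- numeric(nv)
        coef[e_idx(n, s)] <- 1; coef[e_idx(v, s)] <- -1
        coef[n_e + n_s + k] <- 1
        add_row(coef, "<=", 1, "couple")
        coef[e_idx(n, s)] <- -1; coef[e_idx(v, s)] <- 1
        add_row(coef, "<=", 1, "couple")
      }
    }
  }

  # costs
  cost <- numeric(nv)
  if (n_e) cost[seq_len(n_e)] <- gamma
  for (n in ids) cost[s_idx(n)] <- span[as.character(n)]
  for (k in seq_along(msets)) {
    r <- msets[[k]]
    sp <- max(end[as.character(r)]) - min(begin[as.character(r)]) + 1L
    cost[n_e + n_s + k] <- sp * (length(r) - 1)
  }

  ub <- c(rep(1, n_e),
          vapply(ids, function(n)
            max(length(preds[[as.character(n)]]),
                length(succs[[as.character(n)]]), 1) + 1, 1),
          rep(1, n_m))

  A <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, nv)
  structure(list(A = A, dir = dirs, rhs = rhs, labels = labels,
                 cost = cost, ub = ub, gamma = gamma,
                 n_e = n_e, n_s = n_s, n_m = n_m,
                 evars = evars, ids = ids, msets = msets,
                 pred_rhs = pred_rhs, succ_rhs = succ_rhs,
                 pred_coef = pred_coef_list),
            class = "untangling_problem")
}

#' Solve the untangling problem
#'
#' Minimises the operation cost; ties are broken towards fewer operations
#' (a small uniform surcharge per selected operation that can never exceed
#' the integer cost gap).
#'
#' @param problem an `untangling_problem`.
#' @return list with `edges_removed` (data.frame p, n), `splits`
#'   (data.frame id, parts), `merges` (list of id vectors), `objective`.
#' @export
solve_untangling <- function(problem) {
  nv <- length(problem$cost)
  if (nv == 0L)
    return(list(edges_removed = data.frame(p = integer(), n = integer()),
                splits = data.frame(id = integer(), parts = integer()),
                merges = list(), objective = 0))
  eps <- 1 / (4 * max(1, sum(problem$ub[is.finite(problem$ub)])))
  sol <- milp_solve(problem$cost + eps, problem$A, problem$dir, problem$rhs,
                    lb = 0, ub = problem$ub, int_vars = TRUE)
  if (sol$status != "optimal")
    stop("untangling ILP infeasible: ", sol$status)
  z <- sol$solution
  n_e <- problem$n_e; n_s <- problem$n_s
  er <- data.frame(p = integer(), n = integer())
  if (n_e) {
    on <- which(z[seq_len(n_e)] > 0.5)
    if (length(on))
      er <- data.frame(p = vapply(problem$evars[on], `[[`, 1L, "p"),
                       n = vapply(problem$evars[on], `[[`, 1L, "n"))
  }
  sp <- which(z[n_e + seq_len(n_s)] > 0.5)
  splits <- data.frame(id = problem$ids[sp],
                       parts = as.integer(round(z[n_e + sp])) + 1L)
  mg <- which(z[n_e + n_s + seq_len(problem$n_m)] > 0.5)
  list(edges_removed = er, splits = splits,
       merges = problem$msets[mg],
       objective = sum(problem$cost * round(z)))
}

#' Apply untangling operations to a tracking graph
#'
#' Edge removals delete predecessor-successor links; merges concatenate
#' the members' masks per frame into one track; splits partition every
#' mask of a track among seed points taken from the highest
#' distance-transform maxima (greedy minimum-separation selection) and
#' distribute the predecessor/successor links among the parts by centroid
#' proximity.
#'
#' @param graph a `tracking_graph`.
#' @param ops result of [solve_untangling].
#' @return the modified `tracking_graph`; `$untangling_log` records the
#'   applied operations.
#' @export
apply_operations <- function(graph, ops) {
  tr <- graph$tracks
  idx_of <- function(id) which(vapply(tr, function(x) x$id, 1L) == id)
  log <- list()

  # 1. edge removals
  if (nrow(ops$edges_removed)) for (r in seq_len(nrow(ops$edges_removed))) {
    p <- ops$edges_removed$p[r]; n <- ops$edges_removed$n[r]
    ip <- idx_of(p); inn <- idx_of(n)
    tr[[ip]]$succs <- setdiff(tr[[ip]]$succs, n)
    tr[[inn]]$preds <- setdiff(tr[[inn]]$preds, p)
    log[[length(log) + 1L]] <- list(op = "remove_edge", p = p, n = n)
  }

  # 2. merges
  for (r in ops$merges) {
    keep <- min(r)
    ik <- idx_of(keep)
    for (m in setdiff(r, keep)) {
      im <- idx_of(m)
      for (j in seq_along(tr[[im]]$frames)) {
        t <- tr[[im]]$frames[j]
        pos <- match(t, tr[[ik]]$frames)
        if (is.na(pos)) {
          tr[[ik]]$frames <- c(tr[[ik]]$frames, t)
          tr[[ik]]$labels <- c(tr[[ik]]$labels, tr[[im]]$labels[j])
          tr[[ik]]$masks[[length(tr[[ik]]$masks) + 1L]] <- tr[[im]]$masks[[j]]
        } else {
          tr[[ik]]$masks[[pos]] <-
            sort(unique(c(tr[[ik]]$masks[[pos]], tr[[im]]$masks[[j]])))
        }
      }
      tr[[ik]]$preds <- sort(unique(c(tr[[ik]]$preds, tr[[im]]$preds)))
      tr[[ik]]$succs <- sort(unique(c(tr[[ik]]$succs, tr[[im]]$succs)))
      # relink neighbours
      for (q in seq_along(tr)) {
        if (q == im) next
        tr[[q]]$preds <- sort(unique(replace(tr[[q]]$preds,
                                             tr[[q]]$preds == m, keep)))
        tr[[q]]$succs <- sort(unique(replace(tr[[q]]$succs,
                                             tr[[q]]$succs == m, keep)))
      }
      tr[[im]] <- NULL
      ik <- idx_of(keep)
    }
    ik <- idx_of(keep)
    o <- order(tr[[ik]]$frames)
    tr[[ik]]$frames <- tr[[ik]]$frames[o]
    tr[[ik]]$labels <- tr[[ik]]$labels[o]
    tr[[ik]]$masks <- tr[[ik]]$masks[o]
    tr[[ik]]$preds <- setdiff(tr[[ik]]$preds, r)
    tr[[ik]]$succs <- setdiff(tr[[ik]]$succs, r)
    log[[length(log) + 1L]] <- list(op = "merge", tracks = r, into = keep)
  }

  # 3. splits
  next_id <- max(vapply(tr, function(x) x$id, 1L)) + 1L
  if (nrow(ops$splits)) for (r in seq_len(nrow(ops$splits))) {
    id <- ops$splits$id[r]
    # the track may have been merged away; skip if gone
    ii <- idx_of(id)
    if (!length(ii)) next
    parts <- ops$splits$parts[r]
    x <- tr[[ii]]
    k <- as.integer(min(parts, min(lengths(x$masks))))
    if (k < parts)
      log[[length(log) + 1L]] <- list(op = "split_degraded", id = id,
                                      wanted = parts, got = k)
    if (k < 2L) next
    part_tracks <- lapply(seq_len(k), function(s)
      list(id = next_id + s - 1L, frames = x$frames,
           labels = x$labels, masks = vector("list", length(x$frames)),
           preds = integer(), succs = integer()))
    prev_centroids <- NULL
    for (j in seq_along(x$frames)) {
      pix <- x$masks[[j]]
      seeds <- select_seed_points(pix, graph$dim, k)
      pieces <- partition_by_seeds(pix, graph$dim, seeds)
      cent <- t(vapply(pieces, function(p)
        colMeans(pix_coords(p, graph$dim)), numeric(length(graph$dim))))
      if (!is.null(prev_centroids)) {
        # match pieces to the previous frame's parts greedily
        d <- as.matrix(stats::dist(rbind(prev_centroids, cent)))
        d <- d[seq_len(k), k + seq_len(k), drop = FALSE]
        perm <- integer(k); used <- logical(k)
        for (s in order(apply(d, 2, min))) {
          cands <- order(d[, s])
          cands <- cands[!used[cands]]
          perm[s] <- cands[1]; used[cands[1]] <- TRUE
        }
        pieces <- pieces[order(perm)]
        cent <- cent[order(perm), , drop = FALSE]
      }
      prev_centroids <- cent
      for (s in seq_len(k)) part_tracks[[s]]$masks[[j]] <- pieces[[s]]
    }
    # distribute links among parts by proximity
    first_cent <- t(vapply(part_tracks, function(p)
      colMeans(pix_coords(p$masks[[1]], graph$dim)),
      numeric(length(graph$dim))))
    last_cent <- t(vapply(part_tracks, function(p)
      colMeans(pix_coords(p$masks[[length(p$masks)]], graph$dim)),
      numeric(length(graph$dim))))
    npred <- integer(k); nsucc <- integer(k)
    pred_assign <- list(); succ_assign <- list()
    for (p in x$preds) {
      ip <- idx_of(p)
      pc <- colMeans(pix_coords(tr[[ip]]$masks[[length(tr[[ip]]$masks)]],
                                graph$dim))
      d <- sqrt(rowSums(sweep(first_cent, 2, pc)^2))
      ordp <- order(d)
      tgt <- ordp[which(npred[ordp] == 0L)][1]
      if (is.na(tgt)) tgt <- ordp[1]
      npred[tgt] <- npred[tgt] + 1L
      pred_assign[[length(pred_assign) + 1L]] <- c(p, tgt)
    }
    for (v in x$succs) {
      iv <- idx_of(v)
      vc <- colMeans(pix_coords(tr[[iv]]$masks[[1]], graph$dim))
      d <- sqrt(rowSums(sweep(last_cent, 2, vc)^2))
      ordv <- order(d)
      tgt <- ordv[which(nsucc[ordv] < 2L)][1]
      if (is.na(tgt)) tgt <- ordv[1]
      nsucc[tgt] <- nsucc[tgt] + 1L
      succ_assign[[length(succ_assign) + 1L]] <- c(v, tgt)
    }
    for (pa in pred_assign) {
      p <- pa[1]; s <- pa[2]
      part_tracks[[s]]$preds <- c(part_tracks[[s]]$preds, p)
      ip <- idx_of(p)
      tr[[ip]]$succs <- sort(unique(c(setdiff(tr[[ip]]$succs, id),
                                      part_tracks[[s]]$id)))
    }
    for (sa in succ_assign) {
      v <- sa[1]; s <- sa[2]
      part_tracks[[s]]$succs <- c(part_tracks[[s]]$succs, v)
      iv <- idx_of(v)
      tr[[iv]]$preds <- sort(unique(c(setdiff(tr[[iv]]$preds, id),
                                      part_tracks[[s]]$id)))
    }
    # predecessors whose succ list still references id but got no part:
    for (q in seq_along(tr)) {
      tr[[q]]$preds <- setdiff(tr[[q]]$preds, id)
      tr[[q]]$succs <- setdiff(tr[[q]]$succs, id)
    }
    tr[[ii]] <- NULL
    for (p in part_tracks) tr[[length(tr) + 1L]] <- p
    next_id <- next_id + k
    log[[length(log) + 1L]] <- list(op = "split", id = id, parts = k)
  }

  graph$tracks <- tr
  graph$untangling_log <- c(graph$untangling_log, log)
  graph
}

#' Untangle a tracking graph
#'
#' Runs mergeable-set enumeration, ILP construction, solving and
#' operation application, then enforces the final validity guarantee
#' (every track at most one predecessor and at most two successors; any
#' residual violation is resolved by dropping the farthest links, which is
#' recorded in the log).
#'
#' @param graph a `tracking_graph`.
#' @return valid `tracking_graph`.
#' @export
untangle_tracks <- function(graph) {
  if (!length(graph$tracks)) return(graph)
  problem <- build_untangling_ilp(graph)
  ops <- solve_untangling(problem)
  graph <- apply_operations(graph, ops)
  enforce_validity(graph)
}

# safety net: residual multi-predecessor / >2-successor links are dropped
# by proximity (logged); guarantees the structural post-condition
enforce_validity <- function(graph) {
  tr <- graph$tracks
  idx_of <- function(id) which(vapply(tr, function(x) x$id, 1L) == id)
  log <- list()
  centroid_at <- function(i, first) {
    m <- if (first) tr[[i]]$masks[[1]] else
      tr[[i]]$masks[[length(tr[[i]]$masks)]]
    colMeans(pix_coords(m, graph$dim))
  }
  for (i in seq_along(tr)) {
    if (length(tr[[i]]$preds) > 1L) {
      pc <- centroid_at(i, TRUE)
      d <- vapply(tr[[i]]$preds, function(p)
        sqrt(sum((centroid_at(idx_of(p), FALSE) - pc)^2)), 1)
      keep <- tr[[i]]$preds[which.min(d)]
      for (p in setdiff(tr[[i]]$preds, keep)) {
        ip <- idx_of(p)
        tr[[ip]]$succs <- setdiff(tr[[ip]]$succs, tr[[i]]$id)
        log[[length(log) + 1L]] <- list(op = "forced_edge_drop",
                                        p = p, n = tr[[i]]$id)
      }
      tr[[i]]$preds <- keep
    }
  }
  for (i in seq_along(tr)) {
    if (length(tr[[i]]$succs) > 2L) {
      lc <- centroid_at(i, FALSE)
      d <- vapply(tr[[i]]$succs, function(v)
        sqrt(sum((centroid_at(idx_of(v), TRUE) - lc)^2)), 1)
      keep <- tr[[i]]$succs[order(d)[1:2]]
      for (v in setdiff(tr[[i]]$succs, keep)) {
        iv <- idx_of(v)
        tr[[iv]]$preds <- setdiff(tr[[iv]]$preds, tr[[i]]$id)
        log[[length(log) + 1L]] <- list(op = "forced_edge_drop",
                                        p = tr[[i]]$id, n = v)
      }
      tr[[i]]$succs <- keep
    }
  }
  graph$tracks <- tr
  graph$untangling_log <- c(graph$untangling_log, log)
  graph
}
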