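box_seq <- function(boxes, shape = c(40L, 40L)) {
  frames <- lapply(boxes, function(df) {
    img <- matrix(0L, shape[1], shape[2])
    if (!is.null(df) && nrow(df)) for (r in seq_len(nrow(df)))
      img[df$y[r]:(df$y[r] + df$h[r] - 1) + 1,
          df$x[r]:(df$x[r] + df$w[r] - 1) + 1] <- df$label[r]
    img
  })
  labeled_sequence(frames)
}

build_costed <- function(s, cfg = matching_config(delta_t = 2L,
                                                  window_length = 3L,
                                                  window_overlap = 2L),
                         window = c(0L, length(s$frames) - 1L), raw = NULL) {
  ft <- sequence_features(s)
  roi <- default_roi_size(ft, cfg$roi_scale)
  cand <- find_candidates(ft, raw, cfg$delta_t, roi)
  g <- build_flow_graph(ft, cand, cfg, window, roi)
  list(graph = compute_costs(g, ft, cand$disp), ft = ft, cand = cand)
}

test_that("every object node gets one skip node per bridgeable frame", {
  s <- box_seq(list(
    data.frame(label = 1:2, y = c(4, 25), x = c(4, 25), h = 5, w = 5),
    data.frame(label = 1:2, y = c(5, 24), x = c(4, 25), h = 5, w = 5),
    data.frame(label = 1:2, y = c(6, 23), x = c(4, 25), h = 5, w = 5)))
  cfg <- matching_config(delta_t = 2L, window_length = 3L, window_overlap = 2L)
  ft <- sequence_features(s)
  g <- build_flow_graph(ft, find_candidates(ft, NULL, 2L), cfg, c(0L, 2L))
  nd <- g$nodes
  # delta_t = 2: one skip node at t+1 per object (while inside the window)
  for (t in 0:1) for (lb in 1:2)
    expect_equal(sum(nd$type == "x" & nd$label == lb & nd$ot == t &
                       nd$t == t + 1), 1)
  expect_equal(sum(nd$type == "x"), 2 * 2)
})

test_that("an empty window yields only structural nodes and zero flow", {
  s <- labeled_sequence(list(matrix(0L, 10, 10), matrix(0L, 10, 10)))
  ft <- sequence_features(s)
  cfg <- matching_config(delta_t = 2L, window_length = 3L, window_overlap = 2L)
  cand <- list(candidates = data.frame(t = integer(), label = integer(),
                                       step = integer(), cand_t = integer(),
                                       cand_label = integer()),
               disp = list(list(), list()))
  g <- build_flow_graph(ft, cand, cfg, c(0L, 1L),
                        roi = list(size = c(4, 4), alpha = 4))
  expect_setequal(unique(g$nodes$type), c("source", "sink", "a", "d"))
  sol <- solve_matching(compute_costs(g, ft, cand$disp))
  expect_equal(sol$objective, 0)
  expect_true(all(sol$flows$flow == 0))
})

test_that("edge set matches hand enumeration for one object and one candidate", {
  s <- box_seq(list(data.frame(label = 3, y = 10, x = 10, h = 5, w = 5),
                    data.frame(label = 8, y = 11, x = 10, h = 5, w = 5)))
  cfg <- matching_config(delta_t = 1L, window_length = 2L,
                         window_overlap = 1L)
  ft <- sequence_features(s)
  g <- build_flow_graph(ft, find_candidates(ft, NULL, 1L), cfg, c(0L, 1L))
  g <- compute_costs(g, ft, find_candidates(ft, NULL, 1L)$disp)
  nd <- g$nodes
  lbl <- function(id) {
    tp <- nd$type[id]
    paste0(tp, ifelse(is.na(nd$label[id]), "", nd$label[id]),
           ifelse(is.na(nd$t[id]), "", paste0("@", nd$t[id])))
  }
  got <- sort(paste(lbl(g$edges$from), lbl(g$edges$to), sep = "->"))
  expect_equal(got, sort(c(
    "source->o3@0", "source->a@0",
    "o3@0->o8@1", "o3@0->d@1",
    "a@0->o8@1", "a@0->d@1",
    "d@1->sink", "o8@1->sink")))
})

test_that("position-based costs match their closed forms", {
  # coincident centroids, no displacement -> zero movement cost
  s <- box_seq(list(data.frame(label = 1, y = 10, x = 10, h = 5, w = 5),
                    data.frame(label = 2, y = 10, x = 10, h = 5, w = 5)))
  b <- build_costed(s)
  e <- b$graph$edges
  nd <- b$graph$nodes
  mv <- e[nd$type[e$from] == "o" & nd$type[e$to] == "o", ]
  expect_equal(mv$cost, 0)

  # object centroid on the image border -> appear and disappear cost 0
  s2 <- box_seq(list(data.frame(label = 1, y = 0, x = 18, h = 1, w = 5),
                     data.frame(label = 2, y = 0, x = 18, h = 1, w = 5)))
  b2 <- build_costed(s2)
  e2 <- b2$graph$edges; nd2 <- b2$graph$nodes
  ap <- e2[nd2$type[e2$from] == "a" & nd2$type[e2$to] == "o", ]
  dis <- e2[nd2$type[e2$from] == "o" & nd2$type[e2$to] == "d", ]
  expect_true(all(ap$cost == 0))
  expect_true(all(dis$cost == 0))
})

test_that("symmetric daughters yield a zero mitosis pair cost", {
  # mother centred at (12, 12); daughters at (12, 10) and (12, 14)
  s <- box_seq(list(data.frame(label = 1, y = 10, x = 10, h = 5, w = 5),
                    data.frame(label = c(2, 3), y = 10, x = c(9, 13),
                               h = 5, w = 3)))
  b <- build_costed(s)
  prs <- b$graph$pairs
  expect_false(is.null(prs))
  pr <- prs[prs$j == 2 & prs$l == 3, ]
  expect_equal(nrow(pr), 1)
  # c3 = 4 <= 1.5 * bbox diagonal, c1 = c2 = 0
  expect_equal(pr$cost, 0)
})

test_that("mask-point costs beat centroid costs on merged masks", {
  # a correctly segmented object at t and an under-segmented (merged)
  # mask at t+1: the distance from the merged mask's interior points to
  # the object is far below the centroid-to-centroid distance
  s <- box_seq(list(data.frame(label = c(1, 2), y = 10, x = c(4, 10),
                               h = 5, w = c(5, 5)),
                    data.frame(label = 7, y = 10, x = 4, h = 5, w = 11)))
  b <- build_costed(s)
  e <- b$graph$edges; nd <- b$graph$nodes
  o1 <- nd$id[nd$type == "o" & nd$label == 1 & nd$t == 0]
  eq13 <- e$cost[e$from == o1 & nd$type[e$to] == "o" & nd$label[e$to] == 7]
  eq17 <- e$cost[e$from == o1 & nd$type[e$to] == "m"]
  expect_length(eq17, 1)
  expect_lt(eq17, eq13)
})

test_that("solved flows satisfy conservation, unit flow and quantisation", {
  cfg <- simulation_config(shape = c(72L, 72L), n_frames = 4L, n_cells = 4L,
                           seed = 21)
  sim <- generate_sequence(cfg)
  deg <- simulate_underseg(sim$gt, error_spec("under", 10, seed = 3))
  b <- build_costed(labeled_sequence(deg$frames, NULL),
                    cfg = matching_config(delta_t = 2L, window_length = 4L,
                                          window_overlap = 2L))
  sol <- solve_matching(b$graph)
  nd <- sol$nodes
  fl <- sol$flows
  pf <- sol$pair_flows
  flow_at <- function(id, dirn) {
    base <- sum(fl$flow[fl[[dirn]] == id])
    if (!is.null(pf)) {
      if (dirn == "to" && nd$type[id] == "o")
        base <- base + sum(pf$flow[(pf$j == nd$label[id] | pf$l == nd$label[id]) &
                                     pf$tau == nd$t[id]])
      if (dirn == "from" && nd$type[id] == "s")
        base <- base + 2 * sum(pf$flow[pf$sid == id])
    }
    base
  }
  for (id in nd$id) {
    tp <- nd$type[id]
    if (tp %in% c("source", "sink")) next
    infl <- flow_at(id, "to"); outfl <- flow_at(id, "from")
    if (infl + outfl == 0) next
    expect_equal(infl, outfl, info = paste("node", id, tp))
    if (tp == "o") expect_equal(infl, 1)
    if (tp %in% c("s", "m"))
      expect_true(infl == 0 || infl >= 2,
                  info = paste("quantisation at", tp, id))
  }
})

test_that("optimal objectives equal brute-force enumeration on tiny graphs", {
  for (sd in 1:12) {
    s <- tiny_sequence(sd)
    b <- build_costed(s)
    ilp <- matching_ilp(b$graph)
    if (is.null(ilp)) next
    sol <- solve_matching(b$graph)
    ub <- ilp$ub; ub[!is.finite(ub)] <- 9
    bf <- enumerate_milp(ilp$obj, ilp$A, ilp$dir, ilp$rhs, lb = ilp$lb,
                         ub = ub)
    expect_equal(sol$objective, bf$objective, tolerance = 1e-7,
                 info = paste("seed", sd))
  }
})

test_that("a missing middle detection is bridged by a skip node", {
  s <- box_seq(list(data.frame(label = 1, y = 10, x = 10, h = 5, w = 5),
                    data.frame(label = 1, y = 11, x = 10, h = 5, w = 5),
                    NULL,
                    data.frame(label = 1, y = 13, x = 10, h = 5, w = 5)),
               shape = c(40L, 40L))
  cfg <- matching_config(delta_t = 2L, window_length = 4L,
                         window_overlap = 2L)
  ft <- sequence_features(s)
  graph <- match_sequence(ft, NULL, cfg)
  expect_length(graph$tracks, 1)
  expect_equal(graph$tracks[[1]]$frames, c(0L, 1L, 3L))
})

test_that("a division routes flow through one coupled daughter pair", {
  s <- box_seq(list(data.frame(label = 1, y = 14, x = 14, h = 7, w = 7),
                    data.frame(label = c(2, 3), y = 14, x = c(11, 19),
                               h = 5, w = 5)),
               shape = c(40L, 40L))
  b <- build_costed(s)
  sol <- solve_matching(b$graph)
  pf <- sol$pair_flows
  expect_false(is.null(pf))
  act <- pf[pf$flow > 0.5, ]
  expect_equal(nrow(act), 1)
  expect_setequal(c(act$j, act$l), c(2, 3))
  # appear-side and mother-side inflow of the split node both carry the
  # pair's unit
  nd <- sol$nodes
  sid <- act$sid
  a_in <- sol$flows$flow[sol$flows$to == sid &
                           nd$type[sol$flows$from] == "a"]
  o_in <- sol$flows$flow[sol$flows$to == sid &
                           nd$type[sol$flows$from] == "o"]
  expect_equal(sum(a_in), 1)
  expect_equal(sum(o_in), 1)
})

test_that("window stitching produces one track across window borders", {
  cfg <- simulation_config(shape = c(64L, 64L), n_frames = 17L, n_cells = 1L,
                           seed = 2)
  sim <- generate_sequence(cfg)
  graph <- match_sequence(sequence_features(sim$gt), sim$raw,
                          matching_config(window_length = 10L))
  expect_length(graph$windows, 2)
  expect_length(graph$tracks, 1)
  expect_equal(graph$tracks[[1]]$frames, 0:16)
})

test_that("perfect segmentation without divisions reproduces ground truth links", {
  cfg <- simulation_config(shape = c(128L, 128L), n_frames = 8L, n_cells = 6L,
                           seed = 31)
  sim <- generate_sequence(cfg)
  graph <- match_sequence(sequence_features(sim$gt), sim$raw,
                          matching_config())
  expect_length(graph$tracks, 6)
  for (x in graph$tracks) {
    expect_equal(x$frames, 0:7)
    expect_length(x$preds, 0)
    expect_length(x$succs, 0)
    # the track follows one ground-truth label throughout
    expect_length(unique(x$labels), 1)
  }
})
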