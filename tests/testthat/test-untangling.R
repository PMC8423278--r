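test_that("mergeable sets reproduce the worked predecessor example", {
  gr <- untangle_example_graph()
  sets <- enumerate_mergeable_sets(gr)
  keys <- vapply(sets, paste, "", collapse = ",")
  # all mergeable sets containing predecessors of track 5
  mp5 <- keys[vapply(sets, function(s) length(intersect(s, c(2, 3, 4))) > 0,
                     TRUE)]
  expect_setequal(mp5, c("2,3", "2,4", "3,4", "2,3,4"))
  # successors of track 5 form one mergeable pair
  ms5 <- keys[vapply(sets, function(s) length(intersect(s, c(6, 7))) > 0,
                     TRUE)]
  expect_setequal(ms5, "6,7")
})

test_that("a chain graph has no mergeable sets", {
  gr <- untangle_example_graph()
  # keep only 1 -> 2 -> 5 -> 6 with unique links
  keep <- c(1L, 2L, 5L, 6L)
  gr$tracks <- gr$tracks[keep]
  gr$tracks[[1]]$succs <- 2L
  gr$tracks[[2]]$preds <- 1L; gr$tracks[[2]]$succs <- 5L
  gr$tracks[[3]]$preds <- 2L; gr$tracks[[3]]$succs <- 6L
  gr$tracks[[4]]$preds <- 5L; gr$tracks[[4]]$succs <- integer()
  expect_length(enumerate_mergeable_sets(gr), 0)
})

test_that("condition-b sets admit late predecessor-less tracks", {
  dims <- c(30L, 30L)
  mk <- function(frames, ctr) lapply(frames, function(f) {
    arr <- matrix(FALSE, dims[1], dims[2])
    arr[ctr[1] + 1, ctr[2] + 1] <- TRUE
    which(arr)
  })
  tracks <- list(
    list(id = 1L, frames = 0:2, labels = rep(1L, 3), masks = mk(0:2, c(5, 5)),
         preds = integer(), succs = 2L),
    list(id = 2L, frames = 3:9, labels = rep(2L, 7), masks = mk(3:9, c(8, 8)),
         preds = 1L, succs = 4L),
    list(id = 3L, frames = 5:9, labels = rep(3L, 5), masks = mk(5:9, c(10, 10)),
         preds = integer(), succs = 4L),
    list(id = 4L, frames = 10:12, labels = rep(4L, 3),
         masks = mk(10:12, c(9, 9)), preds = c(2L, 3L), succs = integer()))
  gr <- structure(list(tracks = tracks, dim = dims, n_frames = 13L),
                  class = "tracking_graph")
  sets <- enumerate_mergeable_sets(gr)
  keys <- vapply(sets, paste, "", collapse = ",")
  expect_true("2,3" %in% keys)
})

test_that("the worked example's inequality constraints are reproduced", {
  gr <- untangle_example_graph()
  prob <- build_untangling_ilp(gr)
  expect_equal(unname(prob$pred_rhs["5"]), -2)
  expect_equal(unname(prob$succ_rhs["5"]), 1)
  k234 <- match("2,3,4", vapply(prob$msets, paste, "", collapse = ","))
  coef <- prob$pred_coef[["5"]][prob$n_e + prob$n_s + k234]
  expect_equal(coef, -2)
  # the pairwise predecessor merge sets carry coefficient -1
  for (key in c("2,3", "2,4", "3,4")) {
    k <- match(key, vapply(prob$msets, paste, "", collapse = ","))
    expect_equal(prob$pred_coef[["5"]][prob$n_e + prob$n_s + k], -1)
  }
})

test_that("merging K tracks and splitting into K parts cost the same", {
  gr <- untangle_example_graph()
  prob <- build_untangling_ilp(gr)
  # cost of merging {2,3,4} (three tracks over a common span)
  k234 <- match("2,3,4", vapply(prob$msets, paste, "", collapse = ","))
  merge_cost <- prob$cost[prob$n_e + prob$n_s + k234]
  # splitting one track over the same span into 3 parts: z^s = 2
  span <- 2
  split_cost <- span * 2
  expect_equal(merge_cost, span * (3 - 1))
  expect_equal(merge_cost, split_cost)
})

test_that("a valid graph needs no untangling and is returned unchanged", {
  dims <- c(30L, 30L)
  mk <- function(frames, ctr) lapply(frames, function(f) {
    arr <- matrix(FALSE, dims[1], dims[2])
    arr[ctr[1] + 1, ctr[2] + 1] <- TRUE
    which(arr)
  })
  tracks <- list(
    list(id = 1L, frames = 0:3, labels = rep(1L, 4), masks = mk(0:3, c(5, 5)),
         preds = integer(), succs = c(2L, 3L)),
    list(id = 2L, frames = 4:6, labels = rep(2L, 3), masks = mk(4:6, c(3, 3)),
         preds = 1L, succs = integer()),
    list(id = 3L, frames = 4:6, labels = rep(3L, 3), masks = mk(4:6, c(8, 8)),
         preds = 1L, succs = integer()))
  gr <- structure(list(tracks = tracks, dim = dims, n_frames = 7L),
                  class = "tracking_graph")
  ops <- solve_untangling(build_untangling_ilp(gr))
  expect_equal(nrow(ops$edges_removed), 0)
  expect_equal(nrow(ops$splits), 0)
  expect_length(ops$merges, 0)
  out <- untangle_tracks(gr)
  expect_equal(lapply(out$tracks, function(x) x[c("id", "frames", "preds",
                                                  "succs")]),
               lapply(gr$tracks, function(x) x[c("id", "frames", "preds",
                                                 "succs")]))
})

test_that("the example graph is untangled like the exhaustive optimum", {
  gr <- untangle_example_graph()
  prob <- build_untangling_ilp(gr)
  ops <- solve_untangling(prob)
  bf <- untangling_oracle(prob)
  expect_equal(ops$objective, bf, tolerance = 1e-9)
  out <- untangle_tracks(gr)
  check_tracking_validity(out)
})

test_that("untangling matches exhaustive search on random small graphs", {
  for (sd in 1:20) {
    gr <- random_track_graph(sd)
    prob <- build_untangling_ilp(gr)
    ops <- solve_untangling(prob)
    bf <- untangling_oracle(prob)
    expect_equal(ops$objective, bf, tolerance = 1e-9,
                 info = paste("seed", sd))
    out <- untangle_tracks(gr)
    check_tracking_validity(out)
  }
})

test_that("mask operations conserve pixels", {
  dims <- c(24L, 40L)
  # dumbbell: two 5x5 lobes joined by a thin bridge
  arr <- matrix(FALSE, dims[1], dims[2])
  arr[10:14, 5:9] <- TRUE
  arr[10:14, 25:29] <- TRUE
  arr[12, 10:24] <- TRUE
  pix <- which(arr)
  seeds <- select_seed_points(pix, dims, 2L)
  parts <- partition_by_seeds(pix, dims, seeds)
  expect_length(parts, 2)
  expect_setequal(c(parts[[1]], parts[[2]]), pix)
  expect_length(intersect(parts[[1]], parts[[2]]), 0)
  # each lobe centre belongs to a different part
  left <- (12 + 1) + 7 * dims[1]     # linear index of (12, 7)
  right <- (12 + 1) + 27 * dims[1]   # linear index of (12, 27)
  in1 <- c(left %in% parts[[1]], right %in% parts[[1]])
  expect_equal(sum(in1), 1)
})

test_that("applying merge and edge-remove operations updates links and masks", {
  gr <- untangle_example_graph()
  before_px <- sum(lengths(gr$tracks[[2]]$masks)) * 9  # 3x3 masks
  ops <- list(edges_removed = data.frame(p = 1L, n = 2L),
              splits = data.frame(id = integer(), parts = integer()),
              merges = list(c(3L, 4L)))
  out <- apply_operations(gr, ops)
  ids <- vapply(out$tracks, function(x) x$id, 1L)
  # edge 1 -> 2 removed
  t2 <- out$tracks[[which(ids == 2L)]]
  expect_length(t2$preds, 0)
  t1 <- out$tracks[[which(ids == 1L)]]
  expect_false(2L %in% t1$succs)
  # tracks 3 and 4 merged into 3: pixel union per frame
  expect_false(4L %in% ids)
  t3 <- out$tracks[[which(ids == 3L)]]
  expect_equal(lengths(t3$masks), c(18L, 18L))  # two 3x3 masks per frame
  t5 <- out$tracks[[which(ids == 5L)]]
  expect_setequal(t5$preds, c(2L, 3L))
})

test_that("gamma follows the quantile rule", {
  gr <- untangle_example_graph()
  len <- vapply(gr$tracks, function(x) max(x$frames) - min(x$frames) + 1L, 1L)
  links <- vapply(gr$tracks, function(x) length(x$preds) + length(x$succs), 1L)
  expected <- 2 * ceiling(quantile(len, 0.3) * quantile(links, 0.99))
  expect_equal(untangling_gamma(gr), unname(expected))
})
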