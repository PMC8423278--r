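mk_track <- function(id, frames, centroids, dims = c(30L, 30L), size = 1L,
                     preds = integer(), succs = integer()) {
  masks <- lapply(seq_along(frames), function(i) {
    ctr <- centroids[[i]]
    if (is.null(ctr)) return(NULL)
    arr <- matrix(FALSE, dims[1], dims[2])
    ys <- (ctr[1] - size + 1):(ctr[1] + size - 1)
    xs <- (ctr[2] - size + 1):(ctr[2] + size - 1)
    arr[ys + 1, xs + 1] <- TRUE
    which(arr)
  })
  list(id = id, frames = frames, labels = rep(id, length(frames)),
       masks = masks, preds = preds, succs = succs)
}

graph_of <- function(tracks, dims = c(30L, 30L)) {
  structure(list(tracks = tracks, dim = dims,
                 n_frames = max(unlist(lapply(tracks, `[[`, "frames"))) + 1L),
            class = "tracking_graph")
}

centroid_px <- function(pix, dims) colMeans(arrayInd(pix, dims) - 1L)

test_that("gap masks are inserted at linearly interpolated positions", {
  gr <- graph_of(list(mk_track(1L, c(0L, 2L),
                               list(c(10, 10), c(10, 14)), size = 2L)))
  out <- interpolate_masks(gr)
  x <- out$tracks[[1]]
  expect_equal(x$frames, 0:2)
  mid <- x$masks[[2]]
  expect_equal(centroid_px(mid, gr$dim), c(10, 12))
  # shape equals the pre-gap mask, translated
  expect_equal(length(mid), length(x$masks[[1]]))

  gr2 <- graph_of(list(mk_track(2L, c(0L, 3L),
                                list(c(10, 10), c(16, 13)), size = 2L)))
  out2 <- interpolate_masks(gr2)
  x2 <- out2$tracks[[1]]
  expect_equal(x2$frames, 0:3)
  expect_equal(centroid_px(x2$masks[[2]], gr2$dim), c(12, 11))
  expect_equal(centroid_px(x2$masks[[3]], gr2$dim), c(14, 12))
})

test_that("leading or trailing gaps are left unfilled", {
  # a track whose frames are 2:4 has no internal gap even if earlier
  # frames exist in the sequence
  gr <- graph_of(list(mk_track(1L, 2:4,
                               list(c(5, 5), c(6, 5), c(7, 5)))))
  out <- interpolate_masks(gr)
  expect_equal(out$tracks[[1]]$frames, 2:4)
  expect_length(out$fn_log, 0)
})

test_that("conflicting pixels go to the closest centroid, ties to lower id", {
  # disjoint masks stay untouched
  gr <- graph_of(list(mk_track(1L, 0L, list(c(5, 5)), size = 2L),
                      mk_track(2L, 0L, list(c(20, 20)), size = 2L)))
  out <- resolve_conflicts(gr)
  expect_equal(out$tracks[[1]]$masks, gr$tracks[[1]]$masks)
  expect_equal(out$tracks[[2]]$masks, gr$tracks[[2]]$masks)

  # overlapping masks: brute-force nearest-centroid partition
  dims <- c(30L, 30L)
  t1 <- mk_track(1L, 0L, list(c(10, 10)), size = 3L)
  t2 <- mk_track(2L, 0L, list(c(10, 13)), size = 3L)
  gr2 <- graph_of(list(t1, t2), dims)
  c1 <- centroid_px(t1$masks[[1]], dims)
  c2 <- centroid_px(t2$masks[[1]], dims)
  overlap <- intersect(t1$masks[[1]], t2$masks[[1]])
  out2 <- resolve_conflicts(gr2)
  m1 <- out2$tracks[[1]]$masks[[1]]; m2 <- out2$tracks[[2]]$masks[[1]]
  expect_length(intersect(m1, m2), 0)
  for (px in overlap) {
    p <- arrayInd(px, dims) - 1L
    d1 <- sum((p - c1)^2); d2 <- sum((p - c2)^2)
    owner <- if (d1 < d2 || (d1 == d2)) 1L else 2L  # tie: lower id
    expect_true(px %in% (if (owner == 1L) m1 else m2),
                info = paste("pixel", px))
  }
  # non-conflicted pixels were never modified
  expect_setequal(setdiff(t1$masks[[1]], overlap), setdiff(m1, overlap))
})

test_that("corrected tracks have no internal gaps and no overlaps", {
  cfg <- simulation_config(shape = c(96L, 96L), n_frames = 10L, n_cells = 6L,
                           seed = 13)
  sim <- generate_sequence(cfg)
  deg <- simulate_fn(sim$gt, error_spec("fn", 15, seed = 2))
  res <- track_sequence(labeled_sequence(deg$frames, NULL), raw = sim$raw)
  for (x in res$graph$tracks) {
    expect_equal(x$frames, seq(min(x$frames), max(x$frames)),
                 info = paste("track", x$id))
  }
  # no frame has a pixel claimed twice (as_labeled_sequence would error)
  expect_s3_class(res$result, "labeled_sequence")
  # inserted masks sit within one motion step of the true centroid
  for (ins in res$graph$fn_log) {
    t <- ins$frame
    # the matching true object: nearest ground-truth centroid at frame t
    gtf <- sim$gt$frames[[t + 1L]]
    labs <- unique(gtf[gtf > 0])
    cents <- t(vapply(labs, function(lb)
      colMeans(arrayInd(which(gtf == lb), dim(gtf)) - 1L), numeric(2)))
    d <- sqrt(rowSums(sweep(cents, 2, ins$centroid)^2))
    expect_lt(min(d), 3 * cfg$displacement_scale + 1)
  }
})
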