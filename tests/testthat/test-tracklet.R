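make_seq_from_boxes <- function(boxes, shape = c(40L, 40L)) {
  # boxes: list per frame of data.frame(label, y, x, h, w) (0-based corners)
  frames <- lapply(boxes, function(df) {
    img <- matrix(0L, shape[1], shape[2])
    if (!is.null(df)) for (r in seq_len(nrow(df)))
      img[df$y[r]:(df$y[r] + df$h[r] - 1) + 1,
          df$x[r]:(df$x[r] + df$w[r] - 1) + 1] <- df$label[r]
    img
  })
  labeled_sequence(frames)
}

test_that("default ROI size doubles the mean mask extent", {
  # all objects 10x10
  s <- make_seq_from_boxes(list(
    data.frame(label = 1:2, y = c(2, 20), x = c(2, 20), h = 10, w = 10)))
  roi <- default_roi_size(sequence_features(s))
  expect_equal(roi$size, c(20, 20))
  expect_equal(roi$alpha, 20)
  # one 10x10 and one 30x10 -> per-axis mean (20, 10), ROI (40, 20)
  s2 <- make_seq_from_boxes(list(
    data.frame(label = 1:2, y = c(2, 2), x = c(2, 20), h = c(10, 30),
               w = c(10, 10))), shape = c(40L, 40L))
  roi2 <- default_roi_size(sequence_features(s2))
  expect_equal(sort(roi2$size), c(20, 40))
  expect_equal(roi2$alpha, 40)
  expect_error(default_roi_size(list()), "no segmented objects")
})

test_that("default ROI size works in 3D", {
  arr <- array(0L, c(12L, 20L, 20L))
  arr[3:10, 3:10, 3:10] <- 1L           # cube of edge 8
  s <- labeled_sequence(list(arr))
  roi <- default_roi_size(sequence_features(s))
  expect_equal(roi$size, c(16, 16, 16))
  expect_equal(roi$alpha, 16)
})

test_that("phase correlation recovers integer shifts", {
  set.seed(3)
  base <- matrix(rnorm(64 * 64), 64, 64)
  base <- gaussian_blur(base, 2)
  expect_equal(estimate_displacement(base, base), c(0, 0))
  shifted <- base[c(62:64, 1:61), c(3:64, 1:2)]   # content moves +3 rows, -2 cols
  expect_equal(estimate_displacement(base, shifted), c(3, -2))
  flat <- matrix(1, 16, 16)
  expect_equal(estimate_displacement(flat, flat), c(0, 0))
  expect_error(estimate_displacement(base, base[1:32, 1:32]),
               "identical shape")
})

test_that("candidate discovery follows the propagated ROI", {
  # stationary object keeps its counterpart as the only candidate
  s <- make_seq_from_boxes(list(
    data.frame(label = 1, y = 15, x = 15, h = 5, w = 5),
    data.frame(label = 1, y = 15, x = 15, h = 5, w = 5)))
  ft <- sequence_features(s)
  cand <- find_candidates(ft, NULL, delta_t = 1L)
  expect_equal(nrow(cand$candidates), 1)
  expect_equal(cand$candidates$cand_label, 1)

  # object far outside the ROI reach is not a candidate
  s2 <- make_seq_from_boxes(list(
    data.frame(label = 1, y = 1, x = 1, h = 4, w = 4),
    data.frame(label = 9, y = 33, x = 33, h = 4, w = 4)))
  ft2 <- sequence_features(s2)
  cand2 <- find_candidates(ft2, NULL, delta_t = 1L)
  expect_equal(nrow(cand2$candidates), 0)

  # two objects inside the propagated ROI are both candidates
  s3 <- make_seq_from_boxes(list(
    data.frame(label = 1, y = 15, x = 15, h = 5, w = 5),
    data.frame(label = c(4, 8), y = c(12, 20), x = c(14, 17), h = 5, w = 5)))
  ft3 <- sequence_features(s3)
  cand3 <- find_candidates(ft3, NULL, delta_t = 1L)
  expect_setequal(cand3$candidates$cand_label, c(4, 8))
})

test_that("candidates are invariant to a global translation of both frames", {
  cfg <- simulation_config(shape = c(64L, 64L), n_frames = 2L, n_cells = 3L,
                           seed = 9)
  sim <- generate_sequence(cfg)
  shift <- c(4L, 6L)
  shifted <- lapply(sim$gt$frames, function(f) {
    out <- matrix(0L, nrow(f), ncol(f))
    out[(1 + shift[1]):nrow(f), (1 + shift[2]):ncol(f)] <-
      f[1:(nrow(f) - shift[1]), 1:(ncol(f) - shift[2])]
    out
  })
  raw_shifted <- lapply(sim$raw, function(f) {
    out <- matrix(0, nrow(f), ncol(f))
    out[(1 + shift[1]):nrow(f), (1 + shift[2]):ncol(f)] <-
      f[1:(nrow(f) - shift[1]), 1:(ncol(f) - shift[2])]
    out
  })
  c1 <- find_candidates(sequence_features(sim$gt), sim$raw, 2L)
  c2 <- find_candidates(sequence_features(labeled_sequence(shifted)),
                        raw_shifted, 2L)
  k1 <- paste(c1$candidates$t, c1$candidates$label, c1$candidates$cand_t,
              c1$candidates$cand_label)
  k2 <- paste(c2$candidates$t, c2$candidates$label, c2$candidates$cand_t,
              c2$candidates$cand_label)
  expect_setequal(k1, k2)
})

test_that("shrinking the gap span never adds candidates", {
  cfg <- simulation_config(shape = c(96L, 96L), n_frames = 5L, n_cells = 5L,
                           seed = 4)
  sim <- generate_sequence(cfg)
  ft <- sequence_features(sim$gt)
  key <- function(cc) paste(cc$candidates$t, cc$candidates$label,
                            cc$candidates$cand_t, cc$candidates$cand_label)
  k3 <- key(find_candidates(ft, NULL, 3L))
  k2 <- key(find_candidates(ft, NULL, 2L))
  k1 <- key(find_candidates(ft, NULL, 1L))
  expect_true(all(k1 %in% k2))
  expect_true(all(k2 %in% k3))
})
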