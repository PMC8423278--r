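gt_fixture <- function(seed = 5, n_frames = 6L, n_cells = 8L)
  generate_sequence(simulation_config(shape = c(144L, 144L),
                                      n_frames = n_frames,
                                      n_cells = n_cells, seed = seed))$gt

test_that("false negatives remove exactly the floored fraction of masks", {
  gt <- gt_fixture()
  total <- sum(vapply(gt$frames, function(f) length(unique(f[f > 0])), 1L))
  deg <- simulate_fn(gt, error_spec("fn", 20, seed = 1))
  removed <- attr(deg, "modified")
  expect_equal(nrow(removed), floor(0.2 * total))
  left <- sum(vapply(deg$frames, function(f) length(unique(f[f > 0])), 1L))
  expect_equal(left, total - nrow(removed))
  expect_equal(deg$lineage, gt$lineage)

  # a fraction rounding to zero leaves the sequence untouched
  deg0 <- simulate_fn(gt, error_spec("fn", 100 / total / 2, seed = 1))
  expect_equal(deg0$frames, gt$frames)

  # determinism
  dega <- simulate_fn(gt, error_spec("fn", 10, seed = 9))
  degb <- simulate_fn(gt, error_spec("fn", 10, seed = 9))
  expect_equal(dega$frames, degb$frames)
})

test_that("over-segmentation splits masks into exact partitions", {
  gt <- gt_fixture()
  total <- sum(vapply(gt$frames, function(f) length(unique(f[f > 0])), 1L))
  deg <- simulate_overseg(gt, error_spec("over", 10, seed = 3))
  mod <- attr(deg, "modified")
  expect_equal(nrow(mod), floor(0.1 * total))
  for (r in seq_len(nrow(mod))) {
    t <- mod$t[r]; lb <- mod$label[r]
    orig <- which(gt$frames[[t + 1L]] == lb)
    now <- deg$frames[[t + 1L]][orig]
    expect_false(any(now == lb))
    parts <- unique(now)
    expect_length(parts, 2)
    expect_true(all(now > 0))
    # parts appear nowhere else
    expect_equal(sort(which(deg$frames[[t + 1L]] %in% parts)), sort(orig))
  }
  # unmodified masks bit-identical
  touched <- paste(mod$t, mod$label)
  for (t in seq_along(gt$frames) - 1L) {
    for (lb in unique(gt$frames[[t + 1L]][gt$frames[[t + 1L]] > 0])) {
      if (paste(t, lb) %in% touched) next
      expect_equal(which(deg$frames[[t + 1L]] == lb),
                   which(gt$frames[[t + 1L]] == lb))
    }
  }
})

test_that("a two-pixel mask splits into two single pixels", {
  img <- matrix(0L, 8, 8)
  img[3, 4:5] <- 7L
  s <- labeled_sequence(list(img))
  deg <- simulate_overseg(s, error_spec("over", 100, seed = 2))
  f <- deg$frames[[1]]
  labs <- unique(f[f > 0])
  expect_length(labs, 2)
  expect_equal(sum(f > 0), 2)
})

test_that("under-segmentation merges into a superset single label", {
  img <- matrix(0L, 20, 20)
  img[8:12, 3:7] <- 1L
  img[8:12, 10:14] <- 2L
  s <- labeled_sequence(list(img))
  deg <- simulate_underseg(s, error_spec("under", 100, seed = 4))
  f <- deg$frames[[1]]
  labs <- unique(f[f > 0])
  expect_length(labs, 1)
  expect_true(all(which(img > 0) %in% which(f == labs)))
  # the closing bridges the seam: the merged mask is connected along the
  # row through both cell centres
  expect_true(all(f[10 + 1, 3:14 + 1] == labs))
})

test_that("closer pairs are merged more often", {
  img <- matrix(0L, 30, 60)
  img[14:16, 4:6] <- 1L     # pair A-B one pixel apart
  img[14:16, 8:10] <- 2L
  img[14:16, 30:32] <- 3L   # pair C-D nine pixels apart
  img[14:16, 42:44] <- 4L
  s <- labeled_sequence(list(img))
  near <- 0L; far <- 0L
  for (sd in 1:120) {
    deg <- simulate_underseg(s, error_spec("under", 50, seed = sd))
    merged <- attr(deg, "modified")
    if (!nrow(merged)) next
    pair <- sort(c(merged$a[1], merged$b[1]))
    if (identical(pair, c(1L, 2L))) near <- near + 1L
    if (identical(pair, c(3L, 4L))) far <- far + 1L
  }
  expect_gt(near, far)
})

test_that("mixed errors modify the floored total with equal shares", {
  gt <- gt_fixture(seed = 8, n_frames = 8L, n_cells = 10L)
  total <- sum(vapply(gt$frames, function(f) length(unique(f[f > 0])), 1L))
  deg <- simulate_mixed(gt, error_spec("mixed", 20, seed = 6))
  k <- floor(0.2 * total)
  expect_equal(attr(deg, "modified_total"), k)
  # count actually modified ground-truth masks by diffing against gt
  changed <- 0L
  for (t in seq_along(gt$frames) - 1L) {
    g <- gt$frames[[t + 1L]]; d <- deg$frames[[t + 1L]]
    for (lb in unique(g[g > 0])) {
      pix <- which(g == lb)
      now <- d[pix]
      intact <- length(unique(now)) == 1L && all(now > 0) &&
        all(which(d == now[1]) %in% pix) && length(which(d == now[1])) == length(pix)
      if (!intact) changed <- changed + 1L
    }
  }
  expect_equal(changed, k)
  # shares: a third each, remainder to FN removals
  removed <- 0L
  for (t in seq_along(gt$frames) - 1L) {
    g <- gt$frames[[t + 1L]]; d <- deg$frames[[t + 1L]]
    for (lb in unique(g[g > 0]))
      if (all(d[which(g == lb)] == 0)) removed <- removed + 1L
  }
  expect_equal(removed, k - 2L * (k %/% 3L))
})

test_that("tiny mixed fractions put the remainder into false negatives", {
  gt <- gt_fixture(seed = 2, n_frames = 4L, n_cells = 5L)
  total <- sum(vapply(gt$frames, function(f) length(unique(f[f > 0])), 1L))
  frac <- 1.2 * 100 / total  # one mask
  deg <- simulate_mixed(gt, error_spec("mixed", frac, seed = 3))
  removed <- 0L
  for (t in seq_along(gt$frames) - 1L) {
    g <- gt$frames[[t + 1L]]; d <- deg$frames[[t + 1L]]
    for (lb in unique(g[g > 0]))
      if (all(d[which(g == lb)] == 0)) removed <- removed + 1L
  }
  expect_equal(removed, 1L)
})

test_that("the benchmark grid enumerates the full protocol", {
  grid <- generate_benchmark_grid(
    sequences = list(a = NULL, b = NULL, c = NULL, d = NULL),
    fractions = c(1, 2, 5, 10, 20),
    error_types = c("fn", "over", "under", "mixed"), runs = 5L)
  expect_equal(nrow(grid), 400)
  expect_length(unique(grid$seed), 400)
  g1 <- generate_benchmark_grid(list(x = NULL), fractions = 5,
                                error_types = "fn", runs = 1L)
  expect_equal(nrow(g1), 1)
  g2 <- generate_benchmark_grid(
    sequences = list(a = NULL, b = NULL, c = NULL, d = NULL),
    fractions = c(1, 2, 5, 10, 20),
    error_types = c("fn", "over", "under", "mixed"), runs = 5L)
  expect_equal(grid, g2)
})

test_that("materialised grids carry degraded sequences per entry", {
  gt <- gt_fixture(seed = 9, n_frames = 3L, n_cells = 4L)
  grid <- generate_benchmark_grid(list(s = gt), fractions = c(10, 20),
                                  error_types = c("fn", "over"), runs = 1L,
                                  materialise = TRUE)
  expect_equal(nrow(grid), 4)
  total <- sum(vapply(gt$frames, function(f) length(unique(f[f > 0])), 1L))
  for (r in seq_len(nrow(grid))) {
    deg <- grid$sequence[[r]]
    expect_s3_class(deg, "labeled_sequence")
    if (grid$error_type[r] == "fn") {
      left <- sum(vapply(deg$frames, function(f)
        length(unique(f[f > 0])), 1L))
      expect_equal(left, total - floor(grid$fraction[r] / 100 * total))
    }
  }
})

test_that("simulators are pure functions of sequence and spec", {
  gt <- gt_fixture(seed = 3)
  for (sim in list(simulate_overseg, simulate_underseg, simulate_mixed)) {
    a <- sim(gt, error_spec("fn", 15, seed = 11))
    b <- sim(gt, error_spec("fn", 15, seed = 11))
    expect_equal(a$frames, b$frames)
  }
})
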