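#' Segmentation-error specification
#'
#' @param error_type one of `"fn"`, `"over"`, `"under"`, `"mixed"`.
#' @param fraction percentage of ground-truth masks to modify (0 < n <= 100).
#' @param seed RNG seed; all simulators are pure functions of
#'   (sequence, spec).
#' @param run run index (bookkeeping for benchmark grids).
#' @return an `error_spec`.
#' @export
error_spec <- function(error_type = c("fn", "over", "under", "mixed"),
                       fraction, seed = 1L, run = 1L) {
  error_type <- match.arg(error_type)
  stopifnot(fraction > 0, fraction <= 100)
  structure(list(error_type = error_type, fraction = fraction,
                 seed = as.integer(seed), run = as.integer(run)),
            class = "error_spec")
}

# all (frame, label) mask instances of a sequence
mask_table <- function(seq) {
  rows <- lapply(seq_along(seq$frames) - 1L, function(t) {
    labs <- sort(unique(seq$frames[[t + 1L]][seq$frames[[t + 1L]] > 0L]))
    if (length(labs)) data.frame(t = t, label = labs) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(t = integer(), label = integer()) else out
}

#' Simulate false negatives
#'
#' Removes `floor(n% * total masks)` masks drawn uniformly without
#' replacement; the lineage table is left untouched.
#'
#' @param seq ground-truth [labeled_sequence].
#' @param spec an [error_spec] (its `fraction` is used; type ignored).
#' @return degraded [labeled_sequence] with attribute `modified`
#'   (data.frame of the removed masks).
#' @export
simulate_fn <- function(seq, spec, exclude = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  mt <- mask_table(seq)
  k <- floor(spec$fraction / 100 * nrow(mt))
  if (!is.null(exclude) && nrow(exclude)) {
    mt <- mt[!(paste(mt$t, mt$label) %in%
                 paste(exclude$t, exclude$label)), , drop = FALSE]
    k <- min(k, nrow(mt))
  }
  sel <- if (k > 0) mt[sample.int(nrow(mt), k), , drop = FALSE] else mt[0, ]
  frames <- seq$frames
  if (nrow(sel)) for (r in seq_len(nrow(sel))) {
    f <- frames[[sel$t[r] + 1L]]
    f[f == sel$label[r]] <- 0L
    frames[[sel$t[r] + 1L]] <- f
  }
  out <- labeled_sequence(frames, seq$lineage)
  attr(out, "modified") <- sel
  out
}

# split one mask in two by a random hyperplane through its centroid
split_mask_random <- function(frame, label, dims) {
  pix <- which(frame == label)
  if (length(pix) < 2L) return(NULL)
  coords <- pix_coords(pix, dims)
  ctr <- colMeans(coords)
  for (try in 1:25) {
    v <- rnorm(ncol(coords))
    v <- v / sqrt(sum(v^2))
    side <- as.vector(sweep(coords, 2, ctr) %*% v) >= 0
    if (any(side) && any(!side)) {
      return(list(part1 = pix[side], part2 = pix[!side]))
    }
  }
  # forced fallback for degenerate masks: split by pixel order
  half <- ceiling(length(pix) / 2)
  list(part1 = pix[seq_len(half)], part2 = pix[-seq_len(half)])
}

#' Simulate over-segmentation
#'
#' Splits `floor(n% * total)` randomly drawn masks into two nonempty parts
#' by a random hyperplane through the mask centroid; parts get fresh
#' labels. Single-pixel masks are resampled (logged via attribute).
#'
#' @inheritParams simulate_fn
#' @return degraded [labeled_sequence].
#' @export
simulate_overseg <- function(seq, spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  mt <- mask_table(seq)
  k <- floor(spec$fraction / 100 * nrow(mt))
  frames <- seq$frames
  nextlab <- max(vapply(frames, max, 1L)) + 1L
  ord <- sample.int(nrow(mt))
  done <- 0L; resampled <- 0L; sel <- list()
  for (r in ord) {
    if (done >= k) break
    t <- mt$t[r]; lb <- mt$label[r]
    sp <- split_mask_random(frames[[t + 1L]], lb, seq$dim)
    if (is.null(sp)) { resampled <- resampled + 1L; next }
    f <- frames[[t + 1L]]
    f[sp$part1] <- nextlab
    f[sp$part2] <- nextlab + 1L
    nextlab <- nextlab + 2L
    frames[[t + 1L]] <- f
    done <- done + 1L
    sel[[done]] <- data.frame(t = t, label = lb)
  }
  out <- labeled_sequence(frames, seq$lineage)
  attr(out, "modified") <- if (done) do.call(rbind, sel) else mt[0, ]
  attr(out, "resampled") <- resampled
  out
}

#' Simulate under-segmentation
#'
#' Iteratively samples neighbouring mask pairs within a frame with weights
#' favouring smaller centroid distances (`w = 1/(d+1)`), merges each pair
#' into a single label and bridges the seam with a morphological closing
#' (ball radius half the boundary gap), until at least `n%` of the
#' ground-truth masks are merged; chains of more than two cells arise when
#' an already-merged mask is drawn again. Stops short (with attribute
#' `shortfall`) when no neighbour pairs remain.
#'
#' @inheritParams simulate_fn
#' @param neighbor_factor pairs are eligible when their centroid distance
#'   is below this multiple of the mean mask extent (default 4, i.e.
#'   twice the default ROI edge).
#' @return degraded [labeled_sequence].
#' @export
simulate_underseg <- function(seq, spec, neighbor_factor = 4,
                              exclude = NULL, target = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  dims <- seq$dim
  mt <- mask_table(seq)
  if (is.null(target)) target <- floor(spec$fraction / 100 * nrow(mt))
  excl_keys <- if (!is.null(exclude) && nrow(exclude))
    paste(exclude$t, exclude$label) else character()
  frames <- seq$frames
  # mean mask extent for the neighbourhood radius
  fts <- sequence_features(labeled_sequence(frames, NULL))
  allobj <- unlist(fts$objects, recursive = FALSE)
  if (length(allobj) < 2L) {
    out <- labeled_sequence(frames, seq$lineage)
    attr(out, "modified") <- mt[0, ]; attr(out, "shortfall") <- target
    return(out)
  }
  ext <- mean(vapply(allobj, function(o) mean(o$bbox_max - o$bbox_min + 1), 1))
  radius <- neighbor_factor * ext

  # merged_count[label-key] = number of original masks inside a merged mask
  merged_n <- new.env(parent = emptyenv())
  count_of <- function(t, lb) {
    k <- paste(t, lb)
    if (exists(k, envir = merged_n, inherits = FALSE))
      get(k, envir = merged_n) else 1L
  }
  merged_total <- 0L
  sel <- list()

  repeat {
    if (merged_total >= target) break
    remaining <- target - merged_total
    # collect eligible pairs over all frames
    pairs <- list()
    for (t in seq_along(frames) - 1L) {
      f <- frames[[t + 1L]]
      labs <- sort(unique(f[f > 0L]))
      labs <- labs[!(paste(t, labs) %in% excl_keys)]
      if (length(labs) < 2L) next
      cents <- t(vapply(labs, function(lb) {
        colMeans(pix_coords(which(f == lb), dims))
      }, numeric(length(dims))))
      for (i in seq_along(labs)) for (j in seq_along(labs)) {
        if (i >= j) next
        d <- sqrt(sum((cents[i, ] - cents[j, ])^2))
        if (d > radius) next
        ca <- count_of(t, labs[i]); cb <- count_of(t, labs[j])
        # masks not yet part of a merge become newly merged originals
        newly <- (ca == 1L) * ca + (cb == 1L) * cb
        if (newly > remaining) next
        pairs[[length(pairs) + 1L]] <-
          data.frame(t = t, a = labs[i], b = labs[j], d = d, newly = newly)
      }
    }
    if (!length(pairs)) break
    pairs <- do.call(rbind, pairs)
    w <- 1 / (pairs$d + 1)
    pick <- sample.int(nrow(pairs), 1L, prob = w / sum(w))
    t <- pairs$t[pick]; a <- pairs$a[pick]; b <- pairs$b[pick]
    f <- frames[[t + 1L]]
    pa <- which(f == a); pb <- which(f == b)
    gap <- sqrt(min(sq_dist_to_set(pa, dims)[pb]))
    un <- c(pa, pb)
    closed <- close_pixel_set(un, dims, ceiling(gap / 2))
    # never absorb pixels of other masks; the merged mask keeps one label
    # even in the rare case the closing leaves the lobes unbridged
    closed <- closed[f[closed] == 0L | f[closed] %in% c(a, b)]
    f[closed] <- a
    frames[[t + 1L]] <- f
    ncount <- count_of(t, a) + count_of(t, b)
    assign(paste(t, a), ncount, envir = merged_n)
    merged_total <- merged_total + pairs$newly[pick]
    sel[[length(sel) + 1L]] <- data.frame(t = t, a = a, b = b)
  }
  out <- labeled_sequence(frames, seq$lineage)
  attr(out, "modified") <- if (length(sel)) do.call(rbind, sel) else
    data.frame(t = integer(), a = integer(), b = integer())
  attr(out, "merged_masks") <- merged_total
  attr(out, "shortfall") <- max(0L, target - merged_total)
  out
}

#' Simulate a mixture of segmentation errors
#'
#' The target count `floor(n% * total)` is split into three equal shares
#' (remainder assigned to false negatives) applied on disjoint mask
#' selections: FN removals, over-segmentation splits and
#' under-segmentation merges.
#'
#' @inheritParams simulate_fn
#' @return degraded [labeled_sequence].
#' @export
simulate_mixed <- function(seq, spec) {
  total <- nrow(mask_table(seq))
  k <- floor(spec$fraction / 100 * total)
  share <- k %/% 3L
  k_fn <- k - 2L * share
  pct <- function(cnt) if (total > 0) min(100, cnt / total * 100 + 1e-9) else 1e-9
  out <- seq
  touched <- data.frame(t = integer(), label = integer())
  if (share > 0) {
    s_over <- spec; s_over$seed <- spec$seed + 101L
    s_over$fraction <- pct(share)
    out <- simulate_overseg(out, s_over)
    parts <- attr(out, "modified")        # the split originals are gone;
    # the fresh part labels must stay untouched by the later stages:
    part_labels <- mask_table(out)
    gt_labels <- paste(mask_table(seq)$t, mask_table(seq)$label)
    new_parts <- part_labels[!(paste(part_labels$t, part_labels$label) %in%
                                 gt_labels), , drop = FALSE]
    touched <- rbind(touched, new_parts)

    s_under <- spec; s_under$seed <- spec$seed + 202L
    out <- simulate_underseg(out, s_under, exclude = touched,
                             target = share)
    merged <- attr(out, "modified")
    if (nrow(merged))
      touched <- rbind(touched,
                       data.frame(t = rep(merged$t, 2),
                                  label = c(merged$a, merged$b)))
  }
  if (k_fn > 0) {
    s_fn <- spec; s_fn$seed <- spec$seed + 303L
    s_fn$fraction <- pct(k_fn)
    out <- simulate_fn(out, s_fn, exclude = touched)
  }
  attr(out, "modified_total") <- k
  out
}

#' Enumerate (and optionally materialise) a benchmark grid
#'
#' The Cartesian product of sequences, error fractions, error types and
#' run indices, each entry with a distinct derived seed.
#'
#' @param sequences named list of ground-truth [labeled_sequence]s (or any
#'   identifiers when `materialise = FALSE`).
#' @param fractions percentages, e.g. `c(1, 2, 5, 10, 20)`.
#' @param error_types subset of `c("fn", "over", "under", "mixed")`.
#' @param runs number of repetitions per condition.
#' @param base_seed seed offset from which per-entry seeds are derived.
#' @param materialise if `TRUE`, apply the simulators and return degraded
#'   sequences in `$sequence`.
#' @return data.frame with one row per data set (columns `sequence_id,
#'   error_type, fraction, run, seed`, plus a `sequence` list-column when
#'   materialised).
#' @export
generate_benchmark_grid <- function(sequences,
                                    fractions = c(1, 2, 5, 10, 20),
                                    error_types = c("fn", "over", "under",
                                                    "mixed"),
                                    runs = 5L, base_seed = 1000L,
                                    materialise = FALSE) {
  stopifnot(length(sequences) > 0, length(fractions) > 0,
            length(error_types) > 0, runs >= 1)
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  grid <- expand.grid(sequence_id = ids, error_type = error_types,
                      fraction = fractions, run = seq_len(runs),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sequence_id, grid$error_type, grid$fraction,
                     grid$run), ]
  rownames(grid) <- NULL
  grid$seed <- base_seed + seq_len(nrow(grid))
  if (materialise) {
    grid$sequence <- lapply(seq_len(nrow(grid)), function(r) {
      sp <- error_spec(grid$error_type[r], grid$fraction[r],
                       seed = grid$seed[r], run = grid$run[r])
      sim <- switch(grid$error_type[r], fn = simulate_fn,
                    over = simulate_overseg, under = simulate_underseg,
                    mixed = simulate_mixed)
      sim(sequences[[grid$sequence_id[r]]], sp)
    })
  }
  grid
}
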