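#' Default region-of-interest size and appearance threshold
#'
#' The ROI used to collect matching candidates is, per axis, twice the mean
#' bounding-box extent over all segmented objects of the sequence. The
#' appearance/disappearance threshold `alpha` is the largest edge of this
#' default ROI.
#'
#' @param features a `sequence_features` object (or a flat list of
#'   `segmented_object`s).
#' @param roi_scale multiple of the mean mask extent (default 2).
#' @return list with `size` (per-axis ROI extent, px) and `alpha`.
#' @export
default_roi_size <- function(features, roi_scale = 2) {
  objs <- if (inherits(features, "sequence_features"))
    unlist(features$objects, recursive = FALSE) else features
  if (!length(objs)) stop("no segmented objects; cannot derive ROI size")
  ext <- t(vapply(objs, function(o) o$bbox_max - o$bbox_min + 1,
                  numeric(length(objs[[1]]$bbox_min))))
  size <- roi_scale * colMeans(ext)
  list(size = size, alpha = max(size))
}

#' Estimate a translation between two image crops by phase correlation
#'
#' Returns the integer pixel shift that maximises the inverse transform of
#' the normalised cross-power spectrum. Constant crops (zero variance) or a
#' degenerate correlation surface fall back to the zero vector.
#'
#' @param crop_t,crop_t1 equally sized numeric crops from frames t and t+1.
#' @return integer shift vector `s` such that content at position `p` in
#'   `crop_t` appears near `p + s` in `crop_t1`.
#' @export
estimate_displacement <- function(crop_t, crop_t1) {
  if (!identical(dim(crop_t), dim(crop_t1)))
    stop("crops must have identical shape")
  d <- dim(crop_t)
  if (sd(crop_t) < 1e-12 || sd(crop_t1) < 1e-12)
    return(numeric(length(d)))
  # mean removal and a Hann taper suppress the spurious peaks that the
  # pure cross-power normalisation produces on small noisy crops
  w <- Reduce(function(a, k) outer(a, hann_window(d[k])),
              seq_along(d)[-1], hann_window(d[1]))
  dim(w) <- d
  crop_t <- (crop_t - mean(crop_t)) * w
  crop_t1 <- (crop_t1 - mean(crop_t1)) * w
  f1 <- fft(crop_t)
  f2 <- fft(crop_t1)
  cp <- f2 * Conj(f1)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  surf <- Re(fft(cp, inverse = TRUE)) / prod(d)
  pk <- which.max(surf)
  if (surf[pk] < 1e-6) return(numeric(length(d)))
  shift <- arrayInd(pk, .dim = d) - 1L
  wrap <- shift > d / 2
  shift[wrap] <- shift[wrap] - d[wrap]
  as.numeric(shift)
}

hann_window <- function(n) {
  if (n < 2L) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Crop a window of given size centred at `center` (0-based), clipped to the
# image; returns NULL if the window collapses.
crop_window <- function(img, center, size) {
  d <- dim(img)
  lo <- pmax(0L, round(center - size / 2))
  hi <- pmin(d - 1L, lo + pmax(4, round(size)) - 1L)
  lo <- pmax(0L, pmin(lo, hi - 4L))
  if (any(hi - lo < 2L)) return(NULL)
  idx <- lapply(seq_along(d), function(a) (lo[a]:hi[a]) + 1L)
  out <- do.call(`[`, c(list(img), idx, list(drop = FALSE)))
  dim(out) <- hi - lo + 1L
  out
}

#' Propagate objects over a few frames with displacement estimates
#'
#' For every object at frame t the displacement to each of the next
#' `delta_t` frames is estimated by chaining phase-correlation shifts of
#' raw-image crops centred on the propagated position (zero displacement
#' when raw images are absent; the last estimate is reused when a crop
#' leaves the image).
#'
#' @param features a `sequence_features` object.
#' @param raw optional list of raw intensity frames (same length).
#' @param delta_t maximum temporal gap to bridge (frames).
#' @param roi list from [default_roi_size].
#' @return nested list `disp[[t+1]][[label]]`: a `delta_t x ndim` matrix of
#'   cumulative displacements (row k = displacement from t to t+k).
#' @export
propagate_objects <- function(features, raw = NULL, delta_t = 3L,
                              roi = default_roi_size(features)) {
  nT <- length(features$objects)
  nd <- features$ndim
  lapply(seq_len(nT) - 1L, function(t) {
    objs <- features$objects[[t + 1L]]
    out <- lapply(objs, function(o) {
      cum <- matrix(0, nrow = delta_t, ncol = nd)
      if (!is.null(raw)) {
        pos <- o$centroid
        step <- numeric(nd)
        acc <- numeric(nd)
        for (k in seq_len(delta_t)) {
          t2 <- t + k                    # estimate d_{t+k-1, t+k}
          if (t2 <= nT - 1L) {
            c_prev <- crop_window(raw[[t2]], pos, roi$size)
            c_next <- crop_window(raw[[t2 + 1L]], pos, roi$size)
            if (!is.null(c_prev) && !is.null(c_next) &&
                identical(dim(c_prev), dim(c_next))) {
              step <- estimate_displacement(c_prev, c_next)
            } # else reuse the previous estimate (crop left the image)
          }
          acc <- acc + step
          cum[k, ] <- acc
          pos <- o$centroid + acc
        }
      }
      cum
    })
    names(out) <- names(objs)
    out
  })
}

#' Collect matching candidates by ROI propagation
#'
#' For each object at frame t the ROI is placed at its centroid, displaced
#' by the estimated cumulative shift for each of the next `delta_t` frames,
#' and every object whose bounding box intersects the propagated ROI is
#' recorded as a candidate.
#'
#' @param features a `sequence_features` object.
#' @param raw optional raw frames for displacement estimation.
#' @param delta_t maximum gap (frames), at least 1.
#' @param roi from [default_roi_size].
#' @param disp optional precomputed [propagate_objects] result.
#' @return list with `candidates` (data.frame `t, label, step, cand_t,
#'   cand_label`) and `disp`.
#' @export
find_candidates <- function(features, raw = NULL, delta_t = 3L,
                            roi = default_roi_size(features),
                            disp = NULL) {
  stopifnot(delta_t >= 1L)
  if (is.null(disp))
    disp <- propagate_objects(features, raw, delta_t, roi)
  nT <- length(features$objects)
  half <- roi$size / 2
  rows <- list()
  for (t in seq_len(nT) - 1L) {
    objs <- features$objects[[t + 1L]]
    for (lb in names(objs)) {
      o <- objs[[lb]]
      cum <- disp[[t + 1L]][[lb]]
      for (k in seq_len(delta_t)) {
        t2 <- t + k
        if (t2 > nT - 1L) break
        ctr <- o$centroid + cum[k, ]
        lo <- ctr - half; hi <- ctr + half
        for (lb2 in names(features$objects[[t2 + 1L]])) {
          o2 <- features$objects[[t2 + 1L]][[lb2]]
          if (all(o2$bbox_max >= lo - 1e-9) &&
              all(o2$bbox_min <= hi + 1e-9)) {
            rows[[length(rows) + 1L]] <-
              data.frame(t = t, label = o$label, step = k, cand_t = t2,
                         cand_label = o2$label)
          }
        }
      }
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = integer(), label = integer(), step = integer(),
               cand_t = integer(), cand_label = integer())
  list(candidates = cand, disp = disp, roi = roi, delta_t = delta_t)
}
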