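#' Euclidean distance transform
#'
#' Exact distance of every pixel of a binary mask to the nearest background
#' pixel (separable squared-distance transform, works for 2D and 3D arrays).
#' Pixels outside the array are treated as background, so mask pixels on the
#' array border get distance 1.
#'
#' @param mask logical (or 0/1) matrix or 3D array; `TRUE` = foreground.
#' @param squared return squared distances if `TRUE`.
#' @return numeric array of the same shape.
#' @export
distance_transform <- function(mask, squared = FALSE) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or array")
  # pad with one background layer so the array border counts as background
  pd <- d + 2L
  padded <- array(FALSE, dim = pd)
  idx <- lapply(d, function(k) seq_len(k) + 1L)
  padded[do.call(cbind, expand_grid_idx(idx))] <- as.logical(mask)
  sq <- .sqedt_cpp(!padded, as.integer(pd))  # distance to background
  out <- do.call(`[`, c(list(sq), idx, list(drop = FALSE)))
  dim(out) <- d
  out[!as.logical(mask)] <- 0
  if (squared) out else sqrt(out)
}

# expand.grid over index lists returning a matrix of array indices
expand_grid_idx <- function(idx) {
  g <- do.call(expand.grid, idx)
  lapply(seq_along(idx), function(i) g[[i]])
}

# squared distance to a TRUE-set (not restricted to the set itself)
sq_dist_to_set <- function(set, dims) {
  arr <- array(FALSE, dim = dims)
  arr[set] <- TRUE
  .sqedt_cpp(arr, as.integer(dims))
}

# Morphological closing of a pixel set (linear indices into an array of
# dimension `dims`) with a Euclidean ball of radius r.
close_pixel_set <- function(pix, dims, r) {
  if (r <= 0) return(pix)
  d_to <- sq_dist_to_set(pix, dims)
  dil <- d_to <= r^2 + 1e-9
  d_out <- .sqedt_cpp(!dil, as.integer(dims))  # distance to non-dilated
  closed <- d_out > r^2 - 1e-9                 # erosion of the dilation
  # closing is extensive on the interior; keep original pixels regardless
  closed[pix] <- TRUE
  which(closed)
}

# coordinates (0-based, axis order = array dim order) of linear indices
pix_coords <- function(pix, dims) {
  arrayInd(pix, .dim = dims) - 1L
}

# linear indices from 0-based coordinate matrix, dropping out-of-range rows
coords_to_pix <- function(coords, dims) {
  coords <- as.matrix(coords)
  keep <- rep(TRUE, nrow(coords))
  for (a in seq_along(dims))
    keep <- keep & coords[, a] >= 0 & coords[, a] < dims[a]
  coords <- coords[keep, , drop = FALSE]
  if (!nrow(coords)) return(integer())
  idx <- coords[, 1] + 1
  mult <- 1
  for (a in seq_along(dims)[-1]) {
    mult <- mult * dims[a - 1]
    idx <- idx + coords[, a] * mult
  }
  as.integer(idx)
}

# Greedy selection of k well separated interior seed points of a mask,
# ranked by distance-transform depth (approximate cell centres).
select_seed_points <- function(pix, dims, k) {
  n <- length(pix)
  if (n == 0L || k < 1L) return(matrix(numeric(0), 0, length(dims)))
  k <- min(k, n)
  coords <- pix_coords(pix, dims)
  # distance transform on a bbox crop for speed
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  cd <- sweep(coords, 2, lo)
  cdims <- hi - lo + 1L
  cpix <- coords_to_pix(cd, cdims)
  arr <- array(FALSE, cdims); arr[cpix] <- TRUE
  dt <- distance_transform(arr, squared = TRUE)
  depth <- dt[cpix]
  ord <- order(-depth, cd[, 1], if (ncol(cd) > 1) cd[, 2] else 0)
  minsep <- max(2, sqrt(max(depth)))
  seeds <- matrix(numeric(0), 0, ncol(coords))
  for (sep in c(minsep, minsep / 2, 1.0001, 0)) {
    seeds <- matrix(numeric(0), 0, ncol(coords))
    for (i in ord) {
      p <- coords[i, ]
      if (nrow(seeds) == 0L ||
          all(sqrt(rowSums(sweep(seeds, 2, p)^2)) > sep)) {
        seeds <- rbind(seeds, p)
        if (nrow(seeds) == k) break
      }
    }
    if (nrow(seeds) == k) break
  }
  unname(seeds)
}

# Partition a pixel set among seed rows (0-based coords); returns a list of
# linear-index vectors, one per seed. Ties go to the earlier seed.
partition_by_seeds <- function(pix, dims, seeds) {
  coords <- pix_coords(pix, dims)
  k <- nrow(seeds)
  if (k <= 1L) return(list(pix))
  d2 <- sapply(seq_len(k), function(s)
    rowSums(sweep(coords, 2, seeds[s, ])^2))
  assign <- max.col(-d2, ties.method = "first")
  lapply(seq_len(k), function(s) pix[assign == s])
}

# Gaussian blur, separable, for 2D/3D arrays (used by the synthetic imager).
gaussian_blur <- function(img, sigma = 1.2) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  kx <- stats::dnorm(seq(-r, r), sd = sigma)
  kx <- kx / sum(kx)
  d <- dim(img)
  out <- img
  for (a in seq_along(d)) {
    if (d[a] == 1L) next
    out <- apply_along(out, a, function(v) {
      vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
      stats::filter(vp, kx, sides = 2)[(r + 1):(r + length(v))]
    })
  }
  out
}

apply_along <- function(arr, axis, fn) {
  d <- dim(arr)
  perm <- c(axis, seq_along(d)[-axis])
  ap <- aperm(arr, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- apply(m, 2, fn)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}
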