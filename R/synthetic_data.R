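#' Configuration for the synthetic sequence generator
#'
#' The generator emulates fluorescently labelled, blob-like cells: elliptical
#' (2D) or ellipsoidal (thin 3D) masks moving with a Brownian step plus a
#' constant per-cell drift, reflective image boundaries, and occasional
#' divisions that replace a mother by two adjacent daughters. Per-frame
#' displacements are small relative to the image extent, matching the
#' small-motion regime the tracker assumes.
#'
#' @param shape spatial extent in pixels, `(y, x)` or `(z, y, x)`.
#' @param n_frames number of frames.
#' @param n_cells number of cells at frame 0.
#' @param radius_range min/max in-plane cell radius (px).
#' @param displacement_scale standard deviation of the Brownian step (px);
#'   total per-frame steps are clamped to three times this value.
#' @param n_divisions exact number of division events to schedule (may be
#'   fewer if no eligible cell is alive); takes precedence over
#'   `division_prob`.
#' @param division_prob per-cell per-frame division probability, used when
#'   `n_divisions` is `NULL`.
#' @param seed RNG seed; the generator is a pure function of the config.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(shape = c(256L, 256L), n_frames = 30L,
                              n_cells = 15L, radius_range = c(7, 11),
                              displacement_scale = 1.5,
                              n_divisions = 0L, division_prob = NULL,
                              seed = 1L) {
  stopifnot(length(shape) %in% c(2L, 3L), n_frames >= 1, n_cells >= 1,
            displacement_scale > 0)
  if (displacement_scale * 3 > min(shape[length(shape) - 1:0]) / 4)
    stop("displacement scale too large relative to the image extent")
  structure(list(shape = as.integer(shape), n_frames = as.integer(n_frames),
                 n_cells = as.integer(n_cells),
                 radius_range = radius_range,
                 displacement_scale = displacement_scale,
                 n_divisions = if (is.null(division_prob)) as.integer(n_divisions) else NULL,
                 division_prob = division_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic raw + ground-truth sequence
#'
#' @param cfg a [simulation_config].
#' @return list with `raw` (list of numeric intensity frames), `gt`
#'   (a [labeled_sequence] with full lineage) and `config`.
#' @export
generate_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  dims <- cfg$shape
  nd <- length(dims)
  plane <- dims[(nd - 1):nd]            # (y, x)
  nT <- cfg$n_frames
  rmax <- max(cfg$radius_range)

  # initial placement with minimum separation
  cells <- list()
  sep <- 2 * rmax + 3
  for (i in seq_len(cfg$n_cells)) {
    ok <- FALSE
    for (try in 1:300) {
      ctr <- runif(2, rmax + 1, plane - rmax - 2)
      if (!length(cells) ||
          all(vapply(cells, function(cl)
            sqrt(sum((cl$center - ctr)^2)) >= sep, TRUE))) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place ", cfg$n_cells,
                  " cells without overlap; lower the density")
    r <- runif(1, cfg$radius_range[1], cfg$radius_range[2])
    cells[[i]] <- list(id = i, center = ctr,
                       radii = r * runif(2, 0.85, 1.15),
                       angle = runif(1, 0, pi),
                       drift = rnorm(2, 0, cfg$displacement_scale / 2),
                       zc = if (nd == 3) runif(1, 1, dims[1] - 2) else NULL,
                       zr = if (nd == 3) runif(1, 1.2, min(2.5, dims[1] / 2)) else NULL,
                       intensity = runif(1, 140, 220),
                       alive = TRUE, begin = 0L)
  }
  next_id <- cfg$n_cells + 1L
  lineage_parent <- setNames(rep(0L, cfg$n_cells), seq_len(cfg$n_cells))

  # division schedule
  div_frames <- integer()
  if (!is.null(cfg$n_divisions) && cfg$n_divisions > 0) {
    lo <- min(10L, max(2L, nT - 8L)); hi <- max(lo, nT - 6L)
    div_frames <- sort(sample(lo:hi, cfg$n_divisions,
                              replace = hi - lo + 1L < cfg$n_divisions))
  }

  frames <- vector("list", nT)
  raw <- vector("list", nT)
  ends <- list()

  for (t in seq_len(nT) - 1L) {
    if (t > 0L) {
      # move cells
      for (k in seq_along(cells)) {
        cl <- cells[[k]]
        if (!cl$alive) next
        step <- cl$drift + rnorm(2, 0, cfg$displacement_scale)
        nrm <- sqrt(sum(step^2))
        lim <- 3 * cfg$displacement_scale
        if (nrm > lim) step <- step * lim / nrm
        ctr <- cl$center + step
        # reflective boundaries
        for (a in 1:2) {
          lo <- rmax; hi <- plane[a] - rmax - 1
          if (ctr[a] < lo) ctr[a] <- lo + (lo - ctr[a])
          if (ctr[a] > hi) ctr[a] <- hi - (ctr[a] - hi)
          ctr[a] <- min(max(ctr[a], lo), hi)
        }
        # avoid deep overlap with other alive cells
        clash <- function(p) any(vapply(cells[-k], function(o)
          o$alive && sqrt(sum((o$center - p)^2)) <
            0.9 * (max(o$radii) + max(cl$radii)), TRUE))
        if (length(cells) > 1L && clash(ctr)) {
          moved <- FALSE
          for (try in 1:10) {
            alt <- cl$center + rnorm(2, 0, cfg$displacement_scale)
            an <- sqrt(sum((alt - cl$center)^2))
            if (an > lim) alt <- cl$center + (alt - cl$center) * lim / an
            alt <- pmin(pmax(alt, rmax), plane - rmax - 1)
            if (!clash(alt)) { ctr <- alt; moved <- TRUE; break }
          }
          if (!moved) ctr <- cl$center
        }
        cells[[k]]$center <- ctr
      }

      # divisions
      divide_now <- if (length(div_frames)) sum(div_frames == t) else 0L
      if (is.null(cfg$n_divisions) && !is.null(cfg$division_prob)) {
        alive_n <- sum(vapply(cells, function(c) c$alive, TRUE))
        divide_now <- stats::rbinom(1, alive_n, cfg$division_prob)
      }
      for (dv in seq_len(divide_now)) {
        # newborn cells observe a refractory period before dividing again
        alive_idx <- which(vapply(cells, function(c)
          c$alive && (t - c$begin) >= 10, TRUE))
        if (!length(alive_idx)) next
        k <- if (length(alive_idx) == 1L) alive_idx else sample(alive_idx, 1)
        mo <- cells[[k]]
        ang <- runif(1, 0, 2 * pi)
        dirv <- c(sin(ang), cos(ang))
        # cytokinesis conserves area: daughters of radius r/sqrt(2),
        # just touching, symmetric about the mother's position
        r2 <- pmax(mo$radii / sqrt(2), 3)
        off <- max(r2) * 1.05
        for (s in c(-1, 1)) {
          ctr <- mo$center + s * off * dirv
          ctr <- pmin(pmax(ctr, rmax), plane - rmax - 1)
          cells[[length(cells) + 1L]] <-
            list(id = next_id, center = ctr, radii = r2,
                 angle = runif(1, 0, pi),
                 # daughters push apart along the division axis
                 drift = mo$drift + s * 0.4 * cfg$displacement_scale * dirv +
                   rnorm(2, 0, cfg$displacement_scale / 4),
                 zc = mo$zc, zr = mo$zr,
                 intensity = mo$intensity * runif(1, 0.9, 1.1),
                 alive = TRUE, begin = t)
          lineage_parent[as.character(next_id)] <- mo$id
          next_id <- next_id + 1L
        }
        cells[[k]]$alive <- FALSE
        ends[[as.character(mo$id)]] <- t - 1L
      }
    }

    # rasterise
    img <- array(0L, dim = dims)
    bestd <- array(Inf, dim = dims)
    for (cl in cells) {
      if (!cl$alive) next
      yr <- seq(max(0, floor(cl$center[1] - max(cl$radii) - 1)),
                min(plane[1] - 1, ceiling(cl$center[1] + max(cl$radii) + 1)))
      xr <- seq(max(0, floor(cl$center[2] - max(cl$radii) - 1)),
                min(plane[2] - 1, ceiling(cl$center[2] + max(cl$radii) + 1)))
      g <- expand.grid(y = yr, x = xr)
      dy <- g$y - cl$center[1]; dx <- g$x - cl$center[2]
      ca <- cos(cl$angle); sa <- sin(cl$angle)
      u <- (ca * dy + sa * dx) / cl$radii[1]
      v <- (-sa * dy + ca * dx) / cl$radii[2]
      e2 <- u^2 + v^2
      inside2d <- e2 <= 1
      if (!any(inside2d)) next
      if (nd == 2L) {
        sel <- cbind(g$y[inside2d] + 1L, g$x[inside2d] + 1L)
        d2 <- dy[inside2d]^2 + dx[inside2d]^2
        claim <- d2 < bestd[sel]
        if (any(claim)) {
          s2 <- sel[claim, , drop = FALSE]
          img[s2] <- cl$id
          bestd[s2] <- d2[claim]
        }
      } else {
        zs <- seq(max(0, floor(cl$zc - cl$zr)),
                  min(dims[1] - 1, ceiling(cl$zc + cl$zr)))
        for (z in zs) {
          w2 <- ((z - cl$zc) / cl$zr)^2
          inz <- e2 <= 1 - w2
          if (!any(inz)) next
          sel <- cbind(z + 1L, g$y[inz] + 1L, g$x[inz] + 1L)
          d2 <- dy[inz]^2 + dx[inz]^2 + (z - cl$zc)^2
          claim <- d2 < bestd[sel]
          if (any(claim)) {
            s2 <- sel[claim, , drop = FALSE]
            img[s2] <- cl$id
            bestd[s2] <- d2[claim]
          }
        }
      }
    }
    frames[[t + 1L]] <- img

    inten <- array(0, dim = dims)
    for (cl in cells) {
      if (!cl$alive) next
      inten[img == cl$id] <- cl$intensity
    }
    inten <- gaussian_blur(inten, 1.2)
    raw[[t + 1L]] <- inten + array(rnorm(prod(dims), 0, 6), dim = dims)
  }

  for (cl in cells) if (cl$alive) ends[[as.character(cl$id)]] <- nT - 1L
  ids <- sort(as.integer(names(ends)))
  begins <- vapply(ids, function(i)
    cells[[which(vapply(cells, function(c) c$id, 1L) == i)]]$begin, 1L)
  lineage <- data.frame(label = ids, begin = begins,
                        end = vapply(as.character(ids),
                                     function(i) ends[[i]], 1L),
                        parent = unname(lineage_parent[as.character(ids)]))
  list(raw = raw, gt = labeled_sequence(frames, lineage), config = cfg)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
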