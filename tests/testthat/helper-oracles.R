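# Independent brute-force oracle for small integer programs, plus fixture
# builders shared across the test files. The enumerator explores the full
# integer box with constraint-window and cost-bound pruning; it never calls
# the package's simplex solver.

enumerate_milp <- function(obj, A, dir, rhs, lb = 0, ub,
                           node_limit = 5e7) {
  n <- length(obj)
  A <- as.matrix(A)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  stopifnot(all(is.finite(ub)), all(obj > -1e-12))
  m <- nrow(A)
  eq <- dir %in% c("==", "=")
  le <- dir == "<="
  ge <- dir == ">="
  # suffix min/max attainable contribution per row for variables j..n
  minc <- pmin(A * rep(lb, each = m), A * rep(ub, each = m))
  maxc <- pmax(A * rep(lb, each = m), A * rep(ub, each = m))
  sufmin <- cbind(t(apply(minc, 1, function(v) rev(cumsum(rev(v))))), 0)
  sufmax <- cbind(t(apply(maxc, 1, function(v) rev(cumsum(rev(v))))), 0)

  best <- Inf
  best_x <- NULL
  nodes <- 0L
  x <- numeric(n)

  feasible_window <- function(partial, j) {
    lo <- partial + sufmin[, j + 1L]
    hi <- partial + sufmax[, j + 1L]
    if (any(eq & (rhs < lo - 1e-9 | rhs > hi + 1e-9))) return(FALSE)
    if (any(le & lo > rhs + 1e-9)) return(FALSE)
    if (any(ge & hi < rhs - 1e-9)) return(FALSE)
    TRUE
  }

  rec <- function(j, partial, cost) {
    nodes <<- nodes + 1L
    if (nodes > node_limit) stop("enumeration node limit exceeded")
    if (cost >= best - 1e-9) return()
    if (j > n) {
      if (all(abs(partial[eq] - rhs[eq]) < 1e-9) &&
          all(partial[le] <= rhs[le] + 1e-9) &&
          all(partial[ge] >= rhs[ge] - 1e-9)) {
        best <<- cost
        best_x <<- x
      }
      return()
    }
    for (v in lb[j]:ub[j]) {
      x[j] <<- v
      p2 <- partial + A[, j] * v
      if (feasible_window(p2, j)) rec(j + 1L, p2, cost + obj[j] * v)
    }
    x[j] <<- lb[j]
  }
  rec(1L, numeric(m), 0)
  list(objective = best, solution = best_x, nodes = nodes)
}

# tiny moving-square sequences for matching oracle tests
tiny_sequence <- function(seed, n_frames = 3L, max_obj = 3L,
                          shape = c(26L, 26L)) {
  set.seed(seed)
  n_cells <- sample.int(max_obj, 1L)
  pos <- matrix(0, n_cells, 2)
  for (i in seq_len(n_cells)) {
    repeat {
      p <- round(runif(2, 4, shape - 5))
      if (i == 1 || all(rowSums(abs(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                          2, p))) > 8)) break
    }
    pos[i, ] <- p
  }
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    img <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(n_cells)) {
      c0 <- pmin(pmax(round(pos[i, ] + rnorm(2, 0, 1.2)), 2), shape - 3)
      pos[i, ] <- c0
      img[(c0[1] - 1):(c0[1] + 1) + 1, (c0[2] - 1):(c0[2] + 1) + 1] <- i
    }
    frames[[t]] <- img
  }
  labeled_sequence(frames)
}

# small random lineage-graph fixtures for the untangling oracle
random_track_graph <- function(seed, max_tracks = 6L) {
  set.seed(seed)
  n <- sample(2:max_tracks, 1L)
  dims <- c(40L, 40L)
  tracks <- list()
  for (i in seq_len(n)) {
    b <- sample(0:4, 1L); e <- b + sample(0:4, 1L)
    frames <- b:e
    ctr <- round(runif(2, 6, 33))
    masks <- lapply(frames, function(f) {
      arr <- matrix(FALSE, dims[1], dims[2])
      arr[(ctr[1] - 1):(ctr[1] + 1) + 1, (ctr[2] - 1):(ctr[2] + 1) + 1] <- TRUE
      which(arr)
    })
    tracks[[i]] <- list(id = i, frames = frames,
                        labels = rep(i, length(frames)), masks = masks,
                        preds = integer(), succs = integer())
  }
  # random forward links (predecessor ends before successor begins)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (max(tracks[[i]]$frames) < min(tracks[[j]]$frames) &&
        runif(1) < 0.35) {
      tracks[[i]]$succs <- sort(unique(c(tracks[[i]]$succs, j)))
      tracks[[j]]$preds <- sort(unique(c(tracks[[j]]$preds, i)))
    }
  }
  structure(list(tracks = tracks, dim = dims,
                 n_frames = max(vapply(tracks, function(x) max(x$frames), 1L)) + 1L),
            class = "tracking_graph")
}

# the seven-track example graph: one mother feeding three intermediate
# tracks that all converge on track 5, which has two daughters
untangle_example_graph <- function() {
  dims <- c(64L, 64L)
  mk <- function(ctr, frames) {
    lapply(frames, function(f) {
      arr <- matrix(FALSE, dims[1], dims[2])
      arr[(ctr[1] - 1):(ctr[1] + 1) + 1, (ctr[2] - 1):(ctr[2] + 1) + 1] <- TRUE
      which(arr)
    })
  }
  spec <- list(
    list(id = 1L, frames = 0:1, ctr = c(30, 10), preds = integer(), succs = c(2L, 3L, 4L)),
    list(id = 2L, frames = 2:3, ctr = c(20, 20), preds = 1L, succs = 5L),
    list(id = 3L, frames = 2:3, ctr = c(30, 20), preds = 1L, succs = 5L),
    list(id = 4L, frames = 2:3, ctr = c(40, 20), preds = 1L, succs = 5L),
    list(id = 5L, frames = 4:5, ctr = c(30, 32), preds = c(2L, 3L, 4L), succs = c(6L, 7L)),
    list(id = 6L, frames = 6:7, ctr = c(24, 44), preds = 5L, succs = integer()),
    list(id = 7L, frames = 6:7, ctr = c(36, 44), preds = 5L, succs = integer()))
  tracks <- lapply(spec, function(s)
    list(id = s$id, frames = s$frames, labels = rep(s$id, length(s$frames)),
         masks = mk(s$ctr, s$frames), preds = s$preds, succs = s$succs))
  structure(list(tracks = tracks, dim = dims, n_frames = 8L),
            class = "tracking_graph")
}

# exhaustive untangling oracle: enumerate the problem's own variable box
untangling_oracle <- function(problem) {
  nv <- length(problem$cost)
  if (nv == 0L) return(0)
  enumerate_milp(problem$cost, problem$A, problem$dir, problem$rhs,
                 ub = pmin(problem$ub, 4))$objective
}
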