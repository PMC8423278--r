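#' Solve a (mixed-)integer linear program exactly
#'
#' Minimises `obj %*% x` subject to linear constraints, variable bounds and
#' integrality. The backend is a dense bounded-variable two-phase simplex
#' with depth-first branch and bound; it is exact for the moderately sized
#' models this package builds (a few thousand variables). Both optimization
#' stages of the tracker (the coupled minimum-cost flow matching and the
#' lineage untangling) run on this solver.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param mat constraint matrix (`m x n`), dense.
#' @param dir character vector of constraint directions, one of
#'   `"=="`, `"<="`, `">="` per row.
#' @param rhs numeric right-hand sides (length `m`).
#' @param lb,ub numeric lower/upper variable bounds, recycled to length `n`;
#'   `ub` may contain `Inf`.
#' @param int_vars indices (1-based) of integer-constrained variables, or
#'   `TRUE` for all variables.
#' @param max_nodes branch-and-bound node limit.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"limit"`), `objective` and `solution`.
#' @examples
#' # max x + y s.t. x + 2y <= 4, x, y in {0,1,2}
#' r <- milp_solve(c(-1, -1), rbind(c(1, 2)), "<=", 4, ub = c(2, 2),
#'                 int_vars = TRUE)
#' r$solution
#' @export
milp_solve <- function(obj, mat, dir, rhs, lb = 0, ub = Inf,
                       int_vars = TRUE, max_nodes = 50000L) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  n <- ncol(mat)
  m <- nrow(mat)
  stopifnot(length(obj) == n, length(rhs) == m, length(dir) == m)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)

  sense <- integer(m)
  for (i in seq_len(m)) {
    if (dir[i] == "==" || dir[i] == "=") {
      sense[i] <- 0L
    } else if (dir[i] == "<=") {
      sense[i] <- 1L
    } else if (dir[i] == ">=") {
      mat[i, ] <- -mat[i, ]
      rhs[i] <- -rhs[i]
      sense[i] <- 1L
    } else {
      stop("unknown constraint direction: ", dir[i])
    }
  }

  if (isTRUE(int_vars)) int_vars <- seq_len(n)
  iv <- as.integer(int_vars) - 1L

  res <- .milp_solve_cpp(as.numeric(obj), mat, sense, as.numeric(rhs),
                         lb, ub, iv, as.integer(max_nodes))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "limit", "unknown")
  sol <- as.numeric(res$x)
  if (status == "optimal" && length(iv))
    sol[iv + 1L] <- round(sol[iv + 1L])
  list(status = status, objective = res$objective, solution = sol,
       nodes = res$nodes)
}

# Pure LP interface (used in tests to cross-check relaxations).
#' @rdname milp_solve
#' @export
lp_solve <- function(obj, mat, dir, rhs, lb = 0, ub = Inf) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  n <- ncol(mat)
  m <- nrow(mat)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  sense <- integer(m)
  for (i in seq_len(m)) {
    if (dir[i] == "==" || dir[i] == "=") sense[i] <- 0L
    else if (dir[i] == "<=") sense[i] <- 1L
    else if (dir[i] == ">=") { mat[i, ] <- -mat[i, ]; rhs[i] <- -rhs[i]; sense[i] <- 1L }
    else stop("unknown constraint direction: ", dir[i])
  }
  res <- .lp_solve_cpp(as.numeric(obj), mat, sense, as.numeric(rhs), lb, ub)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "limit", "unknown")
  list(status = status, objective = res$objective, solution = as.numeric(res$x))
}
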