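#' @keywords internal
"_PACKAGE"

# Classed condition helper: every package error carries a specific class
# (e.g. "schema_error") plus the umbrella class "overlapnet_error".
abort_on <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "overlapnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic per-stage seed fan-out from a master seed. Stage indices are
# small; the multiplier keeps distinct (seed, stage) pairs distinct while the
# modulus keeps the result a valid 32-bit R integer.
stage_seed <- function(master_seed, stage_index) {
  as.integer((as.numeric(master_seed) * 1009 + stage_index) %% 2147483647)
}

#' Solve the linear assignment problem
#'
#' Finds the permutation `p` minimizing `sum(cost[i, p[i]])` over all
#' bijections of rows to columns, via the shortest-augmenting-path
#' (Jonker-Volgenant style) algorithm. Used to match subnetworks across
#' models where unit order and sign are arbitrary.
#'
#' @param cost square numeric matrix of assignment costs.
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @examples
#' solve_assignment(matrix(c(1, 2, 2, 1), 2, 2))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost) || anyNA(cost)) {
    abort_on("shape_mismatch_error", "cost must be a square numeric matrix without NAs")
  }
  n <- nrow(cost)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, index 1 = virtual column 0
  p <- integer(n + 1L)     # p[j+1] = row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}

# population-SD z-scoring helpers shared by several modules
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

col_pop_sd <- function(X) {
  mu <- colMeans(X)
  sqrt(colMeans(sweep(X, 2L, mu)^2))
}
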