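# Minimum-cost rectangular assignment (Hungarian algorithm, potential /
# shortest-augmenting-path form, O(n^2 m)). No linear-assignment solver is
# available in the dependency set, so the solver lives here; its optimality
# is pinned against exhaustive enumeration in the test suite.

#' Solve a rectangular linear assignment problem
#'
#' Minimum-total-cost one-to-one assignment of rows to columns. When there
#' are more rows than columns (or vice versa) the surplus stays unassigned.
#' Entries must be finite; use a large sentinel for undesirable cells and
#' filter afterwards (see [solve_assignment()], which handles gating).
#'
#' @param cost numeric matrix of finite costs.
#' @return integer vector of length `nrow(cost)`; element `i` is the column
#'   assigned to row `i`, or `NA` if row `i` is unassigned.
#' @export
solve_lap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  stopifnot(all(is.finite(cost)))
  if (n > m) {
    by_col <- solve_lap(t(cost))
    out <- rep(NA_integer_, n)
    ok <- !is.na(by_col)
    out[by_col[ok]] <- which(ok)
    return(out)
  }
  INF <- Inf
  u <- numeric(n + 1)        # row potentials, u[i + 1] for row i (0 = virtual)
  v <- numeric(m + 1)        # column potentials, v[j + 1] for column j
  p <- integer(m + 1)        # p[j + 1] = row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}
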