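# Minimum-cost assignment (Hungarian algorithm, O(n^3) potentials variant).
# No assignment solver ships with the pre-declared dependencies, so this is a
# self-contained implementation used by data association and MOT matching.

#' Solve a rectangular minimum-cost assignment problem
#'
#' @param cost Numeric cost matrix (rows are workers, columns jobs).
#'   Non-finite entries mark forbidden pairs; a row/column left without any
#'   feasible partner stays unassigned.
#' @return Integer vector of length `nrow(cost)`: for each row, the assigned
#'   column index, or `NA` if the row is unassigned or only a forbidden pair
#'   was available.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost))
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (m == 0L) return(rep(NA_integer_, n))

  finite <- cost[is.finite(cost)]
  big <- if (length(finite) > 0) sum(abs(finite)) + 1 else 1
  a <- cost
  a[!is.finite(a)] <- big

  transposed <- FALSE
  if (nrow(a) > ncol(a)) {
    a <- t(a)
    transposed <- TRUE
  }
  nr <- nrow(a)
  nc <- ncol(a)

  # potentials u (rows, index 0 unused), v (cols incl. virtual col 0)
  u <- numeric(nr + 1L)
  v <- numeric(nc + 1L)
  p <- integer(nc + 1L)   # p[j+1]: row matched to column j (0 = none)
  way <- integer(nc + 1L)

  for (i in seq_len(nr)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, nc + 1L)
    used <- rep(FALSE, nc + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- -1L
      for (j in seq_len(nc)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
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
      for (j in 0:nc) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
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

  match_row <- rep(NA_integer_, nr)  # column assigned to each row of `a`
  for (j in seq_len(nc)) if (p[j + 1L] > 0L) match_row[p[j + 1L]] <- j

  if (transposed) {
    # rows of `a` were the original columns
    out <- rep(NA_integer_, n)
    for (jc in seq_len(nr)) {
      r <- match_row[jc]
      if (!is.na(r)) out[r] <- jc
    }
  } else {
    out <- match_row
  }
  # drop assignments that were only possible through a forbidden entry
  for (i in seq_len(n)) {
    if (!is.na(out[i]) && !is.finite(cost[i, out[i]])) out[i] <- NA_integer_
  }
  out
}
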