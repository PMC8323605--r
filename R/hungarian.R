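#' Minimum-cost rectangular assignment
#'
#' Solves the rectangular linear assignment problem: given an `n x m` cost
#' matrix, finds the one-to-one matching of `min(n, m)` source-target pairs
#' with the smallest total cost (the Kuhn-Munkres problem, solved here with
#' the Jonker-Volgenant shortest augmenting path construction with dual
#' potentials, O(n^2 m)). Among equal-cost optima the matching pairing lower
#' source ids with lower target ids is returned (an infinitesimal
#' lexicographic perturbation breaks ties deterministically).
#'
#' @param cost numeric matrix, entries `>= 0`; `n` and `m` may differ.
#' @return A list with `matches` (two-column integer matrix `[row, col]`,
#'   ordered by row), `unmatched_rows`, `unmatched_cols` and `total_cost`
#'   (sum of the original cost entries over the matching).
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) stop("`cost` must be a matrix", call. = FALSE)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) {
    return(list(matches = matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m),
                total_cost = 0))
  }
  if (any(!is.finite(cost))) stop("`cost` must be finite", call. = FALSE)
  # deterministic tie-break: prefer low (row, col) indices among optima
  eps <- 1e-9 * (max(abs(cost)) + 1) / (n * m + 1)
  pert <- cost + outer(seq_len(n), seq_len(m),
                       function(i, j) ((i - 1) * m + (j - 1))) * eps / (n * m)
  flip <- n > m
  a <- if (flip) t(pert) else pert
  p <- lap_augment(a)                 # p[j] = row matched to column j
  rows <- p[p > 0]
  cols <- which(p > 0)
  if (flip) { tmp <- rows; rows <- cols; cols <- tmp }
  o <- order(rows)
  matches <- cbind(row = as.integer(rows[o]), col = as.integer(cols[o]))
  list(matches = matches,
       unmatched_rows = setdiff(seq_len(n), matches[, "row"]),
       unmatched_cols = setdiff(seq_len(m), matches[, "col"]),
       total_cost = sum(cost[matches]))
}

# shortest augmenting path assignment for an n x m matrix with n <= m;
# returns p, length m, p[j] = matched row of column j (0 = unmatched)
lap_augment <- function(a) {
  n <- nrow(a); m <- ncol(a)
  u <- numeric(n + 1)
  v <- numeric(m + 1)       # v[1] is the virtual column's potential
  p <- integer(m + 1)       # p[j+1] = row matched to column j
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      free <- which(!used[-1])
      cur <- a[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1] <- j0
      jmin <- free[which.min(minv[free])]
      delta <- minv[jmin]
      j1 <- jmin
      usedj <- which(used)            # 1-based positions (col index + 1)
      u[p[usedj] + 1] <- u[p[usedj] + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[which(!used[-1])] <- minv[which(!used[-1])] - delta
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
  p[-1]
}
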