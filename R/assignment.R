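# Optimal bipartite assignment (Hungarian algorithm, Jonker-Volgenant style
# shortest augmenting path, O(n^3)). Used by the tracker to match detections
# between frames; rows in excess of columns (or vice versa) stay unmatched
# through padding with a large finite cost.
#
# cost: numeric matrix (rows = workers, cols = jobs), entries may be Inf for
# forbidden pairs. Returns integer vector a with a[i] = assigned column of
# row i, or NA if row i is matched to a padded (forbidden) column.
solve_assignment <- function(cost) {
  nr0 <- nrow(cost); nc0 <- ncol(cost)
  if (nr0 == 0L || nc0 == 0L) return(rep(NA_integer_, nr0))
  n <- max(nr0, nc0)
  big <- 1e9
  C <- matrix(big, n, n)
  fin <- is.finite(cost)
  C[seq_len(nr0), seq_len(nc0)][fin] <- cost[fin]

  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)       # p[j] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- C[i0, j] - u[i0 + 0L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0L:n) {
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
  a <- rep(NA_integer_, nr0)
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= nr0 && j <= nc0 && is.finite(cost[i, j]))
      a[i] <- j
  }
  a
}
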