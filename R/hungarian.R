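#' Minimum-cost bipartite matching (Hungarian / Kuhn-Munkres algorithm)
#'
#' Solves the rectangular assignment problem: given an `n x m` cost matrix,
#' selects `min(n, m)` entries, at most one per row and one per column,
#' minimising their sum. Implemented as the shortest-augmenting-path form of
#' the Hungarian algorithm with row/column potentials, O(n^2 m) after
#' orienting the matrix so rows are the smaller side. Rectangular matrices
#' are solved natively (no dummy padding).
#'
#' @param cost numeric matrix of finite costs.
#' @return a list with `pairs`, an integer matrix with columns `row`, `col`
#'   (one matched pair per row, `min(n,m)` rows), and `total`, the minimal
#'   sum of matched costs. When several matchings attain the optimum, any
#'   one of them may be returned; only `total` is guaranteed unique.
#' @export
#' @examples
#' hungarian_min_matching(rbind(c(0.1, 0.6), c(0.4, 0.2)))$total  # 0.3
hungarian_min_matching <- function(cost) {
  cost <- as.matrix(cost)
  if (!is.numeric(cost) || !all(is.finite(cost))) {
    stop("cost matrix must be numeric and finite")
  }
  transposed <- nrow(cost) > ncol(cost)
  if (transposed) cost <- t(cost)
  n <- nrow(cost)
  m <- ncol(cost)

  u <- numeric(n)          # row potentials
  v <- numeric(m + 1L)     # column potentials; slot m+1 is the virtual start
  p <- integer(m + 1L)     # p[j]: row currently matched to column j (0 = free)
  way <- integer(m)        # predecessor column on the alternating path

  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      jmin <- free[which.min(minv[free])]
      delta <- minv[jmin]
      usedc <- which(used)
      matched <- usedc[p[usedc] > 0L]
      u[p[matched]] <- u[p[matched]] + delta
      v[usedc] <- v[usedc] - delta
      nf <- seq_len(m)[!used[seq_len(m)]]
      minv[nf] <- minv[nf] - delta
      j0 <- jmin
      if (p[j0] == 0L) break
    }
    # unwind the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == m + 1L) i else p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }

  cols <- which(p[seq_len(m)] > 0L)
  rows <- p[cols]
  total <- sum(cost[cbind(rows, cols)])
  pairs <- if (transposed) cbind(row = cols, col = rows) else cbind(row = rows, col = cols)
  pairs <- pairs[order(pairs[, "row"]), , drop = FALSE]
  list(pairs = pairs, total = total)
}
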