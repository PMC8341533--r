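# Independent oracles used only by tests. These deliberately avoid the
# package's code paths: the spline oracle solves the tridiagonal natural
# cubic-spline system directly, and the simplex oracle sorts all pairwise
# distances with plain R.

# natural cubic spline through (x, y), evaluated at xout
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 3, !is.unsorted(x, strictly = TRUE))
  h <- diff(x)
  # second derivatives M, natural boundaries M[1] = M[n] = 0
  A <- matrix(0, n - 2, n - 2)
  b <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    r <- i - 1
    if (r > 1) A[r, r - 1] <- h[i - 1]
    A[r, r] <- 2 * (h[i - 1] + h[i])
    if (r < n - 2) A[r, r + 1] <- h[i]
    b[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- c(0, solve(A, b), 0)
  vapply(xout, function(xx) {
    i <- findInterval(xx, x, rightmost.closed = TRUE)
    i <- max(1L, min(i, n - 1L))
    t1 <- x[i + 1] - xx; t0 <- xx - x[i]
    (M[i] * t1^3 + M[i + 1] * t0^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t0
  }, numeric(1))
}

# local extrema by sign changes of first differences (independent of the
# package's extrema finder)
oracle_extrema <- function(x) {
  d <- sign(diff(x))
  idx <- which(diff(d) != 0) + 1L
  list(max = idx[d[idx - 1] > 0 & d[idx] < 0],
       min = idx[d[idx - 1] < 0 & d[idx] > 0])
}

# brute-force simplex prediction: all distances, full sort, exponential
# weights, uniform weights over zero-distance neighbors. Returns the
# prediction and the neighbor rows actually used.
brute_simplex_oracle <- function(states, row_times, target_by_row, lib, query,
                                 knn, excl) {
  qt <- row_times[query]
  lib <- lib[abs(row_times[lib] - qt) > excl]
  lib <- lib[!is.na(target_by_row[lib])]
  if (length(lib) < knn) return(list(pred = NA_real_, neighbors = integer(0)))
  d <- sqrt(colSums((t(states[lib, , drop = FALSE]) - states[query, ])^2))
  ord <- order(d, lib)                     # ties broken by row index
  nb <- lib[ord[seq_len(knn)]]
  dn <- d[ord[seq_len(knn)]]
  if (dn[1] == 0) {
    w <- as.numeric(dn == 0)
  } else {
    w <- exp(-dn / dn[1])
  }
  w <- w / sum(w)
  list(pred = sum(w * target_by_row[nb]), neighbors = nb)
}

# AR(1) simulation from an explicit recursion (no stats::filter)
ar1_oracle <- function(n, phi, sd = 1, seed = 1) {
  set.seed(seed)
  e <- rnorm(n, 0, sd)
  x <- numeric(n)
  x[1] <- e[1]
  for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
  x
}

# chaotic logistic map series as an emm_series
logistic_series <- function(n, r = 3.9, x0 = 0.37, name = "logis") {
  x <- numeric(n + 100)
  x[1] <- x0
  for (t in seq_len(n + 99)) x[t + 1] <- r * x[t] * (1 - x[t])
  emm_series(monthly_grid(1973, n), x[101:(n + 100)], name = name)
}

write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
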