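#' Sifting configuration for empirical mode decomposition
#'
#' The stopping rule is the classic Cauchy-type criterion: sifting of one
#' intrinsic mode function (IMF) stops when the normalized squared difference
#' between consecutive sift iterates, `SD = sum((h_prev - h)^2) / sum(h_prev^2)`,
#' falls below `sd_stop_threshold`.
#'
#' @param max_sift_iterations Cap on sift iterations per IMF (default 100).
#' @param sd_stop_threshold Cauchy stopping threshold in (0, 1); 0.2 is the
#'   classic default.
#' @param max_imfs Cap on the number of extracted IMFs (default 12).
#' @param boundary_extension Envelope boundary handling; only `"mirror"`
#'   (reflection of two extrema at each end) is implemented.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(max_sift_iterations = 100L, sd_stop_threshold = 0.2,
                        max_imfs = 12L, boundary_extension = "mirror") {
  stopifnot(max_sift_iterations >= 1, max_imfs >= 1,
            sd_stop_threshold > 0, sd_stop_threshold < 1)
  boundary_extension <- match.arg(boundary_extension, "mirror")
  structure(list(max_sift_iterations = as.integer(max_sift_iterations),
                 sd_stop_threshold = sd_stop_threshold,
                 max_imfs = as.integer(max_imfs),
                 boundary_extension = boundary_extension),
            class = "sift_config")
}

# indices of strict local maxima / minima of a numeric vector
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  left <- x[2:(n - 1)] - x[1:(n - 2)]
  right <- x[2:(n - 1)] - x[3:n]
  list(max = which(left > 0 & right > 0) + 1L,
       min = which(left < 0 & right < 0) + 1L)
}

count_extrema <- function(x) {
  e <- local_extrema(x)
  length(e$max) + length(e$min)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# natural cubic spline envelope through extrema (idx, val), mirror-extended
# by two extrema at each end, evaluated on 1..n
envelope_spline <- function(idx, val, n) {
  k <- length(idx)
  # mirror up to two extrema across each boundary
  nl <- min(2L, k)
  nr <- min(2L, k)
  xl <- 2 - idx[seq_len(nl)]            # reflected about index 1
  yl <- val[seq_len(nl)]
  xr <- 2 * n - idx[k - seq_len(nr) + 1L]  # reflected about index n
  yr <- val[k - seq_len(nr) + 1L]
  xx <- c(xl, idx, xr)
  yy <- c(yl, val, yr)
  ord <- order(xx)
  xx <- xx[ord]; yy <- yy[ord]
  keep <- !duplicated(xx)
  xx <- xx[keep]; yy <- yy[keep]
  stats::spline(xx, yy, xout = seq_len(n), method = "natural")$y
}

#' Mean of the upper and lower extrema envelopes
#'
#' The elementary step of EMD sifting: cubic-spline envelopes through the
#' local maxima and minima of a mirror-extended copy of the signal, cropped
#' back to the original support, averaged pointwise. Returns `NULL` when the
#' signal has fewer than two maxima or two minima (a monotone or
#' near-monotone signal from which nothing further can be sifted).
#'
#' @param signal Numeric vector.
#' @return Numeric vector of the envelope mean, or `NULL`.
#' @export
extrema_envelope_mean <- function(signal) {
  e <- local_extrema(signal)
  if (length(e$max) < 2L || length(e$min) < 2L) return(NULL)
  n <- length(signal)
  upper <- envelope_spline(e$max, signal[e$max], n)
  lower <- envelope_spline(e$min, signal[e$min], n)
  (upper + lower) / 2
}

#' Sift one intrinsic mode function from a signal
#'
#' Iterates `h <- h - extrema_envelope_mean(h)` until the Cauchy criterion
#' drops below `cfg$sd_stop_threshold` or the iteration cap is reached.
#'
#' @param signal Numeric vector.
#' @param cfg A [sift_config()].
#' @return The IMF candidate (numeric vector), or `NULL` when the signal is
#'   monotone / has too few extrema to sift.
#' @export
sift_imf <- function(signal, cfg = sift_config()) {
  h <- signal
  m <- extrema_envelope_mean(h)
  if (is.null(m)) return(NULL)
  for (it in seq_len(cfg$max_sift_iterations)) {
    h1 <- h - m
    sd_stat <- sum((h - h1)^2) / sum(h^2)
    h <- h1
    if (sd_stat < cfg$sd_stop_threshold) break
    m <- extrema_envelope_mean(h)
    if (is.null(m)) break
  }
  h
}

#' Empirical mode decomposition of a regularized series
#'
#' Repeatedly sifts IMFs from the running residual until the residual is
#' monotone or has fewer than 3 extrema, or `cfg$max_imfs` is reached. IMF 1
#' is the highest-frequency mode; the residual carries the nonlinear trend.
#' Completeness holds by construction: the IMFs and residual sum back to the
#' source signal to floating-point accuracy.
#'
#' @param ts A regularized [emm_series()] of length >= 32 with no gaps.
#' @param cfg A [sift_config()].
#' @return An object of class `emm_imfset` with fields `source` (the input
#'   series), `imfs` (list of numeric vectors, index 1 = highest frequency)
#'   and `residual`.
#' @export
emm_decompose <- function(ts, cfg = sift_config()) {
  assert_series(ts)
  x <- ts$values
  if (anyNA(x)) stop("series has gaps; regularize first", call. = FALSE)
  if (length(x) < 32L) stop("need length >= 32 for decomposition", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant series cannot be decomposed", call. = FALSE)
  imfs <- list()
  r <- x
  while (length(imfs) < cfg$max_imfs && count_extrema(r) >= 3L) {
    imf <- sift_imf(r, cfg)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- imf
    r <- r - imf
  }
  structure(list(source = ts, imfs = imfs, residual = r),
            class = "emm_imfset")
}

#' @export
print.emm_imfset <- function(x, ...) {
  cat(sprintf("<emm_imfset> %s: %d IMFs + residual (n = %d)\n",
              x$source$name, length(x$imfs), length(x$source$times)))
  invisible(x)
}

#' Mean period of an oscillatory mode via the Hilbert transform
#'
#' Computes the analytic signal by the frequency-domain Hilbert transform,
#' unwraps its phase, differentiates to instantaneous frequency, and averages
#' over the interior of the record (trimming 5% at each end against edge
#' artifacts). The mean period is the reciprocal of the mean instantaneous
#' frequency — not the mean of instantaneous periods.
#'
#' @param imf Numeric vector, oscillatory (at least 2 zero crossings).
#' @param dt Sampling interval in years (1/12 for monthly data).
#' @return Mean period in years.
#' @export
mean_period <- function(imf, dt = 1 / 12) {
  if (count_zero_crossings(imf) < 2L) {
    stop("signal is not oscillatory (fewer than 2 zero crossings)", call. = FALSE)
  }
  n <- length(imf)
  X <- stats::fft(imf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(analytic)
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))  # unwrap increments to (-pi, pi]
  inst_freq <- dph / (2 * pi * dt)             # cycles per year
  trim <- max(1L, floor(0.05 * length(inst_freq)))
  interior <- inst_freq[(trim + 1):(length(inst_freq) - trim)]
  f_mean <- mean(interior)
  if (!is.finite(f_mean) || f_mean <= 0) {
    stop("mean instantaneous frequency is not positive", call. = FALSE)
  }
  1 / f_mean
}

#' Classify IMFs into time-scale bands by Hilbert mean period
#'
#' Band boundaries: sub-annual below 0.5 yr; intra-annual for mean periods
#' between 0.5 and 2 years; interannual for periods greater than 3 years.
#' Periods falling in the 2-3 yr gap between the two definitions are labeled
#' `unclassified-gap` rather than forced into either band. The residual is
#' always labeled `trend`.
#'
#' @param imfset An [emm_decompose()] result.
#' @param dt Sampling interval in years.
#' @return A data frame with columns `component`, `imf_index`,
#'   `mean_period_years`, `band`.
#' @export
classify_imfs <- function(imfset, dt = 1 / 12) {
  stopifnot(inherits(imfset, "emm_imfset"))
  k <- length(imfset$imfs)
  periods <- vapply(imfset$imfs, function(im) {
    tryCatch(mean_period(im, dt), error = function(e) NA_real_)
  }, numeric(1))
  data.frame(
    component = c(sprintf("imf%d", seq_len(k)), "residual"),
    imf_index = c(seq_len(k), NA_integer_),
    mean_period_years = c(periods, NA_real_),
    band = c(vapply(periods, classify_period, character(1)), "trend"),
    stringsAsFactors = FALSE
  )
}

#' Band label for a mean period
#'
#' @param period_years Mean period in years (may be `NA`).
#' @return One of `"sub-annual"`, `"intra-annual"`, `"unclassified-gap"`,
#'   `"interannual"`, or `NA` for a non-oscillatory mode.
#' @export
classify_period <- function(period_years) {
  if (is.na(period_years)) return(NA_character_)
  if (period_years < 0.5) "sub-annual"
  else if (period_years <= 2) "intra-annual"
  else if (period_years <= 3) "unclassified-gap"
  else "interannual"
}

#' Sum selected IMFs (optionally plus the residual) into a band series
#'
#' @param imfset An [emm_decompose()] result.
#' @param indices Integer vector of IMF indices to sum; may be empty.
#' @param include_residual Add the residual (nonlinear trend) to the sum?
#' @param name Label for the output series.
#' @return An [emm_series()] on the source time grid.
#' @export
reconstruct_band <- function(imfset, indices, include_residual = FALSE,
                             name = NULL) {
  stopifnot(inherits(imfset, "emm_imfset"))
  k <- length(imfset$imfs)
  indices <- as.integer(indices)
  if (length(indices) > 0 && (any(indices < 1L) || any(indices > k))) {
    stop(sprintf("IMF index out of range 1..%d", k), call. = FALSE)
  }
  v <- numeric(length(imfset$source$times))
  for (i in indices) v <- v + imfset$imfs[[i]]
  if (include_residual) v <- v + imfset$residual
  if (is.null(name)) {
    name <- sprintf("%s_band[%s%s]", imfset$source$name,
                    paste(indices, collapse = ","),
                    if (include_residual) "+res" else "")
  }
  emm_series(imfset$source$times, v, name = name, units = imfset$source$units)
}

#' Remove the highest-frequency IMF (low-pass filter)
#'
#' Subtracting IMF 1 from the source acts as a data-adaptive low-pass filter
#' removing the fastest, noisiest mode.
#'
#' @param imfset An [emm_decompose()] result with at least 2 IMFs.
#' @return An [emm_series()]: source minus IMF 1.
#' @export
remove_highest_frequency_imf <- function(imfset) {
  stopifnot(inherits(imfset, "emm_imfset"))
  if (length(imfset$imfs) < 2L) {
    stop("need at least 2 IMFs to remove the highest-frequency one", call. = FALSE)
  }
  src <- imfset$source
  emm_series(src$times, src$values - imfset$imfs[[1]],
             name = paste0(src$name, "_lowpass"), units = src$units)
}

#' Tidy table of a decomposition
#'
#' One row per (time, component), components `imf1..imfK` and `residual` —
#' the long format behind decomposition panel plots.
#'
#' @param imfset An [emm_decompose()] result.
#' @return A data frame with columns `time`, `component`, `value`.
#' @export
imfset_to_table <- function(imfset) {
  stopifnot(inherits(imfset, "emm_imfset"))
  k <- length(imfset$imfs)
  comps <- c(imfset$imfs, list(imfset$residual))
  labels <- c(sprintf("imf%d", seq_len(k)), "residual")
  tt <- imfset$source$times
  data.frame(
    time = rep(tt, length(comps)),
    component = rep(labels, each = length(tt)),
    value = unlist(comps),
    stringsAsFactors = FALSE
  )
}
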