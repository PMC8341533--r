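## Synthetic fixtures: a mechanistic coupled-map benchmark for CCM
## directionality, and an additive structural emulator with the statistical
## anatomy of monthly production/nutrient records (slow nonlinear trend,
## strong annual cycle, weak interannual oscillation, AR(1) noise,
## unidirectional driver -> response coupling, irregular station sampling).

#' Unidirectionally coupled logistic-map pair
#'
#' The canonical CCM benchmark: two chaotic logistic maps,
#' `X[t+1] = X[t] (r_x - r_x X[t] - beta_xy Y[t])` and
#' `Y[t+1] = Y[t] (r_y - r_y Y[t] - beta_yx X[t])`. With the defaults
#' (`beta_yx = 0.32`, `beta_xy = 0`) X forces Y and not conversely, so CCM
#' should converge in direction `Y:X` (states of Y predict X) and not in
#' `X:Y`.
#'
#' @param n Length after burn-in.
#' @param r_x,r_y Growth rates (chaotic regime defaults 3.8 and 3.5).
#' @param beta_xy Coupling of Y into X's equation (default 0).
#' @param beta_yx Coupling of X into Y's equation (default 0.32).
#' @param burn_in Discarded initial iterations (>= 100).
#' @param seed Integer seed for the initial conditions.
#' @return A list with [emm_series()] elements `X` and `Y` on a monthly
#'   decimal-year grid.
#' @export
coupled_logistic_pair <- function(n = 1000L, r_x = 3.8, r_y = 3.5,
                                  beta_xy = 0, beta_yx = 0.32,
                                  burn_in = 300L, seed = 1L) {
  n <- as.integer(n); burn_in <- as.integer(burn_in)
  stopifnot(n >= 10L, burn_in >= 100L)
  total <- n + burn_in
  x <- numeric(total); y <- numeric(total)
  init <- with_seed(seed, stats::runif(2, 0.2, 0.8))
  x[1] <- init[1]; y[1] <- init[2]
  for (t in seq_len(total - 1L)) {
    x[t + 1L] <- x[t] * (r_x - r_x * x[t] - beta_xy * y[t])
    y[t + 1L] <- y[t] * (r_y - r_y * y[t] - beta_yx * x[t])
    if (x[t + 1L] <= 0 || x[t + 1L] >= 1 || y[t + 1L] <= 0 || y[t + 1L] >= 1) {
      stop(sprintf("trajectory left (0, 1) at step %d; parameters outside the valid regime",
                   t + 1L), call. = FALSE)
    }
  }
  keep <- (burn_in + 1L):total
  tt <- monthly_grid(1973, n)
  list(X = emm_series(tt, x[keep], name = "X"),
       Y = emm_series(tt, y[keep], name = "Y"))
}

#' Configuration for the structural emulator
#'
#' Defaults emulate a ~47.5-year monthly record (570 points): a slow
#' logistic-growth trend, a strong annual cycle, a weak interannual
#' oscillation (60-month period), and AR(1) noise with lag-1 coefficient
#' 0.8. With noise-dominated settings the driver's lag-1 autocorrelation
#' sits in the 0.7-0.9 regime typical of the monthly production and
#' nutrient records this package targets.
#'
#' @param n_months Record length in months (>= 120; default 570).
#' @param coupling Coupling strength `c` of the lagged driver into the
#'   response (default 0.6; 0 = uncoupled null).
#' @param coupling_lag Lag in months at which the driver enters the
#'   response (default 1).
#' @param trend_amplitude Asymptotic rise of the logistic trend (default 2,
#'   in units of the noise scale).
#' @param trend_rate Logistic growth rate per year (default 0.15).
#' @param trend_midpoint Decimal-year midpoint of the trend (default mid-span).
#' @param seasonal_amplitude_driver,seasonal_amplitude_response Annual-cycle
#'   amplitudes (defaults 1 and 0.8).
#' @param interannual_amplitude Amplitude of the slow oscillation (default 0.8).
#' @param interannual_period_months Period of the slow oscillation (default 60).
#' @param ar1_phi AR(1) coefficient of the noise (default 0.8).
#' @param noise_sd Standard deviation of the AR(1) innovations (default 0.1).
#' @param seasonal_phase,interannual_phase Phase offsets in radians of the
#'   annual and interannual cycles (defaults 0).
#' @param start_year First grid point (default 1973.0).
#' @param seed Integer seed.
#' @return A list of class `emulator_config`.
#' @export
emulator_config <- function(n_months = 570L, coupling = 0.6,
                            coupling_lag = 1L,
                            trend_amplitude = 2, trend_rate = 0.15,
                            trend_midpoint = NULL,
                            seasonal_amplitude_driver = 1,
                            seasonal_amplitude_response = 0.8,
                            interannual_amplitude = 0.8,
                            interannual_period_months = 60,
                            ar1_phi = 0.8, noise_sd = 0.1,
                            seasonal_phase = 0, interannual_phase = 0,
                            start_year = 1973, seed = 1L) {
  n_months <- as.integer(n_months)
  stopifnot(n_months >= 120L, coupling >= 0,
            seasonal_amplitude_driver >= 0, seasonal_amplitude_response >= 0,
            interannual_amplitude >= 0, abs(ar1_phi) < 1, noise_sd >= 0)
  if (is.null(trend_midpoint)) trend_midpoint <- start_year + n_months / 24
  structure(list(n_months = n_months, coupling = coupling,
                 coupling_lag = as.integer(coupling_lag),
                 trend_amplitude = trend_amplitude, trend_rate = trend_rate,
                 trend_midpoint = trend_midpoint,
                 seasonal_amplitude_driver = seasonal_amplitude_driver,
                 seasonal_amplitude_response = seasonal_amplitude_response,
                 interannual_amplitude = interannual_amplitude,
                 interannual_period_months = interannual_period_months,
                 ar1_phi = ar1_phi, noise_sd = noise_sd,
                 seasonal_phase = seasonal_phase,
                 interannual_phase = interannual_phase,
                 start_year = start_year, seed = as.integer(seed)),
            class = "emulator_config")
}

# AR(1) with innovations sd sigma, drawn from the current RNG
ar1_noise <- function(n, phi, sigma) {
  e <- stats::rnorm(n, 0, sigma)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

logistic_trend <- function(t, amplitude, rate, midpoint) {
  amplitude / (1 + exp(-rate * (t - midpoint)))
}

#' Coupled driver/response emulator pair
#'
#' `driver = logistic trend + annual sinusoid + interannual sinusoid +
#' AR(1) noise`; `response = own logistic trend + c * driver(t - lag) +
#' annual sinusoid + AR(1) noise`. The causal direction is driver ->
#' response by construction. The designed components are attached as the
#' `"components"` attribute for recovery checks.
#'
#' @param cfg An [emulator_config()].
#' @return A list with [emm_series()] elements `driver` and `response`.
#' @export
emm_emulator_pair <- function(cfg = emulator_config()) {
  stopifnot(inherits(cfg, "emulator_config"))
  n <- cfg$n_months
  lag <- cfg$coupling_lag
  tt_ext <- monthly_grid(cfg$start_year - lag / 12, n + lag)
  tt <- tt_ext[(lag + 1L):(n + lag)]
  with_seed(cfg$seed, {
    trend_d <- logistic_trend(tt_ext, cfg$trend_amplitude, cfg$trend_rate,
                              cfg$trend_midpoint)
    seas_d <- cfg$seasonal_amplitude_driver *
      sin(2 * pi * tt_ext + cfg$seasonal_phase)
    inter_d <- cfg$interannual_amplitude *
      sin(2 * pi * tt_ext * 12 / cfg$interannual_period_months +
            cfg$interannual_phase)
    noise_d <- ar1_noise(n + lag, cfg$ar1_phi, cfg$noise_sd)
    driver_ext <- trend_d + seas_d + inter_d + noise_d

    # response: its own (slightly offset) trend, phase-shifted annual cycle,
    # the lagged driver, its own AR(1) noise
    trend_r <- logistic_trend(tt, 0.8 * cfg$trend_amplitude,
                              cfg$trend_rate, cfg$trend_midpoint + 1)
    seas_r <- cfg$seasonal_amplitude_response *
      sin(2 * pi * tt + cfg$seasonal_phase + pi / 6)
    noise_r <- ar1_noise(n, cfg$ar1_phi, cfg$noise_sd)
    lagged_driver <- driver_ext[seq_len(n)]   # driver at t - lag
    response_v <- trend_r + cfg$coupling * lagged_driver + seas_r + noise_r

    driver <- emm_series(tt, driver_ext[(lag + 1L):(n + lag)], name = "driver")
    response <- emm_series(tt, response_v, name = "response")
    attr(driver, "components") <- list(
      trend = trend_d[(lag + 1L):(n + lag)],
      seasonal = seas_d[(lag + 1L):(n + lag)],
      interannual = inter_d[(lag + 1L):(n + lag)])
    attr(response, "components") <- list(trend = trend_r, seasonal = seas_r,
                                         lagged_driver = lagged_driver)
    list(driver = driver, response = response)
  })
}

#' Independent emulator pair (the hard null)
#'
#' Two independent emulator realizations with zero coupling that share the
#' annual seasonal *period* but nothing else: each member draws its own
#' seasonal phase, interannual phase/period jitter, trend midpoint, and
#' noise. This is the null against which seasonal spectra and
#' autocorrelation could be mistaken for causality if the exclusion radius
#' were absent.
#'
#' @param cfg An [emulator_config()]; its `coupling` is forced to 0 and its
#'   phases/trend midpoint are re-drawn per member from `cfg$seed`.
#' @return A list with independent [emm_series()] elements `driver` and
#'   `response`.
#' @export
null_pair <- function(cfg = emulator_config()) {
  stopifnot(inherits(cfg, "emulator_config"))
  span_yr <- cfg$n_months / 12
  draws <- with_seed(cfg$seed, {
    list(phases = stats::runif(4, 0, 2 * pi),
         midpoints = cfg$start_year + stats::runif(2, 0.25, 0.75) * span_yr,
         seeds = sample.int(.Machine$integer.max - 10L, 2))
  })
  member <- function(i) {
    ci <- cfg
    ci$coupling <- 0
    ci$seasonal_phase <- draws$phases[i]
    ci$interannual_phase <- draws$phases[i + 2]
    ci$trend_midpoint <- draws$midpoints[i]
    ci$seed <- draws$seeds[i]
    emm_emulator_pair(ci)$driver
  }
  a <- member(1)
  b <- member(2)
  b$name <- "response"
  list(driver = a, response = b)
}

#' Sample a series as multiple irregular stations
#'
#' Emulates a multi-station monitoring record: each station is a copy of the
#' input sampled with random gaps, jittered sampling dates, and independent
#' station noise.
#'
#' @param ts An [emm_series()].
#' @param n_stations Number of stations (default 5).
#' @param gap_fraction Probability a station misses a time (in \[0, 0.9\]).
#' @param jitter_days Uniform jitter of sampling dates, in days (kept below
#'   half the monthly spacing).
#' @param noise_sd Standard deviation of independent station noise
#'   (default 0, i.e. noise-free copies).
#' @param seed Integer seed.
#' @return An [emm_station_set()].
#' @export
irregular_station_sampler <- function(ts, n_stations = 5L, gap_fraction = 0.3,
                                      jitter_days = 10, noise_sd = 0,
                                      seed = 1L) {
  assert_series(ts)
  stopifnot(gap_fraction >= 0, gap_fraction <= 0.9, n_stations >= 1,
            jitter_days >= 0, jitter_days < 15, noise_sd >= 0)
  n <- length(ts$times)
  with_seed(seed, {
    stations <- lapply(seq_len(n_stations), function(s) {
      keep <- stats::runif(n) >= gap_fraction
      if (sum(keep) < 4L) keep[sample.int(n, 4L)] <- TRUE
      jit <- stats::runif(n, -jitter_days, jitter_days) / 365.25
      noise <- stats::rnorm(n, 0, noise_sd)
      tt <- (ts$times + jit)[keep]
      ord <- order(tt)
      emm_series(tt[ord], (ts$values + noise)[keep][ord],
                 name = sprintf("L%03d", s), units = ts$units)
    })
    emm_station_set(stations)
  })
}
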