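# two-tone fixture shared across EMD tests: periods 6 and 40 samples
two_tone <- function(n = 570, a_fast = 1, a_slow = 1) {
  t <- seq_len(n)
  list(t = t,
       fast = a_fast * sin(2 * pi * t / 6),
       slow = a_slow * sin(2 * pi * t / 40))
}

test_that("envelope mean vanishes for a pure sinusoid and follows offsets", {
  x <- sin(2 * pi * seq_len(400) / 20)
  m <- extrema_envelope_mean(x)
  interior <- 40:360
  expect_lt(max(abs(m[interior])), 0.05)

  m2 <- extrema_envelope_mean(x + 3)
  expect_lt(max(abs(m2[interior] - 3)), 0.05)
})

test_that("envelope mean tracks the slow component of a two-tone signal", {
  tt <- two_tone(400)
  x <- tt$fast + tt$slow
  m <- extrema_envelope_mean(x)

  # independent oracle: natural-spline envelopes through independently
  # located extrema, no mirror extension (interior comparison only)
  e <- oracle_extrema(x)
  up <- natural_spline_oracle(e$max, x[e$max], tt$t)
  lo <- natural_spline_oracle(e$min, x[e$min], tt$t)
  oracle <- (up + lo) / 2
  interior <- 40:360
  rms <- sqrt(mean((m[interior] - oracle[interior])^2))
  expect_lt(rms, 0.05 * 1)  # < 5% of the slow amplitude

  # and the envelope mean is closer to the slow tone than to zero
  expect_gt(cor(m[interior], tt$slow[interior]), 0.95)
})

test_that("sifting extracts the fast mode and refuses monotone input", {
  x1 <- sin(2 * pi * seq_len(300) / 12)
  imf <- sift_imf(x1)
  expect_gt(cor(imf, x1), 0.99)

  tt <- two_tone(570)
  imf1 <- sift_imf(tt$fast + tt$slow)
  p <- mean_period(imf1, dt = 1)   # dt = 1 sample -> period in samples
  expect_lt(abs(p - 6) / 6, 0.10)

  expect_null(sift_imf(seq(0, 1, length.out = 100)))
  expect_null(extrema_envelope_mean(seq(0, 1, length.out = 100)))
})

test_that("decomposition is complete and recovers a designed trend", {
  tt <- two_tone(570)
  quad <- 3 * (tt$t / 570 - 0.4)^2
  ts <- emm_series(monthly_grid(1973, 570), tt$fast + tt$slow + quad)
  dec <- emm_decompose(ts)
  expect_gte(length(dec$imfs), 2)

  recon <- Reduce(`+`, dec$imfs) + dec$residual
  expect_lt(max(abs(recon - ts$values)) / max(abs(ts$values)), 1e-8)

  expect_gt(cor(dec$residual, quad), 0.99)
})

test_that("IMFs satisfy the extrema / zero-crossing oscillation property", {
  set.seed(21)
  ts <- emm_series(monthly_grid(1973, 512), rnorm(512))
  dec <- emm_decompose(ts)
  for (imf in dec$imfs) {
    n_ext <- length(oracle_extrema(imf)$max) + length(oracle_extrema(imf)$min)
    n_zc <- sum(diff(sign(imf[imf != 0])) != 0)
    expect_lte(abs(n_ext - n_zc), 2)  # unit slack plus boundary slack
  }
})

test_that("white-noise IMF mean periods increase with index (dyadic filter)", {
  set.seed(9)
  ts <- emm_series(monthly_grid(1973, 512), rnorm(512))
  dec <- emm_decompose(ts)
  periods <- vapply(dec$imfs, function(im) {
    tryCatch(mean_period(im, dt = 1), error = function(e) NA_real_)
  }, numeric(1))
  periods <- periods[!is.na(periods)]
  expect_gte(length(periods), 4)
  expect_true(all(diff(periods) > 0))
})

test_that("Hilbert mean period is accurate for tones and bounded for chirps", {
  n <- 480  # 40 years monthly
  t <- seq_len(n)
  expect_equal(mean_period(sin(2 * pi * t / 12), dt = 1 / 12), 1,
               tolerance = 0.05)
  expect_equal(mean_period(sin(2 * pi * t / 40), dt = 1 / 12), 40 / 12,
               tolerance = 0.05)

  # linear chirp, period 8 -> 4 samples: mean period strictly inside (4, 8)
  f0 <- 1 / 8; f1 <- 1 / 4
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * n))
  p <- mean_period(sin(phase), dt = 1)
  expect_gt(p, 4); expect_lt(p, 8)

  expect_error(mean_period(seq_len(50), dt = 1), "oscillatory")
})

test_that("band classification follows the period boundaries", {
  expect_identical(classify_period(1.0), "intra-annual")
  expect_identical(classify_period(5.0), "interannual")
  expect_identical(classify_period(2.5), "unclassified-gap")
  expect_identical(classify_period(0.3), "sub-annual")
  expect_identical(classify_period(0.5), "intra-annual")
  expect_identical(classify_period(2.0), "intra-annual")
  expect_identical(classify_period(3.0), "unclassified-gap")
  expect_identical(classify_period(3.0001), "interannual")

  # tones strictly inside each band: 12 months (intra-annual, 1 yr) and
  # 40 months (interannual, 3.33 yr)
  t <- seq_len(570)
  ts <- emm_series(monthly_grid(1973, 570),
                   sin(2 * pi * t / 12) + sin(2 * pi * t / 40))
  cls <- classify_imfs(emm_decompose(ts))
  expect_identical(cls$band[nrow(cls)], "trend")
  expect_true(all(c("component", "imf_index", "mean_period_years", "band")
                  %in% names(cls)))
  expect_true("intra-annual" %in% cls$band)
  expect_true("interannual" %in% cls$band)
})

test_that("band reconstruction sums the selected IMFs", {
  tt <- two_tone(570)
  ts <- emm_series(monthly_grid(1973, 570), tt$fast + tt$slow)
  dec <- emm_decompose(ts)

  full <- reconstruct_band(dec, seq_along(dec$imfs), include_residual = TRUE)
  expect_lt(max(abs(full$values - ts$values)) / max(abs(ts$values)), 1e-8)

  none <- reconstruct_band(dec, integer(0))
  expect_equal(none$values, rep(0, 570))

  cls <- classify_imfs(dec)
  slow_idx <- cls$imf_index[!is.na(cls$band) & cls$band == "interannual"]
  slow <- reconstruct_band(dec, slow_idx)
  expect_gt(cor(slow$values, tt$slow), 0.95)

  expect_error(reconstruct_band(dec, 99), "out of range")
})

test_that("removing the highest-frequency IMF low-pass filters the series", {
  tt <- two_tone(570)
  set.seed(14)
  clean <- tt$slow
  noisy <- clean + 0.4 * tt$fast + 0.1 * rnorm(570)
  ts <- emm_series(monthly_grid(1973, 570), noisy)
  dec <- emm_decompose(ts)
  lp <- remove_highest_frequency_imf(dec)
  expect_gt(cor(lp$values, clean), cor(noisy, clean))

  # algebraic identity with reconstruct_band over indices 2..K plus residual
  alt <- reconstruct_band(dec, seq(2, length(dec$imfs)), include_residual = TRUE)
  expect_equal(lp$values, alt$values, tolerance = 1e-10)

  one <- structure(list(source = ts, imfs = dec$imfs[1], residual = ts$values -
                          dec$imfs[[1]]), class = "emm_imfset")
  expect_error(remove_highest_frequency_imf(one), "at least 2")
})

test_that("decomposition errors on constant or gapped input", {
  expect_error(emm_decompose(emm_series(monthly_grid(1973, 64), rep(1, 64))),
               "constant")
  expect_error(emm_decompose(emm_series(monthly_grid(1973, 64),
                                        c(rnorm(63), NA))), "gaps")
  expect_error(emm_decompose(emm_series(monthly_grid(1973, 10), rnorm(10))),
               "length")
})

test_that("the tidy IMF table is long-format and complete", {
  tt <- two_tone(120)
  ts <- emm_series(monthly_grid(1973, 120), tt$fast + tt$slow)
  dec <- emm_decompose(ts)
  tab <- imfset_to_table(dec)
  expect_identical(names(tab), c("time", "component", "value"))
  expect_equal(nrow(tab), 120 * (length(dec$imfs) + 1))
  back <- tapply(tab$value, tab$time, sum)
  expect_equal(as.numeric(back), ts$values, tolerance = 1e-8)
})
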