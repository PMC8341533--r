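test_that("time-delay embedding lays out lagged coordinates", {
  tt <- monthly_grid(1973, 5)
  x <- emm_series(tt, 1:5)
  e1 <- time_delay_embed(x, embedding_config(E = 1, exclusion_radius = 0))
  expect_equal(as.numeric(e1$states), 1:5)

  e2 <- time_delay_embed(x, embedding_config(E = 2, tau = 1))
  expect_equal(unname(e2$states),
               matrix(c(2, 1, 3, 2, 4, 3, 5, 4), ncol = 2, byrow = TRUE))
  expect_equal(e2$row_times, 2:5)

  y <- emm_series(monthly_grid(1973, 10), rnorm(10))
  e3 <- time_delay_embed(y, embedding_config(E = 3, tau = 2))
  expect_equal(nrow(e3$states), 6)

  expect_error(time_delay_embed(x, embedding_config(E = 5, tau = 2)),
               "too short")
})

test_that("simplex predictions match the brute-force oracle exactly", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(20:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    for (E in 1:3) {
      for (excl in c(0L, 2L)) {
        cfg <- embedding_config(E = E, tau = 1, exclusion_radius = excl)
        ts <- emm_series(seq_len(n), x)
        emb <- time_delay_embed(ts, cfg)
        tgt <- y[emb$row_times]
        nr <- nrow(emb$states)
        lib <- sort(sample(nr, max(cfg$knn + 4, nr - 3)))
        for (q in seq_len(nr)) {
          oracle <- brute_simplex_oracle(emb$states, emb$row_times, tgt,
                                         lib, q, cfg$knn, excl)
          got <- emmod:::cpp_simplex_predict(emb$states, emb$row_times, tgt,
                                             lib, q, cfg$knn, excl)
          if (is.na(oracle$pred)) {
            expect_true(is.na(got))
          } else {
            expect_equal(got, oracle$pred, tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("zero-distance neighbors share uniform weight (duplicate states)", {
  # series with an exact repeat: rows of the embedding coincide
  x <- c(1, 5, 2, 7, 1, 5, 2, 7, 3, 8, 4, 6, 2, 9, 1, 5, 2, 7, 4, 3)
  y <- rnorm(20)
  cfg <- embedding_config(E = 2, tau = 1, exclusion_radius = 0)
  ts <- emm_series(seq_len(20), x)
  emb <- time_delay_embed(ts, cfg)
  tgt <- y[emb$row_times]
  nr <- nrow(emb$states)
  for (q in seq_len(nr)) {
    oracle <- brute_simplex_oracle(emb$states, emb$row_times, tgt,
                                   seq_len(nr), q, cfg$knn, 0L)
    got <- emmod:::cpp_simplex_predict(emb$states, emb$row_times, tgt,
                                       seq_len(nr), q, cfg$knn, 0L)
    expect_equal(got, oracle$pred, tolerance = 1e-12)
  }

  # a query whose state is duplicated in the library, target = source
  # coordinate: the zero-distance rule returns the duplicate's value exactly
  tgt_self <- emb$states[, 1]
  q <- 5L  # state (1, 5)... duplicated at rows 1 and 15 of the embedding
  dup_rows <- which(emb$states[, 1] == emb$states[q, 1] &
                      emb$states[, 2] == emb$states[q, 2])
  expect_gte(length(dup_rows), 2)
  p <- simplex_cross_map(emb, emm_series(seq_len(20), x), seq_len(nr), q,
                         cfg)
  expect_equal(p, x[emb$row_times[q]], tolerance = 1e-12)
})

test_that("the exclusion radius bars all temporally close neighbors", {
  set.seed(33)
  n <- 100
  ts <- emm_series(seq_len(n), rnorm(n))
  cfg <- embedding_config(E = 2, tau = 1, exclusion_radius = 12)
  emb <- time_delay_embed(ts, cfg)
  nr <- nrow(emb$states)
  W <- emmod:::cpp_simplex_weights(emb$states, emb$row_times, seq_len(nr),
                                   seq_len(nr), cfg$knn, cfg$exclusion_radius)
  for (q in seq_len(nr)) {
    banned <- which(abs(emb$row_times - emb$row_times[q]) <= 12)
    expect_true(all(W[q, banned] == 0 | is.na(W[q, banned])))
  }
  # an over-wide radius leaves no eligible neighbors
  expect_error(
    simplex_cross_map(emb, ts, seq_len(nr), 5L,
                      embedding_config(E = 2, exclusion_radius = n)),
    "library too small")
})

test_that("cross-map skill: self-prediction is near-perfect, noise is not", {
  X <- logistic_series(500, name = "X")
  cfg0 <- embedding_config(E = 2, exclusion_radius = 0)
  expect_gt(cross_map_skill(X, X, NULL, cfg0), 0.95)

  set.seed(35)
  noise <- emm_series(X$times, rnorm(500), name = "noise")
  expect_lt(abs(cross_map_skill(X, noise, NULL, cfg0)), 0.15)

  const <- emm_series(X$times, rep(0.5, 500), name = "const")
  expect_warning(sk <- cross_map_skill(X, const, NULL, cfg0), "degenerate")
  expect_true(is.na(sk))
})

test_that("skill is invariant under affine rescaling and bounded", {
  X <- logistic_series(300, name = "X")
  Y <- logistic_series(300, r = 3.7, x0 = 0.52, name = "Y")
  cfg <- embedding_config(E = 2, exclusion_radius = 5)
  s1 <- cross_map_skill(X, Y, NULL, cfg)
  X2 <- emm_series(X$times, 10 * X$values - 4, name = "X")
  Y2 <- emm_series(Y$times, -2 * Y$values + 7, name = "Y")
  s2 <- cross_map_skill(X2, Y2, NULL, cfg)
  # affine maps preserve neighbor ORDER only if positive scale on X; the
  # correlation-based skill flips sign with the Y scale
  expect_equal(abs(s2), abs(s1), tolerance = 1e-10)
  expect_lte(abs(s1), 1)
})

test_that("ccm_sweep is deterministic and symmetric for identical series", {
  X <- logistic_series(200, name = "X")
  cfg <- embedding_config(E = 2, exclusion_radius = 0)
  sizes <- c(10, 30, 60, 120, 198)
  r1 <- ccm_sweep(X, X, cfg, sizes, subsamples = 5, seed = 99)
  r2 <- ccm_sweep(X, X, cfg, sizes, subsamples = 5, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$skill > 0.8))
  expect_identical(r1$direction, "X:X")
  expect_error(ccm_sweep(X, X, cfg, c(2, 50), subsamples = 2), "E \\+ 2")
  expect_error(ccm_sweep(X, X, cfg, c(10, 1e5), subsamples = 2), "exceeds")
})

test_that("CCM detects the causal direction of a coupled logistic pair", {
  pair <- coupled_logistic_pair(n = 1000, seed = 7)
  cfg <- embedding_config(E = 2, exclusion_radius = 0)
  sizes <- c(20, 50, 100, 250, 500, 998)
  # X drives Y: Y's states encode X, so direction Y:X converges upward
  yx <- ccm_sweep(pair$Y, pair$X, cfg, sizes, subsamples = 8, seed = 1)
  xy <- ccm_sweep(pair$X, pair$Y, cfg, sizes, subsamples = 8, seed = 2)
  conv_yx <- assess_convergence(yx)
  expect_true(conv_yx$convergent)
  expect_gt(conv_yx$delta_skill, 0.1)
  expect_gt(yx$skill[length(sizes)], xy$skill[length(sizes)])
})

test_that("convergence assessment distinguishes rising from flat curves", {
  mk <- function(skill) structure(
    list(direction = "X:Y", library_sizes = seq(10, 10 * length(skill), 10),
         skill = skill, subsample_count = 1L, seed = 1L,
         cfg = embedding_config()), class = "emm_ccm")
  rising <- assess_convergence(mk(c(0.2, 0.45, 0.6, 0.68, 0.7)))
  expect_true(rising$convergent)
  expect_equal(rising$delta_skill, 0.5)
  flat <- assess_convergence(mk(rep(0.05, 5)))
  expect_false(flat$convergent)
  # a big rise that collapses at the end is not convergence
  dip <- assess_convergence(mk(c(0.1, 0.7, 0.75, 0.3, -0.2)))
  expect_false(dip$convergent)
  expect_error(assess_convergence(mk(c(0.1, 0.2))), "3 library sizes")
})

test_that("embedding-dimension selection finds low-dimensional dynamics", {
  X <- logistic_series(400)
  cfg <- embedding_config(exclusion_radius = 0)
  E1 <- choose_embedding_dimension(X, 1:10, cfg)
  expect_lte(E1, 3)
  expect_identical(E1, choose_embedding_dimension(X, 1:10, cfg))
})
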