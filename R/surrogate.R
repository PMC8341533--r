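## Random-phase (Ebisuzaki) surrogates and the empirical significance test
## for cross-map skill.

# N phase-randomized surrogates of x (columns), drawn from the current RNG.
# Keeps the DC coefficient untouched, rotates each positive-frequency
# coefficient by a uniform random phase, flips the Nyquist coefficient's sign
# at random (even length), mirrors conjugate-symmetrically, inverse-transforms.
rps_matrix <- function(x, N) {
  n <- length(x)
  if (n < 16L) stop("need length >= 16 for phase randomization", call. = FALSE)
  X <- stats::fft(x)
  even <- n %% 2L == 0L
  npos <- if (even) n %/% 2L - 1L else (n - 1L) %/% 2L
  pos <- 1L + seq_len(npos)
  S <- matrix(X, nrow = n, ncol = N)
  rot <- exp(1i * matrix(stats::runif(npos * N, 0, 2 * pi), nrow = npos))
  S[pos, ] <- S[pos, ] * rot
  S[n + 2L - pos, ] <- Conj(S[pos, , drop = FALSE])
  if (even) {
    ny <- n %/% 2L + 1L
    S[ny, ] <- Re(X[ny]) * sample(c(-1, 1), N, replace = TRUE)
  }
  Re(stats::mvfft(S, inverse = TRUE)) / n
}

#' Random-phase surrogate of a series
#'
#' Ebisuzaki-style phase randomization: the surrogate shares the original's
#' power spectrum (hence autocorrelation structure, by Wiener-Khinchin) and
#' mean exactly, but has independent random Fourier phases — the null model
#' for "same spectrum, no shared state-dependence".
#'
#' @param ts A regularized [emm_series()] of length >= 16 without gaps.
#' @param seed Integer seed.
#' @return An [emm_series()] of the same length and times.
#' @export
random_phase_surrogate <- function(ts, seed = 1L) {
  assert_series(ts)
  if (anyNA(ts$values)) stop("series has gaps; regularize first", call. = FALSE)
  vals <- with_seed(seed, rps_matrix(ts$values, 1L))[, 1]
  emm_series(ts$times, vals, name = paste0(ts$name, "_surrogate"),
             units = ts$units)
}

#' Null distribution of cross-map skill under phase randomization
#'
#' Generates `N` random-phase surrogates of one member of the pair and
#' computes, for each, the converged cross-map skill (full library) of the
#' direction `X:Y` (states of `X` predict the — possibly surrogate — `Y`).
#' With `which = "surrogate-Y"` the embedding of `X` is fixed, so one
#' neighbor-weight matrix serves all surrogates; `which = "surrogate-X"`
#' re-embeds each surrogate.
#'
#' @param X,Y Equal-length regularized [emm_series()].
#' @param which Which series to phase-randomize: `"surrogate-Y"` (default,
#'   randomize the cross-map target) or `"surrogate-X"`.
#' @param N Number of surrogates (>= 20).
#' @param cfg An [embedding_config()].
#' @param seed Integer seed; fully reproducible.
#' @return Numeric vector of `N` surrogate skills.
#' @export
surrogate_null_skills <- function(X, Y, which = c("surrogate-Y", "surrogate-X"),
                                  N = 1000L, cfg = embedding_config(),
                                  seed = 1L) {
  which <- match.arg(which)
  assert_series(X); assert_series(Y)
  if (length(X$times) != length(Y$times)) stop("series length mismatch", call. = FALSE)
  N <- as.integer(N)
  if (N < 20L) stop("need N >= 20 surrogates", call. = FALSE)
  if (which == "surrogate-Y") {
    emb <- time_delay_embed(X, cfg)
    nrows <- nrow(emb$states)
    tgt_idx <- emb$row_times + cfg$tp
    valid <- which(tgt_idx >= 1L & tgt_idx <= emb$n)
    W <- cpp_simplex_weights(emb$states, emb$row_times, valid, valid,
                             cfg$knn, cfg$exclusion_radius)
    ok <- !is.na(W[, 1])
    if (sum(ok) < 3L) stop("fewer than 3 valid predictions", call. = FALSE)
    W <- W[ok, , drop = FALSE]
    S <- with_seed(seed, rps_matrix(Y$values, N))
    tgt_rows <- matrix(0, nrow = nrows, ncol = N)
    tgt_rows[valid, ] <- S[tgt_idx[valid], , drop = FALSE]
    preds <- W %*% tgt_rows
    obs <- S[tgt_idx[valid][ok], , drop = FALSE]
    col_cor(preds, obs)
  } else {
    surr <- with_seed(seed, rps_matrix(X$values, N))
    vapply(seq_len(N), function(i) {
      Xs <- emm_series(X$times, surr[, i], name = X$name)
      tryCatch(
        suppressWarnings(cross_map_skill(Xs, Y, NULL, cfg)),
        error = function(e) NA_real_
      )
    }, numeric(1))
  }
}

# columnwise correlation of matching columns of two matrices
col_cor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Empirical p-value of an observed cross-map skill
#'
#' `p = 1 - ECDF(surrogate skills)` evaluated at the observed skill, with
#' `ECDF(v) = #\{surrogates <= v\} / N` (ties count as `<=`). This is a
#' one-sided test: only large observed skill is evidence against the
#' phase-randomized null. `p = 0` means the observation exceeds every
#' surrogate. The optional `corrected` variant uses the
#' `(r + 1) / (N + 1)` rank rule, which cannot return exactly 0.
#'
#' @param rho_observed Observed cross-map skill.
#' @param rho_surrogates Numeric vector of surrogate skills.
#' @param corrected Use the `(r+1)/(N+1)` correction? Default `FALSE`.
#' @return p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(rho_observed, rho_surrogates, corrected = FALSE) {
  rho_surrogates <- rho_surrogates[!is.na(rho_surrogates)]
  N <- length(rho_surrogates)
  if (N == 0L) stop("empty surrogate vector", call. = FALSE)
  if (corrected) {
    (1 + sum(rho_surrogates >= rho_observed)) / (N + 1)
  } else {
    1 - sum(rho_surrogates <= rho_observed) / N
  }
}

#' Surrogate significance test of a cross-map direction
#'
#' Bundles the observed converged skill (full library) of direction `X:Y`,
#' the surrogate null skills, and the empirical p-value.
#'
#' @inheritParams surrogate_null_skills
#' @param corrected Passed to [empirical_pvalue()].
#' @return An object of class `emm_surrtest`: `rho_observed`,
#'   `rho_surrogates`, `n_surrogates`, `p_value`, `seed`, `direction`,
#'   `which`.
#' @export
surrogate_test <- function(X, Y, which = c("surrogate-Y", "surrogate-X"),
                           N = 1000L, cfg = embedding_config(), seed = 1L,
                           corrected = FALSE) {
  which <- match.arg(which)
  rho_obs <- suppressWarnings(cross_map_skill(X, Y, NULL, cfg))
  null_sk <- surrogate_null_skills(X, Y, which, N, cfg, seed)
  structure(list(rho_observed = rho_obs,
                 rho_surrogates = null_sk,
                 n_surrogates = as.integer(N),
                 p_value = empirical_pvalue(rho_obs, null_sk, corrected),
                 seed = as.integer(seed),
                 direction = paste0(X$name, ":", Y$name),
                 which = which),
            class = "emm_surrtest")
}

#' @export
print.emm_surrtest <- function(x, ...) {
  cat(sprintf("<emm_surrtest> %s: rho = %.3f, N = %d, p = %.4f\n",
              x$direction, x$rho_observed, x$n_surrogates, x$p_value))
  invisible(x)
}
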