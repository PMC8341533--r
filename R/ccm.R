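#' Time-delay embedding configuration
#'
#' Defaults follow canonical empirical-dynamic-modeling practice: unit lag,
#' zero prediction horizon, `E + 1` nearest neighbors, and a 12-sample
#' (one year, for monthly data) temporal exclusion radius. The exclusion
#' radius (Theiler window) bars neighbors temporally close to each query so
#' that autocorrelation and seasonal phase-locking cannot masquerade as
#' cross-map skill.
#'
#' @param E Embedding dimension (>= 1).
#' @param tau Lag between embedding coordinates, in samples.
#' @param tp Prediction horizon in samples (0 = contemporaneous mapping).
#' @param exclusion_radius Nonnegative half-width, in samples, of the
#'   temporal neighborhood excluded around each query (the query itself is
#'   always excluded).
#' @param knn Number of nearest neighbors; defaults to `E + 1`.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(E = 3L, tau = 1L, tp = 0L,
                             exclusion_radius = 12L, knn = NULL) {
  E <- as.integer(E); tau <- as.integer(tau); tp <- as.integer(tp)
  exclusion_radius <- as.integer(exclusion_radius)
  stopifnot(E >= 1L, tau >= 1L, exclusion_radius >= 0L)
  if (is.null(knn)) knn <- E + 1L
  knn <- as.integer(knn)
  stopifnot(knn >= 1L)
  structure(list(E = E, tau = tau, tp = tp,
                 exclusion_radius = exclusion_radius, knn = knn),
            class = "embedding_config")
}

#' Time-delay embedding of a series
#'
#' Reconstructs the state space from lagged copies of one observable: row
#' `i` of the state matrix holds `x[t], x[t - tau], ..., x[t - (E-1) tau]`
#' for original index `t = (E-1) tau + i`; the earliest `(E-1) tau` indices
#' are dropped.
#'
#' @param ts A regularized [emm_series()] without gaps.
#' @param cfg An [embedding_config()].
#' @return An object of class `emm_embedding` with fields `states` (matrix,
#'   one row per valid time index) and `row_times` (original sample indices).
#' @export
time_delay_embed <- function(ts, cfg = embedding_config()) {
  assert_series(ts)
  x <- ts$values
  if (anyNA(x)) stop("series has gaps; regularize first", call. = FALSE)
  n <- length(x)
  span <- (cfg$E - 1L) * cfg$tau
  if (n <= span + 1L) {
    stop(sprintf("series too short for E = %d, tau = %d (need > %d points)",
                 cfg$E, cfg$tau, span + 1L), call. = FALSE)
  }
  row_times <- (span + 1L):n
  states <- matrix(NA_real_, nrow = length(row_times), ncol = cfg$E)
  for (j in seq_len(cfg$E)) {
    states[, j] <- x[row_times - (j - 1L) * cfg$tau]
  }
  structure(list(states = states, row_times = row_times, n = n,
                 series_name = ts$name, cfg = cfg),
            class = "emm_embedding")
}

# target value associated with each embedding row (NA = invalid horizon)
row_targets <- function(emb, y, tp) {
  tgt_idx <- emb$row_times + tp
  ok <- tgt_idx >= 1L & tgt_idx <= length(y)
  out <- rep(NA_real_, length(tgt_idx))
  out[ok] <- y[tgt_idx[ok]]
  out
}

#' Single simplex cross-map prediction
#'
#' Predicts the target at one query row as the distance-weighted average of
#' the targets of the `knn` nearest library states (weights
#' `exp(-d_i / d_min)`, normalized; zero-distance neighbors share uniform
#' weight). Library rows within `exclusion_radius` samples of the query are
#' ineligible.
#'
#' @param source An [time_delay_embed()] result.
#' @param target An [emm_series()] of the same length as the embedded series.
#' @param library Integer vector of library row indices (into the embedding).
#' @param query Single query row index.
#' @param cfg An [embedding_config()] (its `knn`, `tp`, `exclusion_radius`
#'   are used).
#' @return The scalar prediction.
#' @export
simplex_cross_map <- function(source, target, library, query,
                              cfg = source$cfg) {
  stopifnot(inherits(source, "emm_embedding"))
  assert_series(target)
  tgt <- row_targets(source, target$values, cfg$tp)
  lib <- as.integer(library)
  lib <- lib[!is.na(tgt[lib])]
  pred <- cpp_simplex_predict(source$states, source$row_times, tgt,
                              lib, as.integer(query), cfg$knn,
                              cfg$exclusion_radius)
  if (is.na(pred)) {
    stop(sprintf("library too small after exclusion radius %d at query time %d",
                 cfg$exclusion_radius, source$row_times[query]), call. = FALSE)
  }
  pred
}

#' Cross-map skill of X's states predicting Y
#'
#' Leave-one-out simplex predictions of `Y` at every valid query row using
#' `X`'s time-delay embedding and the given library, with the temporal
#' exclusion radius enforced around each query. Skill is the product-moment
#' correlation between predictions and observations. In CCM nomenclature
#' this is direction `X:Y` — high converged skill is evidence that `Y`
#' causally forces `X` (the driver is encoded in the states of the driven
#' variable).
#'
#' @param X,Y Equal-length regularized [emm_series()].
#' @param library_rows Integer vector of library rows; `NULL` = all rows.
#' @param cfg An [embedding_config()].
#' @return Correlation in \[-1, 1\] (`NA` with a warning when predictions
#'   are degenerate/constant).
#' @export
cross_map_skill <- function(X, Y, library_rows = NULL,
                            cfg = embedding_config()) {
  assert_series(X); assert_series(Y)
  if (length(X$times) != length(Y$times)) stop("series length mismatch", call. = FALSE)
  emb <- time_delay_embed(X, cfg)
  skill_from_embedding(emb, Y$values, library_rows, cfg)
}

# core used by cross_map_skill and the sweep (embedding precomputed)
skill_from_embedding <- function(emb, yvals, library_rows, cfg) {
  tgt <- row_targets(emb, yvals, cfg$tp)
  nrows <- nrow(emb$states)
  if (is.null(library_rows)) library_rows <- seq_len(nrows)
  lib <- as.integer(library_rows)
  if (any(lib < 1L | lib > nrows)) stop("library row out of range", call. = FALSE)
  lib <- lib[!is.na(tgt[lib])]
  query <- which(!is.na(tgt))
  pred <- cpp_simplex_predict(emb$states, emb$row_times, tgt, lib, query,
                              cfg$knn, cfg$exclusion_radius)
  ok <- !is.na(pred)
  if (sum(ok) < 3L) {
    stop("fewer than 3 valid predictions (library too small for the exclusion radius)",
         call. = FALSE)
  }
  p <- pred[ok]; o <- tgt[query][ok]
  if (stats::sd(p) == 0 || stats::sd(o) == 0) {
    warning("degenerate (constant) predictions; skill undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(p, o)
}

#' CCM library-size sweep
#'
#' For each library size `L`, draws random row subsets of size `L` (uniform,
#' without replacement, seeded), computes cross-map skill for each, and
#' averages. Convergence of the resulting skill curve with `L` is the CCM
#' evidence criterion.
#'
#' @param X,Y Equal-length regularized [emm_series()]; direction `X:Y`
#'   (states of `X` predict `Y`, evidence for `Y -> X`).
#' @param cfg An [embedding_config()].
#' @param library_sizes Increasing integer vector; `NULL` = 8 log-spaced
#'   sizes from `E + 2` to the number of embedding rows.
#' @param subsamples Random subsets per size (the full library is evaluated
#'   once).
#' @param seed Integer seed; identical seeds give identical results.
#' @return An object of class `emm_ccm` with fields `direction`,
#'   `library_sizes`, `skill`, `subsample_count`, `seed`, `cfg`.
#' @export
ccm_sweep <- function(X, Y, cfg = embedding_config(), library_sizes = NULL,
                      subsamples = 100L, seed = 1L) {
  assert_series(X); assert_series(Y)
  if (length(X$times) != length(Y$times)) stop("series length mismatch", call. = FALSE)
  emb <- time_delay_embed(X, cfg)
  nrows <- nrow(emb$states)
  if (is.null(library_sizes)) {
    library_sizes <- unique(round(exp(seq(log(cfg$E + 2L), log(nrows),
                                          length.out = 8))))
  }
  library_sizes <- sort(unique(as.integer(library_sizes)))
  if (any(library_sizes < cfg$E + 2L)) {
    stop(sprintf("library sizes must be >= E + 2 = %d", cfg$E + 2L), call. = FALSE)
  }
  if (max(library_sizes) > nrows) {
    stop(sprintf("library size %d exceeds available rows (%d)",
                 max(library_sizes), nrows), call. = FALSE)
  }
  skills <- with_seed(seed, {
    vapply(library_sizes, function(L) {
      reps <- if (L >= nrows) 1L else as.integer(subsamples)
      vals <- vapply(seq_len(reps), function(r) {
        rows <- if (L >= nrows) seq_len(nrows) else sample.int(nrows, L)
        tryCatch(
          suppressWarnings(skill_from_embedding(emb, Y$values, rows, cfg)),
          error = function(e) NA_real_
        )
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }, numeric(1))
  })
  structure(list(direction = paste0(X$name, ":", Y$name),
                 library_sizes = library_sizes, skill = skills,
                 subsample_count = as.integer(subsamples), seed = as.integer(seed),
                 cfg = cfg),
            class = "emm_ccm")
}

#' @export
print.emm_ccm <- function(x, ...) {
  cat(sprintf("<emm_ccm> %s: skill %.3f -> %.3f over L = %d..%d\n",
              x$direction, x$skill[1], x$skill[length(x$skill)],
              x$library_sizes[1], max(x$library_sizes)))
  invisible(x)
}

#' Assess convergence of a CCM skill curve
#'
#' Convergent cross mapping requires the skill curve to rise and level off
#' as the library grows: the flag is true when the terminal skill is
#' positive, the rise across the sweep exceeds `delta`, and the rise
#' persists under isotonic (monotone nondecreasing) smoothing of the curve.
#'
#' @param result An [ccm_sweep()] result with at least 3 library sizes.
#' @param delta Minimum skill rise (default 0.1).
#' @return A list: `convergent` (flag), `skill_min`, `skill_max`,
#'   `delta_skill` (raw terminal minus initial skill).
#' @export
assess_convergence <- function(result, delta = 0.1) {
  stopifnot(inherits(result, "emm_ccm"))
  if (length(result$library_sizes) < 3L) {
    stop("need at least 3 library sizes to assess convergence", call. = FALSE)
  }
  sk <- result$skill
  s_min <- sk[1]; s_max <- sk[length(sk)]
  d_raw <- s_max - s_min
  iso <- stats::isoreg(result$library_sizes, sk)$yf
  d_iso <- iso[length(iso)] - iso[1]
  list(convergent = isTRUE(s_max > 0 && d_raw > delta && d_iso > delta),
       skill_min = s_min, skill_max = s_max, delta_skill = d_raw)
}

#' Select an embedding dimension by univariate forecast skill
#'
#' Evaluates leave-one-out simplex self-prediction at horizon `tp = 1` for
#' each candidate `E` and returns the maximizer (ties broken toward the
#' smallest `E`). Deterministic: the full library is used.
#'
#' @param ts A regularized [emm_series()].
#' @param E_range Candidate dimensions (default `1:10`).
#' @param cfg An [embedding_config()] supplying `tau` and
#'   `exclusion_radius`.
#' @return The selected embedding dimension (integer).
#' @export
choose_embedding_dimension <- function(ts, E_range = 1:10,
                                       cfg = embedding_config()) {
  assert_series(ts)
  skills <- vapply(E_range, function(E) {
    cfg_e <- embedding_config(E = E, tau = cfg$tau, tp = 1L,
                              exclusion_radius = cfg$exclusion_radius)
    tryCatch(
      suppressWarnings(cross_map_skill(ts, ts, NULL, cfg_e)),
      error = function(e) NA_real_
    )
  }, numeric(1))
  if (all(is.na(skills))) stop("no candidate E produced valid forecasts", call. = FALSE)
  as.integer(E_range[which.max(round(skills, 10))])
}

# evaluate expr under a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
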