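## End-to-end orchestration: decomposition tables -> scaled band comparisons
## -> CCM curve tables -> surrogate significance summary, with a JSON
## manifest sufficient to re-run. All tabular output is CSV at fixed
## 9-significant-digit formatting so reruns are byte-identical.

#' Assemble a pipeline run configuration
#'
#' @param driver,response [emm_series()] inputs (regularized, monthly), or
#'   paths to CSV files in the `read_timeseries_csv()` dialect. `response`
#'   may also be an [emm_station_set()] (or a vector of station CSV paths),
#'   in which case stations are averaged and spline-regularized onto the
#'   driver's monthly grid.
#' @param out_dir Output directory (created if absent).
#' @param sift A [sift_config()].
#' @param E Embedding dimension; `NULL` selects it per embedded series via
#'   [choose_embedding_dimension()].
#' @param tau,tp,exclusion_radius,knn Passed to [embedding_config()].
#' @param band_mode `"auto"` classifies IMFs by mean period;
#'   `"explicit"` uses `interannual_indices` / `intra_annual_indices`.
#' @param interannual_indices,intra_annual_indices Named lists (driver /
#'   response) of explicit IMF index vectors, used when
#'   `band_mode = "explicit"`.
#' @param library_sizes Passed to [ccm_sweep()]; `NULL` = log-spaced.
#' @param subsamples Random library subsets per size.
#' @param n_surrogates Surrogates per significance test.
#' @param seed Master integer seed.
#' @param standardize_for_ccm Standardize series before cross mapping
#'   (default `TRUE`; recorded in the manifest).
#' @return A list of class `emm_run_config`.
#' @export
run_config <- function(driver, response, out_dir = tempfile("emm_run_"),
                       sift = sift_config(), E = NULL, tau = 1L, tp = 0L,
                       exclusion_radius = 12L, knn = NULL,
                       band_mode = c("auto", "explicit"),
                       interannual_indices = NULL, intra_annual_indices = NULL,
                       library_sizes = NULL, subsamples = 100L,
                       n_surrogates = 1000L, seed = 1L,
                       standardize_for_ccm = TRUE) {
  band_mode <- match.arg(band_mode)
  if (band_mode == "explicit" &&
      (is.null(interannual_indices) || is.null(intra_annual_indices))) {
    stop("explicit band mode needs interannual_indices and intra_annual_indices",
         call. = FALSE)
  }
  structure(list(driver = driver, response = response, out_dir = out_dir,
                 sift = sift, E = E, tau = as.integer(tau), tp = as.integer(tp),
                 exclusion_radius = as.integer(exclusion_radius), knn = knn,
                 band_mode = band_mode,
                 interannual_indices = interannual_indices,
                 intra_annual_indices = intra_annual_indices,
                 library_sizes = library_sizes,
                 subsamples = as.integer(subsamples),
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed),
                 standardize_for_ccm = isTRUE(standardize_for_ccm)),
            class = "emm_run_config")
}

#' Read a flat key = value run-configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys
#' mirror the arguments of [run_config()] (paths for `driver` and
#' `response`; `response` may be a comma-separated list of station CSVs).
#' A commented template ships in
#' `system.file("extdata", "run-config-template.txt", package = "emmod")`.
#'
#' @param path Path to the config file.
#' @return An `emm_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop(sprintf("malformed config line: '%s'", lines[bad][1]), call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  cfg <- stats::setNames(as.list(vals), keys)
  num_keys <- c("E", "tau", "tp", "exclusion_radius", "knn", "subsamples",
                "n_surrogates", "seed")
  args <- list()
  for (k in names(cfg)) {
    v <- cfg[[k]]
    if (k %in% num_keys) args[[k]] <- as.integer(v)
    else if (k == "standardize_for_ccm") args[[k]] <- toupper(v) %in% c("TRUE", "1", "YES")
    else if (k == "response" && grepl(",", v)) args[[k]] <- trimws(strsplit(v, ",")[[1]])
    else if (k == "library_sizes") args[[k]] <- as.integer(trimws(strsplit(v, ",")[[1]]))
    else args[[k]] <- v
  }
  do.call(run_config, args)
}

# fixed-format CSV writer (9 significant digits, byte-stable)
write_table9 <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

# resolve driver/response inputs into regularized monthly emm_series
resolve_inputs <- function(cfg) {
  driver <- cfg$driver
  if (is.character(driver)) {
    driver <- read_timeseries_csv(driver, name = "driver")
  }
  assert_series(driver, "driver")
  response <- cfg$response
  if (is.character(response) && length(response) > 1L) {
    response <- emm_station_set(lapply(response, read_timeseries_csv))
  } else if (is.character(response)) {
    response <- read_timeseries_csv(response, name = "response")
  }
  if (inherits(response, "emm_station_set")) {
    avg <- station_average(response, name = "response", bin = "month")
    response <- suppressWarnings(regularize_to_grid(avg, driver$times))
  }
  assert_series(response, "response")
  if (length(response$times) != length(driver$times)) {
    # common support on the driver's grid
    common <- intersect(round(driver$times, 9), round(response$times, 9))
    di <- match(common, round(driver$times, 9))
    ri <- match(common, round(response$times, 9))
    driver <- emm_series(driver$times[di], driver$values[di], name = driver$name)
    response <- emm_series(response$times[ri], response$values[ri],
                           name = response$name)
  }
  list(driver = driver, response = response)
}

band_indices <- function(classification, band, explicit = NULL) {
  if (!is.null(explicit)) return(as.integer(explicit))
  idx <- classification$imf_index[!is.na(classification$band) &
                                    classification$band == band]
  as.integer(idx[!is.na(idx)])
}

#' Stage 1: decompose both series and write band tables
#'
#' Writes, per series: `<name>_imfs.csv` (tidy time/component/value),
#' `<name>_classification.csv` (IMF index, Hilbert mean period, band), and
#' `<name>_bands.csv` with the source, decadal (residual), interannual and
#' intra-annual band series plus the low-pass (source minus IMF 1) series.
#'
#' @param cfg An [run_config()] result.
#' @return (Invisibly) a list with the two `emm_imfset`s, classifications,
#'   and band series.
#' @export
run_decomposition <- function(cfg) {
  stopifnot(inherits(cfg, "emm_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- resolve_inputs(cfg)
  out <- list()
  for (role in c("driver", "response")) {
    ts <- inputs[[role]]
    imfset <- emm_decompose(ts, cfg$sift)
    cls <- classify_imfs(imfset)
    inter_idx <- band_indices(cls, "interannual",
                              if (cfg$band_mode == "explicit")
                                cfg$interannual_indices[[role]])
    intra_idx <- band_indices(cls, "intra-annual",
                              if (cfg$band_mode == "explicit")
                                cfg$intra_annual_indices[[role]])
    bands <- data.frame(
      time = ts$times,
      source = ts$values,
      decadal = imfset$residual,
      interannual = reconstruct_band(imfset, inter_idx)$values,
      intra_annual = reconstruct_band(imfset, intra_idx)$values,
      lowpass = if (length(imfset$imfs) >= 2L)
        remove_highest_frequency_imf(imfset)$values else ts$values
    )
    write_table9(imfset_to_table(imfset),
                 file.path(cfg$out_dir, sprintf("%s_imfs.csv", role)))
    write_table9(cls, file.path(cfg$out_dir, sprintf("%s_classification.csv", role)))
    write_table9(bands, file.path(cfg$out_dir, sprintf("%s_bands.csv", role)))
    out[[role]] <- list(series = ts, imfset = imfset, classification = cls,
                        bands = bands,
                        interannual_indices = inter_idx,
                        intra_annual_indices = intra_idx)
  }
  invisible(out)
}

read_bands <- function(cfg, role) {
  path <- file.path(cfg$out_dir, sprintf("%s_bands.csv", role))
  if (!file.exists(path)) {
    stop(sprintf("missing decomposition output %s; run run_decomposition() first",
                 path), call. = FALSE)
  }
  utils::read.csv(path)
}

band_pair <- function(cfg, column) {
  d <- read_bands(cfg, "driver")
  r <- read_bands(cfg, "response")
  list(driver = emm_series(d$time, d[[column]], name = "driver"),
       response = emm_series(r$time, r[[column]], name = "response"))
}

#' Stage 2: scaled (standardized) band comparisons
#'
#' For each of the four time-scale views — all timescales, decadal
#' (nonlinear trend), interannual, intra-annual — writes
#' `comparison_<band>.csv` with the standardized driver and response.
#'
#' @param cfg An [run_config()] result whose decomposition outputs exist.
#' @return (Invisibly) the list of comparison data frames.
#' @export
run_scaled_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "emm_run_config"))
  views <- c(all = "source", decadal = "decadal", interannual = "interannual",
             intra_annual = "intra_annual")
  out <- list()
  for (v in names(views)) {
    pair <- band_pair(cfg, views[[v]])
    cmp <- data.frame(time = pair$driver$times,
                      driver = standardize(pair$driver)$values,
                      response = standardize(pair$response)$values)
    write_table9(cmp, file.path(cfg$out_dir, sprintf("comparison_%s.csv", v)))
    out[[v]] <- cmp
  }
  invisible(out)
}

ccm_cfg_for <- function(cfg, ts) {
  E <- cfg$E
  base <- embedding_config(E = if (is.null(E)) 3L else E, tau = cfg$tau,
                           tp = cfg$tp, exclusion_radius = cfg$exclusion_radius,
                           knn = cfg$knn)
  if (is.null(E)) {
    E <- choose_embedding_dimension(ts, 1:10, base)
    base <- embedding_config(E = E, tau = cfg$tau, tp = cfg$tp,
                             exclusion_radius = cfg$exclusion_radius,
                             knn = cfg$knn)
  }
  base
}

#' Stage 3: CCM curve tables for the four time-scale cases
#'
#' Cases: (a) all timescales, (b) low pass (source minus IMF 1), (c)
#' interannual band, (d) intra-annual band. Each `ccm_<case>.csv` holds
#' `library_size`, `skill_XY`, `skill_YX` and the zero-lag linear
#' cross-correlation reference, where X is the driver and Y the response
#' (so `skill_XY` = driver's states predicting the response = evidence the
#' response forces the driver, and vice versa). A band with no member IMFs
#' is skipped and noted in `ccm_skipped.txt`.
#'
#' @param cfg An [run_config()] result whose decomposition outputs exist.
#' @return (Invisibly) a list of `emm_ccm` pairs per case.
#' @export
run_ccm_suite <- function(cfg) {
  stopifnot(inherits(cfg, "emm_run_config"))
  cases <- c(all = "source", lowpass = "lowpass", interannual = "interannual",
             intra_annual = "intra_annual")
  out <- list()
  skipped <- character(0)
  for (cs in names(cases)) {
    pair <- band_pair(cfg, cases[[cs]])
    if (stats::sd(pair$driver$values) == 0 || stats::sd(pair$response$values) == 0) {
      skipped <- c(skipped, sprintf("%s: band empty (no IMFs in class)", cs))
      next
    }
    X <- pair$driver; Y <- pair$response
    if (cfg$standardize_for_ccm) {
      X <- standardize(X); Y <- standardize(Y)
    }
    ecfg_x <- ccm_cfg_for(cfg, X)
    ecfg_y <- ccm_cfg_for(cfg, Y)
    xy <- ccm_sweep(X, Y, ecfg_x, cfg$library_sizes, cfg$subsamples,
                    seed = cfg$seed)
    yx <- ccm_sweep(Y, X, ecfg_y, cfg$library_sizes, cfg$subsamples,
                    seed = cfg$seed + 1L)
    L <- sort(union(xy$library_sizes, yx$library_sizes))
    tab <- data.frame(
      library_size = L,
      skill_XY = xy$skill[match(L, xy$library_sizes)],
      skill_YX = yx$skill[match(L, yx$library_sizes)],
      linear_cc = linear_cross_correlation(X, Y)
    )
    write_table9(tab, file.path(cfg$out_dir, sprintf("ccm_%s.csv", cs)))
    out[[cs]] <- list(xy = xy, yx = yx, table = tab,
                      E = c(XY = ecfg_x$E, YX = ecfg_y$E))
  }
  if (length(skipped)) {
    writeLines(skipped, file.path(cfg$out_dir, "ccm_skipped.txt"))
  }
  invisible(out)
}

#' Stage 4: surrogate significance tests on the all-timescales pair
#'
#' Tests both cross-map directions against `n_surrogates` random-phase
#' surrogates of the target series, writing `surrogate_tests.csv` (one
#' summary row per direction: observed skill, N, p-value, seed) and
#' `surrogate_skills.csv` with the full null distributions.
#'
#' @param cfg An [run_config()] result whose decomposition outputs exist.
#' @return (Invisibly) a list of `emm_surrtest` objects.
#' @export
run_surrogate_tests <- function(cfg) {
  stopifnot(inherits(cfg, "emm_run_config"))
  pair <- band_pair(cfg, "source")
  X <- pair$driver; Y <- pair$response
  if (cfg$standardize_for_ccm) {
    X <- standardize(X); Y <- standardize(Y)
  }
  tests <- list(
    XY = surrogate_test(X, Y, "surrogate-Y", cfg$n_surrogates,
                        ccm_cfg_for(cfg, X), seed = cfg$seed + 11L),
    YX = surrogate_test(Y, X, "surrogate-Y", cfg$n_surrogates,
                        ccm_cfg_for(cfg, Y), seed = cfg$seed + 12L)
  )
  summ <- do.call(rbind, lapply(tests, function(tst) {
    data.frame(direction = tst$direction, rho_observed = tst$rho_observed,
               n_surrogates = tst$n_surrogates, p_value = tst$p_value,
               seed = tst$seed)
  }))
  write_table9(summ, file.path(cfg$out_dir, "surrogate_tests.csv"))
  skl <- data.frame(
    surrogate = seq_len(cfg$n_surrogates),
    skill_XY = tests$XY$rho_surrogates,
    skill_YX = tests$YX$rho_surrogates
  )
  write_table9(skl, file.path(cfg$out_dir, "surrogate_skills.csv"))
  invisible(tests)
}

#' Run the full pipeline
#'
#' Decomposition, scaled comparisons, CCM suite, surrogate tests, and a
#' `manifest.json` echoing the configuration, seeds, and package version —
#' enough to reproduce the output directory byte-for-byte.
#'
#' @param cfg An [run_config()] result.
#' @return (Invisibly) a list with all stage results.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "emm_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  decomp <- run_decomposition(cfg)
  comparisons <- run_scaled_comparison(cfg)
  ccm <- run_ccm_suite(cfg)
  surr <- run_surrogate_tests(cfg)
  manifest <- list(
    package = "emmod",
    version = as.character(utils::packageVersion("emmod")),
    seed = cfg$seed,
    n_surrogates = cfg$n_surrogates,
    subsamples = cfg$subsamples,
    exclusion_radius = cfg$exclusion_radius,
    tau = cfg$tau, tp = cfg$tp,
    E = if (is.null(cfg$E)) "auto" else cfg$E,
    band_mode = cfg$band_mode,
    standardize_for_ccm = cfg$standardize_for_ccm,
    direction_nomenclature = paste(
      "X:Y means states of X predict Y;",
      "convergent significant skill in X:Y is evidence that Y forces X"),
    sift = unclass(cfg$sift)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(decomposition = decomp, comparisons = comparisons,
                 ccm = ccm, surrogates = surr))
}
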