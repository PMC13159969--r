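#' Pipeline configuration
#'
#' Collects every stage parameter in one serializable object. Defaults are
#' the analysis's standard values: 500-3500 Hz band-pass with 60 Hz notch
#' and 4 s padding, 5 SD detection threshold, 0.8 waveform-correlation merge
#' threshold, 5% / 2.5 ms ISI rule, 10 ms binarization, 25 ms correlation
#' smoothing, entropy subsampling over K = 2-18 and maximum-entropy fitting
#' over K = 2-14 with 100 subsamples and 100 bootstrap resamples.
#'
#' @param ... overrides for any default field (unknown names are rejected).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter_low_hz = 500, filter_high_hz = 3500, filter_pad_s = 4,
    notch_hz = 60,
    k_sd = 5, dead_time_ms = 1, robust_sd = FALSE,
    waveform_pre = 13L, waveform_post = 24L,
    symmetry_corr_threshold = 0.9, peak_trough_diff = 8,
    pca_components = 2L, max_clusters = 8L,
    merge_corr_threshold = 0.8,
    isi_max_violation = 0.05, isi_refractory_ms = 2.5,
    min_spikes = 10L,
    bin_ms = 10, sigma_ms = 25,
    stationarity_window_ms = 100, stationarity_step_ms = 5,
    kld_bins = 30, stationarity_tol_sd = 3,
    entropy_K_range = 2:18, maxent_K_range = 2:14,
    n_subsamples = 100L, n_bootstrap = 100L,
    maxent_tol = 1e-6, maxent_max_iter = 200L,
    alpha = 0.05, n_comparisons = NULL,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through JSON or YAML (chosen by file
#' extension). Unknown keys are rejected on read with the offending names.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param config a [pipeline_config()] (for writing).
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format: .", ext))
  raw$n_comparisons <- raw$n_comparisons %||% NULL
  do.call(pipeline_config, raw[!vapply(raw, is.null, TRUE)])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  obj <- unclass(config)
  obj <- obj[!vapply(obj, is.null, TRUE)]
  switch(ext,
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA),
         yaml = ,
         yml = yaml::write_yaml(obj, path),
         stop("unsupported config format: .", ext))
  invisible(path)
}

#' Read / write a spike list
#'
#' The delimited spike-list interchange format: a tab-separated table with
#' columns `unit_id` and `time_s`, one row per spike, times sorted
#' increasing within each unit. Malformed rows are rejected with their line
#' number.
#'
#' @param path file path (TSV).
#' @param trains named list of per-unit spike-time vectors, or a
#'   `spike_trains` object, or a `unit_catalog`.
#' @return `read_spike_list` returns a named list of sorted spike-time
#'   vectors; `write_spike_list` returns `path` invisibly.
#' @export
read_spike_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  if (!identical(names(df), c("unit_id", "time_s"))) {
    stop("spike list must have columns unit_id, time_s; got: ",
         paste(names(df), collapse = ", "))
  }
  bad <- which(!is.finite(df$time_s) | df$time_s < 0)
  if (length(bad)) {
    stop("invalid spike time at line ", bad[1] + 1L,
         " (negative or non-finite)")
  }
  trains <- split(df$time_s, df$unit_id)
  for (id in names(trains)) {
    if (is.unsorted(trains[[id]])) {
      stop("spike times for unit ", id, " are not sorted")
    }
  }
  trains
}

#' @rdname read_spike_list
#' @export
write_spike_list <- function(trains, path) {
  if (inherits(trains, "spike_trains")) trains <- trains$trains
  if (inherits(trains, "unit_catalog")) trains <- catalog_trains(trains)
  ids <- names(trains) %||% paste0("u", seq_along(trains))
  df <- data.frame(unit_id = rep(ids, lengths(trains)),
                   time_s = unlist(trains, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a raw voltage recording
#'
#' Stores the channels x samples voltage matrix as a flat little-endian
#' float64 binary file (row-major: channel 1's samples first) with a JSON
#' metadata sidecar (`<path>.json`) carrying `sampling_rate_hz`,
#' `n_channels`, `n_samples` and the channel coordinates. Reading validates
#' the sidecar and the file size; a missing sampling rate or a size
#' mismatch is rejected.
#'
#' @param recording a `voltage_recording`.
#' @param path path of the binary file (sidecar written alongside).
#' @return `read_voltage` returns a `voltage_recording`; `write_voltage`
#'   returns `path` invisibly.
#' @export
write_voltage <- function(recording, path) {
  stopifnot(inherits(recording, "voltage_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$samples)), con, size = 8, endian = "little")
  meta <- list(sampling_rate_hz = recording$sampling_rate_hz,
               n_channels = nrow(recording$samples),
               n_samples = ncol(recording$samples),
               channel_coords = recording$channel_coords)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_voltage
#' @export
read_voltage <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("sampling_rate_hz", "n_channels", "n_samples")) {
    if (is.null(meta[[field]])) stop("sidecar missing required field: ", field)
  }
  n <- meta$n_channels * meta$n_samples
  if (file.size(path) != 8 * n) {
    stop("voltage file size (", file.size(path),
         " bytes) does not match sidecar dimensions (expected ", 8 * n, ")")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  structure(list(samples = matrix(v, meta$n_channels, meta$n_samples,
                                  byrow = TRUE),
                 sampling_rate_hz = meta$sampling_rate_hz,
                 channel_coords = as.data.frame(meta$channel_coords),
                 duration_s = meta$n_samples / meta$sampling_rate_hz),
            class = "voltage_recording")
}

#' Run the full analysis pipeline on one recording
#'
#' Chains all stages on a single recording: spike sorting (skipped when
#' spike trains are supplied directly), the stationarity gate, unit
#' localization (voltage input only), pairwise correlation, count/word
#' entropy with subsampling, and the pairwise maximum-entropy fit with
#' held-out KL divergence per subsampled population. All randomness derives
#' from `config$seed`, so a re-run with the same inputs and config is
#' reproducible.
#'
#' @param input a `voltage_recording`, a `spike_trains` object, or a named
#'   list of spike-time vectors (requires `duration_s`).
#' @param config a [pipeline_config()].
#' @param duration_s recording duration, required when `input` is a plain
#'   list of trains.
#' @param enforce_stationarity exclude the recording (return early with
#'   `stationary = FALSE`) when the stationarity gate fails (default
#'   `TRUE`).
#' @return object of class `recording_result` with elements `n_units`,
#'   `rates_hz`, `stationarity`, `positions` (or NULL), `correlations`
#'   (long format), `entropy` (long format), `maxent` (per-subsample
#'   data.frame: `K`, `subsample`, `kld_bits`), `stationary`, `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), duration_s = NULL,
                         enforce_stationarity = TRUE) {
  cfg <- config
  positions <- NULL
  if (inherits(input, "voltage_recording")) {
    catalog <- sort_spikes(input, cfg)
    trains <- catalog_trains(catalog)
    duration_s <- input$duration_s
    if (length(trains) > 0) positions <- localize_units(catalog)
  } else if (inherits(input, "spike_trains")) {
    trains <- input$trains
    duration_s <- input$duration_s
  } else {
    stopifnot(is.list(input), !is.null(duration_s))
    trains <- input
  }

  empty <- structure(list(n_units = length(trains),
                          rates_hz = lengths(trains) / (duration_s %||% NA),
                          stationarity = NULL, positions = positions,
                          correlations = NULL, entropy = NULL, maxent = NULL,
                          stationary = NA, config = cfg),
                     class = "recording_result")
  if (length(trains) < 2) return(empty)

  stat <- stationarity_report(trains, duration_s,
                              window_ms = cfg$stationarity_window_ms,
                              step_ms = cfg$stationarity_step_ms,
                              n_bins = cfg$kld_bins,
                              alpha = cfg$alpha,
                              tol_sd = cfg$stationarity_tol_sd,
                              seed = cfg$seed)
  empty$stationarity <- stat
  empty$stationary <- stat$stationary
  if (enforce_stationarity && !stat$stationary) return(empty)

  raster <- binarize(trains, duration_s, bin_ms = cfg$bin_ms)
  cm <- pairwise_correlation(raster, sigma_ms = cfg$sigma_ms)
  entropy_tab <- subsampled_entropy(raster, K_range = cfg$entropy_K_range,
                                    n_subsamples = cfg$n_subsamples,
                                    n_bootstrap = cfg$n_bootstrap,
                                    seed = cfg$seed)
  maxent_tab <- maxent_subsampled(raster, K_range = cfg$maxent_K_range,
                                  n_subsamples = cfg$n_subsamples,
                                  tol = cfg$maxent_tol,
                                  max_iter = cfg$maxent_max_iter,
                                  seed = cfg$seed)
  structure(list(n_units = length(trains),
                 rates_hz = lengths(trains) / duration_s,
                 stationarity = stat, positions = positions,
                 correlations = correlation_pairs(cm),
                 entropy = entropy_tab, maxent = maxent_tab,
                 stationary = stat$stationary, config = cfg),
            class = "recording_result")
}

#' @export
print.recording_result <- function(x, ...) {
  cat(sprintf("recording result: %d units, %s\n", x$n_units,
              if (isTRUE(x$stationary)) "stationary" else "non-stationary / ungated"))
  if (!is.null(x$maxent) && nrow(x$maxent)) {
    cat(sprintf("  median held-out Ising KL-D: %.4f bits over %d fits\n",
                stats::median(x$maxent$kld_bits), nrow(x$maxent)))
  }
  invisible(x)
}

#' Held-out Ising KL divergence across subsampled populations
#'
#' For each population size K, draws random K-unit subsets, splits each
#' sub-raster into train/test halves, fits the pairwise maximum-entropy
#' model on the training half and evaluates `KL(test empirical || model)`.
#'
#' @param raster a `binarized_raster`.
#' @param K_range population sizes (default `2:14`); sizes above the unit
#'   count are skipped.
#' @param n_subsamples random subsets per K (default 100).
#' @param tol,max_iter passed to [fit_pairwise_ising()].
#' @param seed RNG seed.
#' @return data.frame: `K`, `subsample`, `kld_bits`, `converged`.
#' @export
maxent_subsampled <- function(raster, K_range = 2:14, n_subsamples = 100,
                              tol = 1e-6, max_iter = 200, seed = 1) {
  n_units <- nrow(raster)
  usable <- K_range[K_range <= n_units]
  with_seed(seed, {
    rows <- list()
    for (K in usable) {
      for (s in seq_len(n_subsamples)) {
        idx <- sample.int(n_units, K)
        halves <- split_train_test(raster[idx, ])
        fit <- suppressWarnings(
          fit_pairwise_ising(halves$train, tol = tol, max_iter = max_iter))
        rows[[length(rows) + 1]] <- data.frame(
          K = K, subsample = s,
          kld_bits = evaluate_fit(fit, halves$test),
          converged = fit$converged)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Compare recording cohorts across experimental groups
#'
#' Pools per-recording statistic distributions by group label and runs the
#' all-pairs Brunner-Munzel comparison with Bonferroni correction for each
#' statistic family (firing rate, pairwise correlation, word entropy,
#' maximum-entropy KL divergence).
#'
#' @param results list of `recording_result` objects.
#' @param groups group label per recording (same length as `results`).
#' @param n_comparisons Bonferroni denominator; defaults to the number of
#'   group pairs per family.
#' @param alpha family-wise level (default 0.05).
#' @return object of class `cohort_result`: `distributions` (named list of
#'   per-group value lists by family) and `tests` (long data.frame with a
#'   `family` column).
#' @export
compare_cohorts <- function(results, groups, n_comparisons = NULL,
                            alpha = 0.05) {
  stopifnot(length(results) == length(groups))
  keep <- vapply(results, function(r) isTRUE(r$stationary) || is.na(r$stationary),
                 TRUE)
  results <- results[keep]; groups <- groups[keep]
  glev <- unique(groups)
  pull <- function(fun) {
    out <- lapply(glev, function(g) {
      v <- unlist(lapply(results[groups == g], fun), use.names = FALSE)
      v[is.finite(v)]
    })
    names(out) <- as.character(glev)
    out
  }
  fams <- list(
    firing_rate = pull(function(r) r$rates_hz),
    pairwise_correlation = pull(function(r) r$correlations$r),
    word_entropy = pull(function(r) {
      e <- r$entropy; if (is.null(e)) NULL else e$entropy_bits[e$kind == "word"]
    }),
    maxent_kld = pull(function(r) r$maxent$kld_bits))
  tests <- list()
  for (fam in names(fams)) {
    smp <- fams[[fam]]
    smp <- smp[lengths(smp) >= 2]
    if (length(smp) < 2) next
    tab <- compare_groups(smp, test = "brunner_munzel",
                          n_comparisons = n_comparisons, alpha = alpha)
    tab$family <- fam
    tests[[fam]] <- tab
  }
  structure(list(distributions = fams,
                 tests = do.call(rbind, tests)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort comparison:\n")
  if (!is.null(x$tests)) {
    for (fam in unique(x$tests$family)) {
      sub <- x$tests[x$tests$family == fam, ]
      cat(sprintf("  %s: %d/%d group pairs significant at corrected alpha %.4g\n",
                  fam, sum(sub$significant), nrow(sub), sub$corrected_alpha[1]))
    }
  }
  invisible(x)
}
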