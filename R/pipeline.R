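# End-to-end orchestration: simulate or load, preprocess, denoise,
# extract features, reference to controls, test features, classify.

#' Run the full screening pipeline
#'
#' Executes simulate-or-load, preprocessing, artifact removal, spectral
#' feature extraction, control-referenced relative power, Kruskal-Wallis
#' feature testing, and (optionally) SMOTE + RBF-SVM cross-validation,
#' all driven by one configuration and one master seed. Per-stage and
#' per-subject seeds are derived deterministically from the master seed,
#' so the whole report is a pure function of (input, config).
#'
#' @param x A [cohort_spec()] (simulated input) or a cohort tibble
#'   (from [generate_cohort()] or [read_cohort()]).
#' @param config A [default_config()] list; `config$seed` is the master
#'   seed.
#' @return An `eeg_run` report: list with `config`, `cohort` (manifest
#'   columns only), `masks`, `features` (absolute), `relative`
#'   (control-referenced), `feature_tests`, `group_means`, and `cv`
#'   (`NULL` when classification is disabled).
#' @export
run_pipeline <- function(x, config = default_config()) {
  t0 <- Sys.time()
  if (inherits(x, "cohort_spec")) {
    cohort <- generate_cohort(x)
  } else if (is.data.frame(x) && all(c("subject_id", "group", "recording") %in% names(x))) {
    cohort <- x
  } else {
    abort_invalid("`x` must be a cohort_spec or a cohort tibble")
  }
  if (nrow(cohort) == 0L) abort_invalid("empty cohort")

  masks <- vector("list", nrow(cohort))
  processed <- cohort
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[i]]
    rec <- tryCatch(
      preprocess(rec, low = config$preprocess$low, high = config$preprocess$high,
                 order = config$preprocess$order,
                 znorm = config$preprocess$znormalize),
      error = function(e) {
        rlang::abort(sprintf("stage preprocess failed for subject %s: %s",
                             cohort$subject_id[i], conditionMessage(e)),
                     class = "eegscreen_stage_error", parent = e)
      })
    if (isTRUE(config$denoise$enabled)) {
      dn <- tryCatch(
        denoise(rec, window_s = config$sdw$window_s, k = config$sdw$k,
                threshold = config$sdw$threshold,
                n_ensemble = config$eemd$n_ensemble,
                noise_sd = config$eemd$noise_sd,
                max_imfs = config$eemd$max_imfs,
                sift_sd = config$eemd$sift_sd,
                max_sifts = config$eemd$max_sifts,
                rejection_threshold = config$rejection$threshold,
                reference = config$rejection$reference,
                crossfade_s = config$denoise$crossfade_s,
                seed = derive_seed(config$seed, 2L, i)),
        error = function(e) {
          rlang::abort(sprintf("stage denoise failed for subject %s: %s",
                               cohort$subject_id[i], conditionMessage(e)),
                       class = "eegscreen_stage_error", parent = e)
        })
      rec <- dn$recording
      masks[[i]] <- dn$mask
    } else {
      masks[[i]] <- tibble::tibble(start = integer(), end = integer())
    }
    processed$recording[[i]] <- rec
  }

  feats <- cohort_features(processed, config, preprocess = FALSE, denoise = FALSE)
  rel <- relative_power(feats, reference_group = config$features$reference_group)
  tests <- select_features(rel, alpha = config$stats$alpha,
                           method = config$stats$method)
  group_means <- rel |>
    tidyr::pivot_longer(dplyr::any_of(feature_names()),
                        names_to = "feature", values_to = "relative_power") |>
    dplyr::summarise(mean = mean(.data$relative_power), .by = c("group", "feature"))

  cv <- NULL
  if (isTRUE(config$classify$enabled)) {
    cv <- cross_validate(rel, folds = config$classify$folds,
                         seed = derive_seed(config$seed, 5L),
                         leakage = config$classify$leakage,
                         alpha = config$stats$alpha,
                         method = config$stats$method,
                         k_neighbors = config$classify$smote_k,
                         cost = config$classify$cost,
                         gamma = config$classify$gamma)
  }

  structure(list(
    config = config,
    cohort = cohort[setdiff(names(cohort), c("recording", "artifact_mask"))],
    masks = masks,
    features = feats,
    relative = rel,
    feature_tests = tests,
    group_means = group_means,
    cv = cv,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "eeg_run")
}

#' @export
print.eeg_run <- function(x, ...) {
  cat(sprintf("<eeg_run> %d subjects (%s)\n", nrow(x$cohort),
              paste(sprintf("%s %d", names(table(x$cohort$group)),
                            as.integer(table(x$cohort$group))), collapse = ", ")))
  cat(sprintf("  flagged intervals: %d across %d subjects\n",
              sum(vapply(x$masks, nrow, integer(1))),
              sum(vapply(x$masks, nrow, integer(1)) > 0)))
  cat(sprintf("  selected features: %d / %d\n",
              sum(x$feature_tests$selected), nrow(x$feature_tests)))
  if (!is.null(x$cv)) print(x$cv$metrics)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits the report as documented plain-text artifacts: feature matrix
#' CSV, relative-power CSV, feature-test CSV, mask CSV, per-group mean
#' relative power CSV, and a JSON summary (config echo, metrics,
#' per-fold results).
#'
#' @param run An `eeg_run` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$features, file.path(dir, "features.csv"))
  readr::write_csv(run$relative, file.path(dir, "relative_power.csv"))
  readr::write_csv(tibble::as_tibble(run$feature_tests),
                   file.path(dir, "feature_tests.csv"))
  readr::write_csv(run$group_means, file.path(dir, "group_means.csv"))
  masks <- purrr::map2_dfr(run$cohort$subject_id, run$masks, function(sid, m) {
    if (nrow(m) == 0L) return(NULL)
    tibble::tibble(subject_id = sid, start_sample = m$start, end_sample = m$end)
  })
  readr::write_csv(masks, file.path(dir, "artifact_masks.csv"))
  summary <- list(config = unclass(run$config),
                  n_subjects = nrow(run$cohort),
                  selected_features = run$feature_tests$feature[run$feature_tests$selected])
  if (!is.null(run$cv)) {
    summary$metrics <- run$cv$metrics
    summary$folds <- run$cv$folds
    summary$confusion_test <- as.data.frame.matrix(run$cv$confusion_test)
    readr::write_csv(run$cv$metrics, file.path(dir, "metrics.csv"))
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(dir)
}
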