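# Reading and writing recordings, cohort manifests and run configuration.
# CSV is the canonical on-disk format; sample indices are 0-based and all
# intervals are half-open [start, end) in samples.

#' Write / read a recording as CSV
#'
#' The canonical format is a two-column CSV `sample_index, amplitude`
#' with a header line. Metadata (sampling rate, subject, channel, MMSE)
#' travels in the manifest, not the sample file; `read_eeg_csv` takes the
#' sampling rate as an argument.
#'
#' @param recording An [eeg_recording()].
#' @param path File path.
#' @param digits Significant digits used on write (serialisation
#'   precision of the round trip).
#' @return `write_eeg_csv` returns `path` invisibly; `read_eeg_csv`
#'   returns an [eeg_recording()].
#' @export
write_eeg_csv <- function(recording, path, digits = 10) {
  assert_recording(recording)
  df <- data.frame(sample_index = recording$sample,
                   amplitude = signif(recording$amplitude, digits))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param fs Sampling rate in Hz of the stored samples.
#' @inheritParams eeg_recording
#' @export
read_eeg_csv <- function(path, fs, subject_id = NA_character_,
                         channel = "Fp1", mmse = NA_integer_,
                         group = NA_character_) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("integer", "numeric")),
    error = function(e) abort_format(paste0("malformed recording CSV ", path, ": ",
                                            conditionMessage(e)))
  )
  if (nrow(df) == 0L) abort_format(paste0("empty recording file: ", path))
  if (!all(c("sample_index", "amplitude") %in% names(df))) {
    abort_format(paste0(path, ": expected columns sample_index, amplitude"))
  }
  if (any(diff(df$sample_index) <= 0)) {
    bad <- which(diff(df$sample_index) <= 0)[1] + 1L
    abort_format(sprintf("%s: non-monotone sample index at line %d", path, bad + 1L))
  }
  if (anyNA(df$amplitude)) {
    abort_format(sprintf("%s: missing amplitude at line %d",
                         path, which(is.na(df$amplitude))[1] + 1L))
  }
  eeg_recording(df$amplitude, fs = fs, subject_id = subject_id,
                channel = channel, mmse = mmse, group = group)
}

#' Write / read a cohort to disk
#'
#' Writes one recording CSV per subject plus a manifest CSV
#' (`subject_id, path, mmse, group, seed, fs`). `read_cohort` loads the
#' manifest and all referenced recordings, enforcing the MMSE/group
#' consistency rule on load.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the manifest path invisibly;
#'   `read_cohort` returns a cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(cohort))
  fss <- numeric(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[i]]
    paths[i] <- file.path(dir, paste0(cohort$subject_id[i], ".csv"))
    fss[i] <- attr(rec, "fs")
    write_eeg_csv(rec, paths[i])
  }
  manifest <- data.frame(subject_id = cohort$subject_id, path = basename(paths),
                         mmse = cohort$mmse, group = cohort$group,
                         seed = cohort$seed, fs = fss)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' @rdname write_cohort
#' @param manifest_path Path to a manifest CSV.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort_format(paste0("manifest not found: ", manifest_path))
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "mmse", "group", "seed", "fs")
  if (!all(need %in% names(man))) {
    abort_format(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  base <- dirname(manifest_path)
  recs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- file.path(base, man$path[i])
    if (!file.exists(p)) abort_format(paste0("recording file missing: ", p))
    recs[[i]] <- read_eeg_csv(p, fs = man$fs[i], subject_id = man$subject_id[i],
                              mmse = man$mmse[i], group = man$group[i])
  }
  tibble::tibble(subject_id = man$subject_id, group = man$group,
                 mmse = as.integer(man$mmse), seed = as.integer(man$seed),
                 recording = recs,
                 artifact_mask = rep(list(tibble::tibble(start = integer(),
                                                         end = integer(),
                                                         type = character())),
                                     nrow(man)))
}

#' Pipeline run configuration
#'
#' All tunables of the pipeline in one (JSON-serialisable) list. The
#' defaults are the documented defaults of the individual stages.
#'
#' @return A named list of class `eeg_config`.
#' @export
default_config <- function() {
  structure(list(
    preprocess = list(low = 1, high = 30, order = 4, znormalize = TRUE),
    sdw = list(window_s = 2, k = 1.3, threshold = NULL),
    eemd = list(n_ensemble = 100, noise_sd = 0.2, max_imfs = 10,
                sift_sd = 0.2, max_sifts = 12),
    rejection = list(threshold = 0.5, reference = "segment"),
    denoise = list(enabled = TRUE, crossfade_s = 0.1),
    stft = list(window_s = 1, taper = "hann"),
    features = list(normalization = "sum_to_one", reference_group = "healthy"),
    stats = list(alpha = 0.05, method = "bonferroni"),
    classify = list(enabled = TRUE, folds = 10, leakage = "safe",
                    smote_k = 5, cost = 1, gamma = NULL),
    seed = 1
  ), class = "eeg_config")
}

#' @rdname default_config
#' @param config An `eeg_config` list.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_format(paste0("config not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (section in names(cfg)) {
    if (is.list(base[[section]])) {
      for (key in names(cfg[[section]])) base[[section]][[key]] <- cfg[[section]][[key]]
    } else {
      base[[section]] <- cfg[[section]]
    }
  }
  base
}
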