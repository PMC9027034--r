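#' Construct a single-channel EEG recording
#'
#' A recording is a tibble with integer column `sample` (0-based index)
#' and numeric column `amplitude`, carrying the sampling rate and subject
#' metadata as attributes. All pipeline stages accept and return this
#' shape, so recordings compose with the pipe.
#'
#' @param amplitude Numeric vector of samples (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier.
#' @param channel Electrode label; the study montage is a single
#'   prefrontal electrode, so the default is `"Fp1"`.
#' @param mmse Optional integer MMSE score in `[0, 30]`.
#' @param group Optional group label; when both `mmse` and `group` are
#'   given they must agree with [mmse_to_group()].
#' @return An `eeg_recording` tibble.
#' @export
eeg_recording <- function(amplitude, fs, subject_id = NA_character_,
                          channel = "Fp1", mmse = NA_integer_, group = NA_character_) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_invalid("`fs` must be a single positive number")
  }
  if (length(amplitude) == 0L) abort_invalid("`amplitude` must be non-empty")
  if (!is.na(mmse)) {
    mmse <- validate_mmse(mmse)
    implied <- mmse_to_group(mmse)
    if (!is.na(group) && !identical(group, implied)) {
      abort_invalid(sprintf("group '%s' inconsistent with MMSE %d (implies '%s')",
                            group, mmse, implied))
    }
    group <- implied
  }
  out <- tibble::tibble(sample = seq_along(amplitude) - 1L,
                        amplitude = as.numeric(amplitude))
  structure(out,
            fs = fs, subject_id = subject_id, channel = channel,
            mmse = mmse, group = group,
            class = c("eeg_recording", class(out)))
}

validate_mmse <- function(score) {
  if (length(score) != 1L || is.na(score) || !is.numeric(score) ||
      score != round(score) || score < 0 || score > 30) {
    abort_invalid("MMSE score must be a single integer in [0, 30]")
  }
  as.integer(score)
}

#' Map an MMSE score to a diagnostic group
#'
#' The study's labelling rule: scores of 24 or lower are dementia,
#' 25--27 mild cognitive impairment, 28 or higher healthy.
#'
#' @param score Integer MMSE score in `[0, 30]` (vectorised).
#' @return Character vector of labels in
#'   `c("dementia", "mci", "healthy")`.
#' @examples
#' mmse_to_group(c(24, 25, 27, 28))
#' @export
mmse_to_group <- function(score) {
  vapply(score, function(s) {
    s <- validate_mmse(s)
    if (s <= 24) "dementia" else if (s <= 27) "mci" else "healthy"
  }, character(1))
}

# Accessors -------------------------------------------------------------

#' @export
#' @rdname eeg_recording
#' @param x An `eeg_recording`.
fs <- function(x) attr(x, "fs")

rec_samples <- function(x) x[["amplitude"]]

rec_meta <- function(x) {
  list(fs = attr(x, "fs"), subject_id = attr(x, "subject_id"),
       channel = attr(x, "channel"), mmse = attr(x, "mmse"),
       group = attr(x, "group"))
}

# Rebuild a recording from new samples, keeping metadata.
rec_update <- function(x, amplitude) {
  m <- rec_meta(x)
  eeg_recording(amplitude, fs = m$fs, subject_id = m$subject_id,
                channel = m$channel, mmse = m$mmse, group = m$group)
}

assert_recording <- function(x, arg = "recording") {
  if (!inherits(x, "eeg_recording")) {
    abort_invalid(sprintf("`%s` must be an eeg_recording (see eeg_recording())", arg))
  }
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  m <- rec_meta(x)
  cat(sprintf("<eeg_recording> %s  %s  %d samples @ %g Hz (%.1f s)",
              m$subject_id %||% "?", m$channel, nrow(x), m$fs, nrow(x) / m$fs))
  if (!is.na(m$mmse)) cat(sprintf("  MMSE %d (%s)", m$mmse, m$group))
  cat("\n")
  NextMethod()
}
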