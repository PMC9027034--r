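# Band-limiting and standardisation applied to every recording before
# artifact handling and feature extraction.

#' Zero-phase Butterworth bandpass
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the passband gain is ~1 and there is no group
#' delay. Defaults to the 1--30 Hz EEG band.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Butterworth order (per direction).
#' @return A filtered [eeg_recording()] of the same length.
#' @examples
#' rec <- generate_recording(spectral_profile(), fs = 256, duration_s = 4, seed = 1)
#' filtered <- bandpass(rec)
#' @export
bandpass <- function(recording, low = 1, high = 30, order = 4) {
  assert_recording(recording)
  fsr <- attr(recording, "fs")
  if (!is.numeric(low) || !is.numeric(high) ||
      low <= 0 || high <= low || high >= fsr / 2) {
    abort_invalid("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fsr / 2), type = "pass")
  y <- signal::filtfilt(bf, rec_samples(recording))
  rec_update(recording, y)
}

#' Z-normalise a recording
#'
#' Centres to mean 0 and scales to population variance 1 (divisor `n`,
#' not `n - 1`; at full recording length the two are indistinguishable
#' but the contract is exact). Idempotent, and invariant to positive
#' affine rescaling of the input.
#'
#' @param recording An [eeg_recording()].
#' @return A standardised [eeg_recording()].
#' @export
znormalize <- function(recording) {
  assert_recording(recording)
  x <- rec_samples(recording)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) abort_degenerate("constant signal cannot be z-normalised")
  rec_update(recording, (x - m) / sqrt(v))
}

#' Bandpass then z-normalise
#'
#' The standard preprocessing applied by the pipeline to every
#' recording.
#'
#' @inheritParams bandpass
#' @param znorm Apply [znormalize()] after filtering.
#' @return A preprocessed [eeg_recording()].
#' @export
preprocess <- function(recording, low = 1, high = 30, order = 4, znorm = TRUE) {
  out <- bandpass(recording, low = low, high = high, order = order)
  if (znorm) out <- znormalize(out)
  out
}
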