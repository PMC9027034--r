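# Artifact detection (windowed derivative-sum score) and removal
# (EEMD in flagged intervals, correlation-based IMF rejection,
# reconstruction with crossfaded splicing).

#' Derivative-sum score of a window
#'
#' The score of a window is the sum of absolute first differences
#' (discrete total variation). Smooth, low-amplitude EEG yields a low
#' score; high-amplitude transients raise it. Zero if and only if the
#' window is constant.
#'
#' @param window Numeric vector, length >= 2.
#' @return Non-negative scalar score.
#' @examples
#' sdw_score(c(0, 1, 0, 1, 0))  # 4
#' @export
sdw_score <- function(window) {
  if (!is.numeric(window) || length(window) < 2) {
    abort_invalid("`window` must be a numeric vector of length >= 2")
  }
  sum(abs(diff(window)))
}

#' Detect contaminated intervals by windowed derivative sums
#'
#' Partitions the recording into consecutive non-overlapping windows of
#' `window_s` seconds (a trailing partial window is never scored or
#' flagged), scores each with [sdw_score()], and flags windows whose
#' score exceeds an adaptive threshold. Adjacent flagged windows are
#' merged into one interval.
#'
#' The default threshold is `median + k * s`, where `s` is a one-sided
#' robust scale: the median of the deviations *below* the median,
#' rescaled for consistency with the normal SD. Because artifacts can
#' only inflate scores, estimating scale from the lower half keeps the
#' threshold calibrated even when a sizeable fraction of windows is
#' contaminated. Pass a finite `threshold` to override the adaptive
#' policy entirely; `threshold = Inf` disables detection.
#'
#' @param recording An [eeg_recording()] (typically preprocessed).
#' @param window_s Window length in seconds (default 2 s).
#' @param k Multiplier of the robust scale in the adaptive threshold.
#' @param threshold Optional absolute score threshold overriding the
#'   adaptive policy.
#' @return An artifact mask: tibble with half-open sample intervals
#'   `[start, end)` (0-based), plus attributes `threshold` and `scores`
#'   for auditability.
#' @export
sdw_detect <- function(recording, window_s = 2, k = 1.3, threshold = NULL) {
  assert_recording(recording)
  x <- rec_samples(recording)
  fsr <- attr(recording, "fs")
  w <- round(window_s * fsr)
  if (w < 2) abort_invalid("window must span at least 2 samples")
  nw <- floor(length(x) / w)
  if (nw < 1) abort_degenerate("recording shorter than one detection window")
  scores <- vapply(seq_len(nw), function(i) {
    sdw_score(x[((i - 1) * w + 1):(i * w)])
  }, numeric(1))
  if (is.null(threshold)) {
    med <- stats::median(scores)
    below <- med - scores[scores < med]
    s <- if (length(below) >= 2) stats::median(below) / 0.6745 else 0
    threshold <- med + k * s
  }
  flagged <- which(scores > threshold)
  mask <- merge_intervals((flagged - 1L) * w, flagged * w)
  structure(mask, threshold = threshold, scores = scores)
}

# -- IMF rejection ------------------------------------------------------

# Maximum over all lags of the absolute normalised cross-correlation
# (biased estimator: fixed denominator sqrt(sum(a^2) * sum(b^2)) after
# demeaning), computed via FFT.
max_crosscorr <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) return(0)
  nf <- stats::nextn(2 * n, 2)
  A <- stats::fft(c(a, rep(0, nf - n)))
  B <- stats::fft(c(b, rep(0, nf - n)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / nf
  max(abs(cc)) / denom
}

#' Reject noise IMFs by cross-correlation
#'
#' Splits a decomposition into kept and rejected IMFs. With
#' `reference = "segment"` (default) each IMF's maximum-over-lags
#' normalised cross-correlation with the original segment (the sum of
#' all IMFs plus residual) is computed, and IMFs exceeding `threshold`
#' are rejected: in a window flagged as contaminated, the segment is
#' dominated by the artifact, so the artifact-carrying components are
#' precisely those that track it. With `reference = "imfs"` the
#' criterion is instead the mean of each IMF's maximum cross-correlation
#' with every other IMF (a single IMF then has mean 0 over the empty set
#' and is kept). The residual is never subject to rejection.
#'
#' @param decomp An `imf_decomposition` from [emd()] or [eemd()].
#' @param threshold Correlation threshold (default 0.5).
#' @param reference `"segment"` or `"imfs"`.
#' @return List with `kept` and `rejected` (lists of IMFs), `residual`,
#'   and `stats` (tibble: imf index, mean/max correlation, rejected
#'   flag).
#' @export
reject_imfs <- function(decomp, threshold = 0.5,
                        reference = c("segment", "imfs")) {
  if (!inherits(decomp, "imf_decomposition")) {
    abort_invalid("`decomp` must be an imf_decomposition")
  }
  reference <- match.arg(reference)
  K <- length(decomp$imfs)
  if (K == 0L) {
    return(list(kept = list(), rejected = list(), residual = decomp$residual,
                stats = tibble::tibble(imf = integer(), correlation = numeric(),
                                       rejected = logical())))
  }
  if (reference == "segment") {
    segment <- Reduce(`+`, decomp$imfs) + decomp$residual
    corr <- vapply(decomp$imfs, function(im) max_crosscorr(im, segment), numeric(1))
  } else {
    corr <- vapply(seq_len(K), function(i) {
      others <- setdiff(seq_len(K), i)
      if (length(others) == 0L) return(0)
      mean(vapply(others, function(j) {
        max_crosscorr(decomp$imfs[[i]], decomp$imfs[[j]])
      }, numeric(1)))
    }, numeric(1))
  }
  rejected <- corr > threshold
  list(kept = decomp$imfs[!rejected],
       rejected = decomp$imfs[rejected],
       residual = decomp$residual,
       stats = tibble::tibble(imf = seq_len(K), correlation = corr,
                              rejected = rejected))
}

#' Reconstruct a signal from kept IMFs and residual
#'
#' Element-wise sum. Keeping every IMF reproduces the decomposed
#' segment exactly; keeping none returns the residual.
#'
#' @param kept List of equal-length numeric vectors (possibly empty).
#' @param residual Numeric vector.
#' @return Numeric vector of the same length as `residual`.
#' @export
reconstruct <- function(kept, residual) {
  if (!is.numeric(residual)) abort_invalid("`residual` must be numeric")
  lens <- vapply(kept, length, integer(1))
  if (any(lens != length(residual))) {
    abort_invalid("all IMFs must have the same length as the residual")
  }
  Reduce(`+`, kept, accumulate = FALSE, right = FALSE,
         init = residual)
}

# Raised-cosine crossfade between original and cleaned samples at the
# boundaries of a replaced interval, within the interval.
splice_cleaned <- function(x, cleaned, start0, end0, fade_n) {
  idx <- (start0 + 1L):end0
  seg <- cleaned
  L <- length(idx)
  f <- min(fade_n, floor(L / 2))
  if (f > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(f) / (f + 1)))
    seg[seq_len(f)] <- (1 - ramp) * x[idx[seq_len(f)]] + ramp * seg[seq_len(f)]
    tail_i <- (L - f + 1):L
    seg[tail_i] <- rev(ramp) * seg[tail_i] + (1 - rev(ramp)) * x[idx[tail_i]]
  }
  x[idx] <- seg
  x
}

#' Detect and remove artifacts from a recording
#'
#' The full artifact-removal stage: flag contaminated intervals with
#' [sdw_detect()], decompose each flagged segment with [eemd()], drop
#' the artifact-carrying IMFs with [reject_imfs()], reconstruct the
#' cleaned segment, and splice it back with a raised-cosine crossfade at
#' the interval boundaries. Samples outside flagged intervals are
#' untouched (up to the crossfade margin, which lies inside the
#' intervals). Deterministic given `seed`.
#'
#' @param recording A preprocessed [eeg_recording()].
#' @param window_s,k,threshold Passed to [sdw_detect()].
#' @param n_ensemble,noise_sd,max_imfs,sift_sd,max_sifts Passed to
#'   [eemd()].
#' @param rejection_threshold,reference Passed to [reject_imfs()].
#' @param crossfade_s Crossfade length in seconds at each interval edge.
#' @param seed Integer seed (per-interval EEMD seeds are derived from
#'   it).
#' @return List with `recording` (cleaned) and `mask` (the detected
#'   intervals, as returned by [sdw_detect()]).
#' @export
denoise <- function(recording, window_s = 2, k = 1.3, threshold = NULL,
                    n_ensemble = 100, noise_sd = 0.2, max_imfs = 10,
                    sift_sd = 0.2, max_sifts = 12,
                    rejection_threshold = 0.5,
                    reference = c("segment", "imfs"),
                    crossfade_s = 0.1, seed = 1) {
  assert_recording(recording)
  reference <- match.arg(reference)
  mask <- sdw_detect(recording, window_s = window_s, k = k, threshold = threshold)
  x <- rec_samples(recording)
  fsr <- attr(recording, "fs")
  fade_n <- round(crossfade_s * fsr)
  if (nrow(mask) > 0) {
    for (i in seq_len(nrow(mask))) {
      seg <- x[(mask$start[i] + 1L):mask$end[i]]
      dec <- eemd(seg, n_ensemble = n_ensemble, noise_sd = noise_sd,
                  seed = derive_seed(seed, i), max_imfs = max_imfs,
                  sift_sd = sift_sd, max_sifts = max_sifts)
      rj <- reject_imfs(dec, threshold = rejection_threshold,
                        reference = reference)
      cleaned <- reconstruct(rj$kept, rj$residual)
      x <- splice_cleaned(x, cleaned, mask$start[i], mask$end[i], fade_n)
    }
  }
  list(recording = rec_update(recording, x), mask = mask)
}
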