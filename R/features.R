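# Spectral features: per-second power spectra, 1-Hz bin features,
# band powers, and control-referenced relative power.

#' Short-time Fourier power spectra
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `window_s` seconds (trailing partial window dropped), applies the
#' taper, and returns the one-sided magnitude-squared spectrum of each
#' window. The normalisation is Parseval-consistent: summing `power`
#' over all frequencies of a window equals that window's mean square
#' value (after tapering, compensated by the taper's power), so spectra
#' are comparable across tapers.
#'
#' @param recording An [eeg_recording()].
#' @param window_s Window length in seconds (default 1 s, i.e. 1 Hz
#'   resolution).
#' @param taper `"hann"` (default) or `"rect"`.
#' @return A tibble with columns `window` (1-based), `freq` (Hz) and
#'   `power` (>= 0).
#' @export
stft_power <- function(recording, window_s = 1, taper = c("hann", "rect")) {
  assert_recording(recording)
  taper <- match.arg(taper)
  x <- rec_samples(recording)
  fsr <- attr(recording, "fs")
  L <- round(window_s * fsr)
  if (L < 2) abort_invalid("window must span at least 2 samples")
  nw <- floor(length(x) / L)
  if (nw < 1) abort_degenerate("recording shorter than one STFT window")
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1))) else rep(1, L)
  wpow <- mean(w^2)
  half <- floor(L / 2)
  freqs <- (0:half) * fsr / L
  out <- vector("list", nw)
  for (i in seq_len(nw)) {
    seg <- x[((i - 1) * L + 1):(i * L)] * w
    X <- stats::fft(seg)[1:(half + 1)]
    p <- Mod(X)^2 / (L^2 * wpow)
    # one-sided: double everything except DC (and Nyquist when L even)
    mult <- rep(2, half + 1)
    mult[1] <- 1
    if (L %% 2 == 0) mult[half + 1] <- 1
    out[[i]] <- tibble::tibble(window = i, freq = freqs, power = p * mult)
  }
  dplyr::bind_rows(out)
}

#' 1-Hz bin features from STFT spectra
#'
#' Averages each integer frequency bin 1..45 Hz across windows, then
#' scales the 45 bins to sum to one (the "sum-to-one" normalisation
#' state). Each bin takes the spectral value at the grid frequency
#' closest to the integer (exact when `fs * window_s` is an integer
#' multiple of 1 Hz, as with 512 Hz and 1 s windows).
#'
#' @param spectra Output of [stft_power()].
#' @param normalize Scale the bins to sum to one (default `TRUE`).
#' @return A one-row tibble with columns `bin_1` ... `bin_45`.
#' @export
bin_features <- function(spectra, normalize = TRUE) {
  if (!all(c("window", "freq", "power") %in% names(spectra))) {
    abort_invalid("`spectra` must come from stft_power()")
  }
  if (nrow(spectra) == 0L) abort_degenerate("no spectra to average")
  mean_spec <- spectra |>
    dplyr::summarise(power = mean(.data$power), .by = "freq")
  bins <- vapply(1:45, function(f) {
    j <- which.min(abs(mean_spec$freq - f))
    if (abs(mean_spec$freq[j] - f) > 0.5) {
      abort_invalid(sprintf("no spectral bin near %d Hz; increase fs or window", f))
    }
    mean_spec$power[j]
  }, numeric(1))
  if (normalize) {
    tot <- sum(bins)
    if (tot <= 0) abort_degenerate("all-zero spectrum: sum-to-one normalisation undefined")
    bins <- bins / tot
  }
  out <- tibble::as_tibble(as.list(stats::setNames(bins, paste0("bin_", 1:45))))
  out
}

#' Band powers from bin features
#'
#' Adds the ten canonical band powers to a feature table. Each band
#' power is the mean of its constituent 1-Hz bins under the half-open
#' edge convention of [eeg_bands()] (so e.g. the 4 Hz bin counts toward
#' theta, not delta). Works on multi-row feature tables.
#'
#' @param features A tibble containing columns `bin_1` ... `bin_45`.
#' @return The input with ten band columns appended (delta, theta,
#'   alpha, alpha1, alpha2, alpha3, beta, beta1, beta2, gamma).
#' @export
band_powers <- function(features) {
  if (!all(paste0("bin_", 1:45) %in% names(features))) {
    abort_invalid("`features` must contain columns bin_1 ... bin_45")
  }
  binmat <- as.matrix(features[paste0("bin_", 1:45)])
  for (b in eeg_bands()$band) {
    features[[b]] <- rowMeans(binmat[, band_bins(b), drop = FALSE])
  }
  features
}

#' Spectral features of one recording
#'
#' Convenience wrapper: [stft_power()] then [bin_features()] then
#' [band_powers()], yielding the 55 candidate features (45 bins + 10
#' bands) of one recording as a one-row tibble.
#'
#' @inheritParams stft_power
#' @return One-row tibble with 55 feature columns.
#' @export
spectral_features <- function(recording, window_s = 1, taper = c("hann", "rect")) {
  stft_power(recording, window_s = window_s, taper = match.arg(taper)) |>
    bin_features() |>
    band_powers()
}

#' Feature matrix of a cohort
#'
#' Applies [spectral_features()] to every recording of a cohort and
#' binds subject metadata, optionally preprocessing and denoising each
#' recording first.
#'
#' @param cohort A cohort tibble (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config An [default_config()] list controlling preprocessing,
#'   denoising and the STFT.
#' @param preprocess,denoise Stage switches; denoising requires
#'   preprocessing.
#' @return A tibble with `subject_id`, `group`, `mmse` and the 55
#'   feature columns.
#' @export
cohort_features <- function(cohort, config = default_config(),
                            preprocess = TRUE, denoise = config$denoise$enabled) {
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[i]]
    if (preprocess) {
      rec <- eegscreen::preprocess(rec, low = config$preprocess$low,
                                   high = config$preprocess$high,
                                   order = config$preprocess$order,
                                   znorm = config$preprocess$znormalize)
    }
    if (denoise) {
      rec <- eegscreen::denoise(
        rec, window_s = config$sdw$window_s, k = config$sdw$k,
        threshold = config$sdw$threshold,
        n_ensemble = config$eemd$n_ensemble, noise_sd = config$eemd$noise_sd,
        max_imfs = config$eemd$max_imfs, sift_sd = config$eemd$sift_sd,
        max_sifts = config$eemd$max_sifts,
        rejection_threshold = config$rejection$threshold,
        reference = config$rejection$reference,
        crossfade_s = config$denoise$crossfade_s,
        seed = derive_seed(config$seed, 2L, i))$recording
    }
    feats <- spectral_features(rec, window_s = config$stft$window_s,
                               taper = config$stft$taper)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = cohort$subject_id[i],
                     group = cohort$group[i], mmse = cohort$mmse[i]),
      feats)
  }
  dplyr::bind_rows(rows)
}

#' Control-referenced relative power
#'
#' Divides every subject's features element-wise by the reference
#' group's mean, so the reference group's post-scaling mean is exactly 1
#' in every feature. This is the study's "relative power spectrum":
#' group contrasts are expressed as ratios to the healthy-control mean.
#'
#' @param features A feature tibble with a `group` column (e.g. from
#'   [cohort_features()]).
#' @param reference_group Group whose mean becomes 1 (default
#'   `"healthy"`).
#' @return The feature tibble with all feature columns rescaled.
#' @export
relative_power <- function(features, reference_group = "healthy") {
  if (!"group" %in% names(features)) abort_invalid("`features` must have a `group` column")
  feat_cols <- intersect(feature_names(), names(features))
  if (length(feat_cols) == 0L) abort_invalid("no feature columns found")
  ref <- features[features$group == reference_group, feat_cols, drop = FALSE]
  if (nrow(ref) == 0L) {
    abort_degenerate(paste0("reference group '", reference_group, "' is empty"))
  }
  ref_mean <- colMeans(as.matrix(ref))
  zero <- names(ref_mean)[ref_mean <= 0]
  if (length(zero)) {
    abort_degenerate(paste0("reference mean is zero in feature(s): ",
                            paste(zero, collapse = ", ")))
  }
  for (cn in feat_cols) features[[cn]] <- features[[cn]] / ref_mean[[cn]]
  features
}
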