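# Synthetic cohort generator: band-structured EEG with 1/f background and
# ground-truth blink / EMG / line-noise artifacts.

#' Spectral profile of a synthetic EEG source
#'
#' Describes one group's resting-state spectrum as relative power weights
#' over the eight generator bands (delta, theta, alpha1, alpha2, alpha3,
#' beta1, beta2, gamma) plus an aperiodic 1/f background. Weights are
#' dimensionless and only their ratios matter; the generated signal is
#' rescaled to `total_rms`.
#'
#' The default weights emulate eyes-closed resting EEG recorded at Fp1 in
#' an elderly population: power concentrated below 13 Hz, modest beta and
#' very little scalp gamma.
#'
#' @param band_weights Named non-negative numeric vector over the
#'   generator bands. At least one of `band_weights`/`pink_weight` must
#'   be positive for a non-degenerate profile.
#' @param pink_exponent Slope of the 1/f^a background (default 1).
#' @param pink_weight Relative weight of the 1/f background next to the
#'   band weights; 0 disables it.
#' @param total_rms Target RMS amplitude of the generated signal
#'   (arbitrary units; the pipeline z-normalises anyway).
#' @return A `spectral_profile` object.
#' @export
spectral_profile <- function(band_weights = c(delta = 0.45, theta = 0.22,
                                              alpha1 = 0.05, alpha2 = 0.10,
                                              alpha3 = 0.05, beta1 = 0.05,
                                              beta2 = 0.025, gamma = 0.01),
                             pink_exponent = 1, pink_weight = 0.25,
                             total_rms = 1) {
  allowed <- c("delta", "theta", "alpha1", "alpha2", "alpha3",
               "beta1", "beta2", "gamma")
  if (length(band_weights) > 0) {
    if (is.null(names(band_weights)) || !all(names(band_weights) %in% allowed)) {
      abort_invalid(paste0("band_weights must be named from: ",
                           paste(allowed, collapse = ", ")))
    }
  }
  if (any(band_weights < 0) || pink_weight < 0) {
    abort_invalid("band and pink weights must be >= 0")
  }
  if (total_rms < 0) abort_invalid("total_rms must be >= 0")
  w <- stats::setNames(rep(0, length(allowed)), allowed)
  w[names(band_weights)] <- band_weights
  structure(list(band_weights = w, pink_exponent = pink_exponent,
                 pink_weight = pink_weight, total_rms = total_rms),
            class = "spectral_profile")
}

#' Ready-made group spectral profiles
#'
#' Two presets covering the two physiologically opposite readings of how
#' patient spectra differ from controls. `"slowing"` gives dementia and
#' MCI groups relatively more low-frequency (delta/theta) and less alpha
#' power than controls -- the classical EEG slowing picture. `"control_delta"`
#' is the reversed reading in which the healthy group carries the higher
#' relative delta power. Neither direction is asserted as ground truth;
#' both orderings are supported so either hypothesis can be simulated.
#'
#' @param direction `"slowing"` or `"control_delta"`.
#' @param total_rms Passed to [spectral_profile()].
#' @return Named list of three `spectral_profile`s
#'   (`dementia`, `mci`, `healthy`).
#' @export
cohort_profiles <- function(direction = c("slowing", "control_delta"),
                            total_rms = 1) {
  direction <- match.arg(direction)
  base <- c(delta = 0.45, theta = 0.22, alpha1 = 0.05, alpha2 = 0.10,
            alpha3 = 0.05, beta1 = 0.05, beta2 = 0.025, gamma = 0.01)
  slow <- c(delta = 0.58, theta = 0.26, alpha1 = 0.035, alpha2 = 0.055,
            alpha3 = 0.03, beta1 = 0.025, beta2 = 0.01, gamma = 0.005)
  mid <- sqrt(base * slow)  # geometric midpoint for the MCI group
  mk <- function(w) spectral_profile(w, total_rms = total_rms)
  if (direction == "slowing") {
    list(dementia = mk(slow), mci = mk(mid), healthy = mk(base))
  } else {
    list(dementia = mk(base), mci = mk(mid), healthy = mk(slow))
  }
}

#' Artifact specification for the generator
#'
#' Event rates are per minute; amplitudes are multiples of the clean
#' signal's RMS. Blinks use a biphasic template (fast ~40 ms rise to the
#' peak, ~90 ms fall overshooting to -0.3 of the peak, ~120 ms recovery),
#' matching the sharp deflection plus rebound seen in frontal blink
#' artifacts. EMG events are band-limited bursts; line noise is a
#' continuous sinusoid and is not covered by the ground-truth mask
#' (the mask marks transient events only).
#'
#' @param blink_rate,emg_rate Events per minute (>= 0).
#' @param blink_count Exact number of blinks to inject, overriding the
#'   Poisson draw implied by `blink_rate` (used by fixed-design test
#'   suites).
#' @param blink_amplitude,emg_amplitude Peak (blink) or RMS (EMG)
#'   amplitude as a multiple of background RMS.
#' @param emg_band Two-element Hz range of the EMG burst.
#' @param emg_duration_s EMG burst duration in seconds.
#' @param line_freq Mains frequency in Hz (50 or 60).
#' @param line_amplitude Line-noise sinusoid amplitude as a multiple of
#'   background RMS; 0 disables.
#' @return An `artifact_spec` object.
#' @export
artifact_spec <- function(blink_rate = 3, blink_amplitude = 10,
                          blink_count = NULL,
                          emg_rate = 0, emg_amplitude = 3,
                          emg_band = c(20, 45), emg_duration_s = 0.5,
                          line_freq = 50, line_amplitude = 0) {
  if (blink_rate < 0 || emg_rate < 0) abort_invalid("rates must be >= 0")
  if (blink_amplitude < 0 || emg_amplitude < 0 || line_amplitude < 0) {
    abort_invalid("amplitudes must be >= 0")
  }
  if (emg_duration_s <= 0) abort_invalid("emg_duration_s must be > 0")
  structure(list(blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 blink_count = blink_count,
                 emg_rate = emg_rate, emg_amplitude = emg_amplitude,
                 emg_band = emg_band, emg_duration_s = emg_duration_s,
                 line_freq = line_freq, line_amplitude = line_amplitude),
            class = "artifact_spec")
}

#' Cohort specification
#'
#' Defaults reproduce the study geometry: 10 dementia, 33 MCI and 77
#' control subjects, 100 s of eyes-closed EEG at 512 Hz each, with MMSE
#' ranges dementia `[0, 24]`, MCI `[25, 27]`, healthy `[28, 30]`.
#'
#' @param n_dementia,n_mci,n_control Subject counts (>= 0).
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param profiles Named list of `spectral_profile`s per group; defaults
#'   to [cohort_profiles()]`("slowing")`.
#' @param artifacts An [artifact_spec()] applied to every subject, or
#'   `NULL` for artifact-free recordings.
#' @param mmse_ranges Named list of inclusive integer score ranges; must
#'   be disjoint and within `[0, 30]`.
#' @param seed Master seed for the cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_dementia = 10, n_mci = 33, n_control = 77,
                        fs = 512, duration_s = 100,
                        profiles = cohort_profiles("slowing"),
                        artifacts = NULL,
                        mmse_ranges = list(dementia = c(0, 24),
                                           mci = c(25, 27),
                                           healthy = c(28, 30)),
                        seed = 1) {
  counts <- c(n_dementia, n_mci, n_control)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_invalid("subject counts must be non-negative integers")
  }
  if (fs <= 0 || duration_s <= 0) abort_invalid("fs and duration_s must be > 0")
  if (!all(eeg_groups() %in% names(mmse_ranges))) {
    abort_invalid("mmse_ranges must name dementia, mci and healthy")
  }
  rng <- do.call(rbind, mmse_ranges[eeg_groups()])
  if (any(rng < 0) || any(rng > 30) || any(rng[, 1] > rng[, 2])) {
    abort_invalid("mmse_ranges must be valid inclusive ranges within [0, 30]")
  }
  covered <- unlist(lapply(eeg_groups(), function(g) {
    seq.int(mmse_ranges[[g]][1], mmse_ranges[[g]][2])
  }))
  if (anyDuplicated(covered)) abort_invalid("mmse_ranges must be disjoint")
  for (g in eeg_groups()) {
    implied <- mmse_to_group(seq.int(mmse_ranges[[g]][1], mmse_ranges[[g]][2]))
    if (!all(implied == g)) {
      abort_invalid(sprintf("mmse_ranges[['%s']] conflicts with the labelling rule", g))
    }
  }
  if (!all(eeg_groups() %in% names(profiles))) {
    abort_invalid("profiles must name dementia, mci and healthy")
  }
  structure(list(n_dementia = n_dementia, n_mci = n_mci, n_control = n_control,
                 fs = fs, duration_s = duration_s, profiles = profiles,
                 artifacts = artifacts, mmse_ranges = mmse_ranges, seed = seed),
            class = "cohort_spec")
}

# -- signal synthesis ---------------------------------------------------

generator_band_edges <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha1 = c(8, 9), alpha2 = c(9, 11),
       alpha3 = c(11, 13), beta1 = c(13, 20), beta2 = c(20, 30),
       gamma = c(30, 45))
}

# Band-limited Gaussian noise with unit RMS (4th-order Butterworth on white
# noise; keeps phases realistic compared to inverse-FFT shaping).
band_noise <- function(n, lo, hi, fs) {
  hi <- min(hi, 0.999 * fs / 2)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Unit-RMS 1/f^a noise via spectral shaping of white Gaussian noise.
pink_noise <- function(n, exponent = 1) {
  X <- stats::fft(stats::rnorm(n))
  k <- c(1, seq_len(n - 1))
  k <- pmin(k, n - k + 1)          # symmetric frequency index
  X <- X / k^(exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Generate one synthetic EEG recording
#'
#' The signal is a sum over bands of band-limited Gaussian noise with
#' per-band power proportional to the profile's weights, superposed on a
#' 1/f background, and rescaled to the profile's target RMS. Exactly
#' `round(fs * duration_s)` samples are produced and the result is
#' deterministic given `seed`.
#'
#' @param profile A [spectral_profile()].
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @inheritParams eeg_recording
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(profile, fs = 512, duration_s = 100, seed = 1,
                               subject_id = NA_character_,
                               mmse = NA_integer_, group = NA_character_) {
  if (!inherits(profile, "spectral_profile")) {
    abort_invalid("`profile` must be a spectral_profile")
  }
  if (fs <= 0 || duration_s <= 0) abort_invalid("fs and duration_s must be > 0")
  n <- round(fs * duration_s)
  if (n < 1) abort_invalid("fs * duration_s must round to at least one sample")
  edges <- generator_band_edges()
  w <- profile$band_weights
  withr::with_seed(seed, {
    x <- numeric(n)
    for (b in names(edges)) {
      if (w[[b]] > 0) {
        x <- x + band_noise(n, edges[[b]][1], edges[[b]][2], fs) * sqrt(w[[b]])
      }
    }
    if (profile$pink_weight > 0) {
      x <- x + pink_noise(n, profile$pink_exponent) * sqrt(profile$pink_weight)
    }
  })
  tot <- sqrt(sum(w) + profile$pink_weight)
  if (tot > 0 && profile$total_rms > 0) {
    r <- sqrt(mean(x^2))
    if (r > 0) x <- x / r * profile$total_rms
  }
  eeg_recording(x, fs = fs, subject_id = subject_id, mmse = mmse, group = group)
}

# Biphasic blink template, unit peak: raised-cosine rise, fall through an
# undershoot of -0.3, raised-cosine recovery back to baseline.
blink_template <- function(fs, undershoot = 0.3,
                           rise_s = 0.04, fall_s = 0.09, recover_s = 0.12) {
  r <- max(2L, round(rise_s * fs))
  f <- max(2L, round(fall_s * fs))
  rc <- max(2L, round(recover_s * fs))
  c(0.5 * (1 - cos(pi * seq_len(r) / r)),
    1 - (1 + undershoot) * 0.5 * (1 - cos(pi * seq_len(f) / f)),
    -undershoot * 0.5 * (1 + cos(pi * seq_len(rc) / rc)))
}

#' Inject artifacts with a ground-truth mask
#'
#' Adds blink transients, EMG bursts and (optionally) continuous line
#' noise to a recording. The returned mask lists the half-open sample
#' intervals `[start, end)` (0-based) covering every transient event;
#' line noise, being continuous, is not masked.
#'
#' @param recording An [eeg_recording()].
#' @param spec An [artifact_spec()].
#' @param seed Integer seed.
#' @return A list with elements `recording` (contaminated copy) and
#'   `mask` (tibble `start`, `end`, `type`).
#' @export
inject_artifacts <- function(recording, spec = artifact_spec(), seed = 1) {
  assert_recording(recording)
  if (!inherits(spec, "artifact_spec")) abort_invalid("`spec` must be an artifact_spec")
  x <- rec_samples(recording)
  n <- length(x)
  fsr <- attr(recording, "fs")
  rms <- sqrt(mean(x^2))
  if (rms == 0) rms <- 1   # degenerate zero signal: amplitudes become absolute
  dur_min <- n / fsr / 60
  starts <- integer(); ends <- integer(); types <- character()
  withr::with_seed(seed, {
    n_blink <- if (!is.null(spec$blink_count)) {
      spec$blink_count
    } else if (spec$blink_rate > 0) {
      stats::rpois(1, spec$blink_rate * dur_min)
    } else 0L
    if (n_blink > 0 && spec$blink_amplitude > 0) {
      tmpl <- blink_template(fsr) * spec$blink_amplitude * rms
      L <- length(tmpl)
      if (n > L) {
        pos <- sort(sample.int(n - L, n_blink, replace = FALSE))
        for (p in pos) {
          x[p:(p + L - 1)] <- x[p:(p + L - 1)] + tmpl
          starts <- c(starts, p - 1L); ends <- c(ends, p + L - 1L)
          types <- c(types, "blink")
        }
      }
    }
    n_emg <- if (spec$emg_rate > 0) stats::rpois(1, spec$emg_rate * dur_min) else 0L
    if (n_emg > 0 && spec$emg_amplitude > 0) {
      L <- round(spec$emg_duration_s * fsr)
      if (n > L && L >= 8) {
        env <- sin(pi * seq_len(L) / L)^2
        pos <- sort(sample.int(n - L, n_emg, replace = FALSE))
        for (p in pos) {
          burst <- band_noise(L, spec$emg_band[1], spec$emg_band[2], fsr)
          burst <- burst * env * spec$emg_amplitude * rms
          x[p:(p + L - 1)] <- x[p:(p + L - 1)] + burst
          starts <- c(starts, p - 1L); ends <- c(ends, p + L - 1L)
          types <- c(types, "emg")
        }
      }
    }
    if (spec$line_amplitude > 0) {
      t <- (seq_len(n) - 1) / fsr
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + spec$line_amplitude * rms * sqrt(2) *
        sin(2 * pi * spec$line_freq * t + phase)
    }
  })
  o <- order(starts)
  mask <- tibble::tibble(start = as.integer(starts[o]), end = as.integer(ends[o]),
                         type = types[o])
  list(recording = rec_update(recording, x), mask = mask)
}

#' Generate a synthetic cohort
#'
#' One recording per subject; each subject's MMSE score is drawn
#' uniformly from the group's range and the group label follows the
#' labelling rule. Per-subject seeds are derived from the cohort seed, so
#' the whole cohort is reproducible and subjects are independent.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble (the cohort manifest) with one row per subject:
#'   `subject_id`, `group`, `mmse`, `seed`, and list-columns `recording`
#'   and `artifact_mask` (empty tibble when no artifacts were injected).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) abort_invalid("`spec` must be a cohort_spec")
  counts <- c(dementia = spec$n_dementia, mci = spec$n_mci, healthy = spec$n_control)
  rows <- list()
  idx <- 0L
  for (g in eeg_groups()) {
    ng <- counts[[g]]
    if (ng == 0) next
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      seed_i <- derive_seed(spec$seed, match(g, eeg_groups()), i)
      rng <- spec$mmse_ranges[[g]]
      mmse_i <- withr::with_seed(derive_seed(seed_i, 1L),
                                 sample(seq.int(rng[1], rng[2]), 1))
      rec <- generate_recording(spec$profiles[[g]], fs = spec$fs,
                                duration_s = spec$duration_s,
                                seed = derive_seed(seed_i, 2L),
                                subject_id = sid, mmse = mmse_i)
      if (!is.null(spec$artifacts)) {
        inj <- inject_artifacts(rec, spec$artifacts, seed = derive_seed(seed_i, 3L))
        rec <- inj$recording
        mask <- inj$mask
      } else {
        mask <- tibble::tibble(start = integer(), end = integer(), type = character())
      }
      rows[[idx]] <- tibble::tibble(subject_id = sid, group = g, mmse = mmse_i,
                                    seed = seed_i,
                                    recording = list(rec),
                                    artifact_mask = list(mask))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(subject_id = character(), group = character(),
                          mmse = integer(), seed = integer(),
                          recording = list(), artifact_mask = list()))
  }
  dplyr::bind_rows(rows)
}
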