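# Shared fixtures built in code. The blink-contamination suite (50
# recordings, 100 s, five 10x-RMS blinks each) is expensive, so it is
# built lazily once per test run and reused by the detection and
# denoising tests.

.suite_cache <- new.env(parent = emptyenv())

# One contaminated recording plus its clean preprocessed counterpart and
# ground-truth blink mask. Preprocessing here is the bandpass alone so
# that clean and contaminated versions share the same scale.
make_contaminated <- function(seed, duration_s = 100, blink_amplitude = 10,
                              blink_count = 5) {
  clean <- generate_recording(spectral_profile(), fs = 512,
                              duration_s = duration_s, seed = seed)
  inj <- inject_artifacts(clean,
                          artifact_spec(blink_count = blink_count,
                                        blink_amplitude = blink_amplitude),
                          seed = derive_seed(seed, 77L))
  list(clean_bp = bandpass(clean),
       contaminated_bp = bandpass(inj$recording),
       mask = inj$mask)
}

contamination_suite <- function(n = 50, duration_s = 100, base_seed = 20260901) {
  key <- paste0("suite_", n, "_", duration_s, "_", base_seed)
  if (is.null(.suite_cache[[key]])) {
    .suite_cache[[key]] <- lapply(seq_len(n), function(i) {
      make_contaminated(derive_seed(base_seed, i), duration_s = duration_s)
    })
  }
  .suite_cache[[key]]
}

# Detection bookkeeping: event-level recall plus clean-window false flags.
detection_counts <- function(case, window_s = 2, k = 1.3) {
  rec <- znormalize(case$contaminated_bp)
  det <- sdw_detect(rec, window_s = window_s, k = k)
  w <- round(window_s * attr(rec, "fs"))
  nw <- floor(nrow(rec) / w)
  flagged_w <- unique(unlist(lapply(seq_len(nrow(det)), function(i) {
    seq.int(det$start[i] %/% w, (det$end[i] - 1L) %/% w)
  })))
  truth_w <- lapply(seq_len(nrow(case$mask)), function(i) {
    seq.int(case$mask$start[i] %/% w, min((case$mask$end[i] - 1L) %/% w, nw - 1L))
  })
  blink_w <- unique(unlist(truth_w))
  hits <- sum(vapply(truth_w, function(tw) any(tw %in% flagged_w), logical(1)))
  list(hits = hits, events = length(truth_w),
       false_flags = sum(!(flagged_w %in% blink_w)),
       clean_windows = nw - length(blink_w))
}

# Well-separated three-class cohort for end-to-end classification: each
# group's power is concentrated in a different band, far beyond any
# clinical effect size, to exercise the machinery rather than the
# biology.
separated_cohort <- function(n_per_group = 15, duration_s = 20, seed = 1) {
  mk <- function(w) spectral_profile(w, pink_weight = 0.1)
  profiles <- list(
    dementia = mk(c(delta = 0.8, theta = 0.1, alpha2 = 0.05, beta1 = 0.05)),
    mci      = mk(c(delta = 0.1, theta = 0.1, alpha2 = 0.7, beta1 = 0.1)),
    healthy  = mk(c(delta = 0.1, theta = 0.1, alpha2 = 0.1, beta1 = 0.7))
  )
  generate_cohort(cohort_spec(n_dementia = n_per_group, n_mci = n_per_group,
                              n_control = n_per_group, duration_s = duration_s,
                              profiles = profiles, seed = seed))
}

# Gaussian feature tibble with the study's group sizes, for SMOTE and
# CV unit tests.
toy_features <- function(n = c(dementia = 10, mci = 33, healthy = 77),
                         d = 5, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(names(n), function(g) {
      m <- shift * (match(g, names(n)) - 1)
      mat <- matrix(stats::rnorm(n[[g]] * d, mean = m), nrow = n[[g]])
      df <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
      names(df) <- paste0("bin_", seq_len(d))
      df$group <- g
      df
    })
    dplyr::bind_rows(rows)
  })
}
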