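# Synthetic cohort generator: geometry, spectral fidelity, artifact
# ground truth, determinism.

test_that("recording geometry matches fs * duration", {
  rec <- generate_recording(spectral_profile(), fs = 512, duration_s = 100, seed = 1)
  expect_equal(nrow(rec), 51200L)
  expect_equal(attr(rec, "fs"), 512)
  rec2 <- generate_recording(spectral_profile(), fs = 250, duration_s = 3.5, seed = 1)
  expect_equal(nrow(rec2), round(250 * 3.5))
  expect_error(generate_recording(spectral_profile(), fs = -1, duration_s = 1),
               class = "eegscreen_invalid_argument")
  expect_error(generate_recording(spectral_profile(), fs = 512, duration_s = 0),
               class = "eegscreen_invalid_argument")
})

test_that("all-zero profile with pink disabled yields the zero signal", {
  prof <- spectral_profile(band_weights = c(delta = 0), pink_weight = 0)
  rec <- generate_recording(prof, fs = 128, duration_s = 2, seed = 1)
  expect_true(all(rec$amplitude == 0))
})

test_that("single-band profiles concentrate spectral power in the band", {
  # FFT of the generated signal as the independent oracle
  cases <- list(alpha2 = c(9, 11), theta = c(4, 8), beta2 = c(20, 30))
  for (b in names(cases)) {
    w <- stats::setNames(1, b)
    prof <- spectral_profile(band_weights = w, pink_weight = 0)
    rec <- generate_recording(prof, fs = 512, duration_s = 60, seed = 42)
    frac <- fft_band_fraction(rec$amplitude, 512, cases[[b]][1], cases[[b]][2])
    expect_gt(frac, 0.8)
  }
})

test_that("generated signal hits the requested RMS and is seed-deterministic", {
  prof <- spectral_profile(total_rms = 2.5)
  rec <- generate_recording(prof, fs = 256, duration_s = 10, seed = 7)
  expect_equal(sqrt(mean(rec$amplitude^2)), 2.5, tolerance = 1e-12)
  rec2 <- generate_recording(prof, fs = 256, duration_s = 10, seed = 7)
  expect_identical(rec$amplitude, rec2$amplitude)
  rec3 <- generate_recording(prof, fs = 256, duration_s = 10, seed = 8)
  expect_false(identical(rec$amplitude, rec3$amplitude))
})

test_that("artifact injection with zero rates is the identity with empty mask", {
  rec <- generate_recording(spectral_profile(), fs = 256, duration_s = 5, seed = 1)
  spec <- artifact_spec(blink_rate = 0, emg_rate = 0, line_amplitude = 0)
  out <- inject_artifacts(rec, spec, seed = 1)
  expect_identical(out$recording$amplitude, rec$amplitude)
  expect_equal(nrow(out$mask), 0L)
})

test_that("every injected transient is contained in the returned mask", {
  rec <- generate_recording(spectral_profile(), fs = 512, duration_s = 30, seed = 3)
  out <- inject_artifacts(rec, artifact_spec(blink_rate = 8, blink_amplitude = 10,
                                             emg_rate = 4, emg_amplitude = 4),
                          seed = 9)
  expect_gt(nrow(out$mask), 0L)
  # every sample where contaminated and clean differ lies inside the mask
  diff_idx <- which(out$recording$amplitude != rec$amplitude) - 1L
  in_mask <- vapply(diff_idx, function(s) {
    any(s >= out$mask$start & s < out$mask$end)
  }, logical(1))
  expect_true(all(in_mask))
  expect_true(all(out$mask$end > out$mask$start))
})

test_that("strong blinks raise the contaminated RMS above the clean RMS", {
  rec <- generate_recording(spectral_profile(), fs = 512, duration_s = 20, seed = 5)
  out <- inject_artifacts(rec, artifact_spec(blink_rate = 6, blink_amplitude = 10),
                          seed = 2)
  expect_gt(nrow(out$mask), 0L)
  expect_gt(sqrt(mean(out$recording$amplitude^2)), sqrt(mean(rec$amplitude^2)))
})

test_that("cohort generation respects counts, labels and MMSE ranges", {
  spec <- cohort_spec(duration_s = 2, fs = 128, seed = 11)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh), 120L)
  expect_equal(as.integer(table(coh$group)[eeg_groups()]), c(10L, 33L, 77L))
  expect_true(all(coh$mmse[coh$group == "dementia"] <= 24))
  expect_true(all(coh$mmse[coh$group == "mci"] %in% 25:27))
  expect_true(all(coh$mmse[coh$group == "healthy"] >= 28))
  expect_true(all(coh$group == mmse_to_group(coh$mmse)))

  single <- generate_cohort(cohort_spec(n_dementia = 0, n_mci = 0, n_control = 1,
                                        duration_s = 2, fs = 128, seed = 1))
  expect_equal(nrow(single), 1L)
  expect_equal(single$group, "healthy")
  expect_true(single$mmse %in% 28:30)
})

test_that("identical cohort spec and seed reproduce identical samples", {
  spec <- cohort_spec(n_dementia = 2, n_mci = 2, n_control = 2,
                      duration_s = 2, fs = 128,
                      artifacts = artifact_spec(blink_rate = 10), seed = 4)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  for (i in seq_len(nrow(a))) {
    expect_identical(a$recording[[i]]$amplitude, b$recording[[i]]$amplitude)
    expect_identical(a$artifact_mask[[i]], b$artifact_mask[[i]])
  }
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_dementia = -1), class = "eegscreen_invalid_argument")
  expect_error(cohort_spec(mmse_ranges = list(dementia = c(0, 25), mci = c(25, 27),
                                              healthy = c(28, 30))),
               class = "eegscreen_invalid_argument")
  expect_error(spectral_profile(band_weights = c(delta = -1)),
               class = "eegscreen_invalid_argument")
  expect_error(artifact_spec(blink_rate = -2), class = "eegscreen_invalid_argument")
})
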