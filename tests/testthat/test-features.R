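# STFT power, bin/band features, control-referenced relative power.

test_that("STFT of the zero signal is all-zero and window count is floor(n/L)", {
  rec <- eeg_recording(rep(0, 512 * 3 + 100), fs = 512)
  sp <- stft_power(rec)
  expect_equal(max(sp$power), 0)
  expect_equal(max(sp$window), 3L)
  expect_error(stft_power(eeg_recording(rnorm(100), fs = 512)),
               class = "eegscreen_degenerate_input")
})

test_that("a pure tone concentrates its window power in its own bin", {
  t <- seq_len(512 * 5) / 512
  rec <- eeg_recording(sin(2 * pi * 10 * t), fs = 512)
  sp <- stft_power(rec, taper = "rect")
  w1 <- sp[sp$window == 1, ]
  expect_gte(w1$power[w1$freq == 10] / sum(w1$power), 0.99)
})

test_that("summed spectral power matches time-domain mean square (Parseval)", {
  withr::with_seed(8, x <- stats::rnorm(512 * 4))
  rec <- eeg_recording(x, fs = 512)
  sp <- stft_power(rec, taper = "rect")
  for (wi in 1:4) {
    seg <- x[((wi - 1) * 512 + 1):(wi * 512)]
    expect_equal(sum(sp$power[sp$window == wi]), mean(seg^2), tolerance = 1e-10)
  }
  # tapered spectra stay Parseval-consistent up to the taper compensation
  sph <- stft_power(rec, taper = "hann")
  expect_equal(sum(sph$power[sph$window == 1]),
               mean(x[1:512]^2), tolerance = 0.35)
})

test_that("bin features average windows then normalise to sum one", {
  t <- seq_len(512 * 2) / 512
  rec <- eeg_recording(sin(2 * pi * 10 * t), fs = 512)
  f <- bin_features(stft_power(rec, taper = "rect"))
  expect_equal(sum(as.matrix(f)), 1, tolerance = 1e-9)
  expect_gt(f$bin_10, 0.99)
  # two windows with known bins: mean then scale, against hand arithmetic
  grid_power <- function(vals) {  # full 0..256 Hz grid, zeros elsewhere
    p <- rep(0, 257)
    p[c(5, 10, 20) + 1] <- vals
    p
  }
  sp <- tibble::tibble(window = rep(1:2, each = 257),
                       freq = rep(0:256, 2),
                       power = c(grid_power(c(1, 2, 3)), grid_power(c(3, 2, 1))))
  f2 <- bin_features(sp)
  expect_equal(f2$bin_5, 2 / 6)
  expect_equal(f2$bin_10, 2 / 6)
  expect_equal(f2$bin_20, 2 / 6)
  expect_error(bin_features(dplyr::mutate(sp, power = 0)),
               class = "eegscreen_degenerate_input")
  expect_error(bin_features(sp[sp$freq < 30, ]),
               class = "eegscreen_invalid_argument")
})

test_that("band powers follow the half-open edge convention", {
  mk <- function(hot) {
    v <- as.list(stats::setNames(rep(0, 45), paste0("bin_", 1:45)))
    v[[paste0("bin_", hot)]] <- 1
    tibble::as_tibble(v)
  }
  at2 <- band_powers(mk(2))
  expect_gt(at2$delta, 0)
  expect_equal(at2$theta + at2$alpha + at2$beta + at2$gamma, 0)
  at4 <- band_powers(mk(4))   # shared edge 4 Hz belongs to theta
  expect_equal(at4$delta, 0)
  expect_gt(at4$theta, 0)
  at45 <- band_powers(mk(45)) # gamma closed at 45
  expect_gt(at45$gamma, 0)
  # flat bins: every band mean equals the common value
  flat <- tibble::as_tibble(as.list(stats::setNames(rep(0.5, 45), paste0("bin_", 1:45))))
  bp <- band_powers(flat)
  for (b in eeg_bands()$band) expect_equal(bp[[b]], 0.5)
  # sub-bands partition their parents
  expect_equal(bp$alpha, mean(c(bp$alpha1, bp$alpha2, bp$alpha2, bp$alpha3, bp$alpha3)),
               tolerance = 1e-12)
})

test_that("band/bin consistency holds on generated recordings", {
  rec <- generate_recording(spectral_profile(), fs = 512, duration_s = 5, seed = 9)
  f <- spectral_features(rec)
  bins <- as.numeric(f[paste0("bin_", 1:45)])
  for (b in eeg_bands()$band) {
    expect_equal(f[[b]], mean(bins[eegscreen:::band_bins(b)]), tolerance = 1e-12)
  }
})

test_that("relative power fixes the reference-group mean at exactly 1", {
  coh <- separated_cohort(n_per_group = 4, duration_s = 5, seed = 13)
  feats <- cohort_features(coh, preprocess = TRUE, denoise = FALSE)
  rel <- relative_power(feats)
  ref <- rel[rel$group == "healthy", intersect(eegscreen:::feature_names(), names(rel))]
  expect_true(all(abs(colMeans(as.matrix(ref)) - 1) < 1e-12))
})

test_that("a one-subject reference makes that subject's features all 1", {
  coh <- separated_cohort(n_per_group = 1, duration_s = 5, seed = 14)
  feats <- cohort_features(coh, preprocess = TRUE, denoise = FALSE)
  rel <- relative_power(feats)
  ref_row <- rel[rel$group == "healthy", intersect(eegscreen:::feature_names(), names(rel))]
  expect_true(all(abs(as.numeric(ref_row) - 1) < 1e-12))
})

test_that("degenerate references are rejected with the offending element named", {
  feats <- tibble::tibble(group = c("healthy", "dementia"),
                          bin_1 = c(0, 1), bin_2 = c(0.5, 0.5))
  expect_error(relative_power(feats), "bin_1",
               class = "eegscreen_degenerate_input")
  expect_error(relative_power(feats, reference_group = "mci"),
               class = "eegscreen_degenerate_input")
})
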