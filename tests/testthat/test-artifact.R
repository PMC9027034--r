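# SDW scoring/detection, IMF rejection, reconstruction, denoising.

test_that("sdw_score matches the absolute first-difference definition", {
  expect_equal(sdw_score(rep(3, 50)), 0)
  n <- 20
  expect_equal(sdw_score(rep_len(c(0, 1), n)), n - 1)
  expect_equal(sdw_score(seq_len(n)), n - 1)
  expect_equal(sdw_score(c(0, -2, 5)), 9)
  expect_error(sdw_score(1), class = "eegscreen_invalid_argument")
})

test_that("sdw_detect returns an empty mask for constant and sub-threshold input", {
  const <- eeg_recording(rep(1, 512 * 4), fs = 512)
  expect_equal(nrow(sdw_detect(const)), 0L)
  noisy <- generate_recording(spectral_profile(), fs = 512, duration_s = 10, seed = 1)
  expect_equal(nrow(sdw_detect(noisy, threshold = Inf)), 0L)
  short <- eeg_recording(rnorm(100), fs = 512)
  expect_error(sdw_detect(short), class = "eegscreen_degenerate_input")
})

test_that("sdw_detect covers an injected strong blink and merges windows", {
  case <- make_contaminated(101, duration_s = 40, blink_count = 3)
  rec <- znormalize(case$contaminated_bp)
  det <- sdw_detect(rec)
  covered <- interval_cover(nrow(rec), det$start, det$end)
  for (i in seq_len(nrow(case$mask))) {
    idx <- (case$mask$start[i] + 1L):case$mask$end[i]
    expect_gte(mean(covered[idx]), 0.9)
  }
  # intervals are sorted, non-overlapping, in bounds
  expect_true(all(diff(det$start) > 0))
  expect_true(all(det$end[-nrow(det)] <= det$start[-1]))
  expect_true(all(det$start >= 0) && all(det$end <= nrow(rec)))
})

test_that("trailing partial windows are never flagged", {
  fs_ <- 512
  x <- rnorm(fs_ * 5 + 300)
  x[(fs_ * 5 + 1):(fs_ * 5 + 300)] <- x[(fs_ * 5 + 1):(fs_ * 5 + 300)] + 50
  det <- sdw_detect(eeg_recording(x, fs = fs_))
  expect_true(all(det$end <= fs_ * 4))  # only full 2 s windows eligible
})

test_that("the FFT cross-correlation matches a brute-force scan", {
  withr::with_seed(31, {
    for (i in 1:8) {
      a <- stats::rnorm(40)
      b <- if (i %% 2) stats::rnorm(40) else a + stats::rnorm(40, sd = 0.1)
      expect_equal(eegscreen:::max_crosscorr(a, b), brute_max_xcorr(a, b),
                   tolerance = 1e-10)
    }
  })
})

test_that("between-IMF rejection keeps singletons and separated tones, drops duplicates", {
  t <- seq_len(4 * 256) / 256
  slow <- sin(2 * pi * 5 * t)
  fast <- sin(2 * pi * 20 * t)
  dup <- eegscreen:::new_imf_decomposition(list(fast, fast), slow)
  rj <- reject_imfs(dup, reference = "imfs")
  expect_equal(length(rj$kept), 0L)
  expect_equal(length(rj$rejected), 2L)
  single <- eegscreen:::new_imf_decomposition(list(fast), slow)
  expect_equal(length(reject_imfs(single, reference = "imfs")$kept), 1L)
  tones <- eegscreen:::new_imf_decomposition(list(fast, slow), rep(0, length(t)))
  rj2 <- reject_imfs(tones, reference = "imfs")
  expect_equal(length(rj2$kept), 2L)
  # oracle agreement on the pair correlation
  expect_equal(rj2$stats$correlation[1], brute_max_xcorr(fast, slow),
               tolerance = 1e-10)
})

test_that("segment-referenced rejection drops the artifact-dominated components", {
  case <- make_contaminated(202, duration_s = 20, blink_count = 2)
  rec <- case$contaminated_bp
  w <- 2 * 512
  w0 <- case$mask$start[1] %/% w
  seg <- rec$amplitude[(w0 * w + 1):((w0 + 1) * w)]
  dec <- eemd(seg, n_ensemble = 30, seed = 1)
  rj <- reject_imfs(dec, reference = "segment")
  expect_gt(length(rj$rejected), 0L)
  expect_lt(length(rj$rejected), length(dec$imfs))
})

test_that("reconstruction is the exact sum and validates lengths", {
  t <- seq_len(512) / 512
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 17 * t) + 0.3 * t
  d <- emd(x)
  expect_lt(max(abs(reconstruct(d$imfs, d$residual) - x)), 1e-8)
  expect_equal(reconstruct(list(), d$residual), d$residual)
  keep <- d$imfs[1]
  expect_equal(reconstruct(keep, d$residual), d$imfs[[1]] + d$residual)
  expect_error(reconstruct(list(rnorm(10)), rnorm(11)),
               class = "eegscreen_invalid_argument")
})

test_that("denoise is the identity when nothing is flagged", {
  rec <- generate_recording(spectral_profile(), fs = 512, duration_s = 10, seed = 6)
  pre <- preprocess(rec)
  out <- denoise(pre, threshold = Inf, seed = 1)
  expect_identical(out$recording$amplitude, pre$amplitude)
  expect_equal(nrow(out$mask), 0L)
})

test_that("denoise reduces in-interval error on a blink-contaminated recording", {
  case <- make_contaminated(303, duration_s = 30, blink_count = 3)
  contaminated <- case$contaminated_bp
  out <- denoise(contaminated, n_ensemble = 30, seed = 11)
  expect_gt(nrow(out$mask), 0L)
  flagged <- interval_cover(nrow(contaminated), out$mask$start, out$mask$end)
  clean <- case$clean_bp$amplitude
  before <- sqrt(mean((contaminated$amplitude[flagged] - clean[flagged])^2))
  after <- sqrt(mean((out$recording$amplitude[flagged] - clean[flagged])^2))
  expect_lt(after, before)
  # untouched outside the flagged intervals
  expect_identical(out$recording$amplitude[!flagged], contaminated$amplitude[!flagged])
})

test_that("denoise is deterministic given the seed", {
  case <- make_contaminated(404, duration_s = 20, blink_count = 2)
  a <- denoise(case$contaminated_bp, n_ensemble = 10, seed = 3)
  b <- denoise(case$contaminated_bp, n_ensemble = 10, seed = 3)
  expect_identical(a$recording$amplitude, b$recording$amplitude)
  expect_identical(tibble::as_tibble(a$mask), tibble::as_tibble(b$mask))
})
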