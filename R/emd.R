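# Empirical mode decomposition (EMD) and its ensemble variant (EEMD).
# Classical cubic-spline envelope sifting: each intrinsic mode function
# (IMF) is obtained by repeatedly subtracting the mean of the upper and
# lower extremal envelopes until a Cauchy-type criterion is met; the
# procedure stops when the residual has too few extrema to sift.

# Strict local extrema; plateaus inherit the preceding slope sign.
find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  z <- which(s == 0)
  if (length(z)) {
    for (i in z) s[i] <- if (i > 1) s[i - 1] else 1
  }
  idx <- which(diff(s) != 0) + 1L
  list(maxima = idx[s[idx - 1] > 0], minima = idx[s[idx - 1] < 0])
}

# Cubic-spline envelope through the extrema at `idx`, with the two
# nearest extrema mirrored across each end to tame boundary swings.
spline_envelope <- function(x, idx, n) {
  k <- min(2L, length(idx))
  xi <- c(2L - rev(idx[seq_len(k)]), idx, 2L * n - rev(idx)[seq_len(k)])
  src <- ifelse(xi < 1L, 2L - xi, ifelse(xi > n, 2L * n - xi, xi))
  stats::spline(xi, x[src], xout = seq_len(n), method = "fmm")$y
}

# IMF definition check: extrema and zero-crossing counts differ by <= 1.
imf_like <- function(h) {
  ex <- find_extrema(h)
  s <- sign(h)
  s <- s[s != 0]
  zc <- if (length(s) < 2) 0L else sum(diff(s) != 0)
  abs(length(ex$maxima) + length(ex$minima) - zc) <= 1L
}

new_imf_decomposition <- function(imfs, residual) {
  structure(list(imfs = imfs, residual = residual),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residual, %d samples\n",
              length(x$imfs), length(x$residual)))
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Decomposes a real sequence into intrinsic mode functions by
#' cubic-spline envelope sifting. Sifting of each candidate mode stops
#' when the Cauchy criterion `sum(m^2)/sum(h^2) < sift_sd` is met (where
#' `m` is the envelope mean subtracted at that pass) or after
#' `max_sifts` passes; extraction stops when the residual has fewer than
#' three extrema (monotone or near-monotone trend) or `max_imfs` modes
#' have been extracted. By construction the IMFs and residual sum
#' exactly back to the input.
#'
#' @param x Numeric vector, length >= 4.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param sift_sd Cauchy-criterion stopping threshold.
#' @param max_sifts Maximum sifting passes per IMF.
#' @return An `imf_decomposition`: list with `imfs` (list of numeric
#'   vectors, possibly empty) and `residual`.
#' @examples
#' t <- seq(0, 2, length.out = 1024)
#' d <- emd(sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t))
#' length(d$imfs)
#' @export
emd <- function(x, max_imfs = 10, sift_sd = 0.2, max_sifts = 12) {
  if (!is.numeric(x)) abort_invalid("`x` must be numeric")
  n <- length(x)
  if (n < 4) abort_degenerate("segment too short to decompose (need >= 4 samples)")
  residual <- x
  imfs <- list()
  repeat {
    ex <- find_extrema(residual)
    if (length(ex$maxima) + length(ex$minima) < 3 || length(imfs) >= max_imfs) break
    h <- residual
    for (s in seq_len(max_sifts)) {
      exh <- find_extrema(h)
      if (length(exh$maxima) < 2 || length(exh$minima) < 2) break
      m <- (spline_envelope(h, exh$maxima, n) +
              spline_envelope(h, exh$minima, n)) / 2
      crit <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h - m
      if (crit < sift_sd && imf_like(h)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  new_imf_decomposition(imfs, residual)
}

#' Ensemble empirical mode decomposition
#'
#' Averages the IMFs of [emd()] applied to `n_ensemble` white-noise
#' perturbed copies of the segment; noise-assisted averaging stabilises
#' mode mixing. Trials yielding fewer modes than the ensemble maximum
#' contribute zeros to the missing slots. The residual is defined as
#' the input minus the summed mean IMFs, so completeness is exact.
#' With `n_ensemble = 1` and `noise_sd = 0` the result equals [emd()].
#'
#' @inheritParams emd
#' @param n_ensemble Number of ensemble trials (>= 1).
#' @param noise_sd Added white-noise SD as a fraction of the segment SD
#'   (>= 0).
#' @param seed Integer seed; the decomposition is deterministic given
#'   the seed.
#' @return An `imf_decomposition`.
#' @export
eemd <- function(x, n_ensemble = 100, noise_sd = 0.2, seed = 1,
                 max_imfs = 10, sift_sd = 0.2, max_sifts = 12) {
  if (n_ensemble < 1) abort_invalid("`n_ensemble` must be >= 1")
  if (noise_sd < 0) abort_invalid("`noise_sd` must be >= 0")
  n <- length(x)
  if (n < 4) abort_degenerate("segment too short to decompose (need >= 4 samples)")
  sdx <- stats::sd(x)
  trials <- withr::with_seed(seed, {
    lapply(seq_len(n_ensemble), function(i) {
      noise <- if (noise_sd > 0 && sdx > 0) stats::rnorm(n, sd = noise_sd * sdx) else 0
      emd(x + noise, max_imfs = max_imfs, sift_sd = sift_sd,
          max_sifts = max_sifts)$imfs
    })
  })
  K <- max(vapply(trials, length, integer(1)))
  if (K == 0L) return(new_imf_decomposition(list(), x))
  imfs <- lapply(seq_len(K), function(k) {
    acc <- numeric(n)
    for (tr in trials) if (length(tr) >= k) acc <- acc + tr[[k]]
    acc / n_ensemble
  })
  new_imf_decomposition(imfs, x - Reduce(`+`, imfs))
}

# Mean zero-crossing rate, used as a cheap frequency ordering oracle.
zero_crossing_rate <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0) / length(x)
}
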