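# Independent oracles used to cross-check the implementation, written
# directly from the defining formulas (no shared code with the package).

# Kruskal-Wallis H from the rank-sum definition with midranks and the
# standard tie correction.
brute_kruskal_h <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)  # midranks
  gs <- unique(groups)
  h <- 12 / (N * (N + 1)) *
    sum(vapply(gs, function(g) {
      ri <- r[groups == g]
      length(ri) * (mean(ri) - (N + 1) / 2)^2
    }, numeric(1)))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else h / corr
}

# Benjamini-Hochberg step-up from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# Maximum-over-lags absolute normalised cross-correlation, O(n^2),
# biased estimator (fixed full-length denominator) after demeaning.
brute_max_xcorr <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) return(0)
  best <- 0
  for (lag in -(n - 1):(n - 1)) {
    if (lag >= 0) {
      s <- sum(a[(1 + lag):n] * b[1:(n - lag)])
    } else {
      s <- sum(a[1:(n + lag)] * b[(1 - lag):n])
    }
    best <- max(best, abs(s))
  }
  best / denom
}

# Fraction of one-sided FFT power of `x` inside [lo, hi] Hz.
fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- floor(n / 2)
  freqs <- (0:half) * fs / n
  p <- p[1:(half + 1)]
  sum(p[freqs >= lo & freqs <= hi]) / sum(p)
}

# TRUE if `point` lies on a segment between some pair of rows of `mat`
# (geometric check of the SMOTE interpolation contract).
is_convex_combination <- function(point, mat, tol = 1e-8) {
  for (a in seq_len(nrow(mat))) {
    d1 <- point - mat[a, ]
    for (b in seq_len(nrow(mat))[-a]) {
      d2 <- mat[b, ] - mat[a, ]
      den <- sum(d2 * d2)
      if (den == 0) next
      tt <- sum(d1 * d2) / den
      if (tt >= -tol && tt <= 1 + tol && sqrt(sum((d1 - tt * d2)^2)) < tol) {
        return(TRUE)
      }
    }
  }
  FALSE
}
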