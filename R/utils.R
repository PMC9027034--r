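# Internal helpers: classed conditions, seed derivation, interval utilities.

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "eegscreen_invalid_argument", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "eegscreen_degenerate_input", ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "eegscreen_format_error", ...)
}

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus any number of integer tags
#' (stage index, subject index, ...) to a new seed in `[1, 2^31 - 2]`.
#' Used throughout the pipeline so that per-stage and per-subject random
#' streams are reproducible functions of one master seed.
#'
#' @param seed Integer master seed.
#' @param ... Further integer tags.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ints <- vapply(c(list(seed), list(...)), function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(ints))) abort_invalid("seed tags must be finite numbers")
  acc <- 0
  for (v in ints) acc <- (acc * 69069 + v + 1) %% 2147483629
  as.integer(acc %% 2147483646) + 1L
}

# Merge sorted half-open intervals [start, end) given as a two-column matrix
# or data frame; adjacent/overlapping intervals are coalesced.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# TRUE for each position in seq_len(n) - 1 covered by any [start, end) interval
interval_cover <- function(n, start, end) {
  covered <- logical(n)
  for (i in seq_along(start)) {
    lo <- max(0L, start[i]); hi <- min(n, end[i])
    if (hi > lo) covered[(lo + 1L):hi] <- TRUE
  }
  covered
}

`%||%` <- function(a, b) if (is.null(a)) b else a
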