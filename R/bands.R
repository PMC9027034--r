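#' Canonical EEG frequency band scheme
#'
#' Returns the ten-band scheme used throughout the pipeline. Edges are in
#' Hz and every band is half-open `[low, high)` except gamma, which is
#' closed at 45 Hz so that the 45 Hz bin belongs to it. Under 1-Hz bins
#' this makes delta = bins \{1,2,3\}, alpha1 = \{8\}, alpha2 = \{9,10\},
#' alpha3 = \{11,12\}, gamma = \{30,...,45\}. The broad alpha and beta
#' bands are the exact unions of their sub-bands.
#'
#' @return A tibble with columns `band`, `low`, `high`.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "alpha1", "alpha2", "alpha3",
             "beta", "beta1", "beta2", "gamma"),
    low  = c(1, 4, 8, 8, 9, 11, 13, 13, 20, 30),
    high = c(4, 8, 13, 9, 11, 13, 30, 20, 30, 45)
  )
}

# Integer 1-Hz bins belonging to a band: [low, high), gamma closed at 45.
band_bins <- function(band) {
  scheme <- eeg_bands()
  row <- scheme[scheme$band == band, ]
  if (nrow(row) != 1L) abort_invalid(paste0("unknown band: ", band))
  if (band == "gamma") seq.int(row$low, row$high) else seq.int(row$low, row$high - 1L)
}

# The 55 candidate feature names: 45 bins then 10 bands.
feature_names <- function() {
  c(paste0("bin_", 1:45), eeg_bands()$band)
}

#' Diagnostic group labels used by the pipeline
#' @return Character vector `c("dementia", "mci", "healthy")`.
#' @export
eeg_groups <- function() c("dementia", "mci", "healthy")
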