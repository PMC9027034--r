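# broom-style tidiers for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy feature-test results
#'
#' @param x An `eeg_feature_tests` object from [select_features()].
#' @param ... Unused.
#' @return A plain tibble, one row per tested feature.
#' @method tidy eeg_feature_tests
#' @export
tidy.eeg_feature_tests <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.eeg_feature_tests
#' @method glance eeg_feature_tests
#' @export
glance.eeg_feature_tests <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 n_selected = sum(x$selected),
                 alpha = attr(x, "alpha"),
                 method = attr(x, "method"))
}

#' Tidy cross-validation results
#'
#' `tidy()` returns per-fold test metrics; `glance()` one row with the
#' pooled train/test metrics.
#'
#' @param x An `eeg_cv` object from [cross_validate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eeg_cv
#' @export
tidy.eeg_cv <- function(x, ...) {
  x$folds
}

#' @rdname tidy.eeg_cv
#' @method glance eeg_cv
#' @export
glance.eeg_cv <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    folds = x$config$folds,
    leakage = x$config$leakage,
    train_accuracy = m$accuracy[m$split == "train"],
    train_sensitivity = m$sensitivity[m$split == "train"],
    train_specificity = m$specificity[m$split == "train"],
    test_accuracy = m$accuracy[m$split == "test"],
    test_sensitivity = m$sensitivity[m$split == "test"],
    test_specificity = m$specificity[m$split == "test"]
  )
}
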