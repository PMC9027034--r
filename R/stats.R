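# Group-difference testing and feature selection: Kruskal-Wallis per
# feature, multiplicity correction, selection at the significance level.

#' Kruskal-Wallis test of k groups
#'
#' Rank-based one-way test with tie correction; the statistic is
#' referred to a chi-square distribution with `k - 1` degrees of
#' freedom. Wraps `stats::kruskal.test`; the fully tied case (all
#' observations identical) is defined as `H = 0`, `p = 1`.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values` (>= 2 non-empty
#'   groups, total N >= 3).
#' @return One-row tibble: `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort_invalid("`values` and `groups` must have equal length")
  }
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) abort_invalid("need at least 2 groups")
  if (any(table(groups) == 0)) abort_invalid("every group must be non-empty")
  if (length(values) < 3) abort_invalid("need at least 3 observations")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value)
}

#' Adjust p-values for multiple testing
#'
#' `"bonferroni"` multiplies by the family size and caps at 1;
#' `"bh_fdr"` is the Benjamini-Hochberg step-up false discovery rate
#' procedure. Thin wrapper over `stats::p.adjust` with validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` (default) or `"bh_fdr"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_invalid("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni",
                                     bh_fdr = "BH"))
}

#' Test and select discriminative features
#'
#' Runs [kruskal_wallis()] on every candidate feature column (the 45
#' bins and 10 bands), adjusts the p-values over the whole family of 55
#' tests, and flags features with adjusted p below `alpha`.
#'
#' @param features Feature tibble with a `group` column (from
#'   [cohort_features()] or [relative_power()]).
#' @param alpha Significance level (default 0.05).
#' @param method Correction method, see [adjust_pvalues()].
#' @return An `eeg_feature_tests` tibble: `feature`, `H`, `p`,
#'   `p_adjusted`, `selected`, ordered as the candidate list.
#' @export
select_features <- function(features, alpha = 0.05,
                            method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (!"group" %in% names(features)) abort_invalid("`features` must have a `group` column")
  if (length(unique(features$group)) < 2) {
    abort_invalid("need at least 2 groups present")
  }
  feat_cols <- intersect(feature_names(), names(features))
  if (length(feat_cols) == 0L) abort_invalid("no feature columns found")
  res <- purrr::map_dfr(feat_cols, function(cn) {
    kt <- kruskal_wallis(features[[cn]], features$group)
    tibble::tibble(feature = cn, H = kt$H, p = kt$p)
  })
  res$p_adjusted <- adjust_pvalues(res$p, method = method)
  res$selected <- res$p_adjusted < alpha
  structure(res, alpha = alpha, method = method,
            class = c("eeg_feature_tests", class(res)))
}

#' Pairwise post-hoc group comparisons
#'
#' For each requested feature, Wilcoxon rank-sum tests between each
#' pair of groups with Bonferroni correction over the pairs. Reported
#' for interpretation; selection itself uses the omnibus test of
#' [select_features()].
#'
#' @param features Feature tibble with a `group` column.
#' @param which_features Character vector of feature columns (defaults
#'   to all candidates).
#' @return Tibble: `feature`, `group1`, `group2`, `p`, `p_adjusted`.
#' @export
pairwise_group_tests <- function(features, which_features = NULL) {
  if (!"group" %in% names(features)) abort_invalid("`features` must have a `group` column")
  feat_cols <- which_features %||% intersect(feature_names(), names(features))
  gs <- sort(unique(features$group))
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  purrr::map_dfr(feat_cols, function(cn) {
    ps <- vapply(pairs, function(pr) {
      a <- features[[cn]][features$group == pr[1]]
      b <- features[[cn]][features$group == pr[2]]
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }, numeric(1))
    tibble::tibble(feature = cn,
                   group1 = vapply(pairs, `[`, character(1), 1),
                   group2 = vapply(pairs, `[`, character(1), 2),
                   p = ps,
                   p_adjusted = adjust_pvalues(ps, "bonferroni"))
  })
}
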