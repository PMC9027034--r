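# Class balancing (SMOTE), RBF-kernel SVM, evaluation metrics, and
# stratified ten-fold cross-validation with a leakage-mode switch.

#' SMOTE class balancing
#'
#' Brings every class up to the majority-class count by synthesising new
#' minority samples: each synthetic sample lies on the segment between a
#' randomly chosen minority sample and one of its `k_neighbors` nearest
#' same-class neighbours (Euclidean distance in feature space), with
#' interpolation factor uniform in `[0, 1]`. Deterministic given `seed`.
#'
#' @param features Tibble whose numeric candidate-feature columns are
#'   used for interpolation; other columns of synthetic rows are copied
#'   from the base sample.
#' @param group_col Name of the class column (default `"group"`).
#' @param k_neighbors Number of nearest neighbours (default 5); every
#'   minority class must have at least `k_neighbors + 1` members.
#' @param seed Integer seed.
#' @return The input tibble with synthetic rows appended and a logical
#'   `synthetic` column marking them; class counts are equal afterwards.
#' @export
smote_balance <- function(features, group_col = "group", k_neighbors = 5,
                          seed = 1) {
  if (!group_col %in% names(features)) {
    abort_invalid(paste0("`features` must have a '", group_col, "' column"))
  }
  feat_cols <- intersect(feature_names(), names(features))
  if (length(feat_cols) == 0L) {
    feat_cols <- names(features)[vapply(features, is.numeric, logical(1))]
    feat_cols <- setdiff(feat_cols, c(group_col, "mmse", "seed"))
  }
  if (length(feat_cols) == 0L) abort_invalid("no numeric feature columns found")
  labels <- as.character(features[[group_col]])
  counts <- table(labels)
  target <- max(counts)
  out <- features
  out$synthetic <- rep(FALSE, nrow(features))
  X <- as.matrix(features[feat_cols])
  new_rows <- list()
  withr::with_seed(seed, {
    for (cls in names(counts)) {
      deficit <- target - counts[[cls]]
      if (deficit == 0) next
      idx <- which(labels == cls)
      if (length(idx) < k_neighbors + 1) {
        abort_invalid(sprintf(
          "class '%s' has %d members; SMOTE with k_neighbors = %d needs at least %d",
          cls, length(idx), k_neighbors, k_neighbors + 1))
      }
      Xc <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
      base_i <- sample.int(length(idx), deficit, replace = TRUE)
      nb_pick <- sample.int(k_neighbors, deficit, replace = TRUE)
      gap <- stats::runif(deficit)
      for (j in seq_len(deficit)) {
        b <- base_i[j]
        nbr <- nn[b, nb_pick[j]]
        synth <- Xc[b, ] + gap[j] * (Xc[nbr, ] - Xc[b, ])
        row <- features[idx[b], ]
        row[feat_cols] <- as.list(synth)
        if ("subject_id" %in% names(row)) {
          row$subject_id <- sprintf("%s_syn%03d", cls, j)
        }
        row$synthetic <- TRUE
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
  })
  if (length(new_rows)) out <- dplyr::bind_rows(out, dplyr::bind_rows(new_rows))
  out
}

#' Train an RBF-kernel SVM
#'
#' Radial-basis-function support vector classifier (via `e1071::svm`,
#' one-vs-one voting for the multiclass decision). Features should be
#' standardised by the caller; `scale = FALSE` is used so that
#' train-fold statistics control the scaling. The default kernel width
#' follows the `1 / (d * var(X))` heuristic.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Class labels (>= 2 classes present).
#' @param cost Soft-margin cost parameter C.
#' @param gamma RBF kernel width; `NULL` for the variance heuristic.
#' @return A fitted `svm` object; predict with `predict(model, newx)`.
#' @export
svm_rbf <- function(x, y, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) abort_invalid("need at least 2 classes to train")
  if (any(!is.finite(x))) abort_invalid("features must be finite")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  e1071::svm(x, droplevels(y), kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Rows are true classes, columns predicted. Accuracy is the trace over
#' the total; sensitivity and specificity are macro-averaged one-vs-rest
#' rates (`TP/(TP+FN)` and `TN/(TN+FP)` per class, averaged over the
#' classes actually present in the truth).
#'
#' @param confusion Square non-negative integer matrix with matching
#'   row/column order.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' compute_metrics(diag(c(5, 5, 5)))
#' @export
compute_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) abort_invalid("confusion matrix must be square")
  if (any(cm < 0) || any(cm != round(cm))) {
    abort_invalid("confusion matrix entries must be non-negative integers")
  }
  total <- sum(cm)
  if (total == 0) abort_invalid("confusion matrix is all zero")
  present <- which(rowSums(cm) > 0)
  sens <- vapply(present, function(i) cm[i, i] / sum(cm[i, ]), numeric(1))
  spec <- vapply(present, function(i) {
    tn <- sum(cm[-i, -i])
    fp <- sum(cm[-i, i])
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  tibble::tibble(accuracy = sum(diag(cm)) / total,
                 sensitivity = mean(sens),
                 specificity = mean(spec, na.rm = TRUE))
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin so every fold gets a near-equal share of each class.
stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validated SMOTE + feature selection + RBF-SVM
#'
#' Stratified k-fold cross-validation of the full classification stage.
#' In `leakage = "safe"` mode (the scientific default) feature selection
#' and SMOTE are fit inside each training fold only, and the held-out
#' fold is scored untouched. In `leakage = "global"` mode both are
#' applied to the complete dataset before splitting, reproducing the
#' optimistic protocol implied by reported all-100% training metrics;
#' its estimates are biased upward and it exists for comparison only.
#'
#' Features are standardised with train-fold statistics before the SVM.
#' If selection leaves no feature (nothing significant), all candidates
#' are used for that fold.
#'
#' @param features Feature tibble with a `group` column and the 55
#'   candidate feature columns (relative power or raw).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and SMOTE.
#' @param leakage `"safe"` or `"global"`.
#' @param select Run Kruskal-Wallis feature selection (default `TRUE`).
#' @param alpha,method Selection parameters, see [select_features()].
#' @param smote Apply SMOTE balancing (default `TRUE`).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param cost,gamma SVM hyperparameters, see [svm_rbf()].
#' @return An `eeg_cv` object: per-fold and pooled confusion matrices
#'   and metrics for train and test. See [tidy.eeg_cv()] and
#'   [glance.eeg_cv()].
#' @export
cross_validate <- function(features, folds = 10, seed = 1,
                           leakage = c("safe", "global"),
                           select = TRUE, alpha = 0.05,
                           method = c("bonferroni", "bh_fdr"),
                           smote = TRUE, k_neighbors = 5,
                           cost = 1, gamma = NULL) {
  leakage <- match.arg(leakage)
  method <- match.arg(method)
  if (!"group" %in% names(features)) abort_invalid("`features` must have a `group` column")
  classes <- sort(unique(features$group))
  if (length(classes) < 2) abort_invalid("need at least 2 classes")
  if (folds > nrow(features)) abort_invalid("more folds than samples")
  all_feats <- intersect(feature_names(), names(features))
  selected_global <- NULL
  data <- features
  if (leakage == "global") {
    if (select) {
      st <- select_features(data, alpha = alpha, method = method)
      selected_global <- st$feature[st$selected]
      if (length(selected_global) == 0L) selected_global <- all_feats
    } else {
      selected_global <- all_feats
    }
    if (smote) data <- smote_balance(data, k_neighbors = k_neighbors,
                                     seed = derive_seed(seed, 99L))
  }
  assignment <- stratified_folds(data$group, folds, derive_seed(seed, 1L))
  empty_cm <- matrix(0L, length(classes), length(classes),
                     dimnames = list(truth = classes, predicted = classes))
  conf_test <- empty_cm; conf_train <- empty_cm
  fold_rows <- list()
  sel_per_fold <- list()
  for (f in seq_len(folds)) {
    train <- data[assignment != f, , drop = FALSE]
    test <- data[assignment == f, , drop = FALSE]
    if (nrow(test) == 0L) next
    if (leakage == "safe") {
      if (select && length(unique(train$group)) >= 2) {
        st <- select_features(train, alpha = alpha, method = method)
        sel <- st$feature[st$selected]
        if (length(sel) == 0L) sel <- all_feats
      } else {
        sel <- all_feats
      }
      if (smote) train <- smote_balance(train, k_neighbors = k_neighbors,
                                        seed = derive_seed(seed, 2L, f))
    } else {
      sel <- selected_global
    }
    sel_per_fold[[f]] <- sel
    Xtr <- as.matrix(train[sel]); Xte <- as.matrix(test[sel])
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, stats::sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    fit <- svm_rbf(Xtr, train$group, cost = cost, gamma = gamma)
    pr_tr <- as.character(predict(fit, Xtr))
    pr_te <- as.character(predict(fit, Xte))
    cm_tr <- table(factor(train$group, classes), factor(pr_tr, classes))
    cm_te <- table(factor(test$group, classes), factor(pr_te, classes))
    conf_train <- conf_train + cm_tr
    conf_test <- conf_test + cm_te
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
                     n_features = length(sel)),
      compute_metrics(cm_te))
  }
  structure(list(
    confusion_test = conf_test,
    confusion_train = conf_train,
    metrics = dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(split = "train"), compute_metrics(conf_train)),
      dplyr::bind_cols(tibble::tibble(split = "test"), compute_metrics(conf_test))),
    folds = dplyr::bind_rows(fold_rows),
    fold_assignment = assignment,
    selected_features = if (leakage == "global") selected_global else sel_per_fold,
    config = list(folds = folds, seed = seed, leakage = leakage,
                  select = select, alpha = alpha, method = method,
                  smote = smote, k_neighbors = k_neighbors,
                  cost = cost, gamma = gamma),
    classes = classes
  ), class = "eeg_cv")
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf("<eeg_cv> %d-fold, leakage = %s\n", x$config$folds, x$config$leakage))
  print(x$metrics)
  invisible(x)
}
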