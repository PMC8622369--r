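#' Confusion matrix
#'
#' `N x N` integer counts with rows indexing the true class and columns
#' the predicted class.
#'
#' @param true,predicted integer label vectors in `1..n_classes`.
#' @param n_classes number of classes; defaults to the largest label seen.
#' @param class_names optional dimnames.
#' @return An `N x N` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted,
                             n_classes = max(true, predicted),
                             class_names = NULL) {
  true <- as.integer(true); predicted <- as.integer(predicted)
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have equal length", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) cm[true[i], predicted[i]] <- cm[true[i], predicted[i]] + 1L
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Classification accuracy
#'
#' `100 * trace / M`, as a percentage.
#'
#' @param cm a [confusion_matrix()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  m <- sum(cm)
  if (m < 1) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(unclass(cm))) / m
}

#' Geometric mean of per-class recalls
#'
#' `100 * (prod_i recall_i)^(1/N)` with `recall_i` the diagonal over the
#' row sum. Collapses to 0 as soon as one class is never recovered, which
#' is what makes it informative under class imbalance.
#'
#' @param cm a [confusion_matrix()]; every true class must have at least
#'   one sample.
#' @return Score in \[0, 100\].
#' @export
geometric_mean <- function(cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("a true class has no samples", call. = FALSE)
  recalls <- diag(cm) / rs
  100 * prod(recalls)^(1 / nrow(cm))
}

mann_whitney_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the ROC curve
#'
#' Binary: the Mann-Whitney statistic of the positive-class score, with
#' half credit for ties — the probability that a random positive outranks
#' a random negative. Multiclass (matrix scores): the unweighted mean of
#' the one-vs-rest AUCs over all classes (macro averaging).
#'
#' @param scores either a numeric vector of positive-class scores
#'   (binary; the positive class is the larger label) or an `M x N`
#'   probability matrix.
#' @param labels integer labels; `1..N` for matrix scores, two distinct
#'   values for vector scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (is.matrix(scores)) {
    N <- ncol(scores)
    missing <- setdiff(seq_len(N), unique(as.integer(labels)))
    if (length(missing) > 0L)
      stop("class ", paste(missing, collapse = ", "),
           " absent from `labels`", call. = FALSE)
    if (N < 2L) stop("need at least 2 classes", call. = FALSE)
    mean(vapply(seq_len(N), function(cl) {
      mann_whitney_auc(scores[labels == cl, cl], scores[labels != cl, cl])
    }, numeric(1L)))
  } else {
    lv <- sort(unique(as.integer(labels)))
    if (length(lv) != 2L)
      stop("vector scores need exactly two label values", call. = FALSE)
    mann_whitney_auc(scores[labels == lv[2L]], scores[labels == lv[1L]])
  }
}

#' Evaluate classifier predictions
#'
#' Bundles the three pipeline metrics plus the confusion matrix.
#'
#' @param probs `M x N` predicted probability matrix.
#' @param labels integer true labels in `1..N`.
#' @param class_names optional class names for the confusion matrix.
#' @return A list with `confusion_matrix`, `accuracy`, `gm`, `auc`.
#' @export
evaluate_predictions <- function(probs, labels, class_names = colnames(probs)) {
  predicted <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(labels, predicted, n_classes = ncol(probs),
                         class_names = class_names)
  list(confusion_matrix = cm, accuracy = accuracy(cm),
       gm = geometric_mean(cm), auc = auc_score(probs, labels))
}
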