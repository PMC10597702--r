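#' Confusion matrix from labelled predictions
#'
#' @param truth,pred integer class indices (1-based) of equal length.
#' @param n_classes number of classes K.
#' @return K x K integer matrix; entry (i, j) counts class-i truths
#'   predicted as class j.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  if (length(truth) && (min(truth, pred) < 1L || max(truth, pred) > n_classes))
    stop("labels out of range 1..n_classes", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  if (length(truth))
    for (i in seq_along(truth))
      cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' Accuracy, macro sensitivity and macro specificity
#'
#' One-vs-rest per class: sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), both averaged unweighted over classes (macro). Classes
#' with no true members contribute no sensitivity term.
#'
#' @param cm confusion matrix (truth in rows).
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (fractions in \[0, 1\]).
#' @export
per_task_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  acc <- sum(diag(cm)) / total
  rs <- rowSums(cm); cs <- colSums(cm); tp <- diag(cm)
  sens <- (tp / rs)[rs > 0]
  tn <- total - rs - cs + tp
  fp <- cs - tp
  spec <- tn / (tn + fp)
  c(accuracy = acc, sensitivity = mean(sens), specificity = mean(spec))
}

# binary ROC by threshold sweep; trapezoid AUC (ties get half credit,
# equal to the Mann-Whitney pair count)
binary_roc <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- positive[o]
  npos <- sum(y); nneg <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest macro-averaged ROC and AUC
#'
#' Sweeps the full threshold range of each class's predicted probability
#' (one-vs-rest), computes trapezoid AUC per class, and macro-averages the
#' curves (mean true-positive rate on a common false-positive-rate grid) and
#' the AUCs over classes that have both positive and negative truths.
#'
#' @param truth integer class indices (1-based).
#' @param probs row-normalised probability matrix (n x K).
#' @return list with `auc` (macro), `auc_per_class`, and `roc_points` (data
#'   frame of class/fpr/tpr, including the `"macro"` curve); `auc` is `NA`
#'   with a warning when no class admits a ROC curve.
#' @export
roc_auc <- function(truth, probs) {
  probs <- as.matrix(probs)
  truth <- as.integer(truth)
  K <- ncol(probs)
  grid <- seq(0, 1, by = 0.01)
  aucs <- rep(NA_real_, K)
  pts <- list()
  macro_tpr <- matrix(NA_real_, K, length(grid))
  for (k in seq_len(K)) {
    pos <- truth == k
    if (!any(pos) || all(pos)) next
    r <- binary_roc(probs[, k], pos)
    aucs[k] <- r$auc
    pts[[length(pts) + 1L]] <- data.frame(class = k, fpr = r$fpr,
                                          tpr = r$tpr)
    macro_tpr[k, ] <- stats::approx(r$fpr, r$tpr, xout = grid, ties = max,
                                    rule = 2)$y
  }
  ok <- !is.na(aucs)
  if (!any(ok)) {
    warning("ROC undefined: truth contains a single class", call. = FALSE)
    return(list(auc = NA_real_, auc_per_class = aucs, roc_points = NULL))
  }
  macro <- colMeans(macro_tpr[ok, , drop = FALSE])
  pts[[length(pts) + 1L]] <- data.frame(class = "macro", fpr = grid,
                                        tpr = macro)
  list(auc = mean(aucs[ok]), auc_per_class = aucs,
       roc_points = do.call(rbind, pts))
}
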