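#' Ten-fold cross-validated training and evaluation
#'
#' Runs the full rotation: each fold serves as the test fold exactly once,
#' with the next two folds (cyclically) for validation and the remaining
#' seven for training. Accumulates the cumulative per-task confusion
#' matrices (each spectrum is tested exactly once, so their grand total
#' equals the dataset size) and reports per-round and aggregate accuracy,
#' macro sensitivity, macro specificity and macro AUC.
#'
#' @param ds a preprocessed [raman_dataset()].
#' @param mtn_cfg an [mtn_config()] matching the data's input length.
#' @param cfg a [train_config()].
#' @param plan optional [make_folds()] plan (default: a 10-fold stratified
#'   plan seeded from `cfg$seed`).
#' @param scaled_down apply the configuration's scaled-down overrides.
#' @param keep_fits retain the per-round `mtn_fit` objects (memory-heavy).
#' @param verbose print progress.
#' @return an object of class `mtn_report`.
#' @export
mtn_cv <- function(ds, mtn_cfg, cfg = train_config(), plan = NULL,
                   scaled_down = FALSE, keep_fits = FALSE,
                   verbose = FALSE) {
  if (is.null(plan)) plan <- make_folds(ds, 10L, seed = cfg$seed)
  ncls <- c(t = mtn_cfg$n_classes[["t"]], n = mtn_cfg$n_classes[["n"]],
            g = mtn_cfg$n_classes[["g"]])
  cls_names <- list(t = ds$scheme$t_classes, n = ds$scheme$n_classes,
                    g = ds$scheme$grade_classes)
  cum <- lapply(c(t = "t", n = "n", g = "g"), function(task)
    matrix(0L, ncls[[task]], ncls[[task]]))
  rounds <- list()
  pooled <- list(t = list(truth = integer(), prob = NULL),
                 n = list(truth = integer(), prob = NULL),
                 g = list(truth = integer(), prob = NULL))
  fits <- list()
  histories <- list()
  for (r in seq_len(plan$n_folds)) {
    fit <- mtn_fit(ds, plan, r, mtn_cfg, cfg, scaled_down = scaled_down,
                   verbose = verbose)
    for (task in c("t", "n", "g")) {
      cum[[task]] <- cum[[task]] +
        confusion_matrix(fit$test$truth[[task]], fit$test$pred[[task]],
                         ncls[[task]])
      pooled[[task]]$truth <- c(pooled[[task]]$truth,
                                fit$test$truth[[task]])
      pooled[[task]]$prob <- rbind(pooled[[task]]$prob,
                                   fit$test$prob[[task]])
    }
    rounds[[r]] <- cbind(round = r, fit$metrics)
    histories[[r]] <- fit$history
    if (keep_fits) fits[[r]] <- fit
    if (verbose) message(sprintf("round %d/%d done", r, plan$n_folds))
  }
  rounds <- do.call(rbind, rounds)
  tasks <- list()
  for (task in c("t", "n", "g")) {
    rt <- rounds[rounds$task == task, ]
    cmat <- cum[[task]]
    dimnames(cmat) <- list(truth = cls_names[[task]],
                           predicted = cls_names[[task]])
    cum_metrics <- per_task_metrics(cmat)
    pooled_roc <- suppressWarnings(
      roc_auc(pooled[[task]]$truth, pooled[[task]]$prob))
    tasks[[task]] <- list(
      classes = cls_names[[task]],
      confusion = cmat,
      rounds = rt[, c("round", "accuracy", "sensitivity", "specificity",
                      "auc")],
      mean = colMeans(rt[, c("accuracy", "sensitivity", "specificity",
                             "auc")], na.rm = TRUE),
      sd = apply(rt[, c("accuracy", "sensitivity", "specificity", "auc")],
                 2L, stats::sd, na.rm = TRUE),
      cumulative = cum_metrics,
      pooled_auc = pooled_roc$auc,
      roc_points = pooled_roc$roc_points)
  }
  out <- list(tasks = tasks, n_folds = plan$n_folds,
              n_spectra = length(plan$assignments),
              averaging = "macro (one-vs-rest, unweighted)",
              histories = histories)
  if (keep_fits) out$fits <- fits
  class(out) <- "mtn_report"
  out
}

#' @export
print.mtn_report <- function(x, ...) {
  cat(sprintf("<mtn_report> %d-fold cross-validation over %d spectra (%s)\n",
              x$n_folds, x$n_spectra, x$averaging))
  task_names <- c(t = "T staging", n = "N staging", g = "Histological grading")
  for (task in names(x$tasks)) {
    tk <- x$tasks[[task]]
    cat(sprintf("  %-22s acc %5.2f%% +- %.2f  sens %5.2f%% +- %.2f  spec %5.2f%% +- %.2f  AUC %.4f\n",
                task_names[[task]],
                100 * tk$mean[["accuracy"]], 100 * tk$sd[["accuracy"]],
                100 * tk$mean[["sensitivity"]], 100 * tk$sd[["sensitivity"]],
                100 * tk$mean[["specificity"]], 100 * tk$sd[["specificity"]],
                tk$mean[["auc"]]))
  }
  invisible(x)
}

#' @export
summary.mtn_report <- function(object, ...) {
  print(object)
  for (task in names(object$tasks)) {
    cat("\nCumulative confusion (", task, "):\n", sep = "")
    print(object$tasks[[task]]$confusion)
  }
  invisible(object)
}

#' @export
plot.mtn_report <- function(x, which = c("curves", "roc"), ...) {
  which <- match.arg(which)
  if (which == "curves") {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
    h1 <- x$histories[[1L]]
    graphics::plot(h1$epoch, h1$train_loss, type = "l", xlab = "epoch",
                   ylab = "training loss (round 1)", ...)
    graphics::matplot(h1$epoch,
                      h1[, c("val_acc_t", "val_acc_n", "val_acc_g")],
                      type = "l", lty = 1, col = c(2, 3, 4),
                      xlab = "epoch", ylab = "validation accuracy")
    graphics::legend("bottomright", c("T", "N", "grade"), col = c(2, 3, 4),
                     lty = 1, bty = "n")
  } else {
    cols <- c(t = 2, n = 3, g = 4)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                   xlab = "false positive rate",
                   ylab = "true positive rate", ...)
    for (task in names(x$tasks)) {
      rp <- x$tasks[[task]]$roc_points
      if (is.null(rp)) next
      m <- rp[rp$class == "macro", ]
      graphics::lines(m$fpr, m$tpr, col = cols[[task]])
    }
    graphics::legend("bottomright",
                     sprintf("%s (AUC %.3f)", c("T", "N", "grade"),
                             vapply(x$tasks, function(t) t$pooled_auc,
                                    numeric(1L))),
                     col = cols, lty = 1, bty = "n")
  }
  invisible(x)
}
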