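#' Training configuration
#'
#' Full-scale defaults follow the reference protocol: SGD with learning rate
#' 1e-4, batch size 256, 1000 epochs, momentum 0.9 and weight decay 2e-5.
#' The `scaled_down` overrides define the desk-scale regime used for testing
#' on simulated cohorts (30 epochs, batch 64, and a learning rate matched to
#' the short schedule); they are applied when a fit is requested with
#' `scaled_down = TRUE`.
#'
#' @param learning_rate,batch_size,epochs,momentum,weight_decay SGD
#'   hyperparameters.
#' @param seed integer master seed; fold shuffling, initialisation and batch
#'   order derive from it.
#' @param loss_weights three nonnegative per-task loss weights.
#' @param scaled_down named list of overrides (any of `epochs`,
#'   `batch_size`, `learning_rate`).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 256L,
                         epochs = 1000L, momentum = 0.9,
                         weight_decay = 2e-5, seed = 1L,
                         loss_weights = c(1, 1, 1),
                         scaled_down = list(epochs = 30L, batch_size = 64L,
                                            learning_rate = 0.05)) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            length(loss_weights) == 3L, all(loss_weights >= 0))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 loss_weights = loss_weights, scaled_down = scaled_down),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config> SGD lr %g, batch %d, %d epochs, momentum %g, wd %g (seed %d)\n",
              x$learning_rate, x$batch_size, x$epochs, x$momentum,
              x$weight_decay, x$seed))
  if (length(x$scaled_down))
    cat("  scaled_down:", paste(names(x$scaled_down), x$scaled_down,
                                sep = "=", collapse = " "), "\n")
  invisible(x)
}

apply_scaled_down <- function(cfg) {
  for (nm in names(cfg$scaled_down)) cfg[[nm]] <- cfg$scaled_down[[nm]]
  cfg
}

# forward in memory-bounded chunks, eval mode
predict_chunked <- function(model, X, chunk = 256L) {
  n <- nrow(X)
  parts <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  lg <- list(t = NULL, n = NULL, g = NULL)
  for (p in parts) {
    r <- mtn_forward(model, X[p, , drop = FALSE], training = FALSE)
    for (task in c("t", "n", "g"))
      lg[[task]] <- rbind(lg[[task]], r$logits[[task]])
  }
  lg
}

task_accuracy <- function(logits, truth)
  mean(max.col(logits, ties.method = "first") == truth)

#' Train the network for one cross-validation round
#'
#' Fits the multi-task network by stochastic gradient descent on the round's
#' seven training folds, monitoring per-task accuracy on the two validation
#' folds after every epoch; the returned model carries the parameters of the
#' epoch with the best mean validation accuracy, and the test fold is
#' predicted exactly once with them. Fully deterministic given the seeds.
#'
#' @param ds a preprocessed [raman_dataset()] (fixed-length spectra, one
#'   common axis).
#' @param plan a [make_folds()] plan for `ds`.
#' @param round round index (the test fold).
#' @param mtn_cfg an [mtn_config()] whose input length matches `ds`.
#' @param cfg a [train_config()].
#' @param scaled_down apply the configuration's scaled-down overrides.
#' @param verbose print one line per epoch.
#' @return an object of class `mtn_fit` with elements `model`, `history`
#'   (per-epoch loss/validation accuracy), `test` (truth, predictions,
#'   probabilities) and `metrics` (per-task accuracy, sensitivity,
#'   specificity, AUC on the test fold).
#' @export
mtn_fit <- function(ds, plan, round, mtn_cfg, cfg = train_config(),
                    scaled_down = FALSE, verbose = FALSE) {
  stopifnot(inherits(ds, "raman_dataset"), inherits(plan, "fold_plan"),
            inherits(mtn_cfg, "mtn_config"), inherits(cfg, "train_config"))
  if (scaled_down) cfg <- apply_scaled_down(cfg)
  roles <- fold_roles(plan, round)
  X <- ds$intensities
  li <- label_indices(ds)
  truth_of <- function(idx) list(t = li$t[idx], n = li$n[idx],
                                 g = li$g[idx])
  model <- mtn(mtn_cfg, seed = cfg$seed + 101L * round)
  vel <- zero_like(model$par)
  n_tr <- length(roles$train)
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_acc_t = double(), val_acc_n = double(),
                        val_acc_g = double())
  best <- list(par = model$par, bn = model$bn_stats, score = -Inf)
  tr_truth <- truth_of(roles$train)
  val_truth <- truth_of(roles$val)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + 1000L * round + epoch,
                     sample.int(n_tr))
    batches <- split(roles$train[ord],
                     ceiling(seq_len(n_tr) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fw <- mtn_forward(model, X[bt, , drop = FALSE], training = TRUE)
      model$bn_stats <- fw$bn_stats
      lw <- ce_loss_grads(fw$logits,
                          list(t = li$t[bt], n = li$n[bt], g = li$g[bt]),
                          cfg$loss_weights)
      if (!is.finite(lw$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch), call. = FALSE)
      grads <- mtn_backward(model, fw$cache, lw$dlogits)
      upd <- sgd_update(model$par, grads, vel, cfg$learning_rate,
                        cfg$momentum, cfg$weight_decay)
      model$par <- upd$p
      vel <- upd$v
      ep_loss <- ep_loss + lw$loss * length(bt)
    }
    ep_loss <- ep_loss / n_tr
    # recalibrate batch-norm running statistics on a training batch: with
    # short schedules the exponential averages lag the fast-moving
    # activations, which would corrupt every evaluation-mode prediction
    # evenly spaced over the (class-ordered) training rows, so the
    # calibration batch represents every class proportionally
    calib <- roles$train[unique(round(seq(1L, n_tr,
                                          length.out = min(256L, n_tr))))]
    cf <- mtn_forward(model, X[calib, , drop = FALSE], training = TRUE,
                      bn_momentum = 1)
    model$bn_stats <- cf$bn_stats
    vl <- predict_chunked(model, X[roles$val, , drop = FALSE])
    va <- c(task_accuracy(vl$t, val_truth$t),
            task_accuracy(vl$n, val_truth$n),
            task_accuracy(vl$g, val_truth$g))
    history[nrow(history) + 1L, ] <- c(epoch, ep_loss, va)
    if (mean(va) > best$score)
      best <- list(par = model$par, bn = model$bn_stats, score = mean(va))
    if (verbose)
      message(sprintf("round %d epoch %3d loss %.4f val acc %.3f/%.3f/%.3f",
                      round, epoch, ep_loss, va[1], va[2], va[3]))
  }
  if (cfg$epochs > 0L) {
    model$par <- best$par
    model$bn_stats <- best$bn
  }
  model$trained <- cfg$epochs > 0L
  te <- predict_chunked(model, X[roles$test, , drop = FALSE])
  te_truth <- truth_of(roles$test)
  prob <- lapply(te, softmax_rows)
  # argmax ties (exactly tied logits, e.g. an untrained model) are resolved
  # uniformly under the round seed so chance-level behaviour is unbiased
  pred <- with_seed(cfg$seed + 7919L + round,
                    lapply(te, max.col, ties.method = "random"))
  ncls <- c(t = model$config$n_classes[["t"]],
            n = model$config$n_classes[["n"]],
            g = model$config$n_classes[["g"]])
  metrics <- do.call(rbind, lapply(c("t", "n", "g"), function(task) {
    cm <- confusion_matrix(te_truth[[task]], pred[[task]], ncls[[task]])
    m <- per_task_metrics(cm)
    auc <- suppressWarnings(roc_auc(te_truth[[task]], prob[[task]])$auc)
    data.frame(task = task, accuracy = m[["accuracy"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]], auc = auc)
  }))
  structure(list(model = model, history = history, round = round,
                 roles = roles,
                 test = list(truth = te_truth, pred = pred, prob = prob),
                 metrics = metrics),
            class = "mtn_fit")
}

#' @export
print.mtn_fit <- function(x, ...) {
  cat(sprintf("<mtn_fit> round %d: %d train / %d val / %d test spectra\n",
              x$round, length(x$roles$train), length(x$roles$val),
              length(x$roles$test)))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.mtn_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot", call. = FALSE)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::matplot(h$epoch, h[, c("val_acc_t", "val_acc_n", "val_acc_g")],
                    type = "l", lty = 1, col = c(2, 3, 4), xlab = "epoch",
                    ylab = "validation accuracy")
  graphics::legend("bottomright", c("T stage", "N stage", "grade"),
                   col = c(2, 3, 4), lty = 1, bty = "n")
  invisible(x)
}
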