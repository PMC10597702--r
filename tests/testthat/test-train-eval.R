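test_that("confusion matrices match a direct counting oracle", {
  expect_equal(confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), 2L),
               matrix(c(1L, 0L, 1L, 2L), 2L))
  expect_equal(confusion_matrix(integer(), integer(), 3L),
               matrix(0L, 3L, 3L))
  # perfect predictions give a diagonal matrix
  set.seed(1)
  y <- sample(4L, 30L, TRUE)
  cmd <- confusion_matrix(y, y, 4L)
  expect_true(all(cmd[upper.tri(cmd) | lower.tri(cmd)] == 0L))
  # brute-force recount on random instances
  for (rep in 1:5) {
    K <- sample(2:6, 1L)
    t0 <- sample(K, 40L, TRUE); p0 <- sample(K, 40L, TRUE)
    cm <- confusion_matrix(t0, p0, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      expect_equal(cm[i, j], sum(t0 == i & p0 == j))
  }
  expect_error(confusion_matrix(1:3, 1:2, 3L), "equal length")
  expect_error(confusion_matrix(c(1, 4), c(1, 2), 3L), "range")
})

test_that("accuracy/sensitivity/specificity match one-vs-rest hand counts", {
  expect_equal(per_task_metrics(matrix(c(8, 1, 2, 9), 2L)),
               c(accuracy = 0.85, sensitivity = 0.85, specificity = 0.85))
  expect_equal(unname(per_task_metrics(diag(c(3L, 5L, 2L)))), c(1, 1, 1))
  # class with zero truths is excluded from the sensitivity average
  cm <- matrix(c(5L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 4L), 3L, byrow = TRUE)
  m <- per_task_metrics(cm)
  expect_equal(m[["sensitivity"]], mean(c(1, 4 / 5)))
  # brute-force recount from raw pairs
  set.seed(2)
  for (rep in 1:5) {
    K <- sample(2:5, 1L)
    t0 <- sample(K, 60L, TRUE); p0 <- sample(K, 60L, TRUE)
    got <- per_task_metrics(confusion_matrix(t0, p0, K))
    expect_equal(got[["accuracy"]], mean(t0 == p0))
    sens <- vapply(seq_len(K), function(k)
      if (any(t0 == k)) mean(p0[t0 == k] == k) else NA_real_, numeric(1L))
    spec <- vapply(seq_len(K), function(k)
      mean(p0[t0 != k] != k), numeric(1L))
    expect_equal(got[["sensitivity"]], mean(sens, na.rm = TRUE))
    expect_equal(got[["specificity"]], mean(spec))
  }
  expect_error(per_task_metrics(matrix(0L, 2L, 2L)), "empty")
})

test_that("AUC equals the Mann-Whitney pair count, ties at half credit", {
  pair_auc <- function(score, pos) {
    p <- score[pos]; n <- score[!pos]
    g <- expand.grid(p = p, n = n)
    mean((g$p > g$n) + 0.5 * (g$p == g$n))
  }
  # published-style 4-sample toys
  s4 <- c(.9, .8, .4, .2)
  r1 <- roc_auc(c(2L, 2L, 1L, 1L), cbind(1 - s4, s4))
  expect_equal(r1$auc_per_class[2L], 1)
  r2 <- roc_auc(c(2L, 1L, 2L, 1L), cbind(1 - s4, s4))
  expect_equal(r2$auc_per_class[2L], 0.75)
  # random instances incl. ties vs the exhaustive pair count
  set.seed(7)
  for (rep in 1:8) {
    y <- sample(0:1, 25L, TRUE)
    if (length(unique(y)) < 2L) next
    s <- round(runif(25L), 1L)  # force ties
    got <- binary_roc(s, y == 1L)$auc
    expect_equal(got, pair_auc(s, y == 1L), tolerance = 1e-12)
  }
  # degenerate cases
  p <- matrix(rep(c(0.3, 0.7), each = 6L), ncol = 2L)
  expect_equal(roc_auc(rep(c(1L, 2L), 3L), p)$auc, 0.5)
  expect_warning(r <- roc_auc(rep(1L, 4L), matrix(runif(8L), ncol = 2L)),
                 "single class")
  expect_true(is.na(r$auc))
})

test_that("AUC agrees with pROC on random multiclass problems", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- sample(3L, 60L, TRUE)
  p <- matrix(runif(180L), ncol = 3L)
  p <- p / rowSums(p)
  ours <- roc_auc(y, p)$auc_per_class
  for (k in 1:3) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = as.integer(y == k), predictor = p[, k], quiet = TRUE,
      levels = c(0L, 1L), direction = "<")))
    expect_equal(ours[k], as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("fold plans are stratified, disjoint, exhaustive partitions", {
  ds <- tiny_dataset(n_per_class = 50L, n_points = 16L)
  plan <- make_folds(ds, 10L, seed = 3L)
  expect_equal(as.vector(table(plan$assignments)), rep(10L, 10L))
  cls <- ds$labels$grade
  for (f in 1:10)
    expect_equal(as.vector(table(cls[plan$assignments == f])), c(5L, 5L))
  # partition property and rotation: every fold is the test fold once
  seen <- integer()
  for (r in 1:10) {
    roles <- fold_roles(plan, r)
    expect_equal(sort(c(roles$train, roles$val, roles$test)), 1:100)
    expect_equal(length(roles$val), 20L)
    seen <- c(seen, unique(plan$assignments[roles$test]))
  }
  expect_equal(sort(seen), 1:10)
  expect_identical(make_folds(ds, 10L, seed = 3L)$assignments,
                   plan$assignments)
  w <- capture_warnings(make_folds(tiny_dataset(n_per_class = 4L), 10L,
                                   seed = 1L))
  expect_match(w, "< 10 folds", all = TRUE)
  expect_length(w, 2L)  # one warning per undersized class
})

test_that("patient-level folds keep a patient's spectra together", {
  ds <- tiny_dataset(n_per_class = 40L, n_points = 16L)
  plan <- suppressWarnings(make_folds(ds, 8L, seed = 2L,
                                      group_by_patient = TRUE))
  split_by_patient <- tapply(plan$assignments, ds$labels$patient_id,
                             function(v) length(unique(v)))
  expect_true(all(split_by_patient == 1L))
})

test_that("a round trains, selects on validation, and is reproducible", {
  ds <- tiny_dataset(n_per_class = 30L, n_points = 64L, noise = 0.03)
  cfg <- train_config(seed = 5L,
                      scaled_down = list(epochs = 6L, batch_size = 16L,
                                         learning_rate = 0.1))
  plan <- make_folds(ds, 10L, seed = 5L)
  fit <- mtn_fit(ds, plan, 1L, tiny_mtn_config(), cfg, scaled_down = TRUE)
  expect_equal(nrow(fit$history), 6L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$metrics$accuracy >= 0 & fit$metrics$accuracy <= 1))
  # two separable classes should be learned quickly
  expect_gte(fit$metrics$accuracy[fit$metrics$task == "g"], 0.8)
  fit2 <- mtn_fit(ds, plan, 1L, tiny_mtn_config(), cfg, scaled_down = TRUE)
  expect_identical(fit$metrics, fit2$metrics)
  expect_identical(fit$history, fit2$history)
})

test_that("epochs = 0 leaves the model untrained at chance level", {
  ds <- tiny_dataset(n_per_class = 20L, n_points = 64L)
  cfg <- train_config(seed = 2L,
                      scaled_down = list(epochs = 0L, batch_size = 16L,
                                         learning_rate = 0.05))
  plan <- make_folds(ds, 10L, seed = 2L)
  fit <- mtn_fit(ds, plan, 1L, tiny_mtn_config(), cfg, scaled_down = TRUE)
  expect_equal(nrow(fit$history), 0L)
  expect_false(fit$model$trained)
  # zero-initialised classifiers: uniform probabilities on every spectrum
  pr <- predict(fit$model, ds)
  expect_true(all(abs(pr$t - 1 / 7) < 1e-9))
})

test_that("cross-validation accumulates one test per spectrum", {
  ds <- tiny_dataset(n_per_class = 25L, n_points = 64L)
  cfg <- train_config(seed = 4L,
                      scaled_down = list(epochs = 2L, batch_size = 16L,
                                         learning_rate = 0.05))
  rep <- mtn_cv(ds, tiny_mtn_config(), cfg, scaled_down = TRUE)
  for (task in c("t", "n", "g")) {
    expect_equal(sum(rep$tasks[[task]]$confusion), 50L)
    expect_equal(nrow(rep$tasks[[task]]$rounds), 10L)
    expect_true(all(rep$tasks[[task]]$rounds$accuracy >= 0))
  }
  expect_output(print(rep), "10-fold")
})
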