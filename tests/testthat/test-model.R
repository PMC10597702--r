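test_that("default construction reproduces the published layer geometry", {
  m <- mtn(mtn_config(), seed = 1L)
  tr <- m$shape_trace
  expect_equal(tr$length[tr$stage == "stem"], 519L)
  expect_equal(tr$channels[tr$stage == "stem"], 64L)
  expect_equal(tr$length[match(c("stage2", "stage3", "stage4", "stage5"),
                               tr$stage)], c(519L, 260L, 130L, 65L))
  expect_equal(tr$channels[match(c("stage2", "stage3", "stage4", "stage5"),
                                 tr$stage)], c(256L, 512L, 1024L, 2048L))
  expect_equal(tr$length[tr$stage == "neck"], 1L)
  expect_equal(m$n_identity_blocks, 12L)
  expect_equal(m$n_head_fc, 6L)
  expect_equal(unname(m$config$n_classes), c(7L, 5L, 5L))
  # projection blocks counted structurally: first block of each stage
  n_proj <- sum(vapply(m$par$stages, function(st)
    sum(vapply(st, function(b) !is.null(b$Wp), logical(1L))), integer(1L)))
  expect_equal(n_proj, 4L)
  expect_equal(sum(m$config$stage_blocks) - n_proj, 12L)
  # head FC widths: 3 layers to 7 classes, 2 to 5, 1 to 5
  expect_equal(vapply(m$par$heads, length, integer(1L)),
               c(t = 3L, n = 2L, g = 1L))
  expect_equal(ncol(m$par$heads$t[[3]]$W), 7L)
  expect_equal(ncol(m$par$heads$n[[2]]$W), 5L)
  expect_equal(ncol(m$par$heads$g[[1]]$W), 5L)
})

test_that("construction is deterministic in the seed", {
  a <- mtn(tiny_mtn_config(), seed = 42L)
  b <- mtn(tiny_mtn_config(), seed = 42L)
  expect_identical(a$par, b$par)
  c <- mtn(tiny_mtn_config(), seed = 43L)
  expect_false(identical(a$par$stem$W, c$par$stem$W))
})

test_that("forward pass honours the shape contract", {
  m <- mtn(tiny_mtn_config(), seed = 1L)
  z <- matrix(0, 1L, 64L)
  lg <- mtn_logits(m, z)
  expect_equal(dim(lg$t), c(1L, 7L))
  expect_equal(dim(lg$n), c(1L, 5L))
  expect_equal(dim(lg$g), c(1L, 5L))
  expect_true(all(is.finite(unlist(lg))))
  # identical rows give identical logits; batch order is immaterial
  set.seed(2)
  X <- matrix(rnorm(3 * 64), 3L, 64L)
  X2 <- X[c(1L, 1L, 3L, 2L), ]
  lg2 <- mtn_logits(m, X2)
  expect_equal(lg2$t[1L, ], lg2$t[2L, ], tolerance = 1e-12)
  lgX <- mtn_logits(m, X)
  expect_equal(lg2$g[4L, ], lgX$g[2L, ], tolerance = 1e-12)
  expect_error(mtn_logits(m, matrix(0, 1L, 65L)), "input length")
})

test_that("all three heads share the backbone parameters", {
  m <- mtn(tiny_mtn_config(), seed = 3L)
  # give the zero-initialised classifier layers signal so heads respond
  set.seed(8)
  for (task in c("t", "n", "g")) {
    last <- length(m$par$heads[[task]])
    m$par$heads[[task]][[last]]$W[] <-
      rnorm(length(m$par$heads[[task]][[last]]$W)) * 0.3
  }
  X <- matrix(rnorm(2 * 64), 2L, 64L)
  base <- mtn_logits(m, X)
  m2 <- m
  # perturb a shortcut projection: active even at zero residual gain
  m2$par$stages[[2]][[1]]$Wp[1L, 1L] <-
    m2$par$stages[[2]][[1]]$Wp[1L, 1L] + 0.5
  pert <- mtn_logits(m2, X)
  expect_gt(max(abs(pert$t - base$t)), 0)
  expect_gt(max(abs(pert$n - base$n)), 0)
  expect_gt(max(abs(pert$g - base$g)), 0)
})

test_that("predicted probabilities are valid softmax outputs", {
  m <- mtn(tiny_mtn_config(), seed = 1L)
  set.seed(4)
  X <- matrix(rnorm(5 * 64), 5L, 64L)
  pr <- predict(m, X, type = "prob")
  for (task in c("t", "n", "g"))
    expect_equal(unname(rowSums(pr[[task]])), rep(1, 5L),
                 tolerance = 1e-6)
  # untrained heads are zero-initialised: logits 0, probabilities uniform
  expect_equal(unname(pr$t[1L, ]), rep(1 / 7, 7L), tolerance = 1e-12)
  expect_equal(unname(pr$n[1L, ]), rep(1 / 5, 5L), tolerance = 1e-12)
  # closed-form softmax oracle on a toy logit row
  z <- c(1.2, -0.3, 0.4)
  expect_equal(as.vector(ramanmtn:::softmax_rows(matrix(z, 1L))),
               exp(z) / sum(exp(z)), tolerance = 1e-12)
  cls <- predict(m, X, type = "class")
  expect_true(all(cls$g %in% label_scheme()$grade_classes))
})

test_that("multi-task loss matches closed forms and honours weights", {
  B <- 4L
  perfect <- function(K, y) {
    lg <- matrix(-50, B, K)
    lg[cbind(seq_len(B), y)] <- 50
    lg
  }
  yt <- c(1L, 2L, 3L, 7L); yn <- c(1L, 5L, 2L, 3L); yg <- c(4L, 1L, 2L, 5L)
  expect_lt(multitask_loss(perfect(7, yt), perfect(5, yn), perfect(5, yg),
                           yt, yn, yg), 1e-6)
  zero7 <- matrix(0, B, 7L); zero5 <- matrix(0, B, 5L)
  expect_equal(multitask_loss(zero7, zero5, zero5, yt, yn, yg),
               log(7) + log(5) + log(5), tolerance = 1e-12)
  expect_equal(multitask_loss(zero7, zero5, zero5, yt, yn, yg,
                              weights = c(1, 0, 0)),
               log(7), tolerance = 1e-12)
  expect_error(multitask_loss(zero7, zero5, zero5, c(0L, 1L, 1L, 1L),
                              yn, yg), "out of range")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- mtn_config(input_length = 48L, stem_channels = 4L,
                    stage_channels = c(8L, 16L, 32L, 64L),
                    stage_blocks = c(1L, 1L, 1L, 1L),
                    head_t_hidden = 8L, head_n_hidden = 8L)
  m <- mtn(cfg, seed = 3L)
  # non-degenerate residual gains and classifier weights
  set.seed(5)
  for (s in 1:4) for (b in seq_along(m$par$stages[[s]]))
    m$par$stages[[s]][[b]]$g3 <- rep(0.7, length(m$par$stages[[s]][[b]]$g3))
  for (task in c("t", "n", "g")) {
    last <- length(m$par$heads[[task]])
    m$par$heads[[task]][[last]]$W[] <-
      rnorm(length(m$par$heads[[task]][[last]]$W)) * 0.3
  }
  B <- 4L
  X <- matrix(rnorm(B * 48L), B)
  truth <- list(t = sample(7L, B, TRUE), n = sample(5L, B, TRUE),
                g = sample(5L, B, TRUE))
  lossfun <- function(model) {
    fw <- ramanmtn:::mtn_forward(model, X, training = TRUE)
    ramanmtn:::ce_loss_grads(fw$logits, truth, c(1, 1, 1))$loss
  }
  fw <- ramanmtn:::mtn_forward(m, X, training = TRUE)
  lw <- ramanmtn:::ce_loss_grads(fw$logits, truth, c(1, 1, 1))
  gr <- ramanmtn:::mtn_backward(m, fw$cache, lw$dlogits)
  eps <- 1e-5
  check <- function(getter, setter, gval) {
    for (i in sample(length(gval), 3L)) {
      mp <- m; v <- getter(mp); v[i] <- v[i] + eps; mp <- setter(mp, v)
      up <- lossfun(mp)
      mp <- m; v <- getter(mp); v[i] <- v[i] - eps; mp <- setter(mp, v)
      dn <- lossfun(mp)
      fd <- (up - dn) / (2 * eps)
      expect_lt(abs(fd - gval[i]) / max(1e-6, abs(fd) + abs(gval[i])),
                1e-4)
    }
  }
  check(function(m) m$par$stem$W,
        function(m, v) { m$par$stem$W[] <- v; m }, gr$stem$W)
  check(function(m) m$par$stages[[2]][[1]]$W2,
        function(m, v) { m$par$stages[[2]][[1]]$W2[] <- v; m },
        gr$stages[[2]][[1]]$W2)
  check(function(m) m$par$stages[[4]][[1]]$gp,
        function(m, v) { m$par$stages[[4]][[1]]$gp[] <- v; m },
        gr$stages[[4]][[1]]$gp)
  check(function(m) m$par$neck$g,
        function(m, v) { m$par$neck$g[] <- v; m }, gr$neck$g)
  check(function(m) m$par$heads$t[[1]]$W,
        function(m, v) { m$par$heads$t[[1]]$W[] <- v; m },
        gr$heads$t[[1]]$W)
})
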