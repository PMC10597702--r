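#' Multi-task network configuration
#'
#' Describes the shared 1D ResNet-50 backbone (stem + four bottleneck
#' stages), the global-average-pooling neck and the three classification
#' heads. The default geometry reproduces the reference architecture: a
#' 2076-point input, a 7-wide stride-2 stem convolution with 64 kernels
#' followed by 3-wide stride-2 max pooling (stem output 519 x 64), bottleneck
#' stages of (3, 4, 6, 3) blocks emitting 519 x 256, 260 x 512, 130 x 1024
#' and 65 x 2048 feature maps, 12 identity blocks, and heads of 3 / 2 / 1
#' fully connected layers producing 7 (T stage), 5 (N stage) and 5 (grade)
#' classes — 6 FC layers in total.
#'
#' @param input_length network input length in points.
#' @param stem_kernel,stem_channels,stem_pool stem convolution width, kernel
#'   count, and max-pool width.
#' @param stage_channels output channels of the four bottleneck stages.
#' @param stage_blocks bottleneck blocks per stage; the first block of each
#'   stage has a projection shortcut, the rest are identity blocks.
#' @param bottleneck_ratio channel compression inside a bottleneck
#'   (mid-channels = out-channels / ratio).
#' @param head_t_hidden,head_n_hidden,head_g_hidden hidden widths of the
#'   three heads (the output layer is appended automatically, so the T head's
#'   default `c(512, 128)` yields 3 FC layers, the N head's `256` yields 2,
#'   and the grade head's empty vector yields a single FC layer).
#' @param n_classes named integer vector of output widths per task.
#' @return an object of class `mtn_config`.
#' @export
mtn_config <- function(input_length = 2076L, stem_kernel = 7L,
                       stem_channels = 64L, stem_pool = 3L,
                       stage_channels = c(256L, 512L, 1024L, 2048L),
                       stage_blocks = c(3L, 4L, 6L, 3L),
                       bottleneck_ratio = 4L,
                       head_t_hidden = c(512L, 128L),
                       head_n_hidden = c(256L),
                       head_g_hidden = integer(0),
                       n_classes = c(t = 7L, n = 5L, g = 5L)) {
  cfg <- list(input_length = as.integer(input_length),
              stem_kernel = as.integer(stem_kernel),
              stem_channels = as.integer(stem_channels),
              stem_pool = as.integer(stem_pool),
              stage_channels = as.integer(stage_channels),
              stage_blocks = as.integer(stage_blocks),
              bottleneck_ratio = as.integer(bottleneck_ratio),
              head_hidden = list(t = as.integer(head_t_hidden),
                                 n = as.integer(head_n_hidden),
                                 g = as.integer(head_g_hidden)),
              n_classes = c(t = as.integer(n_classes[["t"]]),
                            n = as.integer(n_classes[["n"]]),
                            g = as.integer(n_classes[["g"]])))
  if (length(cfg$stage_channels) != 4L || length(cfg$stage_blocks) != 4L)
    stop("exactly four bottleneck stages are required", call. = FALSE)
  if (any(cfg$stage_channels %% cfg$bottleneck_ratio != 0L))
    stop("stage channels must be divisible by bottleneck_ratio",
         call. = FALSE)
  if (cfg$input_length < 32L)
    stop("input_length too short for a 5-layer backbone", call. = FALSE)
  structure(cfg, class = "mtn_config")
}

# symbolic per-stage (length, channels) record
compute_shape_trace <- function(cfg) {
  ceil2 <- function(L) as.integer(ceiling(L / 2))
  L_conv <- ceil2(cfg$input_length)
  L_stem <- ceil2(L_conv)
  lens <- c(L_stem, L_stem, ceil2(L_stem), ceil2(ceil2(L_stem)),
            ceil2(ceil2(ceil2(L_stem))))
  data.frame(stage = c("stem", "stage2", "stage3", "stage4", "stage5",
                       "neck"),
             length = c(lens, 1L),
             channels = c(cfg$stem_channels, cfg$stage_channels,
                          cfg$stage_channels[4L]))
}

#' Build the multi-task network
#'
#' Constructs an untrained model with seeded He-normal initial weights. The
#' shape trace is computed symbolically and, for the canonical 2076-point
#' input, verified against the printed geometry (stem 519 x 64; stages
#' 519 x 256, 260 x 512, 130 x 1024, 65 x 2048) before any parameter is
#' allocated; a mismatch names the offending stage. The residual gain of
#' every block's last batch-norm starts at zero so each block is initially
#' the identity, which stabilises short training runs.
#'
#' @param cfg an [mtn_config()].
#' @param seed integer seed for the weight initialisation.
#' @return an object of class `mtn_model`.
#' @examples
#' m <- mtn(mtn_config(), seed = 1)
#' m$shape_trace
#' @export
mtn <- function(cfg = mtn_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mtn_config"))
  trace <- compute_shape_trace(cfg)
  if (cfg$input_length == 2076L) {
    printed <- c(stem = 519L, stage2 = 519L, stage3 = 260L, stage4 = 130L,
                 stage5 = 65L)
    got <- trace$length[match(names(printed), trace$stage)]
    bad <- which(got != printed)
    if (length(bad))
      stop("geometry mismatch at ", names(printed)[bad[1L]], ": computed ",
           got[bad[1L]], ", expected ", printed[bad[1L]], call. = FALSE)
  }
  par <- with_seed(seed, init_params(cfg))
  stats <- init_bn_stats(cfg)
  n_identity <- sum(cfg$stage_blocks - 1L)
  structure(list(config = cfg, par = par, bn_stats = stats,
                 shape_trace = trace, n_identity_blocks = n_identity,
                 n_head_fc = sum(vapply(cfg$head_hidden, length,
                                        integer(1L)) + 1L),
                 seed = as.integer(seed), trained = FALSE),
            class = "mtn_model")
}

init_params <- function(cfg) {
  bn_par <- function(C, zero_gamma = FALSE)
    list(g = if (zero_gamma) numeric(C) else rep(1, C), b = numeric(C))
  par <- list()
  par$stem <- c(list(W = he_init(cfg$stem_kernel, cfg$stem_channels)),
                bn_par(cfg$stem_channels))
  par$stages <- vector("list", 4L)
  C_in <- cfg$stem_channels
  for (s in 1:4) {
    C_out <- cfg$stage_channels[s]
    C_mid <- C_out %/% cfg$bottleneck_ratio
    blocks <- vector("list", cfg$stage_blocks[s])
    for (b in seq_len(cfg$stage_blocks[s])) {
      cin <- if (b == 1L) C_in else C_out
      blk <- list(W1 = he_init(cin, C_mid),
                  g1 = rep(1, C_mid), b1 = numeric(C_mid),
                  W2 = he_init(3L * C_mid, C_mid),
                  g2 = rep(1, C_mid), b2 = numeric(C_mid),
                  W3 = he_init(C_mid, C_out),
                  g3 = numeric(C_out),  # zero residual gain at init
                  b3 = numeric(C_out))
      if (b == 1L) {
        blk$Wp <- he_init(cin, C_out)
        blk$gp <- rep(1, C_out); blk$bp <- numeric(C_out)
      }
      blocks[[b]] <- blk
    }
    par$stages[[s]] <- blocks
    C_in <- C_out
  }
  # neck feature standardisation: spectra are near-identical inputs, so
  # pooled features have a large common offset and tiny informative
  # variance; normalising them makes head training well-conditioned
  par$neck <- bn_par(cfg$stage_channels[4L])
  par$heads <- list()
  for (task in c("t", "n", "g")) {
    widths <- c(cfg$stage_channels[4L], cfg$head_hidden[[task]],
                cfg$n_classes[[task]])
    # classifier layers start at zero: logits begin uniform and the trained
    # weights carry accumulated gradient signal only, which keeps Grad-CAM
    # channel weights free of initialisation noise
    layers <- vector("list", length(widths) - 1L)
    for (i in seq_along(layers))
      layers[[i]] <- list(W = if (i == length(layers))
                            matrix(0, widths[i], widths[i + 1L])
                          else he_init(widths[i], widths[i + 1L]),
                          b = numeric(widths[i + 1L]))
    par$heads[[task]] <- layers
  }
  par
}

init_bn_stats <- function(cfg) {
  st <- function(C) list(m = numeric(C), v = rep(1, C))
  out <- list(stem = st(cfg$stem_channels), stages = vector("list", 4L),
              neck = st(cfg$stage_channels[4L]))
  for (s in 1:4) {
    C_out <- cfg$stage_channels[s]
    C_mid <- C_out %/% cfg$bottleneck_ratio
    blocks <- vector("list", cfg$stage_blocks[s])
    for (b in seq_len(cfg$stage_blocks[s])) {
      blk <- list(bn1 = st(C_mid), bn2 = st(C_mid), bn3 = st(C_out))
      if (b == 1L) blk$bnp <- st(C_out)
      blocks[[b]] <- blk
    }
    out$stages[[s]] <- blocks
  }
  out
}

#' @export
print.mtn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mtn_model> 1D ResNet-50 backbone, input %d points%s\n",
              cfg$input_length,
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  cat(sprintf("  %d conv modules, %d identity blocks, heads %d/%d/%d classes (%d FC layers)\n",
              5L, x$n_identity_blocks, cfg$n_classes[["t"]],
              cfg$n_classes[["n"]], cfg$n_classes[["g"]], x$n_head_fc))
  print(x$shape_trace, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mtn_model <- function(object, ...) {
  npar <- sum(unlist(rapply(object$par, length, how = "list")))
  cat(sprintf("mtn_model with %s trainable parameters\n",
              format(npar, big.mark = ",")))
  print(object)
  invisible(object)
}

# ---- forward / backward ----------------------------------------------------

block_fwd <- function(fm, p, stride, shortcut, st, training,
                      bn_momentum = 0.1) {
  c1 <- conv_fwd(fm, p$W1, 1L)
  b1 <- bn_fwd(c1$out$x, p$g1, p$b1, st$bn1, training, bn_momentum)
  r1 <- relu_fwd(b1$y)
  fm1 <- list(x = r1$y, B = c1$out$B, L = c1$out$L)
  c2 <- conv_fwd(fm1, p$W2, stride)
  b2 <- bn_fwd(c2$out$x, p$g2, p$b2, st$bn2, training, bn_momentum)
  r2 <- relu_fwd(b2$y)
  fm2 <- list(x = r2$y, B = c2$out$B, L = c2$out$L)
  c3 <- conv_fwd(fm2, p$W3, 1L)
  b3 <- bn_fwd(c3$out$x, p$g3, p$b3, st$bn3, training, bn_momentum)
  sc <- NULL
  if (shortcut == "identity") {
    sx <- fm$x
  } else if (shortcut == "proj") {
    cp <- conv_fwd(fm, p$Wp, stride)
    bp <- bn_fwd(cp$out$x, p$gp, p$bp, st$bnp, training, bn_momentum)
    sx <- bp$y
    sc <- list(cp = cp, bp = bp)
  } else {  # proj_pool: stride-2 average pooling, then 1x1 projection
    pp <- avgpool2_fwd(fm)
    cp <- conv_fwd(pp$out, p$Wp, 1L)
    bp <- bn_fwd(cp$out$x, p$gp, p$bp, st$bnp, training, bn_momentum)
    sx <- bp$y
    sc <- list(pp = pp, cp = cp, bp = bp)
  }
  r3 <- relu_fwd(b3$y + sx)
  new_st <- list(bn1 = b1$st, bn2 = b2$st, bn3 = b3$st)
  if (!is.null(sc)) new_st$bnp <- sc$bp$st
  list(out = list(x = r3$y, B = c3$out$B, L = c3$out$L),
       st = new_st,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$mask,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$mask,
                    c3 = c3$cache, b3 = b3$cache, r3 = r3$mask,
                    shortcut = shortcut, sc = sc))
}

block_bwd <- function(dY, cache) {
  dsum <- relu_bwd(dY, cache$r3)
  g <- list()
  b3 <- bn_bwd(dsum, cache$b3)
  g$g3 <- b3$dgamma; g$b3 <- b3$dbeta
  c3 <- conv_bwd(b3$dX, cache$c3)
  g$W3 <- c3$dW
  d2 <- relu_bwd(c3$dX, cache$r2)
  b2 <- bn_bwd(d2, cache$b2)
  g$g2 <- b2$dgamma; g$b2 <- b2$dbeta
  c2 <- conv_bwd(b2$dX, cache$c2)
  g$W2 <- c2$dW
  d1 <- relu_bwd(c2$dX, cache$r1)
  b1 <- bn_bwd(d1, cache$b1)
  g$g1 <- b1$dgamma; g$b1 <- b1$dbeta
  c1 <- conv_bwd(b1$dX, cache$c1)
  g$W1 <- c1$dW
  dX <- c1$dX
  if (cache$shortcut == "identity") {
    dX <- dX + dsum
  } else {
    bp <- bn_bwd(dsum, cache$sc$bp$cache)
    g$gp <- bp$dgamma; g$bp <- bp$dbeta
    cp <- conv_bwd(bp$dX, cache$sc$cp$cache)
    g$Wp <- cp$dW
    if (cache$shortcut == "proj") dX <- dX + cp$dX
    else dX <- dX + avgpool2_bwd(cp$dX, cache$sc$pp$cache)
  }
  list(grads = g, dX = dX)
}

stage_shortcuts <- c("proj", "proj", "proj_pool", "proj_pool")
stage_strides <- c(1L, 2L, 2L, 2L)

mtn_forward <- function(model, X, training = FALSE, bn_momentum = 0.1) {
  cfg <- model$config
  if (ncol(X) != cfg$input_length)
    stop(sprintf("input length %d does not match the model's %d",
                 ncol(X), cfg$input_length), call. = FALSE)
  B <- nrow(X)
  fm <- list(x = matrix(c(t(X)), ncol = 1L), B = B, L = ncol(X))
  st <- model$bn_stats
  cache <- list()
  cs <- conv_fwd(fm, model$par$stem$W, 2L)
  bs <- bn_fwd(cs$out$x, model$par$stem$g, model$par$stem$b, st$stem,
               training, bn_momentum)
  rs <- relu_fwd(bs$y)
  mp <- maxpool_fwd(list(x = rs$y, B = cs$out$B, L = cs$out$L),
                    cfg$stem_pool, 2L)
  st$stem <- bs$st
  cache$stem <- list(conv = cs$cache, bn = bs$cache, relu = rs$mask,
                     pool = mp$cache)
  fm <- mp$out
  cache$stages <- vector("list", 4L)
  for (s in 1:4) {
    nb <- cfg$stage_blocks[s]
    cache$stages[[s]] <- vector("list", nb)
    for (b in seq_len(nb)) {
      r <- block_fwd(fm, model$par$stages[[s]][[b]],
                     stride = if (b == 1L) stage_strides[s] else 1L,
                     shortcut = if (b == 1L) stage_shortcuts[s]
                                else "identity",
                     st = st$stages[[s]][[b]], training = training,
                     bn_momentum = bn_momentum)
      st$stages[[s]][[b]] <- r$st
      cache$stages[[s]][[b]] <- r$cache
      fm <- r$out
    }
  }
  stage5 <- fm
  gp <- gap_fwd(fm)
  cache$gap <- gp$cache
  nb <- bn_fwd(gp$f, model$par$neck$g, model$par$neck$b, st$neck,
               training, bn_momentum)
  st$neck <- nb$st
  cache$neck <- nb$cache
  feats <- nb$y
  logits <- list()
  cache$heads <- list()
  for (task in c("t", "n", "g")) {
    h <- feats
    layers <- model$par$heads[[task]]
    hc <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      fc <- fc_fwd(h, layers[[i]]$W, layers[[i]]$b)
      hc[[i]] <- list(fc = fc$cache)
      h <- fc$y
      if (i < length(layers)) {
        rl <- relu_fwd(h)
        hc[[i]]$relu <- rl$mask
        h <- rl$y
      }
    }
    logits[[task]] <- h
    cache$heads[[task]] <- hc
  }
  list(logits = logits, feats = feats, stage5 = stage5, cache = cache,
       bn_stats = st)
}

# gradient of the three heads' scores w.r.t. the pooled features
heads_bwd <- function(model, cache, dlogits) {
  grads <- list()
  dfeats <- NULL
  for (task in c("t", "n", "g")) {
    if (is.null(dlogits[[task]])) next
    layers <- model$par$heads[[task]]
    hc <- cache$heads[[task]]
    d <- dlogits[[task]]
    gl <- vector("list", length(layers))
    for (i in rev(seq_along(layers))) {
      if (i < length(layers)) d <- relu_bwd(d, hc[[i]]$relu)
      fb <- fc_bwd(d, hc[[i]]$fc)
      gl[[i]] <- list(W = fb$dW, b = fb$db)
      d <- fb$dX
    }
    grads[[task]] <- gl
    dfeats <- if (is.null(dfeats)) d else dfeats + d
  }
  list(grads = grads, dfeats = dfeats)
}

mtn_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  hb <- heads_bwd(model, cache, dlogits)
  grads <- list(heads = hb$grads)
  nb <- bn_bwd(hb$dfeats, cache$neck)
  grads$neck <- list(g = nb$dgamma, b = nb$dbeta)
  dX <- gap_bwd(nb$dX, cache$gap)
  grads$stages <- vector("list", 4L)
  for (s in 4:1) {
    nb <- cfg$stage_blocks[s]
    grads$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      r <- block_bwd(dX, cache$stages[[s]][[b]])
      grads$stages[[s]][[b]] <- r$grads
      dX <- r$dX
    }
  }
  dX <- maxpool_bwd(dX, cache$stem$pool)
  dX <- relu_bwd(dX, cache$stem$relu)
  bb <- bn_bwd(dX, cache$stem$bn)
  cb <- conv_bwd(bb$dX, cache$stem$conv)
  grads$stem <- list(W = cb$dW, g = bb$dgamma, b = bb$dbeta)
  grads
}

#' Forward pass returning raw logits
#'
#' @param model an `mtn_model`.
#' @param batch numeric matrix (rows = spectra) whose column count equals the
#'   model's input length.
#' @return list with logit matrices `t` (B x 7), `n` (B x 5), `g` (B x 5).
#' @export
mtn_logits <- function(model, batch) {
  stopifnot(inherits(model, "mtn_model"))
  batch <- as.matrix(batch)
  mtn_forward(model, batch, training = FALSE)$logits
}

#' Predict from the multi-task network
#'
#' @param object an `mtn_model`.
#' @param newdata numeric matrix (rows = spectra) or a [raman_dataset()].
#' @param type `"prob"` for per-task softmax probability matrices, `"class"`
#'   for predicted labels, `"logit"` for raw scores.
#' @param scheme a [label_scheme()] used to name classes.
#' @param ... unused.
#' @return a named list with one element per task.
#' @export
predict.mtn_model <- function(object, newdata,
                              type = c("prob", "class", "logit"),
                              scheme = label_scheme(), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raman_dataset")) {
    scheme <- newdata$scheme
    newdata <- newdata$intensities
  }
  lg <- mtn_logits(object, newdata)
  cls <- list(t = scheme$t_classes, n = scheme$n_classes,
              g = scheme$grade_classes)
  out <- list()
  for (task in c("t", "n", "g")) {
    if (type == "logit") { out[[task]] <- lg[[task]]; next }
    P <- softmax_rows(lg[[task]])
    colnames(P) <- cls[[task]][seq_len(ncol(P))]
    out[[task]] <- if (type == "prob") P
                   else cls[[task]][max.col(P, ties.method = "first")]
  }
  out
}

#' Combined multi-task cross-entropy loss
#'
#' Weighted sum of the three per-head softmax cross-entropies, each averaged
#' over the batch.
#'
#' @param t_logits,n_logits,g_logits logit matrices (B x K per task).
#' @param t_true,n_true,g_true integer class indices (1-based).
#' @param weights three nonnegative per-task weights.
#' @return scalar loss.
#' @export
multitask_loss <- function(t_logits, n_logits, g_logits,
                           t_true, n_true, g_true, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  one <- function(lg, y, w) {
    y <- as.integer(y)
    if (any(y < 1L | y > ncol(lg)))
      stop("class index out of range", call. = FALSE)
    P <- softmax_rows(lg)
    -w * mean(log(pmax(P[cbind(seq_len(nrow(lg)), y)], 1e-300)))
  }
  one(t_logits, t_true, weights[1]) + one(n_logits, n_true, weights[2]) +
    one(g_logits, g_true, weights[3])
}

# loss + gradient w.r.t. logits for training
ce_loss_grads <- function(logits, truth, weights) {
  loss <- 0
  dl <- list()
  for (i in 1:3) {
    task <- c("t", "n", "g")[i]
    lg <- logits[[task]]
    y <- truth[[task]]
    P <- softmax_rows(lg)
    B <- nrow(lg)
    loss <- loss - weights[i] * mean(log(pmax(P[cbind(seq_len(B), y)],
                                              1e-300)))
    G <- P
    G[cbind(seq_len(B), y)] <- G[cbind(seq_len(B), y)] - 1
    dl[[task]] <- weights[i] * G / B
  }
  list(loss = loss, dlogits = dl)
}
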