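# Minimal 1D convolutional network engine on BLAS matrix products.
#
# A feature map is a list(x, B, L): x is a (B*L) x C matrix whose rows are
# ordered sample-major (row (b-1)*L + l holds position l of sample b).
# Convolutions are im2col gathers followed by one dgemm; every operator has a
# matching exact backward pass (checked against finite differences in the
# test suite). All length-reducing operators use ceil-mode ("same"-style)
# padding, so an input of length L maps to ceiling(L / stride) positions.

.nn_cache <- new.env(parent = emptyenv())

# gather indices for a (kernel, stride) sliding window with ceil-mode padding
gather_index <- function(B, L, k, stride) {
  key <- paste(B, L, k, stride, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  L_out <- as.integer(ceiling(L / stride))
  pad_total <- max((L_out - 1L) * stride + k - L, 0L)
  pad_left <- pad_total %/% 2L
  zero_row <- B * L + 1L
  G <- matrix(0L, B * L_out, k)
  boff <- rep.int((0:(B - 1L)) * L, rep.int(L_out, B))
  for (t in seq_len(k)) {
    p <- (seq_len(L_out) - 1L) * stride + t - pad_left
    valid <- p >= 1L & p <= L
    col <- rep.int(p, B) + boff
    col[rep.int(!valid, B)] <- zero_row
    G[, t] <- col
  }
  res <- list(L_out = L_out, G = G, zero_row = zero_row)
  .nn_cache[[key]] <- res
  res
}

conv_fwd <- function(fm, W, stride = 1L) {
  Cin <- ncol(fm$x)
  k <- nrow(W) %/% Cin
  if (k == 1L && stride == 1L) {
    y <- fm$x %*% W
    return(list(out = list(x = y, B = fm$B, L = fm$L),
                cache = list(type = "conv1", x = fm$x, W = W)))
  }
  gi <- gather_index(fm$B, fm$L, k, stride)
  Xa <- rbind(fm$x, 0)
  Xcol <- matrix(0, nrow(gi$G), k * Cin)
  for (t in seq_len(k))
    Xcol[, ((t - 1L) * Cin + 1L):(t * Cin)] <- Xa[gi$G[, t], , drop = FALSE]
  y <- Xcol %*% W
  list(out = list(x = y, B = fm$B, L = gi$L_out),
       cache = list(type = "convk", Xcol = Xcol, gi = gi, W = W,
                    Cin = Cin, k = k, B = fm$B, L_in = fm$L))
}

conv_bwd <- function(dY, cache) {
  if (cache$type == "conv1") {
    return(list(dW = crossprod(cache$x, dY), dX = dY %*% t(cache$W)))
  }
  dW <- crossprod(cache$Xcol, dY)
  dXcol <- dY %*% t(cache$W)
  n_in <- cache$B * cache$L_in
  dXa <- matrix(0, n_in + 1L, cache$Cin)
  for (t in seq_len(cache$k)) {
    idx <- cache$gi$G[, t]
    cols <- ((t - 1L) * cache$Cin + 1L):(t * cache$Cin)
    # within one tap the non-padding indices are distinct, so `+` is safe;
    # padding rows collide only on the discarded sentinel row
    keep <- idx <= n_in
    dXa[idx[keep], ] <- dXa[idx[keep], , drop = FALSE] +
      dXcol[keep, cols, drop = FALSE]
  }
  list(dW = dW, dX = dXa[seq_len(n_in), , drop = FALSE])
}

maxpool_fwd <- function(fm, k = 3L, stride = 2L) {
  gi <- gather_index(fm$B, fm$L, k, stride)
  Xa <- rbind(fm$x, -Inf)
  M <- Xa[gi$G[, 1L], , drop = FALSE]
  arg <- matrix(1L, nrow(M), ncol(M))
  for (t in 2:k) {
    Xt <- Xa[gi$G[, t], , drop = FALSE]
    upd <- Xt > M
    M[upd] <- Xt[upd]
    arg[upd] <- t
  }
  list(out = list(x = M, B = fm$B, L = gi$L_out),
       cache = list(gi = gi, arg = arg, k = k, B = fm$B, L_in = fm$L,
                    C = ncol(fm$x)))
}

maxpool_bwd <- function(dY, cache) {
  n_in <- cache$B * cache$L_in
  dXa <- matrix(0, n_in + 1L, cache$C)
  for (t in seq_len(cache$k)) {
    idx <- cache$gi$G[, t]
    dpart <- dY * (cache$arg == t)
    keep <- idx <= n_in
    dXa[idx[keep], ] <- dXa[idx[keep], , drop = FALSE] +
      dpart[keep, , drop = FALSE]
  }
  dXa[seq_len(n_in), , drop = FALSE]
}

# fixed 2-wide stride-2 average pool (ceil mode, right padding); the
# stride-reducing pooling used inside projection shortcuts
avgpool2_fwd <- function(fm) {
  gi <- gather_index(fm$B, fm$L, 2L, 2L)
  Xa <- rbind(fm$x, 0)
  cnt <- (gi$G[, 1L] <= fm$B * fm$L) + (gi$G[, 2L] <= fm$B * fm$L)
  y <- (Xa[gi$G[, 1L], , drop = FALSE] + Xa[gi$G[, 2L], , drop = FALSE]) / cnt
  list(out = list(x = y, B = fm$B, L = gi$L_out),
       cache = list(gi = gi, cnt = cnt, B = fm$B, L_in = fm$L,
                    C = ncol(fm$x)))
}

avgpool2_bwd <- function(dY, cache) {
  n_in <- cache$B * cache$L_in
  dXa <- matrix(0, n_in + 1L, cache$C)
  dpart <- dY / cache$cnt
  for (t in 1:2) {
    idx <- cache$gi$G[, t]
    keep <- idx <= n_in
    dXa[idx[keep], ] <- dXa[idx[keep], , drop = FALSE] +
      dpart[keep, , drop = FALSE]
  }
  dXa[seq_len(n_in), , drop = FALSE]
}

bn_fwd <- function(x, gamma, beta, st, training, momentum = 0.1,
                   eps = 1e-5) {
  # momentum = 1 replaces the running statistics with this batch's
  # (used for post-training recalibration passes)
  if (training) {
    m <- colMeans(x)
    v <- pmax(colMeans(x * x) - m * m, 0)
    new_st <- list(m = (1 - momentum) * st$m + momentum * m,
                   v = (1 - momentum) * st$v + momentum * v)
  } else {
    m <- st$m; v <- st$v; new_st <- st
  }
  ivar <- 1 / sqrt(v + eps)
  xh <- sweep(sweep(x, 2L, m, "-"), 2L, ivar, "*")
  y <- sweep(sweep(xh, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, st = new_st,
       cache = list(xh = xh, ivar = ivar, gamma = gamma,
                    training = training))
}

bn_bwd <- function(dY, cache) {
  dgamma <- colSums(dY * cache$xh)
  dbeta <- colSums(dY)
  dxh <- sweep(dY, 2L, cache$gamma, "*")
  if (!cache$training) {
    return(list(dgamma = dgamma, dbeta = dbeta,
                dX = sweep(dxh, 2L, cache$ivar, "*")))
  }
  n <- nrow(dY)
  t1 <- colSums(dxh)
  t2 <- colSums(dxh * cache$xh)
  dX <- dxh * n
  dX <- sweep(dX, 2L, t1, "-")
  dX <- dX - sweep(cache$xh, 2L, t2, "*")
  dX <- sweep(dX, 2L, cache$ivar / n, "*")
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(dY, mask) dY * mask

gap_fwd <- function(fm) {
  f <- rowsum(fm$x, group = rep.int(seq_len(fm$B), rep.int(fm$L, fm$B)),
              reorder = FALSE) / fm$L
  list(f = f, cache = list(B = fm$B, L = fm$L))
}

gap_bwd <- function(dF, cache) {
  dF[rep.int(seq_len(cache$B), rep.int(cache$L, cache$B)), ,
     drop = FALSE] / cache$L
}

fc_fwd <- function(f, W, b) {
  list(y = sweep(f %*% W, 2L, b, "+"), cache = list(f = f, W = W))
}

fc_bwd <- function(dY, cache) {
  list(dW = crossprod(cache$f, dY), db = colSums(dY),
       dX = dY %*% t(cache$W))
}

softmax_rows <- function(z) {
  zm <- z - apply(z, 1L, max)
  e <- exp(zm)
  e / rowSums(e)
}

# He-normal initial weights
he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc) * sqrt(2 / nr),
                                   nr, nc)

# recursive SGD + momentum + (selective) weight decay over a parameter tree;
# decay applies to weight matrices (leaf names starting "W"), not to biases
# or batch-norm scale/shift
sgd_update <- function(par, grad, vel, lr, momentum, weight_decay) {
  step <- function(p, g, v, name) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      nms <- names(p)
      for (i in seq_along(p)) {
        named <- !is.null(nms) && nzchar(nms[i])
        gi <- if (named && !is.null(names(g)) && nms[i] %in% names(g))
                g[[nms[i]]]
              else if (!named && i <= length(g)) g[[i]]
              else NULL
        if (is.null(gi)) next
        r <- step(p[[i]], gi, v[[i]], if (named) nms[i] else name)
        out_p[[i]] <- r$p; out_v[[i]] <- r$v
      }
      return(list(p = out_p, v = out_v))
    }
    wd <- if (startsWith(name, "W")) weight_decay else 0
    v_new <- momentum * v - lr * (g + wd * p)
    list(p = p + v_new, v = v_new)
  }
  step(par, grad, vel, "root")
}

zero_like <- function(par) {
  if (is.list(par)) return(lapply(par, zero_like))
  par * 0
}
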