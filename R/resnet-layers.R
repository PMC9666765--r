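# Numerical primitives for the residual CNN: 2-D convolution, batch
# normalization, ReLU, 2x2 max pooling, global average pooling, the affine
# classifier head and softmax cross-entropy, each with an exact backward
# pass. Tensors are arrays in (channels, height, width, batch) layout; every
# convolution reduces to k*k BLAS matrix multiplies over shifted slices of
# the zero-padded input, so the whole network runs on optimized linear
# algebra with no compiled code in the package.

convForward <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); Cin <- d[1]; H <- d[2]; Wd <- d[3]; B <- d[4]
  k <- dim(W)[3]; Cout <- dim(W)[1]
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Hout <- (Hp - k) %/% stride + 1L; Wout <- (Wp - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(0, c(Cin, Hp, Wp, B))
    xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- x
  } else xp <- x
  M <- Hout * Wout * B
  ymat <- matrix(b, Cout, M)
  for (dy in seq_len(k)) {
    rows <- seq.int(dy, by = stride, length.out = Hout)
    for (dx in seq_len(k)) {
      cols <- seq.int(dx, by = stride, length.out = Wout)
      Xs <- xp[, rows, cols, , drop = FALSE]
      dim(Xs) <- c(Cin, M)
      ymat <- ymat + matrix(W[, , dy, dx], Cout, Cin) %*% Xs
    }
  }
  out <- ymat; dim(out) <- c(Cout, Hout, Wout, B)
  list(out = out,
       cache = list(xp = xp, k = k, stride = stride, pad = pad,
                    H = H, Wd = Wd, Hout = Hout, Wout = Wout))
}

convBackward <- function(dout, W, cache) {
  cc <- cache
  d <- dim(cc$xp); Cin <- d[1]; B <- d[4]
  Cout <- dim(W)[1]; k <- cc$k
  M <- cc$Hout * cc$Wout * B
  dmat <- dout; dim(dmat) <- c(Cout, M)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cc$xp))
  for (dy in seq_len(k)) {
    rows <- seq.int(dy, by = cc$stride, length.out = cc$Hout)
    for (dx in seq_len(k)) {
      cols <- seq.int(dx, by = cc$stride, length.out = cc$Wout)
      Xs <- cc$xp[, rows, cols, , drop = FALSE]
      dim(Xs) <- c(Cin, M)
      dW[, , dy, dx] <- dmat %*% t(Xs)
      contrib <- t(matrix(W[, , dy, dx], Cout, Cin)) %*% dmat
      dim(contrib) <- c(Cin, cc$Hout, cc$Wout, B)
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + contrib
    }
  }
  dx <- if (cc$pad > 0L)
    dxp[, cc$pad + seq_len(cc$H), cc$pad + seq_len(cc$Wd), , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = rowSums(dmat))
}

bnForward <- function(x, gamma, beta, rs, training, momentum = 0.1,
                      eps = 1e-5) {
  C <- dim(x)[1]
  xm <- x; dim(xm) <- c(C, length(x) %/% C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    rs$mean <- (1 - momentum) * rs$mean + momentum * mu
    rs$var <- (1 - momentum) * rs$var + momentum * v
  } else {
    mu <- rs$mean; v <- rs$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * ivar
  out <- gamma * xhat + beta
  dim(out) <- dim(x)
  list(out = out, rs = rs,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma,
                    M = ncol(xm), shape = dim(x)))
}

bnBackward <- function(dout, cache) {
  cc <- cache
  C <- length(cc$gamma)
  dmat <- dout; dim(dmat) <- c(C, cc$M)
  dgamma <- rowSums(dmat * cc$xhat)
  dbeta <- rowSums(dmat)
  dx <- (cc$gamma * cc$ivar / cc$M) *
    (cc$M * dmat - dbeta - cc$xhat * dgamma)
  dim(dx) <- cc$shape
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

reluBackward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

# 2x2 max pooling, stride 2; ties claimed in fixed slice order so the
# backward routing is deterministic.
maxPoolForward <- function(x) {
  d <- dim(x); H <- d[2]; W <- d[3]
  ro <- seq.int(1L, H, 2L); re <- seq.int(2L, H, 2L)
  co <- seq.int(1L, W, 2L); ce <- seq.int(2L, W, 2L)
  s <- list(x[, ro, co, , drop = FALSE], x[, re, co, , drop = FALSE],
            x[, ro, ce, , drop = FALSE], x[, re, ce, , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  claimed <- array(FALSE, dim(m))
  masks <- vector("list", 4)
  for (i in 1:4) {
    masks[[i]] <- (s[[i]] == m) & !claimed
    claimed <- claimed | masks[[i]]
  }
  list(out = m, cache = list(masks = masks, inDim = d))
}

maxPoolBackward <- function(dout, cache) {
  d <- cache$inDim
  dx <- array(0, d)
  H <- d[2]; W <- d[3]
  ro <- seq.int(1L, H, 2L); re <- seq.int(2L, H, 2L)
  co <- seq.int(1L, W, 2L); ce <- seq.int(2L, W, 2L)
  idx <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (i in 1:4) {
    g <- dout
    g[!cache$masks[[i]]] <- 0
    dx[, idx[[i]][[1]], idx[[i]][[2]], ] <- g
  }
  dx
}

globalAvgPoolForward <- function(x) {
  d <- dim(x)
  out <- colMeans(aperm(x, c(2, 3, 1, 4)), dims = 2)  # (C, B)
  list(out = out, inDim = d)
}

globalAvgPoolBackward <- function(dout, inDim) {
  C <- inDim[1]; H <- inDim[2]; W <- inDim[3]; B <- inDim[4]
  aperm(array(dout / (H * W), c(C, B, H, W)), c(1, 3, 4, 2))
}

fcForward <- function(x, W, b) list(out = W %*% x + b, x = x)

fcBackward <- function(dout, W, cache) {
  list(dx = t(W) %*% dout, dW = dout %*% t(cache$x), db = rowSums(dout))
}

softmaxProbs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy over the batch and its gradient w.r.t. the logits.
softmaxCrossEntropy <- function(logits, y) {
  B <- ncol(logits)
  p <- softmaxProbs(logits)
  picked <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B)
}
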