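# Low-level neural-network layers: 2-D convolution (sparse im2col gather +
# BLAS gemm), batch normalization, ReLU, max pooling, row-collapsing average
# pooling, LSTM, dropout, and the softmax/cross-entropy head.  Activations
# travel as a list `a = list(x, H, W, C, N)` where `x` is a `C x (H*W*N)`
# matrix, spatial index column-major (row fastest) and batch outermost.

.nn_cache <- new.env(parent = emptyenv())

.act <- function(x, H, W, C, N) list(x = x, H = H, W = W, C = C, N = N)

# (C x S*N) -> (S*C x N)
.x_to_sc <- function(a) {
  arr <- a$x
  dim(arr) <- c(a$C, a$H * a$W, a$N)
  arr <- aperm(arr, c(2, 1, 3))
  dim(arr) <- c(a$H * a$W * a$C, a$N)
  arr
}

# (S*C x N) -> (C x S*N)
.sc_to_x <- function(m, H, W, C, N) {
  dim(m) <- c(H * W, C, N)
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(C, H * W * N)
  m
}

.conv_out_dim <- function(d, k, stride, pad) (d + 2L * pad - k) %/% stride + 1L

# Sparse gather matrix turning an (S*C) image vector into im2col rows
# ordered (patch-entry, channel) fastest then output position.
.conv_gather <- function(H, W, C, k, stride, pad) {
  key <- paste("g", H, W, C, k, stride, pad, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- .conv_out_dim(H, k, stride, pad)
  Wo <- .conv_out_dim(W, k, stride, pad)
  So <- Ho * Wo
  k2 <- k * k
  p_v <- rep.int(seq_len(k2), C * So)
  c_v <- rep.int(rep(seq_len(C), each = k2), So)
  so_v <- rep(seq_len(So), each = k2 * C)
  dy <- (p_v - 1L) %% k + 1L
  dx <- (p_v - 1L) %/% k + 1L
  ho <- (so_v - 1L) %% Ho + 1L
  wo <- (so_v - 1L) %/% Ho + 1L
  hi <- (ho - 1L) * stride - pad + dy
  wi <- (wo - 1L) * stride - pad + dx
  valid <- hi >= 1L & hi <= H & wi >= 1L & wi <= W
  j <- hi + H * (wi - 1L) + H * W * (c_v - 1L)
  G <- Matrix::sparseMatrix(i = which(valid), j = j[valid], x = 1,
                            dims = c(k2 * C * So, H * W * C))
  out <- list(G = G, Ho = Ho, Wo = Wo, k2 = k2)
  .nn_cache[[key]] <- out
  out
}

conv_fwd <- function(W_mat, a, k, stride, pad) {
  g <- .conv_gather(a$H, a$W, a$C, k, stride, pad)
  Xs <- .x_to_sc(a)
  Xcol <- as.matrix(g$G %*% Xs)
  dim(Xcol) <- c(g$k2 * a$C, g$Ho * g$Wo * a$N)
  Y <- W_mat %*% Xcol
  list(a = .act(Y, g$Ho, g$Wo, nrow(W_mat), a$N),
       cache = list(Xcol = Xcol, in_dims = c(a$H, a$W, a$C, a$N),
                    k = k, stride = stride, pad = pad))
}

conv_bwd <- function(W_mat, cache, dY) {
  d <- cache$in_dims
  g <- .conv_gather(d[1], d[2], d[3], cache$k, cache$stride, cache$pad)
  dW <- tcrossprod(dY, cache$Xcol)
  dXcol <- crossprod(W_mat, dY)
  dim(dXcol) <- c(g$k2 * d[3] * g$Ho * g$Wo, d[4])
  dXs <- as.matrix(Matrix::crossprod(g$G, dXcol))
  list(dW = dW, da = .act(.sc_to_x(dXs, d[1], d[2], d[3], d[4]),
                          d[1], d[2], d[3], d[4]))
}

bn_fwd <- function(gamma, beta, stats, a, training, momentum = 0.1, eps = 1e-5) {
  x <- a$x
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    istd <- 1 / sqrt(stats$var + eps)
    xhat <- (x - stats$mean) * istd
  }
  out <- a
  out$x <- gamma * xhat + beta
  list(a = out, cache = list(xhat = xhat, istd = istd), stats = stats)
}

bn_bwd <- function(gamma, cache, dY) {
  m <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dx <- (cache$istd / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dgamma = dgamma, dbeta = dbeta, dx = dx)
}

relu_fwd <- function(a) {
  mask <- a$x > 0
  out <- a
  out$x <- a$x * mask
  list(a = out, cache = mask)
}

relu_bwd <- function(cache, dY) dY * cache

# Pool source-index map (k2 x So) over one channel plane; NA marks padding.
.pool_map <- function(H, W, k, stride, pad) {
  key <- paste("p", H, W, k, stride, pad, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- .conv_out_dim(H, k, stride, pad)
  Wo <- .conv_out_dim(W, k, stride, pad)
  So <- Ho * Wo
  k2 <- k * k
  p_v <- rep.int(seq_len(k2), So)
  so_v <- rep(seq_len(So), each = k2)
  dy <- (p_v - 1L) %% k + 1L
  dx <- (p_v - 1L) %/% k + 1L
  ho <- (so_v - 1L) %% Ho + 1L
  wo <- (so_v - 1L) %/% Ho + 1L
  hi <- (ho - 1L) * stride - pad + dy
  wi <- (wo - 1L) * stride - pad + dx
  src <- ifelse(hi >= 1L & hi <= H & wi >= 1L & wi <= W, hi + H * (wi - 1L), NA_integer_)
  out <- list(P = matrix(src, k2, So), Ho = Ho, Wo = Wo, k2 = k2)
  .nn_cache[[key]] <- out
  out
}

maxpool_fwd <- function(a, k = 3L, stride = 2L, pad = 1L) {
  pm <- .pool_map(a$H, a$W, k, stride, pad)
  S <- a$H * a$W
  So <- pm$Ho * pm$Wo
  N <- a$N
  dummy <- S * N + 1L
  xa <- cbind(a$x, rep(-Inf, a$C))
  off <- rep((seq_len(N) - 1L) * S, each = So)
  cols <- vector("list", pm$k2)
  best <- NULL; cur <- NULL
  for (p in seq_len(pm$k2)) {
    src <- rep.int(pm$P[p, ], N) + off
    src[is.na(src)] <- dummy
    cols[[p]] <- src
    v <- xa[, src, drop = FALSE]
    if (p == 1L) {
      cur <- v
      best <- matrix(1L, a$C, So * N)
    } else {
      upd <- v > cur
      cur[upd] <- v[upd]
      best[upd] <- p
    }
  }
  list(a = .act(cur, pm$Ho, pm$Wo, a$C, N),
       cache = list(best = best, cols = cols, S = S, C = a$C, N = N,
                    H = a$H, W = a$W, k2 = pm$k2))
}

maxpool_bwd <- function(cache, dY) {
  dx <- matrix(0, cache$C, cache$S * cache$N + 1L)
  for (p in seq_len(cache$k2)) {
    m <- dY * (cache$best == p)
    cl <- cache$cols[[p]]
    dx[, cl] <- dx[, cl] + m
  }
  .act(dx[, -(cache$S * cache$N + 1L), drop = FALSE],
       cache$H, cache$W, cache$C, cache$N)
}

# Average pooling that collapses the row (frequency) axis, keeping a
# per-column feature sequence for the temporal head.
avgpool_rows_fwd <- function(a) {
  M2 <- a$x
  dim(M2) <- c(a$C * a$H, a$W * a$N)
  y <- matrix(0, a$C, a$W * a$N)
  for (h in seq_len(a$H)) {
    y <- y + M2[(h - 1L) * a$C + seq_len(a$C), , drop = FALSE]
  }
  y <- y / a$H
  list(a = .act(y, 1L, a$W, a$C, a$N), cache = list(H = a$H, W = a$W, C = a$C, N = a$N))
}

avgpool_rows_bwd <- function(cache, dY) {
  dM2 <- matrix(0, cache$C * cache$H, cache$W * cache$N)
  g <- dY / cache$H
  for (h in seq_len(cache$H)) {
    dM2[(h - 1L) * cache$C + seq_len(cache$C), ] <- g
  }
  dim(dM2) <- c(cache$C, cache$H * cache$W * cache$N)
  .act(dM2, cache$H, cache$W, cache$C, cache$N)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM over the column axis of a row-collapsed feature map.
# x: C x (T*N); returns final hidden state (H x N).
lstm_fwd <- function(Wx, Wh, b, a) {
  H <- ncol(Wh)
  Tn <- a$W
  N <- a$N
  h <- matrix(0, H, N)
  cst <- matrix(0, H, N)
  steps <- vector("list", Tn)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(Tn)) {
    cols <- t + Tn * (seq_len(N) - 1L)
    xt <- a$x[, cols, drop = FALSE]
    z <- Wx %*% xt + Wh %*% h + b
    ig <- .sigmoid(z[i1, , drop = FALSE])
    fg <- .sigmoid(z[i2, , drop = FALSE])
    gg <- tanh(z[i3, , drop = FALSE])
    og <- .sigmoid(z[i4, , drop = FALSE])
    c_new <- fg * cst + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    steps[[t]] <- list(xt = xt, hprev = h, cprev = cst, i = ig, f = fg,
                       g = gg, o = og, tc = tc)
    h <- h_new
    cst <- c_new
  }
  list(h = h, cache = list(steps = steps, Tn = Tn, N = N, C = a$C,
                           in_a = a[c("H", "W", "C", "N")]))
}

lstm_bwd <- function(Wx, Wh, cache, dh_final) {
  Tn <- cache$Tn; N <- cache$N
  H <- ncol(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H)
  dX <- matrix(0, cache$C, Tn * N)
  dh <- dh_final
  dc <- matrix(0, H, N)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc * s$o * (1 - s$o)
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    df <- dc * s$cprev * s$f * (1 - s$f)
    dg <- dc * s$i * (1 - s$g^2)
    dz <- rbind(di, df, dg, do_)
    dWx <- dWx + tcrossprod(dz, s$xt)
    dWh <- dWh + tcrossprod(dz, s$hprev)
    db <- db + rowSums(dz)
    cols <- t + Tn * (seq_len(N) - 1L)
    dX[, cols] <- crossprod(Wx, dz)
    dh <- crossprod(Wh, dz)
    dc <- dc * s$f
  }
  ia <- cache$in_a
  list(dWx = dWx, dWh = dWh, db = db,
       da = .act(dX, ia$H, ia$W, ia$C, ia$N))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(x = x, cache = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(x = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dY) if (is.null(cache)) dY else dY * cache

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Cross-entropy loss and gradient wrt logits; y is 0-based class vector.
cross_entropy <- function(probs, y) {
  N <- ncol(probs)
  idx <- cbind(y + 1L, seq_len(N))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N)
}
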