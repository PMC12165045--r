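# Minimal dense/conv/attention layer kit with explicit forward caches and
# hand-derived backward passes, plus an Adam optimizer. Everything runs on
# base-R matrix products (BLAS); arrays are H x W x C, matrices are
# row-per-position. No external deep-learning runtime is used.

he_init <- function(fan_in, dims, rng_scale = 1) {
  array(stats::rnorm(prod(dims), 0, rng_scale * sqrt(2 / fan_in)), dim = dims)
}

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- dense -----------------------------------------------------------

linear_init <- function(d_in, d_out, bias = TRUE) {
  l <- list(W = he_init(d_in, c(d_in, d_out)))
  if (bias) l$b <- numeric(d_out)
  l
}

linear_fwd <- function(layer, X) {
  Y <- X %*% layer$W
  if (!is.null(layer$b)) Y <- Y + rep(layer$b, each = nrow(Y))
  Y
}

linear_bwd <- function(layer, X, gY) {
  g <- list(W = crossprod(X, gY))
  if (!is.null(layer$b)) g$b <- colSums(gY)
  list(grads = g, gX = tcrossprod(gY, layer$W))
}

## ---- 2-D convolution (im2col) ---------------------------------------

conv_init <- function(c_in, c_out, k = 3, stride = 1, pad = (k - 1) %/% 2) {
  list(W = he_init(k * k * c_in, c(c_in * k * k, c_out)),
       b = numeric(c_out), k = k, stride = stride, pad = pad,
       c_in = c_in, c_out = c_out)
}

pad_array <- function(X, p) {
  if (p == 0) return(X)
  d <- dim(X)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- X
  out
}

im2col <- function(X, k, stride, pad) {
  Xp <- pad_array(X, pad)
  d <- dim(Xp); C <- d[3]
  ho <- (d[1] - k) %/% stride + 1
  wo <- (d[2] - k) %/% stride + 1
  cols <- matrix(0, ho * wo, C * k * k)
  rows_idx <- seq.int(1, by = stride, length.out = ho)
  cols_idx <- seq.int(1, by = stride, length.out = wo)
  blk <- 1L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      sl <- Xp[rows_idx + di, cols_idx + dj, , drop = FALSE]
      cols[, seq.int((blk - 1) * C + 1, blk * C)] <- matrix(sl, ho * wo, C)
      blk <- blk + 1L
    }
  }
  list(cols = cols, ho = ho, wo = wo)
}

col2im <- function(gcols, in_dim, k, stride, pad, ho, wo) {
  C <- in_dim[3]
  gXp <- array(0, dim = c(in_dim[1] + 2 * pad, in_dim[2] + 2 * pad, C))
  rows_idx <- seq.int(1, by = stride, length.out = ho)
  cols_idx <- seq.int(1, by = stride, length.out = wo)
  blk <- 1L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      g <- array(gcols[, seq.int((blk - 1) * C + 1, blk * C)],
                 dim = c(ho, wo, C))
      gXp[rows_idx + di, cols_idx + dj, ] <-
        gXp[rows_idx + di, cols_idx + dj, , drop = FALSE] + g
      blk <- blk + 1L
    }
  }
  if (pad == 0) gXp
  else gXp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), , drop = FALSE]
}

conv_fwd <- function(layer, X) {
  ic <- im2col(X, layer$k, layer$stride, layer$pad)
  Y <- ic$cols %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(Y = array(Y, dim = c(ic$ho, ic$wo, layer$c_out)),
       cache = list(cols = ic$cols, in_dim = dim(X), ho = ic$ho, wo = ic$wo))
}

conv_bwd <- function(layer, cache, gY) {
  gYm <- matrix(gY, cache$ho * cache$wo, layer$c_out)
  gW <- crossprod(cache$cols, gYm)
  gb <- colSums(gYm)
  gcols <- tcrossprod(gYm, layer$W)
  gX <- col2im(gcols, cache$in_dim, layer$k, layer$stride, layer$pad,
               cache$ho, cache$wo)
  list(grads = list(W = gW, b = gb), gX = gX)
}

upsample2_fwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample2_bwd <- function(gY) {
  d <- dim(gY)
  h <- d[1] %/% 2; w <- d[2] %/% 2
  out <- array(0, dim = c(h, w, d[3]))
  for (di in 1:2) for (dj in 1:2)
    out <- out + gY[seq.int(di, by = 2, length.out = h),
                    seq.int(dj, by = 2, length.out = w), , drop = FALSE]
  out
}

## ---- multi-head self-attention block --------------------------------

# MHSA(P) = P + (ReLU(P + Attention(P)) Wz1) Wz2, scaled dot-product
# attention with H heads carved out of d columns; no bias terms inside the
# block (the printed formulation uses bare parameter matrices).

mhsa_init <- function(d, heads, ffn_mult = 4) {
  stopifnot(d %% heads == 0)
  list(WQ = he_init(d, c(d, d)), WK = he_init(d, c(d, d)),
       WV = he_init(d, c(d, d)), WO = he_init(d, c(d, d)),
       Wz1 = he_init(d, c(d, ffn_mult * d)),
       Wz2 = he_init(ffn_mult * d, c(ffn_mult * d, d)),
       d = d, heads = heads)
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

mhsa_fwd <- function(layer, P, keep_attention = FALSE) {
  d <- layer$d; H <- layer$heads; dk <- d / H
  Q <- P %*% layer$WQ; K <- P %*% layer$WK; V <- P %*% layer$WV
  n <- nrow(P)
  heads_out <- matrix(0, n, d)
  A_list <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- seq.int((h - 1) * dk + 1, h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    heads_out[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  Att <- heads_out %*% layer$WO
  U <- P + Att
  R <- relu(U)
  Hff <- R %*% layer$Wz1
  out <- P + Hff %*% layer$Wz2
  cache <- list(P = P, Q = Q, K = K, V = V, A = A_list,
                heads_out = heads_out, U = U, R = R, Hff = Hff)
  if (keep_attention) cache$attention <- A_list
  list(out = out, cache = cache)
}

mhsa_bwd <- function(layer, cache, gOut) {
  d <- layer$d; H <- layer$heads; dk <- d / H
  P <- cache$P
  gP <- gOut                                  # outer residual
  gWz2 <- crossprod(cache$Hff, gOut)
  gHff <- tcrossprod(gOut, layer$Wz2)
  gWz1 <- crossprod(cache$R, gHff)
  gR <- tcrossprod(gHff, layer$Wz1)
  gU <- gR * (cache$U > 0)
  gP <- gP + gU                               # inner residual
  gAtt <- gU
  gWO <- crossprod(cache$heads_out, gAtt)
  gHeads <- tcrossprod(gAtt, layer$WO)
  gQ <- gK <- gV <- matrix(0, nrow(P), d)
  for (h in seq_len(H)) {
    idx <- seq.int((h - 1) * dk + 1, h * dk)
    A <- cache$A[[h]]
    gHead <- gHeads[, idx, drop = FALSE]
    gA <- tcrossprod(gHead, cache$V[, idx, drop = FALSE])
    gV[, idx] <- crossprod(A, gHead)
    gS <- A * (gA - rowSums(A * gA))
    gS <- gS / sqrt(dk)
    gQ[, idx] <- gS %*% cache$K[, idx, drop = FALSE]
    gK[, idx] <- crossprod(gS, cache$Q[, idx, drop = FALSE])
  }
  grads <- list(WQ = crossprod(P, gQ), WK = crossprod(P, gK),
                WV = crossprod(P, gV), WO = gWO, Wz1 = gWz1, Wz2 = gWz2)
  gP <- gP + tcrossprod(gQ, layer$WQ) + tcrossprod(gK, layer$WK) +
    tcrossprod(gV, layer$WV)
  list(grads = grads, gP = gP)
}

#' Multi-head self-attention block on a point-feature sequence
#'
#' Computes MHSA(P) = P + (ReLU(P + Attention(P)) Wz1) Wz2 where
#' Attention(P) concatenates H scaled-dot-product heads and projects them
#' with WO. The block is permutation-equivariant in the rows of P.
#'
#' @param P N x d input sequence.
#' @param layer parameters from the internal initializer (or a fitted
#'   model's block).
#' @return N x d output matrix.
#' @export
mhsa_block <- function(P, layer) {
  if (ncol(P) != layer$d) stop("dimension mismatch: ncol(P) != d")
  mhsa_fwd(layer, P)$out
}

## ---- bilinear feature sampling --------------------------------------

# Sample C-channel features at continuous (x, y) feature-map positions
# (0-based pixel centers) with border clamping. Gradients flow to the
# feature map only; sampling positions are treated as fixed.

bilinear_sample <- function(Fmap, pts) {
  d <- dim(Fmap); Hf <- d[1]; Wf <- d[2]; C <- d[3]
  x <- pmin(pmax(pts[, 1], 0), Wf - 1)
  y <- pmin(pmax(pts[, 2], 0), Hf - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, Wf - 1); y1 <- pmin(y0 + 1, Hf - 1)
  wx <- x - x0; wy <- y - y0
  Fm <- matrix(Fmap, Hf * Wf, C)
  at <- function(yy, xx) Fm[yy + 1 + Hf * xx, , drop = FALSE]
  out <- at(y0, x0) * ((1 - wx) * (1 - wy)) + at(y0, x1) * (wx * (1 - wy)) +
    at(y1, x0) * ((1 - wx) * wy) + at(y1, x1) * (wx * wy)
  list(features = out,
       cache = list(y0 = y0, x0 = x0, y1 = y1, x1 = x1, wx = wx, wy = wy,
                    dim = d))
}

bilinear_sample_bwd <- function(cache, gF) {
  d <- cache$dim; Hf <- d[1]; C <- d[3]
  gFm <- matrix(0, Hf * d[2], C)
  acc <- function(yy, xx, w) {
    idx <- yy + 1 + Hf * xx
    for (i in seq_along(idx))
      gFm[idx[i], ] <<- gFm[idx[i], ] + gF[i, ] * w[i]
  }
  with(cache, {
    acc(y0, x0, (1 - wx) * (1 - wy))
    acc(y0, x1, wx * (1 - wy))
    acc(y1, x0, (1 - wx) * wy)
    acc(y1, x1, wx * wy)
  })
  array(gFm, dim = d)
}

## ---- Adam ------------------------------------------------------------

adam_state <- function(params) {
  flat <- rapply(params, function(x) x * 0, classes = "ANY", how = "replace")
  list(m = flat, v = flat, t = 0L)
}

# params/grads are nested lists of numeric arrays with identical shape
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      nms <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        gi <- if (is.numeric(key)) {
          if (length(g) >= key) g[[key]] else NULL
        } else g[[key]]
        if (is.null(gi)) next
        r <- upd(p[[key]], gi, m[[key]], v[[key]])
        out_p[[key]] <- r$p; out_m[[key]] <- r$m; out_v[[key]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (!is.numeric(p)) return(list(p = p, m = m, v = v))
    gg <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * gg
    v <- beta2 * v + (1 - beta2) * gg^2
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two grad lists with the same shape
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    nms <- names(b)
    for (i in seq_along(b)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      a[[key]] <- grads_add(a[[key]], b[[key]])
    }
    return(a)
  }
  a + b
}

grads_scale <- function(a, s) {
  rapply(a, function(x) x * s, classes = "numeric", how = "replace")
}
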