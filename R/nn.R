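# Minimal neural-network engine: 3x3 same-padding convolutions via a
# precomputed im2col index gather (BLAS matmul does the heavy lifting),
# 2x2 average pooling, ReLU, global average pooling, dense layers, a
# batch-normalized 2-layer perceptron, softmax cross-entropy, and
# SGD-with-momentum / Adam optimizers. Tensors are arrays (H, W, C, N);
# feature matrices are (D, N). Everything is seeded through the R RNG.

.conv_cache <- new.env(parent = emptyenv())

# im2col index matrix for a 3x3 kernel, pad 1, stride 1:
# rows = kernel offset within channel (9*C), cols = output pixel within image (H*W*N)
im2col_index <- function(H, W, C, N) {
  key <- paste(H, W, C, N, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  # base: offset o (1..9, row-major over (di,dj) in 0:2 x 0:2) x output pixel p
  di <- rep(0:2, times = 3); dj <- rep(0:2, each = 3)
  pr <- rep(seq_len(H), times = W); pc <- rep(seq_len(W), each = H)
  base <- outer(seq_len(9), seq_len(H * W),
                function(o, p) (pc[p] + dj[o] - 1L) * Hp + pr[p] + di[o])
  storage.mode(base) <- "integer"
  # replicate across channels and images with plane offsets
  b1 <- aperm(array(base, c(9L, H * W, C)), c(1, 3, 2))          # (9, C, HW)
  b1 <- b1 + rep(as.integer((seq_len(C) - 1L) * Hp * Wp), each = 9L)
  idx <- array(b1, c(9L, C, H * W, N))
  idx <- idx + rep(as.integer((seq_len(N) - 1L) * Hp * Wp * C),
                   each = 9L * C * H * W)
  dim(idx) <- c(9L * C, H * W * N)
  .conv_cache[[key]] <- idx
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

conv_forward <- function(x, W, b) {
  d <- dim(x)  # H, W, C, N
  idx <- im2col_index(d[1], d[2], d[3], d[4])
  xp <- pad1(x)
  cols <- matrix(xp[idx], nrow = nrow(idx))
  ym <- W %*% cols + b                       # (F, HW*N); b recycles down rows
  FF <- nrow(W)
  y <- aperm(array(ym, c(FF, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(y = y, cols = cols, dims = d)
}

# rearrange a conv weight (F, 9C) into its transpose-convolution form (C, 9F)
# with the 3x3 kernels rotated 180 degrees
rot_weight <- function(W, C) {
  FF <- nrow(W)
  Wt <- matrix(0, C, 9L * FF)
  o <- rep(1:9, C); cc <- rep(1:C, each = 9)
  for (f in seq_len(FF))
    Wt[cbind(cc, (f - 1L) * 9L + (10L - o))] <- W[f, ]
  Wt
}

conv_backward <- function(dy, W, cache) {
  d <- cache$dims                                              # input dims H,W,C,N
  FF <- dim(dy)[3]
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = FF)           # (F, HW*N)
  dW <- dym %*% t(cache$cols)
  db <- rowSums(dym)
  # dx = full convolution of dy with the 180-degree-rotated kernels
  idx <- im2col_index(d[1], d[2], FF, d[4])
  cols_dy <- matrix(pad1(dy)[idx], nrow = nrow(idx))
  dxm <- rot_weight(W, d[3]) %*% cols_dy                       # (C, HW*N)
  dx <- aperm(array(dxm, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(dx = dx, dW = dW, db = db)
}

avgpool_forward <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], 2L); q <- seq(1L, d[2], 2L)
  y <- (x[o, q, , , drop = FALSE] + x[o + 1L, q, , , drop = FALSE] +
        x[o, q + 1L, , , drop = FALSE] + x[o + 1L, q + 1L, , , drop = FALSE]) / 4
  y
}

avgpool_backward <- function(dy, in_dims) {
  dx <- array(0, in_dims)
  o <- seq(1L, in_dims[1], 2L); q <- seq(1L, in_dims[2], 2L)
  g <- dy / 4
  dx[o, q, , ] <- g; dx[o + 1L, q, , ] <- g
  dx[o, q + 1L, , ] <- g; dx[o + 1L, q + 1L, , ] <- g
  dx
}

relu <- function(x) x * (x > 0)

gap_forward <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  e <- colMeans(m); dim(e) <- c(d[3], d[4])
  e
}

gap_backward <- function(de, in_dims) {
  hw <- in_dims[1] * in_dims[2]
  dx <- rep(as.vector(de) / hw, each = hw)
  dim(dx) <- in_dims
  dx
}

he_init <- function(nrow, ncol) matrix(rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)

# --- small CNN: 4 blocks of (conv3x3 -> relu -> avgpool2), GAP, dense head ---

cnn_init <- function(c_in, widths = c(8L, 16L, 32L, 32L), n_out = NULL) {
  p <- list()
  cin <- c_in
  for (i in seq_along(widths)) {
    p[[paste0("conv", i, "_W")]] <- he_init(widths[i], 9L * cin)
    p[[paste0("conv", i, "_b")]] <- numeric(widths[i])
    cin <- widths[i]
  }
  if (!is.null(n_out)) {
    p$head_W <- he_init(n_out, cin) / sqrt(2)  # Glorot-ish for the linear head
    p$head_b <- numeric(n_out)
  }
  p
}

cnn_forward <- function(p, x, widths, with_head = TRUE) {
  caches <- list()
  h <- x
  for (i in seq_along(widths)) {
    cf <- conv_forward(h, p[[paste0("conv", i, "_W")]], p[[paste0("conv", i, "_b")]])
    a <- relu(cf$y)
    caches[[i]] <- list(conv = cf, act = a, in_dims = dim(cf$y))
    h <- avgpool_forward(a)
  }
  emb <- gap_forward(h)           # (C_last, N)
  out <- list(emb = emb, caches = caches, pre_gap_dims = dim(h))
  if (with_head && !is.null(p$head_W)) out$logits <- p$head_W %*% emb + p$head_b
  out
}

# dlogits: (K, N) or demb: (C_last, N)
cnn_backward <- function(p, fwd, widths, dlogits = NULL, demb = NULL) {
  g <- list()
  if (!is.null(dlogits)) {
    g$head_W <- dlogits %*% t(fwd$emb)
    g$head_b <- rowSums(dlogits)
    demb <- crossprod(p$head_W, dlogits)
  }
  dh <- gap_backward(demb, fwd$pre_gap_dims)
  for (i in rev(seq_along(widths))) {
    ch <- fwd$caches[[i]]
    da <- avgpool_backward(dh, ch$in_dims)
    dz <- da * (ch$act > 0)
    cb <- conv_backward(dz, p[[paste0("conv", i, "_W")]], ch$conv)
    g[[paste0("conv", i, "_W")]] <- cb$dW
    g[[paste0("conv", i, "_b")]] <- cb$db
    dh <- cb$dx
  }
  g
}

softmax_xent <- function(logits, y_idx) {
  K <- nrow(logits); N <- ncol(logits)
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  pr <- sweep(e, 2, colSums(e), "/")
  loss <- -mean(log(pmax(pr[cbind(y_idx, seq_len(N))], 1e-12)))
  dlogits <- pr
  dlogits[cbind(y_idx, seq_len(N))] <- dlogits[cbind(y_idx, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N, prob = pr)
}

# --- 2-layer MLP with batch-normalized hidden layer (BYOL heads) -------------

mlp_init <- function(d_in, d_hidden, d_out) {
  list(W1 = he_init(d_hidden, d_in), b1 = numeric(d_hidden),
       gamma = rep(1, d_hidden), beta = numeric(d_hidden),
       W2 = he_init(d_out, d_hidden), b2 = numeric(d_out))
}

mlp_forward <- function(p, x, eps = 1e-5) {
  h <- p$W1 %*% x + p$b1
  mu <- rowMeans(h)
  hc <- h - mu
  v <- rowMeans(hc^2)
  istd <- 1 / sqrt(v + eps)
  hn <- hc * istd
  hb <- p$gamma * hn + p$beta
  a <- relu(hb)
  y <- p$W2 %*% a + p$b2
  list(y = y, x = x, h = h, hn = hn, istd = istd, hb = hb, a = a)
}

mlp_backward <- function(p, f, dy) {
  g <- list()
  g$W2 <- dy %*% t(f$a); g$b2 <- rowSums(dy)
  da <- crossprod(p$W2, dy)
  dhb <- da * (f$hb > 0)
  g$gamma <- rowSums(dhb * f$hn); g$beta <- rowSums(dhb)
  dhn <- dhb * p$gamma
  N <- ncol(f$x)
  # batchnorm backward (per hidden unit, over the batch)
  dh <- f$istd * (dhn - rowMeans(dhn) - f$hn * rowMeans(dhn * f$hn))
  g$W1 <- dh %*% t(f$x); g$b1 <- rowSums(dh)
  list(grads = g, dx = crossprod(p$W1, dh))
}

# --- optimizers (flat named lists of numeric arrays) --------------------------

sgd_momentum_step <- function(params, grads, state, lr, momentum = 0.9) {
  if (is.null(state)) state <- lapply(params, function(p) p * 0)
  for (nm in names(grads)) {
    state[[nm]] <- momentum * state[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + state[[nm]]
  }
  list(params = params, state = state)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state))
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0)
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# random horizontal/vertical flips, per image, in place on a (H,W,C,N) batch
flip_batch <- function(x, hflip, vflip) {
  d <- dim(x)
  if (any(hflip)) x[, , , hflip] <- x[, d[2]:1, , hflip, drop = FALSE]
  if (any(vflip)) x[, , , vflip] <- x[d[1]:1, , , vflip, drop = FALSE]
  x
}

#' Resize a stack of nucleus images
#'
#' Bilinear resize of an `(H, W, C, N)` image stack to a square side, keeping
#' channel names.
#'
#' @param images array `H x W x C x N`.
#' @param side target side length in pixels.
#' @return array `side x side x C x N`.
#' @export
resize_images <- function(images, side) {
  d <- dim(images)
  if (d[1] == side && d[2] == side) return(images)
  m <- images; dim(m) <- c(d[1], d[2], d[3] * d[4])
  r <- EBImage::resize(EBImage::Image(m), w = side, h = side)
  out <- as.array(r)
  dim(out) <- c(side, side, d[3], d[4])
  dimnames(out) <- list(NULL, NULL, dimnames(images)[[3]], NULL)
  out
}
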