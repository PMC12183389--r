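# Minimal 1-D convolutional feature extractor, written as vectorised matrix
# ops (im2col + BLAS). Two conv/ReLU/max-pool blocks over the biomarker axis
# feed a dense layer whose activations are the "activation map" consumed by
# the SVM stage; a softmax head exists only to train the features.
#
# Internal representation: position-major matrices of shape (n*len) x channels
# with row index (i-1)*len + t for sample i, position t.

cnn_config <- function(channels = c(16L, 32L), kernels = c(7L, 5L),
                       dense_units = 64L, epochs = 150L, learning_rate = 2e-3,
                       weight_decay = 1e-3) {
  list(channels = as.integer(channels), kernels = as.integer(kernels),
       dense_units = as.integer(dense_units), epochs = as.integer(epochs),
       learning_rate = learning_rate, weight_decay = weight_decay)
}

# output length bookkeeping; returns NULL when the input is too short for the
# convolutional stack (caller falls back to the dense extractor)
cnn_shapes <- function(len, cfg) {
  l1 <- len - cfg$kernels[1L] + 1L
  p1 <- l1 %/% 2L
  l2 <- p1 - cfg$kernels[2L] + 1L
  p2 <- l2 %/% 2L
  if (l1 < 2L || l2 < 2L || p2 < 1L) return(NULL)
  list(l1 = l1, p1 = p1, l2 = l2, p2 = p2)
}

relu <- function(x) x * (x > 0)

he_init <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

cnn_init <- function(len, n_classes, cfg) {
  sh <- cnn_shapes(len, cfg)
  if (is.null(sh)) {
    # dense-only fallback for short marker panels
    params <- list(
      W1 = he_init(len, cfg$dense_units), b1 = rep(0, cfg$dense_units),
      W3 = he_init(cfg$dense_units, cfg$dense_units), b3 = rep(0, cfg$dense_units),
      W4 = he_init(cfg$dense_units, n_classes), b4 = rep(0, n_classes)
    )
    return(list(kind = "dense", params = params, cfg = cfg, len = len))
  }
  k1 <- cfg$kernels[1L]; k2 <- cfg$kernels[2L]
  c1 <- cfg$channels[1L]; c2 <- cfg$channels[2L]
  params <- list(
    W1 = he_init(k1, c1), b1 = rep(0, c1),
    W2 = he_init(k2 * c1, c2), b2 = rep(0, c2),
    W3 = he_init(sh$p2 * c2, cfg$dense_units), b3 = rep(0, cfg$dense_units),
    W4 = he_init(cfg$dense_units, n_classes), b4 = rep(0, n_classes)
  )
  list(kind = "conv", params = params, cfg = cfg, len = len, shapes = sh)
}

# gather row indices turning a (n*len_in) x C position matrix into the im2col
# matrix of a kernel-k convolution with len_out positions
conv_rows <- function(n, len_in, len_out, k) {
  len_in <- as.integer(len_in); len_out <- as.integer(len_out); k <- as.integer(k)
  base <- rep((seq_len(n) - 1L) * len_in, each = len_out) + seq_len(len_out)
  vapply(seq_len(k) - 1L, function(u) base + u, integer(n * len_out))
}

im2col <- function(M, rows, k, nc_in) {
  out <- matrix(0, nrow(rows), k * nc_in)
  for (u in seq_len(k)) {
    out[, ((u - 1L) * nc_in + 1L):(u * nc_in)] <- M[rows[, u], , drop = FALSE]
  }
  out
}

pool_pairs <- function(M, len_in, n) {
  len_out <- len_in %/% 2L
  base <- rep((seq_len(n) - 1L) * len_in, each = len_out)
  o <- base + seq(1L, by = 2L, length.out = len_out)
  e <- o + 1L
  A <- M[o, , drop = FALSE]; B <- M[e, , drop = FALSE]
  mask <- A >= B
  list(P = pmax(A, B), mask = mask, o = o, e = e, len_out = len_out)
}

unpool_pairs <- function(dP, pool, nrow_in, nc) {
  dM <- matrix(0, nrow_in, nc)
  dM[pool$o, ] <- dP * pool$mask
  dM[pool$e, ] <- dP * (1 - pool$mask)
  dM
}

# flatten (n*len) x C -> n x (len*C), position fastest
flatten_pm <- function(M, len, n, nc) {
  matrix(aperm(array(M, c(len, n, nc)), c(2L, 1L, 3L)), n, len * nc)
}

unflatten_pm <- function(F_, len, n, nc) {
  matrix(aperm(array(F_, c(n, len, nc)), c(2L, 1L, 3L)), n * len, nc)
}

cnn_forward <- function(net, X, want_cache = FALSE) {
  p <- net$params
  n <- nrow(X)
  if (net$kind == "dense") {
    H1 <- relu(sweep(X %*% p$W1, 2L, p$b1, `+`))
    H <- relu(sweep(H1 %*% p$W3, 2L, p$b3, `+`))
    logits <- sweep(H %*% p$W4, 2L, p$b4, `+`)
    cache <- if (want_cache) list(H1 = H1, H = H) else NULL
    return(list(H = H, logits = logits, cache = cache))
  }
  sh <- net$shapes; cfg <- net$cfg
  c1 <- cfg$channels[1L]; c2 <- cfg$channels[2L]
  r1 <- conv_rows(n, net$len, sh$l1, cfg$kernels[1L])
  Xc1 <- im2col(matrix(t(X), ncol = 1L), r1, cfg$kernels[1L], 1L)
  A1 <- relu(sweep(Xc1 %*% p$W1, 2L, p$b1, `+`))         # (n*l1) x c1
  pl1 <- pool_pairs(A1, sh$l1, n)                         # (n*p1) x c1
  r2 <- conv_rows(n, sh$p1, sh$l2, cfg$kernels[2L])
  Xc2 <- im2col(pl1$P, r2, cfg$kernels[2L], c1)
  A2 <- relu(sweep(Xc2 %*% p$W2, 2L, p$b2, `+`))          # (n*l2) x c2
  pl2 <- pool_pairs(A2, sh$l2, n)                         # (n*p2) x c2
  F_ <- flatten_pm(pl2$P, sh$p2, n, c2)
  H <- relu(sweep(F_ %*% p$W3, 2L, p$b3, `+`))
  logits <- sweep(H %*% p$W4, 2L, p$b4, `+`)
  cache <- if (want_cache) {
    list(Xc1 = Xc1, A1 = A1, pl1 = pl1, r2 = r2, Xc2 = Xc2, A2 = A2,
         pl2 = pl2, F_ = F_, H = H)
  } else NULL
  list(H = H, logits = logits, cache = cache)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cnn_backward <- function(net, X, Y, fwd) {
  p <- net$params; cc <- fwd$cache
  n <- nrow(X)
  wd <- net$cfg$weight_decay
  Pr <- softmax_rows(fwd$logits)
  dZ <- (Pr - Y) / n
  g <- list()
  g$W4 <- crossprod(cc$H, dZ) + wd * p$W4
  g$b4 <- colSums(dZ)
  dH <- tcrossprod(dZ, p$W4) * (cc$H > 0)
  if (net$kind == "dense") {
    g$W3 <- crossprod(cc$H1, dH) + wd * p$W3
    g$b3 <- colSums(dH)
    dH1 <- tcrossprod(dH, p$W3) * (cc$H1 > 0)
    g$W1 <- crossprod(X, dH1) + wd * p$W1
    g$b1 <- colSums(dH1)
    return(g)
  }
  sh <- net$shapes; cfg <- net$cfg
  c1 <- cfg$channels[1L]; c2 <- cfg$channels[2L]
  g$W3 <- crossprod(cc$F_, dH) + wd * p$W3
  g$b3 <- colSums(dH)
  dF <- tcrossprod(dH, p$W3)
  dP2 <- unflatten_pm(dF, sh$p2, n, c2)
  dA2 <- unpool_pairs(dP2, cc$pl2, n * sh$l2, c2) * (cc$A2 > 0)
  g$W2 <- crossprod(cc$Xc2, dA2) + wd * p$W2
  g$b2 <- colSums(dA2)
  dXc2 <- tcrossprod(dA2, p$W2)
  dP1 <- matrix(0, n * sh$p1, c1)
  for (u in seq_len(cfg$kernels[2L])) {
    idx <- cc$r2[, u]
    dP1[idx, ] <- dP1[idx, ] + dXc2[, ((u - 1L) * c1 + 1L):(u * c1)]
  }
  dA1 <- unpool_pairs(dP1, cc$pl1, n * sh$l1, c1) * (cc$A1 > 0)
  g$W1 <- crossprod(cc$Xc1, dA1) + wd * p$W1
  g$b1 <- colSums(dA1)
  g
}

cnn_train <- function(X, y_factor, cfg, seed) {
  withr::local_seed(as.integer(seed))
  n_classes <- nlevels(y_factor)
  Y <- diag(n_classes)[as.integer(y_factor), , drop = FALSE]
  net <- cnn_init(ncol(X), n_classes, cfg)
  if (net$kind == "dense") {
    inform(sprintf(
      "Input length %d below the convolutional minimum; using the dense feature extractor.",
      ncol(X)))
  }
  # Adam state
  mstate <- lapply(net$params, function(w) w * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fwd <- cnn_forward(net, X, want_cache = TRUE)
    Pr <- softmax_rows(fwd$logits)
    loss[ep] <- -mean(log(pmax(Pr[cbind(seq_len(nrow(X)), as.integer(y_factor))], 1e-12)))
    g <- cnn_backward(net, X, Y, fwd)
    for (nm in names(g)) {
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- mstate[[nm]] / (1 - b1^ep)
      vhat <- vstate[[nm]] / (1 - b2^ep)
      net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  net$loss <- loss
  net
}
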