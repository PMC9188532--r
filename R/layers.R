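# Primitive differentiable layers over (H, W, C, N) arrays. Each layer is an
# environment holding parameters, gradients and forward caches; forward/
# backward functions mutate it in place. The optimizer walks `layer_params()`.

glorot_normal <- function(nrow, ncol, fan_in, fan_out) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / (fan_in + fan_out))), nrow, ncol)
}

make_conv <- function(Cin, Cout, k, s) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- k; e$s <- s; e$Cin <- Cin; e$Cout <- Cout
  e$W <- glorot_normal(Cout, k * k * Cin, k * k * Cin, k * k * Cout)
  e$b <- rep(0, Cout)
  e
}

conv_fw <- function(ly, x) {
  ly$x <- x
  cpp_conv_forward(x, dim(x), ly$W, ly$b, ly$k, ly$s)
}

conv_bw <- function(ly, dy) {
  g <- cpp_conv_bwd_filter(ly$x, dim(ly$x), dy, dim(dy), ly$k, ly$s)
  ly$dW <- g$dW; ly$db <- as.vector(g$db)
  dx <- cpp_conv_bwd_data(dy, dim(dy), ly$W, ly$k, ly$s,
                          dim(ly$x)[1], dim(ly$x)[2])
  ly$x <- NULL
  dx
}

# Transposed convolution: the adjoint of a SAME conv mapping the (larger)
# output grid to the (smaller) input grid. W has shape Cin x (k*k*Cout).
make_convT <- function(Cin, Cout, k, s) {
  e <- new.env(parent = emptyenv())
  e$type <- "convT"; e$k <- k; e$s <- s; e$Cin <- Cin; e$Cout <- Cout
  e$W <- glorot_normal(Cin, k * k * Cout, k * k * Cout, k * k * Cin)
  e$b <- rep(0, Cout)
  e
}

convT_fw <- function(ly, x, Hout, Wout) {
  ly$x <- x
  y <- cpp_conv_bwd_data(x, dim(x), ly$W, ly$k, ly$s, Hout, Wout)
  # add per-channel bias
  hw <- Hout * Wout
  y + rep(rep(ly$b, each = hw), dim(x)[4])
}

convT_bw <- function(ly, dy) {
  dx <- cpp_conv_forward(dy, dim(dy), ly$W, rep(0, ly$Cin), ly$k, ly$s)
  g <- cpp_conv_bwd_filter(dy, dim(dy), ly$x, dim(ly$x), ly$k, ly$s)
  ly$dW <- g$dW
  hw <- dim(dy)[1] * dim(dy)[2]
  m <- matrix(dy, nrow = hw)  # (H*W) x (C*N)
  ly$db <- rowSums(matrix(colSums(m), nrow = ly$Cout))
  ly$x <- NULL
  dx
}

make_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$C <- C; e$momentum <- momentum; e$eps <- eps
  e$gamma <- rep(1, C); e$beta <- rep(0, C)
  e$running_mean <- rep(0, C); e$running_var <- rep(1, C)
  e
}

channel_stat <- function(x, fun) {
  d <- dim(x); hw <- d[1] * d[2]
  m <- matrix(x, nrow = hw)            # (H*W) x (C*N)
  v <- fun(m)                          # length C*N
  rowMeans(matrix(v, nrow = d[3]))     # length C, averaged over batch
}

bc <- function(v, d) rep(rep(v, each = d[1] * d[2]), d[4])  # channel broadcast

bn_fw <- function(ly, x, training) {
  d <- dim(x)
  if (training) {
    mu <- channel_stat(x, colMeans)
    xm <- x - bc(mu, d)
    vr <- channel_stat(xm^2, colMeans)
    ly$running_mean <- ly$momentum * ly$running_mean + (1 - ly$momentum) * mu
    ly$running_var <- ly$momentum * ly$running_var + (1 - ly$momentum) * vr
    invstd <- 1 / sqrt(vr + ly$eps)
    xhat <- xm * bc(invstd, d)
    ly$xhat <- xhat; ly$invstd <- invstd
  } else {
    invstd <- 1 / sqrt(ly$running_var + ly$eps)
    xhat <- (x - bc(ly$running_mean, d)) * bc(invstd, d)
  }
  xhat * bc(ly$gamma, d) + bc(ly$beta, d)
}

bn_bw <- function(ly, dy) {
  d <- dim(dy)
  xhat <- ly$xhat
  m <- d[1] * d[2] * d[4]  # samples per channel
  dgamma <- channel_stat(dy * xhat, colSums) * d[4]
  dbeta <- channel_stat(dy, colSums) * d[4]
  ly$dgamma <- dgamma; ly$dbeta <- dbeta
  coef <- bc(ly$gamma * ly$invstd, d)
  dx <- coef * (dy - bc(dbeta / m, d) - xhat * bc(dgamma / m, d))
  ly$xhat <- NULL; ly$invstd <- NULL
  dx
}

make_dense <- function(n_in, n_out) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$n_in <- n_in; e$n_out <- n_out
  e$W <- glorot_normal(n_out, n_in, n_in, n_out)
  e$b <- rep(0, n_out)
  e
}

dense_fw <- function(ly, x) {  # x: n_in x N
  ly$x <- x
  ly$W %*% x + ly$b
}

dense_bw <- function(ly, dy) {
  ly$dW <- dy %*% t(ly$x)
  ly$db <- rowSums(dy)
  dx <- t(ly$W) %*% dy
  ly$x <- NULL
  dx
}

relu_fw <- function(x) pmax(x, 0)

softmax_cols <- function(z) {  # columns are samples
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Per-pixel softmax over the channel axis of (H, W, K, N).
softmax_pixelwise <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1] * d[2])       # (H*W) x (K*N)
  out <- m
  for (n in seq_len(d[4])) {
    cols <- ((n - 1) * d[3] + 1):(n * d[3])
    blk <- m[, cols, drop = FALSE]
    blk <- blk - apply(blk, 1, max)
    eb <- exp(blk)
    out[, cols] <- eb / rowSums(eb)
  }
  array(out, d)
}

layer_params <- function(ly) {
  switch(ly$type,
    conv = ,
    convT = ,
    dense = list(list(env = ly, f = "W", g = "dW", decay = TRUE),
                 list(env = ly, f = "b", g = "db", decay = FALSE)),
    bn = list(list(env = ly, f = "gamma", g = "dgamma", decay = FALSE),
              list(env = ly, f = "beta", g = "dbeta", decay = FALSE)))
}
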