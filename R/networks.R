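#' Residual block specification
#'
#' The contracting residual block `RB_l(C, k1, s1, k2, s2)` applies a first
#' convolution (kernel `k1`, stride `s1`, `C` channels) whose batch-normalized
#' output serves as the shortcut of the residual map, followed by two
#' convolutions with kernel `k2` (3) and stride `s2` (1), following the scheme
#' Convolution - Batch Normalization - Skip Connection - Activation.
#'
#' @param channels Output channels.
#' @param k1,s1 Kernel and stride of the first (down-sampling / shortcut)
#'   convolution.
#' @param k2,s2 Kernel and stride of the two subsequent convolutions.
#' @export
block_spec <- function(channels, k1, s1, k2 = 3, s2 = 1) {
  stopifnot(channels > 0, k1 >= 1, s1 >= 1, k2 >= 1, s2 >= 1)
  structure(list(channels = channels, k1 = k1, s1 = s1, k2 = k2, s2 = s2),
            class = "block_spec")
}

#' Published contracting block specifications
#'
#' The five classifier blocks (channels 32..512) or, with `n = 6`, the full
#' contracting path of the segmenter whose sixth block has 1024 channels and
#' 1/3 down-sampling. The sixth block's down-sampling convolution uses kernel
#' 4 by default, which realizes the documented receptive-field progression
#' 188/284/380; `block6_kernel = 3` selects the label-literal variant
#' (172/268/364).
#'
#' @param n 5 (classifier) or 6 (segmenter contracting path).
#' @param block6_kernel Kernel of the sixth block's first convolution.
#' @return List of [block_spec()].
#' @export
contracting_block_specs <- function(n = 5, block6_kernel = 4) {
  specs <- list(
    block_spec(32, 1, 1), block_spec(64, 2, 2), block_spec(128, 2, 2),
    block_spec(256, 2, 2), block_spec(512, 2, 2),
    block_spec(1024, block6_kernel, 3))
  specs[seq_len(n)]
}

#' Receptive-field progression of a contracting path
#'
#' Standard recursion `r_i = r_{i-1} + (k_i - 1) * j_{i-1}`,
#' `j_i = j_{i-1} * s_i` with `r_0 = j_0 = 1`, applied to the three
#' convolutions of each contracting residual block.
#'
#' @param blocks List of [block_spec()].
#' @return List with one 3-entry numeric vector per block (receptive-field
#'   side length after each of the block's three convolutions).
#' @export
receptive_fields <- function(blocks) {
  r <- 1; j <- 1
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ks <- c(b$k1, b$k2, b$k2)
    ss <- c(b$s1, b$s2, b$s2)
    rf <- numeric(3)
    for (q in 1:3) {
      r <- r + (ks[q] - 1) * j
      j <- j * ss[q]
      rf[q] <- r
    }
    out[[i]] <- rf
  }
  names(out) <- vapply(blocks, function(b)
    sprintf("RB_l(%d,%d,%d,%d,%d)", b$channels, b$k1, b$s1, b$k2, b$s2), "")
  out
}

#' Receptive-field table (Table-style reproduction)
#' @param blocks List of [block_spec()]; defaults to the full 6-block
#'   contracting path.
#' @return data.frame with block notation and the three receptive fields.
#' @export
rf_table <- function(blocks = contracting_block_specs(6)) {
  rf <- receptive_fields(blocks)
  data.frame(block = names(rf),
             conv1 = vapply(rf, `[`, 0, 1),
             conv2 = vapply(rf, `[`, 0, 2),
             conv3 = vapply(rf, `[`, 0, 3),
             row.names = NULL)
}

scaled_channels <- function(base, m) pmax(1L, as.integer(round(base * m)))

#' Classifier network specification
#'
#' Five contracting residual blocks with channels 32, 64, 128, 256, 512
#' (scaled by `width_multiplier`), features from all depth levels pooled and
#' concatenated into one vector feeding a fully connected two-way softmax.
#'
#' @param input_size Input side length (128 at reference scale).
#' @param width_multiplier Fraction scaling all channel counts.
#' @param dropout_rate Input-layer dropout rate used in training.
#' @export
classifier_spec <- function(input_size = 128L, width_multiplier = 1,
                            dropout_rate = 0) {
  structure(list(input_size = as.integer(input_size),
                 width_multiplier = width_multiplier,
                 channels = scaled_channels(c(32, 64, 128, 256, 512),
                                            width_multiplier),
                 dropout_rate = dropout_rate),
            class = "classifier_spec")
}

#' Segmenter network specification
#'
#' Six contracting residual blocks (channels 32..1024 scaled, strides
#' 1,2,2,2,2,3) and six expanding residual blocks halving channels per level
#' with concatenation of the same-resolution contracting features; a final
#' unit-kernel convolution maps the 32-channel space to `n_classes` followed
#' by a pixelwise softmax.
#'
#' @param n_classes Number of classes including background (13 thigh, 7 leg
#'   at reference scale; arbitrary for reduced-scale experiments).
#' @param input_size Input side length (432 at reference scale).
#' @param width_multiplier Fraction scaling all channel counts.
#' @param dropout_rate Input-layer dropout rate used in training.
#' @param block6_kernel Kernel of the sixth block's down-sampling convolution
#'   (4 reproduces the documented receptive fields; 3 is the label-literal
#'   variant).
#' @export
segmenter_spec <- function(n_classes, input_size = 432L, width_multiplier = 1,
                           dropout_rate = 0, block6_kernel = 4) {
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier,
                 channels = scaled_channels(c(32, 64, 128, 256, 512, 1024),
                                            width_multiplier),
                 dropout_rate = dropout_rate,
                 block6_kernel = block6_kernel),
            class = "segmenter_spec")
}

#' Spatial dimensions along a contracting path
#' @param input_size Input side length.
#' @param strides Per-block strides of the down-sampling convolutions.
#' @return Integer vector of per-block output side lengths.
#' @export
contracting_shapes <- function(input_size, strides = c(1, 2, 2, 2, 2, 3)) {
  sz <- input_size
  vapply(strides, function(s) { sz <<- as.integer(ceiling(sz / s)); sz }, 0L)
}

# ---- residual blocks ------------------------------------------------------

make_rbl <- function(Cin, Cout, k1, s1) {
  e <- new.env(parent = emptyenv())
  e$conv1 <- make_conv(Cin, Cout, k1, s1); e$bn1 <- make_bn(Cout)
  e$conv2 <- make_conv(Cout, Cout, 3, 1); e$bn2 <- make_bn(Cout)
  e$conv3 <- make_conv(Cout, Cout, 3, 1); e$bn3 <- make_bn(Cout)
  e
}

rbl_fw <- function(bl, x, training) {
  s0 <- bn_fw(bl$bn1, conv_fw(bl$conv1, x), training)
  t <- relu_fw(s0); bl$mt <- t > 0
  u <- relu_fw(bn_fw(bl$bn2, conv_fw(bl$conv2, t), training)); bl$mu <- u > 0
  v <- bn_fw(bl$bn3, conv_fw(bl$conv3, u), training)
  y <- relu_fw(v + s0); bl$my <- y > 0
  y
}

rbl_bw <- function(bl, dy) {
  dpre <- dy * bl$my
  du <- conv_bw(bl$conv3, bn_bw(bl$bn3, dpre)) * bl$mu
  dt <- conv_bw(bl$conv2, bn_bw(bl$bn2, du)) * bl$mt
  ds0 <- dpre + dt
  bl$my <- NULL; bl$mu <- NULL; bl$mt <- NULL
  conv_bw(bl$conv1, bn_bw(bl$bn1, ds0))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

make_rbr <- function(Cin, Cout, Cskip, k, s) {
  e <- new.env(parent = emptyenv())
  e$up <- make_convT(Cin, Cout, k, s); e$bn1 <- make_bn(Cout)
  e$Cskip <- Cskip
  e$conv2 <- make_conv(Cout + Cskip, Cout, 3, 1); e$bn2 <- make_bn(Cout)
  e$conv3 <- make_conv(Cout, Cout, 3, 1); e$bn3 <- make_bn(Cout)
  e
}

rbr_fw <- function(bl, x, skip, training, Hout, Wout) {
  s0 <- bn_fw(bl$bn1, convT_fw(bl$up, x, Hout, Wout), training)
  t <- relu_fw(s0); bl$mt <- t > 0
  cat <- if (is.null(skip)) t else concat_channels(t, skip)
  u <- relu_fw(bn_fw(bl$bn2, conv_fw(bl$conv2, cat), training)); bl$mu <- u > 0
  v <- bn_fw(bl$bn3, conv_fw(bl$conv3, u), training)
  y <- relu_fw(v + s0); bl$my <- y > 0
  y
}

rbr_bw <- function(bl, dy) {
  dpre <- dy * bl$my
  du <- conv_bw(bl$conv3, bn_bw(bl$bn3, dpre)) * bl$mu
  dcat <- conv_bw(bl$conv2, bn_bw(bl$bn2, du))
  C <- dim(dy)[3]
  if (bl$Cskip > 0) {
    dt <- dcat[, , seq_len(C), , drop = FALSE] * bl$mt
    dskip <- dcat[, , C + seq_len(bl$Cskip), , drop = FALSE]
  } else {
    dt <- dcat * bl$mt
    dskip <- NULL
  }
  ds0 <- dpre + dt
  bl$my <- NULL; bl$mu <- NULL; bl$mt <- NULL
  list(dx = convT_bw(bl$up, bn_bw(bl$bn1, ds0)), dskip = dskip)
}

collect_layers <- function(blocks) {
  out <- list()
  for (bl in blocks)
    for (nm in c("conv1", "conv2", "conv3", "up", "bn1", "bn2", "bn3"))
      if (!is.null(bl[[nm]])) out <- c(out, list(bl[[nm]]))
  out
}

# ---- classifier -----------------------------------------------------------

#' Build the district classification network
#'
#' Five contracting residual blocks with doubled channels and halved
#' resolution per level; features from every depth level are global-average
#' pooled and concatenated into one vector feeding a fully connected two-way
#' softmax. Weights are initialized from a Glorot normal distribution.
#'
#' @param spec A [classifier_spec()].
#' @return Network object of class `muscleseg_net`.
#' @export
build_classifier <- function(spec = classifier_spec()) {
  ch <- spec$channels
  blocks <- list(make_rbl(1, ch[1], 1, 1))
  for (i in 2:5) blocks[[i]] <- make_rbl(ch[i - 1], ch[i], 2, 2)
  dense <- make_dense(sum(ch), 2)
  layers <- c(collect_layers(blocks), list(dense))
  net <- new.env(parent = emptyenv())
  net$kind <- "classifier"; net$spec <- spec
  net$blocks <- blocks; net$dense <- dense; net$layers <- layers
  net$dropout_rate <- spec$dropout_rate
  class(net) <- "muscleseg_net"
  net
}

gap_fw <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
}

gap_bw <- function(dgap, d) {
  hw <- d[1] * d[2]
  array(rep(as.vector(dgap), each = hw) / hw, d)
}

input_dropout_fw <- function(net, x, training) {
  dr <- net$dropout_rate
  if (!training || is.null(dr) || dr <= 0) return(x)
  mask <- array(runif(length(x)) >= dr, dim(x))
  x * mask / (1 - dr)
}

classifier_forward <- function(net, x, training = FALSE) {
  x <- input_dropout_fw(net, x, training)
  gaps <- vector("list", 5)
  dims <- vector("list", 5)
  for (i in 1:5) {
    x <- rbl_fw(net$blocks[[i]], x, training)
    dims[[i]] <- dim(x)
    gaps[[i]] <- gap_fw(x)
  }
  net$gap_dims <- dims
  dense_fw(net$dense, do.call(rbind, gaps))
}

classifier_backward <- function(net, dlogits) {
  dfeat <- dense_bw(net$dense, dlogits)
  ch <- vapply(net$gap_dims, `[`, 0L, 3)
  offs <- cumsum(c(0, ch))
  g <- NULL
  for (i in 5:1) {
    dgap <- dfeat[offs[i] + seq_len(ch[i]), , drop = FALSE]
    gi <- gap_bw(dgap, net$gap_dims[[i]])
    if (!is.null(g)) gi <- gi + g
    g <- rbl_bw(net$blocks[[i]], gi)
  }
  invisible(g)
}

# ---- segmenter ------------------------------------------------------------

#' Build a segmentation network
#'
#' Residual encoder-decoder: six contracting blocks (strides 1,2,2,2,2,3)
#' and six expanding blocks using transposed convolutions that mirror the
#' contracting kernels/strides, halving channels per level and concatenating
#' the same-resolution contracting features; a final 1x1 convolution maps the
#' first-level channel space to `n_classes`, followed by a pixelwise softmax.
#'
#' @param spec A [segmenter_spec()].
#' @return Network object of class `muscleseg_net`.
#' @export
build_segmenter <- function(spec) {
  stopifnot(inherits(spec, "segmenter_spec"))
  ch <- spec$channels
  k6 <- spec$block6_kernel
  enc <- list(make_rbl(1, ch[1], 1, 1))
  for (i in 2:5) enc[[i]] <- make_rbl(ch[i - 1], ch[i], 2, 2)
  enc[[6]] <- make_rbl(ch[5], ch[6], k6, 3)
  # expanding path: channels 1024 -> 512 -> ... -> 32 -> 32
  dec <- list(
    make_rbr(ch[6], ch[5], ch[5], k6, 3),
    make_rbr(ch[5], ch[4], ch[4], 2, 2),
    make_rbr(ch[4], ch[3], ch[3], 2, 2),
    make_rbr(ch[3], ch[2], ch[2], 2, 2),
    make_rbr(ch[2], ch[1], ch[1], 2, 2),
    make_rbr(ch[1], ch[1], 0, 1, 1))
  final <- make_conv(ch[1], spec$n_classes, 1, 1)
  net <- new.env(parent = emptyenv())
  net$kind <- "segmenter"; net$spec <- spec
  net$enc <- enc; net$dec <- dec; net$final <- final
  net$layers <- c(collect_layers(enc), collect_layers(dec), list(final))
  net$dropout_rate <- spec$dropout_rate
  class(net) <- "muscleseg_net"
  net
}

segmenter_forward <- function(net, x, training = FALSE) {
  if (dim(x)[1] %% 1 != 0) stop("bad input")
  x <- input_dropout_fw(net, x, training)
  e_out <- vector("list", 6)
  cur <- x
  for (i in 1:6) {
    cur <- rbl_fw(net$enc[[i]], cur, training)
    e_out[[i]] <- cur
  }
  sizes <- lapply(e_out, function(a) dim(a)[1:2])
  net$enc_sizes <- sizes
  d <- e_out[[6]]
  for (j in 1:6) {
    tgt <- if (j <= 5) sizes[[6 - j]] else sizes[[1]]
    skip <- if (j <= 5) e_out[[6 - j]] else NULL
    d <- rbr_fw(net$dec[[j]], d, skip, training, tgt[1], tgt[2])
  }
  conv_fw(net$final, d)
}

segmenter_backward <- function(net, dlogits) {
  dd <- conv_bw(net$final, dlogits)
  genc <- vector("list", 6)
  for (j in 6:1) {
    res <- rbr_bw(net$dec[[j]], dd)
    dd <- res$dx
    if (j <= 5) genc[[6 - j]] <- res$dskip
  }
  g <- dd  # gradient flowing into the sixth encoder block's output
  for (i in 6:1) {
    if (i < 6 && !is.null(genc[[i]])) g <- g + genc[[i]]
    g <- rbl_bw(net$enc[[i]], g)
  }
  invisible(g)
}

#' Forward pass of a network
#'
#' Classifier: returns the two-class probability matrix (2 x N). Segmenter:
#' returns the per-pixel class-probability array (H, W, K, N).
#'
#' @param net A `muscleseg_net`.
#' @param x Input array `(H, W, 1, N)` or a single `H x W` matrix.
#' @param training Use batch statistics and dropout (TRUE during training).
#' @export
net_forward <- function(net, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  if (net$kind == "classifier") {
    softmax_cols(classifier_forward(net, x, training))
  } else {
    softmax_pixelwise(segmenter_forward(net, x, training))
  }
}

net_logits <- function(net, x, training = FALSE) {
  if (net$kind == "classifier") classifier_forward(net, x, training)
  else segmenter_forward(net, x, training)
}

net_backward <- function(net, dlogits) {
  if (net$kind == "classifier") classifier_backward(net, dlogits)
  else segmenter_backward(net, dlogits)
}

#' Number of trainable parameters
#' @param net A `muscleseg_net`.
#' @param conv_only Count convolutional/dense kernels only.
#' @export
n_parameters <- function(net, conv_only = FALSE) {
  tot <- 0
  for (ly in net$layers) {
    for (p in layer_params(ly)) {
      if (conv_only && !p$decay) next
      tot <- tot + length(p$env[[p$f]])
    }
  }
  tot
}

all_params <- function(net) {
  out <- list()
  for (ly in net$layers) out <- c(out, layer_params(ly))
  out
}

#' @export
print.muscleseg_net <- function(x, ...) {
  cat(sprintf("muscleseg_net (%s): %d parameters, input %dx%d\n", x$kind,
              n_parameters(x), x$spec$input_size, x$spec$input_size))
  invisible(x)
}
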