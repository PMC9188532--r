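#' @useDynLib muscleseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames var
NULL

# 1D Gaussian convolution matrix with zero boundary and row renormalization,
# so that smoothing a constant returns the constant.
gaussian_matrix <- function(n, sigma, renormalize = TRUE) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  for (o in seq(-half, half)) {
    j <- idx + o
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- kern[o + half + 1]
  }
  if (renormalize) K <- K / rowSums(K) else K <- K / sum(kern)
  K
}

# Separable Gaussian smoothing of a matrix via banded matrix products.
gaussian_smooth <- function(x, sigma, renormalize = TRUE) {
  if (sigma <= 0) return(x)
  Kr <- gaussian_matrix(nrow(x), sigma, renormalize)
  Kc <- gaussian_matrix(ncol(x), sigma, renormalize)
  Kr %*% x %*% t(Kc)
}

# Smooth standard-normal random field (unit variance after smoothing).
smooth_noise_field <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  s <- gaussian_smooth(z, sigma, renormalize = FALSE)
  sdv <- stats::sd(as.vector(s))
  if (sdv > 0) s / sdv else s
}

# Per-slice min-max normalization to [0, 1]; constant images map to 0.
normalize_intensity <- function(img) {
  rng <- range(img)
  if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Reproducible child seeds below 2^31 derived from a master seed.
derive_seeds <- function(master_seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Identity sampling grid (0-based source coordinates for each dest pixel).
identity_maps <- function(nr, nc) {
  list(r = matrix(seq_len(nr) - 1, nr, nc),
       c = matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE))
}

warp_image <- function(img, map_r, map_c, method = c("bicubic", "nearest"),
                       fill = 0, border = c("constant", "replicate")) {
  method <- match.arg(method)
  border <- match.arg(border)
  cpp_warp(img, map_r, map_c, if (method == "nearest") 0L else 1L,
           fill, if (border == "replicate") 1L else 0L)
}

bbox_of <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
    cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}
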