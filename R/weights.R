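#' Parameters of the separation-border weight term
#'
#' `w0` scales the Gaussian bump placed on background corridors between
#' neighbouring muscles; `sigma` (pixels) represents the maximum distance
#' between neighbouring muscles. Defaults follow the reference values
#' `w0 = 10` with `sigma = 7` for thigh data and `sigma = 8` for leg data.
#'
#' @param w0 Dimensionless amplitude (> 0).
#' @param sigma Length scale in pixels (> 0).
#' @export
weight_map_params <- function(w0 = 10, sigma = 7) {
  stopifnot(w0 > 0, sigma > 0)
  structure(list(w0 = w0, sigma = sigma), class = "weight_map_params")
}

#' Default border sigma per district (7 thigh, 8 leg)
#' @param district `"thigh"` or `"leg"`.
#' @export
sigma_for_district <- function(district) if (district == "thigh") 7 else 8

#' Inverse class-frequency weights over a training set
#'
#' For each class `c`, the weight is `total pixels / pixels of class c`,
#' optionally normalized so the background class has weight 1 (the default
#' convention, so the class term is on a comparable scale to the absolute
#' border amplitude `w0`). Rarer classes therefore receive strictly larger
#' weights.
#'
#' @param labels_list List of integer label matrices (or of
#'   `annotated_slice`), the training set.
#' @param n_classes Number of classes including background (13 thigh, 7 leg).
#' @param normalize `"background"` (background weight 1) or `"none"`.
#' @return Named numeric vector of length `n_classes` (names `"0"`...).
#' @export
class_frequency_weights <- function(labels_list, n_classes,
                                    normalize = c("background", "none")) {
  normalize <- match.arg(normalize)
  if (inherits(labels_list, "annotated_slice")) labels_list <- list(labels_list)
  counts <- rep(0, n_classes)
  for (l in labels_list) {
    if (inherits(l, "annotated_slice")) l <- l$labels
    tab <- tabulate(as.vector(l) + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  if (any(counts == 0))
    stop("class(es) absent from the training set: ",
         paste(which(counts == 0) - 1L, collapse = ", "))
  w <- sum(counts) / counts
  if (normalize == "background") w <- w / w[1]
  setNames(w, as.character(seq_len(n_classes) - 1L))
}

#' Separation-border weight term
#'
#' For every pixel, `d1` and `d2` are the Euclidean distances to the nearest
#' and second-nearest *distinct muscle class* regions (background excluded);
#' the term is `w0 * exp(-(d1 + d2)^2 / (2 sigma^2))`. With fewer than two
#' muscle classes present the term is identically zero (`d2` undefined). The
#' term is evaluated at all pixels; inside large muscles it is negligible by
#' the Gaussian tail. Computed from per-class exact distance transforms.
#'
#' @param labels Integer label matrix.
#' @param params A [weight_map_params()].
#' @return Numeric matrix, same dimensions as `labels`.
#' @export
separation_border_term <- function(labels, params = weight_map_params()) {
  classes <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- matrix(0, nrow(labels), ncol(labels))
  if (length(classes) < 2) return(out)
  d1 <- matrix(Inf, nrow(labels), ncol(labels))
  d2 <- matrix(Inf, nrow(labels), ncol(labels))
  for (cl in classes) {
    d <- cpp_edt(labels == cl)
    smaller <- d < d1
    d2 <- pmin(d2, ifelse(smaller, d1, d))
    d1 <- pmin(d1, d)
  }
  border_weight(d1, d2, params)
}

#' Border-weight closed form
#'
#' `w0 * exp(-(d1 + d2)^2 / (2 sigma^2))`: the Gaussian bump evaluated at
#' given nearest/second-nearest muscle distances. At `d1 = d2 = 0` (a pixel
#' on the shared border of two touching muscles) the value is exactly `w0`.
#'
#' @param d1,d2 Distances in pixels (scalars or arrays).
#' @param params A [weight_map_params()].
#' @export
border_weight <- function(d1, d2, params = weight_map_params()) {
  params$w0 * exp(-(d1 + d2)^2 / (2 * params$sigma^2))
}

#' Full per-pixel weight map
#'
#' `w(x) = w_l(x) + w0 * exp(-(d1(x) + d2(x))^2 / (2 sigma^2))`: the inverse
#' class-frequency weight of the pixel's true class plus the separation-border
#' term. Used as the per-pixel multiplier of the weighted cross-entropy loss.
#'
#' @param labels Integer label matrix.
#' @param class_weights Named vector from [class_frequency_weights()]
#'   covering every label present.
#' @param params A [weight_map_params()].
#' @return Numeric weight matrix.
#' @export
compute_weight_map <- function(labels, class_weights,
                               params = weight_map_params()) {
  present <- as.character(sort(unique(as.vector(labels))))
  missing <- setdiff(present, names(class_weights))
  if (length(missing))
    stop("missing class weight for class(es): ", paste(missing, collapse = ", "))
  wl <- matrix(class_weights[as.character(labels)], nrow(labels), ncol(labels))
  wl + separation_border_term(labels, params)
}
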