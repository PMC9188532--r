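PROB_EPS <- 1e-7

#' Categorical cross-entropy
#'
#' `-sum_i gt_i log(sf_i)` with a probability floor of `1e-7` before the
#' logarithm. For a matrix input (one sample per column) the mean over
#' samples is returned.
#'
#' @param sf Softmax output vector, or matrix with samples in columns.
#' @param gt One-hot ground truth of the same shape.
#' @export
categorical_cross_entropy <- function(sf, gt) {
  if (is.matrix(sf)) return(mean(-colSums(gt * log(pmax(sf, PROB_EPS)))))
  -sum(gt * log(pmax(sf, PROB_EPS)))
}

#' Weighted cross-entropy over the image domain
#'
#' `L = -sum_x w(x) log(p_l(x)(x))`: the sum (not mean) over all pixels of
#' the weight-map value times the log-probability the softmax assigns to the
#' pixel's true class.
#'
#' @param prob_map `(H, W, K)` array of per-pixel class probabilities.
#' @param labels `H x W` integer label matrix (values in `0..K-1`).
#' @param weights `H x W` weight map.
#' @export
weighted_cross_entropy <- function(prob_map, labels, weights) {
  d <- dim(prob_map)
  if (!all(dim(labels) == d[1:2]) || !all(dim(weights) == d[1:2]))
    stop("shape mismatch between probability map, labels and weights")
  if (any(labels < 0) || any(labels >= d[3]))
    stop("labels outside 0..", d[3] - 1)
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels) + 1L)
  p <- pmax(prob_map[idx], PROB_EPS)
  -sum(as.vector(weights) * log(p))
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (FP + 2 TP + FN)` per class. The overall score is the
#' unweighted mean over foreground classes present in the truth; classes
#' absent from both prediction and truth are skipped (0/0 convention).
#'
#' @param pred,truth Integer label matrices of equal shape.
#' @param class Optional single class: return that class's DSC.
#' @return A scalar if `class` is given, otherwise a list with `per_class`
#'   (named vector over foreground classes evaluated) and `mean`.
#' @export
dice_coefficient <- function(pred, truth, class = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  one <- function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp + fp + fn == 0) return(NA_real_)
    2 * tp / (fp + 2 * tp + fn)
  }
  if (!is.null(class)) return(one(class))
  classes <- sort(setdiff(union(unique(as.vector(pred)),
                                unique(as.vector(truth))), 0L))
  per <- vapply(classes, one, 0)
  names(per) <- as.character(classes)
  evaluated <- per[!is.na(per)]
  list(per_class = evaluated,
       mean = if (length(evaluated)) mean(evaluated) else NA_real_)
}

#' Categorical accuracy
#'
#' Fraction of predictions matching the ground truth.
#'
#' @param pred,truth Equal-length vectors (or equal-shape arrays).
#' @export
categorical_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(pred == truth)
}
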