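#' Area opening and closing of a multi-class label map
#'
#' Removes, per foreground class, connected components smaller than
#' `area_threshold` pixels (area opening; removed islands become background)
#' and then fills holes smaller than `area_threshold` inside each class region
#' with that class (area closing). Classes are processed in ascending label
#' order. This cleans small structures left behind by registration noise.
#'
#' "Smaller than" is strict: a component of exactly `area_threshold` pixels is
#' kept. Foreground components use 8-connectivity by default (holes use the
#' complementary 4-connectivity).
#'
#' @param labels Integer label matrix (0 = background).
#' @param area_threshold Strict area threshold in pixels.
#' @param connectivity 8 (default) or 4, for foreground components.
#' @return Cleaned integer label matrix.
#' @export
clean_mask <- function(labels, area_threshold = 4, connectivity = 8) {
  if (!is.matrix(labels) || any(labels != round(labels)))
    stop("labels must be an integer-valued matrix")
  storage.mode(labels) <- "integer"
  hole_conn <- if (connectivity == 8) 4L else 8L
  classes <- sort(setdiff(unique(as.vector(labels)), 0L))
  for (cl in classes) {
    mask <- labels == cl
    # opening: drop small components
    comp <- cpp_label_components(mask, connectivity)
    sizes <- tabulate(comp)
    drop <- which(sizes < area_threshold)
    if (length(drop)) labels[comp %in% drop] <- 0L
    # closing: fill small holes with the class
    mask <- labels == cl
    if (!any(mask)) next
    holes <- cpp_label_components(!mask, hole_conn)
    hsizes <- tabulate(holes)
    fill <- which(hsizes < area_threshold)
    if (length(fill)) labels[holes %in% fill] <- cl
  }
  labels
}

#' Anti-aliased bicubic down-sizing for the district classifier
#'
#' Down-sizes an intensity image to `size` x `size` (128 by default, the
#' classifier input) through cubic spline interpolation with Gaussian
#' anti-aliasing pre-smoothing. Upsampling is refused.
#'
#' @param image Numeric intensity matrix with both dimensions >= `size`.
#' @param size Target side length in pixels.
#' @return `size` x `size` numeric matrix.
#' @export
downsize_for_classifier <- function(image, size = 128L) {
  if (nrow(image) < size || ncol(image) < size)
    stop("input smaller than ", size, "; upsampling refused")
  scale_r <- nrow(image) / size
  scale_c <- ncol(image) / size
  # skimage-style anti-aliasing sigma
  sig_r <- max(0, (scale_r - 1) / 2)
  sig_c <- max(0, (scale_c - 1) / 2)
  sm <- image
  if (sig_r > 0) sm <- gaussian_matrix(nrow(sm), sig_r) %*% sm
  if (sig_c > 0) sm <- sm %*% t(gaussian_matrix(ncol(sm), sig_c))
  dst_r <- (seq_len(size) - 0.5) * scale_r - 0.5
  dst_c <- (seq_len(size) - 0.5) * scale_c - 0.5
  map_r <- matrix(dst_r, size, size)
  map_c <- matrix(dst_c, size, size, byrow = TRUE)
  warp_image(sm, map_r, map_c, method = "bicubic", border = "replicate")
}
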