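#' Tree-structured segmentation model
#'
#' Bundles the binary district classifier with the thigh (13-class) and leg
#' (7-class) segmentation networks. At prediction time the classifier routes
#' each slice, by argmax over its categorical output, to the matching
#' segmentation network.
#'
#' @param classifier Classifier `muscleseg_net`.
#' @param thigh_seg,leg_seg Segmenter `muscleseg_net`s.
#' @export
tree_model <- function(classifier, thigh_seg, leg_seg) {
  stopifnot(classifier$kind == "classifier",
            thigh_seg$kind == "segmenter", leg_seg$kind == "segmenter")
  structure(list(classifier = classifier, thigh_seg = thigh_seg,
                 leg_seg = leg_seg), class = "tree_model")
}

#' Classify the anatomical district of a slice
#'
#' Down-sizes the (min-max normalized) image to the classifier input size,
#' runs the classifier and applies argmax under the one-hot convention
#' (1,0) = thigh, (0,1) = leg. An exact tie resolves to the lowest class
#' index, i.e. thigh.
#'
#' @param model A [tree_model()].
#' @param image Intensity matrix at least as large as the classifier input.
#' @return List with `district` and the two-class `probabilities`.
#' @export
classify_district <- function(model, image) {
  size <- model$classifier$spec$input_size
  if (nrow(image) < size || ncol(image) < size)
    stop("image smaller than classifier input (", size, ")")
  img <- normalize_intensity(image)
  if (nrow(img) > size || ncol(img) > size)
    img <- downsize_for_classifier(img, size)
  p <- net_forward(model$classifier, array(img, c(dim(img), 1, 1)))
  if (any(!is.finite(p))) stop("non-finite classifier output")
  district <- if (which.max(p) == 1L) "thigh" else "leg"
  list(district = district,
       probabilities = setNames(as.vector(p), c("thigh", "leg")))
}

# Center-pad/crop a matrix to a square target size with constant fill.
pad_crop <- function(x, target, fill = 0) {
  out <- matrix(fill, target, target)
  nr <- nrow(x); nc <- ncol(x)
  ro <- floor((target - nr) / 2); co <- floor((target - nc) / 2)
  src_r <- seq_len(min(nr, target)) + max(0, -ro)
  src_c <- seq_len(min(nc, target)) + max(0, -co)
  dst_r <- src_r + ro
  dst_c <- src_c + co
  out[dst_r, dst_c] <- x[src_r, src_c]
  out
}

#' Segment one slice through the tree
#'
#' Classifies the district, routes the full-size image to the matching
#' segmentation network, and converts the per-pixel softmax into a label map
#' by pixelwise argmax. Arbitrary input sizes are center-padded/cropped to
#' the segmenter's configured input size with constant 0.
#'
#' @param model A [tree_model()].
#' @param image Intensity matrix.
#' @param return_probabilities Also return the per-pixel probability array.
#' @return List with `labels` (cropped back to the input size), `district`,
#'   `district_probabilities`, and optionally `probabilities`.
#' @export
segment_slice <- function(model, image, return_probabilities = FALSE) {
  cls <- classify_district(model, image)
  net <- if (cls$district == "thigh") model$thigh_seg else model$leg_seg
  size <- net$spec$input_size
  img <- pad_crop(normalize_intensity(image), size)
  p <- net_forward(net, array(img, c(size, size, 1, 1)))[, , , 1]
  labels <- argmax_labels(p)
  # map back to the original geometry
  nr <- nrow(image); nc <- ncol(image)
  ro <- floor((size - nr) / 2); co <- floor((size - nc) / 2)
  out_lab <- matrix(0L, nr, nc)
  src_r <- seq_len(min(nr, size)) + max(0, ro)
  src_c <- seq_len(min(nc, size)) + max(0, co)
  out_lab[src_r - ro, src_c - co] <- labels[src_r, src_c]
  res <- list(labels = out_lab, district = cls$district,
              district_probabilities = cls$probabilities)
  if (return_probabilities) res$probabilities <- p
  res
}

#' Segment a volume slice-wise
#'
#' Applies [segment_slice()] along the third (stack) axis of a volume; each
#' slice is classified and routed independently. When ground-truth labels are
#' supplied the report carries per-slice mean and per-class Dice.
#'
#' @param model A [tree_model()].
#' @param volume 3D array `(H, W, S)`, or path to a NIfTI file.
#' @param truth Optional 3D ground-truth label array (or NIfTI path).
#' @return List with `labels` (3D integer array) and `report` (data.frame:
#'   slice, district, district probabilities, and Dice columns when truth is
#'   given).
#' @export
segment_volume <- function(model, volume, truth = NULL) {
  if (is.character(volume)) volume <- as.array(RNifti::readNifti(volume))
  if (is.character(truth)) truth <- as.array(RNifti::readNifti(truth))
  if (length(dim(volume)) == 2) volume <- array(volume, c(dim(volume), 1))
  S <- dim(volume)[3]
  labels <- array(0L, dim(volume))
  rows <- vector("list", S)
  for (s in seq_len(S)) {
    r <- segment_slice(model, volume[, , s])
    labels[, , s] <- r$labels
    row <- data.frame(slice = s, district = r$district,
                      p_thigh = r$district_probabilities["thigh"],
                      p_leg = r$district_probabilities["leg"],
                      row.names = NULL)
    if (!is.null(truth)) {
      dsc <- dice_coefficient(r$labels, matrix(as.integer(truth[, , s]),
                                               dim(truth)[1], dim(truth)[2]))
      row$mean_dsc <- dsc$mean
      for (cl in names(dsc$per_class))
        row[[paste0("dsc_class_", cl)]] <- dsc$per_class[[cl]]
    }
    rows[[s]] <- row
  }
  report <- merge_rows(rows)
  list(labels = labels, report = report)
}

# rbind data.frames with unequal columns (missing Dice classes become NA)
merge_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cl in setdiff(cols, names(r))) r[[cl]] <- NA
    r[cols]
  }))
}
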