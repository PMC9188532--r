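# Readers/writers for slice datasets. Canonical volume format is NIfTI
# (image + label volumes with slices stacked on the third axis); a PNG
# directory layout is supported for 2D fixtures. Axis convention: in-plane
# (row, column), stack = third NIfTI axis; label volumes are integer-valued.

#' Write a dataset of annotated slices
#'
#' NIfTI: writes `<prefix>_image.nii.gz` and (if labelled)
#' `<prefix>_labels.nii.gz` plus a JSON sidecar with district, severity and
#' provenance per slice. PNG: writes per-slice `slice###.png` /
#' `slice###_labels.png` pairs in a directory (labels stored as integer gray
#' levels).
#'
#' @param slices List of `annotated_slice`.
#' @param path Output prefix (NIfTI) or directory (PNG).
#' @param format `"nifti"` or `"png"`.
#' @export
write_slices <- function(slices, path, format = c("nifti", "png")) {
  format <- match.arg(format)
  n <- length(slices)
  d <- dim(slices[[1]]$image)
  meta <- list(
    district = vapply(slices, function(s) s$district, ""),
    severity = vapply(slices, function(s) s$severity, 0),
    seed = vapply(slices, function(s) s$provenance$seed %||% NA_integer_, 0L))
  if (format == "nifti") {
    img <- array(0, c(d, n))
    lab <- array(0L, c(d, n))
    for (i in seq_len(n)) {
      img[, , i] <- slices[[i]]$image
      lab[, , i] <- slices[[i]]$labels
    }
    RNifti::writeNifti(RNifti::asNifti(img), paste0(path, "_image.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(lab), paste0(path, "_labels.nii.gz"))
    jsonlite::write_json(meta, paste0(path, "_meta.json"), auto_unbox = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      png::writePNG(slices[[i]]$image,
                    file.path(path, sprintf("slice%03d.png", i)))
      png::writePNG(slices[[i]]$labels / 255,
                    file.path(path, sprintf("slice%03d_labels.png", i)))
    }
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dataset of annotated slices
#'
#' Accepts the NIfTI prefix or PNG directory produced by [write_slices()].
#' Errors if labels are requested but the label file is absent, or if image
#' and label dimensions disagree.
#'
#' @param path Input prefix (NIfTI) or directory (PNG).
#' @param with_labels Require and read label maps.
#' @return List of `annotated_slice`.
#' @export
read_slices <- function(path, with_labels = TRUE) {
  if (dir.exists(path)) {
    metaf <- file.path(path, "meta.json")
    meta <- if (file.exists(metaf)) jsonlite::read_json(metaf,
                                                        simplifyVector = TRUE)
            else NULL
    imgs <- sort(list.files(path, "^slice[0-9]+\\.png$", full.names = TRUE))
    if (length(imgs) == 0) stop("unknown format: no slices found in ", path)
    out <- lapply(seq_along(imgs), function(i) {
      img <- png::readPNG(imgs[i])
      if (length(dim(img)) == 3) img <- img[, , 1]
      labf <- sub("\\.png$", "_labels.png", imgs[i])
      lab <- NULL
      if (with_labels) {
        if (!file.exists(labf)) stop("missing label file: ", labf)
        lab <- matrix(as.integer(round(png::readPNG(labf) * 255)),
                      nrow(img), ncol(img))
        if (!all(dim(lab) == dim(img)))
          stop("image/label dimension mismatch in ", imgs[i])
      }
      make_read_slice(img, lab, meta, i)
    })
    return(out)
  }
  imgf <- paste0(path, "_image.nii.gz")
  if (!file.exists(imgf)) stop("unknown format or missing file: ", imgf)
  img <- as.array(RNifti::readNifti(imgf))
  lab <- NULL
  if (with_labels) {
    labf <- paste0(path, "_labels.nii.gz")
    if (!file.exists(labf)) stop("missing label file: ", labf)
    lab <- as.array(RNifti::readNifti(labf))
    if (!all(dim(lab) == dim(img)))
      stop("image/label dimension mismatch for ", path)
  }
  metaf <- paste0(path, "_meta.json")
  meta <- if (file.exists(metaf)) jsonlite::read_json(metaf,
                                                      simplifyVector = TRUE)
          else NULL
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  lapply(seq_len(dim(img)[3]), function(i) {
    make_read_slice(img[, , i],
                    if (!is.null(lab)) matrix(as.integer(lab[, , i]),
                                              dim(img)[1], dim(img)[2]),
                    meta, i)
  })
}

make_read_slice <- function(img, lab, meta, i) {
  structure(list(
    image = img,
    labels = lab %||% matrix(0L, nrow(img), ncol(img)),
    district = if (!is.null(meta)) meta$district[i] else NA_character_,
    severity = if (!is.null(meta)) meta$severity[i] else NA_real_,
    provenance = list(seed = if (!is.null(meta)) meta$seed[i] else NA_integer_),
    masks = NULL), class = "annotated_slice")
}

#' Write a label volume as NIfTI
#' @param path Output file (`.nii` / `.nii.gz`).
#' @param volume 3D integer array.
#' @export
write_labels <- function(path, volume) {
  storage.mode(volume) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Round-trippable run configuration
#'
#' Resolves and serializes the full configuration of a run (district, paths,
#' phantom/augmentation/training settings, seed) to YAML next to its outputs,
#' so any run is reproducible from its saved configuration alone.
#'
#' @param config Named list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
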