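#' Augmentation configuration
#'
#' Ranges of the four stochastic geometric transformation families and the
#' bookkeeping of the augmented dataset: per-side translations bounded by the
#' limb's shortest distance to the image borders, per-side rotations in
#' `[-7, 7]` degrees, piecewise-affine displacements on a 4x4 control grid
#' with normal amplitude in `[0.1, 1]` percent of the image size, and elastic
#' displacement fields smoothed by a Gaussian kernel with SD in `[5, 10]` and
#' strength in `[0, 20]`. The builder emits `target_count` augmented pairs
#' split into train/validation by `train_fraction`.
#'
#' @param rotation_range Degrees, length 2.
#' @param pw_affine_grid Control points per axis.
#' @param pw_affine_scale_range Percent of image size, length 2.
#' @param elastic_strength_range,elastic_kernel_sd_range Length-2 ranges.
#' @param target_count Total augmented pairs to produce.
#' @param train_fraction Fraction assigned to the training split.
#' @param include_probability Independent probability that each transform
#'   family is applied to a given image.
#' @param include_originals If TRUE, source slices are copied into the pool
#'   before augmentation counts toward `target_count`.
#' @param seed Integer seed.
#' @export
augmentation_config <- function(rotation_range = c(-7, 7),
                                pw_affine_grid = 4L,
                                pw_affine_scale_range = c(0.1, 1),
                                elastic_strength_range = c(0, 20),
                                elastic_kernel_sd_range = c(5, 10),
                                target_count = 5000L,
                                train_fraction = 0.9,
                                include_probability = 0.5,
                                include_originals = FALSE,
                                seed = 1L) {
  stopifnot(target_count >= 1)
  structure(list(rotation_range = rotation_range,
                 pw_affine_grid = as.integer(pw_affine_grid),
                 pw_affine_scale_range = pw_affine_scale_range,
                 elastic_strength_range = elastic_strength_range,
                 elastic_kernel_sd_range = elastic_kernel_sd_range,
                 target_count = as.integer(target_count),
                 train_fraction = train_fraction,
                 include_probability = include_probability,
                 include_originals = include_originals,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

# Foreground (limb) mask from image intensity: threshold above the border
# background level, then keep filled components.
limb_foreground <- function(image) {
  border <- c(image[1, ], image[nrow(image), ], image[, 1], image[, ncol(image)])
  thr <- stats::median(border) + 0.1 * diff(range(image))
  mask <- image > thr
  # fill internal holes (components of the complement not touching the border)
  holes <- cpp_label_components(!mask, 4L)
  edge_ids <- unique(c(holes[1, ], holes[nrow(holes), ],
                       holes[, 1], holes[, ncol(holes)]))
  mask[holes > 0 & !(holes %in% edge_ids)] <- TRUE
  mask
}

#' Split a slice into left and right limb masks
#'
#' Finds the two largest foreground bodies and partitions the foreground at
#' the vertical midline between their bounding boxes.
#'
#' @param slice An `annotated_slice`.
#' @return List with logical matrices `left` and `right`.
#' @export
split_sides <- function(slice) {
  fg <- limb_foreground(slice$image)
  comp <- cpp_label_components(fg, 8L)
  sizes <- tabulate(comp)
  if (length(sizes) < 2) stop("side-split error: fewer than two foreground bodies")
  big <- order(sizes, decreasing = TRUE)[1:2]
  b1 <- bbox_of(comp == big[1])
  b2 <- bbox_of(comp == big[2])
  if (b1["cmin"] > b2["cmin"]) { tmp <- b1; b1 <- b2; b2 <- tmp }
  if (b1["cmax"] >= b2["cmin"])
    stop("side-split error: limb bounding boxes overlap")
  mid <- (b1["cmax"] + b2["cmin"]) / 2
  cols <- matrix(seq_len(ncol(fg)), nrow(fg), ncol(fg), byrow = TRUE)
  list(left = fg & cols <= mid, right = fg & cols > mid)
}

# Warp one side (image bicubic, labels/mask nearest) by an affine inverse map
# and composite over the base with vacated pixels filled by 0/background.
warp_side <- function(image, labels, mask, map_r, map_c) {
  side_img <- image; side_img[!mask] <- 0
  side_lab <- labels; side_lab[!mask] <- 0L
  wm <- warp_image(mask * 1, map_r, map_c, "nearest") > 0.5
  wi <- warp_image(side_img, map_r, map_c, "bicubic")
  wl <- warp_image(side_lab * 1, map_r, map_c, "nearest")
  list(mask = wm, image = wi, labels = wl)
}

apply_side_transforms <- function(slice, maps_for_side, params) {
  sides <- split_sides(slice)
  img <- slice$image
  lab <- slice$labels
  out_img <- img
  out_lab <- lab
  for (m in list(sides$left, sides$right)) {
    out_img[m] <- 0
    out_lab[m] <- 0L
  }
  for (k in 1:2) {
    m <- if (k == 1) sides$left else sides$right
    maps <- maps_for_side(m, k)
    if (is.null(maps)) {  # identity
      out_img[m] <- img[m]
      out_lab[m] <- lab[m]
      next
    }
    w <- warp_side(img, lab, m, maps$r, maps$c)
    out_img[w$mask] <- pmax(w$image[w$mask], 0)
    out_lab[w$mask] <- as.integer(round(w$labels[w$mask]))
  }
  res <- slice
  res$image <- clip01(out_img)
  res$labels <- out_lab
  attr(res, "transform_params") <- params
  res
}

#' Independent per-side random translation
#'
#' Each limb is translated independently; horizontal and vertical offsets are
#' drawn uniformly from `[-D, D]` where `D` is that side's shortest distance
#' to any image border, so no foreground pixel can leave the canvas. Image
#' resampled bicubically, labels by nearest neighbour. `D = 0` gives the
#' identity for that side.
#'
#' @param slice An `annotated_slice`.
#' @return Transformed slice with sampled offsets in
#'   `attr(, "transform_params")`.
#' @export
random_side_translation <- function(slice) {
  nr <- nrow(slice$image); nc <- ncol(slice$image)
  params <- list()
  maps_for_side <- function(mask, k) {
    bb <- bbox_of(mask)
    D <- min(bb["rmin"] - 1, nr - bb["rmax"], bb["cmin"] - 1, nc - bb["cmax"])
    D <- max(D, 0)
    dy <- runif(1, -D, D); dx <- runif(1, -D, D)
    params[[k]] <<- c(dy = dy, dx = dx, D = D)
    if (D == 0) return(NULL)
    id <- identity_maps(nr, nc)
    list(r = id$r - dy, c = id$c - dx)
  }
  out <- apply_side_transforms(slice, maps_for_side, params)
  attr(out, "transform_params") <- params
  out
}

#' Independent per-side random rotation
#'
#' Each limb is rotated about its centroid by an angle drawn uniformly from
#' `rotation_range` degrees (`[-7, 7]` by default).
#'
#' @param slice An `annotated_slice`.
#' @param rotation_range Degrees, length 2.
#' @export
random_side_rotation <- function(slice, rotation_range = c(-7, 7)) {
  nr <- nrow(slice$image); nc <- ncol(slice$image)
  params <- list()
  maps_for_side <- function(mask, k) {
    ang <- runif(1, rotation_range[1], rotation_range[2])
    params[[k]] <<- c(angle = ang)
    if (ang == 0) return(NULL)
    idx <- which(mask, arr.ind = TRUE)
    cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
    th <- ang * pi / 180
    id <- identity_maps(nr, nc)
    dr <- id$r - cy; dc <- id$c - cx
    # inverse rotation of destination coordinates
    list(r = cy + (-sin(-th)) * dc + cos(-th) * dr,
         c = cx + cos(-th) * dc + sin(-th) * dr)
  }
  out <- apply_side_transforms(slice, maps_for_side, params)
  attr(out, "transform_params") <- params
  out
}

#' Piecewise-affine deformation on a 4x4 control grid
#'
#' Each control point is displaced by a normal amount with standard deviation
#' `scale * image_size / 100`, where `scale` is drawn once per image from
#' `scale_range` (percent of image size). The dense displacement field is the
#' bilinear interpolation of the control displacements; image resampled
#' bicubically, labels by nearest neighbour.
#'
#' @param slice An `annotated_slice`.
#' @param grid_n Control points per axis.
#' @param scale_range Percent of image size, length 2.
#' @export
piecewise_affine <- function(slice, grid_n = 4L, scale_range = c(0.1, 1)) {
  nr <- nrow(slice$image); nc <- ncol(slice$image)
  scale <- runif(1, scale_range[1], scale_range[2])
  sd_r <- scale * nr / 100
  sd_c <- scale * nc / 100
  disp_r <- matrix(rnorm(grid_n^2, 0, sd_r), grid_n, grid_n)
  disp_c <- matrix(rnorm(grid_n^2, 0, sd_c), grid_n, grid_n)
  gr <- seq(0, nr - 1, length.out = grid_n)
  gc <- seq(0, nc - 1, length.out = grid_n)
  field_r <- bilinear_grid(disp_r, gr, gc, nr, nc)
  field_c <- bilinear_grid(disp_c, gr, gc, nr, nc)
  id <- identity_maps(nr, nc)
  out <- slice
  out$image <- clip01(warp_image(slice$image, id$r + field_r, id$c + field_c,
                                 "bicubic"))
  out$labels <- matrix(as.integer(round(warp_image(
    slice$labels * 1, id$r + field_r, id$c + field_c, "nearest"))), nr, nc)
  attr(out, "transform_params") <- list(scale = scale, disp_r = disp_r,
                                        disp_c = disp_c)
  out
}

# Bilinear interpolation of a coarse control grid to a dense field.
bilinear_grid <- function(vals, gr, gc, nr, nc) {
  rr <- seq_len(nr) - 1
  cc <- seq_len(nc) - 1
  ir <- findInterval(rr, gr, rightmost.closed = TRUE)
  ir <- pmin(pmax(ir, 1L), length(gr) - 1L)
  ic <- findInterval(cc, gc, rightmost.closed = TRUE)
  ic <- pmin(pmax(ic, 1L), length(gc) - 1L)
  tr <- (rr - gr[ir]) / (gr[ir + 1] - gr[ir])
  tc <- (cc - gc[ic]) / (gc[ic + 1] - gc[ic])
  v00 <- vals[cbind(rep(ir, nc), rep(ic, each = nr))]
  v10 <- vals[cbind(rep(ir + 1L, nc), rep(ic, each = nr))]
  v01 <- vals[cbind(rep(ir, nc), rep(ic + 1L, each = nr))]
  v11 <- vals[cbind(rep(ir + 1L, nc), rep(ic + 1L, each = nr))]
  TR <- rep(tr, nc); TC <- rep(tc, each = nr)
  matrix((1 - TR) * (1 - TC) * v00 + TR * (1 - TC) * v10 +
           (1 - TR) * TC * v01 + TR * TC * v11, nr, nc)
}

# Random displacement field smoothed by a Gaussian kernel; exposed so tests
# can probe field roughness directly.
elastic_field <- function(nr, nc, kernel_sd, strength) {
  raw_r <- matrix(runif(nr * nc, -1, 1), nr, nc)
  raw_c <- matrix(runif(nr * nc, -1, 1), nr, nc)
  list(r = strength * gaussian_smooth(raw_r, kernel_sd, renormalize = FALSE),
       c = strength * gaussian_smooth(raw_c, kernel_sd, renormalize = FALSE))
}

#' Elastic deformation
#'
#' A per-pixel random displacement field is smoothed with a Gaussian kernel
#' (SD drawn uniformly from `kernel_sd_range`) and scaled by a strength drawn
#' uniformly from `strength_range`. Strength 0 gives the identity.
#'
#' @param slice An `annotated_slice`.
#' @param strength_range,kernel_sd_range Length-2 ranges.
#' @export
elastic <- function(slice, strength_range = c(0, 20),
                    kernel_sd_range = c(5, 10)) {
  nr <- nrow(slice$image); nc <- ncol(slice$image)
  strength <- runif(1, strength_range[1], strength_range[2])
  kernel_sd <- runif(1, kernel_sd_range[1], kernel_sd_range[2])
  fld <- elastic_field(nr, nc, kernel_sd, strength)
  id <- identity_maps(nr, nc)
  out <- slice
  out$image <- clip01(warp_image(slice$image, id$r + fld$r, id$c + fld$c,
                                 "bicubic"))
  out$labels <- matrix(as.integer(round(warp_image(
    slice$labels * 1, id$r + fld$r, id$c + fld$c, "nearest"))), nr, nc)
  attr(out, "transform_params") <- list(strength = strength,
                                        kernel_sd = kernel_sd)
  out
}

#' Build the augmented training and validation datasets
#'
#' Produces exactly `config$target_count` augmented image/label pairs by
#' sampling source slices uniformly with replacement and applying a random
#' subset of the four transform families in the fixed order
#' translation -> rotation -> piecewise-affine -> elastic (each family is
#' included independently with probability `include_probability`). The pool
#' is then split disjointly into `ceil(train_fraction * N)` training and the
#' remaining validation pairs. Fully seeded.
#'
#' @param slices Non-empty list of `annotated_slice`, all the same district.
#' @param config An [augmentation_config()].
#' @return List with `train`, `validation` (lists of slices) and `log`
#'   (data.frame of applied transforms per generated pair).
#' @export
build_augmented_dataset <- function(slices, config = augmentation_config()) {
  if (length(slices) == 0) stop("empty source slice list")
  districts <- unique(vapply(slices, function(s) s$district, ""))
  if (length(districts) != 1) stop("mixed districts in source slices")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  n <- config$target_count
  pool <- vector("list", n)
  log <- data.frame(pair = seq_len(n), source = NA_integer_,
                    translation = FALSE, rotation = FALSE,
                    pw_affine = FALSE, elastic = FALSE, note = "")
  start <- 0L
  if (config$include_originals) {
    take <- min(length(slices), n)
    pool[seq_len(take)] <- slices[seq_len(take)]
    log$source[seq_len(take)] <- seq_len(take)
    log$note[seq_len(take)] <- "original"
    start <- take
  }
  for (i in seq(from = start + 1L, length.out = n - start)) {
    src_i <- sample.int(length(slices), 1)
    s <- slices[[src_i]]
    inc <- runif(4) < config$include_probability
    note <- ""
    if (inc[1]) {
      s <- tryCatch(random_side_translation(s), error = function(e) {
        note <<- conditionMessage(e); s
      })
    }
    if (inc[2]) {
      s <- tryCatch(random_side_rotation(s, config$rotation_range),
                    error = function(e) { note <<- conditionMessage(e); s })
    }
    if (inc[3]) s <- piecewise_affine(s, config$pw_affine_grid,
                                      config$pw_affine_scale_range)
    if (inc[4]) s <- elastic(s, config$elastic_strength_range,
                             config$elastic_kernel_sd_range)
    pool[[i]] <- s
    log$source[i] <- src_i
    log[i, c("translation", "rotation", "pw_affine", "elastic")] <- as.list(inc)
    log$note[i] <- note
  }
  n_train <- ceiling(config$train_fraction * n)
  idx <- sample.int(n)
  list(train = pool[idx[seq_len(n_train)]],
       validation = pool[idx[seq(n_train + 1, length.out = n - n_train)]],
       log = log)
}
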