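#' Configuration for the synthetic limb phantom
#'
#' Describes one bilateral thigh or leg cross-section. The anatomical district
#' fixes the number of muscle compartments and bone discs per side: 12 muscles
#' and 1 bone (femur) for the thigh, 6 muscles and 2 bones (tibia, fibula) for
#' the leg, matching the 13/7 label classes (background included) segmented by
#' the networks.
#'
#' @param district `"thigh"` or `"leg"`.
#' @param image_size Side length in pixels (square image); at least 64.
#' @param severity Fat-replacement fraction in `[0, 1]`. 0 emulates a healthy
#'   subject; values of 0.6 and above emulate severe fatty infiltration.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param bias_field_amplitude Relative amplitude of the smooth multiplicative
#'   intensity bias field.
#' @param seed Integer seed; the generated slice is deterministic given the
#'   full configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(district = c("thigh", "leg"), image_size = 432L,
                           severity = 0, noise_sd = 0.02,
                           bias_field_amplitude = 0.05, seed = 1L) {
  district <- match.arg(district)
  if (image_size < 64) stop("image too small to place two limbs (need >= 64)")
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  structure(list(
    district = district,
    image_size = as.integer(image_size),
    muscles_per_side = if (district == "thigh") 12L else 6L,
    bones_per_side = if (district == "thigh") 1L else 2L,
    severity = severity,
    noise_sd = noise_sd,
    bias_field_amplitude = bias_field_amplitude,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

config_hash <- function(config) {
  digestable <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 12), collapse = ","), ""), collapse = ";")
  sum(utf8ToInt(digestable) * seq_along(utf8ToInt(digestable))) %% 2147483647
}

# Ellipse interior test in limb-local rotated coordinates.
ellipse_mask <- function(nr, nc, cx, cy, rx, ry, theta = 0) {
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - cx
  rr <- matrix(seq_len(nr) - 1, nr, nc) - cy
  u <- cos(theta) * cc + sin(theta) * rr
  v <- -sin(theta) * cc + cos(theta) * rr
  (u / rx)^2 + (v / ry)^2 <= 1
}

# One limb: outer fat ring, muscle annulus split into angular sectors, bone
# disc(s) with dark cortical rim and bright marrow. Returns intensity, label
# and mask layers for compositing.
draw_limb <- function(nr, nc, cx, cy, rx, ry, theta, config, sector_jitter) {
  K <- config$muscles_per_side
  outer <- ellipse_mask(nr, nc, cx, cy, rx, ry, theta)
  muscle_zone <- ellipse_mask(nr, nc, cx, cy, 0.82 * rx, 0.82 * ry, theta)

  # bones in limb-local coordinates
  bone_cortex <- matrix(FALSE, nr, nc)
  bone_marrow <- matrix(FALSE, nr, nc)
  bone_specs <- if (config$bones_per_side == 1L) {
    list(c(dx = 0.05, dy = 0.02, r = 0.22))
  } else {
    list(c(dx = -0.32, dy = -0.18, r = 0.20),
         c(dx = 0.42, dy = 0.15, r = 0.12))
  }
  for (bs in bone_specs) {
    bx <- cx + (cos(theta) * bs["dx"] * rx - sin(theta) * bs["dy"] * ry)
    by <- cy + (sin(theta) * bs["dx"] * rx + cos(theta) * bs["dy"] * ry)
    br <- bs["r"] * rx
    cortex <- ellipse_mask(nr, nc, bx, by, br, br, 0)
    marrow <- ellipse_mask(nr, nc, bx, by, 0.6 * br, 0.6 * br, 0)
    bone_cortex <- bone_cortex | (cortex & !marrow)
    bone_marrow <- bone_marrow | marrow
  }
  bone <- bone_cortex | bone_marrow

  # angular sectors for the K muscle compartments
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - cx
  rr <- matrix(seq_len(nr) - 1, nr, nc) - cy
  u <- (cos(theta) * cc + sin(theta) * rr) / rx
  v <- (-sin(theta) * cc + cos(theta) * rr) / ry
  phi <- atan2(v, u) + pi  # [0, 2*pi)
  bounds <- 2 * pi * (seq_len(K) - 1) / K + sector_jitter
  bounds <- sort(bounds %% (2 * pi))
  sector <- findInterval(phi, bounds)
  sector[sector == 0L] <- K  # wrap-around before the first boundary
  labels <- matrix(0L, nr, nc)
  in_muscle <- muscle_zone & !bone
  labels[in_muscle] <- sector[in_muscle]

  intensity <- matrix(0, nr, nc)
  intensity[outer] <- 0.90              # subcutaneous fat ring
  intensity[in_muscle] <- 0.30          # muscle
  intensity[bone_cortex] <- 0.10        # cortical bone
  intensity[bone_marrow] <- 0.80        # marrow
  list(intensity = intensity, labels = labels, limb = outer, bone = bone,
       muscle = in_muscle)
}

#' Generate one synthetic bilateral limb slice
#'
#' Places two limb cross-sections left and right of the vertical midline. Each
#' limb has an elliptical outer contour with a bright subcutaneous fat ring,
#' bone disc(s) with dark cortical rim and bright marrow, and angular-sector
#' muscle compartments labelled `1..K` identically on both sides (`K` = 12
#' thigh, 6 leg). Muscle intensity is mixed toward the fat intensity by a
#' smooth random field whose mean equals `severity`, emulating patchy fatty
#' infiltration. Additive Gaussian noise and a smooth multiplicative bias
#' field are applied to the image only. Background, fat and bone share label
#' 0: only muscles are segmented.
#'
#' @param config A [phantom_config()].
#' @param center_jitter,scale_jitter,angle_jitter Optional geometric jitter
#'   (fraction of image size, relative scale, degrees) applied to each limb;
#'   used by [generate_dataset()].
#' @return An `annotated_slice`: list with `image` (matrix in `[0, 1]`),
#'   `labels` (integer matrix), `district`, `severity`, `provenance` and
#'   internal `masks` (limb / bone / muscle / mixing field mean).
#' @export
generate_slice <- function(config, center_jitter = 0, scale_jitter = 0,
                           angle_jitter = 0) {
  stopifnot(inherits(config, "phantom_config"))
  s <- config$image_size
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  K <- config$muscles_per_side
  nr <- s; nc <- s
  base_rx <- 0.205 * s
  base_ry <- 0.23 * s
  sides <- list(
    list(cx = 0.27 * s, cy = 0.5 * s),
    list(cx = 0.73 * s, cy = 0.5 * s)
  )
  img <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  limb_mask <- matrix(FALSE, nr, nc)
  bone_mask <- matrix(FALSE, nr, nc)
  muscle_mask <- matrix(FALSE, nr, nc)
  for (sd_ in sides) {
    cx <- sd_$cx + runif(1, -1, 1) * center_jitter * s
    cy <- sd_$cy + runif(1, -1, 1) * center_jitter * s
    sc <- 1 + runif(1, -1, 1) * scale_jitter
    th <- runif(1, -1, 1) * angle_jitter * pi / 180
    jit <- runif(K, -0.25, 0.25) * 2 * pi / K
    lb <- draw_limb(nr, nc, cx, cy, base_rx * sc, base_ry * sc, th, config, jit)
    img[lb$limb] <- lb$intensity[lb$limb]
    labels[lb$limb] <- lb$labels[lb$limb]
    limb_mask <- limb_mask | lb$limb
    bone_mask <- bone_mask | lb$bone
    muscle_mask <- muscle_mask | lb$muscle
  }

  present <- sort(unique(as.vector(labels)))
  if (!identical(present, 0:K))
    stop("phantom geometry failed to realize all ", K + 1, " classes; ",
         "increase image_size")

  # patchy fat-replacement mixing field, mean = severity by construction
  sev <- config$severity
  if (sev > 0) {
    u <- stats::pnorm(smooth_noise_field(nr, nc, 0.06 * s))
    amp <- 1.2 * min(sev, 1 - sev)
    mixing <- clip01(sev + amp * (u - mean(u)))
    img[muscle_mask] <- (1 - mixing[muscle_mask]) * img[muscle_mask] +
      mixing[muscle_mask] * 0.90
    mixing_mean <- mean(mixing[muscle_mask])
  } else {
    mixing_mean <- 0
  }

  # smooth multiplicative bias field and additive noise on the image only
  if (config$bias_field_amplitude > 0) {
    bias <- 1 + config$bias_field_amplitude * smooth_noise_field(nr, nc, 0.25 * s)
    img <- img * bias
  }
  img <- img + 0.05  # faint background signal level
  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  img <- clip01(img)

  structure(list(
    image = img,
    labels = labels,
    district = config$district,
    severity = sev,
    provenance = list(seed = config$seed, config_hash = config_hash(config)),
    masks = list(limb = limb_mask, bone = bone_mask, muscle = muscle_mask,
                 mixing_mean = mixing_mean)
  ), class = "annotated_slice")
}

#' Generate a reproducible phantom dataset
#'
#' Draws `n` slices with per-slice seeds derived from the master seed and
#' random jitter of limb position, size, orientation and severity across
#' slices.
#'
#' @param config Base [phantom_config()].
#' @param n Number of slices (>= 1).
#' @param seed Master seed.
#' @param severity_range Length-2 range from which each slice's severity is
#'   drawn uniformly; defaults to the configured severity (no variation).
#' @param center_jitter,scale_jitter,angle_jitter Jitter amplitudes (fraction
#'   of image size, relative scale, degrees).
#' @return List of `annotated_slice` objects.
#' @export
generate_dataset <- function(config, n, seed = config$seed,
                             severity_range = c(config$severity, config$severity),
                             center_jitter = 0.02, scale_jitter = 0.08,
                             angle_jitter = 4) {
  stopifnot(inherits(config, "phantom_config"), n >= 1)
  child <- derive_seeds(seed, n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sev <- runif(n, severity_range[1], severity_range[2])
  lapply(seq_len(n), function(i) {
    ci <- config
    ci$seed <- child[i]
    ci$severity <- sev[i]
    generate_slice(ci, center_jitter = center_jitter,
                   scale_jitter = scale_jitter, angle_jitter = angle_jitter)
  })
}

#' @export
print.annotated_slice <- function(x, ...) {
  cat(sprintf("annotated_slice: %s, %dx%d, %d classes, severity %.2f\n",
              x$district, nrow(x$image), ncol(x$image),
              length(unique(as.vector(x$labels))), x$severity))
  invisible(x)
}

n_classes_for <- function(district) if (district == "thigh") 13L else 7L
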