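#' Scene configuration for the synthetic plot generator
#'
#' Defines the conditions under which a synthetic plot scene is rendered:
#' scene dimensions, how many bolls to place and how far apart, how much
#' of the ground is covered by vegetation and woody debris, an
#' illumination gradient across the plot, and additive sensor noise.
#' Defaults emulate a defoliated breeding-trial plot at desk scale.
#'
#' @param height,width Scene size in pixels.
#' @param n_bolls Number of cotton bolls to place.
#' @param boll_radius_range `c(min, max)` boll radius in pixels.
#' @param min_separation Minimum center-to-center distance between bolls
#'   (pixels); with the default structuring elements, separations above
#'   the dilation merge distance keep bolls countable as distinct
#'   clusters.
#' @param vegetation_fraction,wood_fraction Approximate fractions of the
#'   scene covered by green vegetation blobs and light-brown woody
#'   segments.
#' @param illumination_gradient Relative brightness change from the left
#'   to the right edge (0 = flat lighting).
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise (8-bit units).
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(height = 240L, width = 360L, n_bolls = 60L,
                         boll_radius_range = c(2, 5), min_separation = 15,
                         vegetation_fraction = 0.25, wood_fraction = 0.05,
                         illumination_gradient = 0.10, noise_sd = 3,
                         seed = 1L) {
  if (n_bolls < 0) stop_validation("n_bolls must be non-negative")
  if (min_separation < 0) stop_validation("min_separation must be non-negative")
  if (vegetation_fraction + wood_fraction > 1)
    stop_validation("cover fractions must sum to at most 1")
  if (boll_radius_range[1] > boll_radius_range[2] || boll_radius_range[1] <= 0)
    stop_validation("invalid boll_radius_range")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_bolls = as.integer(n_bolls),
                 boll_radius_range = as.numeric(boll_radius_range),
                 min_separation = as.numeric(min_separation),
                 vegetation_fraction = vegetation_fraction,
                 wood_fraction = wood_fraction,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# class codes in the class map
SCENE_CLASSES <- c(soil = 1L, vegetation = 2L, wood = 3L, cotton = 4L)

lab_to_srgb255 <- function(lab) {
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = TRUE)
  srgb * 255
}

# pixel indices of a filled disk, clipped to the scene
disk_pixels <- function(H, W, cr, cc, radius) {
  rr <- max(1, floor(cr - radius)):min(H, ceiling(cr + radius))
  cc_ <- max(1, floor(cc - radius)):min(W, ceiling(cc + radius))
  dr <- matrix(rr - cr, length(rr), length(cc_))
  dc <- matrix(rep(cc_ - cc, each = length(rr)), length(rr))
  d <- sqrt(dr^2 + dc^2)
  inside <- d <= radius
  list(idx = cbind(rep(rr, length(cc_))[inside],
                   rep(cc_, each = length(rr))[inside]),
       dist = d[inside])
}

#' Generate a synthetic plot scene with known truth
#'
#' Renders a plot scene of the four pixel classes seen in a defoliated
#' cotton trial: a tan/brown soil base drawn from a small CIELAB palette
#' (L* 45–65, a* 5–15, b* 15–30), green vegetation blobs (high
#' excess-green index), light-brown woody segments (the bright
#' false-positive confuser), and cotton bolls as near-neutral bright
#' disks (L* 85–98 at center) whose lightness falls off linearly by 25 L*
#' units toward the rim — so boll rims are dark enough to be missed, the
#' mechanism behind false-negative pixels on shaded bolls. Boll centers
#' are placed by rejection sampling honoring `min_separation` (placement
#' fails with an error after 10,000 rejected draws). An optional
#' left-to-right illumination gradient and additive Gaussian noise are
#' applied last. Everything is reproducible from `config$seed`.
#'
#' @param config A [scene_config()].
#' @return A `synthetic_scene`: `image` ([plot_image()]), `mask`
#'   ([annotation_mask()] of true cotton pixels), `boll_truth` tibble
#'   (0-based `center_row`, `center_col`, `radius`), `true_count`,
#'   `class_map` (integer matrix coded soil=1, vegetation=2, wood=3,
#'   cotton=4) and the `config`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$height; W <- config$width
  withr::with_seed(config$seed, {
    class_map <- matrix(SCENE_CLASSES[["soil"]], H, W)
    # soil: small palette of exact colors + per-pixel palette assignment
    n_pal <- 8L
    soil_pal <- lab_to_srgb255(cbind(runif(n_pal, 45, 65),
                                     runif(n_pal, 5, 15),
                                     runif(n_pal, 15, 30)))
    pal_id <- matrix(sample.int(n_pal, H * W, replace = TRUE), H, W)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- soil_pal[pal_id, ch]

    # vegetation: random ellipses until the target cover is reached
    target_veg <- config$vegetation_fraction * H * W
    covered <- 0; tries <- 0L
    while (covered < target_veg && tries < 10000L) {
      tries <- tries + 1L
      cr <- runif(1, 1, H); cc <- runif(1, 1, W)
      ax <- runif(2, 4, 14); th <- runif(1, 0, pi)
      col_rgb <- c(runif(1, 30, 80), runif(1, 110, 180), runif(1, 20, 70))
      rr <- max(1, floor(cr - max(ax))):min(H, ceiling(cr + max(ax)))
      cc_ <- max(1, floor(cc - max(ax))):min(W, ceiling(cc + max(ax)))
      dr <- matrix(rr - cr, length(rr), length(cc_))
      dc <- matrix(rep(cc_ - cc, each = length(rr)), length(rr))
      u <- dr * cos(th) + dc * sin(th); v <- -dr * sin(th) + dc * cos(th)
      inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
      idx <- cbind(rep(rr, length(cc_))[inside], rep(cc_, each = length(rr))[inside])
      if (!nrow(idx)) next
      covered <- covered + sum(class_map[idx] != SCENE_CLASSES[["vegetation"]])
      class_map[idx] <- SCENE_CLASSES[["vegetation"]]
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[idx] <- col_rgb[ch]; img[, , ch] <- plane
      }
    }

    # wood: thin bright-brown segments
    target_wood <- config$wood_fraction * H * W
    covered <- 0; tries <- 0L
    while (covered < target_wood && tries < 10000L) {
      tries <- tries + 1L
      r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
      len <- runif(1, 15, 40); th <- runif(1, 0, pi); thick <- runif(1, 0.6, 1.4)
      t_seq <- seq(0, len, by = 0.5)
      pr <- pmin(pmax(round(r0 + t_seq * sin(th)), 1), H)
      pc <- pmin(pmax(round(c0 + t_seq * cos(th)), 1), W)
      pts <- unique(cbind(pr, pc))
      if (thick > 1) {
        pts <- unique(rbind(pts, cbind(pmin(pts[, 1] + 1L, H), pts[, 2]),
                            cbind(pts[, 1], pmin(pts[, 2] + 1L, W))))
      }
      lab_col <- lab_to_srgb255(cbind(runif(1, 62, 75), runif(1, 6, 12),
                                      runif(1, 18, 28)))
      covered <- covered + sum(class_map[pts] != SCENE_CLASSES[["wood"]])
      class_map[pts] <- SCENE_CLASSES[["wood"]]
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[pts] <- lab_col[ch]; img[, , ch] <- plane
      }
    }

    # bolls: rejection-sampled centers, radial lightness falloff
    centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
    rejects <- 0L
    r_rng <- config$boll_radius_range
    margin <- r_rng[2] + 1
    while (nrow(centers) < config$n_bolls) {
      cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= config$min_separation) {
        centers <- rbind(centers, cand)
        radii <- c(radii, runif(1, r_rng[1], r_rng[2]))
      } else {
        rejects <- rejects + 1L
        if (rejects >= 10000L)
          abort(sprintf("could not place %d bolls with min_separation %.1f in %d x %d",
                        config$n_bolls, config$min_separation, H, W),
                class = "bollcount_placement_error")
      }
    }
    mask <- matrix(0L, H, W)
    if (config$n_bolls > 0) {
      for (i in seq_len(config$n_bolls)) {
        dsk <- disk_pixels(H, W, centers[i, 1], centers[i, 2], radii[i])
        Lc <- runif(1, 85, 98)
        a0 <- runif(1, -3, 3); b0 <- runif(1, 0, 5)
        Lpx <- Lc - 25 * (dsk$dist / radii[i])
        rgb <- lab_to_srgb255(cbind(Lpx, a0, b0))
        class_map[dsk$idx] <- SCENE_CLASSES[["cotton"]]
        mask[dsk$idx] <- 1L
        for (ch in 1:3) {
          plane <- img[, , ch]; plane[dsk$idx] <- rgb[, ch]; img[, , ch] <- plane
        }
      }
    }

    # illumination gradient then sensor noise
    if (config$illumination_gradient != 0) {
      fac <- 1 + config$illumination_gradient *
        ((seq_len(W) - 1) / max(W - 1, 1) - 0.5)
      for (ch in 1:3) img[, , ch] <- sweep(img[, , ch], 2, fac, `*`)
    }
    if (config$noise_sd > 0)
      img <- img + rnorm(length(img), 0, config$noise_sd)
    img <- round(pmin(pmax(img, 0), 255))

    structure(
      list(image = plot_image(img, plot_id = sprintf("synthetic_seed%d", config$seed)),
           mask = annotation_mask(mask, plot_id = sprintf("synthetic_seed%d", config$seed)),
           boll_truth = tibble(center_row = centers[, 1] - 1,
                               center_col = centers[, 2] - 1,
                               radius = radii),
           true_count = as.integer(config$n_bolls),
           class_map = class_map,
           config = config),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene '%s'> %d x %d px, %d boll(s)\n",
              x$image$plot_id, x$config$height, x$config$width, x$true_count))
  invisible(x)
}

#' @export
tidy.synthetic_scene <- function(x, ...) x$boll_truth

#' Write a scene to disk as a training fixture
#'
#' Writes the scene's image (PNG), annotation mask (single-band TIFF,
#' foreground 255) and a JSON truth sidecar (boll centers, radii, count,
#' seed and full configuration) in the formats the I/O layer reads back.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to the scene's plot id.
#' @return Named character vector of the three paths, invisibly.
#' @export
scene_to_training_fixture <- function(scene, dir, stem = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- stem %||% scene$image$plot_id
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             mask = file.path(dir, paste0(stem, "_mask.tif")),
             truth = file.path(dir, paste0(stem, "_truth.json")))
  write_plot_image(scene$image, paths[["image"]])
  write_mask(scene$mask, paths[["mask"]])
  jsonlite::write_json(
    list(plot_id = scene$image$plot_id, true_count = scene$true_count,
         bolls = scene$boll_truth, seed = scene$config$seed,
         config = unclass(scene$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
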