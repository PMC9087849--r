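#' Color-space conversions for plot images
#'
#' `to_hsv()` converts an 8-bit RGB image to hexcone HSV with all three
#' components in `[0, 1]` (H of achromatic pixels is defined as 0).
#' `to_cielab()` converts through the standard sRGB transfer and D65 white
#' point to CIELAB, giving L* in `[0, 100]` and a*, b* roughly in
#' `[-128, 127]`.
#'
#' @param image A [plot_image()].
#' @return An `H x W x 3` numeric array (H, S, V or L*, a*, b*).
#' @export
to_hsv <- function(image) {
  stopifnot(inherits(image, "plot_image"))
  d <- dim(image$pixels)
  rgb <- rbind(as.vector(image$pixels[, , 1]),
               as.vector(image$pixels[, , 2]),
               as.vector(image$pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  array(t(hsv), dim = d)
}

#' @rdname to_hsv
#' @export
to_cielab <- function(image) {
  stopifnot(inherits(image, "plot_image"))
  d <- dim(image$pixels)
  srgb <- cbind(as.vector(image$pixels[, , 1]),
                as.vector(image$pixels[, , 2]),
                as.vector(image$pixels[, , 3])) / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' Modified excess-green-minus-excess-red index
#'
#' The vegetation-removal index, computed on chromatic coordinates
#' (channel fractions of the pixel's intensity sum):
#' \deqn{ExGR_{mod} = 2.5\,G_{norm} - 3\,R_{norm} - B_{norm}}
#' with \eqn{R_{norm} = R/(R+G+B)} etc. Values lie in `[-3, 2.5]`;
#' vegetation scores high (pure green gives 2.5), neutral pixels give
#' -0.5, pure red gives -3. Degenerate `(0,0,0)` pixels get the sentinel
#' value 0.
#'
#' `exgr_index()` is the vectorized scalar form on raw channel values.
#'
#' @param image A [plot_image()].
#' @return `H x W` numeric matrix of index values.
#' @export
exgr_mod <- function(image) {
  stopifnot(inherits(image, "plot_image"))
  matrix(exgr_index(image$pixels[, , 1], image$pixels[, , 2], image$pixels[, , 3]),
         nrow = dim(image$pixels)[1])
}

#' @rdname exgr_mod
#' @param r,g,b Numeric vectors of channel intensities.
#' @export
exgr_index <- function(r, g, b) {
  s <- r + g + b
  out <- ifelse(s > 0, (2.5 * g - 3 * r - b) / s, 0)
  as.numeric(out)
}

#' CIELAB-based soil index
#'
#' The soil-removal index
#' \deqn{Soil_{Idx} = 0.5\,L_{norm} - 2\,a_{norm} + b_{norm}}
#' on normalized CIELAB components, with the conventions
#' \eqn{L_{norm} = L^*/100}, \eqn{a_{norm} = a^*/127},
#' \eqn{b_{norm} = b^*/127}. Bright near-neutral pixels (open cotton)
#' score high — reference white gives 0.5 — while tan/brown soil, whose
#' positive a* is doubly penalized, scores low. Degenerate `(0,0,0)`
#' pixels get the sentinel value 0.
#'
#' `soil_index_lab()` is the vectorized scalar form on L*, a*, b* values.
#'
#' @param image A [plot_image()].
#' @param lab Optional precomputed [to_cielab()] array (saves recomputation).
#' @return `H x W` numeric matrix of index values.
#' @export
soil_idx <- function(image, lab = NULL) {
  stopifnot(inherits(image, "plot_image"))
  lab <- lab %||% to_cielab(image)
  idx <- soil_index_lab(lab[, , 1], lab[, , 2], lab[, , 3])
  zero <- image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3] == 0
  idx[zero] <- 0
  matrix(idx, nrow = dim(image$pixels)[1])
}

#' @rdname soil_idx
#' @param L,a,b Numeric vectors of CIELAB components (L* in 0–100).
#' @export
soil_index_lab <- function(L, a, b) {
  as.numeric(0.5 * (L / 100) - 2 * (a / 127) + (b / 127))
}

#' Two-stage color-index background removal
#'
#' Removes vegetation pixels (index above `veg_threshold` on
#' [exgr_mod()]), then, among the survivors, soil pixels (index below
#' `soil_threshold` on [soil_idx()]). Degenerate `(0,0,0)` pixels —
#' zero fill from plot clipping — are always removed. Per-stage pixel
#' counts are recorded so the retention of each stage can be reported.
#'
#' @param image A [plot_image()].
#' @param veg_threshold Vegetation removal threshold on `ExGR_mod`
#'   (default 0, the classic ExG-ExR zero crossing).
#' @param soil_threshold Soil removal threshold on `Soil_Idx`
#'   (default 0.25, calibrated so rendered boll pixels are retained).
#' @return A `background_mask` object with fields `retained` (0/1 matrix)
#'   and `counts` (`raw_pixels`, `after_vegetation`, `after_soil`).
#' @export
background_mask <- function(image, veg_threshold = 0, soil_threshold = 0.25) {
  stopifnot(inherits(image, "plot_image"),
            is_scalar_number(veg_threshold), is_scalar_number(soil_threshold))
  zero <- image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3] == 0
  veg_keep <- exgr_mod(image) <= veg_threshold & !zero
  soil_keep <- veg_keep & soil_idx(image) >= soil_threshold
  structure(
    list(retained = matrix(as.integer(soil_keep), nrow(soil_keep)),
         counts = list(raw_pixels = length(zero),
                       after_vegetation = sum(veg_keep),
                       after_soil = sum(soil_keep)),
         veg_threshold = veg_threshold, soil_threshold = soil_threshold),
    class = "background_mask")
}

#' @export
print.background_mask <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Stage-by-stage retention of background removal
#'
#' @param x A `background_mask`.
#' @param ... Unused.
#' @return A tibble with one row per stage: pixels remaining and the
#'   percentage of the raw image they represent.
#' @export
tidy.background_mask <- function(x, ...) {
  with(x$counts, retention_summary(raw_pixels, after_vegetation, after_soil))
}

#' Retention summary from stage pixel counts
#'
#' Computes the percentage of raw pixels surviving each background-removal
#' stage.
#'
#' @param raw_pixels,after_vegetation,after_soil Pixel counts after each
#'   stage.
#' @return A tibble with columns `stage`, `pixels`, `pct_of_raw`.
#' @export
retention_summary <- function(raw_pixels, after_vegetation, after_soil) {
  tibble(stage = c("raw", "after_vegetation", "after_soil"),
         pixels = c(raw_pixels, after_vegetation, after_soil),
         pct_of_raw = 100 * c(raw_pixels, after_vegetation, after_soil) / raw_pixels)
}

feature_columns <- c("R", "G", "B", "H", "S", "V", "L", "a", "b")

#' Extract the per-pixel feature table
#'
#' Builds the classifier's substrate: one row per retained pixel carrying
#' its 0-based `(row, col)` location and the nine color components —
#' R, G, B (8-bit), H, S, V (unit scale) and CIELAB L*, a*, b* — eleven
#' features in all. When an [annotation_mask()] is supplied its value at
#' each retained pixel is attached as the binary `label` column (1 =
#' cotton).
#'
#' @param image A [plot_image()].
#' @param retained A [background_mask()], a 0/1 matrix, or `NULL` to keep
#'   every pixel.
#' @param annotation Optional [annotation_mask()] (or 0/1 matrix) of the
#'   same dimensions.
#' @return A tibble ordered by raster scan (row, then col).
#' @export
extract_features <- function(image, retained = NULL, annotation = NULL) {
  stopifnot(inherits(image, "plot_image"))
  d <- dim(image$pixels)
  keep <- if (is.null(retained)) matrix(1L, d[1], d[2])
          else if (inherits(retained, "background_mask")) retained$retained
          else retained
  if (!all(dim(keep) == d[1:2]))
    stop_validation("retained mask dimensions do not match the image")
  lab_mask <- NULL
  if (!is.null(annotation)) {
    lab_mask <- if (inherits(annotation, "annotation_mask")) annotation$mask else annotation
    if (!all(dim(lab_mask) == d[1:2]))
      stop_validation("annotation mask dimensions do not match the image")
  }
  idx <- which(keep != 0)
  empty <- tibble(row = integer(), col = integer(),
                  R = numeric(), G = numeric(), B = numeric(),
                  H = numeric(), S = numeric(), V = numeric(),
                  L = numeric(), a = numeric(), b = numeric())
  if (!length(idx)) {
    if (!is.null(lab_mask)) empty$label <- integer()
    return(empty)
  }
  r0 <- (idx - 1L) %% d[1]          # 0-based row
  c0 <- (idx - 1L) %/% d[1]         # 0-based col
  n <- d[1] * d[2]
  R <- image$pixels[, , 1][idx]; G <- image$pixels[, , 2][idx]; B <- image$pixels[, , 3][idx]
  hsv <- grDevices::rgb2hsv(rbind(R, G, B), maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(R, G, B) / 255, from = "sRGB", to = "Lab")
  out <- tibble(row = as.integer(r0), col = as.integer(c0),
                R = R, G = G, B = B,
                H = hsv[1, ], S = hsv[2, ], V = hsv[3, ],
                L = lab[, 1], a = lab[, 2], b = lab[, 3])
  if (!is.null(lab_mask)) out$label <- as.integer(lab_mask[idx])
  arrange(out, .data$row, .data$col)
}
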