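#' Plot image container
#'
#' A `plot_image` holds one plot's 8-bit RGB raster together with its
#' identity and (optional) georeferencing. Pixels are stored as an
#' `H x W x 3` numeric array of integers in `[0, 255]`, channel order
#' R, G, B, row 0 at the top of the image. Pixel coordinates throughout
#' the package are 0-based `(row, col)`.
#'
#' @param pixels `H x W x 3` array of intensities in `[0, 255]`.
#' @param plot_id Character identifier of the plot.
#' @param geotransform Optional 6-number affine `c(x0, dx_col, dx_row,
#'   y0, dy_col, dy_row)` mapping 0-based pixel `(col, row)` corners to
#'   world coordinates: `x = x0 + col*dx_col + row*dx_row`,
#'   `y = y0 + col*dy_col + row*dy_row`.
#' @param crs Optional coordinate reference system code (text).
#'
#' @return A `plot_image` object.
#' @export
plot_image <- function(pixels, plot_id = "plot", geotransform = NULL, crs = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_format("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_format("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_format("intensities must lie in [0, 255]")
  if (!is.null(geotransform) && length(geotransform) != 6L)
    stop_format("`geotransform` must have 6 elements")
  structure(
    list(plot_id = as.character(plot_id), pixels = pixels,
         geotransform = geotransform, crs = crs),
    class = "plot_image"
  )
}

#' @export
dim.plot_image <- function(x) dim(x$pixels)

#' @export
print.plot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plot_image '%s'> %d x %d px, 3 channels%s\n",
              x$plot_id, d[1], d[2],
              if (!is.null(x$geotransform)) ", georeferenced" else ""))
  invisible(x)
}

#' Annotation mask container
#'
#' Binary per-pixel annotation paired with a [plot_image()]: 1 marks cotton
#' pixels, 0 everything else.
#'
#' @param mask `H x W` matrix with values in `{0, 1}`.
#' @param plot_id Character identifier of the plot.
#' @return An `annotation_mask` object.
#' @export
annotation_mask <- function(mask, plot_id = "plot") {
  if (!is.matrix(mask)) stop_format("`mask` must be a matrix")
  if (!all(mask %in% c(0, 1))) stop_format("mask values must be 0 or 1")
  structure(list(plot_id = as.character(plot_id),
                 mask = matrix(as.integer(mask), nrow(mask), ncol(mask))),
            class = "annotation_mask")
}

#' @export
dim.annotation_mask <- function(x) dim(x$mask)

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

sidecar_path <- function(path) paste0(path, ".aux.json")

read_raster_array <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "bollcount_io_error")
  ext <- file_ext(path)
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_format(sprintf("unsupported raster format '.%s' (PNG/TIFF supported)", ext))
  )
  arr
}

#' Read a plot image from PNG or TIFF
#'
#' Reads an 8-bit RGB raster. Extra bands beyond the first three (e.g. an
#' alpha channel) are dropped. Georeferencing, when present, travels in a
#' JSON sidecar file `<path>.aux.json` holding `geotransform` (6 numbers)
#' and optionally `crs`; [write_plot_image()] produces the sidecar
#' automatically for georeferenced images.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param plot_id Plot identifier; defaults to the file stem.
#' @return A [plot_image()].
#' @export
read_plot_image <- function(path, plot_id = NULL) {
  arr <- read_raster_array(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
    stop_format(sprintf("'%s' has fewer than 3 bands", path))
  px <- round(arr[, , 1:3, drop = FALSE] * 255)
  geotransform <- NULL; crs <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    aux <- jsonlite::read_json(sc, simplifyVector = TRUE)
    geotransform <- aux$geotransform
    crs <- aux$crs
  }
  plot_image(px,
             plot_id = plot_id %||% sub("\\.[^.]*$", "", basename(path)),
             geotransform = geotransform, crs = crs)
}

#' Write a plot image to PNG or TIFF
#'
#' @param image A [plot_image()].
#' @param path Destination path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_plot_image <- function(image, path) {
  stopifnot(inherits(image, "plot_image"))
  arr <- image$pixels / 255
  ext <- file_ext(path)
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop_format(sprintf("unsupported raster format '.%s'", ext))
  )
  if (!is.null(image$geotransform)) {
    jsonlite::write_json(
      list(geotransform = image$geotransform, crs = image$crs),
      sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a binary annotation mask
#'
#' Reads a single-band raster and binarizes it: any nonzero intensity maps
#' to 1 (cotton), zero stays 0. Accepts both `{0, 1}` and `{0, 255}`
#' dialects.
#'
#' @param path Path to a single-band TIFF (or PNG).
#' @param plot_id Plot identifier; defaults to the file stem.
#' @return An [annotation_mask()].
#' @export
read_mask <- function(path, plot_id = NULL) {
  arr <- read_raster_array(path)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] != 1L)
      stop_format(sprintf("'%s' is not single-channel", path))
    arr <- arr[, , 1]
  }
  annotation_mask((arr != 0) * 1L,
                  plot_id = plot_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an annotation mask as single-band TIFF
#'
#' Foreground is written as 255 for compatibility with common viewers;
#' [read_mask()] maps it back to 1.
#'
#' @param mask An [annotation_mask()] or a 0/1 matrix.
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "annotation_mask")) mask$mask else mask
  tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Plot boundary polygon
#'
#' @param plot_id Plot identifier.
#' @param polygon Two-column matrix of `(x, y)` vertices, world or pixel
#'   coordinates. The ring is closed automatically (first vertex repeated
#'   last) if it is open.
#' @return A `plot_boundary` object.
#' @export
plot_boundary <- function(plot_id, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L) stop_format("`polygon` must have two columns (x, y)")
  if (!all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- rbind(polygon, polygon[1, ])
  if (nrow(polygon) < 4L) stop_format("polygon needs at least 3 distinct vertices")
  structure(list(plot_id = as.character(plot_id), polygon = polygon),
            class = "plot_boundary")
}

#' Read plot boundaries from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a `plot_id`
#' property; only the outer ring is used.
#'
#' @param path Path to a GeoJSON file.
#' @return A list of [plot_boundary()] objects.
#' @export
read_boundaries <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop_format("not a GeoJSON FeatureCollection")
  purrr::map(gj$features, function(f) {
    pid <- f$properties$plot_id
    if (is.null(pid)) stop_validation("feature lacks a 'plot_id' property")
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
    plot_boundary(pid, xy)
  })
}

world_to_pixel <- function(xy, gt) {
  # invert x = x0 + c*a + r*b ; y = y0 + c*d + r*e  (corner convention)
  A <- matrix(c(gt[2], gt[3], gt[5], gt[6]), 2, 2, byrow = TRUE)
  rhs <- t(sweep(xy, 2, c(gt[1], gt[4])))
  t(solve(A, rhs))  # columns (col, row) per point
}

#' Clip individual plots out of an orthomosaic
#'
#' Each boundary yields one image covering the axis-aligned bounding box of
#' its polygon (intersected with the raster extent); pixels whose centers
#' fall outside the polygon are zero-filled. Boundaries in world coordinates
#' are converted through the inverse geotransform when the orthomosaic is
#' georeferenced. A polygon wholly outside the raster produces a warning and
#' a `NULL` entry.
#'
#' @param orthomosaic A [plot_image()] (typically the stitched field map).
#' @param boundaries A list of [plot_boundary()] objects.
#' @return A named list of [plot_image()] (or `NULL`), one per boundary.
#' @export
clip_plots <- function(orthomosaic, boundaries) {
  stopifnot(inherits(orthomosaic, "plot_image"))
  if (inherits(boundaries, "plot_boundary")) boundaries <- list(boundaries)
  H <- dim(orthomosaic$pixels)[1]; W <- dim(orthomosaic$pixels)[2]
  gt <- orthomosaic$geotransform
  out <- purrr::map(boundaries, function(b) {
    poly <- b$polygon
    if (!is.null(gt)) poly <- world_to_pixel(poly, gt)
    # pixel space: x = col, y = row, 0-based corners
    c0 <- max(0L, floor(min(poly[, 1]))); c1 <- min(W - 1L, ceiling(max(poly[, 1])) - 1L)
    r0 <- max(0L, floor(min(poly[, 2]))); r1 <- min(H - 1L, ceiling(max(poly[, 2])) - 1L)
    if (c0 > c1 || r0 > r1) {
      warn(sprintf("plot '%s': boundary lies outside the raster", b$plot_id))
      return(NULL)
    }
    rows <- r0:r1; cols <- c0:c1
    centers <- cbind(rep(cols, each = length(rows)) + 0.5,
                     rep(rows, times = length(cols)) + 0.5)
    inside <- mgcv::in.out(poly, centers)
    sub <- orthomosaic$pixels[rows + 1L, cols + 1L, , drop = FALSE]
    keep <- matrix(inside, nrow = length(rows), ncol = length(cols))
    for (ch in 1:3) sub[, , ch] <- sub[, , ch] * keep
    new_gt <- NULL
    if (!is.null(gt))
      new_gt <- c(gt[1] + c0 * gt[2] + r0 * gt[3], gt[2], gt[3],
                  gt[4] + c0 * gt[5] + r0 * gt[6], gt[5], gt[6])
    plot_image(sub, plot_id = b$plot_id, geotransform = new_gt,
               crs = orthomosaic$crs)
  })
  names(out) <- purrr::map_chr(boundaries, "plot_id")
  out
}

#' Read a ground-truth boll-count table
#'
#' @param path CSV file with header columns `plot_id`, `genotype`,
#'   `boll_count`.
#' @return A tibble with one validated record per plot.
#' @export
read_ground_truth <- function(path) {
  gt <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("plot_id", "genotype", "boll_count")
  missing <- setdiff(required, names(gt))
  if (length(missing))
    stop_validation(sprintf("ground truth is missing column(s): %s",
                            paste(missing, collapse = ", ")))
  gt <- dplyr::mutate(gt, plot_id = as.character(.data$plot_id),
                      genotype = as.character(.data$genotype),
                      boll_count = as.integer(.data$boll_count))
  if (anyDuplicated(gt$plot_id))
    stop_validation("duplicate plot_id in ground-truth table")
  if (anyNA(gt$boll_count) || any(gt$boll_count < 0))
    stop_validation("boll_count must be a non-negative integer")
  gt[required]
}
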