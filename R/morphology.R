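#' Structuring elements for binary morphology
#'
#' Builds the binary footprint used by [erode_mask()] / [dilate_mask()].
#' A `rectangular` element is all ones; an `elliptic` element is the
#' discrete inscribed ellipse, which at 3 x 3 reduces to the 5-pixel
#' cross (center plus 4-neighbors).
#'
#' @param shape `"elliptic"` or `"rectangular"`.
#' @param size `c(rows, cols)`, odd positive integers.
#' @return A `struct_elem` with the 0/1 `footprint` matrix.
#' @export
struct_elem <- function(shape = c("elliptic", "rectangular"), size = c(3, 3)) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L) || any(size %% 2L == 0L))
    stop_validation("size must be two odd positive integers")
  if (shape == "rectangular") {
    fp <- matrix(1L, size[1], size[2])
  } else {
    ry <- (size[1] - 1) / 2; rx <- (size[2] - 1) / 2
    dy <- matrix(rep(-ry:ry, size[2]), size[1])
    dx <- matrix(rep(-rx:rx, each = size[1]), size[1])
    fp <- 1L * ((dy / max(ry, 1))^2 + (dx / max(rx, 1))^2 <= 1)
  }
  structure(list(shape = shape, size = size, footprint = fp),
            class = "struct_elem")
}

se_offsets <- function(se) {
  fp <- se$footprint
  ctr <- (dim(fp) + 1) / 2
  w <- which(fp == 1L, arr.ind = TRUE)
  cbind(dr = w[, 1] - ctr[1], dc = w[, 2] - ctr[2])
}

# shift a matrix by (dr, dc), padding the exposed margin with `fill`
shift_matrix <- function(m, dr, dc, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Binary erosion and dilation
#'
#' Erosion keeps a pixel only when every position covered by the
#' structuring element is foreground, treating positions outside the
#' image as background (so foreground touching the border erodes away).
#' Dilation sets a pixel when any position covered by the reflected
#' element is foreground; positions outside the image are ignored.
#'
#' @param mask 0/1 matrix.
#' @param se A [struct_elem()].
#' @return 0/1 integer matrix of the same dimensions.
#' @export
erode_mask <- function(mask, se = struct_elem("elliptic", c(3, 3))) {
  off <- se_offsets(se)
  out <- matrix(1L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_matrix(mask, -off[i, 1], -off[i, 2], fill = 0L)
  matrix(as.integer(out), nrow(mask))
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, se = struct_elem("rectangular", c(5, 5))) {
  off <- se_offsets(se)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_matrix(mask, off[i, 1], off[i, 2], fill = 0L)
  matrix(as.integer(out), nrow(mask))
}

#' Morphological post-processing of the predicted cotton mask
#'
#' The noise-removal step applied between pixel classification and boll
#' counting: an erosion with a small elliptic element deletes isolated
#' misclassified pixels and thin bright branches, then a dilation with a
#' larger rectangular element closes gaps and consolidates each boll into
#' a solid cluster.
#'
#' @param mask 0/1 matrix of predicted cotton pixels.
#' @param erode_se Erosion element (default 3 x 3 elliptic, the 5-pixel
#'   cross).
#' @param dilate_se Dilation element (default 5 x 5 rectangular).
#' @return 0/1 integer matrix.
#' @export
morph_postprocess <- function(mask,
                              erode_se = struct_elem("elliptic", c(3, 3)),
                              dilate_se = struct_elem("rectangular", c(5, 5))) {
  if (!all(mask %in% c(0, 1))) stop_validation("mask must be binary")
  dilate_mask(erode_mask(mask, erode_se), dilate_se)
}

#' Rasterize per-pixel predictions into a binary mask
#'
#' @param table Feature table rows with 0-based `row`, `col` columns.
#' @param labels Integer predictions in `{0, 1}`, one per row of `table`.
#' @param shape `c(H, W)` of the target mask.
#' @return 0/1 integer matrix with 1 exactly at pixels predicted cotton.
#' @export
labels_to_mask <- function(table, labels, shape) {
  if (nrow(table) != length(labels))
    stop_validation("one label per table row is required")
  if (anyDuplicated(table[c("row", "col")]))
    stop_validation("duplicate (row, col) coordinates")
  if (nrow(table) &&
      (min(table$row) < 0 || min(table$col) < 0 ||
       max(table$row) >= shape[1] || max(table$col) >= shape[2]))
    stop_validation("coordinates out of bounds")
  mask <- matrix(0L, shape[1], shape[2])
  hit <- labels == 1L
  mask[cbind(table$row[hit] + 1L, table$col[hit] + 1L)] <- 1L
  mask
}

#' Count cotton bolls as 8-connected components
#'
#' Labels each maximal 8-connected (Moore-neighborhood) foreground set of
#' the post-processed mask; the number of components is the boll count.
#' Labels are ordered by first encounter in a raster scan (row-major from
#' the top-left), so output is deterministic.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 8 (Moore neighborhood) or 4.
#' @param min_area Components smaller than this many pixels are discarded
#'   (default 1, i.e. no filtering).
#' @return A `boll_count_result`: `binary_mask`, `label_map` (0 =
#'   background), `boll_count`, and a `components` tibble (label, area,
#'   centroid_row, centroid_col, 0-based centroids).
#' @export
count_components <- function(mask, connectivity = 8, min_area = 1L) {
  if (!all(mask %in% c(0, 1))) stop_validation("mask must be binary")
  if (!connectivity %in% c(4, 8)) stop_validation("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask == 1L)
  label_map <- matrix(0L, H, W)
  if (length(fg)) {
    vid <- matrix(0L, H, W)
    vid[fg] <- seq_along(fg)
    offs <- list(c(0, 1), c(1, 0))
    if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
    edges <- purrr::map(offs, function(o) {
      nb <- shift_matrix(vid, -o[1], -o[2], fill = 0L)  # neighbor's id at each cell
      here <- vid[fg]; there <- nb[fg]
      ok <- there > 0L
      cbind(here[ok], there[ok])
    })
    edges <- do.call(rbind, edges)
    g <- igraph::make_graph(as.vector(t(edges)), n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
    # relabel components by raster-scan (row-major) first encounter
    r0 <- (fg - 1L) %% H; c0 <- (fg - 1L) %/% H
    scan_pos <- r0 * W + c0
    first_pos <- tapply(scan_pos, memb, min)
    relabel <- integer(length(first_pos))
    relabel[order(first_pos)] <- seq_along(first_pos)
    label_map[fg] <- relabel[memb]
    if (min_area > 1L) {
      areas <- tabulate(label_map[fg])
      keep <- which(areas >= min_area)
      remap <- integer(length(areas))
      remap[keep] <- seq_along(keep)
      label_map[fg] <- remap[label_map[fg]]
      mask <- 1L * (label_map > 0L)
      fg <- which(mask == 1L)
    }
  }
  comp <- if (length(fg)) {
    lab <- label_map[fg]
    r0 <- (fg - 1L) %% H; c0 <- (fg - 1L) %/% H
    tibble(label = as.integer(names(tapply(lab, lab, length))) * 1L,
           area = as.integer(tapply(seq_along(lab), lab, length)),
           centroid_row = as.numeric(tapply(r0, lab, mean)),
           centroid_col = as.numeric(tapply(c0, lab, mean))) |>
      arrange(.data$label)
  } else {
    tibble(label = integer(), area = integer(),
           centroid_row = numeric(), centroid_col = numeric())
  }
  structure(list(binary_mask = matrix(as.integer(mask), H, W),
                 label_map = label_map,
                 boll_count = nrow(comp),
                 components = comp),
            class = "boll_count_result")
}

#' @export
print.boll_count_result <- function(x, ...) {
  cat(sprintf("<boll_count_result> %d boll(s), %d foreground px on %d x %d\n",
              x$boll_count, sum(x$binary_mask), nrow(x$binary_mask),
              ncol(x$binary_mask)))
  invisible(x)
}

#' @export
tidy.boll_count_result <- function(x, ...) x$components

#' @export
glance.boll_count_result <- function(x, ...) {
  tibble(boll_count = x$boll_count,
         foreground_px = sum(x$binary_mask),
         stage_counts = list(attr(x, "stage_counts")))
}

#' Export a label map as a single-band TIFF
#'
#' Labels are stored as 16-bit intensities (label / 65535), recoverable
#' exactly for up to 65535 components.
#'
#' @param result A [count_components()] result.
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(result, path) {
  stopifnot(inherits(result, "boll_count_result"))
  tiff::writeTIFF(result$label_map / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Render a label map as an RGB visualization
#'
#' Each cluster gets a distinct hue on a black background, matching the
#' usual colored-cluster inspection figure.
#'
#' @param result A [count_components()] result.
#' @param seed Seed for hue shuffling (adjacent labels get distant hues).
#' @return A [plot_image()].
#' @export
label_map_rgb <- function(result, seed = 1L) {
  stopifnot(inherits(result, "boll_count_result"))
  lm <- result$label_map
  k <- result$boll_count
  img <- array(0, c(nrow(lm), ncol(lm), 3))
  if (k > 0) {
    hues <- withr::with_seed(seed, sample(seq(0, 1 - 1 / k, length.out = k)))
    cols <- grDevices::col2rgb(grDevices::hsv(hues, 0.85, 1))
    fg <- which(lm > 0)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fg] <- cols[ch, lm[fg]]
      img[, , ch] <- plane
    }
  }
  plot_image(img, plot_id = "label_map")
}
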