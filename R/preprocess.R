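# Preprocessing: grayscale conversion, grayscale morphology (dilate / erode /
# close), line-closing hair removal, histogram equalization, PSNR.
#
# Morphology uses edge-replicated borders: a window position outside the image
# reads the nearest edge pixel. Implemented as vectorized shift-and-pmax over
# the structuring-element offsets, which is exact (no separable approximation)
# and fast enough for desk-scale rasters.

#' Structuring element for grayscale morphology
#'
#' @param shape `"disk"` (radius `size`) or `"line"` (length `size` at
#'   `angle` degrees).
#' @param size Radius in pixels for disks, length in pixels for lines
#'   (>= 1).
#' @param angle Line orientation in degrees, in \[0, 180); ignored for disks.
#' @return An object of class `struct_elem` carrying the offset set.
#' @export
struct_elem <- function(shape = c("disk", "line"), size, angle = 0) {
  shape <- match.arg(shape)
  if (size < 1) abort("structuring element `size` must be >= 1",
                      class = "dermoknn_validation_error")
  if (shape == "line" && (angle < 0 || angle >= 180)) {
    abort("line `angle` must lie in [0, 180)", class = "dermoknn_validation_error")
  }
  off <- if (shape == "disk") {
    g <- as.matrix(expand.grid(dy = -size:size, dx = -size:size))
    g[g[, 1]^2 + g[, 2]^2 <= size^2, , drop = FALSE]
  } else {
    h <- (size - 1) / 2
    t <- angle * pi / 180
    s <- seq(-h, h, by = 1)
    unique(cbind(dy = round(-s * sin(t)), dx = round(s * cos(t))))
  }
  structure(list(shape = shape, size = size, angle = angle,
                 offsets = matrix(as.integer(off), ncol = 2)),
            class = "struct_elem")
}

# min/max filter over the SE offsets with edge replication
sweep_extremum <- function(img, se, maximum) {
  off <- se$offsets
  m <- max(abs(off))
  H <- nrow(img); W <- ncol(img)
  xp <- pad_replicate(img, m)
  out <- NULL
  pick <- if (maximum) pmax else pmin
  for (k in seq_len(nrow(off))) {
    sub <- xp[(seq_len(H)) + m + off[k, 1], (seq_len(W)) + m + off[k, 2], drop = FALSE]
    out <- if (is.null(out)) sub else pick(out, sub)
  }
  out
}

#' Grayscale dilation
#'
#' Pixel-wise maximum over the structuring element, borders edge-replicated.
#'
#' @param img Gray raster (numeric matrix).
#' @param se A [struct_elem()].
#' @return Gray raster of the same shape.
#' @export
gray_dilate <- function(img, se) {
  assert_gray(img)
  check_se_fits(se, dim(img))
  sweep_extremum(img, se, maximum = TRUE)
}

#' Grayscale erosion
#'
#' Pixel-wise minimum over the structuring element, borders edge-replicated.
#'
#' @inheritParams gray_dilate
#' @return Gray raster of the same shape.
#' @export
gray_erode <- function(img, se) {
  assert_gray(img)
  check_se_fits(se, dim(img))
  sweep_extremum(img, se, maximum = FALSE)
}

check_se_fits <- function(se, d) {
  span <- 2L * max(abs(se$offsets)) + 1L
  if (span > min(d)) {
    abort(sprintf("structuring element (span %d px) is larger than the image (%d x %d)",
                  span, d[1], d[2]),
          class = "dermoknn_validation_error")
  }
}

#' Grayscale morphological closing
#'
#' Dilation followed by erosion with the same structuring element; removes
#' dark structures thinner than the element while leaving larger regions
#' untouched. Borders are edge-replicated.
#'
#' @inheritParams gray_dilate
#' @return Gray raster of the same shape.
#' @examples
#' img <- matrix(200L, 16, 16); img[8, ] <- 40L   # a thin dark line
#' cl <- morphological_close(img, struct_elem("disk", 3))
#' cl[8, 8]   # line filled to local background
#' @export
morphological_close <- function(img, se) {
  assert_gray(img)
  check_se_fits(se, dim(img))
  sweep_extremum(sweep_extremum(img, se, TRUE), se, FALSE)
}

#' Morphological hair removal
#'
#' Takes the pixel-wise maximum over closings with line structuring elements
#' at evenly spaced orientations. A hair is thin across every orientation
#' except its own, so some rotated closing brightens it to the local
#' background; structures wider than the line length (the lesion itself) are
#' preserved.
#'
#' @param img Gray raster.
#' @param line_length Line element length in pixels (default 15, chosen to
#'   exceed typical hair width by an order of magnitude while staying well
#'   below lesion diameters).
#' @param n_angles Number of evenly spaced orientations in \[0, 180) (>= 1).
#' @return Gray raster with thin dark curvilinear structures suppressed.
#' @export
remove_hair <- function(img, line_length = 15, n_angles = 8) {
  assert_gray(img)
  if (n_angles < 1) abort("`n_angles` must be >= 1", class = "dermoknn_validation_error")
  angles <- (seq_len(n_angles) - 1) * 180 / n_angles
  out <- NULL
  for (a in angles) {
    cl <- morphological_close(img, struct_elem("line", line_length, a))
    out <- if (is.null(out)) cl else pmax(out, cl)
  }
  out
}

#' RGB to grayscale conversion
#'
#' Fixed luminance weights `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer.
#'
#' @param img Integer `(H, W, 3)` RGB array in 0..255.
#' @return Integer gray matrix in 0..255.
#' @export
to_grayscale <- function(img) {
  assert_rgb(img)
  g <- matrix(round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]),
              dim(img)[1], dim(img)[2])
  storage.mode(g) <- "integer"
  g
}

#' Histogram equalization
#'
#' Standard CDF remapping of an 8-bit raster onto \[0, 255\]:
#' `v -> round(255 * CDF(v))`. The map is monotone non-decreasing, so pixel
#' rank order is preserved.
#'
#' @param img Integer gray raster in 0..255.
#' @return Integer gray raster in 0..255.
#' @export
equalize_histogram <- function(img) {
  assert_gray(img)
  v <- as.integer(img)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  map <- as.integer(round(cdf * 255))
  out <- matrix(map[v + 1L], nrow(img), ncol(img))
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(255^2 / MSE)` between two gray rasters of equal shape; returns
#' `Inf` when the rasters are identical (MSE = 0).
#'
#' @param reference,test Gray rasters of the same shape.
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, test) {
  assert_gray(reference, "reference"); assert_gray(test, "test")
  if (!identical(dim(reference), dim(test))) {
    abort("`reference` and `test` must have the same shape",
          class = "dermoknn_shape_error")
  }
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Run the full preprocessing chain
#'
#' Grayscale conversion, line-closing hair removal, then histogram
#' equalization. The reported PSNR compares the grayscale input with the
#' fully preprocessed raster, one value per case.
#'
#' @param img RGB array (0..255) or a `lesion_case`.
#' @param config Pipeline configuration, see [dermo_config()].
#' @return List of class `preproc_result` with `gray`, `dehaired`,
#'   `preprocessed` rasters and `psnr_value`.
#' @export
preprocess_image <- function(img, config = dermo_config()) {
  if (inherits(img, "lesion_case")) img <- img$image
  pp <- config$preprocessing
  gray <- to_grayscale(img)
  dehaired <- remove_hair(gray, pp$hair_line_length, pp$hair_n_angles)
  preprocessed <- if (isTRUE(pp$equalize)) equalize_histogram(dehaired) else dehaired
  structure(list(gray = gray, dehaired = dehaired, preprocessed = preprocessed,
                 psnr_value = psnr(gray, preprocessed)),
            class = "preproc_result")
}
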