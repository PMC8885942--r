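# Raster helpers shared across modules. Conventions: gray rasters are integer
# matrices in 0..255; RGB images are integer (H, W, 3) arrays; masks are
# logical matrices. "Raster order" means row-major scan (row 1 left to right,
# then row 2, ...), the usual image convention.

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a single-plane numeric matrix (gray raster).", arg))
  }
  invisible(img)
}

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort(sprintf("`%s` must be a 3-channel (H, W, 3) array.", arg),
          class = "dermoknn_shape_error")
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (is.matrix(mask) && is.numeric(mask) && all(mask %in% c(0, 1))) {
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort(sprintf("`%s` must be a binary (logical) matrix.", arg))
  }
  mask
}

# Row-major linear index of each cell, used wherever a deterministic raster
# scan order is needed (component tie-breaks, component renumbering).
raster_index <- function(H, W) {
  tmpl <- matrix(0L, H, W)
  (row(tmpl) - 1L) * W + col(tmpl)
}

# Clamped (edge-replicating) padding by `m` pixels on every side.
pad_replicate <- function(x, m) {
  H <- nrow(x); W <- ncol(x)
  x[pmin(pmax(seq_len(H + 2L * m) - m, 1L), H),
    pmin(pmax(seq_len(W + 2L * m) - m, 1L), W),
    drop = FALSE]
}

#' Read an RGB lesion image from disk
#'
#' Decodes a PNG, TIFF or JPEG file to an integer `(H, W, 3)` array with
#' values in 0..255. An alpha channel, if present, is dropped; JPEG support
#' requires the optional \pkg{jpeg} package.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return An integer array of dimension `(H, W, 3)`.
#' @export
read_lesion_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image file '%s': no such file", path),
          class = "dermoknn_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      jpg = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE)) {
          abort("JPEG input needs the 'jpeg' package.", class = "dermoknn_io_error")
        }
        jpeg::readJPEG(path)
      },
      abort(sprintf("unsupported image extension '%s' for '%s'", ext, path),
            class = "dermoknn_io_error")
    ),
    error = function(e) {
      abort(sprintf("cannot read image file '%s': %s", path, conditionMessage(e)),
            class = "dermoknn_io_error")
    }
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  img <- round(raw * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write a raster to a PNG file
#'
#' Gray rasters and RGB arrays are written as 8-bit PNG; logical masks are
#' written as 0/255.
#'
#' @param x Integer raster (matrix or `(H, W, 3)` array) in 0..255, or a
#'   logical mask.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.integer(x) * 255L, nrow(x), ncol(x))
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical masks of the same shape.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- assert_mask(a, "a"); b <- assert_mask(b, "b")
  if (!identical(dim(a), dim(b))) abort("masks must have the same shape")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
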