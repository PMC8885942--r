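# Segmentation: adaptive (local-mean) thresholding plus minimal cleanup.
#
# The local threshold at each pixel is the mean over a square window
# (edge-replicated) shifted by `offset` gray levels. Lesions are darker than
# the surrounding skin, so the default polarity marks pixels *below*
# mean - offset as foreground. Comparisons are done on integer-scaled sums
# (value * window^2 vs window sum - offset * window^2), which is exact and
# makes the mask strictly invariant under image inversion + polarity flip.

#' Adaptive mean thresholding
#'
#' @param img Integer gray raster.
#' @param window Odd window side length in pixels; default
#'   `2 * floor(min(H, W) / 8) + 1`, chosen to exceed hair widths but stay
#'   below lesion diameters.
#' @param offset Threshold offset in gray levels.
#' @param polarity `"dark_foreground"` (pixel < local mean - offset) or
#'   `"bright_foreground"` (pixel > local mean + offset).
#' @return Logical lesion mask.
#' @export
adaptive_threshold <- function(img, window = NULL, offset = 10,
                               polarity = c("dark_foreground", "bright_foreground")) {
  assert_gray(img)
  polarity <- match.arg(polarity)
  H <- nrow(img); W <- ncol(img)
  if (is.null(window)) window <- 2L * (min(H, W) %/% 8L) + 1L
  if (window %% 2 == 0) {
    abort("`window` must be odd", class = "dermoknn_validation_error")
  }
  if (window < 3 || window > min(H, W)) {
    abort("`window` must be >= 3 and <= min(H, W)", class = "dermoknn_validation_error")
  }
  r <- (window - 1L) / 2
  xp <- pad_replicate(img, r)
  # summed-area table with a leading zero row/column
  S <- matrix(0, nrow(xp) + 1L, ncol(xp) + 1L)
  S[-1, -1] <- apply(apply(xp, 2, cumsum), 1, cumsum) |> t()
  i1 <- seq_len(H); j1 <- seq_len(W)
  win_sum <- S[i1 + window, j1 + window] - S[i1, j1 + window] -
    S[i1 + window, j1] + S[i1, j1]
  w2 <- as.numeric(window)^2
  if (polarity == "dark_foreground") {
    img * w2 < win_sum - offset * w2
  } else {
    img * w2 > win_sum + offset * w2
  }
}

# One top-down minimum-label sweep: each row takes the minimum of itself and
# its (already swept) predecessor row, diagonals included for 8-connectivity.
# Sequential in rows, vectorized within a row, so a label travels the whole
# way down in one pass.
sweep_down <- function(ids, mask, conn8) {
  H <- nrow(ids); W <- ncol(ids)
  if (H < 2L) return(ids)
  for (i in 2:H) {
    prev <- ids[i - 1L, ]
    cand <- if (conn8) pmin(prev, c(Inf, prev[-W]), c(prev[-1L], Inf)) else prev
    upd <- mask[i, ] & cand < ids[i, ]
    if (any(upd)) ids[i, upd] <- pmin(ids[i, upd], cand[upd])
  }
  ids
}

#' Label connected components of a binary mask
#'
#' Minimum-label propagation by alternating down/right/up/left raster sweeps
#' until a fixed point; labels are renumbered so that component 1 contains
#' the first foreground pixel in raster (row-major) scan order, component 2
#' the next unlabeled one, and so on.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default) neighbor connectivity.
#' @return Integer matrix; 0 for background, 1..n_components for foreground.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- assert_mask(mask)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  conn8 <- connectivity == 8
  ids <- matrix(Inf, H, W)
  ids[mask] <- raster_index(H, W)[mask]
  rv <- function(m) m[nrow(m):1, , drop = FALSE]
  tm <- t(mask)
  repeat {
    old <- ids
    ids <- sweep_down(ids, mask, conn8)                            # down
    ids <- t(sweep_down(t(ids), tm, conn8))                        # right
    ids <- rv(sweep_down(rv(ids), rv(mask), conn8))                # up
    ids <- t(rv(sweep_down(rv(t(ids)), rv(tm), conn8)))            # left
    if (identical(ids, old)) break
  }
  reps <- sort(unique(ids[mask]))
  lab <- matrix(0L, H, W)
  lab[mask] <- match(ids[mask], reps)
  lab
}

#' Keep only the largest connected component
#'
#' Ties in component size are broken in favor of the component whose first
#' pixel comes earliest in raster scan order. An empty input mask is returned
#' unchanged with a warning.
#'
#' @inheritParams label_components
#' @return Logical mask holding a single component (or empty).
#' @export
largest_component <- function(mask, connectivity = 8) {
  mask <- assert_mask(mask)
  if (!any(mask)) {
    warn("mask is empty: no component to keep", class = "dermoknn_empty_mask")
    return(mask)
  }
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  # labels are already in raster-scan order of first appearance, so the first
  # maximal label is the raster-earliest among ties
  keep <- which.max(sizes)
  lab == keep
}

#' Segment the lesion from a preprocessed raster
#'
#' Adaptive thresholding followed by largest-component selection. Interior
#' holes are deliberately left open: enclosed-background pixel counts are
#' downstream features.
#'
#' @param img Preprocessed integer gray raster.
#' @param window,offset,polarity Passed to [adaptive_threshold()].
#' @param connectivity Foreground connectivity for component selection.
#' @return Logical lesion mask with exactly one connected component.
#' @export
segment_lesion <- function(img, window = NULL, offset = 10,
                           polarity = "dark_foreground", connectivity = 8) {
  th <- adaptive_threshold(img, window = window, offset = offset,
                           polarity = polarity)
  if (!any(th)) {
    abort("no lesion detected: adaptive threshold produced an empty mask",
          class = "dermoknn_no_lesion",
          window = window %||% 2L * (min(dim(img)) %/% 8L) + 1L,
          offset = offset, polarity = polarity, n_candidate_px = 0L)
  }
  largest_component(th, connectivity)
}
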