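# Lesion descriptors: the frozen feature vector feeding the KNN classifier.
#
# The order below is the package's canonical, serialization-stable feature
# order. The first 17 names form the classifier feature space; `psnr_value`
# (preprocessing fidelity) is carried in every feature table for reporting
# but excluded from the distance computation, since it describes the
# preprocessing stage, not the lesion, and is +Inf for a noise-free case.

FEATURE_ORDER <- c(
  "mean_fft", "std_intensity", "hist_mean", "hist_std",
  "area_count", "hole_count", "log_area", "log_hole",
  "asymmetry_index", "compactness_index", "diameter",
  "color_mean_r", "color_mean_g", "color_mean_b",
  "color_std_r", "color_std_g", "color_std_b"
)

#' The frozen feature order
#'
#' @param include_psnr Append `psnr_value` (reported but not used as a
#'   classifier input).
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(include_psnr = FALSE) {
  if (include_psnr) c(FEATURE_ORDER, "psnr_value") else FEATURE_ORDER
}

#' Whole-image mean via the discrete Fourier transform
#'
#' Real part of the zero-frequency (DC) coefficient of the 2-D DFT divided by
#' the pixel count; mathematically identical to the arithmetic mean.
#'
#' @param img Gray raster.
#' @return Mean intensity in gray levels.
#' @export
mean_via_fft <- function(img) {
  assert_gray(img)
  Re(fft(matrix(as.numeric(img), nrow(img)))[1, 1]) / length(img)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Within-mask intensity statistics
#'
#' `std_intensity` is the population standard deviation of the masked pixels;
#' `hist_mean` / `hist_std` are recomputed through the 256-bin integer
#' histogram with bin centers 0..255, which for 8-bit integer input equals the
#' direct statistics exactly.
#'
#' @param img Integer gray raster.
#' @param mask Logical mask (non-empty).
#' @return Named list: `std_intensity`, `hist_mean`, `hist_std`.
#' @export
masked_stats <- function(img, mask) {
  assert_gray(img); mask <- assert_mask(mask)
  v <- as.integer(img[mask])
  if (length(v) == 0L) abort("mask is empty", class = "dermoknn_validation_error")
  counts <- tabulate(v + 1L, nbins = 256L)
  centers <- 0:255
  n <- length(v)
  hm <- sum(centers * counts) / n
  list(std_intensity = pop_sd(v),
       hist_mean = hm,
       hist_std = sqrt(sum(counts * (centers - hm)^2) / n))
}

#' Area and enclosed-hole pixel counts
#'
#' `area_count` is the number of foreground pixels. `hole_count` is the number
#' of background pixels not reachable from the image border by 4-connected
#' background flood fill -- the standard dual connectivity when foreground
#' components use 8-connectivity.
#'
#' @param mask Logical mask.
#' @return Named list: `area_count`, `hole_count`.
#' @export
area_and_holes <- function(mask) {
  mask <- assert_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, H, W)
  reach[1, ] <- bg[1, ]; reach[H, ] <- bg[H, ]
  reach[, 1] <- bg[, 1]; reach[, W] <- bg[, W]
  # 4-connected flood from the border through background, as alternating
  # directional sweeps to a fixed point
  sweep_reach <- function(reach, bg) {
    if (nrow(reach) < 2L) return(reach)
    for (i in 2:nrow(reach)) {
      reach[i, ] <- reach[i, ] | (reach[i - 1L, ] & bg[i, ])
    }
    reach
  }
  rv <- function(m) m[nrow(m):1, , drop = FALSE]
  tbg <- t(bg)
  repeat {
    old <- reach
    reach <- sweep_reach(reach, bg)
    reach <- t(sweep_reach(t(reach), tbg))
    reach <- rv(sweep_reach(rv(reach), rv(bg)))
    reach <- t(rv(sweep_reach(rv(t(reach)), rv(tbg))))
    if (identical(reach, old)) break
  }
  list(area_count = sum(mask), hole_count = sum(bg & !reach))
}

mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Principal-axis asymmetry index
#'
#' Reflects the mask about each of its two principal axes (eigenvectors of the
#' second-order central moments through the centroid) and reports the mean
#' relative non-overlap: `AI = (D1 + D2) / (2 A)`, where `Di` is the XOR pixel
#' count between the mask and its reflection about axis i. 0 for a perfectly
#' symmetric shape, clamped to \[0, 1\].
#'
#' @param mask Logical mask with at least 4 foreground pixels.
#' @return Asymmetry index in \[0, 1\].
#' @export
asymmetry_index <- function(mask) {
  mask <- assert_mask(mask)
  P <- mask_coords(mask)
  n <- nrow(P)
  if (n < 4L) abort("asymmetry index needs >= 4 foreground pixels",
                    class = "dermoknn_validation_error")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  cv <- crossprod(Q) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-9 * eg$values[1]) {
    abort("degenerate (collinear) mask: principal axes undefined",
          class = "dermoknn_validation_error")
  }
  key <- function(M) M[, 1] * 2^20 + M[, 2]
  A_keys <- key(round(Q))
  xor_count <- function(v) {
    # reflection about the line through the centroid with direction v
    proj <- Q %*% v
    Rf <- round(2 * proj %*% t(v) - Q)
    B_keys <- unique(key(Rf))
    sum(!(A_keys %in% B_keys)) + sum(!(B_keys %in% A_keys))
  }
  d1 <- xor_count(eg$vectors[, 1])
  d2 <- xor_count(eg$vectors[, 2])
  min(1, max(0, (d1 + d2) / (2 * n)))
}

# Moore-neighbor boundary trace of the (single) 8-connected component holding
# the raster-first foreground pixel. Returns the closed contour as a matrix of
# (row, col) pixel coordinates (pixels a 1-px-wide arm is traversed along
# appear once per pass, as perimeter measurement requires); a single isolated
# pixel gives a 1-row contour. Terminates when the walk leaves the start pixel
# in the same direction as the first move.
trace_contour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- matrix(FALSE, H + 2L, W + 2L)
  m[2:(H + 1), 2:(W + 1)] <- mask
  ri <- raster_index(H + 2L, W + 2L)
  start_idx <- min(ri[m])
  start <- c((start_idx - 1L) %/% (W + 2L) + 1L,
             (start_idx - 1L) %% (W + 2L) + 1L)
  # clockwise Moore neighborhood starting west, for an image with row 1 on top
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  path <- matrix(0L, 8L * sum(m) + 1L, 2L)
  path[1, ] <- start
  n_path <- 1L
  cur <- start
  kb <- 1L            # scan starts at the backtrack neighbor (west of start)
  first_move <- NA_integer_
  repeat {
    move <- NA_integer_
    for (d in 0:7) {
      k <- ((kb - 1L + d) %% 8L) + 1L
      if (m[cur[1] + nb[k, 1], cur[2] + nb[k, 2]]) {
        move <- k
        before <- ((k - 2L) %% 8L) + 1L   # last background neighbor examined
        break
      }
    }
    if (is.na(move)) break                               # isolated pixel
    if (!is.na(first_move) && all(cur == start) && move == first_move) break
    if (is.na(first_move)) first_move <- move
    newcur <- cur + nb[move, ]
    # backtrack pixel expressed relative to the new current pixel
    rel <- nb[before, ] - nb[move, ]
    kb <- which(nb[, 1] == rel[1] & nb[, 2] == rel[2])
    cur <- newcur
    n_path <- n_path + 1L
    path[n_path, ] <- cur
    if (n_path == nrow(path)) break                      # safety cap
  }
  contour <- path[seq_len(n_path), , drop = FALSE]
  contour[, 1] <- contour[, 1] - 1L
  contour[, 2] <- contour[, 2] - 1L
  contour
}

#' Compactness index
#'
#' `P^2 / (4 pi A)`, where the perimeter `P` is measured along the
#' 8-connected outer contour with unit steps for axial moves and `sqrt(2)`
#' for diagonal moves. Equals 1 for a perfect disk (rasterization inflates it
#' slightly) and grows with border irregularity.
#'
#' @param mask Logical single-component mask with at least 4 foreground
#'   pixels.
#' @return Compactness index (dimensionless, >= ~1).
#' @export
compactness_index <- function(mask) {
  mask <- assert_mask(mask)
  A <- sum(mask)
  if (A < 4L) abort("compactness index needs >= 4 foreground pixels",
                    class = "dermoknn_validation_error")
  ct <- trace_contour(mask)
  if (nrow(ct) < 2L) return(0)
  steps <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
  lens <- ifelse(rowSums(abs(steps)) == 2L, sqrt(2), 1)
  lens[rowSums(abs(steps)) == 0L] <- 0
  P <- sum(lens)
  P^2 / (4 * pi * A)
}

boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  inner <- pad[2:(H + 1), 2:(W + 1)]
  has_bg_nb <- !pad[1:H, 2:(W + 1)] | !pad[3:(H + 2), 2:(W + 1)] |
    !pad[2:(H + 1), 1:W] | !pad[2:(H + 1), 3:(W + 2)]
  inner & has_bg_nb
}

#' Maximum Feret diameter
#'
#' Largest pairwise Euclidean distance between boundary-pixel centers,
#' computed over the convex hull of the boundary (identical to the all-pairs
#' maximum, but cheap).
#'
#' @param mask Logical mask with at least 1 foreground pixel.
#' @return Diameter in pixels (0 for a single pixel).
#' @export
lesion_diameter <- function(mask) {
  mask <- assert_mask(mask)
  if (!any(mask)) abort("mask is empty", class = "dermoknn_validation_error")
  bp <- mask_coords(boundary_pixels(mask))
  if (nrow(bp) < 2L) return(0)
  hull <- bp[chull(bp[, 1], bp[, 2]), , drop = FALSE]
  d2 <- outer(seq_len(nrow(hull)), seq_len(nrow(hull)), function(i, j) {
    (hull[i, 1] - hull[j, 1])^2 + (hull[i, 2] - hull[j, 2])^2
  })
  sqrt(max(d2))
}

#' Within-mask color statistics
#'
#' Per-channel mean and population standard deviation over the masked pixels,
#' in channel order R, G, B.
#'
#' @param img Integer RGB array.
#' @param mask Logical non-empty mask.
#' @return Named list of six values: `color_mean_r/g/b`, `color_std_r/g/b`.
#' @export
color_features <- function(img, mask) {
  assert_rgb(img); mask <- assert_mask(mask)
  if (!any(mask)) abort("mask is empty", class = "dermoknn_validation_error")
  out <- list()
  chn <- c("r", "g", "b")
  for (ch in 1:3) {
    v <- img[, , ch][mask]
    out[[paste0("color_mean_", chn[ch])]] <- mean(v)
    out[[paste0("color_std_", chn[ch])]] <- pop_sd(v)
  }
  out
}

#' Assemble the full feature vector for one case
#'
#' Combines the statistical, shape and color descriptors into a one-row
#' tibble in the canonical order of [feature_names()], plus `psnr_value`
#' (gray vs fully preprocessed raster). `mean_fft` is computed on the whole
#' preprocessed raster; the within-mask information is carried by the masked
#' statistics.
#'
#' @param raw Integer RGB array (the undegraded input image).
#' @param gray Integer gray raster (before hair removal / equalization).
#' @param preprocessed Integer gray raster after the preprocessing chain.
#' @param mask Logical lesion mask.
#' @return A one-row tibble with 18 numeric columns.
#' @export
extract_features <- function(raw, gray, preprocessed, mask) {
  assert_rgb(raw); assert_gray(gray); assert_gray(preprocessed)
  mask <- assert_mask(mask)
  if (!identical(dim(gray), dim(preprocessed)) ||
      !identical(dim(gray), dim(mask)) ||
      !identical(dim(raw)[1:2], dim(gray))) {
    abort("stage rasters must agree in shape", class = "dermoknn_shape_error")
  }
  ms <- masked_stats(preprocessed, mask)
  ah <- area_and_holes(mask)
  cf <- color_features(raw, mask)
  out <- tibble(
    mean_fft = mean_via_fft(preprocessed),
    std_intensity = ms$std_intensity,
    hist_mean = ms$hist_mean,
    hist_std = ms$hist_std,
    area_count = ah$area_count,
    hole_count = ah$hole_count,
    log_area = log1p(ah$area_count),
    log_hole = log1p(ah$hole_count),
    asymmetry_index = asymmetry_index(mask),
    compactness_index = compactness_index(mask),
    diameter = lesion_diameter(mask),
    color_mean_r = cf$color_mean_r,
    color_mean_g = cf$color_mean_g,
    color_mean_b = cf$color_mean_b,
    color_std_r = cf$color_std_r,
    color_std_g = cf$color_std_g,
    color_std_b = cf$color_std_b,
    psnr_value = psnr(gray, preprocessed)
  )
  out[, feature_names(include_psnr = TRUE)]
}
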