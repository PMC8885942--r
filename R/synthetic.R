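# Synthetic dermoscopic-style lesion images with ground-truth masks.
#
# Lesion geometry is a star-convex radial-harmonic blob:
#   r(theta) = R * (1 + A * sum_{k=2,3}  a_k sin(k theta + phi_k)
#                     + B * sum_{k=8..12} b_k sin(k theta + psi_k))
# Low harmonics (k = 2, 3) break mirror symmetry ("A" of the ABCD rule), high
# harmonics (k = 8..12) make the border irregular ("B"). The per-seed
# coefficients a_k, b_k are normalized so the asymmetry term perturbs the
# radius by at most ASYM_AMP and the irregularity term by at most IRR_AMP,
# keeping the blob star-convex and inside the frame for any levels in [0, 1].

ASYM_AMP <- 0.35
IRR_AMP <- 0.25

#' Specification of one synthetic lesion image
#'
#' Collects the generative parameters for a single dermoscopic-style image:
#' label, geometry (radius plus low/high radial-harmonic amplitudes), lesion
#' and skin colors, hair-artifact parameters, sensor noise, and the seed that
#' makes the render bit-reproducible.
#'
#' @param label Class label, `0` (normal) or `1` (melanoma).
#' @param image_size Integer `(H, W)` in pixels.
#' @param center Lesion center `(row, col)`; defaults to the image center.
#' @param base_radius Mean lesion radius in pixels (>= 4).
#' @param asymmetry_level Amplitude in \[0, 1\] of the low-order (k = 2, 3)
#'   radial harmonics that break mirror symmetry.
#' @param border_irregularity Amplitude in \[0, 1\] of the high-order
#'   (k = 8..12) radial harmonics that roughen the border.
#' @param lesion_colors List of 1--4 RGB triplets (0..255) mixed across the
#'   lesion.
#' @param color_weights Mixing weights, one per color; defaults to equal.
#' @param skin_color RGB triplet of the background skin.
#' @param hair_count Number of dark hair-line segments drawn over the image.
#' @param hair_width Hair stroke width in pixels.
#' @param noise_sigma Standard deviation (gray levels) of additive Gaussian
#'   noise applied per channel after drawing.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   render.
#' @return A validated object of class `lesion_spec`.
#' @seealso [generate_lesion_image()], [generate_dataset()]
#' @export
lesion_spec <- function(label = 1L,
                        image_size = c(256L, 256L),
                        center = NULL,
                        base_radius = 30,
                        asymmetry_level = 0.3,
                        border_irregularity = 0.3,
                        lesion_colors = list(c(110, 70, 50), c(150, 100, 70)),
                        color_weights = NULL,
                        skin_color = c(225, 185, 160),
                        hair_count = 3L,
                        hair_width = 2,
                        noise_sigma = 4,
                        seed = 1L) {
  if (is.null(center)) center <- floor((image_size + 1) / 2)
  if (is.null(color_weights)) {
    color_weights <- rep(1, length(lesion_colors)) / length(lesion_colors)
  }
  spec <- structure(
    list(label = as.integer(label), image_size = as.integer(image_size),
         center = as.numeric(center), base_radius = base_radius,
         asymmetry_level = asymmetry_level,
         border_irregularity = border_irregularity,
         lesion_colors = lapply(lesion_colors, as.numeric),
         color_weights = color_weights / sum(color_weights),
         skin_color = as.numeric(skin_color),
         hair_count = as.integer(hair_count), hair_width = hair_width,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "lesion_spec")
  validate_lesion_spec(spec)
  spec
}

validate_lesion_spec <- function(spec) {
  bad <- function(field, why) {
    abort(sprintf("invalid lesion spec: field `%s` %s", field, why),
          class = "dermoknn_validation_error")
  }
  if (!spec$label %in% c(0L, 1L)) bad("label", "must be 0 (normal) or 1 (melanoma)")
  if (length(spec$image_size) != 2L || any(spec$image_size < 16L)) {
    bad("image_size", "must be (H, W) with both >= 16")
  }
  if (spec$base_radius < 4) bad("base_radius", "must be >= 4")
  if (spec$asymmetry_level < 0 || spec$asymmetry_level > 1) {
    bad("asymmetry_level", "must lie in [0, 1]")
  }
  if (spec$border_irregularity < 0 || spec$border_irregularity > 1) {
    bad("border_irregularity", "must lie in [0, 1]")
  }
  # worst-case radius under the normalized harmonic amplitudes
  rmax <- spec$base_radius *
    (1 + ASYM_AMP * spec$asymmetry_level + IRR_AMP * spec$border_irregularity)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  if (spec$center[1] - rmax < 3 || spec$center[1] + rmax > H - 2 ||
      spec$center[2] - rmax < 3 || spec$center[2] + rmax > W - 2) {
    bad("center", "places the lesion closer than 2 px to the image border")
  }
  nc <- length(spec$lesion_colors)
  if (nc < 1L || nc > 4L) bad("lesion_colors", "must hold 1-4 RGB triplets")
  cols <- do.call(rbind, spec$lesion_colors)
  if (ncol(cols) != 3L || any(cols < 0) || any(cols > 255)) {
    bad("lesion_colors", "entries must be RGB triplets in [0, 255]")
  }
  if (length(spec$skin_color) != 3L || any(spec$skin_color < 0) ||
      any(spec$skin_color > 255)) {
    bad("skin_color", "must be an RGB triplet in [0, 255]")
  }
  lum <- c(0.299, 0.587, 0.114)
  lesion_lum <- sum(spec$color_weights * (cols %*% lum))
  if (lesion_lum >= sum(spec$skin_color * lum)) {
    bad("lesion_colors", "mean luminance must be strictly below the skin luminance")
  }
  if (spec$hair_count < 0L) bad("hair_count", "must be >= 0")
  if (spec$hair_width < 1) bad("hair_width", "must be >= 1 px")
  if (spec$noise_sigma < 0) bad("noise_sigma", "must be >= 0")
  invisible(spec)
}

#' Render one synthetic lesion image with its ground-truth mask
#'
#' Draws a star-convex radial-harmonic lesion on a flat skin background,
#' freezes the ground-truth mask, then overlays dark hair-line segments and
#' additive Gaussian noise. Hairs and noise are applied *after* the mask is
#' frozen, so hair-removal and segmentation quality can be scored against
#' truth.
#'
#' @param spec A [lesion_spec()].
#' @return A list of class `lesion_case` with elements `image` (integer
#'   `(H, W, 3)` array), `mask` (logical matrix, the pre-noise lesion region),
#'   `label` and `spec`.
#' @examples
#' case <- generate_lesion_image(lesion_spec(seed = 7))
#' sum(case$mask)
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  validate_lesion_spec(spec)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cy <- spec$center[1]; cx <- spec$center[2]

  withr::with_seed(spec$seed, {
    # per-seed harmonic coefficients (always drawn, so the lesion geometry for
    # a given seed does not depend on which amplitudes are switched off)
    a_k <- runif(2, 0.3, 1); a_k <- a_k / sum(a_k) * ASYM_AMP
    phi_a <- runif(2, 0, 2 * pi)
    b_k <- runif(5, 0.3, 1); b_k <- b_k / sum(b_k) * IRR_AMP
    phi_b <- runif(5, 0, 2 * pi)

    dy <- matrix(seq_len(H) - cy, H, W)
    dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
    theta <- atan2(dy, dx)
    dist <- sqrt(dy^2 + dx^2)

    pert <- matrix(0, H, W)
    if (spec$asymmetry_level > 0) {
      for (i in 1:2) pert <- pert + spec$asymmetry_level * a_k[i] * sin((i + 1) * theta + phi_a[i])
    }
    if (spec$border_irregularity > 0) {
      for (i in 1:5) pert <- pert + spec$border_irregularity * b_k[i] * sin((i + 7) * theta + phi_b[i])
    }
    mask <- dist <= spec$base_radius * (1 + pert)

    img <- array(rep(spec$skin_color, each = H * W), c(H, W, 3))
    nc <- length(spec$lesion_colors)
    if (nc == 1L) {
      col <- spec$lesion_colors[[1]]
      for (ch in 1:3) { pl <- img[, , ch]; pl[mask] <- col[ch]; img[, , ch] <- pl }
    } else {
      # smooth color variegation: soft blend toward per-color anchor points
      ang <- runif(nc, 0, 2 * pi)
      rad <- runif(nc, 0, 0.6) * spec$base_radius
      sy <- cy + rad * sin(ang); sx <- cx + rad * cos(ang)
      tau <- spec$base_radius / 1.5
      wsum <- matrix(0, H, W)
      acc <- array(0, c(H, W, 3))
      for (i in seq_len(nc)) {
        d2 <- (dy - (sy[i] - cy))^2 + (dx - (sx[i] - cx))^2
        wf <- spec$color_weights[i] * exp(-d2 / (2 * tau^2))
        wsum <- wsum + wf
        for (ch in 1:3) acc[, , ch] <- acc[, , ch] + wf * spec$lesion_colors[[i]][ch]
      }
      for (ch in 1:3) {
        pl <- img[, , ch]; blend <- acc[, , ch] / wsum
        pl[mask] <- blend[mask]; img[, , ch] <- pl
      }
    }

    if (spec$hair_count > 0L) {
      for (h in seq_len(spec$hair_count)) {
        my <- runif(1, 1, H); mx <- runif(1, 1, W)
        ang <- runif(1, 0, pi)
        len <- runif(1, 0.4, 0.9) * min(H, W)
        ay <- my - len / 2 * sin(ang); ax <- mx - len / 2 * cos(ang)
        by <- my + len / 2 * sin(ang); bx <- mx + len / 2 * cos(ang)
        hair_col <- pmax(0, c(45, 35, 25) + runif(3, -10, 10))
        vy <- by - ay; vx <- bx - ax
        tt <- ((dy + cy - ay) * vy + (dx + cx - ax) * vx) / (vy^2 + vx^2)
        tt <- pmin(pmax(tt, 0), 1)
        d <- sqrt((dy + cy - (ay + tt * vy))^2 + (dx + cx - (ax + tt * vx))^2)
        on_hair <- d <= spec$hair_width / 2
        for (ch in 1:3) { pl <- img[, , ch]; pl[on_hair] <- hair_col[ch]; img[, , ch] <- pl }
      }
    }

    if (spec$noise_sigma > 0) {
      img <- img + array(rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"

    structure(list(image = img, mask = mask, label = spec$label, spec = spec),
              class = "lesion_case")
  })
}

#' Per-class generative profiles for the synthetic dataset
#'
#' Defaults encode the intended class contrast: melanoma-like lesions are
#' stochastically larger, more asymmetric, more border-irregular and more
#' color-variegated than normal ones, on a shared light-skin background, with
#' the same hair and noise nuisance levels in both classes.
#'
#' @return A list with elements `normal` and `malignant`, each a list of
#'   sampling ranges over [lesion_spec()] fields.
#' @export
default_profiles <- function() {
  list(
    normal = list(
      base_radius = c(18, 30),
      asymmetry_level = c(0.05, 0.30),
      border_irregularity = c(0.05, 0.30),
      n_colors = c(1L, 2L),
      color_low = c(120, 75, 55), color_high = c(175, 125, 95),
      hair_count = c(0L, 4L), hair_width = 2, noise_sigma = 4
    ),
    malignant = list(
      base_radius = c(32, 48),
      asymmetry_level = c(0.50, 0.90),
      border_irregularity = c(0.50, 0.90),
      n_colors = c(2L, 4L),
      color_low = c(55, 30, 20), color_high = c(160, 110, 90),
      hair_count = c(0L, 4L), hair_width = 2, noise_sigma = 4
    )
  )
}

sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Draw one lesion_spec from a per-class profile. All randomness comes from
# `seed`; the render seed is drawn inside the same stream.
draw_spec <- function(label, prof, image_size, seed) {
  withr::with_seed(seed, {
    radius <- runif(1, prof$base_radius[1], prof$base_radius[2])
    rmax <- radius * (1 + ASYM_AMP + IRR_AMP)
    slack <- pmax(0, floor(min(image_size) / 2 - rmax - 3))
    center <- floor((image_size + 1) / 2) + round(runif(2, -1, 1) * min(slack, 10))
    nc <- sample_range(prof$n_colors[1], prof$n_colors[2])
    cols <- lapply(seq_len(nc), function(i) {
      runif(3, prof$color_low, prof$color_high)
    })
    lesion_spec(
      label = label, image_size = image_size, center = center,
      base_radius = radius,
      asymmetry_level = runif(1, prof$asymmetry_level[1], prof$asymmetry_level[2]),
      border_irregularity = runif(1, prof$border_irregularity[1], prof$border_irregularity[2]),
      lesion_colors = cols,
      color_weights = runif(nc, 0.5, 1),
      hair_count = sample_range(prof$hair_count[1], prof$hair_count[2]),
      hair_width = prof$hair_width,
      noise_sigma = prof$noise_sigma,
      seed = sample.int(2147483646L, 1)
    )
  })
}

#' Generate a labeled synthetic dataset
#'
#' Draws per-class lesion specifications from a profile and renders each one.
#' The default sizes mirror a 40 + 40 training collection (40 melanoma,
#' label 1, and 40 normal, label 0). Output order is deterministic: all normal
#' cases first, then all malignant ones.
#'
#' @param n_normal,n_malignant Number of cases per class (>= 0).
#' @param profile Per-class parameter ranges, as from [default_profiles()].
#' @param image_size Integer `(H, W)` for every image.
#' @param seed Integer seed controlling the whole dataset.
#' @return A tibble with one row per case: `id`, `label`, `seed`, the drawn
#'   spec fields, and list-columns `spec`, `image`, `mask`.
#' @examples
#' ds <- generate_dataset(2, 2, seed = 1)
#' ds$label
#' @export
generate_dataset <- function(n_normal = 40L, n_malignant = 40L,
                             profile = default_profiles(),
                             image_size = c(256L, 256L), seed = 1L) {
  stopifnot(n_normal >= 0L, n_malignant >= 0L)
  n <- n_normal + n_malignant
  if (n == 0L) {
    return(tibble(id = integer(), label = integer(), seed = integer(),
                  base_radius = numeric(), asymmetry_level = numeric(),
                  border_irregularity = numeric(), n_colors = integer(),
                  hair_count = integer(), hair_width = numeric(),
                  noise_sigma = numeric(), spec = list(), image = list(),
                  mask = list()))
  }
  labels <- c(rep(0L, n_normal), rep(1L, n_malignant))
  item_seeds <- withr::with_seed(seed, sample.int(2147483646L, n))
  cases <- purrr::map(seq_len(n), function(i) {
    prof <- if (labels[i] == 0L) profile$normal else profile$malignant
    sp <- draw_spec(labels[i], prof, as.integer(image_size), item_seeds[i])
    generate_lesion_image(sp)
  })
  tibble(
    id = seq_len(n),
    label = labels,
    seed = vapply(cases, function(cs) cs$spec$seed, integer(1)),
    base_radius = vapply(cases, function(cs) cs$spec$base_radius, numeric(1)),
    asymmetry_level = vapply(cases, function(cs) cs$spec$asymmetry_level, numeric(1)),
    border_irregularity = vapply(cases, function(cs) cs$spec$border_irregularity, numeric(1)),
    n_colors = vapply(cases, function(cs) length(cs$spec$lesion_colors), integer(1)),
    hair_count = vapply(cases, function(cs) cs$spec$hair_count, integer(1)),
    hair_width = vapply(cases, function(cs) cs$spec$hair_width, numeric(1)),
    noise_sigma = vapply(cases, function(cs) cs$spec$noise_sigma, numeric(1)),
    spec = purrr::map(cases, "spec"),
    image = purrr::map(cases, "image"),
    mask = purrr::map(cases, "mask")
  )
}

#' Write a generated dataset to disk
#'
#' Writes each image as 8-bit RGB PNG, each mask as a 0/255 PNG, and a
#' `manifest.csv` with columns `file`, `mask_file`, `label`, `seed` and the
#' drawn spec fields (colors serialized as semicolon-separated hex strings).
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_lesion_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("case_%03d.png", dataset$id)
  mask_files <- sprintf("case_%03d_mask.png", dataset$id)
  purrr::walk(seq_len(nrow(dataset)), function(i) {
    write_image_png(dataset$image[[i]], file.path(dir, files[i]))
    write_image_png(dataset$mask[[i]], file.path(dir, mask_files[i]))
  })
  hexcols <- vapply(dataset$spec, function(sp) {
    paste(vapply(sp$lesion_colors,
                 function(cc) rgb(cc[1], cc[2], cc[3], maxColorValue = 255),
                 character(1)), collapse = ";")
  }, character(1))
  skin <- vapply(dataset$spec, function(sp) {
    rgb(sp$skin_color[1], sp$skin_color[2], sp$skin_color[3], maxColorValue = 255)
  }, character(1))
  manifest <- dplyr::bind_cols(
    tibble(file = files, mask_file = mask_files),
    dplyr::select(dataset, -dplyr::any_of(c("spec", "image", "mask"))),
    tibble(lesion_colors = hexcols, skin_color = skin)
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
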