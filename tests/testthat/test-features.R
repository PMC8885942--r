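test_that("the DC-coefficient mean equals the arithmetic mean", {
  expect_equal(mean_via_fft(matrix(7, 5, 5)), 7)
  expect_equal(mean_via_fft(matrix(c(0, 100, 100, 200), 2, 2)), 100)
  set.seed(301)
  for (rep in 1:20) {
    x <- matrix(runif(12 * 17, 0, 255), 12, 17)
    expect_lt(abs(mean_via_fft(x) - mean(x)) / mean(x), 1e-9)
  }
})

test_that("masked statistics match direct computation, histogram route exactly", {
  m <- matrix(TRUE, 4, 4)
  u <- matrix(90L, 4, 4)
  s <- masked_stats(u, m)
  expect_equal(unlist(s), c(std_intensity = 0, hist_mean = 90, hist_std = 0))

  two <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  s2 <- masked_stats(two, m)
  expect_equal(s2$std_intensity, 127.5)
  expect_equal(s2$hist_mean, 127.5)

  set.seed(302)
  x <- matrix(sample(0:255, 400, TRUE), 20, 20)
  mk <- matrix(runif(400) < 0.5, 20, 20)
  s3 <- masked_stats(x, mk)
  expect_identical(s3$hist_mean, mean(as.numeric(x[mk])))
  expect_equal(s3$hist_std, pop <- sqrt(mean((x[mk] - mean(x[mk]))^2)))
  expect_error(masked_stats(x, matrix(FALSE, 20, 20)),
               class = "dermoknn_validation_error")
})

test_that("area and hole counts match counting and the flood-fill oracle", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_equal(area_and_holes(sq), list(area_count = 100L, hole_count = 0L))
  holed <- sq; holed[6:7, 6:7] <- FALSE
  expect_equal(area_and_holes(holed), list(area_count = 96L, hole_count = 4L))
  for (s in 1:20) {
    m <- random_blob_mask(s)
    ah <- area_and_holes(m)
    expect_identical(ah$area_count, sum(m))
    expect_identical(ah$hole_count, bf_hole_count(m))
  }
})

test_that("asymmetry index: symmetric disks near 0, half-disks clearly asymmetric", {
  disk <- digital_disk(100, 100, 50, 50, 40)
  expect_lte(asymmetry_index(disk), 0.02)
  # the half-disk's principal axes are axis-aligned, so reflection about the
  # centroid rows/columns is an independent oracle for the XOR counts
  half <- disk & row(disk) <= 50
  idx <- which(half, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  keys <- function(M) M[, 1] * 1000 + M[, 2]
  xor_about <- function(B) {
    a <- keys(idx); b <- unique(keys(B))
    sum(!(a %in% b)) + sum(!(b %in% a))
  }
  d_row <- xor_about(cbind(round(2 * cy - idx[, 1]), idx[, 2]))
  d_col <- xor_about(cbind(idx[, 1], round(2 * cx - idx[, 2])))
  oracle <- (d_row + d_col) / (2 * nrow(idx))
  ai_half <- asymmetry_index(half)
  expect_lt(abs(ai_half - oracle), 0.03)
  expect_gt(ai_half, 0.15)                 # far above the symmetric disk
  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_error(asymmetry_index(line), class = "dermoknn_validation_error")
  expect_error(asymmetry_index(matrix(FALSE, 5, 5)), class = "dermoknn_validation_error")
})

test_that("asymmetry is invariant to translation and 90-degree rotation", {
  cs <- generate_lesion_image(lesion_spec(seed = 17, asymmetry_level = 0.8,
                                          border_irregularity = 0.4,
                                          hair_count = 0, noise_sigma = 0))
  m <- cs$mask
  ai <- asymmetry_index(m)
  shifted <- matrix(FALSE, 300, 300)
  idx <- which(m, arr.ind = TRUE)
  shifted[cbind(idx[, 1] + 11, idx[, 2] + 23)] <- TRUE
  expect_lt(abs(asymmetry_index(shifted) - ai), 0.02)
  expect_lt(abs(asymmetry_index(rot90(m)) - ai), 0.02)
})

test_that("compactness: near 1 for disks, ~31 for a unit-width bar, grows with irregularity", {
  disk <- digital_disk(100, 100, 50, 50, 40)
  ci <- compactness_index(disk)
  expect_gte(ci, 1.0); expect_lte(ci, 1.15)

  bar <- matrix(FALSE, 5, 104); bar[3, 3:102] <- TRUE
  # contour walk: 99 steps out + 99 back => P = 198, CI = 198^2 / (400 pi)
  ci_bar <- compactness_index(bar)
  expect_gte(ci_bar, 31); expect_lte(ci_bar, 33)

  ci_by_irr <- sapply(c(0.1, 0.7), function(b) {
    cs <- generate_lesion_image(lesion_spec(seed = 13, asymmetry_level = 0.2,
                                            border_irregularity = b,
                                            hair_count = 0, noise_sigma = 0))
    compactness_index(cs$mask)
  })
  expect_gt(ci_by_irr[2], ci_by_irr[1])
})

test_that("Feret diameter: extremes, disks, and exact agreement with all pairs", {
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(lesion_diameter(single), 0)
  disk <- digital_disk(100, 100, 50, 50, 40)
  expect_lt(abs(lesion_diameter(disk) - 80), 2)
  for (s in 1:10) {
    m <- random_blob_mask(s, carve_holes = FALSE)
    bp <- which(dermoknn:::boundary_pixels(m), arr.ind = TRUE)
    d2 <- 0
    for (i in seq_len(nrow(bp))) for (j in seq_len(nrow(bp))) {
      d2 <- max(d2, sum((bp[i, ] - bp[j, ])^2))
    }
    expect_identical(lesion_diameter(m), sqrt(d2))
  }
})

test_that("color features report per-channel within-mask mean and spread", {
  img <- array(0L, c(6, 6, 3))
  img[, , 1] <- 120L; img[, , 2] <- 80L; img[, , 3] <- 60L
  m <- matrix(TRUE, 6, 6)
  cf <- color_features(img, m)
  expect_equal(unlist(cf[c("color_mean_r", "color_mean_g", "color_mean_b")]),
               c(color_mean_r = 120, color_mean_g = 80, color_mean_b = 60))
  expect_true(all(unlist(cf[c("color_std_r", "color_std_g", "color_std_b")]) == 0))

  img[1:3, , 1] <- 100L; img[4:6, , 1] <- 200L
  cf2 <- color_features(img, m)
  expect_equal(cf2$color_mean_r, 150)
  expect_equal(cf2$color_std_r, 50)

  std_for <- function(colors, seed) {
    cs <- generate_lesion_image(lesion_spec(lesion_colors = colors,
                                            hair_count = 0, noise_sigma = 0,
                                            seed = seed))
    cf <- color_features(cs$image, cs$mask)
    mean(unlist(cf[c("color_std_r", "color_std_g", "color_std_b")]))
  }
  three <- list(c(60, 35, 25), c(120, 75, 55), c(170, 120, 95))
  one <- list(c(110, 70, 50))
  expect_gt(std_for(three, 19), std_for(one, 19))
})

test_that("asymmetry and compactness are scale-invariant within rasterization tolerance", {
  vals <- sapply(c(20, 60), function(r) {
    cs <- generate_lesion_image(lesion_spec(base_radius = r, asymmetry_level = 0.6,
                                            border_irregularity = 0.4,
                                            image_size = c(256L, 256L),
                                            hair_count = 0, noise_sigma = 0,
                                            seed = 23))
    c(asymmetry_index(cs$mask), compactness_index(cs$mask))
  })
  expect_lt(abs(vals[1, 1] - vals[1, 2]), 0.05)
  expect_lt(abs(vals[2, 1] - vals[2, 2]), 0.05)
})

test_that("the assembled feature vector is frozen in order and serializes losslessly", {
  cs <- generate_lesion_image(lesion_spec(seed = 29))
  pre <- preprocess_image(cs$image)
  mask <- segment_lesion(pre$dehaired)
  fv <- extract_features(cs$image, pre$gray, pre$preprocessed, mask)
  expect_identical(names(fv), feature_names(include_psnr = TRUE))
  expect_identical(length(feature_names()), 17L)
  expect_identical(fv$log_area, log1p(fv$area_count))
  expect_identical(fv$log_hole, log1p(fv$hole_count))
  expect_gte(fv$asymmetry_index, 0); expect_lte(fv$asymmetry_index, 1)
  expect_gte(fv$compactness_index, 0.95)
  expect_lte(fv$diameter, sqrt(sum(dim(mask)^2)))

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(fv), path, digits = I(17), auto_unbox = TRUE)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON carries no int/double distinction; values must survive exactly
  expect_identical(vapply(back, as.numeric, numeric(1)),
                   vapply(as.list(fv), as.numeric, numeric(1)))
})
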