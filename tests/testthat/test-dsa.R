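# small deterministic fixture: identical voids on a flat background
make_blob_image <- function(centers_x, center_z, nrow, ncol, rx = 12, rz = 9,
                            bright = 0.9, dark = 0.2) {
  img <- matrix(dark, nrow, ncol)
  for (x0 in centers_x) {
    for (cc in max(1, floor(x0 - rx)):min(ncol, ceiling(x0 + rx))) {
      dx <- (cc - x0) / rx
      if (abs(dx) > 1) next
      hz <- rz * sqrt(1 - dx^2)
      rows <- max(1, round(center_z - hz)):min(nrow, round(center_z + hz))
      img[rows, cc] <- bright
    }
  }
  img
}

# sub-pixel full width at half contrast of a profile around index c0
profile_fwhm <- function(v, c0) {
  half <- (max(v) + min(v)) / 2
  lo <- c0
  while (lo > 1 && v[lo - 1] >= half) lo <- lo - 1
  hi <- c0
  while (hi < length(v) && v[hi + 1] >= half) hi <- hi + 1
  lo_f <- if (lo > 1) lo - (v[lo] - half) / (v[lo] - v[lo - 1]) else lo
  hi_f <- if (hi < length(v)) hi + (v[hi] - half) / (v[hi] - v[hi + 1]) else hi
  hi_f - lo_f
}

# phase-locked quasi-periodicity of a B-layer linecut: mean intensity at
# the wall positions of the averaged frame minus mean at the void
# positions.  Channels correlated with the walls push this towards +1;
# uncorrelated channels average to a structureless band and leave it near 0
wall_void_contrast <- function(cut, half_period) {
  cc <- (length(cut) + 1) / 2
  at <- function(pos) {
    mean(sapply(pos, function(p) mean(cut[round(cc + p + -8:8)])))
  }
  at(c(-half_period, half_period)) - at(c(-2, 0, 2) * half_period)
}

test_that("void maps demand at least three sorted centres", {
  expect_error(void_map(data.frame(x = c(10, 50), z = c(5, 5))), "3")
  vm <- void_map(data.frame(x = c(90, 10, 50), z = c(5, 5, 5)))
  expect_equal(vm$centers$x, c(10, 50, 90))
})

test_that("detection recovers known centres on a clean image", {
  centers <- seq(40, 360, by = 40)
  img <- make_blob_image(centers, 30, 60, 400)
  vm <- detect_void_centers(img, expected_spacing = 40, band = c(15, 45))
  expect_equal(nrow(vm$centers), length(centers))
  expect_true(all(abs(vm$centers$x - centers) <= 1))
  expect_true(all(abs(vm$centers$z - 30) <= 1))
})

test_that("detection on a blank image reports too few centres", {
  img <- matrix(0.2, 60, 400)
  expect_error(detect_void_centers(img, 40, c(15, 45)), "< 3")
})

test_that("detection survives jitter and noise on synthetic scales", {
  geom <- dorsal_geometry()
  gt <- generate_tem_image(
    geom,
    image_disorder_params(spacing_jitter = 0.2, noise_sigma = 5, seed = 42),
    pixel_scale = 2, n_voids = 25)
  vm <- detect_void_centers(gt$image,
                            expected_spacing = geom$p_xy / gt$pixel_scale,
                            band = gt$band)
  truth <- gt$voids$centers$x
  hits <- sapply(truth, function(x) min(abs(vm$centers$x - x)))
  expect_gte(mean(hits <= 2), 0.95)
})

test_that("three identical equispaced voids average to the central view", {
  centers <- c(60, 140, 220)
  img <- make_blob_image(centers, 40, 80, 280)
  vm <- void_map(data.frame(x = centers, z = 40))
  res <- dsa_average(img, vm, window = c(101, 61))
  w <- res$window["width"]; h <- res$window["height"]
  sub <- img[40 - (h - 1) / 2 + 0:(h - 1), 140 - (w - 1) / 2 + 0:(w - 1)]
  rms <- sqrt(mean((res$averaged_image - sub)^2))
  expect_equal(res$n_averaged, 1)
  expect_lt(rms, 1 / 255)  # interpolation only
})

test_that("a perfectly periodic lattice averages to one period", {
  # dimensions chosen so band centres land on integer pixel rows
  geom <- scale_geometry(200, 148, 52, w_a = 100, w_b = 100, c_len = 24)
  gt <- generate_tem_image(
    geom,
    image_disorder_params(spacing_jitter = 0, noise_sigma = 0, seed = 1),
    pixel_scale = 2, n_voids = 15)
  vm <- gt$voids
  res <- dsa_average(gt$image, vm)
  i <- 5
  w <- res$window["width"]; h <- res$window["height"]
  x0 <- round(vm$centers$x[i]); z0 <- round(vm$centers$z[i])
  sub <- gt$image[z0 - (h - 1) / 2 + 0:(h - 1), x0 - (w - 1) / 2 + 0:(w - 1)]
  rng <- diff(range(gt$image))
  rms <- sqrt(mean((res$averaged_image - sub)^2))
  expect_lt(rms, 0.02 * rng)
})

test_that("waviness is transformed out: void axes recovered within 5%", {
  geom <- dorsal_geometry()
  gt <- generate_tem_image(
    geom,
    image_disorder_params(spacing_jitter = 0.1, waviness_amplitude = 10,
                          waviness_period = 400, noise_sigma = 2, seed = 7),
    pixel_scale = 2, n_voids = 25)
  res <- dsa_average(gt$image, gt$voids)
  img <- res$averaged_image
  cz <- round((nrow(img) + 1) / 2)
  cx <- round((ncol(img) + 1) / 2)
  width_px <- profile_fwhm(img[cz, ], cx)
  height_px <- profile_fwhm(img[, cx], cz)
  px <- gt$pixel_scale
  expect_lt(abs(width_px - geom$v_xy / px) / (geom$v_xy / px), 0.05)
  expect_lt(abs(height_px - geom$v_z / px) / (geom$v_z / px), 0.05)
})

test_that("averaging is invariant under whole-image translation", {
  centers <- c(60, 140, 220, 300)
  img <- make_blob_image(centers, 40, 90, 360)
  res1 <- dsa_average(img, void_map(data.frame(x = centers, z = 40)),
                      window = c(81, 51))
  shifted <- rbind(matrix(0.2, 10, 360), img[1:80, ])
  res2 <- dsa_average(shifted,
                      void_map(data.frame(x = centers, z = 50)),
                      window = c(81, 51))
  expect_equal(res1$averaged_image, res2$averaged_image, tolerance = 1e-8)
})

test_that("linecuts are rescaled to [0, 1]; constant rows are flagged", {
  centers <- c(60, 140, 220)
  img <- make_blob_image(centers, 40, 80, 280)
  res <- dsa_average(img, void_map(data.frame(x = centers, z = 40)),
                     window = c(101, 61))
  mid <- (res$window["height"] + 1) / 2
  cut <- dsa_linecut(res, mid)
  expect_equal(range(cut), c(0, 1))
  expect_false(attr(cut, "constant"))
  # the averaged void sits at the window centre, so the centre is maximal
  expect_equal(unname(cut[(res$window["width"] + 1) / 2]), 1)
  flat <- dsa_average(matrix(0.5, 80, 280),
                      void_map(data.frame(x = centers, z = 40)),
                      window = c(101, 61))
  fcut <- dsa_linecut(flat, 10)
  expect_true(attr(fcut, "constant"))
  expect_true(all(fcut == 0))
})

test_that("B-layer linecuts are quasi-periodic only for correlated channels", {
  geom <- dorsal_geometry()
  score <- function(correlation, side) {
    gt <- generate_tem_image(
      geom,
      image_disorder_params(spacing_jitter = 0.12, noise_sigma = 3,
                            channel_correlation = correlation, seed = 11),
      pixel_scale = 2, n_voids = 30)
    res <- dsa_average(gt$image, gt$voids,
                       window = c(3 * geom$p_xy / 2, 1.4 * geom$p_z / 2))
    dz <- round((geom$d_a / 2 + geom$d_b / 2) / gt$pixel_scale)
    mid <- (res$window["height"] + 1) / 2
    cut <- dsa_linecut(res, mid + side * dz)
    wall_void_contrast(as.numeric(cut),
                       half_period = geom$p_xy / 2 / gt$pixel_scale)
  }
  for (side in c(-1, 1)) {       # B bands above and below the middle layer
    s_corr <- score("above_wall", side)
    s_rand <- score("random", side)
    expect_gt(s_corr, 0.8)
    expect_lt(s_rand, s_corr - 0.3)
  }
})

test_that("correlated channels align with the walls of the central void", {
  geom <- dorsal_geometry()
  gt <- generate_tem_image(
    geom,
    image_disorder_params(spacing_jitter = 0.1, noise_sigma = 2,
                          channel_correlation = "above_wall", seed = 5),
    pixel_scale = 2, n_voids = 25)
  res <- dsa_average(gt$image, gt$voids,
                     window = c(3 * geom$p_xy / 2, 1.4 * geom$p_z / 2))
  dz <- round((geom$d_a / 2 + geom$d_b / 2) / gt$pixel_scale)
  mid_row <- (res$window["height"] + 1) / 2
  mid_col <- (res$window["width"] + 1) / 2
  cut <- dsa_linecut(res, mid_row - dz)
  half_p <- geom$p_xy / 2 / gt$pixel_scale
  # intensity centroid of each flank window lands on the wall position
  for (wall in mid_col + c(-half_p, half_p)) {
    win <- round(wall + seq(-35, 35))
    v <- cut[win] - min(cut[win])
    centroid <- sum(seq_along(v) * v) / sum(v)
    expect_gt(max(cut[win]), 0.5)
    expect_lt(abs(centroid - 36), 10)
  }
})
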