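test_that("residual integral: zero, constant offset, triangle", {
  lam <- wavelength_grid()
  flat <- spectrum(lam, rep(1, length(lam)), kind = "relative")
  expect_equal(residual_integral(flat, flat), 0)
  off <- spectrum(lam, rep(1.01, length(lam)), kind = "relative")
  expect_equal(residual_integral(flat, off), 0.01^2 * 600, tolerance = 1e-12)
  # triangle difference of height h and half-width W centred at 500:
  # integral of its square is 2 W h^2 / 3
  h <- 0.05; W <- 100
  tri <- pmax(0, h * (1 - abs(lam - 500) / W))
  tri_sp <- spectrum(lam, 1 + tri, kind = "relative")
  expect_equal(residual_integral(flat, tri_sp), 2 * W * h^2 / 3,
               tolerance = 1e-3)
  expect_error(residual_integral(flat, off, 900, 1000), "outside")
})

test_that("round trip recovers the fitted dorsal and ventral parameters", {
  media <- default_media()
  bg <- default_bg()
  cases <- list(
    list(geom = dorsal_geometry(), coef = paper_dorsal_coefficients(),
         truth = c(0.04, 0.04, 0.008)),
    list(geom = ventral_geometry(), coef = paper_ventral_coefficients(),
         truth = c(0.2, 0, 0.006))
  )
  for (cs in cases) {
    model <- relative_spectrum_model(cs$geom, media, bg, 15)
    meas <- model$predict(state_at_x(cs$coef, 0.5))
    st <- fit_state(meas, model, x_fit = 0.5)
    expect_equal(st$c_B, cs$truth[1], tolerance = 1e-3)
    expect_equal(st$c_AB, cs$truth[2], tolerance = 1e-3)
    expect_equal(st$s, cs$truth[3], tolerance = 1e-3)
    # optimiser sanity: fitted residual no worse than at the truth
    res_true <- residual_integral(meas, model$predict(
      filling_state(0.5, cs$truth[1], cs$truth[2], cs$truth[3])))
    expect_lte(attr(st, "residual"), res_true + 1e-12)
  }
})

test_that("a flat measured spectrum fits to the zero state", {
  model <- relative_spectrum_model(dorsal_geometry(), default_media(),
                                   default_bg(), 15)
  lam <- wavelength_grid()
  flat <- spectrum(lam, rep(1, length(lam)), kind = "relative")
  st <- fit_state(flat, model, x_fit = 0.5)
  expect_equal(st$c_B, 0, tolerance = 1e-6)
  expect_equal(st$c_AB, 0, tolerance = 1e-6)
  expect_equal(st$s, 0, tolerance = 1e-6)
})

test_that("recovery tolerates mild multiplicative noise", {
  media <- default_media()
  bg <- default_bg()
  geom <- dorsal_geometry()
  truth <- fit_coefficients(0.4, 0, 0.012)  # (0.2, 0, 0.006) at x = 0.5
  err <- matrix(NA_real_, 20, 3)
  for (k in 1:20) {
    gen <- generate_spectra_series(
      geom, media, bg, 15,
      spectra_series_params(truth, x_values = 0.5, noise_cv = 0.001,
                            seed = 1000 + k))
    st <- fit_state(gen$series[[1]]$spectrum, gen$model, x_fit = 0.5)
    err[k, ] <- c(st$c_B - 0.2, st$c_AB - 0, st$s - 0.006)
  }
  expect_true(all(abs(err[, 1]) < 0.02))
  expect_true(all(abs(err[, 2]) < 0.02))
  expect_true(all(abs(err[, 3]) < 0.001))
})

test_that("round-trip recovery holds for random valid parameter draws", {
  media <- default_media()
  bg <- default_bg()
  model <- relative_spectrum_model(dorsal_geometry(), media, bg, 15)
  set.seed(202)
  for (i in 1:50) {
    c_B <- runif(1, 0, 0.3)
    c_AB <- runif(1, 0, 0.3)
    s <- runif(1, 0, 0.02)
    meas <- model$predict(filling_state(0.5, c_B, c_AB, s))
    st <- fit_state(meas, model, x_fit = 0.5)
    expect_equal(st$c_B, c_B, tolerance = 2e-3)
    expect_equal(st$c_AB, c_AB, tolerance = 2e-3)
    expect_equal(st$s, s, tolerance = 2e-4)
  }
})

test_that("degenerate forward models are flagged as non-identifiable", {
  # ethanol indistinguishable from air: filling cannot change the spectrum
  media <- optical_media(n_ethanol = 1.0)
  model <- relative_spectrum_model(dorsal_geometry(), media, default_bg(), 15)
  lam <- wavelength_grid()
  flat <- spectrum(lam, rep(1, length(lam)), kind = "relative")
  expect_error(fit_state(flat, model, 0.5), "degenerate")
})

test_that("linearize_in_x reproduces the printed coefficient laws", {
  st_d <- filling_state(0.5, 0.04, 0.04, 0.008)
  co_d <- linearize_in_x(st_d, 0.5)
  expect_equal(co_d$cB_slope, 0.08)
  expect_equal(co_d$cAB_slope, 0.08)
  expect_equal(co_d$s_slope, 0.016)
  st_v <- filling_state(0.5, 0.2, 0, 0.006)
  co_v <- linearize_in_x(st_v, 0.5)
  expect_equal(co_v$cB_slope, 0.4)
  expect_equal(co_v$cAB_slope, 0)
  expect_equal(co_v$s_slope, 0.012)
  zeros <- linearize_in_x(filling_state(0.5, 0, 0, 0), 0.5)
  expect_equal(zeros$cB_slope, 0)
  expect_error(linearize_in_x(st_d, 0), "positive")
})

test_that("filling factors follow f_A = c_AB, f_B = c_AB + c_B", {
  expect_equal(filling_factors(filling_state(0.5, 0.04, 0.04, 0)),
               c(f_A = 0.04, f_B = 0.08))
  expect_equal(filling_factors(filling_state(0.5, 0.2, 0, 0)),
               c(f_A = 0, f_B = 0.2))
  expect_equal(filling_factors(filling_state(0, 0, 0, 0)),
               c(f_A = 0, f_B = 0))
})

test_that("peak shift: identity, analytic rescale, asymmetric fixture", {
  lam <- wavelength_grid()
  base <- 0.05 + 0.3 * exp(-(lam - 467)^2 / (2 * 35^2))
  sp <- spectrum(lam, base)
  expect_equal(peak_shift(sp, sp), 0)
  # resampling at lambda/(1+s) shifts the peak by s * lambda_peak
  s <- 0.01
  shifted <- spectrum(lam, stats::approx(lam, base, xout = lam / (1 + s),
                                         rule = 2)$y)
  expect_equal(peak_shift(shifted, sp), s * 467, tolerance = 0.07)
  # asymmetric peak moved by a known sub-grid amount
  asym <- 0.3 * exp(-(lam - 500)^2 / (2 * (30 + 0.08 * (lam - 500))^2))
  delta <- 3.4
  moved <- stats::approx(lam, asym, xout = lam - delta, rule = 2)$y
  expect_equal(peak_shift(spectrum(lam, moved), spectrum(lam, asym)),
               delta, tolerance = 0.06)
  # maxima on the window edge are refused
  ramp <- spectrum(lam, lam / 1000)
  expect_error(peak_shift(ramp, sp), "edge")
})

test_that("peak shift is linear in x under the linear coefficient law", {
  xs <- seq(0.1, 0.5, by = 0.1)
  for (side in c("dorsal", "ventral")) {
    geom <- if (side == "dorsal") dorsal_geometry() else ventral_geometry()
    coef <- if (side == "dorsal") paper_dorsal_coefficients()
            else paper_ventral_coefficients()
    shifts <- sapply(xs, function(x) {
      pr <- forward_wing_pair(geom, coef, x)
      peak_shift(pr$vapor, pr$zero, window = c(380, 720))
    })
    fit <- stats::lm(shifts ~ xs)
    expect_gt(summary(fit)$r.squared, 0.99)
  }
})

test_that("the ventral model shifts more than the dorsal at equal x", {
  for (x in c(0.25, 0.5)) {
    pd <- forward_wing_pair(dorsal_geometry(), paper_dorsal_coefficients(), x)
    pv <- forward_wing_pair(ventral_geometry(), paper_ventral_coefficients(),
                            x)
    expect_lt(peak_shift(pd$vapor, pd$zero, c(380, 720)),
              peak_shift(pv$vapor, pv$zero, c(380, 720)))
  }
})
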