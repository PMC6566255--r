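#' Linear-in-concentration coefficient law
#'
#' The fitted parameters at the largest measured vapour concentration are
#' extrapolated to smaller concentrations by assuming each parameter is
#' linear in the concentration `x`: `c_B = cB_slope * x`, `c_AB =
#' cAB_slope * x`, `s = s_slope * x`.
#'
#' @param cB_slope,cAB_slope,s_slope Per-unit-concentration slopes.
#' @param residual Residual integral at the fitted optimum, if known.
#' @return Object of class `fit_coefficients`.
#' @seealso [linearize_in_x()], [state_at_x()]
#' @export
fit_coefficients <- function(cB_slope, cAB_slope, s_slope, residual = NA_real_) {
  if (cB_slope < 0 || cAB_slope < 0 || s_slope < 0)
    stop("coefficient slopes must be non-negative", call. = FALSE)
  structure(list(cB_slope = cB_slope, cAB_slope = cAB_slope,
                 s_slope = s_slope, residual = residual),
            class = "fit_coefficients")
}

#' @export
print.fit_coefficients <- function(x, ...) {
  cat(sprintf("c_B = %.4f x,  c_AB = %.4f x,  s = %.4f x",
              x$cB_slope, x$cAB_slope, x$s_slope))
  if (is.finite(x$residual)) cat(sprintf("   (residual %.3g)", x$residual))
  cat("\n")
  invisible(x)
}

#' Filling state implied by a coefficient law at concentration x
#'
#' @param coef A [fit_coefficients()].
#' @param x Vapour concentration in `[0, 1]`.
#' @return A [filling_state()].
#' @export
state_at_x <- function(coef, x) {
  filling_state(x, c_B = coef$cB_slope * x, c_AB = coef$cAB_slope * x,
                s = coef$s_slope * x)
}

#' Integrated squared residual between two spectra
#'
#' Trapezoidal integral of the squared pointwise difference over
#' `[lambda_min, lambda_max]`, the objective minimised by the vapour fit.
#'
#' @param measured,modeled Spectra on one shared grid.
#' @param lambda_min,lambda_max Integration window (nm); must lie inside
#'   the grid.
#' @return Scalar integral (value^2 x nm).
#' @export
residual_integral <- function(measured, modeled,
                              lambda_min = 200, lambda_max = 800) {
  check_shared_grid(measured, modeled)
  sel <- measured$wavelength >= lambda_min & measured$wavelength <= lambda_max
  if (sum(sel) < 2)
    stop("integration window lies outside the wavelength grid", call. = FALSE)
  pracma::trapz(measured$wavelength[sel],
                (measured$value[sel] - modeled$value[sel])^2)
}

#' Forward model for relative reflectance spectra
#'
#' Precomputes everything that does not depend on the filling state: the
#' three end-state scale spectra and the broadened, background-corrected
#' zero-vapour whole-wing spectrum that serves as the ratio denominator.
#' The returned object predicts the whole-wing relative spectrum for any
#' [filling_state()] and exposes the linear structure in `(c_B, c_AB)`
#' exploited by [fit_state()].
#'
#' @inheritParams effective_stack
#' @param bg A [background_line()].
#' @param sigma Gaussian broadening width (nm).
#' @param wavelengths Wavelength grid (nm).
#' @param floor Denominator clamp passed to [relative_spectrum()].
#' @return Object of class `relative_spectrum_model` with elements
#'   `predict(state)`, `components` (the `R0`/`RB`/`RAB` scale spectra) and
#'   `zero` (the zero-vapour whole-wing spectrum).
#' @export
relative_spectrum_model <- function(geom, media, bg, sigma = 15,
                                    wavelengths = wavelength_grid(),
                                    floor = 1e-4) {
  comp <- scenario_spectra(geom, media, wavelengths)
  zero <- whole_wing_spectrum(comp$R0, bg, sigma)
  step <- diff(wavelengths[1:2])
  denom <- pmax(zero$value, floor)
  bgv <- evaluate_background(bg, wavelengths)

  # relative-spectrum basis at fixed swelling s: the model is affine in
  # (c_B, c_AB) because rescaling, broadening and the background are
  basis_at_s <- function(s) {
    b0 <- gaussian_broaden(rescale_spectrum(comp$R0, s), step, sigma)
    bB <- gaussian_broaden(rescale_spectrum(comp$RB, s), step, sigma)
    bAB <- gaussian_broaden(rescale_spectrum(comp$RAB, s), step, sigma)
    list(base = (b0 + bgv) / denom,
         dB = (bB - b0) / denom,
         dAB = (bAB - b0) / denom)
  }

  predict_state <- function(state) {
    mixed <- mix_spectra(comp$R0, comp$RB, comp$RAB, state)
    relative_spectrum(whole_wing_spectrum(mixed, bg, sigma), zero,
                      floor = floor)
  }

  structure(list(predict = predict_state, basis_at_s = basis_at_s,
                 components = comp, zero = zero,
                 wavelengths = wavelengths, geom = geom, media = media,
                 bg = bg, sigma = sigma, floor = floor),
            class = "relative_spectrum_model")
}

# Constrained 2-parameter linear least squares:
# minimise sum w (m - base - cB dB - cAB dAB)^2 subject to
# cB >= 0, cAB >= 0, cB + cAB <= 1.  Solved exactly: try the unconstrained
# stationary point, then each active constraint edge and vertex.
solve_weights <- function(m, base, dB, dAB, w) {
  r <- m - base
  sww <- function(a, b) sum(w * a * b)
  G <- matrix(c(sww(dB, dB), sww(dB, dAB), sww(dB, dAB), sww(dAB, dAB)), 2)
  h <- c(sww(dB, r), sww(dAB, r))
  obj <- function(cB, cAB) sum(w * (r - cB * dB - cAB * dAB)^2)

  cands <- list(c(0, 0))
  if (rcond(G) > 1e-12) {
    cands <- c(cands, list(as.numeric(solve(G, h))))
  }
  # edges: cB = 0, cAB = 0, cB + cAB = 1 (each a clamped 1D problem)
  if (G[2, 2] > 0) cands <- c(cands, list(c(0, min(max(h[2] / G[2, 2], 0), 1))))
  if (G[1, 1] > 0) cands <- c(cands, list(c(min(max(h[1] / G[1, 1], 0), 1), 0)))
  dd <- dB - dAB
  denom <- sww(dd, dd)
  if (denom > 0) {
    t <- min(max(sww(dd, r - dAB) / denom, 0), 1)
    cands <- c(cands, list(c(t, 1 - t)))
  }
  feas <- Filter(function(p) p[1] >= -1e-12 && p[2] >= -1e-12 &&
                   p[1] + p[2] <= 1 + 1e-12, cands)
  vals <- vapply(feas, function(p) obj(p[1], p[2]), numeric(1))
  best <- feas[[which.min(vals)]]
  pmax(best, 0)
}

#' Fit the filling state to a measured relative spectrum
#'
#' Least-squares recovery of `(c_B, c_AB, s)` from one measured relative
#' reflectance spectrum at concentration `x_fit`, minimising the
#' [residual_integral()] over the fit window.  The residual is linear in
#' `c_B` and `c_AB` but nonlinear in `s`, so the search is split: an outer
#' deterministic 1D search over `s` (coarse grid followed by golden-section
#' refinement in the best bracket) with, for each `s`, an exact constrained
#' linear solve for the two weights.
#'
#' @param measured A relative [spectrum()].
#' @param model A [relative_spectrum_model()].
#' @param x_fit Concentration at which `measured` was taken.
#' @param s_max Upper bound of the swelling search (fraction).
#' @param n_s Coarse `s`-grid size.
#' @param lambda_min,lambda_max Fit window (nm).
#' @return A [filling_state()] with attribute `residual` (the minimised
#'   integral).
#' @export
fit_state <- function(measured, model, x_fit, s_max = 0.05, n_s = 51,
                      lambda_min = 200, lambda_max = 800) {
  stopifnot(inherits(model, "relative_spectrum_model"))
  lam <- model$wavelengths
  if (nrow(measured) != length(lam) ||
      any(abs(measured$wavelength - lam) > 1e-9))
    stop("measured spectrum must live on the model wavelength grid",
         call. = FALSE)
  sel <- lam >= lambda_min & lam <= lambda_max
  # trapezoid quadrature weights on the fit window
  lw <- lam[sel]
  w <- c(diff(lw) / 2, 0) + c(0, diff(lw) / 2)
  m <- measured$value[sel]

  # identifiability: the basis must actually respond to filling
  b0 <- model$basis_at_s(0)
  if (max(abs(b0$dB[sel])) < 1e-12 && max(abs(b0$dAB[sel])) < 1e-12)
    stop("forward model is degenerate: filling leaves the spectrum unchanged",
         call. = FALSE)

  obj_s <- function(s) {
    b <- model$basis_at_s(s)
    cc <- solve_weights(m, b$base[sel], b$dB[sel], b$dAB[sel], w)
    res <- sum(w * (m - b$base[sel] - cc[1] * b$dB[sel] -
                      cc[2] * b$dAB[sel])^2)
    list(res = res, c_B = cc[1], c_AB = cc[2])
  }

  s_grid <- seq(0, s_max, length.out = n_s)
  res_grid <- vapply(s_grid, function(s) obj_s(s)$res, numeric(1))
  i <- which.min(res_grid)
  lo <- s_grid[max(1, i - 1)]
  hi <- s_grid[min(n_s, i + 1)]
  opt <- stats::optimize(function(s) obj_s(s)$res, c(lo, hi), tol = 1e-7)
  # the bracket endpoints are legal optima too (s = 0 in particular)
  s_star <- if (opt$objective <= min(res_grid)) opt$minimum else s_grid[i]
  best <- obj_s(s_star)
  st <- filling_state(x_fit, c_B = best$c_B, c_AB = best$c_AB, s = s_star)
  attr(st, "residual") <- best$res
  st
}

#' Turn a fitted state into the linear-in-x coefficient law
#'
#' Divides each fitted parameter by the fit concentration, assuming each
#' parameter grows linearly from zero with `x`.
#'
#' @param state_at_xfit A [filling_state()] fitted at concentration
#'   `x_fit`.
#' @param x_fit Fit concentration (> 0).
#' @return A [fit_coefficients()].
#' @export
linearize_in_x <- function(state_at_xfit, x_fit) {
  if (x_fit <= 0) stop("x_fit must be positive", call. = FALSE)
  res <- attr(state_at_xfit, "residual")
  fit_coefficients(cB_slope = state_at_xfit$c_B / x_fit,
                   cAB_slope = state_at_xfit$c_AB / x_fit,
                   s_slope = state_at_xfit$s / x_fit,
                   residual = if (is.null(res)) NA_real_ else res)
}

#' Layer filling factors of a filling state
#'
#' `f_A = c_AB` and `f_B = c_AB + c_B`: the fraction of each layer's air
#' volume occupied by condensed liquid.
#'
#' @param state A [filling_state()].
#' @return Named numeric vector `c(f_A = ..., f_B = ...)`.
#' @export
filling_factors <- function(state) {
  stopifnot(inherits(state, "filling_state"))
  c(f_A = state$f_A, f_B = state$f_B)
}

#' Sub-grid peak wavelength of a spectrum
#'
#' Locates the maximum grid point inside the search window and refines it
#' by a parabola through that point and its two neighbours; the 2 nm grid
#' is coarse compared with the few-nm vapour-induced shifts.
#'
#' @param spec A [spectrum()].
#' @param window Search window `(nm, nm)`.
#' @return Peak wavelength (nm).
#' @export
peak_wavelength <- function(spec, window = c(400, 700)) {
  sel <- which(spec$wavelength >= window[1] & spec$wavelength <= window[2])
  if (length(sel) < 3)
    stop("search window covers fewer than 3 grid points", call. = FALSE)
  i <- sel[which.max(spec$value[sel])]
  if (i == sel[1] || i == sel[length(sel)])
    stop(sprintf(
      "maximum at the edge of the search window (%.0f nm); widen the window",
      spec$wavelength[i]), call. = FALSE)
  y <- spec$value[(i - 1):(i + 1)]
  step <- spec$wavelength[i] - spec$wavelength[i - 1]
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom == 0) return(spec$wavelength[i])
  spec$wavelength[i] + step * (y[1] - y[3]) / (2 * denom)
}

#' Main-peak wavelength shift between two spectra
#'
#' Difference of the sub-grid peak wavelengths (vapour minus zero-vapour);
#' positive values are red shifts.
#'
#' @param R_vapor,R_zero Spectra on one shared grid.
#' @param window Search window `(nm, nm)`.
#' @return Shift in nm.
#' @export
peak_shift <- function(R_vapor, R_zero, window = c(400, 700)) {
  check_shared_grid(R_vapor, R_zero)
  peak_wavelength(R_vapor, window) - peak_wavelength(R_zero, window)
}
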