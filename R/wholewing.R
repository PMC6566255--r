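#' Linear melanin background
#'
#' The ground scales of lycaenid wings are loaded with melanin; their
#' contribution to the whole-wing reflectance is approximated by a straight
#' line in wavelength, added to the single-scale spectrum.
#'
#' @param intercept Reflectance extrapolated to wavelength 0.
#' @param slope Reflectance change per nm.
#' @return Object of class `background_line`.
#' @export
background_line <- function(intercept, slope) {
  bg <- structure(list(intercept = intercept, slope = slope),
                  class = "background_line")
  if (any(evaluate_background(bg, c(200, 800)) < 0))
    stop("background must stay non-negative on the 200-800 nm range",
         call. = FALSE)
  bg
}

evaluate_background <- function(bg, wavelength) {
  bg$intercept + bg$slope * wavelength
}

#' Fit the linear background of a whole-wing spectrum
#'
#' Ordinary least squares line through the points of two flanking windows
#' (below and above the structural-colour peak), where the photonic
#' contribution is negligible and only the melanin background remains.
#'
#' @param reference A [spectrum()].
#' @param low_window,high_window Wavelength intervals `(nm, nm)` used for
#'   the fit; must not overlap.
#' @return A [background_line()].
#' @export
fit_background <- function(reference, low_window = c(200, 250),
                           high_window = c(750, 800)) {
  if (low_window[2] >= high_window[1])
    stop("background windows must not overlap", call. = FALSE)
  sel <- (reference$wavelength >= low_window[1] &
            reference$wavelength <= low_window[2]) |
    (reference$wavelength >= high_window[1] &
       reference$wavelength <= high_window[2])
  if (sum(sel) < 2)
    stop("background windows contain fewer than 2 grid points", call. = FALSE)
  fit <- stats::lm(value ~ wavelength, data = reference[sel, ])
  co <- stats::coef(fit)
  structure(list(intercept = unname(co[1]), slope = unname(co[2])),
            class = "background_line")
}

# Gaussian smoothing along the wavelength axis with a unit-area kernel and
# nearest-value (replicate) edge padding.  sigma in nm; sigma = 0 is the
# identity.
gaussian_broaden <- function(values, step, sigma) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(values)
  half <- max(1L, ceiling(4 * sigma / step))
  k <- stats::dnorm(seq(-half, half) * step, sd = sigma)
  k <- k / sum(k)
  n <- length(values)
  padded <- c(rep(values[1], half), values, rep(values[n], half))
  as.numeric(stats::filter(padded, k, sides = 2))[half + seq_len(n)]
}

#' Whole-wing spectrum from a single-scale spectrum
#'
#' Two corrections turn the normal-incidence reflectance of one scale into
#' an approximate whole-wing spectrum: a Gaussian broadening of width
#' `sigma` accounting for the random angular distribution of the scales,
#' and an additive linear melanin background from the ground scales.
#'
#' @param scale_spectrum A [spectrum()].
#' @param bg A [background_line()] (use `background_line(0, 0)` for none).
#' @param sigma Gaussian broadening width (nm); 0 disables broadening.
#' @return A [spectrum()] on the same grid.
#' @export
whole_wing_spectrum <- function(scale_spectrum, bg, sigma = 15) {
  step <- diff(scale_spectrum$wavelength[1:2])
  v <- gaussian_broaden(scale_spectrum$value, step, sigma) +
    evaluate_background(bg, scale_spectrum$wavelength)
  spectrum(scale_spectrum$wavelength, v)
}

#' Relative reflectance spectrum
#'
#' Pointwise ratio of the spectrum under vapour to the zero-vapour
#' reference, the quantity a spectrometer reports when the zero-vapour
#' spectrum is stored as reference.  The denominator is clamped at `floor`
#' so that near-zero UV reflectance cannot blow the ratio up.
#'
#' @param R_vapor,R_zero Two [spectrum()] objects on one grid.
#' @param floor Minimum denominator reflectance.
#' @return A [spectrum()] with `kind = "relative"`.
#' @export
relative_spectrum <- function(R_vapor, R_zero, floor = 1e-4) {
  check_shared_grid(R_vapor, R_zero)
  spectrum(R_zero$wavelength,
           R_vapor$value / pmax(R_zero$value, floor),
           kind = "relative")
}
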