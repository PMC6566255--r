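#' Default wavelength grid
#'
#' Uniform grid from 200 to 800 nm in 2 nm steps (301 points), the grid on
#' which all spectra in the pipeline live.
#'
#' @param from,to,by Grid limits and step (nm).
#' @return Numeric vector of wavelengths.
#' @export
wavelength_grid <- function(from = 200, to = 800, by = 2) {
  seq(from, to, by = by)
}

#' Reflectance spectrum container
#'
#' A spectrum is a two-column data frame (`wavelength`, `value`) on a
#' strictly increasing wavelength grid.  `kind` distinguishes absolute
#' reflectance (bounded by 1) from relative (ratio) spectra.
#'
#' @param wavelength Strictly increasing wavelengths (nm).
#' @param value Reflectance (or ratio) at each wavelength.
#' @param kind `"reflectance"` or `"relative"`.
#' @return A data frame of class `spectrum`.
#' @export
spectrum <- function(wavelength, value, kind = c("reflectance", "relative")) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length", call. = FALSE)
  if (length(wavelength) > 1 && any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value)))
    stop("spectrum values must be finite", call. = FALSE)
  if (kind == "reflectance" && any(value < -1e-12 | value > 1 + 1e-9))
    stop("reflectance values must lie in [0, 1]", call. = FALSE)
  structure(data.frame(wavelength = as.numeric(wavelength),
                       value = as.numeric(value)),
            kind = kind, class = c("spectrum", "data.frame"))
}

spectrum_kind <- function(s) attr(s, "kind", exact = TRUE)

check_shared_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$wavelength - b$wavelength) > 1e-9))
    stop("spectra must share one wavelength grid", call. = FALSE)
  invisible(TRUE)
}

#' Normal-incidence reflectance of a planar multilayer
#'
#' Standard characteristic-matrix (transfer-matrix) recursion for a stack of
#' homogeneous planar layers between semi-infinite ambient and substrate,
#' at normal incidence.  For each layer of index \eqn{n_j} and thickness
#' \eqn{d_j} the phase thickness is \eqn{\delta_j = 2\pi n_j d_j/\lambda};
#' the stack matrix is the ordered product of the layer matrices
#' \deqn{M_j = \begin{pmatrix}\cos\delta_j & i\sin\delta_j/n_j\\
#'       i n_j \sin\delta_j & \cos\delta_j\end{pmatrix}}
#' and the amplitude reflectance is
#' \eqn{r = (n_0 B - C)/(n_0 B + C)} with
#' \eqn{(B, C)^T = M (1, n_s)^T}.  The function returns \eqn{R = |r|^2}.
#'
#' @param layers Data frame or list with components `n` (complex index) and
#'   `d` (thickness, nm), ordered from the side the light enters.  An empty
#'   stack gives the bare ambient/substrate Fresnel reflectance.
#' @param n_ambient,n_substrate Indices of the semi-infinite media.
#' @param wavelengths Wavelength grid (nm).
#' @return A [spectrum()].
#' @export
#' @examples
#' # quarter-wave-ish chitin film on air
#' s <- multilayer_reflectance(list(n = 1.56 + 0.033i, d = 75),
#'                             wavelengths = wavelength_grid())
#' max(s$value) < 1
multilayer_reflectance <- function(layers, n_ambient = 1, n_substrate = 1,
                                   wavelengths = wavelength_grid()) {
  n <- as.complex(unlist(layers[["n"]], use.names = FALSE))
  d <- as.numeric(unlist(layers[["d"]], use.names = FALSE))
  if (length(n) != length(d))
    stop("layers must supply one thickness per index", call. = FALSE)
  if (any(d <= 0))
    stop("layer thicknesses must be strictly positive", call. = FALSE)
  if (length(n) && (any(Re(n) < 1) || any(Im(n) < 0)))
    stop("layer indices need Re >= 1 and Im >= 0", call. = FALSE)
  # the characteristic-matrix formulas below follow the thin-film (Macleod)
  # convention N = n - ik; indices are supplied as n + ik, so conjugate
  n <- Conj(n)
  n0 <- Conj(as.complex(n_ambient))
  ns <- Conj(as.complex(n_substrate))
  lam <- as.numeric(wavelengths)

  # vectorised over wavelength: carry the 2x2 matrix entries as vectors
  m11 <- m22 <- rep(1 + 0i, length(lam))
  m12 <- m21 <- rep(0 + 0i, length(lam))
  for (j in seq_along(n)) {
    delta <- 2 * pi * n[j] * d[j] / lam
    cd <- cos(delta)
    sd <- sin(delta)
    a11 <- cd;              a12 <- 1i * sd / n[j]
    a21 <- 1i * n[j] * sd;  a22 <- cd
    t11 <- m11 * a11 + m12 * a21
    t12 <- m11 * a12 + m12 * a22
    t21 <- m21 * a11 + m22 * a21
    t22 <- m21 * a12 + m22 * a22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  B <- m11 + m12 * ns
  C <- m21 + m22 * ns
  r <- (n0 * B - C) / (n0 * B + C)
  R <- pmin(Mod(r)^2, 1)
  spectrum(lam, R)
}

#' Effective layer stack for one vapour filling scenario
#'
#' Builds the 1D effective-medium stack of `n_stories` A-B layer pairs for
#' one of the three filling end states: all voids air-filled (`"air"`), the
#' small "B"-layer channels filled with liquid ethanol (`"B_filled"`), or
#' all air spaces filled (`"AB_filled"`).  The top layer is a "B" layer;
#' light impinges from above.  Partial filling is never represented by
#' intermediate indices -- partially filled wings are modelled downstream by
#' incoherent mixing of these end-state spectra.
#'
#' @inheritParams effective_stack
#' @param scenario `"air"`, `"B_filled"` or `"AB_filled"`.
#' @return A data frame with complex column `n` and numeric column `d`,
#'   ordered from the illuminated side.
#' @export
scenario_stack <- function(geom, media,
                           scenario = c("air", "B_filled", "AB_filled")) {
  scenario <- match.arg(scenario)
  P_A <- perforation_factor(geom, "A")
  P_B <- perforation_factor(geom, "B")
  void_a <- switch(scenario,
                   air = media$n_air,
                   B_filled = media$n_air,
                   AB_filled = media$n_ethanol)
  void_b <- switch(scenario,
                   air = media$n_air,
                   B_filled = media$n_ethanol,
                   AB_filled = media$n_ethanol)
  n_a <- effective_index(P_A, media, void_a)
  n_b <- effective_index(P_B, media, void_b)
  k <- geom$n_stories
  data.frame(n = rep(c(n_b, n_a), k),
             d = rep(c(geom$d_b, geom$d_a), k))
}

#' Reflectance spectra of the three filling end states
#'
#' Convenience wrapper computing `R0` (air), `RB` (B filled) and `RAB`
#' (A and B filled) with [multilayer_reflectance()]; ambient and substrate
#' are air.
#'
#' @inheritParams effective_stack
#' @param wavelengths Wavelength grid (nm).
#' @return Named list of three [spectrum()] objects `R0`, `RB`, `RAB`.
#' @export
scenario_spectra <- function(geom, media, wavelengths = wavelength_grid()) {
  list(
    R0  = multilayer_reflectance(scenario_stack(geom, media, "air"),
                                 wavelengths = wavelengths),
    RB  = multilayer_reflectance(scenario_stack(geom, media, "B_filled"),
                                 wavelengths = wavelengths),
    RAB = multilayer_reflectance(scenario_stack(geom, media, "AB_filled"),
                                 wavelengths = wavelengths)
  )
}

#' Capillary-condensation filling state
#'
#' Describes one vapour concentration `x` through the weights of the two
#' filling processes and the chitin swelling: `c_B` is the weight of the
#' process filling only the small "B"-layer channels, `c_AB` the weight of
#' the process filling both layers, and `s` the fractional isotropic
#' swelling of the chitin skeleton.  The layer filling factors follow as
#' `f_A = c_AB` and `f_B = c_AB + c_B` (the small voids fill first, so an
#' "A-only" process has no physical meaning).
#'
#' @param x Vapour concentration as a fraction of saturation, in `[0, 1]`.
#' @param c_B,c_AB Process weights; non-negative with `c_B + c_AB <= 1`.
#' @param s Fractional swelling (0.008 means 0.8 % linear enlargement).
#' @return An object of class `filling_state` with derived `f_A`, `f_B`.
#' @export
filling_state <- function(x, c_B, c_AB, s) {
  if (x < 0 || x > 1) stop("x must lie in [0, 1]", call. = FALSE)
  if (c_B < 0 || c_AB < 0)
    stop("filling weights must be non-negative", call. = FALSE)
  if (c_B + c_AB > 1 + 1e-12)
    stop("c_B + c_AB must not exceed 1", call. = FALSE)
  if (s < 0) stop("swelling s must be non-negative", call. = FALSE)
  structure(list(x = x, c_B = c_B, c_AB = c_AB, s = s,
                 f_A = c_AB, f_B = c_AB + c_B),
            class = "filling_state")
}

#' @export
print.filling_state <- function(x, ...) {
  cat(sprintf(
    "Filling state at x = %.3f: c_B = %.4f, c_AB = %.4f, s = %.4f\n",
    x$x, x$c_B, x$c_AB, x$s))
  cat(sprintf("  filling factors f_A = %.1f %%, f_B = %.1f %%; swelling %.2f %%\n",
              100 * x$f_A, 100 * x$f_B, 100 * x$s))
  invisible(x)
}

# Evaluate a spectrum at lambda / (1 + s): an isotropic enlargement of the
# structure by (1 + s) red-shifts every feature from lambda to lambda (1 + s).
# Linear interpolation on the grid; wavelengths mapping outside the grid take
# the boundary value.
rescale_spectrum <- function(spec, s) {
  if (s == 0) return(spec$value)
  stats::approx(spec$wavelength, spec$value,
                xout = spec$wavelength / (1 + s), rule = 2)$y
}

#' Incoherent mixing of the filling end-state spectra
#'
#' For coherence-length reasons the reflectance of a partially filled scale
#' is the weighted incoherent sum of the end-state spectra,
#' \deqn{R(\lambda) = (1 - c_B - c_{AB})\,R_0(\lambda') +
#'       c_B R_B(\lambda') + c_{AB} R_{AB}(\lambda'),}
#' with each component evaluated at the swelling-rescaled wavelength
#' \eqn{\lambda' = \lambda/(1+s)}.
#'
#' @param R0,RB,RAB End-state spectra on one common grid (see
#'   [scenario_spectra()]).
#' @param state A [filling_state()].
#' @return A [spectrum()] on the same grid.
#' @export
mix_spectra <- function(R0, RB, RAB, state) {
  check_shared_grid(R0, RB)
  check_shared_grid(R0, RAB)
  stopifnot(inherits(state, "filling_state"))
  w0 <- 1 - state$c_B - state$c_AB
  v <- w0 * rescale_spectrum(R0, state$s) +
    state$c_B * rescale_spectrum(RB, state$s) +
    state$c_AB * rescale_spectrum(RAB, state$s)
  spectrum(R0$wavelength, v)
}
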