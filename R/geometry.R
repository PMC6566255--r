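#' Parametric wing-scale geometry
#'
#' The scale interior is modelled as a vertical stack of `n_stories` layer
#' pairs.  Each pair consists of an "A" layer -- a perforated chitin sheet
#' carrying one large cuboid air void per lateral unit cell, connected to its
#' lateral neighbours by horizontal air channels -- and a "B" layer, a thin
#' chitin sheet crossed only by one narrow vertical air channel per cell.
#' All air spaces are cuboids; the lateral unit cell is `p_xy` x `p_xy`.
#'
#' Derived fields are computed, never supplied: the vertical periodicity is
#' `p_z = d_a + d_b`, the void width `v_xy = p_xy - c` and the void height
#' `v_z = d_a`.
#'
#' @param p_xy Lateral periodicity (nm).
#' @param d_a "A" layer thickness (nm).
#' @param d_b "B" layer thickness (nm).
#' @param w_a Horizontal air channel width (nm); square cross-section.
#' @param w_b Vertical air channel width (nm); square cross-section.
#' @param c_len Horizontal air channel length (nm); equals the chitin wall
#'   thickness between two neighbouring voids, so `v_xy = p_xy - c_len`.
#' @param n_stories Number of A-B layer pairs in the stack.
#'
#' @return An object of class `scale_geometry`: a list with the supplied
#'   fields plus the derived `p_z`, `v_xy` and `v_z`.
#' @seealso [dorsal_geometry()], [ventral_geometry()], [perforation_factor()]
#' @export
#' @examples
#' g <- scale_geometry(p_xy = 200, d_a = 150, d_b = 50,
#'                     w_a = 100, w_b = 100, c_len = 25)
#' g$v_xy  # 175
scale_geometry <- function(p_xy, d_a, d_b, w_a, w_b, c_len, n_stories = 4L) {
  geom <- structure(
    list(
      p_xy = as.numeric(p_xy),
      p_z  = as.numeric(d_a + d_b),
      d_a  = as.numeric(d_a),
      d_b  = as.numeric(d_b),
      w_a  = as.numeric(w_a),
      w_b  = as.numeric(w_b),
      c_len = as.numeric(c_len),
      v_xy = as.numeric(p_xy - c_len),
      v_z  = as.numeric(d_a),
      n_stories = as.integer(n_stories)
    ),
    class = "scale_geometry"
  )
  validate_scale_geometry(geom)
  geom
}

validate_scale_geometry <- function(geom) {
  stopifnot(inherits(geom, "scale_geometry"))
  with(geom, {
    if (!(p_xy > 0 && d_a > 0 && d_b > 0))
      stop("p_xy, d_a and d_b must be strictly positive", call. = FALSE)
    if (w_a < 0 || w_b < 0 || c_len < 0)
      stop("channel dimensions must be non-negative", call. = FALSE)
    if (c_len > p_xy)
      stop("channel length c_len cannot exceed the lateral period p_xy",
           call. = FALSE)
    if (w_a > v_xy || w_b > v_xy)
      stop(sprintf(
        "channel wider than the air void: w_a = %g, w_b = %g, v_xy = %g",
        w_a, w_b, v_xy), call. = FALSE)
    if (w_a > d_a)
      stop("horizontal channel taller than the A layer", call. = FALSE)
    if (n_stories < 1L)
      stop("n_stories must be at least 1", call. = FALSE)
  })
  # derived-field consistency (guards lists manipulated by hand)
  stopifnot(isTRUE(all.equal(geom$p_z, geom$d_a + geom$d_b)),
            isTRUE(all.equal(geom$v_xy, geom$p_xy - geom$c_len)),
            isTRUE(all.equal(geom$v_z, geom$d_a)))
  invisible(geom)
}

#' @export
print.scale_geometry <- function(x, ...) {
  cat("Wing-scale geometry (nm):\n")
  cat(sprintf("  lateral period p_xy = %g, vertical period p_z = %g\n",
              x$p_xy, x$p_z))
  cat(sprintf("  layers: d_a = %g, d_b = %g  (%d stories)\n",
              x$d_a, x$d_b, x$n_stories))
  cat(sprintf("  void: %g x %g x %g; channels: w_a = %g, w_b = %g, c = %g\n",
              x$v_xy, x$v_xy, x$v_z, x$w_a, x$w_b, x$c_len))
  invisible(x)
}

#' Reference geometries for the dorsal (blue) and ventral (gold-green) sides
#'
#' Cuboid-model dimensions measured on electron micrographs of
#' *Albulina metallica* cover scales.  The ventral structure is the dorsal
#' one scaled by a factor 1.3.
#'
#' @param n_stories Number of A-B layer pairs (four observed).
#' @return A [scale_geometry()] object.
#' @export
dorsal_geometry <- function(n_stories = 4L) {
  scale_geometry(p_xy = 200, d_a = 150, d_b = 50,
                 w_a = 100, w_b = 100, c_len = 25, n_stories = n_stories)
}

#' @rdname dorsal_geometry
#' @export
ventral_geometry <- function(n_stories = 4L) {
  scale_geometry(p_xy = 260, d_a = 195, d_b = 65,
                 w_a = 130, w_b = 130, c_len = 32.5, n_stories = n_stories)
}

#' Optical constants of the scale materials
#'
#' Chitin carries a small imaginary index accounting for the pigment content
#' of the scales; ethanol and air are non-absorbing.
#'
#' @param n_chitin Complex refractive index of (pigmented) chitin.
#' @param n_ethanol Real refractive index of liquid ethanol.
#' @param n_air Refractive index of air (fixed at 1 in practice).
#' @return An object of class `optical_media`.
#' @export
optical_media <- function(n_chitin = complex(real = 1.56, imaginary = 0.033),
                          n_ethanol = 1.36, n_air = 1.0) {
  n_chitin <- as.complex(n_chitin)
  if (Re(n_chitin) < 1 || Re(n_ethanol) < 1 || Re(n_air) < 1)
    stop("real parts of refractive indices must be >= 1", call. = FALSE)
  if (Im(n_chitin) < 0 || Im(as.complex(n_ethanol)) < 0)
    stop("imaginary parts of refractive indices must be >= 0", call. = FALSE)
  structure(list(n_chitin = n_chitin,
                 n_ethanol = as.complex(n_ethanol),
                 n_air = as.complex(n_air)),
            class = "optical_media")
}

#' Perforation factor of one layer
#'
#' The perforation factor P of a layer is the air volume fraction of its
#' lateral unit cell, `P = V_air / (V_air + V_chitin)`.  For an "A" layer the
#' air space is the union of the central cuboid void (`v_xy` x `v_xy` x
#' `v_z`) and the horizontal channels (square cross-section `w_a` x `w_a`)
#' that cross the chitin walls along both lateral axes; overlaps between the
#' channels and the void count once.  For a "B" layer it is the single
#' vertical channel `w_b` x `w_b` x `d_b`.
#'
#' @param geom A [scale_geometry()].
#' @param layer `"A"` or `"B"`.
#' @return Air volume fraction in `[0, 1]`.
#' @export
#' @examples
#' perforation_factor(dorsal_geometry(), "A")
#' perforation_factor(dorsal_geometry(), "B")  # (w_b / p_xy)^2
perforation_factor <- function(geom, layer = c("A", "B")) {
  validate_scale_geometry(geom)
  layer <- match.arg(layer)
  cell_area <- geom$p_xy^2
  if (layer == "B") {
    return((geom$w_b^2 * geom$d_b) / (cell_area * geom$d_b))
  }
  # "A" layer: union of the central void and the two axis-aligned channel
  # families.  The void spans the full layer height (v_z = d_a) and the
  # channels are centred laterally and vertically, so within the chitin wall
  # (outside the void's lateral extent) each axis contributes one channel of
  # cross-section w_a^2 and in-cell length c_len; the channel cross-section
  # lies inside the void's lateral span (w_a <= v_xy), so the two families
  # are disjoint from one another and only overlap the void itself, where
  # they add nothing.
  v_void <- geom$v_xy^2 * geom$v_z
  v_channels <- 2 * geom$w_a^2 * geom$c_len
  (v_void + v_channels) / (cell_area * geom$d_a)
}

#' Volume-weighted effective refractive index of a perforated layer
#'
#' `n_eff = P * n_void + (1 - P) * n_chitin`, where the void medium is air,
#' ethanol, or whatever fills the air fraction.
#'
#' @param P Air volume fraction in `[0, 1]`.
#' @param media An [optical_media()] object supplying the chitin index.
#' @param n_void Complex index of the medium occupying the air fraction
#'   (defaults to air).
#' @return Complex effective refractive index.
#' @export
effective_index <- function(P, media, n_void = media$n_air) {
  if (any(P < 0 | P > 1))
    stop("perforation factor P must lie in [0, 1]", call. = FALSE)
  P * as.complex(n_void) + (1 - P) * media$n_chitin
}

#' Effective 1D stack summary of a geometry
#'
#' Collapses the lateral structure of each layer into its perforation factor
#' and effective index, then forms the effective vertical periodicity
#' `p_eff = Re(n_a) d_a + Re(n_b) d_b` and the main-peak predictor
#' `lambda_main = 2 p_eff` (first-order Bragg condition of the layer-pair
#' stack).  Air-filled voids are assumed.
#'
#' @inheritParams perforation_factor
#' @param media An [optical_media()].
#' @return An object of class `effective_stack` with fields `P_A`, `P_B`,
#'   `n_a`, `n_b`, `p_eff`, `lambda_main`.
#' @export
effective_stack <- function(geom, media) {
  P_A <- perforation_factor(geom, "A")
  P_B <- perforation_factor(geom, "B")
  n_a <- effective_index(P_A, media)
  n_b <- effective_index(P_B, media)
  p_eff <- Re(n_a) * geom$d_a + Re(n_b) * geom$d_b
  structure(list(P_A = P_A, P_B = P_B, n_a = n_a, n_b = n_b,
                 p_eff = p_eff, lambda_main = 2 * p_eff),
            class = "effective_stack")
}

#' @export
print.effective_stack <- function(x, ...) {
  cat(sprintf("Effective stack: P_A = %.4f, P_B = %.4f\n", x$P_A, x$P_B))
  cat(sprintf("  n_a = %.4f%+.4fi, n_b = %.4f%+.4fi\n",
              Re(x$n_a), Im(x$n_a), Re(x$n_b), Im(x$n_b)))
  cat(sprintf("  p_eff = %.2f nm, lambda_main = %.2f nm\n",
              x$p_eff, x$lambda_main))
  invisible(x)
}

#' Predicted main reflectance peak wavelength
#'
#' `lambda_main = 2 (Re(n_a) d_a + Re(n_b) d_b)` with air-filled voids.
#'
#' @inheritParams effective_stack
#' @return Wavelength in nm.
#' @export
main_peak_wavelength <- function(geom, media) {
  effective_stack(geom, media)$lambda_main
}

#' Calibrate the air-channel width against a measured peak position
#'
#' Finds the common channel width `w* = w_a = w_b` for which the effective
#' stack's main-peak predictor matches `lambda_target`.  Widening the
#' channels adds air, lowers both effective indices and blue-shifts the
#' peak, so the map from width to wavelength is strictly decreasing and a
#' bracketed 1D root find suffices.
#'
#' @inheritParams effective_stack
#' @param lambda_target Measured main-peak wavelength (nm).
#' @param tol Convergence tolerance on the peak wavelength (nm).
#' @return The input geometry with `w_a` and `w_b` replaced by the
#'   calibrated width.
#' @export
calibrate_channel_width <- function(geom, media, lambda_target, tol = 0.1) {
  validate_scale_geometry(geom)
  w_max <- min(geom$v_xy, geom$d_a)
  lam_at <- function(w) {
    g <- geom
    g$w_a <- w
    g$w_b <- w
    main_peak_wavelength(g, media)
  }
  lam_hi <- lam_at(0)       # no channels: highest index, reddest peak
  lam_lo <- lam_at(w_max)   # widest channels: bluest peak
  if (lambda_target > lam_hi || lambda_target < lam_lo)
    stop(sprintf(
      "lambda_target = %.1f nm outside the achievable range [%.1f, %.1f] nm",
      lambda_target, lam_lo, lam_hi), call. = FALSE)
  f <- function(w) lam_at(w) - lambda_target
  if (abs(f(0)) < .Machine$double.eps^0.5) {
    w_star <- 0
  } else {
    w_star <- stats::uniroot(f, interval = c(0, w_max),
                             tol = 1e-6 * w_max)$root
  }
  # refine until the wavelength (not the width) meets tol
  stopifnot(abs(lam_at(w_star) - lambda_target) <= tol)
  out <- geom
  out$w_a <- w_star
  out$w_b <- w_star
  validate_scale_geometry(out)
  out
}
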