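# run code under a local, seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Disorder parameters of the synthetic TEM image generator
#'
#' @param spacing_jitter Std of the void spacing as a fraction of the
#'   lateral period, in `[0, 0.5]`.
#' @param waviness_amplitude Amplitude of the sinusoidal layer waviness (px).
#' @param waviness_period Period of the waviness (px).
#' @param channel_correlation `"above_wall"` places the vertical channels of
#'   the "B" layers above the chitin walls separating the voids (the
#'   correlation seen in real scales); `"random"` places them uniformly.
#' @param noise_sigma Additive Gaussian noise std in 8-bit gray levels.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return Object of class `image_disorder_params`.
#' @export
image_disorder_params <- function(spacing_jitter = 0.05,
                                  waviness_amplitude = 0,
                                  waviness_period = 300,
                                  channel_correlation = c("above_wall",
                                                          "random"),
                                  noise_sigma = 0,
                                  seed = 1L) {
  channel_correlation <- match.arg(channel_correlation)
  if (spacing_jitter < 0 || spacing_jitter > 0.5)
    stop("spacing_jitter must lie in [0, 0.5]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (waviness_period <= 0) stop("waviness_period must be > 0", call. = FALSE)
  structure(list(spacing_jitter = spacing_jitter,
                 waviness_amplitude = waviness_amplitude,
                 waviness_period = waviness_period,
                 channel_correlation = channel_correlation,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "image_disorder_params")
}

# gray levels of the three-phase rendering: solid chitin, projected
# channels (partial-thickness air in the 70 nm slice), and through-going
# air voids
.tem_gray <- c(chitin = 0.25, channel = 0.55, void = 0.90)

# paint an axis-aligned ellipse (or rectangle) column by column, displaced
# vertically by the waviness of each column
paint_feature <- function(img, x0, z0, rx, rz, value, wav,
                          shape = c("ellipse", "rect"), above = NULL) {
  shape <- match.arg(shape)
  nc <- ncol(img)
  nr <- nrow(img)
  cols <- max(1L, floor(x0 - rx)):min(nc, ceiling(x0 + rx))
  for (cc in cols) {
    dx <- (cc - x0) / rx
    if (shape == "ellipse") {
      if (abs(dx) > 1) next
      hz <- rz * sqrt(max(0, 1 - dx^2))
    } else {
      if (abs(cc - x0) > rx) next
      hz <- rz
    }
    zc <- z0 + wav[cc]
    rows <- max(1L, round(zc - hz)):min(nr, round(zc + hz))
    if (is.null(above)) {
      img[rows, cc] <- value
    } else {
      # only brighten: channels never darken a void they run into
      img[rows, cc] <- pmax(img[rows, cc], value)
    }
  }
  img
}

#' Generate a synthetic cross-sectional TEM image with ground truth
#'
#' Renders the layered "pepper-pot" morphology as seen in cross-sectional
#' TEM: alternating "B" (thin chitin) and "A" (perforated) bands, bright
#' elliptical voids at jittered lateral spacings in the "A" bands,
#' mid-gray projected channel marks (horizontal channels in the walls
#' between voids, vertical channels crossing the "B" bands), a sinusoidal
#' vertical waviness shared by all layers, and additive Gaussian noise.
#' Three gray levels stand in for the projection contrast of a 70 nm
#' slice: through-going voids render bright, partial-thickness channels
#' mid-gray, solid chitin dark.
#'
#' The layer layout is B A B A ... B (one more "B" than "A" bands, as in
#' real scale sections).  Ground truth for the middle "A" layer is
#' returned alongside the image.
#'
#' @param geom A [scale_geometry()].
#' @param params An [image_disorder_params()].
#' @param pixel_scale nm per pixel.
#' @param n_voids Approximate void count per "A" layer (>= 3).
#' @return List with `image` (matrix, intensities in `[0, 1]`),
#'   `voids` (a [void_map()] of the middle "A" layer), `channels`
#'   (data frame of vertical-channel positions per "B" layer), `band`
#'   (row range of the middle "A" layer) and the rendering scales.
#' @export
generate_tem_image <- function(geom, params, pixel_scale = 2, n_voids = 20) {
  validate_scale_geometry(geom)
  stopifnot(inherits(params, "image_disorder_params"))
  if (n_voids < 3) stop("n_voids must be >= 3", call. = FALSE)
  px <- pixel_scale
  if (geom$v_xy / px < 3)
    stop("pixel_scale too coarse: voids would span < 3 px", call. = FALSE)

  n_a <- max(3L, geom$n_stories - 1L)      # A bands between B bands
  p_xy <- geom$p_xy / px
  d_a <- geom$d_a / px
  d_b <- geom$d_b / px
  width <- ceiling((n_voids + 0.5) * p_xy)
  height <- ceiling(n_a * (d_a + d_b) + d_b + 2 * params$waviness_amplitude + 4)

  with_local_seed(params$seed, {
    img <- matrix(.tem_gray["chitin"], height, width)
    wav <- params$waviness_amplitude *
      sin(2 * pi * seq_len(width) / params$waviness_period)

    # band centre rows (flat frame): B A B A ... B from the top
    z_top <- params$waviness_amplitude + 2
    a_centers <- z_top + d_b + (seq_len(n_a) - 1) * (d_a + d_b) + d_a / 2
    b_centers <- z_top + (seq_len(n_a + 1) - 1) * (d_a + d_b) + d_b / 2
    mid <- ceiling(n_a / 2)

    # jittered void positions per A band
    void_x <- vector("list", n_a)
    for (l in seq_len(n_a)) {
      xs <- p_xy / 2 + params$spacing_jitter * p_xy * stats::rnorm(1)
      while (xs[length(xs)] < width - p_xy / 2) {
        step <- p_xy * (1 + params$spacing_jitter * stats::rnorm(1))
        xs <- c(xs, xs[length(xs)] + max(step, 0.5 * p_xy))
      }
      void_x[[l]] <- xs[xs >= p_xy / 4 & xs <= width - p_xy / 4]
    }

    # horizontal channels first (walls), then voids on top of them
    for (l in seq_len(n_a)) {
      xs <- void_x[[l]]
      for (i in seq_len(length(xs) - 1)) {
        gap_mid <- (xs[i] + xs[i + 1]) / 2
        gap_half <- (xs[i + 1] - xs[i]) / 2
        img <- paint_feature(img, gap_mid, a_centers[l],
                             rx = gap_half, rz = geom$w_a / px / 2,
                             value = .tem_gray["channel"], wav = wav,
                             shape = "rect")
      }
      for (x0 in xs)
        img <- paint_feature(img, x0, a_centers[l],
                             rx = geom$v_xy / px / 2, rz = geom$v_z / px / 2,
                             value = .tem_gray["void"], wav = wav)
    }

    # vertical channels in the B bands
    channels <- list()
    for (l in seq_len(n_a + 1)) {
      # channels connect the voids of the two A bands the B band separates;
      # tie each B band to its adjacent A band nearer the middle band, so
      # both neighbours of the analysed (middle) layer carry its correlation
      ref_layer <- min(max(c(l - 1, l)[which.min(abs(c(l - 1, l) - mid))],
                           1), n_a)
      xs <- void_x[[ref_layer]]
      walls <- (xs[-length(xs)] + xs[-1]) / 2
      ch_x <- if (params$channel_correlation == "above_wall") {
        walls
      } else {
        sort(stats::runif(length(walls), min(xs), max(xs)))
      }
      for (x0 in ch_x)
        img <- paint_feature(img, x0, b_centers[l],
                             rx = geom$w_b / px / 2, rz = d_b / 2,
                             value = .tem_gray["channel"], wav = wav,
                             shape = "rect", above = TRUE)
      channels[[l]] <- data.frame(b_layer = l, x = ch_x)
    }

    if (params$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), sd = params$noise_sigma / 255)
      img <- pmin(pmax(img, 0), 1)
    }

    mid_xs <- void_x[[mid]]
    centers <- data.frame(x = mid_xs, z = a_centers[mid] + wav[round(mid_xs)])
    band <- c(floor(a_centers[mid] - d_a / 2 - params$waviness_amplitude),
              ceiling(a_centers[mid] + d_a / 2 + params$waviness_amplitude))
    band <- pmin(pmax(band, 1), height)

    list(image = img,
         voids = void_map(centers, pixel_scale = px),
         channels = do.call(rbind, channels),
         band = band,
         a_centers = a_centers, b_centers = b_centers,
         waviness = wav, pixel_scale = px)
  })
}

#' Parameters of the synthetic vapour spectra series
#'
#' @param coefficients Ground-truth [fit_coefficients()] (linear-in-x law).
#' @param x_values Vapour concentrations, each in `[0, 1]`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal) noise on the relative spectra; 0 for noise-free.
#' @param seed Integer seed.
#' @return Object of class `spectra_series_params`.
#' @export
spectra_series_params <- function(coefficients,
                                  x_values = seq(0.05, 0.5, by = 0.05),
                                  noise_cv = 0, seed = 1L) {
  stopifnot(inherits(coefficients, "fit_coefficients"))
  if (any(x_values < 0 | x_values > 1))
    stop("x_values must lie in [0, 1]", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(coefficients = coefficients, x_values = x_values,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "spectra_series_params")
}

#' Generate a vapour-concentration series of relative spectra
#'
#' Runs the forward chain (end-state spectra, incoherent mixing, whole-wing
#' broadening and background, ratio to the zero-vapour spectrum) for each
#' concentration of the series, then multiplies each spectrum by seeded
#' mean-one lognormal noise with the requested coefficient of variation.
#'
#' @inheritParams relative_spectrum_model
#' @param params A [spectra_series_params()].
#' @return List with the `model` used and `series`, a list of
#'   `list(x =, spectrum =)` entries in `x_values` order.
#' @export
generate_spectra_series <- function(geom, media, bg, sigma, params,
                                    wavelengths = wavelength_grid()) {
  stopifnot(inherits(params, "spectra_series_params"))
  model <- relative_spectrum_model(geom, media, bg, sigma, wavelengths)
  sdlog <- sqrt(log(1 + params$noise_cv^2))
  series <- with_local_seed(params$seed, {
    lapply(params$x_values, function(x) {
      rel <- model$predict(state_at_x(params$coefficients, x))
      if (params$noise_cv > 0) {
        noise <- stats::rlnorm(nrow(rel), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
        rel <- spectrum(rel$wavelength, rel$value * noise, kind = "relative")
      }
      list(x = x, spectrum = rel)
    })
  })
  list(model = model, series = series)
}
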