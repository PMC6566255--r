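# Independent oracles and fixture builders shared by the test files.

# Brute-force voxel count of the air union of one unit cell at `res` nm.
# Deliberately independent of the analytic inclusion-exclusion in the
# package: builds the 3D occupancy array and counts voxels whose centres
# fall inside the union of the void and channel cuboids.
voxel_perforation <- function(geom, layer, res = 1) {
  p <- geom$p_xy
  xs <- seq(res / 2, p, by = res)
  xs <- xs[xs < p]
  if (layer == "B") {
    inw <- xs > p / 2 - geom$w_b / 2 & xs < p / 2 + geom$w_b / 2
    return(mean(outer(inw, inw)))  # channel spans the full B thickness
  }
  zs <- seq(res / 2, geom$d_a, by = res)
  zs <- zs[zs < geom$d_a]
  arr <- array(FALSE, c(length(xs), length(xs), length(zs)))
  inv <- xs > p / 2 - geom$v_xy / 2 & xs < p / 2 + geom$v_xy / 2
  arr[inv, inv, ] <- TRUE  # central void spans the full layer height
  inw <- xs > p / 2 - geom$w_a / 2 & xs < p / 2 + geom$w_a / 2
  inz <- zs > geom$d_a / 2 - geom$w_a / 2 & zs < geom$d_a / 2 + geom$w_a / 2
  arr[, inw, inz] <- TRUE  # channel along x (runs through void and walls)
  arr[inw, , inz] <- TRUE  # channel along y
  mean(arr)
}

# Closed-form Fresnel reflectance of a bare interface at normal incidence
fresnel_R <- function(n0, ns) Mod((n0 - ns) / (n0 + ns))^2

# Closed-form Airy reflectance of a single film between two media
airy_R <- function(n0, n1, ns, d, lambda) {
  r01 <- (n0 - n1) / (n0 + n1)
  r1s <- (n1 - ns) / (n1 + ns)
  phase <- exp(2i * 2 * pi * n1 * d / lambda)
  Mod((r01 + r1s * phase) / (1 + r01 * r1s * phase))^2
}

# Random valid geometry with even-integer nm dimensions (measured sizes
# are integer nm; even values put cuboid faces between voxel centres)
random_geometry <- function(n_stories = 4L) {
  p <- 2 * sample(60:130, 1)
  c_len <- 2 * sample(ceiling(0.05 * p / 2):floor(0.2 * p / 2), 1)
  d_a <- 2 * sample(ceiling(0.3 * p / 2):floor(0.45 * p / 2), 1)
  d_b <- 2 * sample(ceiling(0.1 * p / 2):floor(0.2 * p / 2), 1)
  w_max <- min(p - c_len, d_a)
  w <- 2 * sample(ceiling(0.1 * w_max / 2):floor(0.45 * w_max / 2), 1)
  scale_geometry(p, d_a, d_b, w, w, c_len, n_stories)
}

default_media <- function() optical_media()
lossless_media <- function() optical_media(n_chitin = 1.56 + 0i)
default_bg <- function() background_line(0.05, 5e-5)

paper_dorsal_coefficients <- function() fit_coefficients(0.08, 0.08, 0.016)
paper_ventral_coefficients <- function() fit_coefficients(0.4, 0, 0.012)

# Forward whole-wing spectra pair (vapour at x, zero vapour) for one side
forward_wing_pair <- function(geom, coef, x, media = default_media(),
                              bg = default_bg(), sigma = 15) {
  model <- relative_spectrum_model(geom, media, bg, sigma)
  st <- state_at_x(coef, x)
  mixed <- mix_spectra(model$components$R0, model$components$RB,
                       model$components$RAB, st)
  list(vapor = whole_wing_spectrum(mixed, bg, sigma), zero = model$zero,
       model = model)
}
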