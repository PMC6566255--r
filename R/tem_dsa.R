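#' Void-centre map of a cross-sectional TEM image
#'
#' Images are numeric matrices with intensities in `[0, 1]`; rows run down
#' the vertical (z) axis and columns along the horizontal (x) axis, and air
#' appears bright.  A void map holds the centres of the air voids of one
#' "A" layer, ordered left to right, in (possibly fractional) pixel
#' coordinates.
#'
#' @param centers Data frame with columns `x` (column) and `z` (row).
#' @param pixel_scale nm per pixel.
#' @return Object of class `void_map`.
#' @export
void_map <- function(centers, pixel_scale = NA_real_) {
  centers <- as.data.frame(centers)[, c("x", "z")]
  if (nrow(centers) < 3)
    stop("at least 3 void centres are required (each averaged void needs ",
         "both neighbours)", call. = FALSE)
  centers <- centers[order(centers$x), , drop = FALSE]
  rownames(centers) <- NULL
  structure(list(centers = centers, pixel_scale = pixel_scale),
            class = "void_map")
}

#' @export
print.void_map <- function(x, ...) {
  cat(sprintf("Void map: %d centres", nrow(x$centers)))
  if (is.finite(x$pixel_scale))
    cat(sprintf(" at %.3g nm/px", x$pixel_scale))
  cat("\n")
  invisible(x)
}

# 1D Gaussian smoothing with replicate padding (detection plumbing)
smooth_profile <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
  as.numeric(stats::filter(padded, k, sides = 2))[half + seq_along(v)]
}

#' Detect void centres in one layer band
#'
#' Bright-blob detection restricted to a horizontal band of rows: the
#' band's column-mean intensity profile is Gaussian-smoothed, local maxima
#' above the profile mean are kept with a minimum separation of half the
#' expected spacing, and each centre is refined to sub-pixel precision by
#' intensity-weighted centroids in x and z.  Hand-marked centre files
#' override detection in the pipeline whenever supplied.
#'
#' @param image Numeric intensity matrix in `[0, 1]`, voids bright.
#' @param expected_spacing Expected void-to-void spacing (px).
#' @param band Row range `c(row_min, row_max)` of the layer to search.
#' @param pixel_scale nm per pixel, forwarded to the result.
#' @return A [void_map()].
#' @export
detect_void_centers <- function(image, expected_spacing, band,
                                pixel_scale = NA_real_) {
  band <- as.integer(round(band))
  if (band[1] < 1 || band[2] > nrow(image) || band[1] >= band[2])
    stop("band must lie inside the image", call. = FALSE)
  if (mean(image[band[1]:band[2], ]) < mean(image))
    warning("band is darker than the image mean; is the image inverted ",
            "(voids should be bright)?", call. = FALSE)
  sub <- image[band[1]:band[2], , drop = FALSE]
  # heavily smoothed profile for peak finding, lightly smoothed for the
  # sub-pixel refinement (heavy smoothing biases the centroid towards
  # asymmetric neighbour flanks)
  prof_coarse <- smooth_profile(colMeans(sub), sigma = expected_spacing / 10)
  prof_fine <- smooth_profile(colMeans(sub), sigma = expected_spacing / 20)
  half_w <- max(2L, floor(expected_spacing / 4))
  n <- length(prof_coarse)
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half_w)
    hi <- min(n, i + half_w)
    prof_coarse[i] >= max(prof_coarse[lo:hi]) &&
      prof_coarse[i] > mean(prof_coarse)
  }, logical(1))
  cand <- which(is_max)
  # greedy non-maximum suppression at half the expected spacing
  cand <- cand[order(prof_coarse[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || min(abs(keep - i)) >= expected_spacing / 2)
      keep <- c(keep, i)
  keep <- sort(keep)
  if (length(keep) < 3)
    stop(sprintf("found only %d void centres (< 3)", length(keep)),
         call. = FALSE)

  ref_w <- max(2L, round(expected_spacing / 6))
  centers <- do.call(rbind, lapply(keep, function(i) {
    x <- i
    for (pass in 1:2) {  # iterated narrow-window baseline-removed centroid
      lo <- max(1, round(x) - ref_w)
      hi <- min(n, round(x) + ref_w)
      wx <- prof_fine[lo:hi] - min(prof_fine[lo:hi])
      if (sum(wx) > 0) x <- sum((lo:hi) * wx) / sum(wx)
    }
    lo <- max(1, round(x) - ref_w)
    hi <- min(n, round(x) + ref_w)
    col_block <- sub[, lo:hi, drop = FALSE]
    wz <- rowSums(col_block - min(col_block))
    z <- if (sum(wz) > 0) {
      sum((band[1]:band[2]) * wz) / sum(wz)
    } else {
      mean(band)
    }
    data.frame(x = x, z = z)
  }))
  void_map(centers, pixel_scale)
}

# bilinear sampling with replicate (clamped) edge padding; also reports
# whether each source point fell inside the image
bilinear_sample <- function(image, x, z) {
  nr <- nrow(image)
  nc <- ncol(image)
  inside <- x >= 1 & x <= nc & z >= 1 & z <= nr
  x <- pmin(pmax(x, 1), nc)
  z <- pmin(pmax(z, 1), nr)
  x0 <- pmin(floor(x), nc - 1)
  z0 <- pmin(floor(z), nr - 1)
  fx <- x - x0
  fz <- z - z0
  v <- (1 - fx) * (1 - fz) * image[cbind(z0, x0)] +
    fx * (1 - fz) * image[cbind(z0, x0 + 1)] +
    (1 - fx) * fz * image[cbind(z0 + 1, x0)] +
    fx * fz * image[cbind(z0 + 1, x0 + 1)]
  list(value = v, inside = inside)
}

#' Direct-space average of the void local environments
#'
#' For every interior void (the leftmost and rightmost centres are
#' excluded, since each averaged void needs both neighbours) the image is
#' shifted so the void sits at the window centre, rotated so the line
#' through its left and right neighbours is horizontal, and rescaled so
#' the neighbour distance `d` equals a common reference distance (the
#' median of all `d`); the transformed sub-images are then averaged pixel
#' by pixel.  Layer waviness and spacing jitter are thereby transformed
#' out and the mean local environment of a void emerges.
#'
#' Resampling is bilinear in the order shift, rotate, scale; source pixels
#' falling outside the image contribute their clamped edge value and are
#' flagged in the coverage mask.
#'
#' @param image Numeric intensity matrix, voids bright.
#' @param voids A [void_map()] for the analysed layer.
#' @param window Output window `c(width, height)` in px; defaults to
#'   1.5 x and 0.75 x the reference neighbour distance.
#' @return Object of class `dsa_result`: `averaged_image`, `n_averaged`,
#'   `reference_distance`, `coverage` (fraction of contributing source
#'   pixels per output pixel) and the window geometry.
#' @export
dsa_average <- function(image, voids, window = NULL) {
  stopifnot(inherits(voids, "void_map"))
  ctr <- voids$centers
  n <- nrow(ctr)
  interior <- 2:(n - 1)
  d_all <- sqrt((ctr$x[interior + 1] - ctr$x[interior - 1])^2 +
                  (ctr$z[interior + 1] - ctr$z[interior - 1])^2)
  ref_d <- stats::median(d_all)
  if (is.null(window))
    window <- c(1.5 * ref_d, 0.75 * ref_d)
  w <- 2L * floor(window[1] / 2) + 1L   # odd sizes so the centre is a pixel
  h <- 2L * floor(window[2] / 2) + 1L
  if (w >= ncol(image) || h >= nrow(image))
    stop("window must be smaller than the image", call. = FALSE)
  u <- rep(seq_len(w) - (w + 1) / 2, each = h)   # horizontal offsets
  v <- rep(seq_len(h) - (h + 1) / 2, times = w)  # vertical offsets

  acc <- matrix(0, h, w)
  cov <- matrix(0, h, w)
  for (k in seq_along(interior)) {
    i <- interior[k]
    alpha <- atan2(ctr$z[i + 1] - ctr$z[i - 1], ctr$x[i + 1] - ctr$x[i - 1])
    sc <- d_all[k] / ref_d
    xs <- ctr$x[i] + sc * (cos(alpha) * u - sin(alpha) * v)
    zs <- ctr$z[i] + sc * (sin(alpha) * u + cos(alpha) * v)
    smp <- bilinear_sample(image, xs, zs)
    acc <- acc + matrix(smp$value, h, w)
    cov <- cov + matrix(as.numeric(smp$inside), h, w)
  }
  structure(list(averaged_image = acc / length(interior),
                 n_averaged = length(interior),
                 reference_distance = ref_d,
                 coverage = cov / length(interior),
                 window = c(width = w, height = h)),
            class = "dsa_result")
}

#' @export
print.dsa_result <- function(x, ...) {
  cat(sprintf("DSA average of %d voids; window %d x %d px; d_ref = %.1f px\n",
              x$n_averaged, x$window["width"], x$window["height"],
              x$reference_distance))
  invisible(x)
}

#' Normalised intensity linecut of a DSA image
#'
#' Extracts one row of the averaged image and rescales it so the minimum
#' maps to 0 and the maximum to 1.  A constant row has no contrast to
#' rescale; it is returned as zeros with attribute `constant = TRUE`.
#'
#' @param result A [dsa_result()].
#' @param row Row index inside the averaged image (1 = top).
#' @param label Optional layer tag stored with the profile.
#' @return Numeric profile in `[0, 1]` with attributes `row` and `label`.
#' @export
dsa_linecut <- function(result, row, label = NULL) {
  img <- result$averaged_image
  if (row < 1 || row > nrow(img))
    stop("row lies outside the averaged image", call. = FALSE)
  v <- img[row, ]
  rng <- range(v)
  if (diff(rng) == 0) {
    out <- rep(0, length(v))
    attr(out, "constant") <- TRUE
  } else {
    out <- (v - rng[1]) / diff(rng)
    attr(out, "constant") <- FALSE
  }
  attr(out, "row") <- row
  attr(out, "label") <- label
  out
}
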