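#' Read a spectrum from two-column delimited text
#'
#' Files carry a header `wavelength_nm,<value-name>` followed by one
#' comma-separated pair per line; the value name `relative_reflectance`
#' marks a relative spectrum, anything else an absolute one.
#'
#' @param path File path.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) != 2 || header[1] != "wavelength_nm")
    stop("expected header 'wavelength_nm,<value-name>' in ", path,
         call. = FALSE)
  kind <- if (header[2] == "relative_reflectance") "relative" else "reflectance"
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  bad <- sort(unique(c(bad, which(colSums(is.na(vals)) > 0))))
  if (length(bad))
    stop(sprintf("malformed spectrum row at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  wl <- vals[1, ]
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    i <- which(diff(wl) <= 0)[1]
    stop(sprintf(
      "wavelengths not strictly increasing at line %d of %s", i + 2L, path),
      call. = FALSE)
  }
  spectrum(wl, vals[2, ], kind = kind)
}

#' Write a spectrum as two-column delimited text
#'
#' Values are written with 15 significant digits, so a write-read round
#' trip is lossless well below 1e-9.
#'
#' @param spec A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  name <- if (identical(spectrum_kind(spec), "relative")) {
    "relative_reflectance"
  } else {
    "reflectance"
  }
  lines <- c(paste0("wavelength_nm,", name),
             sprintf("%.15g,%.15g", spec$wavelength, spec$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structured run configuration
#'
#' YAML file with sections `geometry` (Table-style symbols in snake_case,
#' nm), `media` (complex chitin index as `[real, imag]`), `wholewing`
#' (background windows or an explicit line, broadening sigma, denominator
#' floor) and `fit` (search bounds and windows).  Geometry invariants are
#' validated on load.
#'
#' @param path YAML file path.
#' @return List with elements `geometry` ([scale_geometry()]), `media`
#'   ([optical_media()]), `wholewing` and `fit` (lists with defaults
#'   filled in), plus the raw config.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  if (is.null(g)) stop("config lacks a 'geometry' section", call. = FALSE)
  geom <- scale_geometry(
    p_xy = g$p_xy, d_a = g$d_a, d_b = g$d_b,
    w_a = g$w_a, w_b = g$w_b, c_len = if (!is.null(g$c)) g$c else g$c_len,
    n_stories = if (is.null(g$n_stories)) 4L else g$n_stories)

  m <- cfg$media
  media <- optical_media(
    n_chitin = if (is.null(m$n_chitin)) {
      complex(real = 1.56, imaginary = 0.033)
    } else {
      complex(real = m$n_chitin[[1]], imaginary = m$n_chitin[[2]])
    },
    n_ethanol = if (is.null(m$n_ethanol)) 1.36 else m$n_ethanol)

  ww <- cfg$wholewing
  wholewing <- list(
    background = if (is.null(ww$background)) {
      background_line(0.05, 5e-5)
    } else {
      background_line(ww$background[[1]], ww$background[[2]])
    },
    low_window = if (is.null(ww$low_window)) c(200, 250)
                 else unlist(ww$low_window),
    high_window = if (is.null(ww$high_window)) c(750, 800)
                  else unlist(ww$high_window),
    sigma = if (is.null(ww$sigma)) 15 else ww$sigma,
    floor = if (is.null(ww$floor)) 1e-4 else ww$floor)

  ft <- cfg$fit
  fit <- list(
    x_fit = if (is.null(ft$x_fit)) 0.5 else ft$x_fit,
    s_max = if (is.null(ft$s_max)) 0.05 else ft$s_max,
    n_s = if (is.null(ft$n_s)) 51L else ft$n_s,
    lambda_min = if (is.null(ft$lambda_min)) 200 else ft$lambda_min,
    lambda_max = if (is.null(ft$lambda_max)) 800 else ft$lambda_max,
    peak_window = if (is.null(ft$peak_window)) c(400, 700)
                  else unlist(ft$peak_window))

  list(geometry = geom, media = media, wholewing = wholewing, fit = fit,
       raw = cfg)
}

#' Read and write grayscale images
#'
#' Images travel as 8- or 16-bit grayscale PNG; in memory they are plain
#' numeric matrices with intensities in `[0, 1]` (rows = z, top first).
#'
#' @param path PNG file path.
#' @return `read_gray_png`: a numeric matrix.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]   # first channel of RGB(A) input
  a
}

#' @rdname read_gray_png
#' @param image Numeric matrix in `[0, 1]`.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
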