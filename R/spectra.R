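#' Construct a spectrum
#'
#' A spectrum is one wavelength-resolved intensity measurement: a strictly
#' ascending wavelength axis in nanometres and detector counts (arbitrary
#' units), plus acquisition metadata. All wavelengths in this package are nm
#' and all times are seconds.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 1 (length >= 2 for anything that interpolates).
#' @param intensities Numeric vector of detector counts, same length as
#'   `wavelengths`, finite.
#' @param exposure_s Exposure time in seconds (default 5, one spectrometer
#'   frame).
#' @param t_acq_s Acquisition time in seconds since irradiation start, or
#'   `NA` for basis spectra acquired outside a treatment.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths`, `intensities`, `exposure_s`, `t_acq_s`.
#' @examples
#' s <- spectrum(c(1200, 1270, 1600), c(0, 10, 0))
#' s
#' @export
spectrum <- function(wavelengths, intensities, exposure_s = 5, t_acq_s = NA_real_) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 1L)
    stop("spectrum needs at least one wavelength", call. = FALSE)
  if (length(intensities) != length(wavelengths))
    stop("wavelengths and intensities must have the same length", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite", call. = FALSE)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite (no NaN/Inf)", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = FALSE)) {
    o <- order(wavelengths)
    wavelengths <- wavelengths[o]
    intensities <- intensities[o]
  }
  if (anyDuplicated(wavelengths))
    stop("duplicate wavelengths in spectrum", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         exposure_s = as.numeric(exposure_s), t_acq_s = as.numeric(t_acq_s)),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelengths)
  cat(sprintf("<spectrum> %d points, %.6g-%.6g nm", length(x$wavelengths),
              rng[1], rng[2]))
  if (!is.na(x$t_acq_s)) cat(sprintf(", t = %.6g s", x$t_acq_s))
  cat(sprintf(", peak %.6g counts at %.6g nm\n",
              max(x$intensities), x$wavelengths[which.max(x$intensities)]))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, xlab = "wavelength (nm)",
                          ylab = "intensity (counts)", type = "l", ...) {
  graphics::plot(x$wavelengths, x$intensities, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, intensity = x$intensities)
}

#' Define a uniform wavelength grid
#'
#' @param start_nm,stop_nm Grid endpoints in nm, `start_nm < stop_nm`.
#' @param n_points Number of grid nodes, >= 2.
#' @return An object of class `"wavelength_grid"` with a `$wavelengths`
#'   vector of `n_points` equally spaced nodes.
#' @examples
#' wavelength_grid(1200, 1600, 256)
#' @export
wavelength_grid <- function(start_nm = 1200, stop_nm = 1600, n_points = 256) {
  if (!(start_nm < stop_nm)) stop("start_nm must be < stop_nm", call. = FALSE)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, n_points = as.integer(n_points),
         wavelengths = seq(start_nm, stop_nm, length.out = n_points)),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, %d points\n",
              x$start_nm, x$stop_nm, x$n_points))
  invisible(x)
}

#' Read spectra from CSV
#'
#' Two dialects are supported. `"two_column"` has header
#' `wavelength_nm,intensity` and holds a single spectrum. `"long_format"` has
#' header `t_s,wavelength_nm,intensity`; rows are grouped by `t_s` into one
#' spectrum per acquisition time and a list of spectra is returned, ordered by
#' time.
#'
#' @param path Path to a CSV file.
#' @param dialect `"two_column"` or `"long_format"`.
#' @param exposure_s Exposure metadata attached to the returned spectra.
#' @return A `spectrum` (two_column) or a list of `spectrum` objects
#'   (long_format).
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, dialect = c("two_column", "long_format"),
                          exposure_s = 5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- switch(dialect,
                 two_column  = c("wavelength_nm", "intensity"),
                 long_format = c("t_s", "wavelength_nm", "intensity"))
  if (!identical(names(df), want))
    stop(sprintf("malformed header in %s: expected '%s', got '%s'",
                 path, paste(want, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  if (dialect == "two_column") {
    spectrum(df$wavelength_nm, df$intensity, exposure_s = exposure_s)
  } else {
    ts <- sort(unique(df$t_s))
    lapply(ts, function(t) {
      sub <- df[df$t_s == t, ]
      spectrum(sub$wavelength_nm, sub$intensity,
               exposure_s = exposure_s, t_acq_s = t)
    })
  }
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectrum()]: a single spectrum is written in the
#' two-column dialect, a list of spectra in the long format. Values are
#' written with 12 significant digits so a read/write round trip preserves
#' them to well below any tolerance used in this package.
#'
#' @param x A `spectrum` or a list of `spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  if (inherits(x, "spectrum")) {
    lines <- c("wavelength_nm,intensity",
               paste(fmt(x$wavelengths), fmt(x$intensities), sep = ","))
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "spectrum"))) {
    lines <- "t_s,wavelength_nm,intensity"
    for (s in x) {
      if (is.na(s$t_acq_s))
        stop("long-format writing needs t_acq_s on every spectrum", call. = FALSE)
      lines <- c(lines, paste(fmt(rep(s$t_acq_s, length(s$wavelengths))),
                              fmt(s$wavelengths), fmt(s$intensities), sep = ","))
    }
  } else {
    stop("x must be a spectrum or a list of spectra", call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto the grid nodes. The grid must lie inside the
#' wavelength range of the data; extrapolation is refused because measured
#' and basis spectra must share a grid without inventing values.
#'
#' @param x A `spectrum`.
#' @param grid A `wavelength_grid`, or a numeric vector of target wavelengths.
#' @return A `spectrum` on the grid, carrying over the metadata of `x`.
#' @export
resample <- function(x, grid) {
  stopifnot(inherits(x, "spectrum"))
  wl <- if (inherits(grid, "wavelength_grid")) grid$wavelengths else as.numeric(grid)
  if (min(wl) < min(x$wavelengths) || max(wl) > max(x$wavelengths))
    stop("grid extends beyond the data: refusing to extrapolate", call. = FALSE)
  yi <- stats::approx(x$wavelengths, x$intensities, xout = wl, method = "linear",
                      ties = "ordered")$y
  spectrum(wl, yi, exposure_s = x$exposure_s, t_acq_s = x$t_acq_s)
}

#' Five-point moving-average smoothing
#'
#' Centred moving average with window 5. At the edges the window shrinks
#' symmetrically: 3 points at the second and second-to-last index, 1 point
#' (identity) at the first and last, so no boundary artifacts are introduced
#' and a constant spectrum is reproduced exactly. Wavelengths are unchanged.
#'
#' @param x A `spectrum`.
#' @return The smoothed `spectrum`.
#' @examples
#' s <- spectrum(1:5, c(0, 0, 5, 0, 0))
#' smooth_five_point(s)$intensities  # 0, 5/3, 1, 5/3, 0
#' @export
smooth_five_point <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  y <- x$intensities
  n <- length(y)
  out <- y
  for (i in seq_len(n)) {
    h <- min(2L, i - 1L, n - i)  # symmetric half-width, shrunk at the edges
    out[i] <- mean(y[(i - h):(i + h)])
  }
  spectrum(x$wavelengths, out, exposure_s = x$exposure_s, t_acq_s = x$t_acq_s)
}

# Shared grid check used by the unmixing operations.
same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol * pmax(1, abs(a)))
}
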