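#' Construct a basis matrix
#'
#' Named component spectra on a common wavelength grid, used as the design
#' matrix for spectral unmixing. The matrix must have full column rank:
#' proportional components make the amplitudes unidentifiable.
#'
#' @param wavelengths Strictly increasing wavelength axis in nm.
#' @param components Numeric matrix, one column per component, rows matching
#'   `wavelengths`; must have column names.
#' @return An object of class `"basis_matrix"`.
#' @export
basis_matrix <- function(wavelengths, components) {
  wavelengths <- as.numeric(wavelengths)
  components <- as.matrix(components)
  if (nrow(components) != length(wavelengths))
    stop("components must have one row per wavelength", call. = FALSE)
  if (is.null(colnames(components)) || anyDuplicated(colnames(components)))
    stop("components must have unique column names", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  sv <- svd(components, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-10 * sv[1])
    stop("collinear basis: components are numerically rank-deficient",
         call. = FALSE)
  structure(list(wavelengths = wavelengths, components = components,
                 condition = sv[1] / sv[length(sv)]),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("<basis_matrix> %d components (%s), %d wavelengths %g-%g nm, cond %.3g\n",
              ncol(x$components), paste(colnames(x$components), collapse = ", "),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$condition))
  invisible(x)
}

# Minimum-norm least squares via SVD pseudoinverse with a relative
# singular-value cutoff. Returns the coefficient vector.
svd_solve <- function(B, y, rcond = 1e-12) {
  s <- svd(B)
  keep <- s$d > rcond * s$d[1]
  coef <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep])
  drop(coef)
}

# Lawson-Hanson active-set non-negative least squares refinement.
nnls_solve <- function(B, y, rcond = 1e-12, max_iter = 10 * ncol(B)) {
  p <- ncol(B)
  passive <- rep(FALSE, p)
  x <- rep(0, p)
  tol <- 1e-10 * max(abs(crossprod(B, y)), 1)
  for (outer in seq_len(max_iter)) {
    w <- drop(crossprod(B, y - B %*% x))
    cand <- which(!passive & w > tol)
    if (length(cand) == 0) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- rep(0, p)
      z[passive] <- svd_solve(B[, passive, drop = FALSE], y, rcond)
      if (all(z[passive] > 0)) { x <- z; break }
      bad <- passive & z <= 0
      alpha <- min(x[bad] / (x[bad] - z[bad]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' Unmix a spectrum against a basis by SVD least squares
#'
#' Finds the component amplitudes minimising the sum of squared residuals
#' over the wavelength grid, solved via singular-value pseudoinverse with a
#' relative cutoff of 1e-12. With `nonneg = TRUE` the amplitudes are
#' additionally constrained to be >= 0 by active-set refinement. Negative
#' amplitudes under the unconstrained fit indicate model mismatch and are
#' reported, not clipped, by default.
#'
#' @param x A `spectrum`, already on the basis grid (use [resample()] first).
#' @param basis A `basis_matrix`.
#' @param nonneg Constrain amplitudes to be non-negative? Default `FALSE`.
#' @return An object of class `"unmix_result"`: list with `amplitudes`
#'   (named, counts), `residual_rms` (counts), `condition` (of the basis),
#'   `fitted` (reconstruction), `nonneg`.
#' @examples
#' B <- make_basis()
#' s <- spectrum(B$wavelengths, drop(B$components %*% c(2, 3, 1)))
#' svd_unmix(s, B)$amplitudes
#' @export
svd_unmix <- function(x, basis, nonneg = FALSE) {
  stopifnot(inherits(x, "spectrum"), inherits(basis, "basis_matrix"))
  if (!same_grid(x$wavelengths, basis$wavelengths))
    stop("spectrum and basis are on different wavelength grids", call. = FALSE)
  B <- basis$components
  y <- x$intensities
  a <- if (nonneg) nnls_solve(B, y) else svd_solve(B, y)
  names(a) <- colnames(B)
  fitted <- drop(B %*% a)
  res <- y - fitted
  structure(list(amplitudes = a,
                 residual_rms = sqrt(mean(res^2)),
                 condition = basis$condition,
                 fitted = fitted, nonneg = nonneg),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result>", if (x$nonneg) "(non-negative)" else "", "\n")
  print(round(x$amplitudes, 6))
  cat(sprintf("  residual RMS %.6g counts, basis condition %.3g\n",
              x$residual_rms, x$condition))
  invisible(x)
}

#' Quench-difference extraction of the singlet oxygen band
#'
#' Pointwise difference (pre minus post) of spectra acquired before and
#' after chemical quenching of singlet oxygen with sodium azide; phosphorescence
#' and background cancel, leaving the singlet oxygen luminescence.
#'
#' @param pre,post `spectrum` objects on the same grid.
#' @return A `spectrum` holding `pre - post`.
#' @export
quench_difference <- function(pre, post) {
  stopifnot(inherits(pre, "spectrum"), inherits(post, "spectrum"))
  if (!same_grid(pre$wavelengths, post$wavelengths))
    stop("pre and post spectra are on different wavelength grids", call. = FALSE)
  spectrum(pre$wavelengths, pre$intensities - post$intensities,
           exposure_s = pre$exposure_s, t_acq_s = pre$t_acq_s)
}

#' Unmix a time series of spectra
#'
#' Applies [svd_unmix()] to every spectrum in a series, optionally after
#' five-point smoothing, and returns the per-time amplitudes ordered by
#' acquisition time.
#'
#' @param series List of `spectrum` objects sharing the basis grid, each
#'   with `t_acq_s` set.
#' @param basis A `basis_matrix`.
#' @param smooth Apply [smooth_five_point()] before fitting? Default `FALSE`.
#' @param nonneg Passed to [svd_unmix()].
#' @return data.frame with one row per time point, columns `t_s`, one column
#'   per basis component (`a_<name>`), and `residual_rms`, sorted by `t_s`.
#' @export
unmix_series <- function(series, basis, smooth = FALSE, nonneg = FALSE) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  rows <- lapply(series, function(s) {
    if (smooth) s <- smooth_five_point(s)
    u <- svd_unmix(s, basis, nonneg = nonneg)
    c(t_s = s$t_acq_s, u$amplitudes, residual_rms = u$residual_rms)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t_s", paste0("a_", colnames(basis$components)),
                  "residual_rms")
  out <- out[order(out$t_s), ]
  rownames(out) <- NULL
  out
}

#' Unmix a fluorescence-window spectrum
#'
#' Fits a spectrum in the ~600-800 nm fluorescence window against the
#' photosensitizer fluorescence shape, a background shape, and `n_fourier`
#' cosine/sine pairs over the window (slowly varying residual structure).
#' The photosensitizer amplitude is the photobleaching-tracking output; its
#' ratio to the pre-treatment amplitude gives the relative ground-state
#' concentration.
#'
#' @param x A `spectrum` in the fluorescence window.
#' @param ps_basis,background_basis `spectrum` objects on the same grid as
#'   `x` holding the component shapes.
#' @param n_fourier Number of cosine/sine pairs to append (default 1;
#'   0 reduces to a two-component fit).
#' @param nonneg Passed to the solver (applies to all components).
#' @return An `unmix_result`; the amplitudes are named `ps`, `bg`,
#'   `cos1`, `sin1`, ...
#' @export
fluorescence_unmix <- function(x, ps_basis, background_basis, n_fourier = 1,
                               nonneg = FALSE) {
  stopifnot(inherits(x, "spectrum"), inherits(ps_basis, "spectrum"),
            inherits(background_basis, "spectrum"))
  if (!same_grid(x$wavelengths, ps_basis$wavelengths) ||
      !same_grid(x$wavelengths, background_basis$wavelengths))
    stop("spectrum and bases are on different wavelength grids", call. = FALSE)
  if (n_fourier < 0) stop("n_fourier must be >= 0", call. = FALSE)
  wl <- x$wavelengths
  comps <- cbind(ps = ps_basis$intensities, bg = background_basis$intensities)
  if (n_fourier > 0) {
    u <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
    for (k in seq_len(n_fourier)) {
      comps <- cbind(comps, cos(2 * pi * k * u), sin(2 * pi * k * u))
      colnames(comps)[ncol(comps) - 1:0] <- paste0(c("cos", "sin"), k)
    }
  }
  svd_unmix(x, basis_matrix(wl, comps), nonneg = nonneg)
}

#' Track relative photosensitizer concentration by fluorescence unmixing
#'
#' Applies [fluorescence_unmix()] to a fluorescence time series and divides
#' each photosensitizer amplitude by the amplitude of the first (pre-PDT)
#' acquisition.
#'
#' @param series List of `spectrum` objects with `t_acq_s` set.
#' @inheritParams fluorescence_unmix
#' @return data.frame `t_s, a_ps, rel_concentration`, sorted by `t_s`.
#' @export
fluorescence_series <- function(series, ps_basis, background_basis,
                                n_fourier = 1) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  rows <- vapply(series, function(s) {
    u <- fluorescence_unmix(s, ps_basis, background_basis, n_fourier)
    c(s$t_acq_s, u$amplitudes[["ps"]])
  }, numeric(2))
  out <- data.frame(t_s = rows[1, ], a_ps = rows[2, ])
  out <- out[order(out$t_s), ]
  rownames(out) <- NULL
  out$rel_concentration <- out$a_ps / out$a_ps[1]
  out
}
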