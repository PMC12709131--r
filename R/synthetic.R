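#' Basis-shape configuration for the synthetic spectrometer
#'
#' Shapes of the three NIR components mixed into every synthetic spectrum:
#' the singlet oxygen emission band (Gaussian at 1270 nm), a broad
#' monotone-decaying photosensitizer phosphorescence, and a laser background
#' concentrated at the short-wavelength edge of the window. Each shape is
#' peak-normalised to 1 on the grid. The band parameters are configurable:
#' real instruments resolve the 1270 nm band but its exact width depends on
#' solvent and spectrometer; the background tail shape is synthetic.
#'
#' @param o2_center_nm Centre of the singlet oxygen band (default 1270).
#' @param o2_fwhm_nm Full width at half maximum of the band (default 20).
#' @param phos_scale_nm Exponential decay scale of the phosphorescence
#'   component across the window (default 200).
#' @param bg_scale_nm Exponential decay scale of the laser background from
#'   the short-wavelength edge (default 30).
#' @param grid A `wavelength_grid` (default 1200-1600 nm, 256 points).
#' @return An object of class `"basis_shape_config"`.
#' @export
basis_shape_config <- function(o2_center_nm = 1270, o2_fwhm_nm = 20,
                               phos_scale_nm = 200, bg_scale_nm = 30,
                               grid = wavelength_grid(1200, 1600, 256)) {
  if (o2_center_nm < grid$start_nm || o2_center_nm > grid$stop_nm)
    stop("o2_center_nm must lie inside the grid", call. = FALSE)
  if (o2_fwhm_nm <= 0 || phos_scale_nm <= 0 || bg_scale_nm <= 0)
    stop("shape scales must be > 0", call. = FALSE)
  structure(list(o2_center_nm = o2_center_nm, o2_fwhm_nm = o2_fwhm_nm,
                 phos_scale_nm = phos_scale_nm, bg_scale_nm = bg_scale_nm,
                 grid = grid),
            class = "basis_shape_config")
}

#' Noise model configuration
#'
#' @param model `"gaussian_constant"` (additive Gaussian, sd = `sigma`
#'   counts), `"gaussian_scaled"` (additive Gaussian, sd = `sigma` times the
#'   peak of the noiseless series) or `"poisson"` (counts drawn as
#'   `gain * rpois(intensity / gain)`).
#' @param sigma Noise sd (counts, or fraction of peak for
#'   `gaussian_scaled`); >= 0.
#' @param gain Counts per photoelectron for the Poisson model.
#' @param seed Integer seed; reproducibly determines the noise stream.
#' @return An object of class `"noise_config"`.
#' @export
noise_config <- function(model = c("gaussian_constant", "gaussian_scaled", "poisson"),
                         sigma = 0, gain = 1, seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  structure(list(model = model, sigma = sigma, gain = gain,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Build the three-component basis matrix
#'
#' @param config A `basis_shape_config`.
#' @return A `basis_matrix` (see [basis_matrix()]) with components
#'   `o2`, `phos`, `bg`, each peak-normalised to 1 on the grid.
#' @examples
#' B <- make_basis(basis_shape_config())
#' B
#' @export
make_basis <- function(config = basis_shape_config()) {
  wl <- config$grid$wavelengths
  s <- config$o2_fwhm_nm / (2 * sqrt(2 * log(2)))
  o2 <- exp(-(wl - config$o2_center_nm)^2 / (2 * s^2))
  phos <- exp(-(wl - wl[1]) / config$phos_scale_nm)
  bg <- exp(-(wl - wl[1]) / config$bg_scale_nm)
  norm1 <- function(v) v / max(v)
  basis_matrix(wavelengths = wl,
               components = cbind(o2 = norm1(o2), phos = norm1(phos),
                                  bg = norm1(bg)))
}

#' Build a fluorescence-window basis
#'
#' Photosensitizer fluorescence band (Gaussian, default 690 nm / 25 nm FWHM)
#' and a broad excitation-background component on a 600-800 nm grid, used for
#' photobleaching tracking.
#'
#' @param grid A `wavelength_grid` (default 600-800 nm, 128 points).
#' @param center_nm,fwhm_nm Fluorescence band centre and width.
#' @param bg_scale_nm Background decay scale from the short-wavelength edge.
#' @return A `basis_matrix` with components `ps`, `bg`.
#' @export
make_fluorescence_basis <- function(grid = wavelength_grid(600, 800, 128),
                                    center_nm = 690, fwhm_nm = 25,
                                    bg_scale_nm = 120) {
  wl <- grid$wavelengths
  s <- fwhm_nm / (2 * sqrt(2 * log(2)))
  ps <- exp(-(wl - center_nm)^2 / (2 * s^2))
  bg <- exp(-(wl - wl[1]) / bg_scale_nm)
  basis_matrix(wavelengths = wl,
               components = cbind(ps = ps / max(ps), bg = bg / max(bg)))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

add_noise <- function(mat, noise, peak) {
  switch(noise$model,
    gaussian_constant = mat + stats::rnorm(length(mat), 0, noise$sigma),
    gaussian_scaled   = mat + stats::rnorm(length(mat), 0, noise$sigma * peak),
    poisson           = {
      lam <- pmax(mat, 0) / noise$gain
      noise$gain * stats::rpois(length(mat), lam)
    })
}

#' Simulate a noisy MSOLD time series with ground truth
#'
#' Forward model of the phantom experiment: the SOED trajectory is integrated
#' for the phantom and protocol, and at each acquisition time `t` the emitted
#' spectrum is the linear mixture
#' `a_o2(t) * B_o2 + a_phos(t) * B_phos + a_bg * B_bg + noise`, with
#' `a_o2(t) = kappa_detect * [1O2](t)` (instantaneous singlet oxygen),
#' `a_phos(t) = kappa_phos * phi(t) * [S0](t)` (phosphorescence proportional
#' to excitation rate and remaining ground-state photosensitizer) and a
#' constant background amplitude. `kappa_detect` and `kappa_phos` are free
#' detection constants: absolute count scales are setup-dependent.
#'
#' @param phantom A `phantom_spec`.
#' @param protocol An `irradiation_protocol`.
#' @param params A `soed_parameters` object.
#' @param basis A three-component `basis_matrix` with components
#'   `o2`, `phos`, `bg` (see [make_basis()]).
#' @param noise A `noise_config`.
#' @param kappa_detect Detection scale, counts per uM of instantaneous
#'   singlet oxygen (default 500).
#' @param kappa_phos Phosphorescence scale, counts per (mW/cm2 uM)
#'   (default 2e-4).
#' @param a_bg Constant background amplitude in counts (default 0.5).
#' @return A list with elements:
#'   \describe{
#'     \item{spectra}{list of `spectrum` objects, one per acquisition time}
#'     \item{truth}{data.frame `t_s, a_o2, a_phos, a_bg, S0_uM, O2_uM,
#'       O2rx_uM, inst_1O2_uM` (the ground truth)}
#'     \item{trajectory}{the underlying `soed_trajectory`}
#'     \item{kappa_detect, kappa_phos, seed}{the generator constants}
#'   }
#' @export
simulate_series <- function(phantom, protocol = irradiation_protocol(),
                            params = soed_parameters(),
                            basis = make_basis(),
                            noise = noise_config(),
                            kappa_detect = 500, kappa_phos = 2e-4,
                            a_bg = 0.5) {
  stopifnot(inherits(basis, "basis_matrix"))
  if (!all(c("o2", "phos", "bg") %in% colnames(basis$components)))
    stop("basis must have components o2, phos, bg", call. = FALSE)
  if (kappa_detect < 0 || kappa_phos < 0 || a_bg < 0)
    stop("amplitudes must be >= 0", call. = FALSE)

  tacq <- acquisition_times(protocol)
  traj <- integrate_soed(phantom, protocol, params, dt_out = protocol$cadence_s)
  traj_at <- traj[match(tacq, traj$t_s), ]
  stopifnot(!anyNA(traj_at$t_s))

  a_o2 <- kappa_detect * traj_at$inst_1O2_uM
  a_phos <- kappa_phos * fluence_rate_at(protocol, tacq) * traj_at$S0_uM
  amps <- cbind(o2 = a_o2, phos = a_phos, bg = rep(a_bg, length(tacq)))

  clean <- basis$components %*% t(amps)           # n_wavelengths x n_times
  peak <- max(abs(clean), 1e-300)
  noisy <- with_seed(noise$seed, add_noise(clean, noise, peak))

  spectra <- lapply(seq_along(tacq), function(i) {
    spectrum(basis$wavelengths, noisy[, i],
             exposure_s = protocol$exposure_s, t_acq_s = tacq[i])
  })
  truth <- data.frame(t_s = tacq, a_o2 = a_o2, a_phos = a_phos, a_bg = a_bg,
                      S0_uM = traj_at$S0_uM, O2_uM = traj_at$O2_uM,
                      O2rx_uM = traj_at$O2rx_uM,
                      inst_1O2_uM = traj_at$inst_1O2_uM)
  list(spectra = spectra, truth = truth, trajectory = traj,
       kappa_detect = kappa_detect, kappa_phos = kappa_phos,
       seed = noise$seed)
}

#' Simulate a fluorescence-window time series for photobleaching tracking
#'
#' The photosensitizer fluorescence amplitude is proportional to the
#' remaining ground-state concentration: `a_ps(t) = kappa_fluor * [S0](t)`,
#' on top of a constant background, using the same SOED trajectory as the
#' NIR series.
#'
#' @inheritParams simulate_series
#' @param basis A two-component `basis_matrix` with components `ps`, `bg`
#'   (see [make_fluorescence_basis()]).
#' @param kappa_fluor Counts per uM of ground-state photosensitizer.
#' @return As [simulate_series()], with truth columns
#'   `t_s, a_ps, a_bg, S0_uM, rel_S0`.
#' @export
simulate_fluorescence_series <- function(phantom,
                                         protocol = irradiation_protocol(),
                                         params = soed_parameters(),
                                         basis = make_fluorescence_basis(),
                                         noise = noise_config(),
                                         kappa_fluor = 100, a_bg = 0.5) {
  stopifnot(inherits(basis, "basis_matrix"))
  if (!all(c("ps", "bg") %in% colnames(basis$components)))
    stop("basis must have components ps, bg", call. = FALSE)
  tacq <- acquisition_times(protocol)
  traj <- integrate_soed(phantom, protocol, params, dt_out = protocol$cadence_s)
  traj_at <- traj[match(tacq, traj$t_s), ]
  a_ps <- kappa_fluor * traj_at$S0_uM
  amps <- cbind(ps = a_ps, bg = rep(a_bg, length(tacq)))
  clean <- basis$components %*% t(amps)
  peak <- max(abs(clean), 1e-300)
  noisy <- with_seed(noise$seed + 1L, add_noise(clean, noise, peak))
  spectra <- lapply(seq_along(tacq), function(i) {
    spectrum(basis$wavelengths, noisy[, i],
             exposure_s = protocol$exposure_s, t_acq_s = tacq[i])
  })
  truth <- data.frame(t_s = tacq, a_ps = a_ps, a_bg = a_bg,
                      S0_uM = traj_at$S0_uM,
                      rel_S0 = traj_at$S0_uM / traj_at$S0_uM[1])
  list(spectra = spectra, truth = truth, trajectory = traj,
       kappa_fluor = kappa_fluor, seed = noise$seed)
}

#' Simulate a sodium-azide quenching pair
#'
#' Returns a (pre-quench, post-quench) pair of spectra in which quenching
#' suppresses the singlet oxygen amplitude to a residual fraction `r`,
#' leaving phosphorescence and background unchanged — the difference spectrum
#' isolates the singlet oxygen band.
#'
#' @inheritParams simulate_series
#' @param a_o2,a_phos Pre-quench component amplitudes in counts.
#' @param r Residual singlet oxygen fraction after quenching, in `[0, 1)`
#'   (default 0.05: quenching is never perfect).
#' @return List with elements `pre` and `post`, both `spectrum` objects.
#' @export
simulate_quench_pair <- function(basis = make_basis(), a_o2 = 10, a_phos = 5,
                                 a_bg = 0.5, r = 0.05,
                                 noise = noise_config()) {
  if (r < 0 || r >= 1)
    stop("residual fraction r must lie in [0, 1)", call. = FALSE)
  if (a_o2 < 0 || a_phos < 0 || a_bg < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  B <- basis$components
  pre_clean <- B %*% c(a_o2, a_phos, a_bg)
  post_clean <- B %*% c(r * a_o2, a_phos, a_bg)
  peak <- max(abs(pre_clean), 1e-300)
  noisy <- with_seed(noise$seed, {
    list(pre = add_noise(pre_clean, noise, peak),
         post = add_noise(post_clean, noise, peak))
  })
  list(pre = spectrum(basis$wavelengths, noisy$pre),
       post = spectrum(basis$wavelengths, noisy$post))
}

#' Write a simulated series to disk
#'
#' Writes the long-format spectra CSV, a ground-truth CSV and a JSON sidecar
#' recording the generator constants and seed, so a simulation is fully
#' reproducible from its files.
#'
#' @param sim Result of [simulate_series()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_series <- function(sim, dir, stem = "series") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_spec <- file.path(dir, paste0(stem, "_spectra.csv"))
  f_truth <- file.path(dir, paste0(stem, "_truth.csv"))
  f_meta <- file.path(dir, paste0(stem, "_meta.json"))
  write_spectrum(sim$spectra, f_spec)
  truth <- sim$truth
  utils::write.csv(format(truth, digits = 12, trim = TRUE), f_truth,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(kappa_detect = sim$kappa_detect, kappa_phos = sim$kappa_phos,
         seed = sim$seed),
    f_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(spectra = f_spec, truth = f_truth, meta = f_meta))
}
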