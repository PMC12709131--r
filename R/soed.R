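#' Photophysical parameters of the SOED model
#'
#' Defaults are the in-vitro literature values for the benzoporphyrin
#' derivative (BPD) photosensitizer. All concentrations are uM, times s,
#' fluence rates mW/cm2.
#'
#' @param xi Specific oxygen consumption rate, cm2 mW^-1 s^-1 (default 51e-3).
#' @param beta Oxygen quenching threshold concentration, uM (default 11.9).
#' @param delta Low-concentration correction, uM (default 33).
#' @param sigma Specific photobleaching ratio, uM^-1 (default 1.7e-5).
#' @param tau_delta Singlet oxygen lifetime, s (default 9.4e-6).
#' @param k7 Rate constant for singlet-oxygen quenching by substrate,
#'   uM^-1 s^-1 (default 0; with `A = 0` the term vanishes).
#' @param A Concentration of biomolecular acceptors being oxidised, uM
#'   (default 0: no azide/substrate in the solvent).
#' @return An object of class `"soed_parameters"`.
#' @examples
#' soed_parameters()
#' @export
soed_parameters <- function(xi = 51e-3, beta = 11.9, delta = 33,
                            sigma = 1.7e-5, tau_delta = 9.4e-6,
                            k7 = 0, A = 0) {
  p <- list(xi = xi, beta = beta, delta = delta, sigma = sigma,
            tau_delta = tau_delta, k7 = k7, A = A)
  if (any(unlist(p) < 0)) stop("SOED parameters must be >= 0", call. = FALSE)
  if (tau_delta <= 0) stop("tau_delta must be > 0", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(p, class = "soed_parameters")
}

#' @export
print.soed_parameters <- function(x, ...) {
  cat("<soed_parameters>\n")
  cat(sprintf("  xi        %g cm2 mW^-1 s^-1\n", x$xi))
  cat(sprintf("  beta      %g uM\n", x$beta))
  cat(sprintf("  delta     %g uM\n", x$delta))
  cat(sprintf("  sigma     %g uM^-1\n", x$sigma))
  cat(sprintf("  tau_delta %g s\n", x$tau_delta))
  cat(sprintf("  k7        %g uM^-1 s^-1, [A] %g uM\n", x$k7, x$A))
  invisible(x)
}

#' Irradiation protocol
#'
#' A constant treatment fluence rate over a fixed duration, with optional
#' pauses (laser off) used e.g. for fluorescence measurements. The default is
#' the 850 mW/cm2 x 900 s protocol (765 J/cm2 delivered).
#'
#' @param phi Fluence rate in mW/cm2 (default 850).
#' @param duration_s Total protocol duration in s (default 900).
#' @param pauses Optional two-column matrix or data.frame `(start_s,
#'   length_s)`; the fluence rate is 0 inside each pause. Pauses must lie
#'   within `[0, duration_s]` and not overlap.
#' @param cadence_s Acquisition cadence in s (default 100): one spectrometer
#'   exposure every `cadence_s`, starting at t = 0.
#' @param exposure_s Exposure length of each acquisition in s (default 5).
#' @return An object of class `"irradiation_protocol"`.
#' @export
irradiation_protocol <- function(phi = 850, duration_s = 900, pauses = NULL,
                                 cadence_s = 100, exposure_s = 5) {
  if (phi < 0) stop("phi must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (!is.null(pauses)) {
    pauses <- as.matrix(pauses)
    if (ncol(pauses) != 2) stop("pauses must have columns (start_s, length_s)",
                                call. = FALSE)
    colnames(pauses) <- c("start_s", "length_s")
    if (any(pauses < 0) || any(pauses[, 1] + pauses[, 2] > duration_s))
      stop("pauses must lie within [0, duration_s]", call. = FALSE)
    pauses <- pauses[order(pauses[, 1]), , drop = FALSE]
    if (nrow(pauses) > 1 &&
        any(pauses[-1, 1] < (pauses[-nrow(pauses), 1] + pauses[-nrow(pauses), 2])))
      stop("pauses must not overlap", call. = FALSE)
  }
  structure(list(phi = phi, duration_s = duration_s, pauses = pauses,
                 cadence_s = cadence_s, exposure_s = exposure_s),
            class = "irradiation_protocol")
}

#' @export
print.irradiation_protocol <- function(x, ...) {
  cat(sprintf("<irradiation_protocol> %g mW/cm2 for %g s (%g J/cm2), %d pause(s)\n",
              x$phi, x$duration_s, cumulative_fluence(x, x$duration_s),
              if (is.null(x$pauses)) 0L else nrow(x$pauses)))
  invisible(x)
}

#' Fluence rate at a given time
#'
#' `phi` inside the irradiation window and outside any pause, otherwise 0.
#'
#' @param protocol An `irradiation_protocol`.
#' @param t Time(s) in s.
#' @return Fluence rate(s) in mW/cm2.
#' @export
fluence_rate_at <- function(protocol, t) {
  phi <- ifelse(t >= 0 & t <= protocol$duration_s, protocol$phi, 0)
  if (!is.null(protocol$pauses)) {
    for (i in seq_len(nrow(protocol$pauses))) {
      a <- protocol$pauses[i, 1]
      b <- a + protocol$pauses[i, 2]
      phi[t >= a & t < b] <- 0
    }
  }
  phi
}

#' Acquisition schedule of a protocol
#'
#' @param protocol An `irradiation_protocol`.
#' @return Numeric vector of acquisition start times: `0, cadence_s, ...`
#'   up to `duration_s`.
#' @export
acquisition_times <- function(protocol) {
  seq(0, protocol$duration_s, by = protocol$cadence_s)
}

#' Phantom description
#'
#' @param bpd_mg_per_L Photosensitizer concentration in mg/L.
#' @param molecular_weight_g_per_mol Photosensitizer molecular weight
#'   (default 718.8 g/mol for BPD), used only for the mg/L -> uM conversion.
#' @param O2_uM Initial ground-state oxygen concentration in uM
#'   (default 194, the measured phantom value).
#' @param oxygen_mode `"clamped"` (oxygen held constant, the phantom regime:
#'   air diffusion resupplies the thin sensed layer) or `"evolving"` (oxygen
#'   follows its rate equation).
#' @return An object of class `"phantom_spec"` with the derived `S0_uM`.
#' @export
phantom_spec <- function(bpd_mg_per_L, molecular_weight_g_per_mol = 718.8,
                         O2_uM = 194, oxygen_mode = c("clamped", "evolving")) {
  oxygen_mode <- match.arg(oxygen_mode)
  if (bpd_mg_per_L < 0 || O2_uM < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(bpd_mg_per_L = bpd_mg_per_L,
                 molecular_weight_g_per_mol = molecular_weight_g_per_mol,
                 S0_uM = mgL_to_uM(bpd_mg_per_L, molecular_weight_g_per_mol),
                 O2_uM = O2_uM, oxygen_mode = oxygen_mode),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %g mg/L BPD (%.4g uM), O2 %g uM (%s)\n",
              x$bpd_mg_per_L, x$S0_uM, x$O2_uM, x$oxygen_mode))
  invisible(x)
}

#' Convert a mass concentration to a molar concentration
#'
#' @param c Concentration in mg/L.
#' @param mw Molecular weight in g/mol.
#' @return Concentration in uM (`1000 * c / mw`).
#' @examples
#' mgL_to_uM(6, 718.8)  # ~8.347 uM
#' @export
mgL_to_uM <- function(c, mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  1000 * c / mw
}

#' Convert an oxygen partial pressure to a concentration
#'
#' Uses the 1.295 uM/mmHg conversion factor standard in tissue studies.
#'
#' @param p Partial pressure in mmHg, >= 0.
#' @return Concentration in uM.
#' @examples
#' mmHg_to_uM(100)  # 129.5
#' @export
mmHg_to_uM <- function(p) {
  if (any(p < 0)) stop("pressure must be >= 0", call. = FALSE)
  1.295 * p
}

#' Cumulative delivered fluence
#'
#' Time integral of the fluence rate up to `t`, with pauses contributing
#' zero, converted from mW s/cm2 to J/cm2.
#'
#' @param protocol An `irradiation_protocol`.
#' @param t Time in s, within `[0, duration_s]`.
#' @return Fluence in J/cm2.
#' @examples
#' cumulative_fluence(irradiation_protocol(phi = 850, duration_s = 900), 900)  # 765
#' @export
cumulative_fluence <- function(protocol, t) {
  if (any(t < 0 | t > protocol$duration_s))
    stop("t must lie in [0, duration_s]", call. = FALSE)
  on_time <- t
  if (!is.null(protocol$pauses)) {
    for (i in seq_len(nrow(protocol$pauses))) {
      a <- protocol$pauses[i, 1]
      b <- a + protocol$pauses[i, 2]
      on_time <- on_time - pmax(0, pmin(t, b) - a)
    }
  }
  protocol$phi * on_time / 1000
}

#' Instantaneous singlet oxygen concentration
#'
#' The quasi-steady-state singlet oxygen concentration of the Type II
#' photodynamic process:
#' \deqn{[^1O_2] = \xi \tau_\Delta \frac{[^3O_2]}{[^3O_2]+\beta} \phi [S_0]
#'       \frac{1}{\sigma([S_0]+\delta)+1}.}
#'
#' @param S0 Ground-state photosensitizer concentration, uM.
#' @param O2 Ground-state oxygen concentration, uM.
#' @param params A `soed_parameters` object.
#' @param phi Fluence rate, mW/cm2.
#' @return Instantaneous singlet oxygen concentration in uM.
#' @examples
#' instantaneous_singlet_oxygen(S0 = mgL_to_uM(6, 718.8), O2 = 194,
#'                              params = soed_parameters(), phi = 850)
#' @export
instantaneous_singlet_oxygen <- function(S0, O2, params = soed_parameters(), phi) {
  f <- O2 / (O2 + params$beta)
  g <- params$sigma * (S0 + params$delta)
  params$xi * params$tau_delta * f * phi * S0 / (g + 1)
}

#' Right-hand side of the SOED rate equations
#'
#' With \eqn{f = [^3O_2]/([^3O_2]+\beta)}, \eqn{g = \sigma([S_0]+\delta)} and
#' \eqn{r_0 = \xi f \phi [S_0]}:
#' \deqn{d[S_0]/dt = -r_0\, g/(g+1)}
#' \deqn{d[^3O_2]/dt = -r_0\,(g + k_7 [A] \tau_\Delta)/(g+1)}
#' \deqn{d[^1O_2]_{rx}/dt = r_0/(g+1)}
#' Note that at \eqn{[A]=0} the oxygen and photosensitizer equations are
#' identical as printed, so \eqn{[^3O_2]-[S_0]} is conserved in evolving mode.
#' In clamped mode `dO2` is 0.
#'
#' @param S0,O2 State concentrations, uM.
#' @param params A `soed_parameters` object.
#' @param phi Fluence rate, mW/cm2.
#' @param oxygen_mode `"clamped"` or `"evolving"`.
#' @return Named numeric vector `c(dS0, dO2, dO2rx)` in uM/s.
#' @export
soed_rhs <- function(S0, O2, params = soed_parameters(), phi,
                     oxygen_mode = c("clamped", "evolving")) {
  oxygen_mode <- match.arg(oxygen_mode)
  f <- O2 / (O2 + params$beta)
  g <- params$sigma * (S0 + params$delta)
  r0 <- params$xi * f * phi * S0
  dS0 <- -r0 * g / (g + 1)
  dO2 <- if (oxygen_mode == "clamped") 0 else
    -r0 * (g + params$k7 * params$A * params$tau_delta) / (g + 1)
  dO2rx <- r0 / (g + 1)
  c(dS0 = dS0, dO2 = dO2, dO2rx = dO2rx)
}

#' Integrate the SOED model over an irradiation protocol
#'
#' Adaptive integration (lsoda) of the photobleaching / oxygen / cumulative
#' dose system from t = 0 to the protocol duration, with relative tolerance
#' 1e-8 and absolute tolerance 1e-12 uM. Pauses are handled by integrating
#' piecewise between fluence-rate discontinuities. States are clipped to 0
#' only within the absolute tolerance; a more negative state is an
#' integration failure and raises an error.
#'
#' @param phantom A `phantom_spec`.
#' @param protocol An `irradiation_protocol`.
#' @param params A `soed_parameters` object.
#' @param dt_out Output time step in s (default the protocol cadence).
#' @param rtol,atol Integrator relative / absolute (uM) tolerances.
#' @return An object of class `"soed_trajectory"`: a data.frame with columns
#'   `t_s`, `S0_uM`, `O2_uM`, `O2rx_uM`, `inst_1O2_uM`, `fluence_J_cm2`.
#' @examples
#' tr <- integrate_soed(phantom_spec(6), irradiation_protocol(), dt_out = 100)
#' head(tr)
#' @export
integrate_soed <- function(phantom, protocol, params = soed_parameters(),
                           dt_out = protocol$cadence_s,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(protocol, "irradiation_protocol"))
  if (dt_out <= 0) stop("dt_out must be > 0", call. = FALSE)

  t_out <- seq(0, protocol$duration_s, by = dt_out)
  if (t_out[length(t_out)] < protocol$duration_s)
    t_out <- c(t_out, protocol$duration_s)

  # segment boundaries: protocol start/end plus pause edges
  edges <- c(0, protocol$duration_s)
  if (!is.null(protocol$pauses))
    edges <- c(edges, protocol$pauses[, 1], protocol$pauses[, 1] + protocol$pauses[, 2])
  edges <- sort(unique(edges))

  deriv <- function(t, y, parms) {
    d <- soed_rhs(S0 = y[1], O2 = y[2], params = params, phi = parms$phi,
                  oxygen_mode = phantom$oxygen_mode)
    list(d)
  }

  y <- c(S0 = phantom$S0_uM, O2 = phantom$O2_uM, O2rx = 0)
  rows <- list(c(t = 0, y))
  for (k in seq_len(length(edges) - 1)) {
    a <- edges[k]; b <- edges[k + 1]
    phi_seg <- fluence_rate_at(protocol, (a + b) / 2)
    tt <- unique(c(a, t_out[t_out > a & t_out < b], b))
    sol <- deSolve::lsoda(y, tt, deriv, parms = list(phi = phi_seg),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("SOED integration failed in segment [", a, ", ", b, "]", call. = FALSE)
    sol <- as.data.frame(sol)
    neg <- sol$S0 < -100 * atol | sol$O2 < -100 * atol
    if (any(neg))
      stop("SOED integration produced a negative state beyond tolerance",
           call. = FALSE)
    sol$S0 <- pmax(sol$S0, 0)
    sol$O2 <- pmax(sol$O2, 0)
    keep <- sol$time %in% t_out & sol$time > a
    for (i in which(keep))
      rows[[length(rows) + 1]] <- c(t = sol$time[i], S0 = sol$S0[i],
                                    O2 = sol$O2[i], O2rx = sol$O2rx[i])
    last <- nrow(sol)
    y <- c(S0 = sol$S0[last], O2 = sol$O2[last], O2rx = sol$O2rx[last])
  }
  m <- do.call(rbind, rows)
  out <- data.frame(t_s = m[, "t"], S0_uM = m[, "S0"], O2_uM = m[, "O2"],
                    O2rx_uM = m[, "O2rx"])
  out <- out[!duplicated(out$t_s), ]
  out <- out[order(out$t_s), ]
  rownames(out) <- NULL
  out$inst_1O2_uM <- instantaneous_singlet_oxygen(
    S0 = out$S0_uM, O2 = out$O2_uM, params = params,
    phi = fluence_rate_at(protocol, out$t_s))
  out$fluence_J_cm2 <- cumulative_fluence(protocol, out$t_s)
  class(out) <- c("soed_trajectory", "data.frame")
  attr(out, "phantom") <- phantom
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  out
}

#' @export
print.soed_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<soed_trajectory> %d time points, 0-%g s\n", n, x$t_s[n]))
  cat(sprintf("  S0: %.4g -> %.4g uM; O2rx total: %.6g uM; fluence %.4g J/cm2\n",
              x$S0_uM[1], x$S0_uM[n], x$O2rx_uM[n], x$fluence_J_cm2[n]))
  invisible(x)
}

#' Fixed-step Euler integration of the SOED model
#'
#' Brute-force reference integrator used for validating the adaptive one:
#' forward Euler at a fixed (small) step. Not for production use.
#'
#' @inheritParams integrate_soed
#' @param dt Euler step in s.
#' @param t_end End time in s.
#' @return data.frame `t_s, S0_uM, O2_uM, O2rx_uM` at `t_end` steps of `dt`,
#'   reported at `0` and `t_end` only.
#' @keywords internal
#' @export
soed_euler <- function(phantom, params = soed_parameters(), phi, t_end, dt) {
  n <- round(t_end / dt)
  S0 <- phantom$S0_uM; O2 <- phantom$O2_uM; O2rx <- 0
  for (i in seq_len(n)) {
    d <- soed_rhs(S0, O2, params, phi, oxygen_mode = phantom$oxygen_mode)
    S0 <- S0 + dt * d[[1]]
    O2 <- O2 + dt * d[[2]]
    O2rx <- O2rx + dt * d[[3]]
  }
  data.frame(t_s = n * dt, S0_uM = S0, O2_uM = O2, O2rx_uM = O2rx)
}
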