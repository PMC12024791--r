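#' Linearized periodic ERK* response to a Fourier-decomposed input
#'
#' Propagates each harmonic of a periodic ligand waveform through the
#' pathway's frequency response: the mean term `a0/2` maps to the nonlinear
#' equilibrium ERK* at that constant dose, and each sinusoid at harmonic
#' frequency `w_n = 2 pi n / T` is scaled by the modulation `M(w_n)` and
#' shifted by the phase `phi(w_n)` of the transfer function evaluated at
#' the equilibrium. The reconstruction is the steady periodic response;
#' metrics are taken over one full cycle.
#'
#' @param series A `fourier_series` describing the input waveform.
#' @param baseline_eq An `equilibrium` at the constant dose `a0/2` (solved
#'   automatically when omitted).
#' @param params A `pathway_params`; defaults to those in `baseline_eq`.
#' @param ss Optional precomputed `pathway_ss` linearization at
#'   `baseline_eq`.
#' @param t_step Output time resolution in seconds (default 1).
#' @return An object of class `forced_response`: list with `t` (one cycle),
#'   `input` (reconstructed input waveform), `erk_star` (periodic output),
#'   `baseline` (equilibrium ERK*), and `metrics` (list
#'   `equilibrium_level`, `peak`, `trough`, `gain_modulation` =
#'   peak / equilibrium_level).
#' @examples
#' sp <- pulse_train_spec("rectangular", A = 0.08, T = 1200, tau = 180)
#' fr <- forced_response(fourier_rectangular(sp),
#'                       params = pathway_params("EGF"))
#' fr$metrics$gain_modulation
#' @export
forced_response <- function(series, baseline_eq = NULL, params = NULL,
                            ss = NULL, t_step = 1) {
  stopifnot(inherits(series, "fourier_series"))
  if (is.null(baseline_eq)) {
    if (is.null(params)) stop("supply either baseline_eq or params")
    baseline_eq <- solve_equilibrium(params, series$a0 / 2)
  }
  if (is.null(params)) params <- baseline_eq$params
  if (abs(baseline_eq$ue - series$a0 / 2) > 1e-9 * max(1, series$a0)) {
    stop("baseline equilibrium dose must equal the waveform mean a0/2")
  }
  if (!baseline_eq$stable) {
    stop("equilibrium is unstable: steady periodic response undefined")
  }
  if (is.null(ss)) ss <- linearize(baseline_eq, params)

  n <- seq_len(series$N)
  wn <- 2 * pi * n / series$T
  tfv <- resolvent_tf(ss, 1i * wn)
  M <- abs(tfv)
  phi <- Arg(tfv)

  t <- seq(0, series$T, by = t_step)
  erk <- rep(baseline_eq$xe[["ERKp"]], length(t))
  for (k in n) {
    ph <- wn[k] * t + phi[k]
    if (series$an[k] != 0) erk <- erk + M[k] * series$an[k] * cos(ph)
    if (series$bn[k] != 0) erk <- erk + M[k] * series$bn[k] * sin(ph)
  }
  base <- baseline_eq$xe[["ERKp"]]
  metrics <- list(
    equilibrium_level = base,
    peak = max(erk),
    trough = min(erk),
    gain_modulation = max(erk) / base
  )
  structure(list(t = t, input = fourier_eval(series, t), erk_star = erk,
                 baseline = base, metrics = metrics, series = series,
                 params = params),
            class = "forced_response")
}

#' @export
print.forced_response <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Periodic ERK* response (%s, mean dose %.4g Kd, period %g s):\n",
    x$params$ligand, x$series$a0 / 2, x$series$T))
  cat(sprintf(
    "  equilibrium %.4g, peak %.4g, gain modulation %.3g\n",
    m$equilibrium_level, m$peak, m$gain_modulation))
  invisible(x)
}

#' Predicted ERK* response to a sinusoidal ligand input
#'
#' A single-harmonic special case of [forced_response()]: the output is a
#' sinusoid at the input frequency, demodulated by `M(omega)` and shifted
#' by `phi(omega)`, about the equilibrium ERK* at the mean dose.
#'
#' @param params A `pathway_params` object.
#' @param mean_dose Mean ligand level, Kd units.
#' @param amplitude Sinusoid amplitude, Kd units (must not exceed
#'   `mean_dose`).
#' @param omega Angular frequency, rad/s.
#' @param t_step Output time resolution, seconds.
#' @return A `forced_response` whose metrics additionally contain
#'   `dc_level`, `modulation` and `phase_lag_deg`.
#' @examples
#' sinusoid_prediction(pathway_params("EGF"), 0.03, 0.01, 1e-3)$metrics$dc_level
#' @export
sinusoid_prediction <- function(params, mean_dose, amplitude, omega,
                                t_step = NULL) {
  stopifnot(amplitude >= 0, amplitude <= mean_dose, omega > 0)
  eq <- solve_equilibrium(params, mean_dose)
  if (!eq$stable) stop("equilibrium is unstable")
  ss <- linearize(eq, params)
  tfv <- resolvent_tf(ss, 1i * omega)[1]
  M <- abs(tfv); phi <- Arg(tfv)
  Tper <- 2 * pi / omega
  if (is.null(t_step)) t_step <- Tper / 1000
  t <- seq(0, Tper, by = t_step)
  base <- eq$xe[["ERKp"]]
  erk <- base + M * amplitude * sin(omega * t + phi)
  metrics <- list(
    equilibrium_level = base,
    dc_level = base,
    peak = max(erk),
    trough = min(erk),
    gain_modulation = max(erk) / base,
    modulation = M,
    phase_lag_deg = -phi * 180 / pi
  )
  structure(list(t = t, input = mean_dose + amplitude * sin(omega * t),
                 erk_star = erk, baseline = base, metrics = metrics,
                 series = new_fourier_series(2 * mean_dose, 0, amplitude,
                                             Tper),
                 params = params),
            class = "forced_response")
}
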