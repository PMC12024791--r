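#' Specify a periodic ligand waveform
#'
#' Describes the synthetic periodic growth-factor inputs used throughout
#' the forcing pipeline: a rectangular pulse train (ligand on at amplitude
#' `A` for `tau` seconds out of every `T` seconds), a triangular wave
#' (linear ramp from 0 up to `A` and back each period), or a pure sinusoid
#' about a mean.
#'
#' @param shape `"rectangular"`, `"triangular"` or `"sinusoid"`.
#' @param A Amplitude in Kd units (>= 0). For the sinusoid this is the
#'   oscillation amplitude about `mean`.
#' @param T Period in seconds (> 0).
#' @param tau Pulse width in seconds, rectangular shape only
#'   (`0 < tau < T`).
#' @param mean Mean level in Kd units, sinusoid only (must be >= `A` so the
#'   ligand concentration stays non-negative).
#' @param phase_origin Time of the first pulse onset, seconds.
#' @return An object of class `pulse_train_spec`.
#' @examples
#' pulse_train_spec("rectangular", A = 0.08, T = 1200, tau = 180)
#' @export
pulse_train_spec <- function(shape = c("rectangular", "triangular",
                                       "sinusoid"),
                             A, T, tau = NULL, mean = NULL,
                             phase_origin = 0) {
  shape <- match.arg(shape)
  stopifnot(A >= 0, T > 0)
  if (shape == "rectangular") {
    if (is.null(tau) || tau <= 0 || tau >= T) {
      stop("rectangular pulse requires 0 < tau < T")
    }
  }
  if (shape == "sinusoid") {
    if (is.null(mean)) stop("sinusoid requires a mean level")
    if (A > mean) stop("sinusoid amplitude must not exceed the mean (input would go negative)")
  }
  structure(list(shape = shape, A = A, T = T, tau = tau, mean = mean,
                 phase_origin = phase_origin),
            class = "pulse_train_spec")
}

new_fourier_series <- function(a0, an, bn, T, spec = NULL) {
  stopifnot(length(an) == length(bn))
  structure(list(a0 = a0, an = an, bn = bn, T = T, N = length(an),
                 spec = spec),
            class = "fourier_series")
}

#' Closed-form Fourier series of a rectangular pulse train
#'
#' For a train of height `A`, width `tau` and period `T` (on during
#' `[0, tau)` each period) the coefficients are `a0/2 = A tau / T` (the
#' mean), `an = (A / (pi n)) sin(2 pi n tau / T)` and
#' `bn = (A / (pi n)) (1 - cos(2 pi n tau / T))`.
#'
#' @param spec A rectangular `pulse_train_spec`.
#' @param N Number of harmonics retained (default 200).
#' @return A `fourier_series` object with fields `a0`, `an`, `bn`, `T`,
#'   `N`. The series represents
#'   `f(t) = a0/2 + sum an cos(2 pi n t / T) + sum bn sin(2 pi n t / T)`.
#' @examples
#' s <- fourier_rectangular(
#'   pulse_train_spec("rectangular", A = 0.08, T = 1200, tau = 180))
#' s$a0 / 2  # mean dose 0.012 Kd
#' @export
fourier_rectangular <- function(spec, N = 200) {
  stopifnot(inherits(spec, "pulse_train_spec"), spec$shape == "rectangular")
  if (N < 1) stop("N must be at least 1")
  n <- seq_len(N)
  th <- 2 * pi * n * spec$tau / spec$T
  an <- spec$A / (pi * n) * sin(th)
  bn <- spec$A / (pi * n) * (1 - cos(th))
  new_fourier_series(2 * spec$A * spec$tau / spec$T, an, bn, spec$T, spec)
}

#' Closed-form Fourier series of a triangular wave
#'
#' For a symmetric triangle of peak `A` and period `T` starting at its
#' minimum (0) at `t = 0`, the mean is `A/2` and only odd cosine harmonics
#' survive, with coefficients `-4 A / ((2n-1)^2 pi^2)`.
#'
#' @param spec A triangular `pulse_train_spec`.
#' @param N Highest harmonic index retained (default 199; even-index
#'   coefficients are zero).
#' @return A `fourier_series` object.
#' @examples
#' s <- fourier_triangular(
#'   pulse_train_spec("triangular", A = 4.2, T = 3600))
#' s$a0 / 2  # mean dose 2.1 Kd
#' @export
fourier_triangular <- function(spec, N = 199) {
  stopifnot(inherits(spec, "pulse_train_spec"), spec$shape == "triangular")
  if (N < 1) stop("N must be at least 1")
  n <- seq_len(N)
  an <- ifelse(n %% 2 == 1, -4 * spec$A / (n^2 * pi^2), 0)
  bn <- rep(0, N)
  new_fourier_series(spec$A, an, bn, spec$T, spec)
}

#' Evaluate a Fourier series (or the exact waveform it represents)
#'
#' @param series A `fourier_series` object.
#' @param t Time points, seconds.
#' @return Reconstructed waveform values.
#' @examples
#' s <- fourier_triangular(pulse_train_spec("triangular", A = 1, T = 100))
#' fourier_eval(s, 50)  # peak of the triangle
#' @export
fourier_eval <- function(series, t) {
  stopifnot(inherits(series, "fourier_series"))
  w <- 2 * pi / series$T
  out <- rep(series$a0 / 2, length(t))
  for (n in seq_len(series$N)) {
    if (series$an[n] != 0) out <- out + series$an[n] * cos(w * n * t)
    if (series$bn[n] != 0) out <- out + series$bn[n] * sin(w * n * t)
  }
  out
}

#' Exact waveform described by a pulse-train specification
#'
#' @param spec A `pulse_train_spec`.
#' @param t Time points, seconds.
#' @return Ligand concentration at each time (Kd units).
#' @examples
#' sp <- pulse_train_spec("rectangular", A = 1, T = 10, tau = 2)
#' waveform_eval(sp, c(1, 5))
#' @export
waveform_eval <- function(spec, t) {
  tt <- (t - spec$phase_origin) %% spec$T
  switch(spec$shape,
    rectangular = ifelse(tt < spec$tau, spec$A, 0),
    triangular = spec$A * (1 - abs(2 * tt / spec$T - 1)),
    sinusoid = spec$mean + spec$A * sin(2 * pi * tt / spec$T))
}
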