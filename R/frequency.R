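#' Linearize the pathway model at an equilibrium
#'
#' Computes the Jacobian state-space system of the rate equations at a
#' steady state: `A = dF/dx`, `B = dF/du`, output `y = ERK*` so `C` is the
#' ERK* selector row and the feedthrough `D` is exactly zero (the output
#' does not contain the input). Derivatives are obtained by complex-step
#' differentiation and are therefore accurate to machine precision.
#'
#' @param eq An `equilibrium` object (residual below `1e-9`).
#' @param params Optional `pathway_params`; defaults to the set stored in
#'   `eq`.
#' @return An object of class `pathway_ss`: list with matrices `A`
#'   (16 x 16), `B` (16 x 1), `C` (1 x 16), scalar `D = 0`, and the
#'   linearization point (`xe`, `ue`, `params`).
#' @examples
#' ss <- linearize(solve_equilibrium(pathway_params("EGF"), 0.01))
#' dim(ss$A)
#' @export
linearize <- function(eq, params = NULL) {
  stopifnot(inherits(eq, "equilibrium"))
  if (is.null(params)) params <- eq$params
  if (eq$residual >= 1e-9) {
    stop("equilibrium residual too large for linearization: ", eq$residual)
  }
  x <- eq$xe; u <- eq$ue
  h <- 1e-100
  A <- matrix(0, 16, 16, dimnames = list(STATE_NAMES, STATE_NAMES))
  for (j in 1:16) {
    xc <- as.complex(x)
    xc[j] <- xc[j] + h * 1i
    A[, j] <- Im(time_derivative(xc, u, params)) / h
  }
  B <- matrix(Im(time_derivative(x, u + h * 1i, params)) / h, ncol = 1,
              dimnames = list(STATE_NAMES, NULL))
  C <- matrix(0, 1, 16, dimnames = list(NULL, STATE_NAMES))
  C[1, ERKP_IDX] <- 1
  structure(list(A = A, B = B, C = C, D = 0,
                 xe = x, ue = u, params = params),
            class = "pathway_ss")
}

#' @export
print.pathway_ss <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  cat(sprintf(
    "Linearized ERK pathway (%s, dose %.4g Kd): 16 states, max Re(eig) = %.3e\n",
    x$params$ligand, x$ue, max(Re(ev))))
  invisible(x)
}

# Evaluate the transfer function directly from the state-space matrices:
# T(s) = C (sI - A)^{-1} B + D, one linear solve per frequency point.
resolvent_tf <- function(ss, s) {
  vapply(s, function(sk) {
    M <- diag(16 + 0i) * sk - ss$A
    drop(ss$C %*% solve(M, ss$B)) + ss$D
  }, complex(1))
}

# relative degree: smallest r with C A^(r-1) B != 0, plus that Markov
# parameter (sets the sign of the high-frequency asymptote).
relative_degree <- function(ss, tol = 1e-12) {
  v <- as.vector(ss$B)
  scale <- max(abs(ss$A))
  for (r in 1:16) {
    m <- drop(ss$C %*% v)
    if (abs(m) > tol * scale^r) return(list(r = r, markov = m))
    v <- ss$A %*% v
  }
  stop("all Markov parameters vanish: zero transfer function")
}

#' Minimal rational transfer function from ligand to ERK*
#'
#' Reduces `T(s) = C (sI - A)^{-1} B` to coprime numerator/denominator
#' polynomials by modal cancellation. Poles are the eigenvalues of `A`;
#' a mode is removed when it cannot appear in the input-output map, i.e.
#' when it is uncontrollable or unobservable. Two kinds of modes cancel
#' here: the structural zero eigenvalues contributed by the conservation
#' laws, and (under EGF, where the positive-feedback rate is zero) the
#' feedback-protein modes that the output cannot see. The test is modal —
#' `|C v| < cancel_tol` or `|w B| < cancel_tol * |B|` for the unit right /
#' left eigenvectors `v`, `w` — rather than a pole-zero distance, because
#' at low receptor occupancy the weakly coupled negative-feedback modes
#' produce genuine pole-zero pairs far closer than any practical distance
#' threshold, yet still part of the minimal system.
#'
#' The numerator polynomial of the reduced system is recovered without
#' symbolic determinant expansion: `T(s)` times the retained-pole
#' characteristic polynomial is evaluated on a circle of sample points in
#' the complex plane (resolvent linear solves times the
#' eigenvalue-factorized polynomial) and its coefficients are obtained by
#' FFT interpolation, which is exactly conditioned on a uniform circle.
#'
#' @param ss A `pathway_ss` linearization.
#' @param cancel_tol Relative modal cancellation tolerance (default
#'   `1e-8`; exactly-cancelling modes test many orders of magnitude below
#'   this, genuine modes many orders above).
#' @return An object of class `rational_tf`: list with `num` and `den`
#'   (polynomial coefficients, highest degree first, `den[1] = 1`),
#'   `zeros`, `poles`, `gain` (leading numerator coefficient), and the
#'   linearization point metadata.
#' @examples
#' ss <- linearize(solve_equilibrium(pathway_params("EGF"), 0.01))
#' tf <- to_transfer_function(ss)
#' c(length(tf$num), length(tf$den))  # degree 3 over degree 8
#' @export
to_transfer_function <- function(ss, cancel_tol = 1e-8) {
  stopifnot(inherits(ss, "pathway_ss"))
  evR <- eigen(ss$A)
  evL <- eigen(t(ss$A))
  poles <- evR$values
  sigma <- max(abs(poles))

  # conservation laws give structural zero eigenvalues; T(s) has no pole at
  # the origin, so their factor cancels exactly and is deflated up front
  nz <- which(abs(poles) >= 1e-9 * sigma)

  keep <- vapply(nz, function(i) {
    v <- evR$vectors[, i]
    w <- evL$vectors[, which.min(abs(evL$values - poles[i]))]
    obs <- abs(drop(ss$C %*% v))                    # ||v|| = 1 from eigen
    ctr <- abs(sum(w * ss$B)) / sqrt(sum(abs(ss$B)^2))
    obs >= cancel_tol && ctr >= cancel_tol
  }, logical(1))
  pk <- poles[nz[keep]]

  # sample T(s) * prod(s - pk) on a circle and FFT-interpolate: with the
  # cancelling modes removed this product is a low-degree polynomial
  m <- 64L
  r <- exp(mean(log(abs(pk))))
  sj <- r * exp(2i * pi * (seq_len(m) - 1) / m)
  gj <- resolvent_tf(ss, sj)
  denj <- vapply(sj, function(sk) prod(sk - pk), complex(1))
  numj <- gj * denj
  coef <- stats::fft(numj) / m                      # c_k for s^k
  coef <- coef / r^(seq_len(m) - 1)
  # drop machine-noise high-order coefficients
  mag <- abs(coef) * r^(seq_len(m) - 1)
  deg <- min(max(which(mag > 1e-9 * max(mag))) - 1L, length(pk) - 1L)
  coef <- Re(coef[seq_len(deg + 1L)])
  zk <- polyroot(coef)                              # ascending-order input

  num <- Re(poly_from_roots(zk))
  den <- Re(poly_from_roots(pk))
  gain <- coef[length(coef)]  # leading coefficient of the numerator
  num <- gain * num

  # the reduced form must reproduce the resolvent
  s_chk <- 1i * sigma * 10^seq(-3, 1, length.out = 7)
  t_full <- resolvent_tf(ss, s_chk)
  t_red <- polyval_cmplx(num, s_chk) / polyval_cmplx(den, s_chk)
  rel <- max(abs(t_red - t_full) / abs(t_full))
  if (rel > 1e-7) {
    stop(sprintf(paste0(
      "modal cancellation failed to reach a coprime form; near-cancelling ",
      "pairs likely (reduced-form check error %.2e). Retained %d poles, ",
      "%d zeros."), rel, length(pk), length(zk)))
  }
  structure(list(num = num, den = den, zeros = zk, poles = pk, gain = gain,
                 ue = ss$ue, ligand = ss$params$ligand,
                 cancel_tol = cancel_tol),
            class = "rational_tf")
}

# monic polynomial with the given roots, coefficients highest degree first
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (rt in r) coef <- c(coef, 0) - c(0, rt * coef)
  coef
}

polyval_cmplx <- function(coef, s) {
  out <- rep(coef[1] + 0i, length(s))
  for (k in seq_along(coef)[-1]) out <- out * s + coef[k]
  out
}

#' Evaluate a rational transfer function
#'
#' @param tf A `rational_tf` object.
#' @param s Complex frequency points (use `1i * omega` for the frequency
#'   response).
#' @return Complex values of `T(s)`, evaluated in factorized zero-pole-gain
#'   form for numerical stability.
#' @examples
#' ss <- linearize(solve_equilibrium(pathway_params("EGF"), 0.01))
#' tf <- to_transfer_function(ss)
#' abs(eval_tf(tf, 1i * 1e-4))
#' @export
eval_tf <- function(tf, s) {
  vapply(s, function(sk) {
    tf$gain * prod(sk - tf$zeros) / prod(sk - tf$poles)
  }, complex(1))
}

#' @export
print.rational_tf <- function(x, ...) {
  cat(sprintf(
    "Rational transfer function %s -> ERK* at dose %.4g Kd: degree %d / %d (%d coefficients)\n",
    x$ligand, x$ue, length(x$num) - 1L, length(x$den) - 1L,
    length(x$num) + length(x$den)))
  cat("  T(0) =", format(Re(eval_tf(x, 0 + 0i)), digits = 6), "\n")
  invisible(x)
}

#' Bode modulation and phase of the linearized pathway
#'
#' Evaluates the frequency response `T(i omega)` by direct resolvent
#' solves, returning the modulation `M = |T|` and the continuously
#' unwrapped phase. The unwrapped curve is anchored at the high-frequency
#' asymptote implied by the system's relative degree (each pole beyond the
#' zeros contributes -90 degrees), which places the low-frequency phase in
#' `[0, 360)` and makes total phase change across the sweep meaningful.
#'
#' @param ss A `pathway_ss` linearization.
#' @param omega Ascending positive frequency grid in rad/s. Default 100
#'   points per decade over `1e-6` to `1e2` (the top two decades lie beyond
#'   the fastest pathway time scale so the phase has settled onto its
#'   asymptote).
#' @return An object of class `bode_data`: `data.frame` with columns
#'   `omega_rad_s`, `modulation`, `phase_deg`.
#' @examples
#' ss <- linearize(solve_equilibrium(pathway_params("EGF"), 0.01))
#' bd <- frequency_response(ss)
#' bd$phase_deg[1]  # in-phase at low frequency and low occupancy
#' @export
frequency_response <- function(ss,
                               omega = 10^seq(-6, 2, by = 0.01)) {
  stopifnot(all(omega > 0), !is.unsorted(omega))
  tv <- resolvent_tf(ss, 1i * omega)
  modulation <- abs(tv)
  ph <- unwrap_phase(Arg(tv))
  # refine internally if adjacent principal phases jump too far to unwrap
  if (max(abs(diff(ph))) > pi / 2) {
    warning("phase grid coarse; refining internally for unwrapping")
    omega_f <- 10^seq(log10(omega[1]), log10(omega[length(omega)]),
                      length.out = 8L * length(omega))
    ph_f <- unwrap_phase(Arg(resolvent_tf(ss, 1i * omega_f)))
    ph <- stats::approx(omega_f, ph_f, xout = omega)$y
  }
  ph_deg <- ph * 180 / pi
  rd <- relative_degree(ss)
  asym <- -90 * rd$r + if (rd$markov < 0) -180 else 0
  shift <- 360 * round((asym - ph_deg[length(ph_deg)]) / 360)
  ph_deg <- ph_deg + shift
  structure(data.frame(omega_rad_s = omega, modulation = modulation,
                       phase_deg = ph_deg),
            class = c("bode_data", "data.frame"))
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}

#' Summary metrics of a Bode sweep
#'
#' @param bd A `bode_data` object spanning at least `1e-6` to `1` rad/s.
#' @return List with `peak_modulation` (maximum gain over the grid),
#'   `omega_peak` (frequency of that maximum), `total_phase_change_deg`
#'   (absolute unwrapped phase difference between the grid ends) and
#'   `low_freq_phase_deg` (phase at the lowest frequency).
#' @examples
#' ss <- linearize(solve_equilibrium(pathway_params("EGF"), 0.01))
#' bode_metrics(frequency_response(ss))$total_phase_change_deg
#' @export
bode_metrics <- function(bd) {
  stopifnot(inherits(bd, "bode_data"))
  om <- bd$omega_rad_s
  if (om[1] > 1e-6 || om[length(om)] < 1) {
    stop("Bode grid must span at least 1e-6 to 1 rad/s")
  }
  i_max <- which.max(bd$modulation)
  if (i_max %in% c(1L, nrow(bd))) {
    warning("modulation peak lies on the grid boundary; grid may be too narrow")
  }
  list(
    peak_modulation = bd$modulation[i_max],
    omega_peak = om[i_max],
    total_phase_change_deg = abs(bd$phase_deg[nrow(bd)] - bd$phase_deg[1]),
    low_freq_phase_deg = bd$phase_deg[1]
  )
}
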