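# Reduced coordinates for steady-state solving: the seven conservation laws
# make seven of the sixteen equations redundant, so the root-finding problem
# is posed in the nine free variables (one active fraction per pair, plus
# dusp and DUSP).
REDUCED_IDX <- c(PAIR_IDX[, "active"], 15L, 16L)

reduced_to_state <- function(y, params) {
  x <- if (is.complex(y)) complex(16) else numeric(16)
  names(x) <- STATE_NAMES
  x[PAIR_IDX[, "active"]] <- y[1:7]
  x[PAIR_IDX[, "inactive"]] <- params$totals - y[1:7]
  x[15] <- y[8]
  x[16] <- y[9]
  x
}

reduced_residual <- function(y, u, params) {
  x <- reduced_to_state(y, params)
  time_derivative(x, u, params)[REDUCED_IDX]
}

# Jacobian of the reduced residual by complex-step differentiation: exact
# to machine precision because the rate laws are rational functions.
reduced_jacobian <- function(y, u, params, h = 1e-100) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    yc <- as.complex(y)
    yc[j] <- yc[j] + h * 1i
    J[, j] <- Im(reduced_residual(yc, u, params)) / h
  }
  J
}

#' Solve the pathway steady state at constant ligand input
#'
#' Finds the root of the 16-species rate equations under a constant ligand
#' dose by damped Newton iteration in reduced coordinates (active fraction
#' of each conserved pair plus dusp and DUSP; 9 unknowns), which removes
#' the seven structural zero modes from the root-finding problem. When no
#' guess is supplied the solver continues the basal (zero-ligand)
#' equilibrium branch up to the requested dose, so the reported state is
#' always the branch reachable from the resting cell.
#'
#' @param params A `pathway_params` object.
#' @param u_const Constant ligand dose in Kd units (>= 0).
#' @param guess Optional starting state (16-vector); defaults to
#'   continuation from the basal state.
#' @param tol Convergence tolerance on the max-norm of the residual.
#' @param max_iter Newton iteration cap per dose step.
#' @return An object of class `equilibrium`: list with `xe` (state),
#'   `ue` (dose), `residual` (max-norm of the full derivative), `stable`
#'   (all reduced-Jacobian eigenvalues have negative real part) and
#'   `params`.
#' @examples
#' eq <- solve_equilibrium(pathway_params("EGF"), 0.04)
#' eq$xe[["ERKp"]]
#' @export
solve_equilibrium <- function(params, u_const, guess = NULL,
                              tol = 1e-11, max_iter = 60) {
  stopifnot(u_const >= 0)
  if (is.null(guess)) {
    # dose continuation from the exact basal equilibrium
    y <- basal_state(params)[REDUCED_IDX]
    if (u_const > 0) {
      steps <- u_const * seq(0.1, 1, length.out = 10)
      for (uu in steps) y <- newton_equilibrium(y, uu, params, tol, max_iter)
    }
  } else {
    check_state(guess)
    y <- guess[REDUCED_IDX]
    y <- newton_equilibrium(y, u_const, params, tol, max_iter)
  }
  xe <- reduced_to_state(y, params)
  res <- max(abs(time_derivative(xe, u_const, params)))
  if (any(xe < -1e-12)) {
    stop("equilibrium solution violates non-negativity")
  }
  xe[xe < 0] <- 0
  J <- reduced_jacobian(y, u_const, params)
  stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
  structure(list(xe = xe, ue = u_const, residual = res, stable = stable,
                 params = params),
            class = "equilibrium")
}

newton_equilibrium <- function(y, u, params, tol, max_iter) {
  lo <- c(rep(0, 7), 0, 0)
  hi <- c(unname(params$totals), Inf, Inf)
  f <- reduced_residual(y, u, params)
  fn <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (fn < tol) return(y)
    J <- reduced_jacobian(y, u, params)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      # regularize a near-singular Jacobian
      step <- solve(J + diag(1e-12, length(y)), -f)
    }
    lambda <- 1
    improved <- FALSE
    for (k in 1:40) {
      y_try <- pmin(pmax(y + lambda * step, lo), hi)
      f_try <- reduced_residual(y_try, u, params)
      fn_try <- max(abs(f_try))
      if (is.finite(fn_try) && fn_try < fn) {
        y <- y_try; f <- f_try; fn <- fn_try; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (fn >= tol) {
    stop(sprintf(
      "steady-state solver did not converge at dose %.6g (residual %.3e)",
      u, fn))
  }
  y
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf(
    "ERK pathway equilibrium (%s, dose %.4g Kd): ERK* = %.5g, residual %.2e, %s\n",
    x$params$ligand, x$ue, x$xe[["ERKp"]], x$residual,
    if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Equilibrium ERK* as a function of ligand dose
#'
#' Traces the steady-state ERK activation level over a dose grid by
#' continuation: each converged equilibrium seeds the Newton solve at the
#' next dose, following the branch that starts at the basal state. With
#' `probe_multistability = TRUE` every dose is additionally re-solved from
#' a strongly activated guess and doses where the two solves disagree are
#' flagged.
#'
#' @param params A `pathway_params` object.
#' @param doses Ascending non-negative dose grid (Kd units). Default 60
#'   log-spaced points over 0.001 to 2.5 Kd.
#' @param probe_multistability Also search for an alternative equilibrium
#'   branch at each dose (slower).
#' @return A `data.frame` of class `dose_response` with columns `dose_kd`,
#'   `erk_star`, `stable`, `multistable`, `ligand_mode`.
#' @examples
#' dr <- dose_response(pathway_params("EGF"),
#'                     doses = c(0.01, 0.04, 0.1, 0.5))
#' dr$erk_star
#' @export
dose_response <- function(params,
                          doses = 10^seq(log10(0.001), log10(2.5),
                                         length.out = 60),
                          probe_multistability = FALSE) {
  if (is.unsorted(doses) || any(doses < 0)) {
    stop("doses must be ascending and non-negative")
  }
  erk <- stable <- multi <- numeric(length(doses))
  guess <- NULL
  for (i in seq_along(doses)) {
    eq <- tryCatch(
      solve_equilibrium(params, doses[i], guess = guess),
      error = function(e) {
        stop("dose_response failed at dose ", doses[i], ": ",
             conditionMessage(e))
      })
    erk[i] <- eq$xe[["ERKp"]]
    stable[i] <- eq$stable
    guess <- eq$xe
    multi[i] <- FALSE
    if (probe_multistability) {
      alt <- tryCatch({
        g <- pathway_state(
          active = stats::setNames(0.9 * params$totals, PAIR_SPECIES),
          params = params)
        solve_equilibrium(params, doses[i], guess = g)
      }, error = function(e) NULL)
      if (!is.null(alt) && max(abs(alt$xe - eq$xe)) > 1e-6) multi[i] <- TRUE
    }
  }
  structure(
    data.frame(dose_kd = doses, erk_star = erk, stable = as.logical(stable),
               multistable = as.logical(multi),
               ligand_mode = params$ligand),
    class = c("dose_response", "data.frame"))
}
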