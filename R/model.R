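#' Construct a pathway state vector
#'
#' A state is a named numeric vector of 16 species fractions. Each of the
#' seven signalling proteins is split into an inactive/active pair whose sum
#' is conserved; `dusp` (transcript) and `DUSP` (protein) are produced and
#' degraded and carry no conservation law.
#'
#' @param active Named numeric vector of active-form fractions, names among
#'   `R`, `Ras`, `Raf`, `MEK`, `ERK`, `NFB`, `PFB`. Unnamed species default
#'   to fully inactive.
#' @param dusp,DUSP Transcript and protein levels; default to the
#'   zero-ERK* fixed point `duspbasal` so the basal state is an equilibrium.
#' @param params A `pathway_params` object supplying totals and `duspbasal`.
#' @return Named numeric vector of length 16 (classless).
#' @examples
#' x0 <- basal_state(pathway_params("EGF"))
#' sum(x0[c("ERK", "ERKp")])  # conserved ERK total
#' @export
pathway_state <- function(active = numeric(0), dusp = NULL, DUSP = NULL,
                          params = pathway_params("EGF")) {
  bad <- setdiff(names(active), PAIR_SPECIES)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  x <- numeric(16)
  names(x) <- STATE_NAMES
  for (i in seq_along(PAIR_SPECIES)) {
    sp <- PAIR_SPECIES[i]
    a <- if (sp %in% names(active)) active[[sp]] else 0
    tot <- params$totals[[sp]]
    if (a < 0 || a > tot) {
      stop("active ", sp, " must lie in [0, total = ", tot, "]")
    }
    x[PAIR_IDX[i, "active"]] <- a
    x[PAIR_IDX[i, "inactive"]] <- tot - a
  }
  x["dusp"] <- if (is.null(dusp)) params$duspbasal else dusp
  x["DUSP"] <- if (is.null(DUSP)) params$duspbasal else DUSP
  if (any(x < 0)) stop("state entries must be non-negative")
  x
}

#' @rdname pathway_state
#' @export
basal_state <- function(params = pathway_params("EGF")) {
  pathway_state(params = params)
}

check_state <- function(x) {
  if (length(x) != 16) stop("state must have 16 entries")
  if (is.numeric(x) && any(x < 0)) stop("state entries must be non-negative")
  invisible(x)
}

#' Reaction fluxes of the ERK pathway model
#'
#' Evaluates the eleven reaction rates. Activation/deactivation cycles are
#' net fluxes (forward minus reverse) in Michaelis form (the MEK
#' dephosphorylation term saturates in inactive MEK rather than in its MEK*
#' substrate). The Raf activation flux carries the negative-feedback
#' Hill gate `KNFB^2 / (KNFB^2 + NFB*^2)`; NFB activation requires active
#' receptor through `R*^2 / (K3R^2 + R*^2)`; dusp transcription is induced
#' by ERK* through `ERK*^2 / (Kdusp + ERK*^2)`. The dusp/DUSP tiers turn
#' over with first-order rates `log(2)/Tdusp` and `log(2)/TDUSP`.
#'
#' All arithmetic is rational in the state, so the function also accepts
#' complex-valued states (used internally for complex-step
#' differentiation).
#'
#' @param x State vector (see [pathway_state()]).
#' @param u Ligand concentration in Kd units (scalar, >= 0).
#' @param params A `pathway_params` object.
#' @return Named vector of fluxes `v1, v6, v5, v5a, v4, v2, v3a, v7a,
#'   v8, v9, v10, v11` (per second).
#' @examples
#' p <- pathway_params("EGF")
#' reaction_fluxes(basal_state(p), u = 0.1, p)[["v1"]]
#' @export
reaction_fluxes <- function(x, u, params) {
  check_state(x)
  if (is.numeric(u) && u < 0) stop("ligand input must be non-negative")
  p <- params
  R <- x[[1]]; Rp <- x[[2]]; Ras <- x[[3]]; Rasp <- x[[4]]
  Raf <- x[[5]]; Rafp <- x[[6]]; MEK <- x[[7]]; MEKp <- x[[8]]
  ERK <- x[[9]]; ERKp <- x[[10]]; NFB <- x[[11]]; NFBp <- x[[12]]
  PFB <- x[[13]]; PFBp <- x[[14]]; dusp <- x[[15]]; DUSP <- x[[16]]

  v1 <- p$k1R * R * u - p$kd1R * p$PtaseR * Rp
  v6 <- p$k6R * Rp * Ras / (p$K6 + Ras) -
    p$kd6 * p$GAP * Rasp / (p$D6 + Rasp)
  v5 <- p$k5 * Rasp * Raf / (p$K5 + Raf) *
    p$KNFB^2 / (p$KNFB^2 + NFBp^2) -
    p$kd5 * p$PtaseRaf * Rafp / (p$D5 + Rafp)
  v5a <- p$kPFB * PFBp * Raf / (p$KPFB + Raf)
  v4 <- p$k4 * Rafp * MEK / (p$K4 + MEK) -
    p$kd4 * p$PtaseMEK * MEKp / (p$D4 + MEK)
  v2 <- p$k2 * MEKp * ERK / (p$K2 + ERK) -
    p$kd2 * DUSP * ERKp / (p$D2 + ERKp)
  v3a <- p$k3F * ERKp * NFB / (p$K3 + NFB) *
    Rp^2 / (p$K3R^2 + Rp^2) -
    p$kd3 * p$PtaseNFB * NFBp / (p$D3 + NFBp)
  v7a <- p$k7 * ERKp * Rp * PFB / (p$K7 + PFB) -
    p$kd7 * p$PtasePFB * PFBp / (p$D7 + PFBp)
  hill_den <- if (params$dusp_hill_squared) p$Kdusp^2 + ERKp^2 else
    p$Kdusp + ERKp^2
  v8 <- p$duspbasal * (1 + p$duspind * ERKp^2 / hill_den) * log(2) / p$Tdusp
  v9 <- dusp * log(2) / p$Tdusp
  v10 <- dusp * log(2) / p$TDUSP
  v11 <- DUSP * log(2) / p$TDUSP

  c(v1 = v1, v6 = v6, v5 = v5, v5a = v5a, v4 = v4, v2 = v2,
    v3a = v3a, v7a = v7a, v8 = v8, v9 = v9, v10 = v10, v11 = v11)
}

#' Time derivative of the pathway state
#'
#' Assembles the signed flux combinations for all 16 species. Each
#' activation pair receives `(-v, +v)` so the pair sum is conserved
#' exactly; the transcript and protein tiers obey `d(dusp)/dt = v8 - v9`
#' and `d(DUSP)/dt = v10 - v11`.
#'
#' @inheritParams reaction_fluxes
#' @return Named vector of 16 time derivatives (per second).
#' @examples
#' p <- pathway_params("EGF")
#' f <- time_derivative(basal_state(p), u = 0, p)
#' max(abs(f))  # basal state with no ligand is an equilibrium
#' @export
time_derivative <- function(x, u, params) {
  v <- reaction_fluxes(x, u, params)
  out <- c(-v[["v1"]], v[["v1"]],
           -v[["v6"]], v[["v6"]],
           -v[["v5"]] - v[["v5a"]], v[["v5"]] + v[["v5a"]],
           -v[["v4"]], v[["v4"]],
           -v[["v2"]], v[["v2"]],
           -v[["v3a"]], v[["v3a"]],
           -v[["v7a"]], v[["v7a"]],
           v[["v8"]] - v[["v9"]],
           v[["v10"]] - v[["v11"]])
  names(out) <- STATE_NAMES
  out
}
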