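#' Rate constants and totals for the ERK pathway model
#'
#' Builds the full parameter set of the growth-factor-driven ERK cascade:
#' receptor (R) activation by ligand, the Ras-Raf-MEK-ERK core as
#' activation/inactivation cycles with Michaelis-Menten kinetics, an
#' ERK*-induced negative feedback protein (NFB) acting on Raf activation, a
#' positive feedback protein (PFB, active under NGF only), and a
#' two-tier DUSP negative regulator (transcript `dusp`, protein `DUSP`)
#' with explicit first-order turnover time constants.
#'
#' Rates are per second; all concentrations are dimensionless fractions of
#' each protein's conserved total, and ligand is measured in units of the
#' receptor dissociation constant Kd (the forward and reverse receptor rate
#' constants are equal, so dose 1 Kd gives half receptor occupancy at
#' equilibrium).
#'
#' The two ligand modes share every constant except `kPFB`: the positive
#' feedback loop is silent under EGF (`kPFB = 0`) and active under NGF
#' (`kPFB = 0.75/60` per second).
#'
#' @param ligand `"EGF"` or `"NGF"`; selects the positive-feedback rate.
#' @param totals Named numeric vector of conserved totals for the seven
#'   activation pairs, names `R`, `Ras`, `Raf`, `MEK`, `ERK`, `NFB`, `PFB`.
#'   All fractions, default 1 for each.
#' @param dusp_hill_squared If `TRUE`, use `Kdusp^2 + ERK*^2` in the
#'   denominator of the ERK*-induced dusp transcription term instead of the
#'   default `Kdusp + ERK*^2`.
#' @param ... Named overrides for individual rate constants.
#'
#' @return An object of class `pathway_params`: a list of rate constants
#'   plus `ligand`, `totals` and `dusp_hill_squared`.
#'
#' @examples
#' p <- pathway_params("EGF")
#' p$k1R * 60  # 0.5 per minute
#' pathway_params("NGF")$kPFB > 0
#' @export
pathway_params <- function(ligand = c("EGF", "NGF"),
                           totals = c(R = 1, Ras = 1, Raf = 1, MEK = 1,
                                      ERK = 1, NFB = 1, PFB = 1),
                           dusp_hill_squared = FALSE,
                           ...) {
  ligand <- match.arg(ligand)
  p <- list(
    # receptor activation / deactivation
    k1R = 0.5 / 60, kd1R = 0.5 / 60, PtaseR = 1,
    # Ras cycle
    k6R = 40 / 60, K6 = 1, kd6 = 7.5 / 60, D6 = 1, GAP = 1,
    # Raf cycle (NFB-gated activation) + PFB-driven activation
    k5 = 10 / 60, K5 = 1, kd5 = 3.75 / 60, D5 = 1, KNFB = 0.05,
    PtaseRaf = 1,
    kPFB = if (ligand == "NGF") 0.75 / 60 else 0, KPFB = 0.01,
    # MEK cycle
    k4 = 2 / 60, K4 = 1, kd4 = 0.5 / 60, D4 = 1, PtaseMEK = 1,
    # ERK cycle (deactivated by DUSP)
    k2 = 2 / 60, K2 = 1, kd2 = 0.25 / 60, D2 = 0.1,
    # NFB cycle (requires ERK* and active receptor)
    k3F = 0.0286 / 60, K3 = 0.01, K3R = 0.85, kd3 = 0.0057 / 60,
    D3 = 0.5, PtaseNFB = 1,
    # PFB cycle
    k7 = 0.1 / 60, K7 = 0.1, kd7 = 0.005 / 60, D7 = 0.1, PtasePFB = 1,
    # dusp/DUSP induction and turnover
    duspbasal = 1, duspind = 6, Kdusp = 0.1,
    Tdusp = 90 * 60, TDUSP = 90 * 60
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  need <- c("R", "Ras", "Raf", "MEK", "ERK", "NFB", "PFB")
  if (!all(need %in% names(totals))) {
    stop("totals must name all of: ", paste(need, collapse = ", "))
  }
  totals <- totals[need]
  p$ligand <- ligand
  p$totals <- totals
  p$dusp_hill_squared <- isTRUE(dusp_hill_squared)
  validate_pathway_params(p)
  structure(p, class = "pathway_params")
}

validate_pathway_params <- function(p) {
  rates <- p[setdiff(names(p), c("ligand", "totals", "dusp_hill_squared"))]
  rv <- unlist(rates)
  if (any(!is.finite(rv)) || any(rv < 0)) {
    stop("all rate constants must be finite and non-negative")
  }
  ks <- c("K6", "D6", "K5", "D5", "KNFB", "KPFB", "K4", "D4", "K2", "D2",
          "K3", "K3R", "D3", "K7", "D7", "Kdusp", "Tdusp", "TDUSP")
  if (any(unlist(p[ks]) <= 0)) {
    stop("saturation constants and time constants must be strictly positive")
  }
  if (any(p$totals <= 0)) stop("every conserved total must be > 0")
  invisible(p)
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("ERK pathway parameter set (", x$ligand, " mode)\n", sep = "")
  cat("  kPFB =", format(x$kPFB), "s^-1;",
      if (x$kPFB > 0) "positive feedback active\n" else
        "positive feedback silent\n")
  cat("  totals:", paste(names(x$totals), x$totals, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a pathway parameter set as a flat key = value file
#'
#' The file is plain text, one `key = value` pair per line, keys named as
#' the model's rate-constant symbols plus `ligand`, `dusp_hill_squared` and
#' `total_<species>` entries. Unknown keys are an error on read, so stale
#' or misspelled configuration entries never pass silently.
#'
#' @param params A `pathway_params` object.
#' @param path File path.
#' @return `write_pathway_params` returns `path` invisibly;
#'   `read_pathway_params` returns a `pathway_params` object.
#' @examples
#' f <- tempfile(fileext = ".conf")
#' write_pathway_params(pathway_params("NGF"), f)
#' identical(read_pathway_params(f)$kPFB, 0.75 / 60)
#' @export
write_pathway_params <- function(params, path) {
  stopifnot(inherits(params, "pathway_params"))
  rates <- params[setdiff(names(params),
                          c("ligand", "totals", "dusp_hill_squared"))]
  lines <- c(
    paste("ligand =", params$ligand),
    paste("dusp_hill_squared =", tolower(params$dusp_hill_squared)),
    paste0("total_", names(params$totals), " = ",
           format(unname(params$totals), digits = 17)),
    paste(names(rates), "=", vapply(rates, format, "", digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pathway_params
#' @param path File path.
#' @export
read_pathway_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("malformed line(s) in parameter file: expected 'key = value'")
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  names(vals) <- keys
  if (anyDuplicated(keys)) stop("duplicate key(s) in parameter file")

  template <- pathway_params("EGF")
  rate_keys <- setdiff(names(template), c("ligand", "totals",
                                          "dusp_hill_squared"))
  total_keys <- paste0("total_", names(template$totals))
  known <- c("ligand", "dusp_hill_squared", rate_keys, total_keys)
  bad <- setdiff(keys, known)
  if (length(bad)) {
    stop("unknown key(s) in parameter file: ", paste(bad, collapse = ", "))
  }
  ligand <- if ("ligand" %in% keys) vals[["ligand"]] else "EGF"
  totals <- template$totals
  for (sp in names(totals)) {
    k <- paste0("total_", sp)
    if (k %in% keys) totals[[sp]] <- as.numeric(vals[[k]])
  }
  overrides <- lapply(vals[intersect(keys, rate_keys)], as.numeric)
  hill2 <- "dusp_hill_squared" %in% keys &&
    tolower(vals[["dusp_hill_squared"]]) %in% c("true", "t", "1", "yes")
  do.call(pathway_params,
          c(list(ligand = ligand, totals = totals,
                 dusp_hill_squared = hill2),
            overrides))
}
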