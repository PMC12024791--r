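# Shared fixtures, memoized: equilibria and linearizations at the
# reference doses are reused across test files.
.fix <- new.env(parent = emptyenv())

fix <- function(key, build) {
  if (is.null(.fix[[key]])) .fix[[key]] <- build()
  .fix[[key]]
}

egf <- function() fix("egf", function() pathway_params("EGF"))
ngf <- function() fix("ngf", function() pathway_params("NGF"))

eq_at <- function(ligand, dose) {
  fix(sprintf("eq_%s_%g", ligand, dose), function() {
    solve_equilibrium(pathway_params(ligand), dose)
  })
}

ss_at <- function(ligand, dose) {
  fix(sprintf("ss_%s_%g", ligand, dose), function() {
    linearize(eq_at(ligand, dose))
  })
}

bode_at <- function(ligand, dose) {
  fix(sprintf("bd_%s_%g", ligand, dose), function() {
    bode_metrics(frequency_response(ss_at(ligand, dose)))
  })
}

# random valid state for property-style loops
random_state <- function(params, seed) {
  set.seed(seed)
  act <- stats::runif(7) * params$totals
  names(act) <- c("R", "Ras", "Raf", "MEK", "ERK", "NFB", "PFB")
  pathway_state(active = act, dusp = stats::runif(1, 0, 3),
                DUSP = stats::runif(1, 0, 3), params = params)
}
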