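test_that("flux formulas match their closed forms at reference states", {
  p <- egf()
  x0 <- basal_state(p)

  # no receptor activity and no ligand: binding flux vanishes entirely
  v <- reaction_fluxes(x0, 0, p)
  expect_identical(v[["v1"]], 0)

  # basal dusp transcription rate: duspbasal * log(2) / Tdusp
  expect_equal(v[["v8"]], log(2) / 5400, tolerance = 1e-12)

  # saturating negative feedback shuts off Raf activation: forward term of
  # v5 tends to zero, leaving only the dephosphorylation term
  x <- pathway_state(active = c(Ras = 0.5, Raf = 0.4), params = p)
  x["NFBp"] <- 1e8
  x["NFB"] <- 0
  v_sat <- reaction_fluxes(x, 0, p)
  expect_equal(v_sat[["v5"]],
               -p$kd5 * p$PtaseRaf * 0.4 / (p$D5 + 0.4),
               tolerance = 1e-12)

  # hand-evaluated fluxes at a generic state (independent arithmetic)
  xr <- random_state(p, 42)
  vr <- reaction_fluxes(xr, 0.3, p)
  expect_equal(vr[["v1"]],
               p$k1R * xr[["R"]] * 0.3 - p$kd1R * xr[["Rp"]],
               tolerance = 1e-14)
  expect_equal(vr[["v6"]],
               p$k6R * xr[["Rp"]] * xr[["Ras"]] / (1 + xr[["Ras"]]) -
                 p$kd6 * xr[["Rasp"]] / (1 + xr[["Rasp"]]),
               tolerance = 1e-14)
  expect_equal(vr[["v2"]],
               p$k2 * xr[["MEKp"]] * xr[["ERK"]] / (1 + xr[["ERK"]]) -
                 p$kd2 * xr[["DUSP"]] * xr[["ERKp"]] / (0.1 + xr[["ERKp"]]),
               tolerance = 1e-14)
})

test_that("derivative assembles signed fluxes with exact pair conservation", {
  p <- egf()
  for (seed in 1:5) {
    x <- random_state(p, seed)
    u <- stats::runif(1, 0, 2)
    f <- time_derivative(x, u, p)
    v <- reaction_fluxes(x, u, p)
    # every activation pair conserves its total
    pair_sums <- f[seq(1, 13, 2)] + f[seq(2, 14, 2)]
    expect_true(all(abs(pair_sums) < 1e-18))
    # transcript and protein tiers
    expect_equal(unname(f[["dusp"]]), unname(v[["v8"]] - v[["v9"]]))
    expect_equal(unname(f[["DUSP"]]), unname(v[["v10"]] - v[["v11"]]))
  }
})

test_that("EGF and NGF fluxes differ only through the positive-feedback term", {
  x <- random_state(egf(), 7)
  ve <- reaction_fluxes(x, 0.5, egf())
  vn <- reaction_fluxes(x, 0.5, ngf())
  expect_identical(ve[["v5a"]], 0)
  expect_gt(vn[["v5a"]], 0)
  same <- setdiff(names(ve), "v5a")
  expect_equal(ve[same], vn[same], tolerance = 1e-15)
})

test_that("parameter construction validates inputs and modes", {
  expect_equal(pathway_params("EGF")$kPFB, 0)
  expect_equal(pathway_params("NGF")$kPFB, 0.75 / 60)
  expect_error(pathway_params("EGF", k5 = -1), "non-negative")
  expect_error(pathway_params("EGF", nosuch = 2), "unknown parameter")
  expect_error(
    pathway_params("EGF", totals = c(R = 0, Ras = 1, Raf = 1, MEK = 1,
                                     ERK = 1, NFB = 1, PFB = 1)),
    "total")
  expect_error(pathway_state(active = c(ERK = 2)), "\\[0, total")
  expect_error(reaction_fluxes(basal_state(egf()), -0.1, egf()),
               "non-negative")
})

test_that("parameter files round-trip and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".conf")
  p <- pathway_params("NGF", k5 = 0.123)
  write_pathway_params(p, f)
  q <- read_pathway_params(f)
  expect_equal(q$k5, 0.123)
  expect_equal(q$ligand, "NGF")
  expect_equal(q$kPFB, 0.75 / 60)

  writeLines(c("ligand = EGF", "bogus_key = 1"), f)
  expect_error(read_pathway_params(f), "unknown key")

  # bundled defaults reproduce the in-code parameter tables
  for (lig in c("egf", "ngf")) {
    path <- system.file("extdata", paste0("params_", lig, ".conf"),
                        package = "erkfreq")
    expect_true(nzchar(path))
    got <- read_pathway_params(path)
    ref <- pathway_params(toupper(lig))
    expect_equal(got[order(names(got))], ref[order(names(ref))],
                 ignore_attr = TRUE)
  }
})
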