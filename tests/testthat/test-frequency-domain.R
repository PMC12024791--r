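test_that("linearization reproduces finite differences with structural zeros", {
  p <- egf()
  eq <- eq_at("EGF", 0.04)
  ss <- ss_at("EGF", 0.04)

  expect_identical(ss$D, 0)
  # conservation: each pair's rows are exact negatives
  for (i in seq(1, 13, 2)) {
    expect_equal(ss$A[i, ], -ss$A[i + 1, ], tolerance = 1e-15)
  }
  expect_equal(unname(ss$B[1, 1]), -p$k1R * eq$xe[["R"]], tolerance = 1e-12)

  # central finite differences as the independent derivative oracle
  fd <- matrix(0, 16, 16)
  for (j in 1:16) {
    h <- 1e-6 * max(1, abs(eq$xe[j]))
    xp <- eq$xe; xp[j] <- xp[j] + h
    xm <- eq$xe; xm[j] <- xm[j] - h
    fd[, j] <- (time_derivative(xp, eq$ue, p) -
                  time_derivative(xm, eq$ue, p)) / (2 * h)
  }
  scale <- max(abs(ss$A))
  expect_lt(max(abs(ss$A - fd)) / scale, 1e-7)

  expect_error(linearize(structure(list(residual = 1e-3), class = "equilibrium")),
               "residual")
})

test_that("frequency response machinery is exact on a single-pole system", {
  # T(s) = 1/(s + a): gain a^-1 at DC, -90 degrees total phase change
  a <- 1e-3
  toy <- structure(list(A = diag(-a, 16), B = matrix(c(rep(0, 9), 1, rep(0, 6))),
                        C = matrix(c(rep(0, 9), 1, rep(0, 6)), 1), D = 0,
                        ue = 0, params = pathway_params("EGF")),
                   class = "pathway_ss")
  bd <- frequency_response(toy)
  expect_equal(bd$modulation[1], 1 / a, tolerance = 1e-6)
  bm <- suppressWarnings(bode_metrics(bd))  # low-pass peak sits on the edge
  expect_equal(bm$total_phase_change_deg, 90, tolerance = 0.1)
  expect_equal(bm$low_freq_phase_deg, 0, tolerance = 0.1)
  # analytic check at an interior frequency
  i_mid <- which.min(abs(bd$omega_rad_s - a))
  expect_equal(bd$modulation[i_mid], 1 / abs(1i * bd$omega_rad_s[i_mid] + a),
               tolerance = 1e-10)
})

test_that("minimal transfer function is coprime, stable and matches the resolvent", {
  ss <- ss_at("EGF", 0.01)
  tf <- fix("tf_egf_0.01", function() to_transfer_function(ss))

  # reduced orders for the EGF map: cubic over octic, monic denominator
  expect_length(tf$num, 4)
  expect_length(tf$den, 9)
  expect_identical(tf$den[1], 1)
  # all retained poles strictly stable
  expect_true(all(Re(tf$poles) < 0))

  # rational form vs direct resolvent evaluation at random frequencies
  set.seed(101)
  w <- 10^stats::runif(50, -6, 0)
  t_direct <- vapply(w, function(wk) {
    drop(ss$C %*% solve(1i * wk * diag(16) - ss$A, ss$B))
  }, complex(1))
  expect_lt(max(Mod(eval_tf(tf, 1i * w) - t_direct) / Mod(t_direct)), 1e-8)

  # DC gain equals the local slope of the dose-response curve
  du <- 1e-4
  slope <- (solve_equilibrium(egf(), 0.01 + du)$xe[["ERKp"]] -
              solve_equilibrium(egf(), 0.01 - du)$xe[["ERKp"]]) / (2 * du)
  expect_equal(Re(eval_tf(tf, 0 + 0i)), slope, tolerance = 1e-3)
})

test_that("reduced order is found, not assumed: NGF keeps its feedback mode", {
  # under NGF the positive-feedback protein influences the output, so one
  # fewer mode cancels and the minimal orders grow by one
  tf_n <- to_transfer_function(ss_at("NGF", 0.25))
  expect_length(tf_n$num, 5)
  expect_length(tf_n$den, 10)
})

test_that("phase unwrapping is continuous and settles on the -450 asymptote", {
  bd <- frequency_response(ss_at("EGF", 0.01))
  expect_true(all(diff(bd$phase_deg) > -90 & diff(bd$phase_deg) < 90))
  expect_true(all(bd$modulation > 0))
  # high-frequency magnitude rolls off as omega^-5 (relative degree five)
  n <- nrow(bd)
  slope <- diff(log10(bd$modulation[c(n - 100, n)])) /
    diff(log10(bd$omega_rad_s[c(n - 100, n)]))
  expect_equal(slope, -5, tolerance = 0.01)
  # and the phase lands 450 degrees below its zero-frequency value
  expect_equal(bd$phase_deg[n], -450, tolerance = 1)
})

test_that("bode metrics flag degenerate grids", {
  bd <- frequency_response(ss_at("EGF", 0.01))
  expect_error(bode_metrics(bd[bd$omega_rad_s > 1e-4, ]), "span")
  # a pure low-pass places the modulation maximum on the low boundary
  a <- 1e-3
  toy <- structure(list(A = diag(-a, 16),
                        B = matrix(c(rep(0, 9), 1, rep(0, 6))),
                        C = matrix(c(rep(0, 9), 1, rep(0, 6)), 1), D = 0,
                        ue = 0, params = pathway_params("EGF")),
                   class = "pathway_ss")
  expect_warning(bode_metrics(frequency_response(toy)), "boundary")
})
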