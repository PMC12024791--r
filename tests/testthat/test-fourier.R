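# Adaptive-quadrature Fourier coefficients: the independent oracle for the
# closed forms. Integrates each smooth piece of the waveform separately.
# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
gl_rule <- local({
  k <- 1:11
  beta <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, 12)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
})

quad_coef <- function(f, Tper, n, breaks = numeric(0)) {
  # split at waveform kinks and once per oscillation half-period so each
  # piece is smooth and slowly varying; 12-point Gauss-Legendre per piece
  osc <- seq(0, Tper, length.out = 2L * n + 1L)
  pts <- sort(unique(c(0, breaks, osc, Tper)))
  piece <- function(g) {
    sum(vapply(seq_len(length(pts) - 1), function(i) {
      a <- pts[i]; b <- pts[i + 1]
      sum(gl_rule$w * g((a + b) / 2 + (b - a) / 2 * gl_rule$x)) *
        (b - a) / 2
    }, 0))
  }
  w <- 2 * pi * n / Tper
  list(an = 2 / Tper * piece(function(t) f(t) * cos(w * t)),
       bn = 2 / Tper * piece(function(t) f(t) * sin(w * t)))
}

test_that("rectangular closed-form coefficients match quadrature", {
  spec <- pulse_train_spec("rectangular", A = 0.08, T = 1200, tau = 180)
  s <- fourier_rectangular(spec, N = 500)
  expect_equal(s$a0 / 2, 0.012, tolerance = 1e-14)  # mean = A tau / T

  f <- function(t) waveform_eval(spec, t)
  for (n in c(1, 2, 3, 7, 50, 499)) {
    q <- quad_coef(f, 1200, n, breaks = 180)
    expect_equal(s$an[n], q$an, tolerance = 1e-10)
    expect_equal(s$bn[n], q$bn, tolerance = 1e-10)
  }
})

test_that("half-duty rectangular train reduces to the odd sine series", {
  spec <- pulse_train_spec("rectangular", A = 0.6, T = 100, tau = 50)
  s <- fourier_rectangular(spec, N = 20)
  n <- 1:20
  expect_equal(s$an, rep(0, 20), tolerance = 1e-15)
  expect_equal(s$bn[n %% 2 == 1], 2 * 0.6 / (pi * n[n %% 2 == 1]),
               tolerance = 1e-13)
  expect_equal(s$bn[n %% 2 == 0], rep(0, 10), tolerance = 1e-15)
})

test_that("triangular series has odd cosine harmonics in 1/(2n-1)^2", {
  spec <- pulse_train_spec("triangular", A = 4.2, T = 3600)
  s <- fourier_triangular(spec, N = 199)
  expect_equal(s$a0 / 2, 2.1, tolerance = 1e-14)
  expect_equal(abs(s$an[1] / s$an[3]), 9, tolerance = 1e-12)
  expect_true(all(s$an[seq(2, 198, 2)] == 0))
  expect_true(all(s$bn == 0))

  f <- function(t) waveform_eval(spec, t)
  for (n in c(1, 3, 5, 99)) {
    q <- quad_coef(f, 3600, n, breaks = 1800)
    expect_equal(s$an[n], q$an, tolerance = 1e-10)
  }

  # reconstruction converges to the exact triangle waveform at the 1/N
  # rate set by the kink: error ~ (4A/pi^2) * 1/(2N)
  t <- seq(0, 3600, by = 5)
  err199 <- max(abs(fourier_eval(s, t) - waveform_eval(spec, t)))
  expect_lt(err199, 4 * 4.2 / pi^2 / (2 * 199) * 1.1)
  s_big <- fourier_triangular(spec, N = 2999)
  err2999 <- max(abs(fourier_eval(s_big, t) - waveform_eval(spec, t)))
  expect_lt(err2999, 1e-4 * 4.2)
})

test_that("reconstructed trains have the stated mean and stay near-positive", {
  spec <- pulse_train_spec("rectangular", A = 0.08, T = 1200, tau = 180)
  s <- fourier_rectangular(spec, N = 400)
  t <- seq(0, 1200, by = 0.5)
  recon <- fourier_eval(s, t)
  expect_equal(mean(recon[-length(recon)]), s$a0 / 2, tolerance = 1e-6)
  expect_gt(min(recon), -0.09 * spec$A)  # Gibbs overshoot allowance
})

test_that("waveform specifications validate their geometry", {
  expect_error(pulse_train_spec("rectangular", A = 1, T = 100, tau = 100),
               "tau")
  expect_error(pulse_train_spec("rectangular", A = 1, T = 100), "tau")
  expect_error(pulse_train_spec("sinusoid", A = 2, T = 100, mean = 1),
               "amplitude")
  expect_error(
    fourier_rectangular(
      pulse_train_spec("rectangular", A = 1, T = 100, tau = 10), N = 0),
    "N")
})
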