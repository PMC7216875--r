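test_that("candidate initialization picks psi = 0 for on-resonance data", {
  tis <- study_tissue()
  s <- study_protocol()$settings[[1]]
  ep <- ellipse_from_tissue(tis, s, psi = 0, phi_rf = 0)
  samples <- ellipse_signal(ep, s$phase_increments)
  g <- ellipse_initial_guess(samples, s$phase_increments, s$tr, s$alpha)
  expect_equal(g$psi, 0)
  expect_error(ellipse_initial_guess(rep(0 + 0i, 6), s$phase_increments,
                                     s$tr, s$alpha),
               class = "degenerate_input")
})

test_that("candidate selection is equivariant to a global complex scale", {
  tis <- study_tissue()
  s <- study_protocol()$settings[[2]]
  ep <- ellipse_from_tissue(tis, s, psi = -2.9, phi_rf = 0.4)
  samples <- ellipse_signal(ep, ep$psi + s$phase_increments)
  g1 <- ellipse_initial_guess(samples, s$phase_increments, s$tr, s$alpha)
  cc <- 2.5 * exp(1i * 0.8)
  g2 <- ellipse_initial_guess(cc * samples, s$phase_increments, s$tr, s$alpha)
  expect_equal(g2$psi, g1$psi)             # same candidate wins
  expect_equal(g2$me, abs(cc) * g1$me, tolerance = 1e-12)
  expect_equal(wrap_angle(g2$phi_rf - g1$phi_rf), wrap_angle(0.8),
               tolerance = 1e-12)
})

test_that("noiseless ellipses are recovered to solver tolerance from random truths", {
  set.seed(202)
  s <- study_protocol()$settings[[1]]
  for (k in 1:25) {
    a <- runif(1, 0.5, 0.98)
    ep <- ellipse_params(me = runif(1, 0.5, 30), a = a,
                         b = min(runif(1, 0.05, 0.9),
                                 0.95 * 2 * a / (1 + a^2)),
                         psi = runif(1, -pi, pi),
                         phi_rf = runif(1, -pi, pi))
    samples <- ellipse_signal(ep, ep$psi + s$phase_increments)
    f <- fit_ellipse(samples, s$phase_increments, s$tr, s$alpha)
    expect_lt(abs(f$params$me - ep$me) / ep$me, 1e-6)
    expect_lt(abs(f$params$a - ep$a) / ep$a, 1e-6)
    expect_lt(abs(f$params$b - ep$b) / max(ep$b, 1e-3), 1e-5)
    expect_lt(abs(wrap_angle(f$params$psi - ep$psi)), 1e-6)
    expect_lt(abs(wrap_angle(f$params$phi_rf - ep$phi_rf)), 1e-6)
    expect_lt(f$rmse, 1e-8)
    expect_true(f$converged)
  }
})

test_that("estimator dispersion and bias shrink with the noise level", {
  tis <- study_tissue()
  s <- study_protocol()$settings[[1]]
  run_at <- function(sigma, n = 48) {
    set.seed(55)
    est <- replicate(n, {
      psi <- runif(1, -pi, pi); phi <- runif(1, -pi, pi)
      ep <- ellipse_from_tissue(tis, s, psi = psi, phi_rf = phi)
      z <- ellipse_signal(ep, psi + s$phase_increments)
      z <- z + complex(real = rnorm(6, sd = sigma / sqrt(2)),
                       imaginary = rnorm(6, sd = sigma / sqrt(2)))
      f <- fit_ellipse(z, s$phase_increments, s$tr, s$alpha)
      c(f$params$me, f$params$a, f$params$b)
    })
    truth <- ellipse_from_tissue(tis, s)
    list(bias = abs(rowMeans(est) - c(truth$me, truth$a, truth$b)) /
           c(truth$me, truth$a, truth$b),
         cv = apply(est, 1, sd) / rowMeans(est))
  }
  hi <- run_at(100 / 500)
  lo <- run_at(100 / 2000)
  expect_true(all(lo$cv < hi$cv))
  expect_true(all(lo$bias < 0.01))
  expect_true(all(hi$bias < 0.05))
})

test_that("fit is equivariant under a global phase and sample permutation", {
  tis <- study_tissue()
  s <- study_protocol()$settings[[3]]
  gam <- 0.6
  # exact equivariance on noiseless data
  ep <- ellipse_from_tissue(tis, s, psi = 0.9, phi_rf = -0.2)
  z0 <- ellipse_signal(ep, ep$psi + s$phase_increments)
  g0 <- fit_ellipse(z0, s$phase_increments, s$tr, s$alpha)
  g1 <- fit_ellipse(z0 * exp(1i * gam), s$phase_increments, s$tr, s$alpha)
  expect_equal(g1$params$me, g0$params$me, tolerance = 1e-8)
  expect_equal(g1$params$a, g0$params$a, tolerance = 1e-8)
  expect_equal(g1$params$b, g0$params$b, tolerance = 1e-8)
  expect_equal(wrap_angle(g1$params$psi - g0$params$psi), 0, tolerance = 1e-6)
  expect_equal(wrap_angle(g1$params$phi_rf - g0$params$phi_rf - gam), 0,
               tolerance = 1e-6)
  # on noisy data the optimum may shift within solver resolution only
  set.seed(77)
  z <- z0 + complex(real = rnorm(6, sd = 0.14),
                    imaginary = rnorm(6, sd = 0.14))
  f0 <- fit_ellipse(z, s$phase_increments, s$tr, s$alpha)
  f1 <- fit_ellipse(z * exp(1i * gam), s$phase_increments, s$tr, s$alpha)
  expect_equal(f1$params$me, f0$params$me, tolerance = 5e-3)
  expect_equal(f1$params$a, f0$params$a, tolerance = 5e-3)
  expect_equal(f1$params$b, f0$params$b, tolerance = 2e-2)
  expect_equal(wrap_angle(f1$params$phi_rf - f0$params$phi_rf - gam), 0,
               tolerance = 1e-2)
  p <- sample(6)
  f2 <- fit_ellipse(z[p], s$phase_increments[p], s$tr, s$alpha)
  expect_equal(f2$params$me, f0$params$me, tolerance = 1e-9)
  expect_equal(f2$rmse, f0$rmse, tolerance = 1e-9)
})

test_that("the Huber loss dampens a gross outlier relative to plain least squares", {
  tis <- study_tissue()
  s <- study_protocol()$settings[[1]]
  sigma <- 100 / 500
  set.seed(13)
  shifts_h <- matrix(0, 0, 3); shifts_p <- matrix(0, 0, 3)
  for (k in 1:8) {
    psi <- runif(1, -pi, pi); phi <- runif(1, -pi, pi)
    ep <- ellipse_from_tissue(tis, s, psi = psi, phi_rf = phi)
    # otherwise clean samples with a single gross outlier
    zo <- ellipse_signal(ep, psi + s$phase_increments)
    zo[3] <- zo[3] + 5 * sigma * exp(1i * runif(1, 0, 2 * pi))
    truth <- c(ep$me, ep$a, ep$b)
    fh <- fit_ellipse(zo, s$phase_increments, s$tr, s$alpha, huber = TRUE)
    fp <- fit_ellipse(zo, s$phase_increments, s$tr, s$alpha, huber = FALSE)
    shifts_h <- rbind(shifts_h, abs(c(fh$params$me, fh$params$a, fh$params$b) - truth) / truth)
    shifts_p <- rbind(shifts_p, abs(c(fp$params$me, fp$params$a, fp$params$b) - truth) / truth)
  }
  # aggregate over repeats: the robust fit tracks the truth more closely on
  # every parameter (a is insensitive to the outlier and may tie within 2%)
  expect_true(all(colMeans(shifts_h) <= 1.02 * colMeans(shifts_p)))
  expect_lt(colMeans(shifts_h)[1], colMeans(shifts_p)[1])   # M_E
  expect_lt(colMeans(shifts_h)[3], colMeans(shifts_p)[3])   # b
  expect_lt(mean(shifts_h), mean(shifts_p))
})

test_that("degenerate or undersized inputs are refused", {
  s <- study_protocol()$settings[[1]]
  expect_error(fit_ellipse(c(1 + 0i, 2, 3, 4), (1:4) * pi / 3, s$tr, s$alpha),
               class = "underdetermined")
  expect_error(fit_ellipse(rep(1 + 0i, 5), (1:6) * pi / 3, s$tr, s$alpha),
               class = "invalid_input")
  expect_error(fit_ellipse(rep(0i, 6), s$phase_increments, s$tr, s$alpha),
               class = "degenerate_input")
})

test_that("rmse_map reports absolute and relative residuals in input shape", {
  tis <- study_tissue()
  s <- study_protocol()$settings[[1]]
  ep <- ellipse_from_tissue(tis, s, psi = 0.2, phi_rf = 0.1)
  z <- ellipse_signal(ep, ep$psi + s$phase_increments)
  f <- fit_ellipse(z, s$phase_increments, s$tr, s$alpha)
  mp <- rmse_map(list(f, f))
  expect_length(mp$rmse, 2)
  expect_lt(max(mp$rmse), 1e-8)
  expect_equal(mp$rel_rmse, mp$rmse / f$params$me, tolerance = 1e-12)
})
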