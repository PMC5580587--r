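test_that("the corrected series is affine in the whitening coefficients", {
  fx <- noisy_fixture(1, r = 3)
  expect_equal(objective_vector(fx$series), fx$series$values)
  a1 <- c(0.1, 0.9, 0.4); a2 <- c(0.8, 0.2, 0.6); lam <- 0.37
  F1 <- approx_vector(fx$fit, fx$part, fx$trans, a1)
  F2 <- approx_vector(fx$fit, fx$part, fx$trans, a2)
  Fm <- approx_vector(fx$fit, fx$part, fx$trans, lam * a1 + (1 - lam) * a2)
  expect_equal(Fm, lam * F1 + (1 - lam) * F2, tolerance = 1e-12)
  # the anchor is never touched by the correction
  expect_equal(F1[1], fx$series$values[1])
  # independently derived affine map gives the same values
  map <- affine_correction_map(fx$fit, fx$part, fx$trans)
  expect_equal(F1, map$base + as.numeric(map$M %*% a1), tolerance = 1e-12)
})

test_that("finite-difference Jacobian equals the analytic affine derivative", {
  for (seed in c(6, 14)) {
    fx <- noisy_fixture(seed, r = 3)
    map <- affine_correction_map(fx$fit, fx$part, fx$trans)
    alpha <- c(0.5, 0.5, 0.5)
    A <- fd_jacobian(fx$fit, fx$part, fx$trans, alpha)
    expect_equal(A, map$M, tolerance = 1e-8)
    # the probe step is floored at alpha = 0, and the affine map makes the
    # difference exact for any step ratio
    A0 <- fd_jacobian(fx$fit, fx$part, fx$trans, c(0, 0, 0))
    expect_true(all(is.finite(A0)))
    expect_equal(A0, map$M, tolerance = 1e-8)
    A_bigR <- fd_jacobian(fx$fit, fx$part, fx$trans, alpha,
                          optimizer_control(step_ratio = 400))
    expect_equal(A_bigR, A, tolerance = 1e-8)
  }
})

test_that("one Gauss-Newton step solves the linearized problem", {
  set.seed(55)
  A <- qr.Q(qr(matrix(stats::rnorm(24), 8, 3)))   # orthonormal columns
  alpha <- c(0.5, 0.5, 0.5)
  FD <- stats::rnorm(8)
  st <- gauss_newton_step(A, FD, alpha)
  expect_equal(st$eta, as.numeric(t(A) %*% FD), tolerance = 1e-12)
  expect_equal(gauss_newton_step(A, rep(0, 8), alpha)$eta, rep(0, 3))
  expect_true(all(st$alpha >= 0 & st$alpha <= 1))
  # on the affine objective, one unconstrained step lands on the optimum
  fx <- noisy_fixture(1, r = 3)
  map <- affine_correction_map(fx$fit, fx$part, fx$trans)
  FD <- objective_vector(fx$series) -
    approx_vector(fx$fit, fx$part, fx$trans, alpha)
  eta <- gauss_newton_step(map$M, FD, alpha)$eta
  direct <- qr.solve(map$M, objective_vector(fx$series) - map$base)
  expect_equal(alpha + eta, as.numeric(direct), tolerance = 1e-9)
})

test_that("the evaluation function is the squared linearized residual", {
  set.seed(77)
  A <- matrix(stats::rnorm(20), 10, 2)
  FD <- stats::rnorm(10)
  expect_equal(evaluate_q(A, FD, c(0, 0)), sum(FD^2))
  eta <- qr.solve(A, FD)
  # residual after the exact step is the orthogonal-complement energy
  proj <- A %*% qr.solve(A, FD)
  expect_equal(evaluate_q(A, FD, eta), sum((FD - proj)^2), tolerance = 1e-10)
  expect_equal(evaluate_q(A, A %*% c(1, -2), c(1, -2)), 0, tolerance = 1e-12)
})

test_that("the optimizer fixed point is the box-constrained least-squares optimum", {
  checked <- 0
  for (seed in c(1, 5, 6, 8, 9, 10, 12, 13, 15, 19, 23, 25)) {
    r <- 2 + seed %% 3
    fx <- noisy_fixture(seed, r = r)
    map <- affine_correction_map(fx$fit, fx$part, fx$trans)
    opt <- optimize_alpha(fx$fit, fx$part, fx$trans)
    expect_true(all(opt$alpha >= 0 & opt$alpha <= 1))
    oracle <- box_ls_oracle(map$M, objective_vector(fx$series) - map$base)
    rss_opt <- sum((objective_vector(fx$series) -
                      approx_vector(fx$fit, fx$part, fx$trans, opt$alpha))^2)
    expect_equal(rss_opt, oracle$rss, tolerance = 1e-6)
    if (qr(map$M)$rank == r) {           # unique optimum: compare coefficients
      expect_equal(opt$alpha, oracle$x, tolerance = 1e-6)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 10)
})

test_that("the optimizer is deterministic and handles degenerate intervals", {
  fx <- noisy_fixture(19, r = 3)
  o1 <- optimize_alpha(fx$fit, fx$part, fx$trans)
  o2 <- optimize_alpha(fx$fit, fx$part, fx$trans)
  expect_identical(o1$alpha, o2$alpha)
  expect_identical(o1$q_trace, o2$q_trace)
  expect_true(o1$converged)
  # zero-width intervals at 0: alpha is irrelevant, Q settles at ||G - F||^2
  flat <- fx$part
  flat$lower <- flat$upper <- rep(0, 3)
  o3 <- optimize_alpha(fx$fit, flat, fx$trans)
  expect_true(o3$converged)
  expect_equal(o3$q_trace[length(o3$q_trace)],
               sum((objective_vector(fx$series) - fitted(fx$fit))^2),
               tolerance = 1e-10)
})

test_that("custom starting points and tolerances are honoured", {
  fx <- noisy_fixture(9, r = 2)
  ctl <- optimizer_control(alpha0 = c(0, 1), tol = 1e-10, max_iter = 50)
  opt <- optimize_alpha(fx$fit, fx$part, fx$trans, control = ctl)
  base <- optimize_alpha(fx$fit, fx$part, fx$trans)
  expect_equal(opt$alpha, base$alpha, tolerance = 1e-6)
  expect_error(optimizer_control(step_ratio = 0), "step_ratio")
  expect_error(optimizer_control(alpha0 = c(-0.1, 0.5)), "\\[0, 1\\]")
})
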