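test_that("equal-width partition bounds and labels follow the construction", {
  p <- partition_states(c(-1, 0, 2), r = 3)
  expect_equal(p$lower, c(-1, 0, 1))
  expect_equal(p$upper, c(0, 1, 2))
  expect_equal(p$labels, c(1L, 2L, 3L))
  # adjacent states share their boundary
  expect_equal(p$upper[-3], p$lower[-1])
  # r = 1 collapses to a single spanning state
  p1 <- partition_states(c(-1, 0, 2), r = 1)
  expect_equal(c(p1$lower, p1$upper), c(-1, 2))
  expect_equal(p1$labels, rep(1L, 3))
  # a residual exactly on an internal boundary goes to the higher state
  pb <- partition_states(c(0, 1, 2, 4), r = 2)
  expect_equal(pb$labels, c(1L, 1L, 2L, 2L))  # 2 sits on the shared bound
  expect_error(partition_states(rep(0.5, 4), r = 3), "degenerate")
})

test_that("every labeled residual lies inside its state's interval", {
  for (seed in c(5, 11, 23)) {
    for (r in 2:5) {
      fx <- noisy_fixture(seed, r = r)
      e <- residuals(fx$fit)[-1]
      p <- fx$part
      expect_true(all(e >= p$lower[p$labels] - 1e-12))
      expect_true(all(e <= p$upper[p$labels] + 1e-12))
    }
  }
})

test_that("transition counts and row-stochastic matrix match hand counts", {
  tm <- estimate_transitions(c(1, 1, 2, 1), r = 2, m = 1)
  expect_equal(tm$matrix, rbind(c(0.5, 0.5), c(1, 0)))
  expect_equal(tm$totals, c(2L, 1L))
  tm2 <- estimate_transitions(c(1, 2, 1, 2), r = 2, m = 2)
  expect_equal(tm2$matrix, diag(2))
  # a state never observed as a predecessor gets the uniform row
  tm3 <- estimate_transitions(c(1, 1, 1), r = 2, m = 1)
  expect_equal(tm3$matrix[2, ], c(0.5, 0.5))
  expect_error(estimate_transitions(c(1, 2), r = 2, m = 2), "smaller")
})

test_that("estimated transition rows always sum to one", {
  for (seed in 1:6) {
    fx <- noisy_fixture(seed, r = sample(2:5, 1))
    expect_equal(rowSums(fx$trans$matrix), rep(1, fx$part$r), tolerance = 1e-12)
    expect_true(all(fx$trans$matrix >= 0))
  }
})

test_that("probability vectors stay on the simplex under propagation", {
  P <- rbind(c(0.5, 0.5), c(1, 0))
  expect_equal(propagate(c(1, 0), P, 1), c(0.5, 0.5))
  expect_equal(propagate(c(1, 0), P, 2), c(0.75, 0.25))
  expect_equal(propagate(c(0.3, 0.7), diag(2), 5), c(0.3, 0.7))
  expect_error(propagate(c(1, 0, 0), P), "mismatch")
  set.seed(9)
  for (k in 1:10) {
    r <- sample(2:5, 1)
    P <- matrix(stats::rexp(r * r), r)
    P <- P / rowSums(P)
    a0 <- stats::rexp(r); a0 <- a0 / sum(a0)
    a <- propagate(a0, P, sample(1:6, 1))
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a >= 0))
  }
})

test_that("whitened corrections interpolate their state intervals", {
  p <- partition_states(c(-1, 0, 2), r = 3)
  expect_equal(whiten(p, c(1, 1, 1)), p$lower)
  expect_equal(whiten(p, c(0, 0, 0)), p$upper)
  expect_equal(whiten(partition_states(c(-1, 1), 1), 0.5), 0)
  expect_error(whiten(p, c(0.5, 1.2, 0)), "\\[0, 1\\]")
  set.seed(4)
  for (k in 1:10) {
    alpha <- stats::runif(3)
    v <- whiten(p, alpha)
    expect_true(all(v >= p$lower & v <= p$upper))
  }
})

test_that("the correction collapses as the state distribution dictates", {
  fx <- noisy_fixture(13, r = 3)
  v <- whiten(fx$part, c(0.2, 0.7, 0.4))
  corr <- corrected_series(fx$fit, fx$part, fx$trans, c(0.2, 0.7, 0.4))
  n <- fx$fit$n
  # anchor and first labeled point are returned uncorrected
  expect_equal(corr[1:2], fitted(fx$fit)[1:2])
  # each corrected point adds exactly the propagated expectation of v
  for (t in 3:n) {
    w <- fx$trans$matrix[fx$part$labels[t - 2], ]
    expect_equal(corr[t], fitted(fx$fit)[t] + sum(w * v), tolerance = 1e-12)
  }
  # correction never exceeds the widest interval bound
  expect_lte(max(abs(corr - fitted(fx$fit))),
             max(abs(c(fx$part$lower, fx$part$upper))) + 1e-12)
})

test_that("identity transitions shift every forecast by the last state's value", {
  fx <- noisy_fixture(21, r = 2)
  ident <- fx$trans
  ident$matrix <- diag(2)
  alpha <- c(0.3, 0.8)
  v <- whiten(fx$part, alpha)
  last <- fx$part$labels[length(fx$part$labels)]
  fc <- forecast_corrected(fx$fit, fx$part, ident, alpha, horizon = 4)
  expect_equal(fc, forecast_gm11(fx$fit, 4) + v[last], tolerance = 1e-12)
  # zero-width whitening at 0 reduces to the plain grey forecast
  zero <- fx$part
  zero$lower <- zero$upper <- c(0, 0)
  fc0 <- forecast_corrected(fx$fit, zero, fx$trans, alpha, horizon = 3)
  expect_equal(fc0, forecast_gm11(fx$fit, 3), tolerance = 1e-12)
})

test_that("alternating two-state noise is recovered exactly and correction helps", {
  flip <- rbind(c(0, 1), c(1, 0))
  for (seed in c(2, 8, 31)) {
    s <- sim_grey_series(a = -0.1, b = 3, x1 = 3, n = 12,
                         noise_states = rbind(c(1, 0.4), c(1, -0.4)),
                         transition = flip, seed = seed)
    fit <- gm11(s)
    part <- partition_states(residuals(fit)[-1], r = 2)
    expect_equal(abs(diff(part$labels)), rep(1L, length(part$labels) - 1))
    trans <- estimate_transitions(part$labels, r = 2, m = 1)
    expect_identical(trans$matrix, flip)
    opt <- optimize_alpha(fit, part, trans)
    corr <- corrected_series(fit, part, trans, opt$alpha)
    expect_lt(mape(s$values, corr), mape(s$values, fitted(fit)))
  }
})
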