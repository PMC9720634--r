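test_that("parameter invariants are enforced", {
  expect_error(listener_params(sigma = 0), "sigma")
  expect_error(listener_params(gamma = 1.1), "gamma")
  expect_error(listener_params(gamma = 0.6, lam = 0.5), "gamma \\+ lam")
  expect_error(listener_params(theta0 = -1), "theta0")
  expect_error(listener_params(miss_rate = 1), "miss_rate")
  expect_error(midpoint_tmr(listener_params(), -5), "non-negative")
})

test_that("midpoint curve: no release co-located, saturating release far out", {
  l <- listener_params(T0 = 0, srm_max = 10, theta0 = 25, lam = 0)
  expect_equal(midpoint_tmr(l, 0), 0)
  expect_equal(midpoint_tmr(l, 1e9), -10)
  # closed-form evaluation at theta = theta0
  expect_equal(midpoint_tmr(l, 25), -10 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(midpoint_tmr(l, 25), -6.321206, tolerance = 1e-6)
  # babble shifts move the effective midpoint and asymptote
  lb <- listener_params(T0 = 0, srm_max = 10, theta0 = 25,
                        babble_shift = 3, babble_srm_shift = -2)
  expect_equal(midpoint_tmr(lb, 0, babble = TRUE), 3)
  expect_equal(midpoint_tmr(lb, 1e9, babble = TRUE), 3 - 8)
})

test_that("psychometric surface respects guess/lapse bounds and midpoint", {
  l <- listener_params(T0 = 0, sigma = 4, gamma = 1/9, lam = 0)
  expect_equal(p_correct(l, -1e3, 0), 1/9, tolerance = 1e-12)
  expect_equal(p_correct(l, 0, 0), 1/9 + (8/9) * 0.5, tolerance = 1e-12)
  expect_equal(p_correct(l, 0, 0), 0.5555556, tolerance = 1e-6)
  # numeric evaluation against the reference normal CDF
  l2 <- listener_params(T0 = 0, sigma = 4, gamma = 1/9, lam = 0.02)
  expect_equal(p_correct(l2, 2, 0),
               1/9 + (1 - 1/9 - 0.02) * pnorm(2 / 4), tolerance = 1e-12)
  expect_true(p_correct(l2, 1e3, 0) <= 1 - 0.02 + 1e-12)
})

test_that("p_correct is monotone in TMR and in separation", {
  l <- listener_params()
  tmrs <- seq(-20, 20, by = 0.5)
  for (th in c(0, 10, 45, 90)) {
    expect_true(all(diff(p_correct(l, tmrs, th)) > 0))
  }
  thetas <- seq(0, 90, by = 1)
  for (tmr in c(-10, -2, 4)) {
    expect_true(all(diff(p_correct(l, tmr, thetas)) >= 0))
  }
})

test_that("threshold inversion matches the inverse-CDF oracle", {
  l0 <- listener_params(T0 = 0, sigma = 1, gamma = 0, lam = 0,
                        srm_max = 0)
  expect_equal(threshold_tmr_at(l0, 0, p_target = 0.7071),
               qnorm(0.7071), tolerance = 1e-9)
  expect_equal(threshold_tmr_at(l0, 0, p_target = 0.7071), 0.5449,
               tolerance = 1e-3)
  l1 <- listener_params(T0 = 0, sigma = 1, gamma = 1/9, lam = 0,
                        srm_max = 0)
  expect_equal(threshold_tmr_at(l1, 0, p_target = 0.7071),
               qnorm((0.7071 - 1/9) / (8/9)), tolerance = 1e-9)
  expect_equal(threshold_tmr_at(l1, 0, p_target = 0.7071), 0.4413,
               tolerance = 1e-3)
  expect_error(threshold_tmr_at(l1, 0, p_target = 0.05), "p_target")
  expect_error(threshold_tmr_at(listener_params(lam = 0.02), 0,
                                p_target = 0.99), "p_target")
})

test_that("threshold_tmr_at round-trips through p_correct", {
  set.seed(21)
  for (i in 1:25) {
    l <- listener_params(T0 = runif(1, -10, 5), sigma = runif(1, 1, 6),
                         gamma = 1/9, lam = runif(1, 0, 0.05),
                         srm_max = runif(1, 0, 12),
                         theta0 = runif(1, 5, 40))
    th <- runif(1, 0, 90)
    p <- runif(1, 0.3, 0.9)
    tmr <- threshold_tmr_at(l, th, p)
    expect_equal(p_correct(l, tmr, th), p, tolerance = 1e-9)
  }
})

test_that("SRM identity: threshold release equals midpoint release exactly", {
  l <- listener_params(T0 = -1, sigma = 3, gamma = 1/9, lam = 0.03,
                       srm_max = 9, theta0 = 20)
  for (th in c(5, 15, 30, 60, 90)) {
    release <- threshold_tmr_at(l, 0) - threshold_tmr_at(l, th)
    expect_equal(release, midpoint_tmr(l, 0) - midpoint_tmr(l, th),
                 tolerance = 1e-12)
  }
})

test_that("behaviour sampling honours degenerate rates and the ceiling", {
  miss_all <- listener_params(miss_rate = 0.999)
  # miss_rate cannot be exactly 1; near-1 must dominate
  set.seed(1)
  expect_true(mean(sample_behavior(miss_all, 0, 0, n = 2000) == "miss")
              > 0.99)
  clean <- clean_listener(T0 = -2, sigma = 4)
  set.seed(2)
  ev <- sample_behavior(clean, tmr = 60, theta = 0, n = 10000)
  expect_true(all(ev == "correct"))
})

test_that("behaviour sampling is reproducible from a seed", {
  l <- listener_params(miss_rate = 0.1, errant_rate = 0.1)
  set.seed(33); a <- sample_behavior(l, 0, 20, n = 500)
  set.seed(33); b <- sample_behavior(l, 0, 20, n = 500)
  expect_identical(a, b)
  expect_true(all(a %in% c("correct", "wrong_digit", "miss", "errant")))
  expect_gt(length(unique(a)), 2)  # rates 0.1 must surface all failure modes
})

test_that("population generation is reproducible and respects the spec", {
  zero <- population_spec(5, spreads = list(
    T0 = 0, sigma = 0, gamma = 0, lam = 0, srm_max = 0, theta0 = 0,
    miss_rate = 0, errant_rate = 0, babble_shift = 0,
    babble_srm_shift = 0), seed = 7)
  pop <- generate_population(zero)
  expect_length(pop, 5)
  for (p in pop) {
    expect_equal(p$T0, -2)
    expect_equal(p$srm_max, 8)
  }

  spec <- population_spec(20, seed = 42)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1, p2)
  # all draws respect the invariants
  for (p in p1) expect_s3_class(p, "listener_params")

  # law-of-large-numbers check on a large draw: srm_max mean 8, spread 2
  big <- generate_population(population_spec(
    400, means = list(srm_max = 8), spreads = list(srm_max = 2),
    seed = 9))
  m <- mean(vapply(big, `[[`, numeric(1), "srm_max"))
  se <- 2 / sqrt(400)
  expect_lt(abs(m - 8), 3 * se + 0.05)  # slight truncation shift allowed
})

test_that("impossible truncation with zero spread is a configuration error", {
  bad <- population_spec(3, means = list(sigma = -2),
                         spreads = list(sigma = 0))
  expect_error(generate_population(bad), "sigma")
})
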