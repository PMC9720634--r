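test_that("SRM-offset and SRM-derivation arithmetic is exact", {
  expect_equal(fixed_tmr_for_srm(0, 6), -6)
  expect_equal(fixed_tmr_for_srm(-2.5, 9), -11.5)
  expect_error(fixed_tmr_for_srm(0, 0), "positive")
  expect_error(fixed_tmr_for_srm(0, -3), "positive")

  expect_equal(derive_srm(-2.0, -8.7), 6.7)
  expect_equal(derive_srm(-1.0, -9.3), 8.3)
  expect_equal(derive_srm(-4, -4), 0)
})

test_that("condition specs validate their fields", {
  expect_error(condition_spec("quiet", "adaptive_angle"), "target_srm")
  expect_error(condition_spec("quiet", "colocated", target_srm = 6),
               "adaptive_angle")
  cs <- condition_spec("babble", "adaptive_angle", target_srm = 9)
  expect_equal(cs$label, "adaptive_9dB_babble")
  expect_equal(cs$n_tracks, 3L)
})

test_that("run_condition runs the right track type at the right point", {
  l <- clean_listener(T0 = -2, sigma = 3)
  set.seed(61)
  co <- run_condition(l, condition_spec("quiet", "colocated"))
  expect_length(co$thresholds, 3)
  expect_equal(co$threshold, mean(co$thresholds))
  expect_equal(co$mode, "track_tmr")
  expect_equal(co$fixed_other, 0)

  f30 <- run_condition(l, condition_spec("quiet", "fixed_separation"))
  expect_equal(f30$fixed_other, 30)
  expect_equal(f30$mode, "track_tmr")

  ad <- run_condition(l, condition_spec("quiet", "adaptive_angle",
                                        target_srm = 6),
                      colocated_threshold = -2)
  expect_equal(ad$mode, "track_angle")
  expect_equal(ad$fixed_other, -8)  # co-located average minus 6 dB

  expect_error(run_condition(l, condition_spec("quiet", "adaptive_angle",
                                               target_srm = 6)),
               "co-located")
})

test_that("a minimal study yields thresholds and one derived SRM", {
  l <- clean_listener(T0 = -2, sigma = 3, srm_max = 8, theta0 = 15)
  conds <- list(condition_spec("quiet", "colocated"),
                condition_spec("quiet", "fixed_separation"))
  st <- run_study(list(l), conds, seed = 13)
  expect_equal(nrow(st$conditions), 2)
  expect_equal(nrow(st$srm), 1)
  expect_equal(st$srm$srm,
               st$srm$colocated - st$srm$separated)
  # separation helps, so SRM should be clearly positive for this listener
  expect_gt(st$srm$srm, 2)
})

test_that("studies are reproducible and honour the protocol ordering", {
  pop <- generate_population(population_spec(4, seed = 5))
  conds <- standard_conditions()
  a <- run_study(pop, conds, seed = 99)
  b <- run_study(pop, conds, seed = 99)
  expect_identical(a, b)

  # 4 listeners x 2 backgrounds x 4 conditions
  expect_equal(nrow(a$conditions), 32)
  expect_equal(nrow(a$tracks), 96)

  # every adaptive-angle condition sits exactly target_srm below that
  # listener's own co-located average in the same background
  cond <- a$conditions
  for (i in which(cond$masker_mode == "adaptive_angle")) {
    r <- cond[i, ]
    co <- cond$threshold[cond$listener == r$listener &
                           cond$background == r$background &
                           cond$masker_mode == "colocated"]
    expect_equal(r$fixed_value, co - r$target_srm)
  }
})

test_that("adaptive-angle without a co-located anchor is a protocol error", {
  l <- listener_params()
  conds <- list(condition_spec("quiet", "adaptive_angle", target_srm = 6))
  expect_error(run_study(list(l), conds, seed = 1), "colocated")
})

test_that("a 9 dB target needs more separation than 6 dB when release allows", {
  # noise-free margins: srm_max comfortably above 9 dB, steep slope
  l <- clean_listener(T0 = -2, sigma = 2, srm_max = 14, theta0 = 20)
  conds <- list(condition_spec("quiet", "colocated"),
                condition_spec("quiet", "adaptive_angle", target_srm = 6),
                condition_spec("quiet", "adaptive_angle", target_srm = 9))
  st <- run_study(list(l), conds, seed = 31)
  th6 <- st$conditions$threshold[st$conditions$condition ==
                                   "adaptive_6dB_quiet"]
  th9 <- st$conditions$threshold[st$conditions$condition ==
                                   "adaptive_9dB_quiet"]
  expect_gt(th9, th6)
  expect_true(all(st$conditions$srm_attainable))
})

test_that("targets beyond the listener's release are flagged unattainable", {
  l <- clean_listener(T0 = -2, sigma = 3, srm_max = 5, theta0 = 15)
  set.seed(17)
  res <- run_condition(l, condition_spec("quiet", "adaptive_angle",
                                         target_srm = 9),
                       colocated_threshold = -0.5)
  expect_false(res$srm_attainable)
})

test_that("angle-track recovery matches the listener-model inversion", {
  # study-level parameter recovery: recovered angle threshold close to the
  # analytic theta* implied by the co-located estimate actually used
  l <- clean_listener(T0 = -2, sigma = 2, srm_max = 10, theta0 = 15)
  conds <- list(condition_spec("quiet", "colocated", n_tracks = 3),
                condition_spec("quiet", "adaptive_angle", target_srm = 6,
                               n_tracks = 3))
  set.seed(23)
  reps <- replicate(60, {
    st <- run_study(list(l), conds)
    cond <- st$conditions
    co <- cond$threshold[cond$masker_mode == "colocated"]
    ad <- cond$threshold[cond$masker_mode == "adaptive_angle"]
    c(recovered = ad,
      analytic = closed_form_theta_star(l, co - 6))
  })
  expect_lt(abs(mean(reps["recovered", ] - reps["analytic", ])), 3)
})
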