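test_that("configuration invariants are enforced", {
  expect_error(staircase_config(45, initial_step = -5, reduced_step = 2,
                                floor = 0, ceiling = 90),
               "initial_step")
  expect_error(staircase_config(45, initial_step = 1, reduced_step = 2,
                                floor = 0, ceiling = 90),
               "exceed")
  expect_error(staircase_config(45, 5, 2, floor = 90, ceiling = 0),
               "floor")
  expect_error(staircase_config(95, 5, 2, floor = 0, ceiling = 90),
               "initial_value")
  expect_error(staircase_config(45, 5, 2, threshold_reversals = 13,
                                floor = 0, ceiling = 90),
               "threshold_reversals")
})

test_that("init_track starts at the configured point with empty logs", {
  angle <- angle_track_config()
  st <- init_track(angle)
  expect_equal(st$current_value, 45)
  expect_equal(st$current_step, 5)
  expect_equal(st$consecutive_correct, 0L)
  expect_identical(st$last_move, "none")
  expect_length(st$reversal_values, 0)
  expect_false(st$complete)

  tmr <- tmr_track_config()
  st2 <- init_track(tmr)
  expect_equal(st2$current_value, 12)
  expect_equal(st2$current_step, 2)
})

test_that("2-down/1-up moves follow the transformed up-down rules", {
  cfg <- angle_track_config()
  st <- init_track(cfg)
  # first correct arms the counter, no move
  st <- update_track(st, cfg, TRUE)
  expect_equal(st$current_value, 45)
  expect_equal(st$consecutive_correct, 1L)
  # second consecutive correct narrows the maskers by one step
  st <- update_track(st, cfg, TRUE)
  expect_equal(st$current_value, 40)
  expect_equal(st$consecutive_correct, 0L)
  expect_identical(st$last_move, "harder")
  # an incorrect broadens immediately, whatever the counter
  st <- update_track(st, cfg, TRUE)
  st <- update_track(st, cfg, FALSE)
  expect_equal(st$current_value, 45)
  expect_equal(st$consecutive_correct, 0L)
  expect_identical(st$last_move, "easier")
  # that direction change is the first reversal, at the pre-move extremum
  expect_equal(st$reversal_values, 40)
})

test_that("step is reduced after the configured reversal count", {
  cfg <- angle_track_config()
  # alternate double-correct / incorrect to force a reversal on every move
  st <- init_track(cfg)
  resp <- rep(c(TRUE, TRUE, FALSE), 10)
  for (r in resp) {
    if (st$complete) break
    st <- update_track(st, cfg, r)
  }
  log <- track_log(st)
  moves <- log[log$move != "none", ]
  n_rev_before <- cumsum(moves$reversal) - moves$reversal
  # moves up to and including the 3rd reversal use 5 deg, later ones 2 deg
  expect_true(all(moves$step[n_rev_before < 3] == 5))
  expect_true(all(moves$step[n_rev_before >= 3] == 2))
})

test_that("values clamp at the floor and clamped flips still reverse", {
  cfg <- staircase_config(1, 2, 1, floor = 0, ceiling = 90,
                          reversals_before_reduction = 50)
  st <- init_track(cfg)
  st <- update_track(st, cfg, TRUE)
  st <- update_track(st, cfg, TRUE)       # 1 - 2 clamps to 0
  expect_equal(st$current_value, 0)
  st <- update_track(st, cfg, TRUE)
  st <- update_track(st, cfg, TRUE)       # still 0, move direction harder
  expect_equal(st$current_value, 0)
  st <- update_track(st, cfg, FALSE)      # easier: direction change at 0
  expect_equal(st$current_value, 2)
  expect_equal(st$reversal_values, 0)
})

test_that("threshold is the mean of the last threshold_reversals reversals", {
  revs <- c(30, 34, 30, 32, 28, 30, 26, 28, 24, 26, 22, 24)
  # hand-sum oracle over the listed last 9 values
  expect_equal(mean(revs[4:12]), 26.66667, tolerance = 1e-6)
  st <- structure(list(reversal_values = revs, complete = TRUE),
                  class = "track_state")
  cfg <- angle_track_config()
  expect_equal(track_threshold(st, cfg), mean(revs[4:12]))

  st$reversal_values <- rep(20, 12)
  expect_equal(track_threshold(st, cfg), 20)

  st_inc <- structure(list(reversal_values = revs[1:11], complete = FALSE),
                      class = "track_state")
  expect_error(track_threshold(st_inc, cfg), "not complete")
  expect_error(update_track(st, cfg, TRUE), "complete")
})

test_that("constant responders drive the track monotonically to a bound", {
  cfg <- angle_track_config()
  st <- init_track(cfg)
  vals <- numeric(0)
  for (i in 1:80) {
    st <- update_track(st, cfg, TRUE)
    vals <- c(vals, st$current_value)
  }
  expect_true(all(diff(vals) <= 0))
  expect_equal(st$current_value, cfg$floor)
  expect_length(st$reversal_values, 0)
  expect_false(st$complete)

  st <- init_track(cfg)
  vals <- numeric(0)
  for (i in 1:40) {
    st <- update_track(st, cfg, FALSE)
    vals <- c(vals, st$current_value)
  }
  expect_true(all(diff(vals) >= 0))
  expect_equal(st$current_value, cfg$ceiling)
  expect_length(st$reversal_values, 0)
  expect_false(st$complete)
})

test_that("engine matches the independent replay oracle on random sequences", {
  cfg_angle <- angle_track_config()
  cfg_tmr <- tmr_track_config()
  set.seed(414)
  for (i in 1:1000) {
    cfg <- if (i %% 2 == 0) cfg_angle else cfg_tmr
    p <- runif(1, 0.4, 0.8)
    resp <- runif(300) < p
    st <- feed_responses(cfg, resp)
    ref <- replay_staircase(resp, cfg)
    expect_equal(st$reversal_values, ref$reversal_values)
    expect_equal(isTRUE(st$complete), ref$complete)
    if (ref$complete) {
      expect_equal(track_threshold(st, cfg), ref$threshold)
    }
  }
})

test_that("completed tracks hold exactly total_reversals reversals", {
  cfg <- tmr_track_config()
  set.seed(99)
  for (i in 1:50) {
    resp <- runif(300) < 0.65
    st <- feed_responses(cfg, resp)
    if (st$complete) {
      expect_length(st$reversal_values, cfg$total_reversals)
    }
  }
})

test_that("track logs export one tidy row per response", {
  cfg <- angle_track_config()
  st <- feed_responses(cfg, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  log <- track_log(st)
  expect_equal(nrow(log), 5)
  expect_named(log, c("index", "value", "response", "move", "step",
                      "reversal"))
  expect_equal(log$value[1:3], c(45, 45, 40))
  expect_equal(log$move, c("none", "harder", "easier", "none", "harder"))
})
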