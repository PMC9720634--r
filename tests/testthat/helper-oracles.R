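# Independent reference implementations used as oracles. These replay the
# published rules with their own bookkeeping, kept deliberately separate
# from the package's engine.

# Replay a 2-down/1-up track from a logical response sequence: derive the
# move for each response, then the level series, then reversal values as
# the pre-move level wherever the move direction flips.
replay_staircase <- function(responses, config) {
  harder <- if (config$harder_direction == "decrease") -1 else 1
  value <- config$initial_value
  step <- config$initial_step
  streak <- 0L
  dirs <- integer(0)       # -1 easier, +1 harder, per move
  pre_values <- numeric(0) # level before each move
  for (r in responses) {
    d <- 0L
    if (r) {
      streak <- streak + 1L
      if (streak == 2L) { d <- 1L; streak <- 0L }
    } else {
      d <- -1L
      streak <- 0L
    }
    if (d != 0L) {
      dirs <- c(dirs, d)
      pre_values <- c(pre_values, value)
      value <- value + (if (d == 1L) harder else -harder) * step
      value <- min(max(value, config$floor), config$ceiling)
      n_rev <- sum(diff(dirs) != 0)
      if (n_rev >= config$reversals_before_reduction) {
        step <- config$reduced_step
      }
      if (n_rev >= config$total_reversals) break
    }
  }
  flips <- which(diff(dirs) != 0) + 1L
  revs <- pre_values[flips]
  list(reversal_values = revs,
       complete = length(revs) >= config$total_reversals,
       threshold = if (length(revs) >= config$total_reversals) {
         mean(tail(revs[seq_len(config$total_reversals)],
                   config$threshold_reversals))
       } else NA_real_)
}

# Drive an engine track with a fixed response sequence; returns the state.
feed_responses <- function(config, responses, stop_when_complete = TRUE) {
  st <- init_track(config)
  for (r in responses) {
    if (stop_when_complete && st$complete) break
    st <- update_track(st, config, r)
  }
  st
}

# Closed-form separation threshold for the saturating-exponential midpoint
# and probit kernel: solve threshold_tmr_at(theta) = fixed_tmr for theta.
closed_form_theta_star <- function(params, fixed_tmr, p_target = sqrt(0.5),
                                   babble = FALSE) {
  b <- as.numeric(isTRUE(babble))
  T0 <- params$T0 + b * params$babble_shift
  srm <- params$srm_max + b * params$babble_srm_shift
  k <- params$sigma *
    qnorm((p_target - params$gamma) / (1 - params$gamma - params$lam))
  need <- T0 + k - fixed_tmr      # release required at theta*
  if (need <= 0) return(0)
  if (need >= srm) return(NA_real_)
  -params$theta0 * log(1 - need / srm)
}

# A "clean" listener: responds from the psychometric surface only.
clean_listener <- function(...) {
  listener_params(lam = 0, miss_rate = 0, errant_rate = 0, ...)
}
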