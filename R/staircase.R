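#' Configure a transformed up-down (2-down/1-up) staircase
#'
#' Builds the rule set for a single adaptive track. The same engine serves
#' both tracked variables used in the SRM paradigm: target-to-masker ratio
#' (dB) with the maskers fixed in space, and masker azimuth (degrees) with
#' the TMR fixed. "Harder" means lower TMR or smaller separation, so both
#' standard conditions use `harder_direction = "decrease"`.
#'
#' Two consecutive correct responses move the track one step in the harder
#' direction; any incorrect response moves it one step easier immediately.
#' The step size is reduced once `reversals_before_reduction` reversals have
#' been recorded, the track completes at `total_reversals` reversals, and
#' the threshold is the mean of the last `threshold_reversals` reversal
#' values.
#'
#' @param initial_value Starting value of the tracked variable (dB TMR or
#'   degrees of separation).
#' @param initial_step Step size used until the reversal count reaches
#'   `reversals_before_reduction`. Must exceed `reduced_step`.
#' @param reduced_step Step size used thereafter. Must be positive.
#' @param reversals_before_reduction Number of reversals after which the
#'   step is reduced (default 3).
#' @param total_reversals Number of reversals that ends the track
#'   (default 12).
#' @param threshold_reversals Number of final reversals averaged into the
#'   threshold (default 9).
#' @param harder_direction `"decrease"` if smaller tracked values are harder
#'   (the case for both TMR and separation tracking), `"increase"` otherwise.
#' @param floor,ceiling Hard bounds on the tracked value; moves are clamped.
#' @param max_responses Guard against non-converging tracks: a run is
#'   aborted with a diagnostic after this many responses without reaching
#'   `total_reversals` (default 300).
#'
#' @return An object of class `staircase_config`.
#' @seealso [tmr_track_config()], [angle_track_config()] for the two
#'   standard parameterizations; [init_track()], [update_track()],
#'   [track_threshold()].
#' @export
#' @examples
#' cfg <- angle_track_config()
#' st <- init_track(cfg)
#' st <- update_track(st, cfg, correct = TRUE)
#' st <- update_track(st, cfg, correct = TRUE)  # two correct -> 5 deg harder
#' st$current_value
staircase_config <- function(initial_value,
                             initial_step,
                             reduced_step,
                             reversals_before_reduction = 3L,
                             total_reversals = 12L,
                             threshold_reversals = 9L,
                             harder_direction = c("decrease", "increase"),
                             floor = -Inf,
                             ceiling = Inf,
                             max_responses = 300L) {
  harder_direction <- match.arg(harder_direction)
  cfg <- list(
    initial_value = as.numeric(initial_value),
    initial_step = as.numeric(initial_step),
    reduced_step = as.numeric(reduced_step),
    reversals_before_reduction = as.integer(reversals_before_reduction),
    total_reversals = as.integer(total_reversals),
    threshold_reversals = as.integer(threshold_reversals),
    harder_direction = harder_direction,
    floor = as.numeric(floor),
    ceiling = as.numeric(ceiling),
    max_responses = as.integer(max_responses)
  )
  validate_staircase_config(cfg)
  class(cfg) <- "staircase_config"
  cfg
}

validate_staircase_config <- function(cfg) {
  stopifnot_config(is.finite(cfg$initial_step) && cfg$initial_step > 0,
                   "initial_step must be positive")
  stopifnot_config(is.finite(cfg$reduced_step) && cfg$reduced_step > 0,
                   "reduced_step must be positive")
  stopifnot_config(cfg$initial_step > cfg$reduced_step,
                   "initial_step must exceed reduced_step")
  stopifnot_config(cfg$threshold_reversals >= 1L &&
                     cfg$threshold_reversals <= cfg$total_reversals,
                   "threshold_reversals must lie in [1, total_reversals]")
  stopifnot_config(cfg$reversals_before_reduction >= 0L,
                   "reversals_before_reduction must be non-negative")
  stopifnot_config(cfg$floor < cfg$ceiling, "floor must be below ceiling")
  stopifnot_config(cfg$initial_value >= cfg$floor &&
                     cfg$initial_value <= cfg$ceiling,
                   "initial_value must lie within [floor, ceiling]")
  stopifnot_config(cfg$max_responses >= 1L, "max_responses must be >= 1")
  invisible(cfg)
}

stopifnot_config <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid staircase configuration: ", msg, call. = FALSE)
}

#' Standard TMR-tracking staircase configuration
#'
#' The fixed masker-location rules: start at +12 dB TMR, 2-dB steps reduced
#' to 1 dB after 3 reversals, 12 reversals total with the last 9 averaged.
#' Bounds default to a generous +/-30 dB, wide enough that ordinary tracks
#' never touch them.
#'
#' @param ... Overrides passed on to [staircase_config()].
#' @return A `staircase_config`.
#' @export
tmr_track_config <- function(...) {
  defaults <- list(initial_value = 12, initial_step = 2, reduced_step = 1,
                   floor = -30, ceiling = 30)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(staircase_config, defaults)
}

#' Standard angle-tracking staircase configuration
#'
#' The adaptive masker-location rules: start at 45 degrees separation,
#' 5-degree steps reduced to 2 degrees after 3 reversals, 12 reversals with
#' the last 9 averaged. Separation is bounded to [0, 90] degrees, the range
#' the loudspeaker layout supports for symmetric maskers.
#'
#' @param ... Overrides passed on to [staircase_config()].
#' @return A `staircase_config`.
#' @export
angle_track_config <- function(...) {
  defaults <- list(initial_value = 45, initial_step = 5, reduced_step = 2,
                   floor = 0, ceiling = 90)
  override <- list(...)
  defaults[names(override)] <- override
  do.call(staircase_config, defaults)
}

#' Initialize a staircase track
#'
#' @param config A [staircase_config()].
#' @return A `track_state` at the configured starting value with empty logs.
#' @export
init_track <- function(config) {
  if (!inherits(config, "staircase_config")) {
    config <- do.call(staircase_config, as.list(config))
  }
  validate_staircase_config(config)
  state <- list(
    current_value = config$initial_value,
    consecutive_correct = 0L,
    current_step = config$initial_step,
    last_move = "none",
    reversal_values = numeric(0),
    n_responses = 0L,
    log_value = numeric(0),
    log_response = logical(0),
    log_move = character(0),
    log_step = numeric(0),
    log_reversal = logical(0),
    complete = FALSE
  )
  class(state) <- "track_state"
  state
}

#' Feed one response to a staircase track
#'
#' Applies the 2-down/1-up bookkeeping: an incorrect response moves one step
#' easier immediately and resets the consecutive-correct counter; a first
#' correct response only arms the counter; a second consecutive correct moves
#' one step harder and resets it. The counter also resets after every level
#' change. A reversal is recorded whenever the direction of a move differs
#' from the previous move's direction; the value recorded is the tracked
#' value at which the direction change occurs (the extremum), i.e. the value
#' before the new move is applied. The first move of a track never counts as
#' a reversal since no prior direction exists.
#'
#' Moves are clamped to `[floor, ceiling]`; a clamped move that changed
#' direction still counts as a reversal, which keeps tracks terminating when
#' they ride a bound. Once the reversal count reaches
#' `reversals_before_reduction` the step used by all subsequent moves is
#' `reduced_step` (the move coinciding with that reversal itself still uses
#' the initial step). The track is complete when `total_reversals` reversals
#' have been recorded.
#'
#' @param state A `track_state` from [init_track()] or a previous update.
#' @param config The same [staircase_config()] the track was created with.
#' @param correct Logical: was the response correct?
#' @return The updated `track_state`.
#' @export
update_track <- function(state, config, correct) {
  if (isTRUE(state$complete)) {
    stop("cannot update a complete track", call. = FALSE)
  }
  correct <- isTRUE(correct)
  presented_value <- state$current_value

  move <- "none"
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      move <- "harder"
      state$consecutive_correct <- 0L
    }
  } else {
    move <- "easier"
    state$consecutive_correct <- 0L
  }

  reversal <- FALSE
  step_used <- NA_real_
  if (move != "none") {
    if (state$last_move != "none" && move != state$last_move) {
      reversal <- TRUE
      state$reversal_values <- c(state$reversal_values, state$current_value)
    }
    step_used <- state$current_step
    sgn <- if (config$harder_direction == "decrease") -1 else 1
    delta <- if (move == "harder") sgn * step_used else -sgn * step_used
    state$current_value <- min(max(state$current_value + delta, config$floor),
                               config$ceiling)
    state$last_move <- move
    if (length(state$reversal_values) >= config$reversals_before_reduction) {
      state$current_step <- config$reduced_step
    }
    if (length(state$reversal_values) >= config$total_reversals) {
      state$complete <- TRUE
    }
  }

  state$n_responses <- state$n_responses + 1L
  state$log_value <- c(state$log_value, presented_value)
  state$log_response <- c(state$log_response, correct)
  state$log_move <- c(state$log_move, move)
  state$log_step <- c(state$log_step, step_used)
  state$log_reversal <- c(state$log_reversal, reversal)
  state
}

#' Threshold estimate from a completed track
#'
#' The arithmetic mean of the final `threshold_reversals` reversal values
#' (by default the last 9 of 12).
#'
#' @param state A complete `track_state`.
#' @param config The track's [staircase_config()].
#' @return Threshold in the tracked units (dB TMR or degrees).
#' @export
track_threshold <- function(state, config) {
  if (!isTRUE(state$complete)) {
    stop("track is not complete: ", length(state$reversal_values), " of ",
         config$total_reversals, " reversals recorded", call. = FALSE)
  }
  k <- config$threshold_reversals
  mean(utils::tail(state$reversal_values, k))
}

#' Tidy per-response log of a staircase track
#'
#' @param state A `track_state`.
#' @return A data frame with one row per response: `index`, `value` (the
#'   tracked value at which the response was collected), `response`
#'   (logical), `move` (`"harder"`, `"easier"` or `"none"`), `step` (step
#'   size of the move, `NA` when no move occurred) and `reversal`.
#' @export
track_log <- function(state) {
  data.frame(
    index = seq_len(state$n_responses),
    value = state$log_value,
    response = state$log_response,
    move = state$log_move,
    step = state$log_step,
    reversal = state$log_reversal,
    stringsAsFactors = FALSE
  )
}

#' @export
print.staircase_config <- function(x, ...) {
  cat("2-down/1-up staircase configuration\n")
  cat(sprintf("  start %g, step %g -> %g after %d reversals\n",
              x$initial_value, x$initial_step, x$reduced_step,
              x$reversals_before_reduction))
  cat(sprintf("  stop at %d reversals, threshold = mean of last %d\n",
              x$total_reversals, x$threshold_reversals))
  cat(sprintf("  harder = %s, bounds [%g, %g], abort after %d responses\n",
              x$harder_direction, x$floor, x$ceiling, x$max_responses))
  invisible(x)
}

#' @export
print.track_state <- function(x, ...) {
  cat(sprintf("staircase track: value %g, %d responses, %d reversals%s\n",
              x$current_value, x$n_responses, length(x$reversal_values),
              if (x$complete) " (complete)" else ""))
  invisible(x)
}
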