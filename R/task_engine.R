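#' Build a continuous three-stream word/digit timeline
#'
#' Lays out word slots for one target and two masker streams at the word
#' period (2 words/s by default, each word followed by a 100-ms inter-word
#' interval). In the target stream, roughly every `digit_period_slots`-th
#' slot carries a digit drawn uniformly from \{1..10\} without 7; the gap
#' between successive digits is jittered uniformly by up to `jitter_slots`
#' slots, so with the defaults digits arrive every 2.5-3.5 s with mean
#' spacing 3.0 s. Masker slots never carry digits.
#'
#' @param duration Stream duration in seconds; must cover at least one digit
#'   period.
#' @param word_period Slot length in seconds (default 0.5 = 2 words/s).
#' @param inter_word_interval Silent tail inside each slot, seconds
#'   (default 0.1).
#' @param digit_period_slots Nominal slots between digits (default 6, i.e.
#'   3 s).
#' @param jitter_slots Maximum uniform jitter of each digit gap, in slots
#'   (default 1; 0 disables jitter).
#' @param seed Optional RNG seed for reproducible timelines.
#' @return A `stream_timeline`: list with an `events` data frame (`onset`,
#'   `slot`, `stream`, `kind`, `digit`, `talker`, `token`) plus the timing
#'   parameters.
#' @export
#' @examples
#' tl <- build_timeline(12, jitter_slots = 0, seed = 1)
#' subset(tl$events, kind == "digit")
build_timeline <- function(duration, word_period = 0.5,
                           inter_word_interval = 0.1,
                           digit_period_slots = 6L, jitter_slots = 1L,
                           seed = NULL) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (duration < digit_period_slots * word_period) {
    stop("duration shorter than one digit period", call. = FALSE)
  }
  if (jitter_slots >= digit_period_slots) {
    stop("jitter_slots must be smaller than digit_period_slots",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_slots <- floor(duration / word_period + 1e-9)
  digit_slots <- digit_slot_sequence(n_slots, digit_period_slots,
                                     jitter_slots)
  streams <- c("target", "masker1", "masker2")
  talkers <- c(target = "m1", masker1 = "f1", masker2 = "f2")
  events <- do.call(rbind, lapply(streams, function(s) {
    slot <- seq_len(n_slots) - 1L
    kind <- rep("word", n_slots)
    digit <- rep(NA_integer_, n_slots)
    if (s == "target" && length(digit_slots)) {
      kind[digit_slots + 1L] <- "digit"
      digit[digit_slots + 1L] <- sample_digits(length(digit_slots))
    }
    data.frame(onset = slot * word_period, slot = slot, stream = s,
               kind = kind, digit = digit, talker = talkers[[s]],
               token = sample.int(2500L, n_slots, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  events <- events[order(events$onset, events$stream), ]
  rownames(events) <- NULL
  structure(list(events = events, word_period = word_period,
                 inter_word_interval = inter_word_interval,
                 digit_period_slots = as.integer(digit_period_slots),
                 jitter_slots = as.integer(jitter_slots),
                 duration = n_slots * word_period),
            class = "stream_timeline")
}

# 0-based slot indices carrying digits: successive gaps are uniform on
# digit_period_slots +/- jitter_slots; the first digit falls one slot
# before the end of its (jittered) period, so with no jitter and period 6
# the digit slots are 5, 11, 17, ...
digit_slot_sequence <- function(n_slots, period, jitter) {
  gaps_max <- ceiling(n_slots / max(period - jitter, 1L)) + 2L
  gaps <- if (jitter > 0) {
    sample(seq.int(period - jitter, period + jitter), gaps_max,
           replace = TRUE)
  } else rep(period, gaps_max)
  slots <- cumsum(gaps) - 1L
  slots[slots < n_slots]
}

# digits 1-10 excluding 7 (nine alternatives)
allowed_digits <- function() c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 9L, 10L)

sample_digits <- function(n) {
  allowed_digits()[sample.int(9L, n, replace = TRUE)]
}

#' Score a listener's behaviour in one digit window
#'
#' Applies the response-window rule: a correct identification counts only
#' if it lands within `window` seconds of the digit onset; misses, errant
#' presses, wrong digits and late responses are all incorrect outcomes, and
#' all of them are fed to the staircase as "incorrect" (the procedure does
#' not distinguish among failure modes when updating).
#'
#' @param event A single digit row from a timeline's `events` (or any list
#'   with `kind == "digit"`).
#' @param behavior A behavioural event from [sample_behavior()].
#' @param latency Response latency in seconds (`NA` for misses).
#' @param window Response window in seconds (default 2).
#' @return A list with `outcome` (one of `"correct"`, `"incorrect_wrong"`,
#'   `"incorrect_miss"`, `"incorrect_errant"`), `correct` (logical fed to
#'   the staircase) and `latency`.
#' @export
score_digit <- function(event, behavior, latency = NA_real_, window = 2) {
  if (is.null(event$kind) || !identical(event$kind, "digit")) {
    stop("score_digit() applies only to digit events", call. = FALSE)
  }
  outcome <- switch(behavior,
    correct = if (!is.na(latency) && latency <= window) "correct"
              else "incorrect_miss",
    wrong_digit = "incorrect_wrong",
    miss = "incorrect_miss",
    errant = "incorrect_errant",
    stop("unknown behaviour event: ", behavior, call. = FALSE)
  )
  list(outcome = outcome, correct = outcome == "correct",
       latency = if (outcome %in% c("correct", "incorrect_wrong"))
         latency else NA_real_)
}

#' Run one adaptive track on a virtual listener
#'
#' Couples the continuous-stream digit schedule, the listener model and the
#' staircase: digits are presented at jittered ~3-s intervals, the listener's
#' behaviour is sampled at the track's current operating point, scored
#' against the 2-s response window, and the outcome drives the 2-down/1-up
#' update. In `"track_tmr"` mode the staircase variable is TMR at a fixed
#' masker separation; in `"track_angle"` mode it is the separation at a
#' fixed TMR. Staircase updates are applied at the close of each response
#' window, so every digit is presented at the value in force at its onset.
#'
#' Simulated response latencies are uniform on [0.3, 1.5] s for responded
#' windows, comfortably inside the 2-s window; latency matters only
#' relative to the window.
#'
#' @param listener A [listener_params()].
#' @param config A [staircase_config()]; see [tmr_track_config()] and
#'   [angle_track_config()] for the standard settings.
#' @param mode `"track_tmr"` or `"track_angle"`.
#' @param fixed_other The non-tracked coordinate: masker separation in
#'   degrees for `"track_tmr"`, TMR in dB for `"track_angle"`.
#' @param babble Logical: background babble present?
#' @param seed Optional RNG seed; when `NULL` the current stream is used
#'   (callers running many tracks seed once upstream).
#' @param digit_period_slots,jitter_slots,word_period Digit schedule
#'   parameters, as in [build_timeline()].
#' @param window Response window in seconds.
#' @return A `track_result`: list with the final `state`, the `config`,
#'   `mode`, `fixed_other`, `babble`, a tidy `responses` data frame (one
#'   row per digit: `trial`, `onset`, `tmr`, `theta`, `behavior`,
#'   `outcome`, `correct`, `latency`), `duration` (onset of the last scored
#'   digit plus one word period), `completed`, `aborted`, `n_responses`,
#'   and `threshold` (`NA` if aborted).
#' @export
run_track <- function(listener, config, mode = c("track_tmr", "track_angle"),
                      fixed_other, babble = FALSE, seed = NULL,
                      digit_period_slots = 6L, jitter_slots = 1L,
                      word_period = 0.5, window = 2) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  state <- init_track(config)
  max_n <- config$max_responses

  trial <- integer(max_n); onset <- numeric(max_n)
  tmr_v <- numeric(max_n); theta_v <- numeric(max_n)
  behavior <- character(max_n); outcome <- character(max_n)
  correct <- logical(max_n); latency <- numeric(max_n)

  slot <- -1L
  n <- 0L
  while (!state$complete && n < max_n) {
    gap <- if (jitter_slots > 0) {
      sample(seq.int(digit_period_slots - jitter_slots,
                     digit_period_slots + jitter_slots), 1L)
    } else digit_period_slots
    slot <- slot + gap
    n <- n + 1L
    val <- state$current_value
    tmr <- if (mode == "track_tmr") val else fixed_other
    theta <- if (mode == "track_tmr") fixed_other else val
    beh <- sample_behavior(listener, tmr, theta, babble)
    lat <- if (beh %in% c("correct", "wrong_digit", "errant")) {
      stats::runif(1, 0.3, 1.5)
    } else NA_real_
    sc <- score_digit(list(kind = "digit"), beh, lat, window)
    state <- update_track(state, config, sc$correct)

    trial[n] <- n; onset[n] <- slot * word_period
    tmr_v[n] <- tmr; theta_v[n] <- theta
    behavior[n] <- beh; outcome[n] <- sc$outcome
    correct[n] <- sc$correct; latency[n] <- sc$latency
  }

  idx <- seq_len(n)
  responses <- data.frame(trial = trial[idx], onset = onset[idx],
                          tmr = tmr_v[idx], theta = theta_v[idx],
                          behavior = behavior[idx], outcome = outcome[idx],
                          correct = correct[idx], latency = latency[idx],
                          stringsAsFactors = FALSE)
  completed <- isTRUE(state$complete)
  res <- list(state = state, config = config, mode = mode,
              fixed_other = fixed_other, babble = babble,
              responses = responses,
              duration = if (n > 0) onset[n] + word_period else 0,
              completed = completed, aborted = !completed,
              n_responses = n,
              threshold = if (completed) track_threshold(state, config)
                          else NA_real_)
  class(res) <- "track_result"
  res
}

#' @export
print.track_result <- function(x, ...) {
  units <- if (x$mode == "track_tmr") "dB TMR" else "deg"
  cat(sprintf("adaptive track (%s): %d digits, %.1f s stream time\n",
              x$mode, x$n_responses, x$duration))
  if (x$completed) {
    cat(sprintf("  threshold %.3f %s (mean of last %d reversals)\n",
                x$threshold, units, x$config$threshold_reversals))
  } else {
    cat(sprintf("  ABORTED after %d responses with %d of %d reversals\n",
                x$n_responses, length(x$state$reversal_values),
                x$config$total_reversals))
  }
  invisible(x)
}

#' Event table of a timeline
#'
#' @param timeline A `stream_timeline`.
#' @return Its tidy `events` data frame.
#' @export
timeline_events <- function(timeline) {
  stopifnot(inherits(timeline, "stream_timeline"))
  timeline$events
}
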