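#' Group summary of a simulated study
#'
#' Per background and condition: mean, sample SD, minimum and maximum of
#' the listeners' averaged thresholds, plus the same descriptives for the
#' derived SRM of the fixed-separation conditions. With a single listener
#' the SD is reported as `NA` (undefined).
#'
#' @param result An `srm_study` from [run_study()].
#' @return A data frame with columns `background`, `condition`, `measure`
#'   (`"threshold"` or `"srm"`), `units`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_study <- function(result) {
  stopifnot(inherits(result, "srm_study"))
  cond <- result$conditions
  if (is.null(cond) || nrow(cond) == 0) {
    stop("empty study result", call. = FALSE)
  }
  descr <- function(x) {
    c(n = length(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      min = min(x), max = max(x))
  }
  rows <- list()
  for (key in unique(cond$condition)) {
    sub <- cond[cond$condition == key, ]
    d <- descr(sub$threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      background = sub$background[1], condition = key,
      measure = "threshold",
      units = if (sub$masker_mode[1] == "adaptive_angle") "deg" else "dB",
      n = d[["n"]], mean = d[["mean"]], sd = d[["sd"]],
      min = d[["min"]], max = d[["max"]], stringsAsFactors = FALSE)
  }
  if (!is.null(result$srm)) {
    for (bg in unique(result$srm$background)) {
      d <- descr(result$srm$srm[result$srm$background == bg])
      rows[[length(rows) + 1L]] <- data.frame(
        background = bg, condition = paste0("fixed_srm_", bg),
        measure = "srm", units = "dB",
        n = d[["n"]], mean = d[["mean"]], sd = d[["sd"]],
        min = d[["min"]], max = d[["max"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Separation at which a fixed TMR meets criterion performance
#'
#' The angle-domain ground truth for the adaptive-angle procedure: the
#' separation `theta*` at which the listener's criterion-level TMR
#' ([threshold_tmr_at()]) equals the track's fixed TMR. Solved by bisection
#' on [0, `theta_max`] to `tol` degrees, which keeps the solver valid for
#' any monotone midpoint curve or kernel. Returns 0 when performance is
#' already at criterion co-located, and `NA` (with a warning) when even the
#' maximal separation cannot reach criterion — the "SRM unattainable" case.
#'
#' @param params A [listener_params()].
#' @param fixed_tmr The track's fixed TMR, dB.
#' @param p_target Criterion probability (default `sqrt(0.5)`).
#' @param babble Logical: babble background?
#' @param theta_max Upper bound of the search, degrees (default 90).
#' @param tol Bisection tolerance in degrees (default 1e-6).
#' @return `theta*` in degrees, 0, or `NA`.
#' @export
solve_angle_threshold <- function(params, fixed_tmr, p_target = sqrt(0.5),
                                  babble = FALSE, theta_max = 90,
                                  tol = 1e-6) {
  f <- function(th) threshold_tmr_at(params, th, p_target, babble) - fixed_tmr
  if (f(0) <= 0) return(0)
  if (f(theta_max) > 0) {
    warning("criterion not reachable within [0, ", theta_max,
            "] degrees (targeted SRM exceeds this listener's release)")
    return(NA_real_)
  }
  lo <- 0; hi <- theta_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Monte-Carlo characterization of the adaptive procedure
#'
#' Runs `n_replicates` independent simulated tracks of one condition on one
#' listener and summarizes what the procedure actually measures: the
#' distribution of recovered thresholds against the analytic truth, the
#' mean psychometric height at the recovered thresholds (how close the
#' procedure gets to its nominal 70.7\% convergence point), the completion
#' rate, and the mean realized stream time per track.
#'
#' For TMR-tracking conditions the truth is [threshold_tmr_at()] at the
#' condition's angle; for the adaptive-angle condition the fixed TMR is set
#' `target_srm` dB below the listener's analytic co-located criterion TMR
#' and the truth is [solve_angle_threshold()].
#'
#' @param listener A [listener_params()].
#' @param condition A [condition_spec()].
#' @param n_replicates Number of independent tracks (>= 1).
#' @param seed Optional RNG seed.
#' @param p_target Criterion probability used for the analytic truth.
#' @param tmr_config,angle_config Staircase configurations.
#' @return A `characterization_report`: list with `condition`, `mode`,
#'   `units`, `n_replicates`, `completion_rate`, `mean_threshold`,
#'   `sd_threshold` (`NA` when fewer than 2 completed tracks),
#'   `true_threshold`, `bias`, `mean_p_at_threshold`, `mean_duration`,
#'   `thresholds` (per completed replicate) and `seed`.
#' @export
characterize_procedure <- function(listener, condition, n_replicates = 2000L,
                                   seed = NULL, p_target = sqrt(0.5),
                                   tmr_config = tmr_track_config(),
                                   angle_config = angle_track_config()) {
  stopifnot(inherits(condition, "condition_spec"), n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  babble <- condition$background == "babble"
  if (condition$masker_mode == "adaptive_angle") {
    mode <- "track_angle"
    config <- angle_config
    coloc <- threshold_tmr_at(listener, 0, p_target, babble)
    fixed_other <- fixed_tmr_for_srm(coloc, condition$target_srm)
    truth <- solve_angle_threshold(listener, fixed_other, p_target, babble,
                                   theta_max = config$ceiling)
  } else {
    mode <- "track_tmr"
    config <- tmr_config
    fixed_other <- if (condition$masker_mode == "colocated") 0 else
      condition$fixed_angle
    truth <- threshold_tmr_at(listener, fixed_other, p_target, babble)
  }

  thresholds <- numeric(0)
  p_at <- numeric(0)
  durations <- numeric(n_replicates)
  n_complete <- 0L
  for (r in seq_len(n_replicates)) {
    tr <- run_track(listener, config, mode, fixed_other, babble)
    durations[r] <- tr$duration
    if (tr$completed) {
      n_complete <- n_complete + 1L
      thresholds <- c(thresholds, tr$threshold)
      p_at <- c(p_at, if (mode == "track_tmr") {
        p_correct(listener, tr$threshold, fixed_other, babble)
      } else {
        p_correct(listener, fixed_other, tr$threshold, babble)
      })
    }
  }
  structure(list(
    condition = condition$label, mode = mode,
    units = if (mode == "track_tmr") "dB" else "deg",
    n_replicates = as.integer(n_replicates),
    completion_rate = n_complete / n_replicates,
    mean_threshold = if (n_complete) mean(thresholds) else NA_real_,
    sd_threshold = if (n_complete > 1) stats::sd(thresholds) else NA_real_,
    true_threshold = truth,
    bias = if (n_complete) mean(thresholds) - truth else NA_real_,
    mean_p_at_threshold = if (n_complete) mean(p_at) else NA_real_,
    mean_duration = mean(durations),
    thresholds = thresholds, seed = seed),
    class = "characterization_report")
}

#' Contrast group variability between backgrounds
#'
#' Tabulates, per matched condition, the group SD with and without babble
#' and their ratio (babble / quiet) — a descriptive tool for exploring
#' whether a background babble stabilizes thresholds across listeners. No
#' inference is performed.
#'
#' @param sd_quiet Named numeric vector of group SDs in quiet, one per
#'   condition.
#' @param sd_babble Named numeric vector of group SDs with babble, with the
#'   same names.
#' @return A data frame with `condition`, `sd_quiet`, `sd_babble`, `ratio`.
#' @export
#' @examples
#' variability_contrast(c(srm6 = 15.1, srm9 = 17.0),
#'                      c(srm6 = 10.8, srm9 = 12.9))
variability_contrast <- function(sd_quiet, sd_babble) {
  if (is.null(names(sd_quiet)) || is.null(names(sd_babble)) ||
      !setequal(names(sd_quiet), names(sd_babble)) ||
      anyDuplicated(names(sd_quiet))) {
    stop("sd_quiet and sd_babble must be named by the same condition set",
         call. = FALSE)
  }
  sd_babble <- sd_babble[names(sd_quiet)]
  data.frame(condition = names(sd_quiet),
             sd_quiet = as.numeric(sd_quiet),
             sd_babble = as.numeric(sd_babble),
             ratio = as.numeric(sd_babble) / as.numeric(sd_quiet),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("procedure characterization: %s (%d replicates)\n",
              x$condition, x$n_replicates))
  cat(sprintf("  completion rate %.3f, mean stream time %.1f s\n",
              x$completion_rate, x$mean_duration))
  cat(sprintf("  recovered threshold %.3f +/- %s %s (truth %s, bias %+.3f)\n",
              x$mean_threshold,
              if (is.na(x$sd_threshold)) "NA (undefined)" else
                sprintf("%.3f", x$sd_threshold),
              x$units,
              if (is.na(x$true_threshold)) "unattainable" else
                sprintf("%.3f", x$true_threshold),
              x$bias))
  cat(sprintf("  mean p(correct) at recovered thresholds: %.4f\n",
              x$mean_p_at_threshold))
  invisible(x)
}
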