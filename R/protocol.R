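#' Specify one experimental condition
#'
#' A condition is a background (quiet or babble) crossed with a masker
#' mode: `"colocated"` (TMR tracking with maskers at 0 degrees),
#' `"fixed_separation"` (TMR tracking with maskers fixed at
#' `fixed_angle`, 30 degrees by default), or `"adaptive_angle"` (separation
#' tracking at a TMR set `target_srm` dB below the listener's own
#' co-located threshold). Each condition is run `n_tracks` times and the
#' per-track thresholds are averaged.
#'
#' @param background `"quiet"` or `"babble"`.
#' @param masker_mode `"colocated"`, `"fixed_separation"` or
#'   `"adaptive_angle"`.
#' @param fixed_angle Masker angle for `"fixed_separation"`, degrees.
#' @param target_srm Targeted spatial release for `"adaptive_angle"`, dB
#'   (the paradigm uses 6 and 9); must be given for that mode only.
#' @param n_tracks Tracks per condition (default 3).
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(background = c("quiet", "babble"),
                           masker_mode = c("colocated", "fixed_separation",
                                           "adaptive_angle"),
                           fixed_angle = 30, target_srm = NULL,
                           n_tracks = 3L) {
  background <- match.arg(background)
  masker_mode <- match.arg(masker_mode)
  if (masker_mode == "adaptive_angle") {
    if (is.null(target_srm)) {
      stop("adaptive_angle conditions need a target_srm", call. = FALSE)
    }
  } else if (!is.null(target_srm)) {
    stop("target_srm applies only to adaptive_angle conditions",
         call. = FALSE)
  }
  structure(list(background = background, masker_mode = masker_mode,
                 fixed_angle = fixed_angle, target_srm = target_srm,
                 n_tracks = as.integer(n_tracks),
                 label = condition_label(background, masker_mode,
                                         fixed_angle, target_srm)),
            class = "condition_spec")
}

condition_label <- function(background, masker_mode, fixed_angle,
                            target_srm) {
  core <- switch(masker_mode,
                 colocated = "colocated",
                 fixed_separation = sprintf("fixed_%gdeg", fixed_angle),
                 adaptive_angle = sprintf("adaptive_%gdB", target_srm))
  paste(core, background, sep = "_")
}

#' Fixed TMR for a targeted spatial release
#'
#' The adaptive-angle conditions fix the TMR `target_srm` dB below the
#' listener's co-located threshold, so that reaching criterion performance
#' requires exactly `target_srm` dB of spatial release.
#'
#' @param colocated_threshold Co-located threshold, dB TMR.
#' @param target_srm Targeted release, dB (> 0).
#' @return The fixed TMR in dB.
#' @export
#' @examples
#' fixed_tmr_for_srm(-2.5, 9)  # -11.5
fixed_tmr_for_srm <- function(colocated_threshold, target_srm) {
  if (!is.numeric(target_srm) || target_srm <= 0) {
    stop("target_srm must be positive", call. = FALSE)
  }
  colocated_threshold - target_srm
}

#' Spatial release from masking from a pair of thresholds
#'
#' SRM is the co-located threshold minus the spatially separated threshold
#' (both in dB TMR, from the same background condition); positive values
#' mean separation helped.
#'
#' @param colocated_threshold Co-located threshold, dB TMR.
#' @param separated_threshold Separated-condition threshold, dB TMR.
#' @return SRM in dB.
#' @export
derive_srm <- function(colocated_threshold, separated_threshold) {
  colocated_threshold - separated_threshold
}

#' Run all tracks of one condition on one listener
#'
#' Runs `n_tracks` adaptive tracks: TMR tracking at the condition's fixed
#' angle (0 for co-located) for the TMR modes, or separation tracking at
#' the SRM-offset TMR for `"adaptive_angle"` (which therefore requires the
#' listener's co-located threshold from the same background). The averaged
#' threshold is the arithmetic mean of the per-track thresholds, with no
#' outlier rejection; aborted tracks contribute `NA` and are flagged.
#'
#' @param listener A [listener_params()].
#' @param spec A [condition_spec()].
#' @param colocated_threshold This listener's averaged co-located threshold
#'   in the same background (dB TMR); required for `"adaptive_angle"`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param tmr_config,angle_config Staircase configurations for the two
#'   track types; default to the standard settings.
#' @return A `condition_result`: list with the spec, per-track results,
#'   `thresholds`, `threshold` (their mean), `durations`,
#'   `mean_duration`, `n_aborted`, the operating `fixed_tmr` or angle, and
#'   `srm_attainable` (`FALSE` when the listener's effective asymptotic
#'   release is below the targeted SRM, so the angle track cannot truly
#'   converge and rides the 90-degree bound).
#' @export
run_condition <- function(listener, spec, colocated_threshold = NULL,
                          seed = NULL,
                          tmr_config = tmr_track_config(),
                          angle_config = angle_track_config()) {
  stopifnot(inherits(spec, "condition_spec"))
  if (!is.null(seed)) set.seed(seed)
  babble <- spec$background == "babble"
  if (spec$masker_mode == "adaptive_angle") {
    if (is.null(colocated_threshold) || is.na(colocated_threshold)) {
      stop("adaptive_angle condition requires the co-located threshold ",
           "(the co-located condition is always administered first)",
           call. = FALSE)
    }
    mode <- "track_angle"
    config <- angle_config
    fixed_other <- fixed_tmr_for_srm(colocated_threshold, spec$target_srm)
  } else {
    mode <- "track_tmr"
    config <- tmr_config
    fixed_other <- if (spec$masker_mode == "colocated") 0 else
      spec$fixed_angle
  }
  tracks <- lapply(seq_len(spec$n_tracks), function(i) {
    run_track(listener, config, mode, fixed_other, babble)
  })
  thresholds <- vapply(tracks, `[[`, numeric(1), "threshold")
  durations <- vapply(tracks, `[[`, numeric(1), "duration")
  eff <- effective_midpoint_params(listener, babble)
  attainable <- if (spec$masker_mode == "adaptive_angle") {
    eff$srm > spec$target_srm
  } else TRUE
  structure(list(spec = spec, tracks = tracks, thresholds = thresholds,
                 threshold = mean(thresholds),
                 durations = durations, mean_duration = mean(durations),
                 n_aborted = sum(vapply(tracks, `[[`, logical(1),
                                        "aborted")),
                 mode = mode, fixed_other = fixed_other,
                 srm_attainable = attainable),
            class = "condition_result")
}

#' The standard condition set of the paradigm
#'
#' For each requested background: co-located, fixed 30-degree separation,
#' and adaptive-angle conditions targeting 6 and 9 dB SRM, three tracks
#' each.
#'
#' @param backgrounds Character vector of backgrounds to include.
#' @param n_tracks Tracks per condition.
#' @return A list of [condition_spec()]s.
#' @export
standard_conditions <- function(backgrounds = c("quiet", "babble"),
                                n_tracks = 3L) {
  out <- list()
  for (bg in backgrounds) {
    out <- c(out, list(
      condition_spec(bg, "colocated", n_tracks = n_tracks),
      condition_spec(bg, "fixed_separation", fixed_angle = 30,
                     n_tracks = n_tracks),
      condition_spec(bg, "adaptive_angle", target_srm = 6,
                     n_tracks = n_tracks),
      condition_spec(bg, "adaptive_angle", target_srm = 9,
                     n_tracks = n_tracks)
    ))
  }
  out
}

#' Run a full simulated study over a population
#'
#' For every listener, backgrounds are taken in the order given for
#' odd-indexed listeners and reversed for even-indexed listeners
#' (counterbalancing); within a background the co-located condition always
#' runs first and its averaged threshold feeds the adaptive-angle
#' conditions of that background. Fully reproducible from `seed`.
#'
#' @param population List of [listener_params()] (e.g. from
#'   [generate_population()]).
#' @param conditions List of [condition_spec()]s; every background that
#'   appears must include a co-located condition.
#' @param seed Integer seed for the whole study.
#' @param tmr_config,angle_config Staircase configurations passed to
#'   [run_condition()].
#' @return An `srm_study` object: list with `tracks` (one row per track),
#'   `conditions` (one row per listener x condition, with the averaged
#'   threshold and diagnostics), `srm` (per listener and background, the
#'   SRM derived from the fixed 30-degree condition when present) and the
#'   `seed`.
#' @export
run_study <- function(population, conditions, seed = NULL,
                      tmr_config = tmr_track_config(),
                      angle_config = angle_track_config()) {
  if (inherits(population, "listener_params")) population <- list(population)
  stopifnot(length(population) >= 1, length(conditions) >= 1)
  backgrounds <- unique(vapply(conditions, `[[`, character(1), "background"))
  for (bg in backgrounds) {
    modes <- vapply(Filter(function(cn) cn$background == bg, conditions),
                    `[[`, character(1), "masker_mode")
    if (any(modes == "adaptive_angle") && !any(modes == "colocated")) {
      stop("background '", bg, "' has adaptive_angle conditions but no ",
           "colocated condition to anchor them", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  cond_rows <- list(); track_rows <- list()
  for (i in seq_along(population)) {
    listener <- population[[i]]
    bg_order <- if (i %% 2L == 1L) backgrounds else rev(backgrounds)
    for (bg in bg_order) {
      conds_bg <- Filter(function(cn) cn$background == bg, conditions)
      is_coloc <- vapply(conds_bg, function(cn)
        cn$masker_mode == "colocated", logical(1))
      conds_bg <- c(conds_bg[is_coloc], conds_bg[!is_coloc])
      coloc_thr <- NA_real_
      for (cn in conds_bg) {
        res <- run_condition(listener, cn,
                             colocated_threshold = coloc_thr,
                             tmr_config = tmr_config,
                             angle_config = angle_config)
        if (cn$masker_mode == "colocated") coloc_thr <- res$threshold
        cond_rows[[length(cond_rows) + 1L]] <- data.frame(
          listener = i, background = bg, condition = cn$label,
          masker_mode = cn$masker_mode,
          target_srm = if (is.null(cn$target_srm)) NA_real_ else
            cn$target_srm,
          fixed_value = res$fixed_other,
          threshold = res$threshold,
          mean_duration = res$mean_duration,
          n_aborted = res$n_aborted,
          srm_attainable = res$srm_attainable,
          stringsAsFactors = FALSE)
        track_rows[[length(track_rows) + 1L]] <- data.frame(
          listener = i, background = bg, condition = cn$label,
          masker_mode = cn$masker_mode,
          track = seq_len(cn$n_tracks),
          threshold = res$thresholds, duration = res$durations,
          n_responses = vapply(res$tracks, `[[`, integer(1),
                               "n_responses"),
          completed = vapply(res$tracks, `[[`, logical(1), "completed"),
          stringsAsFactors = FALSE)
      }
    }
  }
  cond_df <- do.call(rbind, cond_rows)
  track_df <- do.call(rbind, track_rows)
  srm_df <- derive_study_srm(cond_df)
  structure(list(tracks = track_df, conditions = cond_df, srm = srm_df,
                 seed = seed),
            class = "srm_study")
}

derive_study_srm <- function(cond_df) {
  rows <- list()
  for (i in seq_len(nrow(cond_df))) {
    r <- cond_df[i, ]
    if (r$masker_mode != "fixed_separation") next
    cl <- cond_df$listener == r$listener &
      cond_df$background == r$background &
      cond_df$masker_mode == "colocated"
    if (!any(cl)) next
    rows[[length(rows) + 1L]] <- data.frame(
      listener = r$listener, background = r$background,
      colocated = cond_df$threshold[cl][1],
      separated = r$threshold,
      srm = derive_srm(cond_df$threshold[cl][1], r$threshold),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.condition_result <- function(x, ...) {
  units <- if (x$mode == "track_tmr") "dB TMR" else "deg"
  cat(sprintf("condition %s: threshold %.3f %s (tracks: %s)\n",
              x$spec$label, x$threshold, units,
              paste(sprintf("%.2f", x$thresholds), collapse = ", ")))
  if (x$n_aborted > 0) cat("  ", x$n_aborted, "track(s) aborted\n")
  if (!x$srm_attainable) {
    cat("  NOTE: targeted SRM exceeds this listener's asymptotic release",
        "(SRM unattainable)\n")
  }
  invisible(x)
}

#' @export
print.srm_study <- function(x, ...) {
  cat(sprintf("simulated SRM study: %d listeners, %d conditions, %d tracks\n",
              length(unique(x$conditions$listener)),
              length(unique(x$conditions$condition)), nrow(x$tracks)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  cat("  mean stream time per track:",
      sprintf("%.1f s", mean(x$tracks$duration)), "\n")
  invisible(x)
}
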