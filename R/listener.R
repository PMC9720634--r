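#' Parametric virtual listener
#'
#' Defines a listener's psychometric surface for digit identification as a
#' function of target-to-masker ratio (TMR, dB) and symmetric masker
#' separation (degrees), together with response-habit rates. The surface is
#'
#' \deqn{p(tmr, \theta) = \gamma + (1 - \gamma - \lambda)\,
#'       F\!\left(\frac{tmr - m(\theta)}{\sigma}\right)}
#'
#' where `F` is the psychometric kernel (standard normal CDF by default) and
#' the midpoint follows a saturating spatial-release curve
#'
#' \deqn{m(\theta) = T_0 - srm_{max}\,(1 - e^{-\theta/\theta_0}).}
#'
#' With background babble present, `babble_shift` is added to `T0` and
#' `babble_srm_shift` to `srm_max`.
#'
#' @param T0 Co-located psychometric midpoint, dB TMR.
#' @param sigma Psychometric spread, dB (> 0). A spread of 4 dB corresponds
#'   to a slope of roughly 10 percentage points per dB near the midpoint.
#' @param gamma Guess rate; defaults to 1/9 because the response set has
#'   nine digit alternatives (1-10 without 7).
#' @param lam Lapse rate: probability of an incorrect response even at very
#'   favourable TMR.
#' @param srm_max Asymptotic spatial release, dB (>= 0).
#' @param theta0 Spatial saturation constant, degrees (> 0): the separation
#'   at which 63\% of the asymptotic release has accrued.
#' @param miss_rate Probability of failing to respond within the window,
#'   independent of audibility.
#' @param errant_rate Expected number of errant key presses per digit
#'   window; the probability that a window is spoiled by at least one errant
#'   press is `1 - exp(-errant_rate)` (Poisson arrivals).
#' @param babble_shift dB added to `T0` when babble is present.
#' @param babble_srm_shift dB added to `srm_max` when babble is present.
#' @param kernel Psychometric kernel: `"probit"` (default, standard for dB
#'   variables) or `"logistic"`.
#'
#' @return An object of class `listener_params`.
#' @export
#' @examples
#' l <- listener_params(T0 = 0, sigma = 4, lam = 0)
#' p_correct(l, tmr = 0, theta = 0)   # gamma + (1 - gamma)/2
#' threshold_tmr_at(l, theta = 30)    # 70.7%-correct TMR at 30 deg
listener_params <- function(T0 = -2, sigma = 4, gamma = 1/9, lam = 0.02,
                            srm_max = 8, theta0 = 15,
                            miss_rate = 0.02, errant_rate = 0.02,
                            babble_shift = 0, babble_srm_shift = 0,
                            kernel = c("probit", "logistic")) {
  kernel <- match.arg(kernel)
  p <- list(T0 = as.numeric(T0), sigma = as.numeric(sigma),
            gamma = as.numeric(gamma), lam = as.numeric(lam),
            srm_max = as.numeric(srm_max), theta0 = as.numeric(theta0),
            miss_rate = as.numeric(miss_rate),
            errant_rate = as.numeric(errant_rate),
            babble_shift = as.numeric(babble_shift),
            babble_srm_shift = as.numeric(babble_srm_shift),
            kernel = kernel)
  validate_listener_params(p)
  class(p) <- "listener_params"
  p
}

validate_listener_params <- function(p) {
  ok <- function(cond, msg) {
    if (!isTRUE(cond)) stop("invalid listener parameters: ", msg, call. = FALSE)
  }
  ok(p$gamma >= 0 && p$gamma < 1, "gamma must lie in [0, 1)")
  ok(p$lam >= 0 && p$lam < 1, "lam must lie in [0, 1)")
  ok(p$gamma + p$lam < 1, "gamma + lam must be below 1")
  ok(p$sigma > 0, "sigma must be positive")
  ok(p$theta0 > 0, "theta0 must be positive")
  ok(p$srm_max >= 0, "srm_max must be non-negative")
  ok(p$miss_rate >= 0 && p$miss_rate < 1, "miss_rate must lie in [0, 1)")
  ok(p$errant_rate >= 0, "errant_rate must be non-negative")
  invisible(p)
}

kernel_cdf <- function(kernel) {
  switch(kernel, probit = stats::pnorm, logistic = stats::plogis)
}

kernel_quantile <- function(kernel) {
  switch(kernel, probit = stats::qnorm, logistic = stats::qlogis)
}

effective_midpoint_params <- function(params, babble) {
  b <- as.numeric(isTRUE(babble))
  list(T0 = params$T0 + b * params$babble_shift,
       srm = params$srm_max + b * params$babble_srm_shift)
}

#' Psychometric midpoint TMR at a given masker separation
#'
#' Evaluates the listener's midpoint curve
#' `m(theta) = T0_eff - srm_eff * (1 - exp(-theta / theta0))`, the TMR at
#' which the kernel sits at its half-way point. It is monotone
#' non-increasing in separation and saturates at `T0_eff - srm_eff`.
#'
#' @param params A [listener_params()].
#' @param theta Masker separation in degrees (>= 0); vectorized.
#' @param babble Logical: is background babble present?
#' @return Midpoint TMR(s) in dB.
#' @export
midpoint_tmr <- function(params, theta, babble = FALSE) {
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  eff <- effective_midpoint_params(params, babble)
  eff$T0 - eff$srm * (1 - exp(-theta / params$theta0))
}

#' Probability of correct digit identification
#'
#' The listener's psychometric surface: guess-and-lapse-bounded kernel of
#' the TMR distance to the separation-dependent midpoint. Strictly
#' increasing in TMR and bounded in `[gamma, 1 - lam]`.
#'
#' @inheritParams midpoint_tmr
#' @param tmr Target-to-masker ratio in dB; vectorized.
#' @return Probability (or vector of probabilities) of a correct
#'   identification, ignoring misses and errant presses.
#' @export
p_correct <- function(params, tmr, theta = 0, babble = FALSE) {
  m <- midpoint_tmr(params, theta, babble)
  F <- kernel_cdf(params$kernel)
  params$gamma + (1 - params$gamma - params$lam) * F((tmr - m) / params$sigma)
}

#' TMR at which the listener reaches a target proportion correct
#'
#' Inverts the closed-form psychometric surface at a fixed separation. The
#' default target is `sqrt(1/2)` (70.7\%), the convergence point of the
#' 2-down/1-up rule.
#'
#' @inheritParams midpoint_tmr
#' @param p_target Target probability, strictly between `gamma` and
#'   `1 - lam`.
#' @return TMR in dB with `p_correct` equal to `p_target`.
#' @export
threshold_tmr_at <- function(params, theta = 0, p_target = sqrt(0.5),
                             babble = FALSE) {
  if (p_target <= params$gamma || p_target >= 1 - params$lam) {
    stop("p_target must lie strictly between gamma and 1 - lam",
         call. = FALSE)
  }
  m <- midpoint_tmr(params, theta, babble)
  Q <- kernel_quantile(params$kernel)
  m + params$sigma *
    Q((p_target - params$gamma) / (1 - params$gamma - params$lam))
}

#' Sample one behavioural event from a listener
#'
#' Draws what the listener does in a single digit window at the given
#' operating point. With probability `miss_rate` the window is a `"miss"`
#' (no response); otherwise with probability `1 - exp(-errant_rate)` an
#' errant press spoils it (`"errant"`); otherwise identification succeeds
#' with probability `p_correct` (`"correct"` vs `"wrong_digit"`).
#' Identification applies only on responded, non-errant windows. Draws come
#' from R's current RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @inheritParams p_correct
#' @param n Number of independent events to draw.
#' @return Character vector of events among `"correct"`, `"wrong_digit"`,
#'   `"miss"`, `"errant"`.
#' @export
sample_behavior <- function(params, tmr, theta = 0, babble = FALSE, n = 1L) {
  p_id <- p_correct(params, tmr, theta, babble)
  p_err <- 1 - exp(-params$errant_rate)
  out <- character(n)
  u_miss <- stats::runif(n)
  u_err <- stats::runif(n)
  u_id <- stats::runif(n)
  out[] <- ifelse(u_id < p_id, "correct", "wrong_digit")
  out[u_err < p_err] <- "errant"
  out[u_miss < params$miss_rate] <- "miss"
  out
}

#' Specify a virtual-listener population
#'
#' Describes the across-listener distribution from which
#' [generate_population()] draws: independent normals per parameter,
#' truncated to the parameter's valid range. Defaults emulate a cohort of
#' 20 young normal-hearing listeners with mid-range co-located thresholds
#' near -2 dB TMR, asymptotic release near 8 dB, and wide individual spread
#' in spatial-release capability.
#'
#' @param n_listeners Number of listeners (>= 1).
#' @param means Named list of mean values; defaults are the
#'   [listener_params()] defaults.
#' @param spreads Named list of standard deviations (>= 0) per field; fields
#'   omitted from either list keep their default.
#' @param seed Optional RNG seed stored with the spec.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_listeners = 20L, means = list(),
                            spreads = list(), seed = NULL) {
  mean_defaults <- list(T0 = -2, sigma = 4, gamma = 1/9, lam = 0.02,
                        srm_max = 8, theta0 = 15,
                        miss_rate = 0.02, errant_rate = 0.02,
                        babble_shift = 0, babble_srm_shift = 0)
  spread_defaults <- list(T0 = 2, sigma = 1, gamma = 0, lam = 0.01,
                          srm_max = 2, theta0 = 5,
                          miss_rate = 0.01, errant_rate = 0.01,
                          babble_shift = 1, babble_srm_shift = 1)
  bad <- setdiff(names(means), names(mean_defaults))
  if (length(bad)) stop("unknown listener fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(spreads), names(spread_defaults))
  if (length(bad)) stop("unknown listener fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  mean_defaults[names(means)] <- means
  spread_defaults[names(spreads)] <- spreads
  if (n_listeners < 1) stop("n_listeners must be >= 1", call. = FALSE)
  if (any(unlist(spread_defaults) < 0)) {
    stop("spreads must be non-negative", call. = FALSE)
  }
  structure(list(n_listeners = as.integer(n_listeners),
                 means = mean_defaults, spreads = spread_defaults,
                 seed = seed),
            class = "population_spec")
}

# Valid range per listener field, used for truncation when sampling.
listener_field_ranges <- list(
  T0 = c(-Inf, Inf), sigma = c(1e-6, Inf), gamma = c(0, 1 - 1e-6),
  lam = c(0, 1 - 1e-6), srm_max = c(0, Inf), theta0 = c(1e-6, Inf),
  miss_rate = c(0, 1 - 1e-6), errant_rate = c(0, Inf),
  babble_shift = c(-Inf, Inf), babble_srm_shift = c(-Inf, Inf)
)

draw_truncated <- function(n, mean, sd, range, field) {
  if (sd == 0) {
    if (mean < range[1] || mean > range[2]) {
      stop("population spec cannot satisfy the valid range of '", field,
           "' with zero spread (mean ", mean, ")", call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  for (i in 1:1000) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= range[1] & draw <= range[2]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (!length(todo)) return(out)
  }
  stop("truncated sampling for '", field,
       "' failed: the valid range has negligible mass", call. = FALSE)
}

#' Draw a population of virtual listeners
#'
#' Samples `n_listeners` parameter sets from the distributions in a
#' [population_spec()], truncating each field to its valid range and
#' re-drawing until `gamma + lam < 1`. Reproducible from the spec's seed.
#'
#' @param spec A [population_spec()].
#' @return A list of [listener_params()] objects.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_listeners
  fields <- names(spec$means)
  draws <- lapply(fields, function(f) {
    draw_truncated(n, spec$means[[f]], spec$spreads[[f]],
                   listener_field_ranges[[f]], f)
  })
  names(draws) <- fields
  # enforce the joint guess + lapse constraint
  bad <- which(draws$gamma + draws$lam >= 1)
  for (i in bad) {
    for (k in 1:1000) {
      draws$lam[i] <- draw_truncated(1, spec$means$lam, spec$spreads$lam,
                                     listener_field_ranges$lam, "lam")
      if (draws$gamma[i] + draws$lam[i] < 1) break
      if (k == 1000) stop("cannot satisfy gamma + lam < 1", call. = FALSE)
    }
  }
  lapply(seq_len(n), function(i) {
    do.call(listener_params, lapply(draws, `[`, i))
  })
}

#' @export
print.listener_params <- function(x, ...) {
  cat("virtual listener (", x$kernel, " kernel)\n", sep = "")
  cat(sprintf("  T0 %.2f dB, sigma %.2f dB, guess %.3f, lapse %.3f\n",
              x$T0, x$sigma, x$gamma, x$lam))
  cat(sprintf("  srm_max %.2f dB, theta0 %.1f deg\n", x$srm_max, x$theta0))
  cat(sprintf("  miss %.3f, errant %.3f/window, babble shifts %+.2f / %+.2f dB\n",
              x$miss_rate, x$errant_rate, x$babble_shift, x$babble_srm_shift))
  invisible(x)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("population spec: %d listeners%s\n", x$n_listeners,
              if (is.null(x$seed)) "" else sprintf(" (seed %s)", x$seed)))
  m <- unlist(x$means); s <- unlist(x$spreads)
  for (f in names(m)) cat(sprintf("  %-16s %8.3f +/- %.3f\n", f, m[f], s[f]))
  invisible(x)
}
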