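#' Horizontal loudspeaker-ring geometry
#'
#' A ring of `n_speakers` loudspeakers evenly spaced around the full circle
#' (default 24 speakers at 15-degree spacing). Azimuths follow the
#' convention 0 = front, positive = right, normalized to (-180, 180];
#' channels are ordered by ascending azimuth, so the default ring runs
#' -165, -150, ..., 180.
#'
#' @param n_speakers Number of loudspeakers; must divide 360 evenly.
#' @param radius Ring radius in meters (metadata only; default 1.04,
#'   i.e. 41 inches).
#' @return An object of class `array_geometry` with fields `n_speakers`,
#'   `spacing`, `azimuths` (ascending) and `radius`.
#' @export
array_geometry <- function(n_speakers = 24L, radius = 1.04) {
  n_speakers <- as.integer(n_speakers)
  if (n_speakers < 3L || 360 %% n_speakers != 0) {
    stop("n_speakers must divide 360 evenly (and be at least 3)",
         call. = FALSE)
  }
  spacing <- 360 / n_speakers
  az <- normalize_azimuth((seq_len(n_speakers) - 1L) * spacing)
  structure(list(n_speakers = n_speakers, spacing = spacing,
                 azimuths = sort(az), radius = radius),
            class = "array_geometry")
}

#' Normalize an azimuth to (-180, 180]
#'
#' @param azimuth Angle(s) in degrees.
#' @return Equivalent angle(s) in (-180, 180].
#' @export
normalize_azimuth <- function(azimuth) {
  r <- azimuth %% 360
  r[r > 180] <- r[r > 180] - 360
  r
}

#' Equal-power panning gains for a point source
#'
#' Maps a source azimuth to per-channel gains on the ring. A source on a
#' loudspeaker gets gain 1 on that channel; a source between two adjacent
#' loudspeakers is split across them with the sine/cosine constant-power
#' law: for fractional position `phi` in (0, 1) between the lower and upper
#' speaker, the gains are `cos(phi * pi/2)` and `sin(phi * pi/2)`, so the
#' squared gains always sum to one and perceived level is preserved across
#' pan positions.
#'
#' @param geometry An [array_geometry()].
#' @param azimuth Source azimuth in degrees (any value; normalized
#'   internally).
#' @return A `gain_vector`: numeric vector of length `n_speakers` in the
#'   geometry's channel order, with the source azimuth as attribute.
#' @export
#' @examples
#' g <- array_geometry()
#' sum(pan_gains(g, 7.5)^2)  # exactly 1
pan_gains <- function(geometry, azimuth) {
  stopifnot(inherits(geometry, "array_geometry"))
  az <- normalize_azimuth(azimuth)
  pos <- (az %% 360) / geometry$spacing
  lower <- floor(pos + 1e-9)
  phi <- pos - lower
  gains <- numeric(geometry$n_speakers)
  lower_az <- normalize_azimuth(lower * geometry$spacing)
  upper_az <- normalize_azimuth((lower + 1) * geometry$spacing)
  i_lower <- match(round(lower_az, 6), round(geometry$azimuths, 6))
  if (phi < 1e-9) {
    gains[i_lower] <- 1
  } else {
    i_upper <- match(round(upper_az, 6), round(geometry$azimuths, 6))
    gains[i_lower] <- cos(phi * pi / 2)
    gains[i_upper] <- sin(phi * pi / 2)
  }
  structure(gains, azimuth = az, class = "gain_vector")
}

#' Specify a spatial scene
#'
#' One frontal target, two maskers split symmetrically at +/- `
#' masker_separation`, and optionally a diffuse four-speaker babble
#' background behind the listener. The TMR is defined per masker: each of
#' the two maskers plays at `masker_level`, and TMR = `target_level -
#' masker_level`. The target level is fixed (65 dB SPL by default) and TMR
#' manipulations change the masker level only, so babble at 55 dB SPL sits
#' at -10 dB SNR relative to the target.
#'
#' @param masker_separation Masker angle theta in degrees; maskers sit at
#'   +theta and -theta. Must lie in [0, 90].
#' @param target_level Target level, dB SPL (default 65).
#' @param tmr Target-to-masker ratio in dB (per masker). Exactly one of
#'   `tmr` and `masker_level` must be given.
#' @param masker_level Per-masker level, dB SPL.
#' @param babble Logical: include the babble background?
#' @param babble_level Overall babble level, dB SPL (default 55), split
#'   equally in power across the four babble speakers.
#' @param babble_azimuths Babble speaker azimuths (default
#'   `c(-165, -135, 135, 165)`).
#' @param target_azimuth Target azimuth (default 0).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(masker_separation, target_level = 65, tmr = NULL,
                       masker_level = NULL, babble = FALSE,
                       babble_level = 55,
                       babble_azimuths = c(-165, -135, 135, 165),
                       target_azimuth = 0) {
  if (masker_separation < 0 || masker_separation > 90) {
    stop("masker_separation must lie in [0, 90] degrees", call. = FALSE)
  }
  if (is.null(masker_level) == is.null(tmr)) {
    stop("give exactly one of tmr or masker_level", call. = FALSE)
  }
  if (is.null(masker_level)) masker_level <- target_level - tmr
  structure(list(masker_separation = masker_separation,
                 target_level = target_level,
                 masker_level = masker_level,
                 tmr = target_level - masker_level,
                 babble = isTRUE(babble), babble_level = babble_level,
                 babble_azimuths = babble_azimuths,
                 target_azimuth = target_azimuth),
            class = "scene_spec")
}

#' Per-source gain vectors and levels for a scene
#'
#' Pans the target at its azimuth, the two maskers at +/- theta, and (if
#' enabled) the babble split equally across its four fixed speakers, each
#' babble channel carrying a quarter of the babble power. Symmetric maskers
#' produce left/right mirror-image gain vectors.
#'
#' @param geometry An [array_geometry()].
#' @param scene A [scene_spec()].
#' @return A `scene_gains` object: list of sources, each with `name`,
#'   `azimuth`, `level_db` and `gains` (a [pan_gains()] vector); the
#'   scene's TMR is attached as attribute `tmr`.
#' @export
scene_gains <- function(geometry, scene) {
  stopifnot(inherits(scene, "scene_spec"))
  th <- scene$masker_separation
  sources <- list(
    list(name = "target", azimuth = scene$target_azimuth,
         level_db = scene$target_level,
         gains = pan_gains(geometry, scene$target_azimuth)),
    list(name = "masker1", azimuth = th, level_db = scene$masker_level,
         gains = pan_gains(geometry, th)),
    list(name = "masker2", azimuth = -th, level_db = scene$masker_level,
         gains = pan_gains(geometry, -th))
  )
  if (scene$babble) {
    per_speaker <- scene$babble_level - 10 * log10(length(scene$babble_azimuths))
    for (a in scene$babble_azimuths) {
      sources[[length(sources) + 1L]] <-
        list(name = "babble", azimuth = a, level_db = per_speaker,
             gains = pan_gains(geometry, a))
    }
  }
  structure(sources, class = "scene_gains", tmr = scene$tmr)
}

#' Render a scene and timeline as multichannel audio
#'
#' Optional demonstration output: each word slot becomes a distinct
#' synthetic token (a Hann-enveloped harmonic complex whose fundamental is
#' keyed to the talker and whose upper partials are keyed to the token id),
#' panned through the scene's gain vectors; babble is rendered as
#' independent Gaussian noise on its four speakers. No recorded speech is
#' used: tokens are placeholders that carry the correct timing, levels and
#' spatial layout.
#'
#' @param geometry An [array_geometry()].
#' @param scene A [scene_spec()].
#' @param timeline A `stream_timeline` from [build_timeline()].
#' @param sr Sample rate in Hz (default 44100).
#' @param seed Optional RNG seed for babble noise.
#' @return A numeric matrix, samples x channels (channel order = ascending
#'   azimuth), with attribute `sr`. Levels are linear amplitudes relative
#'   to a 65 dB SPL reference amplitude of 0.1.
#' @export
render_scene <- function(geometry, scene, timeline, sr = 44100,
                         seed = NULL) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(timeline, "stream_timeline"))
  if (!is.null(seed)) set.seed(seed)
  n_samp <- ceiling(timeline$duration * sr)
  buf <- matrix(0, nrow = n_samp, ncol = geometry$n_speakers)
  word_dur <- timeline$word_period - timeline$inter_word_interval
  n_word <- round(word_dur * sr)
  env <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_word) / (n_word + 1))

  stream_az <- c(target = scene$target_azimuth,
                 masker1 = scene$masker_separation,
                 masker2 = -scene$masker_separation)
  stream_lvl <- c(target = scene$target_level,
                  masker1 = scene$masker_level,
                  masker2 = scene$masker_level)
  f0 <- c(m1 = 110, f1 = 190, f2 = 230)

  ev <- timeline$events
  t_word <- seq_len(n_word) / sr
  for (i in seq_len(nrow(ev))) {
    s <- ev$stream[i]
    amp <- 0.1 * 10^((stream_lvl[[s]] - 65) / 20)
    g <- pan_gains(geometry, stream_az[[s]])
    base <- f0[[ev$talker[i]]]
    partial <- 2 + (ev$token[i] %% 7)
    tok <- sin(2 * pi * base * t_word) +
      0.5 * sin(2 * pi * base * partial * t_word + ev$token[i])
    tok <- amp * env * tok / sqrt(mean(tok^2) + 1e-12)
    i0 <- round(ev$onset[i] * sr)
    idx <- i0 + seq_len(n_word)
    idx_ok <- idx <= n_samp
    nz <- which(unclass(g) != 0)
    for (ch in nz) {
      buf[idx[idx_ok], ch] <- buf[idx[idx_ok], ch] + g[ch] * tok[idx_ok]
    }
  }

  if (scene$babble) {
    per_amp <- 0.1 * 10^((scene$babble_level -
                            10 * log10(length(scene$babble_azimuths)) - 65) / 20)
    for (a in scene$babble_azimuths) {
      g <- pan_gains(geometry, a)
      ch <- which(unclass(g) != 0)
      for (c2 in ch) {
        buf[, c2] <- buf[, c2] + g[c2] * per_amp * stats::rnorm(n_samp)
      }
    }
  }
  attr(buf, "sr") <- sr
  buf
}

#' Write a multichannel buffer as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, format code 3) for the rendered
#' scene buffers; channel order is the buffer's column order (ascending
#' azimuth from -165 to 180 for the default ring).
#'
#' @param buffer Numeric matrix, samples x channels.
#' @param path Output file path.
#' @param sr Sample rate in Hz; defaults to the buffer's `sr` attribute or
#'   44100.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(buffer, path, sr = NULL) {
  if (is.null(sr)) sr <- attr(buffer, "sr")
  if (is.null(sr)) sr <- 44100L
  buffer <- as.matrix(buffer)
  n_ch <- ncol(buffer); n_samp <- nrow(buffer)
  bytes_per_sample <- 4L
  data_bytes <- n_samp * n_ch * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w4(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w4(16L)
  w2(3L)                       # IEEE float
  w2(n_ch); w4(sr)
  w4(sr * n_ch * bytes_per_sample)
  w2(n_ch * bytes_per_sample); w2(8L * bytes_per_sample)
  writeChar("data", con, eos = NULL); w4(data_bytes)
  writeBin(as.numeric(t(buffer)), con, size = 4, endian = "little")
  invisible(path)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("loudspeaker ring: %d speakers, %g deg spacing, radius %g m\n",
              x$n_speakers, x$spacing, x$radius))
  invisible(x)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene: target %g dB SPL at %g deg, maskers at +/-%g deg, TMR %+.1f dB%s\n",
              x$target_level, x$target_azimuth, x$masker_separation, x$tmr,
              if (x$babble) sprintf(", babble %g dB SPL", x$babble_level) else ""))
  invisible(x)
}
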