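#' Recording configuration
#'
#' Configuration of a synthetic insole recording. Defaults encode the study
#' conditions: 20 Hz sampling, gait cycles of 1.24 +/- 0.02 s (per-cycle
#' duration truncated at +/- 3 sd), 5 kPa additive sensor noise on active
#' channels, a 100 kPa calcaneus peak for a normal pattern, and five
#' near-inactive channels (default: the layout's `Other` units, carrying
#' only 0.5 kPa residual noise).
#'
#' Either `n_cycles` or `duration_s` fixes the length: with `duration_s`
#' set, cycles are drawn until they cover it and the grid has exactly
#' `round(sampling_rate * duration_s)` frames.
#'
#' @param sampling_rate Sampling frequency, Hz.
#' @param cycle_duration_mean,cycle_duration_sd Gait-cycle duration, s.
#' @param n_cycles Number of gait cycles (ignored when `duration_s` given).
#' @param duration_s Optional exact recording duration, s.
#' @param noise_sd Additive Gaussian noise on active channels, kPa.
#' @param base_amplitude Calcaneus peak pressure of a normal pattern, kPa.
#' @param inactive_channels Unit ids of the five near-inactive channels;
#'   `NULL` means the layout's `Other` units.
#' @param inactive_noise_sd Residual noise on inactive channels, kPa.
#' @param shift_ramp Medial--lateral gain range at the sole edges for a
#'   full shift of +/- 1 (default 0.30, i.e. +/- 30 percent).
#' @param seed Integer seed; every stochastic draw in the generator flows
#'   from it.
#' @return List of class `recording_config`.
#' @export
recording_config <- function(sampling_rate = 20,
                             cycle_duration_mean = 1.24,
                             cycle_duration_sd = 0.02,
                             n_cycles = 5L,
                             duration_s = NULL,
                             noise_sd = 5,
                             base_amplitude = 100,
                             inactive_channels = NULL,
                             inactive_noise_sd = 0.5,
                             shift_ramp = 0.30,
                             seed = 42L) {
  stopifnot(sampling_rate > 0, cycle_duration_mean > 0,
            cycle_duration_sd >= 0, noise_sd >= 0, base_amplitude > 0)
  structure(list(
    sampling_rate = sampling_rate,
    cycle_duration_mean = cycle_duration_mean,
    cycle_duration_sd = cycle_duration_sd,
    n_cycles = as.integer(n_cycles),
    duration_s = duration_s,
    noise_sd = noise_sd,
    base_amplitude = base_amplitude,
    inactive_channels = inactive_channels,
    inactive_noise_sd = inactive_noise_sd,
    shift_ramp = shift_ramp,
    seed = as.integer(seed)
  ), class = "recording_config")
}

# relative pressure amplitude of each region (fraction of base_amplitude)
region_amplitude <- c(Cal = 1.00, Nav = 0.35, M1 = 0.80, M5 = 0.70,
                      Pha = 0.75, Other = 0)

# raised-cosine lobe centres / half-widths (fraction of cycle)
region_peak_phase <- c(Cal = 0.10, Nav = 0.30, M1 = 0.45, M5 = 0.45,
                       Pha = 0.55)
region_lobe_width <- c(Cal = 0.15, Nav = 0.20, M1 = 0.18, M5 = 0.18,
                       Pha = 0.15)

stance_fraction <- 0.60

#' Region activation over the gait cycle
#'
#' Normalised (0--1) activation of a plantar region as a function of cycle
#' phase. Each key region is a raised-cosine lobe — calcaneus peaking in
#' early stance (phase 0.10), navicular low mid-stance (0.30), metatarsals
#' mid-to-late (0.45), phalanx at push-off (0.55) — multiplied by a smooth
#' stance envelope occupying the first 60 percent of the cycle; activation
#' is identically zero in the swing window. `Other` returns zero
#' everywhere.
#'
#' @param region Region tag (`Cal`, `Nav`, `M1`, `M5`, `Pha`, `Other`).
#' @param phase Cycle phase in `[0, 1)`; vectorised.
#' @return Numeric activation in `[0, 1]`, same length as `phase`.
#' @export
#' @examples
#' cycle_template("Cal", c(0.1, 0.55, 0.8))
cycle_template <- function(region, phase) {
  if (length(region) != 1L || !region %in% c(key_regions(), "Other"))
    stop("unknown region: ", paste(region, collapse = ","))
  stopifnot(all(phase >= 0 & phase < 1))
  if (region == "Other") return(numeric(length(phase)))
  centre <- region_peak_phase[[region]]
  hw <- region_lobe_width[[region]]
  lobe <- ifelse(abs(phase - centre) <= hw,
                 0.5 * (1 + cos(pi * (phase - centre) / hw)), 0)
  lobe * stance_envelope(phase)
}

# smooth stance envelope: cosine ramp-in over [0, 0.04], flat, cosine
# ramp-out over [0.52, 0.60], zero in swing
stance_envelope <- function(phase) {
  e <- numeric(length(phase))
  up <- phase < 0.04
  flat <- phase >= 0.04 & phase <= 0.52
  down <- phase > 0.52 & phase < stance_fraction
  e[up] <- 0.5 * (1 - cos(pi * phase[up] / 0.04))
  e[flat] <- 1
  e[down] <- 0.5 * (1 + cos(pi * (phase[down] - 0.52) / 0.08))
  e
}

#' Generate a synthetic insole recording
#'
#' Simulates one continuous recording of the 18-channel pressure insole for
#' a given gait pattern. Per-cycle durations are drawn
#' Normal(`cycle_duration_mean`, `cycle_duration_sd`) truncated at three
#' standard deviations; each active channel follows
#' `base_amplitude * unit_gain * region_amplitude * region template *
#' pattern region gain * medial-lateral shift weight`, plus Gaussian noise,
#' clipped at zero. Channels listed as inactive carry only small residual
#' noise. The same `(pattern, cfg)` pair reproduces the recording exactly.
#'
#' @param pattern A `gait_pattern` (or a label accepted by
#'   [gait_pattern()]).
#' @param cfg A [recording_config()].
#' @param layout Sensor layout (default [make_default_layout()]).
#' @param amplitude_scale Extra overall amplitude factor (used by the
#'   activity gait-condition profiles; default 1).
#' @return Object of class `pressure_recording`: list with `times` (s),
#'   `pressures` (frames x 18 matrix, kPa, columns `ch01`..`ch18`),
#'   `phase` (cycle phase per frame), `cycle_starts`, `layout`, `label`,
#'   `asa_worn` and `config`.
#' @export
#' @examples
#' rec <- generate_recording("normal", recording_config(duration_s = 5))
#' nrow(rec$pressures)  # 100 frames at 20 Hz
generate_recording <- function(pattern, cfg = recording_config(),
                               layout = make_default_layout(),
                               amplitude_scale = 1) {
  if (is.character(pattern)) pattern <- gait_pattern(pattern)
  stopifnot(inherits(pattern, "gait_pattern"),
            inherits(cfg, "recording_config"))
  validate_layout(layout)
  if (is.null(cfg$duration_s) && cfg$n_cycles <= 0L)
    stop("n_cycles must be positive")

  set.seed(cfg$seed)
  fs <- cfg$sampling_rate

  draw_cycles <- function(n) {
    d <- stats::rnorm(n, cfg$cycle_duration_mean, cfg$cycle_duration_sd)
    lo <- cfg$cycle_duration_mean - 3 * cfg$cycle_duration_sd
    hi <- cfg$cycle_duration_mean + 3 * cfg$cycle_duration_sd
    pmin(pmax(d, lo), hi)
  }

  if (!is.null(cfg$duration_s)) {
    stopifnot(cfg$duration_s > 0)
    durations <- numeric(0)
    while (sum(durations) < cfg$duration_s)
      durations <- c(durations, draw_cycles(1L))
    n_frames <- round(fs * cfg$duration_s)
  } else {
    durations <- draw_cycles(cfg$n_cycles)
    n_frames <- round(fs * sum(durations))
  }
  times <- (seq_len(n_frames) - 1) / fs
  starts <- cumsum(c(0, durations))
  cyc_idx <- findInterval(times, starts, rightmost.closed = FALSE)
  cyc_idx <- pmin(cyc_idx, length(durations))
  phase <- (times - starts[cyc_idx]) / durations[cyc_idx]
  phase <- pmin(pmax(phase, 0), 1 - 1e-9)

  inactive <- cfg$inactive_channels
  if (is.null(inactive)) inactive <- region_units(layout, "Other")

  xmax <- max(abs(layout$x_mm))
  shift_w <- 1 + pattern$medial_lateral_shift * cfg$shift_ramp *
    layout$x_mm / xmax

  press <- matrix(0, n_frames, 18L,
                  dimnames = list(NULL, sprintf("ch%02d", 1:18)))
  # one template evaluation per region, reused across its units
  tmpl <- sapply(c(key_regions(), "Other"), cycle_template, phase = phase)
  for (i in seq_len(nrow(layout))) {
    ch <- layout$id[i]
    if (ch %in% inactive) next
    reg <- layout$region[i]
    amp <- cfg$base_amplitude * amplitude_scale * layout$unit_gain[i] *
      region_amplitude[[reg]] * pattern$region_gain[[reg]] * shift_w[i]
    press[, ch] <- amp * tmpl[, reg]
  }
  noise_sd_ch <- ifelse(1:18 %in% inactive, cfg$inactive_noise_sd,
                        cfg$noise_sd)
  noise <- matrix(stats::rnorm(n_frames * 18L), n_frames, 18L)
  press <- press + sweep(noise, 2L, noise_sd_ch, `*`)
  press[press < 0] <- 0

  structure(list(
    times = times, pressures = press, phase = phase,
    cycle_starts = starts[seq_along(durations)],
    cycle_durations = durations,
    layout = layout, label = pattern$label, asa_worn = FALSE,
    config = cfg
  ), class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf(
    "<pressure_recording> %d frames @ %g Hz (%.2f s), label=%s, ASA %s\n",
    nrow(x$pressures), x$config$sampling_rate, max(x$times),
    x$label %||% "?", if (isTRUE(x$asa_worn)) "worn" else "not worn"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default per-region ASA relief fractions
#'
#' Draws the relief fraction applied to each load-bearing region (Cal, M1,
#' M5, Pha) uniformly within the configured relief band. The band default
#' is the 16.71--33.64 percent peak-pressure relief span the arch support
#' achieves across everyday gaits; any pressure-weighted average of
#' per-region draws therefore also lies inside the band.
#'
#' @param seed Optional seed for the draw; `NULL` leaves the RNG state
#'   alone and returns the band midpoint for all four regions.
#' @param band Length-2 numeric, the relief band as fractions.
#' @return Named numeric vector over Cal, M1, M5, Pha.
#' @export
default_relief <- function(seed = NULL, band = c(0.1671, 0.3364)) {
  regions <- c("Cal", "M1", "M5", "Pha")
  if (is.null(seed)) {
    r <- rep(mean(band), 4L)
  } else {
    set.seed(seed)
    r <- stats::runif(4L, band[1], band[2])
  }
  names(r) <- regions
  r
}

#' Apply the arch-support auxiliary to a recording
#'
#' Models the mechanical effect of wearing the spring-loaded arch support:
#' the navicular (arch) region takes up extra load (`support_gain`), and
#' the peak pressures of the other four key regions drop by their relief
#' fractions. Channel pressures within a region are scaled uniformly, so
#' within-region pressure ordering is preserved.
#'
#' @param recording A `pressure_recording` with `asa_worn = FALSE`.
#' @param relief Named relief fractions in `[0, 1)` over Cal, M1, M5, Pha
#'   (default: band midpoints from [default_relief()]).
#' @param support_gain Fractional increase of navicular pressure.
#' @return A copy of the recording with `asa_worn = TRUE`.
#' @export
apply_asa <- function(recording, relief = default_relief(),
                      support_gain = 0.15) {
  stopifnot(inherits(recording, "pressure_recording"))
  if (isTRUE(recording$asa_worn))
    stop("recording already has the ASA applied")
  regions <- c("Cal", "M1", "M5", "Pha")
  if (!all(regions %in% names(relief)))
    stop("relief must name the regions ", paste(regions, collapse = ", "))
  relief <- relief[regions]
  if (any(relief < 0 | relief >= 1))
    stop("relief fractions must lie in [0, 1)")
  stopifnot(support_gain >= 0)

  out <- recording
  for (reg in regions) {
    ch <- region_units(recording$layout, reg)
    out$pressures[, ch] <- recording$pressures[, ch] * (1 - relief[[reg]])
  }
  nav <- region_units(recording$layout, "Nav")
  out$pressures[, nav] <- recording$pressures[, nav] * (1 + support_gain)
  out$asa_worn <- TRUE
  out$relief <- relief
  out$support_gain <- support_gain
  out
}

#' Generate a multi-segment walking session
#'
#' Concatenates seeded recordings for a sequence of (pattern, duration)
#' segments into one continuous recording with a frame-aligned ground-truth
#' label track. Segment boundaries fall on frame edges.
#'
#' @param segments List of `list(pattern =, duration_s =)` entries (pattern
#'   as label or `gait_pattern`).
#' @param cfg Base [recording_config()]; segment `i` uses seed
#'   `cfg$seed + i - 1`.
#' @param layout Sensor layout.
#' @return A `pressure_recording` whose `label` is `"session"` and which
#'   carries a per-frame `label_track` character vector.
#' @export
generate_session <- function(segments, cfg = recording_config(),
                             layout = make_default_layout()) {
  if (!length(segments)) stop("segments must be nonempty")
  durs <- vapply(segments, function(s) as.numeric(s$duration_s), 0)
  if (sum(durs) <= 0) stop("total session duration must be positive")
  fs <- cfg$sampling_rate
  recs <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg_cfg <- cfg
    seg_cfg$duration_s <- durs[i]
    seg_cfg$seed <- cfg$seed + i - 1L
    recs[[i]] <- generate_recording(segments[[i]]$pattern, seg_cfg, layout)
  }
  frames <- vapply(recs, function(r) nrow(r$pressures), 0L)
  offsets_t <- cumsum(c(0, vapply(recs, function(r) nrow(r$pressures) / fs,
                                  0)))
  times <- unlist(lapply(seq_along(recs),
                         function(i) recs[[i]]$times + offsets_t[i]))
  press <- do.call(rbind, lapply(recs, `[[`, "pressures"))
  phase <- unlist(lapply(recs, `[[`, "phase"))
  cyc <- unlist(lapply(seq_along(recs),
                       function(i) recs[[i]]$cycle_starts + offsets_t[i]))
  labels <- rep(vapply(recs, `[[`, "", "label"), times = frames)
  structure(list(
    times = times, pressures = press, phase = phase, cycle_starts = cyc,
    cycle_durations = unlist(lapply(recs, `[[`, "cycle_durations")),
    layout = layout, label = "session", asa_worn = FALSE,
    label_track = labels, config = cfg
  ), class = "pressure_recording")
}

#' Write / read a recording as delimited text plus JSON side-car
#'
#' The recording matrix goes to a comma-separated file with header
#' `time_s,ch01..ch18`; label, seed, configuration, cycle starts and the
#' layout go to `<path>.json`.
#'
#' @param recording A `pressure_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   the reconstructed `pressure_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "pressure_recording"))
  df <- data.frame(time_s = recording$times, recording$pressures,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  meta <- list(
    label = recording$label,
    asa_worn = recording$asa_worn,
    config = unclass(recording$config),
    cycle_starts = recording$cycle_starts,
    cycle_durations = recording$cycle_durations,
    phase = recording$phase,
    label_track = recording$label_track,
    layout = unclass(recording$layout)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layout <- as.data.frame(meta$layout, stringsAsFactors = FALSE)
  class(layout) <- c("sensor_layout", "data.frame")
  cfg <- meta$config
  cfg$n_cycles <- as.integer(cfg$n_cycles)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "recording_config"
  structure(list(
    times = df$time_s,
    pressures = as.matrix(df[, -1, drop = FALSE]),
    phase = meta$phase,
    cycle_starts = meta$cycle_starts,
    cycle_durations = meta$cycle_durations,
    layout = layout,
    label = meta$label,
    asa_worn = meta$asa_worn,
    label_track = meta$label_track,
    config = cfg
  ), class = "pressure_recording")
}
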