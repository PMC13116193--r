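#' Arch-support spring specification
#'
#' The ASA houses a compression coil spring in an installation space of
#' about 10 mm height; springs of different free length (25, 35, 45 mm)
#' therefore carry different pre-compression and a stiffness that falls
#' inversely with free length.
#'
#' @param free_length Free (uncompressed) length, mm.
#' @param stiffness Spring rate, N/mm.
#' @param installed_height Installed height, mm (default 10).
#' @return List of class `spring_spec`.
#' @export
spring_spec <- function(free_length, stiffness, installed_height = 10) {
  stopifnot(free_length > 0, stiffness > 0, installed_height > 0)
  if (installed_height > free_length)
    stop("installed_height must not exceed free_length")
  structure(list(free_length = free_length, stiffness = stiffness,
                 installed_height = installed_height),
            class = "spring_spec")
}

#' Spring stiffness from free length (inverse-length coil law)
#'
#' For a coil spring cut from the same stock, the rate scales inversely
#' with the number of active coils and hence with free length:
#' `k(L) = k_ref * L_ref / L`. Anchored at the 25 mm / 10.00 N/mm
#' reference this reproduces the measured 35 mm -> 7.14 N/mm and
#' 45 mm -> 5.56 N/mm rates after rounding to two decimals.
#'
#' @param free_length Free length, mm.
#' @param ref_length Reference free length, mm (default 25).
#' @param ref_stiffness Reference stiffness, N/mm (default 10.00).
#' @param digits Decimal places for the reported value (default 2).
#' @return Stiffness in N/mm, rounded to `digits`.
#' @export
#' @examples
#' spring_stiffness_from_length(35)  # 7.14
spring_stiffness_from_length <- function(free_length, ref_length = 25,
                                         ref_stiffness = 10.00,
                                         digits = 2) {
  if (any(c(free_length, ref_length) <= 0))
    stop("spring lengths must be positive")
  stopifnot(ref_stiffness > 0)
  round(ref_stiffness * ref_length / free_length, digits)
}

#' Spring preload force
#'
#' Hooke's law force of the spring at its installed height:
#' `k * (free_length - installed_height)`.
#'
#' @param spring A [spring_spec()].
#' @return Preload force, N.
#' @export
#' @examples
#' preload_force(spring_spec(25, 10))  # 150 N
preload_force <- function(spring) {
  stopifnot(inherits(spring, "spring_spec"))
  spring$stiffness * (spring$free_length - spring$installed_height)
}

#' Supportive pressure under the arch
#'
#' Converts an arch support force into pressure over the navicular contact
#' pad and flags whether it falls inside the 80--100 kPa band estimated as
#' the suitable supportive-pressure range for the arch. The default pad
#' area (16.7 cm^2) is a declared module default, not a measured quantity.
#'
#' @param force Support force, N.
#' @param contact_area Pad area, m^2 (default 1.67e-3).
#' @param band Acceptable band in kPa (default `c(80, 100)`, closed).
#' @return List with `pressure_kpa` and logical `in_band`.
#' @export
supportive_pressure <- function(force, contact_area = 1.67e-3,
                                band = c(80, 100)) {
  if (contact_area <= 0) stop("contact_area must be positive")
  stopifnot(force >= 0)
  p <- force / contact_area / 1000  # Pa -> kPa
  list(pressure_kpa = p, in_band = p >= band[1] && p <= band[2])
}

#' Stance-phase peak pressure
#'
#' Maximum pressure over the stance phase, defined as cycle phase in the
#' closed interval `[0, 0.60]` (frames at exactly 60 percent of the cycle
#' are included).
#'
#' @param series Numeric pressure series, kPa.
#' @param phase Cycle phase per sample in `[0, 1)`; required.
#' @return Peak stance pressure, kPa.
#' @export
stance_peak <- function(series, phase) {
  if (missing(phase) || is.null(phase))
    stop("stance_peak needs a phase annotation")
  stopifnot(length(series) == length(phase))
  in_stance <- phase <= stance_fraction
  if (!any(in_stance)) stop("series contains no stance-phase samples")
  max(series[in_stance])
}

# per-region stance peak of a recording: max across the region's channels
regional_stance_peaks <- function(recording,
                                  regions = key_regions()) {
  vapply(regions, function(reg) {
    ch <- region_units(recording$layout, reg)
    stance_peak(apply(recording$pressures[, ch, drop = FALSE], 1L, max),
                recording$phase)
  }, 0)
}

# per-cycle mean regional stance peak (excluding Nav), used for pairing
per_cycle_mean_peak <- function(recording) {
  regions <- setdiff(key_regions(), "Nav")
  starts <- recording$cycle_starts
  ends <- c(starts[-1], Inf)
  vapply(seq_along(starts), function(k) {
    idx <- recording$times >= starts[k] & recording$times < ends[k] &
      recording$phase <= stance_fraction
    if (!any(idx)) return(NA_real_)
    mean(vapply(regions, function(reg) {
      ch <- region_units(recording$layout, reg)
      max(recording$pressures[idx, ch])
    }, 0))
  }, 0)
}

#' Pressure-relief statistics for a with/without-ASA pair
#'
#' Compares a recording worn with the arch support against the matched
#' recording without it. For each key region the reduction of the
#' stance-phase peak is `100 * (peak_without - peak_with) / peak_without`
#' (for the navicular region, which the support loads deliberately, this
#' comes out negative, i.e. an increase). The overall figure is the
#' reduction of the mean regional peak excluding the navicular region. A
#' paired t-test across per-cycle mean peaks tests whether the relief is
#' systematic; significance is declared at p < 0.05. If the paired
#' differences have zero variance, the test degenerates: all-zero
#' differences report p = 1 (no difference), a constant nonzero
#' difference p = 0.
#'
#' @param with_asa,without_asa Matched `pressure_recording`s (same layout,
#'   same gait label).
#' @return List of class `relief_stats`: `per_region_reduction_pct`,
#'   `overall_reduction_pct`, `p_value`, `significant`, `n_cycles`.
#' @export
relief_stats <- function(with_asa, without_asa) {
  stopifnot(inherits(with_asa, "pressure_recording"),
            inherits(without_asa, "pressure_recording"))
  if (!identical(dim(with_asa$pressures)[2], dim(without_asa$pressures)[2]) ||
      !identical(with_asa$layout$region, without_asa$layout$region) ||
      !identical(with_asa$layout$id, without_asa$layout$id))
    stop("recordings must share the same sensor layout")
  if (!identical(with_asa$label, without_asa$label))
    stop("recordings must carry the same gait label")

  pk_w <- regional_stance_peaks(with_asa)
  pk_wo <- regional_stance_peaks(without_asa)
  red <- 100 * (pk_wo - pk_w) / pk_wo

  load_regions <- setdiff(key_regions(), "Nav")
  overall <- 100 * (mean(pk_wo[load_regions]) - mean(pk_w[load_regions])) /
    mean(pk_wo[load_regions])

  cyc_wo <- stats::na.omit(per_cycle_mean_peak(without_asa))
  cyc_w <- stats::na.omit(per_cycle_mean_peak(with_asa))
  n <- min(length(cyc_wo), length(cyc_w))
  d <- cyc_wo[seq_len(n)] - cyc_w[seq_len(n)]
  if (n < 2 || stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
  } else {
    p <- stats::t.test(cyc_wo[seq_len(n)], cyc_w[seq_len(n)],
                       paired = TRUE)$p.value
  }
  structure(list(
    per_region_reduction_pct = red,
    overall_reduction_pct = overall,
    p_value = p,
    significant = p < 0.05,
    n_cycles = n
  ), class = "relief_stats")
}

#' Mean electrical peak power over gait cycles
#'
#' The electrical power output is the ratio of the square of the external
#' peak voltage to the load resistance, averaged over consecutive gait
#' cycles (20 by default).
#'
#' @param peak_voltage Peak voltage per cycle, V; a scalar is recycled to
#'   `n_cycles`.
#' @param load_resistance Load resistance, Ohm.
#' @param n_cycles Number of cycles to average over when `peak_voltage` is
#'   scalar (default 20).
#' @return Mean peak power, W.
#' @export
#' @examples
#' peak_power(2, 4)  # 1 W
peak_power <- function(peak_voltage, load_resistance, n_cycles = 20) {
  if (load_resistance <= 0) stop("load_resistance must be positive")
  v <- if (length(peak_voltage) == 1L) rep(peak_voltage, n_cycles)
       else peak_voltage
  mean(v^2 / load_resistance)
}

#' Energy stored in a charged capacitor
#'
#' `E = C V^2 / 2`.
#'
#' @param capacitance Capacitance, F (non-negative).
#' @param voltage Voltage, V.
#' @return Energy, J.
#' @export
#' @examples
#' capacitor_energy(2.2e-3, 28.6)
capacitor_energy <- function(capacitance, voltage) {
  if (any(capacitance < 0)) stop("capacitance must be non-negative")
  0.5 * capacitance * voltage^2
}

#' Gravimetric and volumetric power density
#'
#' @param power Power, W.
#' @param mass Device mass, g.
#' @param volume Device volume, cm^3.
#' @return Named numeric: `mw_per_g`, `mw_per_cm3`.
#' @export
power_density <- function(power, mass, volume) {
  if (mass <= 0 || volume <= 0)
    stop("mass and volume must be positive")
  stopifnot(power >= 0)
  c(mw_per_g = 1000 * power / mass, mw_per_cm3 = 1000 * power / volume)
}
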