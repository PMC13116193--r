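#' The seven gait pattern labels
#'
#' Canonical label order used throughout the package: normal gait,
#' supinator (lateral-edge loading), pronator (medial-edge loading), and
#' localised pressure abnormalities in the heel, arch, first metatarsal and
#' fifth metatarsal regions.
#'
#' @return Character vector of length 7.
#' @export
gait_labels <- function() {
  c("normal", "supinator", "pronator", "heel_abn", "arch_abn",
    "m1_abn", "m5_abn")
}

#' Gait pattern specification
#'
#' Builds the per-region signature of one of the seven gait patterns. A
#' pattern is a set of multiplicative region gains plus a signed
#' medial--lateral shift in `[-1, 1]` that tilts loading across the sole
#' (negative = lateral/supinated, positive = medial/pronated). The four
#' localised abnormalities raise exactly their named region's gain to
#' `abn_gain`, which must exceed the abnormality threshold used by the
#' class-signature checks.
#'
#' @param label One of [gait_labels()].
#' @param abn_gain Gain applied to the affected region of an `*_abn`
#'   pattern (default 1.6).
#' @param edge_gain,edge_loss Gains applied to the loaded / unloaded
#'   metatarsal edge of supinator and pronator patterns.
#' @param shift_mag Magnitude of the medial--lateral shift for supinator /
#'   pronator (default 1, i.e. the full ramp configured in the generator).
#' @return An object of class `gait_pattern`: list with `label`,
#'   `region_gain` (named over Cal, Nav, M1, M5, Pha, Other) and
#'   `medial_lateral_shift`.
#' @export
#' @examples
#' gait_pattern("m1_abn")$region_gain
gait_pattern <- function(label, abn_gain = 1.6, edge_gain = 1.25,
                         edge_loss = 0.8, shift_mag = 1) {
  label <- match.arg(label, gait_labels())
  gain <- c(Cal = 1, Nav = 1, M1 = 1, M5 = 1, Pha = 1, Other = 1)
  shift <- 0
  if (label == "supinator") {
    shift <- -shift_mag
    gain["M5"] <- edge_gain
    gain["M1"] <- edge_loss
  } else if (label == "pronator") {
    shift <- shift_mag
    gain["M1"] <- edge_gain
    gain["M5"] <- edge_loss
  } else if (label == "heel_abn") {
    gain["Cal"] <- abn_gain
  } else if (label == "arch_abn") {
    gain["Nav"] <- abn_gain
  } else if (label == "m1_abn") {
    gain["M1"] <- abn_gain
  } else if (label == "m5_abn") {
    gain["M5"] <- abn_gain
  }
  structure(
    list(label = label, region_gain = gain, medial_lateral_shift = shift),
    class = "gait_pattern"
  )
}

#' Region affected by an abnormality label
#' @param label A gait label.
#' @return Region tag, or `NA` for patterns without a single focal region.
#' @export
abnormal_region <- function(label) {
  switch(label,
         heel_abn = "Cal", arch_abn = "Nav", m1_abn = "M1", m5_abn = "M5",
         supinator = "M5", pronator = "M1",
         NA_character_)
}

#' Activity gait-condition profiles
#'
#' Presets for the six representative everyday gait conditions used in the
#' with/without-ASA pressure-relief comparison: jogging, walking, climbing
#' and descending stairs, and walking up and down a slope. These are
#' cadence/amplitude variants of the normal walking pattern (a different
#' taxonomy from the seven classification patterns): jogging is faster and
#' harder-striking, stair climbing loads the forefoot, stair descent and
#' downslope walking load the heel.
#'
#' @param condition One of `"jogging"`, `"walking"`, `"upstairs"`,
#'   `"downstairs"`, `"upslope"`, `"downslope"`.
#' @return List with a `gait_pattern`, a cycle-duration mean (s) and an
#'   amplitude scale relative to normal walking.
#' @export
gait_condition_profile <- function(condition = c("jogging", "walking",
                                                 "upstairs", "downstairs",
                                                 "upslope", "downslope")) {
  condition <- match.arg(condition)
  pat <- gait_pattern("normal")
  amp <- 1
  cyc <- 1.24
  tweak <- function(pat, region, g) {
    pat$region_gain[region] <- g
    pat
  }
  switch(condition,
    jogging = { amp <- 1.35; cyc <- 0.80 },
    walking = { },
    upstairs = { amp <- 1.10; cyc <- 1.40
                 pat <- tweak(tweak(pat, "Pha", 1.25), "Cal", 0.85) },
    downstairs = { amp <- 1.20; cyc <- 1.30
                   pat <- tweak(pat, "Cal", 1.25) },
    upslope = { amp <- 1.05; cyc <- 1.35
                pat <- tweak(pat, "Pha", 1.15) },
    downslope = { amp <- 1.10; cyc <- 1.30
                  pat <- tweak(pat, "Cal", 1.15) }
  )
  list(condition = condition, pattern = pat,
       cycle_duration_mean = cyc, amplitude_scale = amp)
}
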