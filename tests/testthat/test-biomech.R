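test_that("inverse-length law reproduces the measured stiffness triplet", {
  expect_equal(spring_stiffness_from_length(35, 25, 10.00), 7.14)
  expect_equal(spring_stiffness_from_length(45, 25, 10.00), 5.56)
  expect_equal(spring_stiffness_from_length(25, 25, 10.00), 10.00)
  expect_error(spring_stiffness_from_length(-5), "positive")
  # unrounded, k(L) * L is exactly the reference product
  for (L in c(10, 25, 33.3, 45, 80))
    expect_equal(spring_stiffness_from_length(L, 25, 10, digits = 12) * L,
                 250, tolerance = 1e-9)
})

test_that("preload force follows Hooke's law at the installed height", {
  expect_equal(preload_force(spring_spec(25, 10.00, 10)), 150)
  expect_equal(preload_force(spring_spec(35, 7.14, 10)), 178.5)
  expect_equal(preload_force(spring_spec(25, 10.00, 25)), 0)
  expect_error(spring_spec(25, 10, installed_height = 30), "free_length")
})

test_that("supportive pressure converts and flags the 80-100 kPa band", {
  z <- supportive_pressure(0, 1e-3)
  expect_equal(z$pressure_kpa, 0)
  expect_false(z$in_band)
  p <- supportive_pressure(150, 0.00167)
  expect_equal(p$pressure_kpa, 89.82, tolerance = 1e-3)
  expect_true(p$in_band)
  q <- supportive_pressure(150, 0.001)
  expect_equal(q$pressure_kpa, 150)
  expect_false(q$in_band)
  expect_error(supportive_pressure(10, 0), "positive")
})

test_that("stance peak is the brute-force max over the 0-60% window", {
  phase <- seq(0, 0.995, by = 0.005)
  expect_equal(stance_peak(rep(50, length(phase)), phase), 50)
  # ramp peaking at 70% of the cycle is cut at the 60% boundary
  ramp <- 100 * pmax(0, 1 - abs(phase - 0.70) / 0.7)
  expect_equal(stance_peak(ramp, phase), ramp[phase == 0.60])
  # random series vs explicit maximum over the closed window
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(length(phase), 50, 20)
    expect_equal(stance_peak(x, phase), max(x[phase <= 0.60]))
  }
  expect_error(stance_peak(ramp), "phase")
})

test_that("generated calcaneus pressure peaks inside the stance window", {
  rec <- generate_recording("normal", recording_config(duration_s = 5,
                                                       seed = 2))
  cal <- region_units(rec$layout, "Cal")
  series <- apply(rec$pressures[, cal], 1, max)
  expect_lt(rec$phase[which.max(series)], 0.60)
})

# hand-built two-region pair with exactly known peaks
fake_recording <- function(peaks, n = 120) {
  layout <- make_default_layout()
  phase <- rep(seq(0, 0.95, by = 0.05), n / 20)
  times <- seq(0, by = 0.05, length.out = length(phase))
  press <- matrix(0, length(phase), 18,
                  dimnames = list(NULL, sprintf("ch%02d", 1:18)))
  for (reg in names(peaks)) {
    ch <- region_units(layout, reg)
    press[, ch[1]] <- peaks[[reg]] * cycle_template(reg, phase)
  }
  structure(list(times = times, pressures = press, phase = phase,
                 cycle_starts = times[phase == 0],
                 cycle_durations = rep(1, sum(phase == 0)),
                 layout = layout, label = "normal", asa_worn = FALSE,
                 config = recording_config()),
            class = "pressure_recording")
}

test_that("relief percentages are plain peak arithmetic", {
  without <- fake_recording(list(Cal = 100, Nav = 20, M1 = 80, M5 = 60,
                                 Pha = 50))
  with_asa <- fake_recording(list(Cal = 70, Nav = 20, M1 = 60, M5 = 60,
                                  Pha = 50))
  with_asa$asa_worn <- TRUE
  rs <- relief_stats(with_asa, without)
  tmpl_max <- function(reg)
    max(cycle_template(reg, seq(0, 0.95, by = 0.05)))
  expect_equal(unname(rs$per_region_reduction_pct["Cal"]), 30)
  expect_equal(unname(rs$per_region_reduction_pct["M1"]), 25)
  expect_equal(unname(rs$per_region_reduction_pct["M5"]), 0)
  manual <- 100 * (1 -
    (70 * tmpl_max("Cal") + 60 * tmpl_max("M1") + 60 * tmpl_max("M5") +
       50 * tmpl_max("Pha")) /
    (100 * tmpl_max("Cal") + 80 * tmpl_max("M1") + 60 * tmpl_max("M5") +
       50 * tmpl_max("Pha")))
  expect_equal(rs$overall_reduction_pct, manual)
})

test_that("identical recordings give zero relief and no difference", {
  rec <- fake_recording(list(Cal = 100, Nav = 20, M1 = 80, M5 = 60,
                             Pha = 50))
  rec2 <- rec
  rec2$asa_worn <- TRUE
  rs <- relief_stats(rec2, rec)
  expect_equal(unname(rs$per_region_reduction_pct), rep(0, 5))
  expect_equal(rs$overall_reduction_pct, 0)
  expect_equal(rs$p_value, 1)
  expect_false(rs$significant)
})

test_that("swapping the relief comparison flips the sign", {
  cfg <- recording_config(duration_s = 10, seed = 21)
  rec <- generate_recording("normal", cfg)
  worn <- apply_asa(rec, default_relief(22))
  fwd <- relief_stats(worn, rec)
  rec_flag <- rec; rec_flag$asa_worn <- TRUE
  worn_flag <- worn; worn_flag$asa_worn <- FALSE
  rev <- relief_stats(rec_flag, worn_flag)
  expect_gt(fwd$overall_reduction_pct, 0)
  expect_lt(rev$overall_reduction_pct, 0)
  expect_true(all(sign(fwd$per_region_reduction_pct) ==
                    -sign(rev$per_region_reduction_pct)))
})

test_that("electrical accounting reproduces the printed quantities", {
  expect_equal(peak_power(2, 4), 1)
  # load resistance back-solved from the printed jogging pair
  expect_equal(peak_power(59.3, 673.6), 5.22, tolerance = 1e-3)
  expect_lt(peak_power(59.3, 1e9), 1e-5)
  expect_error(peak_power(10, 0), "positive")

  expect_equal(capacitor_energy(2.2e-3, 28.6), 0.900, tolerance = 1e-3)
  expect_equal(capacitor_energy(4.7e-3, 25.0), 1.469, tolerance = 1e-3)
  expect_equal(capacitor_energy(1, 0), 0)
  expect_error(capacitor_energy(-1, 5), "non-negative")

  expect_equal(unname(power_density(1, 100, 100)), c(10, 10))
  expect_equal(unname(power_density(0, 10, 10)), c(0, 0))
  expect_equal(unname(power_density(5.22, 261, 125.5)), c(20.0, 41.6),
               tolerance = 1e-3)
  expect_error(power_density(1, 0, 10), "positive")
})

test_that("capacitor energy is strictly increasing in |V| and C", {
  volts <- seq(0.5, 30, length.out = 20)
  caps <- seq(1e-4, 1e-2, length.out = 20)
  e_v <- capacitor_energy(2.2e-3, volts)
  e_c <- capacitor_energy(caps, 25)
  expect_true(all(diff(e_v) > 0))
  expect_true(all(diff(e_c) > 0))
  expect_equal(capacitor_energy(2.2e-3, -28.6),
               capacitor_energy(2.2e-3, 28.6))
})
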