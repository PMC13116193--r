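test_that("default layout satisfies the insole contract", {
  layout <- make_default_layout()
  expect_s3_class(layout, "sensor_layout")
  expect_equal(nrow(layout), 18)
  expect_false(anyDuplicated(layout$id) > 0)
  for (reg in key_regions())
    expect_gt(length(region_units(layout, reg)), 0)
  expect_length(region_units(layout, "Other"), 5)
})

test_that("layout JSON round-trips", {
  layout <- make_default_layout()
  path <- withr::local_tempfile(fileext = ".json")
  write_layout(layout, path)
  expect_equal(read_layout(path), layout)
})

test_that("cycle templates follow the roll-over sequence", {
  grid <- seq(0, 0.999, by = 0.001)
  act <- sapply(key_regions(), cycle_template, phase = grid)
  expect_true(all(act >= 0))
  # heel loads before the toes: at the calcaneus peak, Cal dominates Pha
  cal_peak <- grid[which.max(act[, "Cal"])]
  expect_gt(cycle_template("Cal", cal_peak), cycle_template("Pha", cal_peak))
  expect_lt(cal_peak, 0.3)                    # early stance
  expect_gt(grid[which.max(act[, "Pha"])], 0.4)  # late stance
  # swing sub-window is unloaded, but every region loads at some point
  expect_equal(unname(sapply(key_regions(), cycle_template, phase = 0.8)),
               rep(0, 5))
  expect_true(all(colMeans(act) > 0))
  expect_error(cycle_template("Shin", 0.5), "unknown region")
})

test_that("generated recordings have the configured shape and are seeded", {
  cfg <- recording_config(duration_s = 5, seed = 7)
  rec <- generate_recording("normal", cfg)
  expect_equal(nrow(rec$pressures), 100)  # 5 s at 20 Hz
  expect_equal(ncol(rec$pressures), 18)
  expect_true(all(rec$pressures >= 0))
  expect_false(rec$asa_worn)

  rec2 <- generate_recording("normal", cfg)
  expect_identical(rec, rec2)

  quiet <- recording_config(duration_s = 5, noise_sd = 0, seed = 7)
  expect_identical(generate_recording("pronator", quiet),
                   generate_recording("pronator", quiet))
  expect_error(generate_recording("normal",
                                  recording_config(n_cycles = 0)),
               "n_cycles")
})

test_that("exactly five default channels are near-inactive", {
  rec <- generate_recording("normal", recording_config(duration_s = 10))
  v <- apply(rec$pressures, 2, var)
  expect_equal(sum(v < 1), 5)
  expect_setequal(which(v < 1), region_units(rec$layout, "Other"))
})

test_that("abnormal patterns raise their region's peak above normal", {
  cfg <- recording_config(duration_s = 5, seed = 11)
  normal <- generate_recording("normal", cfg)
  margin <- 1.2  # abnormality margin: at least 20 percent above normal
  for (lab in c("heel_abn", "arch_abn", "m1_abn", "m5_abn")) {
    abn <- generate_recording(lab, cfg)
    reg <- abnormal_region(lab)
    ch <- region_units(normal$layout, reg)
    expect_gt(max(abn$pressures[, ch]), margin * max(normal$pressures[, ch]),
              label = sprintf("%s peak in %s", lab, reg))
  }
})

test_that("supinator and pronator tilt load to opposite edges", {
  cfg <- recording_config(duration_s = 5, seed = 3)
  sup <- generate_recording("supinator", cfg)
  pro <- generate_recording("pronator", cfg)
  m1 <- region_units(sup$layout, "M1")
  m5 <- region_units(sup$layout, "M5")
  expect_gt(max(sup$pressures[, m5]), max(sup$pressures[, m1]))
  expect_gt(max(pro$pressures[, m1]), max(pro$pressures[, m5]))
})

test_that("apply_asa relieves load regions and supports the arch", {
  cfg <- recording_config(duration_s = 5, seed = 5)
  rec <- generate_recording("normal", cfg)

  # zero relief and zero support change nothing but the flag
  same <- apply_asa(rec, c(Cal = 0, M1 = 0, M5 = 0, Pha = 0),
                    support_gain = 0)
  expect_true(same$asa_worn)
  expect_equal(same$pressures, rec$pressures)

  worn <- apply_asa(rec, default_relief(1))
  cal <- region_units(rec$layout, "Cal")
  nav <- region_units(rec$layout, "Nav")
  expect_lt(max(worn$pressures[, cal]), max(rec$pressures[, cal]))
  expect_gt(max(worn$pressures[, nav]), max(rec$pressures[, nav]))
  expect_error(apply_asa(worn), "already")
})

test_that("default relief draws keep the overall reduction inside the band", {
  for (s in 1:6) {
    rec <- generate_recording("normal",
                              recording_config(duration_s = 10, seed = s))
    worn <- apply_asa(rec, default_relief(100 + s))
    rs <- relief_stats(worn, rec)
    expect_gte(rs$overall_reduction_pct, 16.71)
    expect_lte(rs$overall_reduction_pct, 33.64)
  }
})

test_that("sessions concatenate with frame-aligned truth labels", {
  cfg <- recording_config(seed = 9)
  ses1 <- generate_session(list(list(pattern = "normal", duration_s = 5)),
                           cfg)
  expect_true(all(ses1$label_track == "normal"))

  ses2 <- generate_session(list(list(pattern = "normal", duration_s = 5),
                                list(pattern = "pronator", duration_s = 5)),
                           cfg)
  expect_equal(unname(table(ses2$label_track)["normal"]), 100)
  expect_equal(unname(table(ses2$label_track)["pronator"]), 100)
  expect_equal(nrow(ses2$pressures), 200)

  ses3 <- generate_session(list(list(pattern = "normal", duration_s = 5),
                                list(pattern = "pronator", duration_s = 5)),
                           cfg)
  expect_identical(ses2$label_track, ses3$label_track)
  expect_identical(ses2$pressures, ses3$pressures)

  expect_error(generate_session(list(), cfg), "nonempty")
  expect_error(generate_session(list(list(pattern = "normal",
                                          duration_s = 0)), cfg),
               "positive")
})

test_that("recording text + side-car round trip preserves the data", {
  rec <- generate_recording("m5_abn", recording_config(duration_s = 5,
                                                       seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$pressures, rec$pressures, ignore_attr = TRUE)
  expect_equal(back$times, rec$times)
  expect_equal(back$phase, rec$phase)
  expect_equal(back$label, rec$label)
  expect_equal(back$layout$region, rec$layout$region)
})
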