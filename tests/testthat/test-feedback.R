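# streaming classifier fixture: 1.5 s windows (one full gait cycle).
# Training windows are cut at a 0.2 s stride so every cycle-phase offset
# the 0.5 s streaming stride can produce is represented. Trained once and
# reused across this file.
stream_fixture <- local({
  by_pattern <- list()
  for (j in seq_along(gait_labels())) {
    lab <- gait_labels()[j]
    by_pattern[[lab]] <- lapply(1:6, function(i)
      generate_recording(lab, recording_config(duration_s = 6,
                                               seed = 5000 + 10 * j + i)))
  }
  ds <- build_dataset(by_pattern, window_s = 1.5, stride_s = 0.2)
  ds <- normalize_dataset(stratified_split(ds, 0.5, seed = 500))
  m <- build_model(model_config(), c(13, 30), seed = 500)
  fit <- train_cnn(m, ds, train_config(epochs = 80, seed = 500))
  list(model = fit, dataset = ds)
})

test_that("the streaming fixture actually learned the patterns", {
  ev <- evaluate_cnn(stream_fixture$model, stream_fixture$dataset)
  expect_gte(ev$accuracy, 0.95)
})

test_that("streaming windows are ordered, labelled and counted correctly", {
  rec <- generate_session(list(list(pattern = "normal", duration_s = 8)),
                          recording_config(seed = 61))
  st <- stream_classify(stream_fixture$model, rec, window_s = 1.5,
                        stride_s = 1.5)
  expect_equal(nrow(st), 5)  # floor(duration / window), non-overlapping
  expect_true(!is.unsorted(st$start_s))
  expect_true(all(st$label == "normal"))
  expect_true(all(st$probability >= 1 / 7))
  st2 <- stream_classify(stream_fixture$model, rec, window_s = 1.5,
                         stride_s = 0.5)
  expect_equal(nrow(st2), 14)
  expect_error(stream_classify(stream_fixture$model, rec, window_s = 2.5),
               "frames")
})

test_that("warning detection implements the debounced state machine", {
  rule <- warning_rule(min_consecutive_windows = 3, cooldown_s = 5)
  mk <- function(labels, start0 = 0, step = 1)
    data.frame(start_s = start0 + step * (seq_along(labels) - 1),
               end_s = start0 + step * seq_along(labels),
               label = labels, probability = 1)

  expect_equal(nrow(detect_warnings(mk(rep("normal", 10)), rule)), 0)

  ev <- detect_warnings(mk(c("normal", "normal", "pronator", "pronator",
                             "pronator", "normal")), rule)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "pronator")
  expect_equal(ev$start_s, 2)
  expect_equal(ev$end_s, 5)
  expect_equal(ev$n_windows, 3)

  # two-window run stays below the debounce threshold
  ev2 <- detect_warnings(mk(c("pronator", "pronator", "normal")), rule)
  expect_equal(nrow(ev2), 0)

  # degenerate rule: every abnormal window opens or extends an event
  eager <- warning_rule(min_consecutive_windows = 1, cooldown_s = 0)
  ev3 <- detect_warnings(mk(c("m1_abn", "normal", "m1_abn")), eager)
  expect_equal(nrow(ev3), 2)

  # a same-label event inside the cooldown is suppressed
  lab4 <- c(rep("pronator", 3), "normal", rep("pronator", 3))
  ev4 <- detect_warnings(mk(lab4), rule)
  expect_equal(nrow(ev4), 1)
  ev5 <- detect_warnings(mk(lab4, step = 6), rule)
  expect_equal(nrow(ev5), 2)
})

test_that("session reports summarise a clean walk as clean", {
  rec <- generate_session(list(list(pattern = "normal", duration_s = 10)),
                          recording_config(seed = 71))
  st <- stream_classify(stream_fixture$model, rec, 1.5, 0.5)
  rep1 <- generate_report(st, rec)
  expect_equal(sum(rep1$class_fractions), 1, tolerance = 1e-6)
  expect_equal(unname(rep1$class_fractions["normal"]), 1)
  expect_equal(nrow(rep1$events), 0)
  expect_true(is.na(rep1$dominant_abnormality))
  expect_equal(rep1$guidance, "maintain")
})

test_that("an injected abnormality surfaces in the report", {
  rec <- generate_session(list(list(pattern = "normal", duration_s = 6),
                               list(pattern = "m1_abn", duration_s = 6),
                               list(pattern = "normal", duration_s = 4)),
                          recording_config(seed = 73))
  st <- stream_classify(stream_fixture$model, rec, 1.5, 0.5)
  rep2 <- generate_report(st, rec)
  expect_gte(sum(rep2$events$label == "m1_abn"), 1)
  expect_equal(rep2$dominant_abnormality, "m1_abn")
  expect_equal(rep2$guidance, "unload_first_metatarsal")
  expect_equal(sum(rep2$class_fractions), 1, tolerance = 1e-6)
  # the M1 region peak is elevated relative to a clean session
  clean <- generate_session(list(list(pattern = "normal",
                                      duration_s = 16)),
                            recording_config(seed = 73))
  clean_rep <- generate_report(
    stream_classify(stream_fixture$model, clean, 1.5, 0.5), clean)
  expect_gt(rep2$region_peaks_kpa[["M1"]], clean_rep$region_peaks_kpa[["M1"]])
})

test_that("report JSON serialisation is byte-stable", {
  rec <- generate_session(list(list(pattern = "normal", duration_s = 6)),
                          recording_config(seed = 77))
  st <- stream_classify(stream_fixture$model, rec, 1.5, 0.5)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(generate_report(st, rec), p1)
  write_report(generate_report(st, rec), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("session comparison flags a successful correction", {
  before_rec <- generate_session(
    list(list(pattern = "pronator", duration_s = 8),
         list(pattern = "normal", duration_s = 4)),
    recording_config(seed = 81))
  after_rec <- generate_session(
    list(list(pattern = "normal", duration_s = 12)),
    recording_config(seed = 82))
  before <- generate_report(
    stream_classify(stream_fixture$model, before_rec, 1.5, 0.5), before_rec)
  after <- generate_report(
    stream_classify(stream_fixture$model, after_rec, 1.5, 0.5), after_rec)

  cmp <- compare_sessions(before, after)
  expect_true(cmp$corrected)
  expect_gt(cmp$abnormal_fraction_before, 0)
  expect_equal(cmp$abnormal_fraction_after, 0)
  expect_equal(unname(cmp$delta_fraction),
               unname(after$class_fractions - before$class_fractions))

  same <- compare_sessions(before, before)
  expect_equal(unname(same$delta_fraction), rep(0, 7))
  expect_equal(unname(same$delta_events), rep(0L, 7))
  expect_false(same$corrected)

  other_rule <- generate_report(
    stream_classify(stream_fixture$model, after_rec, 1.5, 0.5), after_rec,
    rule = warning_rule(min_consecutive_windows = 2))
  expect_error(compare_sessions(before, other_rule), "rules")
})
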