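#' Warning rule for the closed-loop feedback stage
#'
#' Debounce policy for real-time abnormality warnings: an event opens only
#' after `min_consecutive_windows` identical abnormal window labels, closes
#' when the label changes, and a new event with the same label is
#' suppressed within `cooldown_s` of the previous one's end.
#'
#' @param min_consecutive_windows Windows needed to open an event.
#' @param cooldown_s Same-label suppression period after an event, s.
#' @param abnormal_labels Labels treated as abnormal (default: the six
#'   non-normal gait labels).
#' @return List of class `warning_rule`.
#' @export
warning_rule <- function(min_consecutive_windows = 3L, cooldown_s = 5,
                         abnormal_labels = setdiff(gait_labels(),
                                                   "normal")) {
  stopifnot(min_consecutive_windows >= 1, cooldown_s >= 0)
  structure(list(
    min_consecutive_windows = as.integer(min_consecutive_windows),
    cooldown_s = cooldown_s,
    abnormal_labels = abnormal_labels
  ), class = "warning_rule")
}

#' Classify a recording in streaming windows
#'
#' Replays a recording through the trained classifier in sliding windows
#' (default 1.5 s window, 0.5 s stride), applying the model's stored
#' channel selection and normalisation to each raw window. The default
#' window is chosen to always cover one full gait cycle (1.24 +/- 0.02 s):
#' shorter windows can land mostly in the swing phase and are then
#' intrinsically ambiguous between patterns.
#'
#' @param model A trained `gait_cnn` (with stored preprocessing).
#' @param recording A `pressure_recording`.
#' @param window_s Window length, s; must match the frame count the model
#'   was trained on.
#' @param stride_s Stride, s.
#' @return Data frame with one row per window: `start_s`, `end_s`,
#'   `label`, `probability` (the argmax probability). Empty (with a
#'   warning) when the recording is shorter than one window.
#' @export
stream_classify <- function(model, recording, window_s = 1.5,
                            stride_s = 0.5) {
  stopifnot(inherits(model, "gait_cnn"),
            inherits(recording, "pressure_recording"))
  if (is.null(model$preproc))
    stop("model carries no preprocessing; train it on a dataset first")
  fs <- recording$config$sampling_rate
  wf <- round(window_s * fs)
  if (wf != model$preproc$window_frames)
    stop(sprintf(
      "window of %d frames does not match the model's input of %d frames",
      wf, model$preproc$window_frames))
  retained <- model$preproc$retained_channels
  if (max(retained) > ncol(recording$pressures))
    stop("recording has fewer channels than the model expects")
  wins <- windowize(recording, window_s, stride_s, channels = retained,
                    source_id = "stream")
  if (!length(wins))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0), probability = numeric(0)))
  rows <- lapply(wins, function(w) {
    x <- apply_norm(w$channels, model$preproc$norm)
    p <- forward(model, t(x))
    k <- argmax_class(p)
    data.frame(
      start_s = recording$times[w$source$offset_frames + 1L],
      end_s = recording$times[w$source$offset_frames + 1L] + window_s,
      label = model$classes[k],
      probability = unname(p[k])
    )
  })
  do.call(rbind, rows)
}

#' Detect debounced warning events in a window-label stream
#'
#' Scans chronologically ordered window labels with the rule's state
#' machine: a run of `min_consecutive_windows` identical abnormal labels
#' opens an event starting at the run's first window; the event closes
#' when the label changes; a same-label event starting within the
#' cooldown of the previous one's end is suppressed.
#'
#' @param stream Data frame from [stream_classify()] (needs `start_s`,
#'   `end_s`, `label`).
#' @param rule A [warning_rule()].
#' @return Data frame of events: `label`, `start_s`, `end_s`,
#'   `n_windows`; zero rows when nothing triggers.
#' @export
detect_warnings <- function(stream, rule = warning_rule()) {
  stopifnot(inherits(rule, "warning_rule"))
  empty <- data.frame(label = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_windows = integer(0))
  if (is.null(stream) || nrow(stream) == 0) return(empty)
  if (is.unsorted(stream$start_s))
    stop("stream windows must be in chronological order")
  events <- list()
  last_end <- list()  # per-label end time of the last emitted event
  run_label <- NA_character_
  run_start_idx <- NA_integer_
  open <- FALSE
  flush <- function(i_end) {
    lab <- run_label
    st <- stream$start_s[run_start_idx]
    en <- stream$end_s[i_end]
    prev <- last_end[[lab]]
    if (!is.null(prev) && (st - prev) < rule$cooldown_s) return(NULL)
    data.frame(label = lab, start_s = st, end_s = en,
               n_windows = i_end - run_start_idx + 1L)
  }
  n <- nrow(stream)
  for (i in seq_len(n)) {
    lab <- stream$label[i]
    if (identical(lab, run_label)) {
      run_len <- i - run_start_idx + 1L
    } else {
      if (open) {
        ev <- flush(i - 1L)
        if (!is.null(ev)) {
          events[[length(events) + 1L]] <- ev
          last_end[[ev$label]] <- ev$end_s
        }
      }
      run_label <- lab
      run_start_idx <- i
      run_len <- 1L
      open <- FALSE
    }
    if (!open && lab %in% rule$abnormal_labels &&
        run_len >= rule$min_consecutive_windows)
      open <- TRUE
  }
  if (open) {
    ev <- flush(n)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  if (!length(events)) return(empty)
  do.call(rbind, events)
}

# static guidance lookup: one entry per gait label
guidance_table <- c(
  normal = "maintain",
  supinator = "shift_weight_medially",
  pronator = "shift_weight_laterally",
  heel_abn = "soften_heel_strike",
  arch_abn = "support_arch",
  m1_abn = "unload_first_metatarsal",
  m5_abn = "unload_fifth_metatarsal"
)

#' Generate a session feedback report
#'
#' Summarises a completed walking session: per-class time fractions over
#' the classified windows, debounced warning events, the per-region
#' stance-phase peak pressures of the raw recording, the dominant
#' abnormality and a keyed correction-guidance entry.
#'
#' @param stream Data frame from [stream_classify()].
#' @param recording The raw session `pressure_recording`.
#' @param rule The [warning_rule()] used for the session.
#' @return Object of class `session_report`: `class_fractions` (over the
#'   7 labels, summing to 1), `events`, `region_peaks_kpa`,
#'   `dominant_abnormality` (`NA` if the session is clean), `guidance`,
#'   `n_windows`, `rule`.
#' @export
generate_report <- function(stream, recording, rule = warning_rule()) {
  if (is.null(stream) || nrow(stream) == 0)
    stop("session produced no classified windows")
  frac <- vapply(gait_labels(),
                 function(l) mean(stream$label == l), 0)
  events <- detect_warnings(stream, rule)
  peaks <- regional_stance_peaks(recording)
  abn_frac <- frac[setdiff(gait_labels(), "normal")]
  dominant <- if (any(abn_frac > 0))
    names(abn_frac)[which.max(abn_frac)] else NA_character_
  guide_key <- if (is.na(dominant)) "normal" else dominant
  structure(list(
    schema_version = 1L,
    class_fractions = frac,
    events = events,
    region_peaks_kpa = peaks,
    dominant_abnormality = dominant,
    guidance = unname(guidance_table[guide_key]),
    n_windows = nrow(stream),
    rule = rule
  ), class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>\n")
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable rendering of a session report
#' @param report A `session_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  fr <- report$class_fractions
  lines <- c(
    sprintf("windows: %d", report$n_windows),
    sprintf("  %-10s %5.1f%%", names(fr), 100 * fr),
    sprintf("warning events: %d", nrow(report$events)),
    if (nrow(report$events))
      sprintf("  [%s] %.1f-%.1f s (%d windows)", report$events$label,
              report$events$start_s, report$events$end_s,
              report$events$n_windows),
    sprintf("stance peaks (kPa): %s",
            paste(sprintf("%s=%.1f", names(report$region_peaks_kpa),
                          report$region_peaks_kpa), collapse = ", ")),
    sprintf("dominant abnormality: %s",
            ifelse(is.na(report$dominant_abnormality), "none",
                   report$dominant_abnormality)),
    sprintf("guidance: %s", report$guidance)
  )
  lines
}

#' Write a session report as versioned JSON
#'
#' Field order and number formatting are stable, so identical reports
#' serialise to identical bytes.
#'
#' @param report A `session_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  obj <- list(
    schema_version = report$schema_version,
    class_fractions = as.list(report$class_fractions),
    events = report$events,
    region_peaks_kpa = as.list(report$region_peaks_kpa),
    dominant_abnormality = report$dominant_abnormality,
    guidance = report$guidance,
    n_windows = report$n_windows,
    rule = unclass(report$rule)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Compare two session reports (before / after correction)
#'
#' @param before,after `session_report`s produced under the same rule.
#' @return List of class `session_comparison`: `delta_fraction` and
#'   `delta_events` per label (after minus before), `abnormal_fraction`
#'   for both sessions, and `corrected` (TRUE when the after-session
#'   abnormal fraction is zero).
#' @export
compare_sessions <- function(before, after) {
  stopifnot(inherits(before, "session_report"),
            inherits(after, "session_report"))
  if (!identical(unclass(before$rule), unclass(after$rule)))
    stop("reports were produced under different warning rules")
  labs <- gait_labels()
  count_events <- function(rep) {
    vapply(labs, function(l) sum(rep$events$label == l), 0L)
  }
  d_frac <- after$class_fractions[labs] - before$class_fractions[labs]
  d_events <- count_events(after) - count_events(before)
  abn <- setdiff(labs, "normal")
  abn_before <- sum(before$class_fractions[abn])
  abn_after <- sum(after$class_fractions[abn])
  structure(list(
    delta_fraction = d_frac,
    delta_events = d_events,
    abnormal_fraction_before = abn_before,
    abnormal_fraction_after = abn_after,
    corrected = abn_after == 0
  ), class = "session_comparison")
}
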