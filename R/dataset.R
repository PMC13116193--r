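#' Channel exclusion by pooled variance
#'
#' Identifies the insole channels with very small pressure changes and
#' excludes them from the dataset. A channel is retained when its variance
#' pooled across all recordings reaches `variance_threshold`; with
#' generator defaults the five near-inactive channels fall below the
#' threshold, leaving thirteen. The result preserves channel order and is
#' invariant to the order of the recordings.
#'
#' @param recordings List of `pressure_recording`s sharing a layout.
#' @param variance_threshold Pooled variance threshold, kPa^2 (default 1).
#' @return Integer vector of retained channel ids.
#' @export
exclude_channels <- function(recordings, variance_threshold = 1.0) {
  stopifnot(length(recordings) >= 1)
  regions <- recordings[[1]]$layout$region
  for (r in recordings)
    if (!identical(r$layout$region, regions))
      stop("recordings must share the same sensor layout")
  all_p <- do.call(rbind, lapply(recordings, `[[`, "pressures"))
  v <- apply(all_p, 2L, stats::var)
  keep <- which(v >= variance_threshold)
  if (!length(keep)) stop("no channels pass the variance threshold")
  as.integer(keep)
}

#' Cut a recording into fixed-length samples
#'
#' Slides a window of `window_s` seconds over the recording (stride equal
#' to the window by default, i.e. non-overlapping) and emits one gait
#' sample per complete window. Each sample carries window-local times, the
#' retained channels and the recording's label.
#'
#' @param recording A `pressure_recording`.
#' @param window_s Window length, s (> 0).
#' @param stride_s Stride, s (default: `window_s`).
#' @param channels Channel ids to keep (default: all 18).
#' @param source_id Identifier stored in each sample's provenance.
#' @return List of `gait_sample` objects (possibly empty, with a warning,
#'   when the recording is shorter than one window).
#' @export
windowize <- function(recording, window_s = 5, stride_s = window_s,
                      channels = NULL, source_id = "recording") {
  stopifnot(inherits(recording, "pressure_recording"))
  if (window_s <= 0) stop("window_s must be positive")
  if (stride_s <= 0) stop("stride_s must be positive")
  fs <- recording$config$sampling_rate
  wf <- round(window_s * fs)
  sf <- round(stride_s * fs)
  n <- nrow(recording$pressures)
  if (is.null(channels)) channels <- seq_len(ncol(recording$pressures))
  if (n < wf) {
    warning("recording shorter than one window; no samples produced")
    return(list())
  }
  starts <- seq(1L, n - wf + 1L, by = sf)
  lapply(starts, function(s0) {
    idx <- s0:(s0 + wf - 1L)
    structure(list(
      times = recording$times[idx] - recording$times[s0],
      channels = recording$pressures[idx, channels, drop = FALSE],
      label = recording$label,
      source = list(id = source_id, offset_frames = s0 - 1L)
    ), class = "gait_sample")
  })
}

#' Assemble a gait dataset from raw recordings
#'
#' Composes the dataset-construction rules: pooled-variance channel
#' exclusion, fixed-window cutting, and assembly into a labelled dataset
#' with recorded provenance. With generator defaults (7 patterns x 40
#' recordings, one 5 s window each) this yields 280 samples of 13
#' channels.
#'
#' @param recordings_by_pattern Named list: for each pattern label, a list
#'   of `pressure_recording`s.
#' @param window_s,stride_s Window and stride, s.
#' @param variance_threshold Channel-exclusion threshold, kPa^2.
#' @param seed Seed recorded for provenance and used by later splitting.
#' @return Object of class `gait_dataset`: `samples`, `retained_channels`,
#'   `classes`, `split` (NULL until [stratified_split()]), `norm` (NULL
#'   until [normalize_dataset()]), `seed`, `config`.
#' @export
build_dataset <- function(recordings_by_pattern, window_s = 5,
                          stride_s = window_s, variance_threshold = 1.0,
                          seed = 42L) {
  stopifnot(length(recordings_by_pattern) >= 1,
            !is.null(names(recordings_by_pattern)))
  all_recs <- unlist(recordings_by_pattern, recursive = FALSE)
  retained <- exclude_channels(all_recs, variance_threshold)
  samples <- list()
  for (lab in names(recordings_by_pattern)) {
    recs <- recordings_by_pattern[[lab]]
    lab_samples <- list()
    for (i in seq_along(recs)) {
      s <- windowize(recs[[i]], window_s, stride_s, channels = retained,
                     source_id = sprintf("%s_%02d", lab, i))
      lab_samples <- c(lab_samples, s)
    }
    if (!length(lab_samples))
      stop("pattern '", lab, "' produced no usable samples")
    samples <- c(samples, lab_samples)
  }
  structure(list(
    samples = samples,
    retained_channels = retained,
    classes = names(recordings_by_pattern),
    split = NULL,
    norm = NULL,
    seed = as.integer(seed),
    config = list(window_s = window_s, stride_s = stride_s,
                  variance_threshold = variance_threshold)
  ), class = "gait_dataset")
}

#' Default synthetic gait dataset
#'
#' Convenience wrapper reproducing the study's dataset construction on
#' synthetic data: 40 seeded recordings per gait pattern across all 7
#' patterns, one 5 s window each, pooled-variance channel exclusion.
#'
#' @param n_per_class Recordings per pattern (default 40).
#' @param seed Master seed; recording `i` of pattern `j` uses
#'   `seed + 1000 * j + i`.
#' @param window_s Window length, s.
#' @param cfg Base [recording_config()] (its seed is overridden per
#'   recording; its duration is set to `window_s`).
#' @return A `gait_dataset` with `n_per_class * 7` samples.
#' @export
default_gait_dataset <- function(n_per_class = 40L, seed = 42L,
                                 window_s = 5, cfg = recording_config()) {
  layout <- make_default_layout()
  by_pattern <- list()
  for (j in seq_along(gait_labels())) {
    lab <- gait_labels()[j]
    pat <- gait_pattern(lab)
    by_pattern[[lab]] <- lapply(seq_len(n_per_class), function(i) {
      rc <- cfg
      rc$duration_s <- window_s
      rc$seed <- as.integer(seed + 1000L * j + i)
      generate_recording(pat, rc, layout)
    })
  }
  build_dataset(by_pattern, window_s = window_s, seed = seed)
}

#' Stratified train/test split
#'
#' Randomly assigns samples to train and test within each class so that
#' the per-class train count is `round(fraction * class size)` (banker's
#' rounding; the remainder goes to test). With 40 samples per class and
#' fraction 0.5 this is the exact 20/20 split.
#'
#' @param dataset A `gait_dataset`.
#' @param fraction Train fraction in (0, 1).
#' @param seed Seed for the assignment (default: the dataset seed).
#' @return The dataset with `$split` set (character vector `"train"` /
#'   `"test"` per sample).
#' @export
stratified_split <- function(dataset, fraction = 0.5, seed = dataset$seed) {
  stopifnot(inherits(dataset, "gait_dataset"),
            fraction > 0, fraction < 1)
  labels <- vapply(dataset$samples, `[[`, "", "label")
  split <- character(length(labels))
  set.seed(seed)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < 2)
      stop("class '", lab, "' has fewer than 2 samples")
    n_train <- round(fraction * length(idx))
    if (n_train == 0 || n_train == length(idx))
      stop("class '", lab, "' would get an empty train or test split")
    train_idx <- sample(idx, n_train)
    split[idx] <- "test"
    split[train_idx] <- "train"
  }
  dataset$split <- split
  dataset$split_fraction <- fraction
  dataset$split_seed <- as.integer(seed)
  dataset
}

#' Normalise a dataset per channel
#'
#' Applies per-channel z-scoring with statistics fitted on the train split
#' only (pooled over that split's frames); the fitted transform is stored
#' on the dataset for reuse at inference time. A channel with zero
#' variance on the train split falls back to centering with a warning.
#' Re-normalising an already-normalised dataset is an error. The
#' `"identity"` scheme returns the dataset unchanged apart from recording
#' the scheme.
#'
#' @param dataset A split `gait_dataset`.
#' @param scheme `"zscore"` (default) or `"identity"`.
#' @return The dataset with transformed samples and `$norm` set to
#'   `list(scheme, mean, sd)`.
#' @export
normalize_dataset <- function(dataset, scheme = c("zscore", "identity")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "gait_dataset"))
  if (!is.null(dataset$norm))
    stop("dataset is already normalised; refusing to apply twice")
  if (scheme == "identity") {
    dataset$norm <- list(scheme = "identity")
    return(dataset)
  }
  if (is.null(dataset$split))
    stop("z-score normalisation needs a train split; run stratified_split first")
  train <- dataset$samples[dataset$split == "train"]
  pooled <- do.call(rbind, lapply(train, `[[`, "channels"))
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2L, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning("zero-variance channel(s) ",
            paste(which(zero), collapse = ","),
            " on the train split; falling back to centering for them")
    sdv[zero] <- 1
  }
  dataset$samples <- lapply(dataset$samples, function(s) {
    s$channels <- sweep(sweep(s$channels, 2L, mu), 2L, sdv, `/`)
    s
  })
  dataset$norm <- list(scheme = "zscore", mean = mu, sd = sdv)
  dataset
}

#' Apply a fitted normalisation to a raw channel matrix
#' @param x Frames x channels matrix on the raw kPa scale.
#' @param norm A `$norm` entry from a normalised dataset (or model).
#' @return Transformed matrix.
#' @export
apply_norm <- function(x, norm) {
  if (is.null(norm) || norm$scheme == "identity") return(x)
  sweep(sweep(x, 2L, norm$mean), 2L, norm$sd, `/`)
}

#' @export
print.gait_dataset <- function(x, ...) {
  labels <- vapply(x$samples, `[[`, "", "label")
  cat(sprintf(
    "<gait_dataset> %d samples, %d classes, %d channels%s%s\n",
    length(x$samples), length(unique(labels)),
    length(x$retained_channels),
    if (!is.null(x$split)) sprintf(", split %d/%d",
                                   sum(x$split == "train"),
                                   sum(x$split == "test")) else "",
    if (!is.null(x$norm)) paste0(", norm=", x$norm$scheme) else ""))
  invisible(x)
}

#' Save / load a gait dataset
#'
#' Writes a manifest JSON (classes, seeds, thresholds, retained channels,
#' split, normalisation) plus one comma-separated file per sample with
#' header `time_s,ch<id>...`. Numbers are formatted with 17 significant
#' digits so a round trip is lossless.
#'
#' @param dataset A `gait_dataset`.
#' @param dir Directory to write into (created if needed).
#' @return `save_dataset` returns `dir` invisibly; `load_dataset` the
#'   reconstructed `gait_dataset`.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = 1L,
    classes = dataset$classes,
    seed = dataset$seed,
    config = dataset$config,
    retained_channels = dataset$retained_channels,
    split = dataset$split,
    split_fraction = dataset$split_fraction,
    split_seed = dataset$split_seed,
    norm = dataset$norm,
    labels = vapply(dataset$samples, `[[`, "", "label"),
    sources = lapply(dataset$samples, `[[`, "source"),
    n_samples = length(dataset$samples)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    df <- data.frame(time_s = s$times, s$channels, check.names = FALSE)
    names(df) <- c("time_s", sprintf("ch%02d", dataset$retained_channels))
    fmt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
    lines <- c(paste(names(df), collapse = ","),
               apply(matrix(fmt, nrow = nrow(df)), 1L, paste, collapse = ","))
    writeLines(lines, file.path(dir, sprintf("sample_%04d.csv", i)))
  }
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  required <- c("classes", "seed", "retained_channels", "labels",
                "n_samples")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("dataset manifest is missing field(s): ",
         paste(missing, collapse = ", "))
  samples <- lapply(seq_len(m$n_samples), function(i) {
    df <- utils::read.table(file.path(dir, sprintf("sample_%04d.csv", i)),
                            sep = ",", header = TRUE, check.names = FALSE)
    structure(list(
      times = df$time_s,
      channels = as.matrix(df[, -1, drop = FALSE]),
      label = m$labels[i],
      source = m$sources[[i]]
    ), class = "gait_sample")
  })
  norm <- m$norm
  if (!is.null(norm) && !is.null(norm$mean)) {
    norm$mean <- unlist(norm$mean)
    norm$sd <- unlist(norm$sd)
  }
  structure(list(
    samples = samples,
    retained_channels = as.integer(m$retained_channels),
    classes = m$classes,
    split = m$split,
    split_fraction = m$split_fraction,
    split_seed = m$split_seed,
    norm = norm,
    seed = as.integer(m$seed),
    config = m$config
  ), class = "gait_dataset")
}
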