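#' Configuration for the synthetic EEG generator
#'
#' Defines the statistical structure of the simulated recording: a 1/f
#' ("pink") background shared by all classes, a low-amplitude 7--9 Hz
#' rhythm marking the preictal class, and a high-amplitude ~3 Hz
#' spike-wave discharge marking the ictal class.
#'
#' @param sampling_rate Samples per second (Hz). Default 256.
#' @param n_channels Number of EEG channels (>= 1). Default 6, a minimal
#'   scalp montage of the size commonly retained for seizure detection.
#' @param segment_length_s Window length in seconds; one of 1, 2 or 4.
#' @param background_amp Root-mean-square scale of the 1/f background, in
#'   microvolts. Default 20.
#' @param ictal_spike_freq Fundamental frequency of the ictal spike-wave
#'   train in Hz. Default 3.
#' @param ictal_amp_ratio Peak amplitude of the ictal discharge as a
#'   multiple of `background_amp`; must be > 1. Default 5.
#' @param preictal_drift_amp Amplitude (microvolts) of the preictal
#'   rhythmic drift. Default `1.5 * background_amp`.
#' @param seed Integer seed controlling all randomness downstream.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate = 256,
                             n_channels = 6L,
                             segment_length_s = 4,
                             background_amp = 20,
                             ictal_spike_freq = 3,
                             ictal_amp_ratio = 5,
                             preictal_drift_amp = 1.5 * background_amp,
                             seed = 1L) {
  assert_scalar_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  assert_scalar_number(n_channels, "n_channels", 1)
  if (!segment_length_s %in% c(1, 2, 4)) {
    stop("`segment_length_s` must be one of 1, 2 or 4 seconds", call. = FALSE)
  }
  n_samples <- sampling_rate * segment_length_s
  if (abs(n_samples - round(n_samples)) > 1e-9 || n_samples < 8) {
    stop("sampling_rate * segment_length_s must be an integer >= 8", call. = FALSE)
  }
  assert_scalar_number(background_amp, "background_amp", 0)
  assert_scalar_number(ictal_spike_freq, "ictal_spike_freq", 0, strict = TRUE)
  assert_scalar_number(ictal_amp_ratio, "ictal_amp_ratio", 1, strict = TRUE)
  assert_scalar_number(preictal_drift_amp, "preictal_drift_amp", 0)
  structure(
    list(
      sampling_rate = sampling_rate,
      n_channels = as.integer(n_channels),
      segment_length_s = segment_length_s,
      background_amp = background_amp,
      ictal_spike_freq = ictal_spike_freq,
      ictal_amp_ratio = ictal_amp_ratio,
      preictal_drift_amp = preictal_drift_amp,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

eeg_labels <- function() c("normal", "preictal", "ictal")

# 1/f background: ~40 random-phase sinusoids with amplitude decaying as
# 1/f, rescaled to the requested RMS, plus a white-noise floor.
pink_background <- function(n, fs, amp, n_components = 40L) {
  t <- (seq_len(n) - 1L) / fs
  freqs <- runif(n_components, 0.5, 45)
  phases <- runif(n_components, 0, 2 * pi)
  weights <- 1 / freqs
  x <- drop(sin(outer(2 * pi * t, freqs) + rep(phases, each = n)) %*% weights)
  sdx <- stats::sd(x)
  if (sdx > 0) x <- x / sdx
  amp * (sqrt(0.8) * x + sqrt(0.2) * stats::rnorm(n))
}

# Ictal morphology: a spike-and-wave surrogate built from a half-wave
# rectified, sharpened sinusoid. The exponent 12 narrows the spike to a
# ~55 ms width at 3 Hz (the physiological 50-70 ms range), giving it the
# sharp transients real discharges show; the rectified-squared opposite
# half-cycle supplies the slow wave. Mean-centred so the discharge adds
# no DC offset.
spike_wave <- function(n, fs, freq, peak_amp) {
  t <- (seq_len(n) - 1L) / fs
  phase <- runif(1, 0, 2 * pi)
  s <- sin(2 * pi * freq * t + phase)
  w <- pmax(s, 0)^12 + 0.6 * pmax(-s, 0)^2
  peak_amp * (w - mean(w))
}

preictal_rhythm <- function(n, fs, amp) {
  t <- (seq_len(n) - 1L) / fs
  f0 <- runif(1, 7, 9)
  amp * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
}

#' Generate a single labelled EEG segment
#'
#' @param label One of `"normal"`, `"preictal"`, `"ictal"`.
#' @param config A [generator_config()].
#' @param seed Seed for this segment; defaults to `config$seed`.
#' @param segment_id Optional identifier stored with the segment.
#'
#' @return An `eeg_segment`: a list with `samples` (channels x time matrix,
#'   microvolts), `sampling_rate`, `label` and `segment_id`.
#' @export
generate_segment <- function(label, config, seed = config$seed,
                             segment_id = NULL) {
  if (!is.character(label) || length(label) != 1L || !label %in% eeg_labels()) {
    stop(sprintf("unknown label '%s'; expected one of %s",
                 paste(label, collapse = ","),
                 paste(eeg_labels(), collapse = ", ")), call. = FALSE)
  }
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(round(config$sampling_rate * config$segment_length_s))
  samples <- with_local_seed(seed, {
    m <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      x <- pink_background(n, config$sampling_rate, config$background_amp)
      if (label == "preictal") {
        x <- x + preictal_rhythm(n, config$sampling_rate, config$preictal_drift_amp)
      } else if (label == "ictal") {
        x <- x + spike_wave(n, config$sampling_rate, config$ictal_spike_freq,
                            config$ictal_amp_ratio * config$background_amp)
      }
      m[ch, ] <- x
    }
    m
  })
  rownames(samples) <- paste0("ch", seq_len(config$n_channels))
  structure(
    list(
      samples = samples,
      sampling_rate = config$sampling_rate,
      label = label,
      segment_id = segment_id %||% sprintf("%s_seed%d", label, as.integer(seed))
    ),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment %s> %d channel(s) x %d samples @ %g Hz, label '%s'\n",
              x$segment_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate, x$label))
  invisible(x)
}

#' Generate a balanced labelled dataset of EEG segments
#'
#' Emits exactly `n_per_class` segments for each of the three classes,
#' with per-segment sub-seeds derived deterministically from `config$seed`.
#'
#' @param n_per_class Segments per class (>= 1).
#' @param config A [generator_config()].
#'
#' @return A list of `eeg_segment` objects, normal first, then preictal,
#'   then ictal.
#' @export
generate_dataset <- function(n_per_class, config) {
  assert_scalar_number(n_per_class, "n_per_class", 1)
  stopifnot(inherits(config, "generator_config"))
  n_per_class <- as.integer(n_per_class)
  labels <- rep(eeg_labels(), each = n_per_class)
  seeds <- derive_seeds(config$seed, length(labels))
  ids <- sprintf("%s_%03d", labels, rep(seq_len(n_per_class), times = 3L))
  Map(function(lab, sd, id) generate_segment(lab, config, seed = sd, segment_id = id),
      labels, seeds, ids, USE.NAMES = FALSE)
}

#' Write EEG segments to disk (CSV or EDF) with a JSON manifest
#'
#' CSV files contain one row per sample and one column per channel; EDF
#' files use the plain (non-plus) 16-bit EDF dialect with one data record
#' per second. Labels and sampling rates are stored in `manifest.json`
#' beside the data files.
#'
#' @param segments Non-empty list of `eeg_segment` objects.
#' @param path Output directory (created if missing).
#' @param format `"csv"` or `"edf"`.
#'
#' @return Invisibly, the manifest as a data frame.
#' @export
write_segments <- function(segments, path, format = c("csv", "edf")) {
  if (length(segments) == 0L) stop("`segments` must be non-empty", call. = FALSE)
  format <- match.arg(format)
  stopifnot(all(vapply(segments, inherits, logical(1), "eeg_segment")))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    fname <- sprintf("%s.%s", seg$segment_id, format)
    fpath <- file.path(path, fname)
    if (format == "csv") {
      utils::write.csv(as.data.frame(t(seg$samples)), fpath, row.names = FALSE)
    } else {
      write_edf(seg, fpath)
    }
    files[i] <- fname
  }
  manifest <- data.frame(
    segment_id = vapply(segments, `[[`, character(1), "segment_id"),
    label = vapply(segments, `[[`, character(1), "label"),
    sampling_rate = vapply(segments, `[[`, numeric(1), "sampling_rate"),
    file = files,
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       dataframe = "rows", auto_unbox = FALSE)
  invisible(manifest)
}

#' Read EEG segments previously written by [write_segments()]
#'
#' @param path Directory containing data files and `manifest.json`.
#' @return A list of `eeg_segment` objects in manifest order.
#' @export
read_segments <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json found in ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest)), function(i) {
    fpath <- file.path(path, manifest$file[i])
    if (grepl("\\.csv$", fpath)) {
      df <- utils::read.csv(fpath)
      samples <- t(as.matrix(df))
    } else {
      samples <- read_edf(fpath)$samples
    }
    structure(
      list(samples = samples,
           sampling_rate = manifest$sampling_rate[i],
           label = manifest$label[i],
           segment_id = manifest$segment_id[i]),
      class = "eeg_segment"
    )
  })
}
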