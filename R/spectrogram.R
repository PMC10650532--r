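#' Short-time Fourier transform parameters
#'
#' Defaults: Hann window of `sampling_rate / 4` samples, 75% overlap, FFT
#' length the next power of two at or above the window length. The window
#' is set at config time from the sampling rate if not given.
#'
#' @param window Window length in samples, or `NULL` to derive from the
#'   segment's sampling rate.
#' @param overlap Fractional overlap between consecutive windows in
#'   \[0, 1).
#' @param nfft FFT length, or `NULL` for the next power of two >= window.
#' @param max_freq Upper edge (Hz) of the retained frequency band, or
#'   `NULL` to keep the full band up to Nyquist. EEG carries its clinical
#'   information below ~40 Hz, so the image is cropped there by default;
#'   quantization happens after the crop.
#' @return A list of class `stft_params`.
#' @export
stft_params <- function(window = NULL, overlap = 0.75, nfft = NULL,
                        max_freq = 40) {
  if (!is.null(window)) assert_scalar_number(window, "window", 4)
  assert_scalar_number(overlap, "overlap", 0)
  if (overlap >= 1) stop("`overlap` must be < 1", call. = FALSE)
  if (!is.null(nfft)) assert_scalar_number(nfft, "nfft", 4)
  if (!is.null(max_freq)) assert_scalar_number(max_freq, "max_freq", 0, strict = TRUE)
  structure(list(window = window, overlap = overlap, nfft = nfft,
                 max_freq = max_freq),
            class = "stft_params")
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Convert one EEG channel into a quantized spectrogram image
#'
#' The channel is (optionally) passed through the discrete Teager-Kaiser
#' energy operator, then short-time Fourier transformed; the magnitude is
#' log-scaled and min-max quantized to 8-bit integers. A flat (all-equal)
#' magnitude surface maps to an all-zero image rather than dividing by
#' zero.
#'
#' @param segment An `eeg_segment`.
#' @param channel Channel index (row of `segment$samples`).
#' @param params An [stft_params()] object.
#' @param apply_tkeo If `TRUE` (default) the TKEO series is transformed
#'   rather than the raw signal; the raw-signal option is kept for
#'   ablation.
#'
#' @return A `spectrogram_image`: list with `pixels` (frequency x time
#'   integer matrix in \[0, 255\], low frequencies in row 1), `freq`, `time`,
#'   `side` (NA until square-resized), `source_channel` and `label`.
#' @export
to_spectrogram <- function(segment, channel = 1L, params = stft_params(),
                           apply_tkeo = TRUE) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (channel < 1L || channel > nrow(segment$samples)) {
    stop("channel ", channel, " does not exist", call. = FALSE)
  }
  x <- segment$samples[channel, ]
  fs <- segment$sampling_rate
  # a one-second window resolves the ~3 Hz spike-wave comb (Hann mainlobe
  # half-width 2/T Hz); shorter windows smear it into the 1/f background
  win <- params$window %||% min(length(x), max(8L, round(fs)))
  if (win > length(x)) {
    stop("STFT window (", win, ") longer than segment (", length(x), ")",
         call. = FALSE)
  }
  nfft <- params$nfft %||% next_pow2(win)
  if (apply_tkeo) x <- tkeo_discrete(x)$values
  sg <- signal::specgram(x, n = nfft, Fs = fs,
                         window = signal::hanning(win),
                         overlap = floor(params$overlap * win))
  freq <- as.numeric(sg$f)
  mag <- abs(sg$S)
  # a window spanning the whole segment yields a single frame (a vector)
  if (is.null(dim(mag))) mag <- matrix(mag, ncol = 1L)
  if (!is.null(params$max_freq) && params$max_freq < fs / 2) {
    keep <- freq <= params$max_freq
    mag <- mag[keep, , drop = FALSE]
    freq <- freq[keep]
  }
  lg <- log10(mag + 1e-12)
  rng <- range(lg)
  pixels <- if (rng[2] - rng[1] <= 0) {
    matrix(0L, nrow(lg), ncol(lg))
  } else {
    matrix(as.integer(round(255 * (lg - rng[1]) / (rng[2] - rng[1]))),
           nrow(lg), ncol(lg))
  }
  structure(
    list(pixels = pixels, freq = freq, time = as.numeric(sg$t),
         side = NA_integer_, source_channel = channel, label = segment$label),
    class = "spectrogram_image"
  )
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image> %d x %d pixels, label '%s', channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$label %||% "?",
              x$source_channel %||% "?"))
  invisible(x)
}

#' Resize a spectrogram image to a square side
#'
#' Bilinear interpolation on the pixel grid, re-clamped and re-quantized
#' to \[0, 255\]. A resize to the image's own (already square) size is the
#' identity.
#'
#' @param image A `spectrogram_image`.
#' @param side Target side in pixels (>= 8), e.g. 227 for AlexNet-shaped
#'   inputs or 224 for GoogLeNet/ResNet-50-shaped inputs.
#' @return A square `spectrogram_image` with `side` set.
#' @export
resize_image <- function(image, side) {
  stopifnot(inherits(image, "spectrogram_image"))
  assert_scalar_number(side, "side", 8)
  side <- as.integer(side)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr == side && nc == side) {
    out <- image
    out$side <- side
    return(out)
  }
  # duplicate degenerate single-row/column images so bilinear
  # interpolation has a grid to work on (values are constant along the
  # duplicated axis)
  if (nr == 1L) {
    px <- px[c(1L, 1L), , drop = FALSE]
    nr <- 2L
  }
  if (nc == 1L) {
    px <- px[, c(1L, 1L), drop = FALSE]
    nc <- 2L
  }
  # pracma::interp2 expects Z as length(y) x length(x)
  yq <- seq(1, nr, length.out = side)
  xq <- seq(1, nc, length.out = side)
  grid_x <- rep(xq, each = side)
  grid_y <- rep(yq, times = side)
  vals <- pracma::interp2(x = seq_len(nc), y = seq_len(nr), Z = px,
                          xp = grid_x, yp = grid_y, method = "linear")
  out <- image
  out$pixels <- matrix(as.integer(round(clamp(vals, 0, 255))), side, side)
  out$side <- side
  out$freq <- NULL
  out$time <- NULL
  out
}

#' Write a spectrogram image as 8-bit grayscale PNG with a JSON sidecar
#'
#' @param image A `spectrogram_image`.
#' @param path Output PNG path; the sidecar is written as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_spectrogram_png <- function(image, path) {
  stopifnot(inherits(image, "spectrogram_image"))
  png::writePNG(image$pixels / 255, path)
  jsonlite::write_json(
    list(label = image$label, source_channel = image$source_channel,
         side = image$side),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' Read a spectrogram image written by [write_spectrogram_png()]
#'
#' @param path PNG path.
#' @return A `spectrogram_image`.
#' @export
read_spectrogram_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  pixels <- matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
  meta <- list(label = NULL, source_channel = NULL, side = NA_integer_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  structure(
    list(pixels = pixels, freq = NULL, time = NULL,
         side = meta$side %||% NA_integer_,
         source_channel = meta$source_channel, label = meta$label),
    class = "spectrogram_image"
  )
}
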