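# Minimal EDF (European Data Format, not EDF+) writer and reader.
#
# Dialect: one data record per second; per-channel physical range taken
# from the data; digital range -32768..32767; 16-bit little-endian
# samples. Sufficient for round-tripping simulated segments and for
# interchange with standard EDF readers; annotations and EDF+ fields are
# not supported.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

# Render a number into at most 8 ASCII characters (the EDF physical
# min/max field width), dropping precision only as far as needed.
edf_num <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8L) return(s)
    }
    stop("value does not fit an 8-character EDF field: ", v, call. = FALSE)
  }, character(1))
}

#' Write one EEG segment as an EDF file
#'
#' @param segment An `eeg_segment`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(segment, path) {
  stopifnot(inherits(segment, "eeg_segment"))
  ns <- nrow(segment$samples)
  fs <- segment$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n_records <- ncol(segment$samples) / fs
  if (abs(n_records - round(n_records)) > 1e-9) {
    stop("segment length must be a whole number of seconds for EDF", call. = FALSE)
  }
  n_records <- as.integer(round(n_records))

  phys_min <- apply(segment$samples, 1, min)
  phys_max <- apply(segment$samples, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad(segment$segment_id, 80),       # patient id field (reused)
    edf_pad("chaoseeg synthetic", 80),     # recording id
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256L + 256L * ns, 8),          # header length
    edf_pad("", 44),                       # reserved
    edf_pad(n_records, 8),
    edf_pad(1L, 8),                        # record duration, seconds
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width), collapse = ""),
              con, eos = NULL)
  }
  chn <- rownames(segment$samples) %||% paste0("ch", seq_len(ns))
  field(chn, 16)                                   # label
  field(rep("", ns), 80)                           # transducer
  field(rep("uV", ns), 8)                          # physical dimension
  field(edf_num(phys_min), 8)
  field(edf_num(phys_max), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                           # prefiltering
  field(rep(fs, ns), 8)                            # samples per record
  field(rep("", ns), 32)                           # reserved

  # physical values must be recovered from the ASCII header, so quantize
  # against the header's (rounded) physical range, not the raw one
  pmin_hdr <- as.numeric(edf_num(phys_min))
  pmax_hdr <- as.numeric(edf_num(phys_max))
  gain <- (pmax_hdr - pmin_hdr) / (dig_max - dig_min)
  for (rec in seq_len(n_records)) {
    idx <- ((rec - 1L) * fs + 1L):(rec * fs)
    for (ch in seq_len(ns)) {
      x <- segment$samples[ch, idx]
      d <- round((x - pmin_hdr[ch]) / gain[ch]) + dig_min
      d <- as.integer(clamp(d, dig_min, dig_max))
      writeBin(d, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain 16-bit EDF)
#'
#' @param path EDF file path.
#' @return A list with `samples` (channels x time), `sampling_rate`,
#'   `channel_labels` and `segment_id` (the EDF patient-identification
#'   field).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file: ", path, call. = FALSE)
  patient <- rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width, as = identity) {
    vapply(seq_len(ns), function(i) as(rd(width)), vector(mode(as("1")), 1))
  }
  labels <- rdv(16, as.character)
  rdv(80, as.character); rdv(8, as.character)
  phys_min <- rdv(8, as.numeric)
  phys_max <- rdv(8, as.numeric)
  dig_min <- rdv(8, as.numeric)
  dig_max <- rdv(8, as.numeric)
  rdv(80, as.character)
  spr <- rdv(8, as.numeric)
  rdv(32, as.character)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (rec in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2L,
                   endian = "little", signed = TRUE)
      idx <- ((rec - 1L) * spr[ch] + 1L):(rec * spr[ch])
      samples[ch, idx] <- phys_min[ch] + (d - dig_min[ch]) * gain[ch]
    }
  }
  rownames(samples) <- labels
  list(samples = samples,
       sampling_rate = spr[1] / rec_dur,
       channel_labels = labels,
       segment_id = patient)
}
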