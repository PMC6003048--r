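## Multichannel signal containers and EDF/CSV input-output.

#' Single-channel sampled signal
#'
#' Container for one sensor's sampled amplitude trace, interpreted as a
#' piecewise-linear function of time. Amplitudes are in microvolts.
#'
#' @param samples Numeric vector of amplitudes (microvolts), length >= 1,
#'   all finite.
#' @param fs Sampling frequency in Hz, a single positive number.
#' @param sensor_id Integer sensor identifier (1-based montage position).
#' @param sensor_label Character label of the sensor (e.g. a 10-20 system
#'   bipolar derivation such as \code{"FP1-F7"}).
#'
#' @return An object of class \code{channel_signal}: a list with elements
#'   \code{samples}, \code{fs}, \code{sensor_id}, \code{sensor_label}.
#' @export
#' @examples
#' s <- channel_signal(c(0, 2, 1), fs = 1)
#' length(s$samples)
channel_signal <- function(samples, fs, sensor_id = 1L, sensor_label = paste0("CH", sensor_id)) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    ts_error("data_error", "a channel signal needs at least one sample")
  if (!all(is.finite(samples)))
    ts_error("data_error", "channel amplitudes must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    ts_error("config_error", "fs must be a single positive number")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         sensor_id = as.integer(sensor_id),
         sensor_label = as.character(sensor_label)),
    class = "channel_signal"
  )
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %s (id %d): %d samples at %g Hz\n",
              x$sensor_label, x$sensor_id, length(x$samples), x$fs))
  invisible(x)
}

#' Multichannel recording
#'
#' Bundles the channels of one recording session (23 bipolar derivations in
#' the scalp-EEG setting this package targets, but any number >= 1 is
#' accepted). All channels must share sampling frequency and length.
#'
#' @param channels List of \code{\link{channel_signal}} objects.
#' @param patient_id Character identifier of the subject/recording.
#' @param label Class label: \code{"epileptic"}, \code{"healthy"} or
#'   \code{"unknown"}.
#'
#' @return An object of class \code{recording}.
#' @export
recording <- function(channels, patient_id = "unknown", label = "unknown") {
  if (!is.list(channels))
    ts_error("data_error", "channels must be a list of channel_signal objects")
  if (length(channels) > 0L) {
    ok <- vapply(channels, inherits, logical(1), "channel_signal")
    if (!all(ok)) ts_error("data_error", "all channels must be channel_signal objects")
    fs <- vapply(channels, function(ch) ch$fs, numeric(1))
    ns <- vapply(channels, function(ch) length(ch$samples), integer(1))
    if (length(unique(fs)) != 1L)
      ts_error("data_error", "all channels must share the same sampling frequency")
    if (length(unique(ns)) != 1L)
      ts_error("data_error", "all channels must have the same number of samples")
  }
  label <- match.arg(label, c("epileptic", "healthy", "unknown"))
  structure(list(channels = channels, patient_id = as.character(patient_id),
                 label = label),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$channels)
  if (n == 0L) {
    cat(sprintf("<recording> %s: empty (label: %s)\n", x$patient_id, x$label))
  } else {
    cat(sprintf("<recording> %s: %d channels x %d samples at %g Hz (label: %s)\n",
                x$patient_id, n, length(x$channels[[1L]]$samples),
                x$channels[[1L]]$fs, x$label))
  }
  invisible(x)
}

#' @rdname recording
#' @param x A \code{recording}.
#' @export
n_channels <- function(x) length(x$channels)

#' @rdname recording
#' @export
n_samples <- function(x) if (length(x$channels)) length(x$channels[[1L]]$samples) else 0L

#' Labeled collection of recordings
#'
#' @param recordings List of \code{\link{recording}} objects.
#' @return An object of class \code{eeg_dataset}.
#' @export
eeg_dataset <- function(recordings) {
  if (!is.list(recordings) ||
      (length(recordings) && !all(vapply(recordings, inherits, logical(1), "recording"))))
    ts_error("data_error", "recordings must be a list of recording objects")
  structure(list(recordings = recordings), class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- vapply(x$recordings, function(r) r$label, character(1))
  cat(sprintf("<eeg_dataset> %d recordings (%s)\n", length(x$recordings),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)), collapse = ", ")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## CSV input/output: one column per channel, one header row of sensor labels,
## one row per sample, '.' decimal, comma separator.

#' Read a multichannel recording from CSV
#'
#' The CSV dialect is: comma-separated, one header row of sensor labels, one
#' column per channel, one row per sample. The sampling frequency is not part
#' of the format and must be supplied.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling frequency in Hz to attach to every channel.
#' @param patient_id,label Metadata attached to the returned recording.
#' @return A \code{\link{recording}}.
#' @export
read_recording_csv <- function(path, fs = 256, patient_id = basename(path),
                               label = "unknown") {
  if (!file.exists(path)) ts_error("format_error", paste("file not found:", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) ts_error("format_error", paste("unparseable CSV:", conditionMessage(e)))
  )
  if (nrow(df) < 1L || ncol(df) < 1L)
    ts_error("format_error", "CSV contains no samples")
  chans <- lapply(seq_len(ncol(df)), function(i)
    channel_signal(df[[i]], fs = fs, sensor_id = i, sensor_label = names(df)[i]))
  recording(chans, patient_id = patient_id, label = label)
}

#' Write a multichannel recording to CSV
#'
#' @param rec A \code{\link{recording}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  if (!inherits(rec, "recording")) ts_error("data_error", "rec must be a recording")
  mat <- vapply(rec$channels, function(ch) ch$samples, numeric(n_samples(rec)))
  mat <- matrix(mat, nrow = n_samples(rec))
  colnames(mat) <- vapply(rec$channels, function(ch) ch$sensor_label, character(1))
  utils::write.csv(mat, path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## EDF (European Data Format) input/output. Minimal reader/writer for
## continuous EDF: fixed-width ASCII headers, 16-bit little-endian samples,
## linear digital-to-physical scaling. EDF+ annotations are out of scope.

edf_read_ascii <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n) ts_error("format_error", "truncated EDF header")
  trimws(raw)
}

#' Read an EDF file
#'
#' Reads a continuous European Data Format file into a
#' \code{\link{recording}}. Digital values are mapped to physical units with
#' the per-signal linear calibration from the header; physical units are
#' assumed to be microvolts and are not converted.
#'
#' @param path Path to the EDF file.
#' @param montage Optional character vector of channel labels; the recording
#'   contains exactly these channels in this order. Default: all channels in
#'   file order.
#' @param patient_id,label Metadata for the returned recording; default
#'   patient id is taken from the EDF local patient identification field.
#' @return A \code{\link{recording}}; sensor ids are montage positions
#'   (1-based).
#' @export
read_edf <- function(path, montage = NULL, patient_id = NULL, label = "unknown") {
  if (!file.exists(path)) ts_error("format_error", paste("file not found:", path))
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edf_read_ascii(con, 8L)
  if (version != "0") ts_error("format_error", "not an EDF file (bad version field)")
  pat_field <- edf_read_ascii(con, 80L)
  edf_read_ascii(con, 80L)  # recording id
  edf_read_ascii(con, 8L)   # start date
  edf_read_ascii(con, 8L)   # start time
  edf_read_ascii(con, 8L)   # header byte count
  edf_read_ascii(con, 44L)  # reserved
  n_records <- suppressWarnings(as.integer(edf_read_ascii(con, 8L)))
  duration <- suppressWarnings(as.numeric(edf_read_ascii(con, 8L)))
  ns <- suppressWarnings(as.integer(edf_read_ascii(con, 4L)))
  if (is.na(n_records) || is.na(duration) || is.na(ns) || ns < 1L)
    ts_error("format_error", "malformed EDF header")

  rd <- function(w) vapply(seq_len(ns), function(i) edf_read_ascii(con, w), character(1))
  labels <- rd(16L)
  rd(80L)                                   # transducer
  rd(8L)                                    # physical dimension
  phys_min <- as.numeric(rd(8L))
  phys_max <- as.numeric(rd(8L))
  dig_min <- as.numeric(rd(8L))
  dig_max <- as.numeric(rd(8L))
  rd(80L)                                   # prefiltering
  nr <- as.integer(rd(8L))
  rd(32L)                                   # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, nr)))
    ts_error("format_error", "malformed EDF signal headers")

  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- vector("list", n_records)
  for (rec_i in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = nr[i], size = 2L, signed = TRUE,
                      endian = "little")
      if (length(vals) != nr[i]) ts_error("format_error", "truncated EDF data record")
      data[[i]][[rec_i]] <- vals
    }
  }

  idx <- seq_len(ns)
  if (!is.null(montage)) {
    idx <- match(montage, labels)
    if (anyNA(idx))
      ts_error("missing_channel_error",
               paste("channel(s) not in file:",
                     paste(montage[is.na(idx)], collapse = ", ")))
  }
  chans <- lapply(seq_along(idx), function(pos) {
    i <- idx[pos]
    dig <- as.numeric(unlist(data[[i]], use.names = FALSE))
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- (dig - dig_min[i]) * scale + phys_min[i]
    fs <- nr[i] / duration
    ## the 8-character duration field limits precision; sampling rates are
    ## integers in practice, so snap when within 0.1%
    if (abs(fs - round(fs)) < 1e-3 * max(1, round(fs))) fs <- round(fs)
    channel_signal(phys, fs = fs, sensor_id = pos, sensor_label = labels[i])
  })
  recording(chans, patient_id = patient_id %||% pat_field, label = label)
}

#' Write an EDF file
#'
#' Minimal continuous-EDF writer: one data record holding the whole
#' recording, 16-bit samples, per-channel physical range taken from the data.
#' Quantisation to the 16-bit digital range limits round-trip precision to
#' about 1/65000 of each channel's amplitude range.
#'
#' @param rec A \code{\link{recording}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "recording") || n_channels(rec) < 1L)
    ts_error("data_error", "rec must be a recording with at least one channel")
  ns <- n_channels(rec)
  nsamp <- n_samples(rec)
  fs <- rec$channels[[1L]]$fs
  duration <- nsamp / fs

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(edf_field(x, w), con, eos = NULL)

  wr("0", 8L)
  wr(rec$patient_id, 80L)
  wr("toposeize export", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(256L + ns * 256L, 8L)
  wr("", 44L)
  wr(1L, 8L)                      # one data record
  wr(format(duration, digits = 7), 8L)
  wr(ns, 4L)

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]$samples
    phys_min[i] <- min(x); phys_max[i] <- max(x)
    if (phys_max[i] == phys_min[i]) phys_max[i] <- phys_min[i] + 1
  }
  for (i in seq_len(ns)) wr(rec$channels[[i]]$sensor_label, 16L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr("uV", 8L)
  for (i in seq_len(ns)) wr(format(phys_min[i], digits = 7), 8L)
  for (i in seq_len(ns)) wr(format(phys_max[i], digits = 7), 8L)
  for (i in seq_len(ns)) wr(-32768L, 8L)
  for (i in seq_len(ns)) wr(32767L, 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(nsamp, 8L)
  for (i in seq_len(ns)) wr("", 32L)

  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]$samples
    dig <- round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}
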