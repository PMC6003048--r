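## Denoising and downsampling ahead of topological feature extraction.
## All filters are applied forward-backward (zero phase): the downstream
## feature depends on the positions and depths of signal extrema, which
## phase distortion would move.

#' Preprocessing configuration
#'
#' @param band_low,band_high Band-pass corner frequencies in Hz
#'   (defaults 1 and 70).
#' @param notch_freq Power-line notch centre frequency in Hz (default 50;
#'   set to \code{NA} to skip the notch).
#' @param notch_q Quality factor of the notch (centre / -3 dB width).
#' @param decimation_factor Integer downsampling factor (default 10).
#' @param wide_notch If \code{TRUE}, replace the narrow power-line notch by a
#'   literal band-stop over 8-52 Hz. Not recommended: it removes most of the
#'   physiological EEG band; provided only to reproduce a published variant
#'   of the pipeline verbatim.
#'
#' @return A list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(band_low = 1, band_high = 70, notch_freq = 50,
                              notch_q = 30, decimation_factor = 10,
                              wide_notch = FALSE) {
  if (!is.na(band_low) && (band_low <= 0 || band_low >= band_high))
    ts_error("config_error", "need 0 < band_low < band_high")
  df <- decimation_factor
  if (length(df) != 1L || is.na(df) || df < 1 || df != round(df))
    ts_error("config_error", "decimation_factor must be a positive integer")
  structure(list(band_low = band_low, band_high = band_high,
                 notch_freq = notch_freq, notch_q = notch_q,
                 decimation_factor = as.integer(df), wide_notch = wide_notch),
            class = "preprocess_config")
}

## Zero-phase application of an ARMA filter to a channel's samples.
apply_filtfilt <- function(filt, x) {
  as.numeric(signal::filtfilt(filt, x))
}

#' Band-pass filter a channel
#'
#' Fourth-order Butterworth band-pass, applied forward-backward so the net
#' phase response is zero and the effective attenuation is the squared
#' magnitude response.
#'
#' @param sig A \code{\link{channel_signal}}.
#' @param low,high Corner frequencies in Hz; must satisfy
#'   \code{low < high < fs/2}.
#' @return A filtered \code{\link{channel_signal}} of the same length and fs.
#' @export
bandpass <- function(sig, low = 1, high = 70) {
  if (!inherits(sig, "channel_signal")) ts_error("data_error", "sig must be a channel_signal")
  nyq <- sig$fs / 2
  if (!(low > 0 && low < high)) ts_error("config_error", "need 0 < low < high")
  if (high >= nyq) ts_error("config_error", "high corner must be below fs/2")
  bw <- signal::butter(4, c(low, high) / nyq, type = "pass")
  out <- sig
  out$samples <- apply_filtfilt(bw, sig$samples)
  out
}

## Second-order IIR notch biquad (constrained-poles design): zeros on the
## unit circle at +-w0, poles pulled inward by the -3 dB bandwidth w0/q.
design_notch <- function(freq, fs, q) {
  w0 <- 2 * pi * freq / fs
  bw <- w0 / q
  r <- 1 - tan(bw / 2) / (1 + tan(bw / 2))   # pole radius from bandwidth
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * (1 + a[2] + a[3]) / (1 + b[2] + b[3])  # unit gain at DC
  signal::Arma(b = b, a = a)
}

#' Notch (band-stop) filter a channel
#'
#' Narrow second-order IIR notch centred at \code{freq}, zero-phase. With
#' \code{wide = TRUE} a fourth-order Butterworth band-stop over
#' \code{c(8, 52)} Hz is applied instead (see
#' \code{\link{preprocess_config}}).
#'
#' @param sig A \code{\link{channel_signal}}.
#' @param freq Notch centre frequency in Hz, below \code{fs/2}.
#' @param q Quality factor (centre frequency / -3 dB width).
#' @param wide Use the literal 8-52 Hz band-stop variant.
#' @return A filtered \code{\link{channel_signal}}.
#' @export
notch <- function(sig, freq = 50, q = 30, wide = FALSE) {
  if (!inherits(sig, "channel_signal")) ts_error("data_error", "sig must be a channel_signal")
  nyq <- sig$fs / 2
  out <- sig
  if (wide) {
    if (52 >= nyq) ts_error("config_error", "band-stop edge must be below fs/2")
    bs <- signal::butter(4, c(8, 52) / nyq, type = "stop")
    out$samples <- apply_filtfilt(bs, sig$samples)
    return(out)
  }
  if (!is.finite(freq) || freq <= 0 || freq >= nyq)
    ts_error("config_error", "notch frequency must lie in (0, fs/2)")
  out$samples <- apply_filtfilt(design_notch(freq, sig$fs, q), sig$samples)
  out
}

#' Decimate (downsample) a channel
#'
#' Anti-aliased downsampling by an integer factor: an 8th-order Chebyshev
#' type I low-pass with cutoff at 0.8 of the post-decimation Nyquist
#' frequency (0.05 dB passband ripple) is applied forward-backward, then
#' every \code{df}-th sample is kept starting from the first. The output has
#' \code{floor(N/df)} samples and sampling frequency \code{fs/df}.
#'
#' @param sig A \code{\link{channel_signal}}.
#' @param df Positive integer decimation factor; \code{df = 1} is the
#'   identity.
#' @return The decimated \code{\link{channel_signal}}.
#' @export
decimate_signal <- function(sig, df) {
  if (!inherits(sig, "channel_signal")) ts_error("data_error", "sig must be a channel_signal")
  if (length(df) != 1L || is.na(df) || df < 1 || df != round(df))
    ts_error("config_error", "df must be a positive integer")
  df <- as.integer(df)
  if (df == 1L) return(sig)
  n_out <- length(sig$samples) %/% df
  if (n_out < 1L) ts_error("config_error", "df larger than the signal length")
  cheb <- signal::cheby1(8, 0.05, 0.8 / df, type = "low")
  y <- apply_filtfilt(cheb, sig$samples)
  out <- sig
  out$samples <- y[seq.int(1L, by = df, length.out = n_out)]
  out$fs <- sig$fs / df
  out
}

#' Preprocess a recording
#'
#' Applies, identically to every channel: band-pass, power-line notch, then
#' decimation, per the supplied \code{\link{preprocess_config}}.
#'
#' Optionally checks the shape-preservation criterion for downsampling: the
#' normalized persistent entropy of each channel before and after decimation
#' must agree within \code{shape_tol}; violations raise a warning naming the
#' channel (the recording is still returned).
#'
#' @param rec A \code{\link{recording}}.
#' @param config A \code{\link{preprocess_config}}.
#' @param check_shape Logical: run the entropy-based shape diagnostic
#'   (default \code{FALSE}; it costs an extra persistence computation per
#'   channel).
#' @param shape_tol Tolerance for the shape diagnostic.
#' @return The preprocessed \code{\link{recording}}.
#' @export
preprocess <- function(rec, config = preprocess_config(), check_shape = FALSE,
                       shape_tol = 0.05) {
  if (!inherits(rec, "recording")) ts_error("data_error", "rec must be a recording")
  if (!inherits(config, "preprocess_config"))
    ts_error("config_error", "config must be a preprocess_config")
  if (n_channels(rec) == 0L) return(rec)
  out <- rec
  out$channels <- lapply(rec$channels, function(ch) {
    f <- bandpass(ch, config$band_low, config$band_high)
    if (!is.na(config$notch_freq) || config$wide_notch)
      f <- notch(f, config$notch_freq, config$notch_q, wide = config$wide_notch)
    d <- decimate_signal(f, config$decimation_factor)
    if (check_shape && config$decimation_factor > 1L) {
      h_before <- try(normalized_persistent_entropy(persistence_0d(piecewise_filtration(f))),
                      silent = TRUE)
      h_after <- try(normalized_persistent_entropy(persistence_0d(piecewise_filtration(d))),
                     silent = TRUE)
      if (!inherits(h_before, "try-error") && !inherits(h_after, "try-error") &&
          abs(h_before - h_after) >= shape_tol)
        ts_warning("shape_warning",
                   sprintf("channel %d: decimation changed normalized persistent entropy by %.4f",
                           ch$sensor_id, abs(h_before - h_after)))
    }
    d
  })
  out
}
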