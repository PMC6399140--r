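#' Multichannel EEG recording
#'
#' Container for a channels-by-samples voltage matrix with its sampling rate
#' and channel metadata. All pipeline stages consume and return this class.
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `Ch01`, `Ch02`, ...
#' @param subject_id identifier carried through the pipeline outputs.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("EEG data must be a finite numeric matrix")
  if (nrow(data) < 2)
    stop("an EEG recording needs at least 2 channels")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar (Hz)")
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must match the number of channels")
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels),
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Re-reference a recording to the common average
#'
#' Subtracts each sample's channel mean so that every column of the data
#' matrix sums to zero. Idempotent.
#'
#' @param rec an [eeg_recording].
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("average reference requires at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

# Linear-phase FIR band-pass taps (Hamming window) with a heuristic
# transition bandwidth: a quarter of each edge frequency, floored at 2 Hz and
# capped at the distance to DC/Nyquist.
design_bandpass <- function(sampling_rate, low, high) {
  tbw_low <- min(max(0.25 * low, 2), low)
  tbw_high <- min(max(0.25 * high, 2), sampling_rate / 2 - high)
  tbw <- min(tbw_low, tbw_high)
  n <- ceiling(3.3 * sampling_rate / tbw)
  if (n %% 2 == 1) n <- n + 1  # even order -> odd, symmetric tap vector
  signal::fir1(n, c(low, high) / (sampling_rate / 2), type = "pass")
}

# Zero-phase single-pass filtering of a symmetric odd-length FIR: centred
# convolution with odd-reflection padding at both ends.
filter_zerophase <- function(b, x) {
  h <- (length(b) - 1) / 2
  n <- length(x)
  if (n <= h + 1)
    stop("recording too short for the requested filter length")
  head_pad <- 2 * x[1] - rev(x[2:(h + 1)])
  tail_pad <- 2 * x[n] - rev(x[(n - h):(n - 1)])
  xp <- c(head_pad, x, tail_pad)
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y[(h + 1):(h + n)])
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a linear-phase FIR (Hamming window, heuristic
#' transition band) applied without group delay, the conventional front end
#' of microstate analysis (default band 2-20 Hz).
#'
#' @param rec an [eeg_recording].
#' @param low,high band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 2, high = 20) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < sampling_rate/2")
  b <- design_bandpass(rec$sampling_rate, low, high)
  rec$data <- t(apply(rec$data, 1, function(ch) filter_zerophase(b, ch)))
  rec
}
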