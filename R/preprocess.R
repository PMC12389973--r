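# Preprocessing chain for raw EEG recordings:
#   notch -> band-pass -> downsample -> artifact flag -> z-score -> epoch
# All filters are zero-phase (forward-backward Butterworth order 4), so
# phase-based connectivity downstream is not biased by filter phase lag.

#' Construct an EEG recording
#'
#' @param data numeric matrix, channels x time samples (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names optional character vector, one per channel.
#' @param subject_id subject identifier.
#' @param label class label: 0 = depressed, 1 = healthy control.
#' @param domain_id domain identifier for adversarial training (defaults
#'   to the subject id: one domain per subject).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_names = NULL,
                          subject_id = "s1", label = NA_integer_,
                          domain_id = subject_id) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("recording data must be a finite numeric matrix")
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  stopifnot(length(channel_names) == nrow(data))
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = channel_names, subject_id = subject_id,
         label = label, domain_id = domain_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject=%s label=%s  %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$label, nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate))
  invisible(x)
}

.filter_channels <- function(rec, b, a) {
  out <- t(apply(rec$data, 1, function(ch) filtfilt_iir(b, a, ch)))
  rec$data <- out
  rec
}

#' Notch filter for power-line interference
#'
#' Zero-phase Butterworth band-stop centred on `freq` (default stop band
#' `freq` +/- 2 Hz; the order-2 prototype gives an order-4 band-stop),
#' attenuating the line component by > 20 dB while leaving neighbouring
#' frequencies essentially untouched. Applied at the recording rate,
#' before any downsampling.
#'
#' @param rec an [eeg_recording()].
#' @param freq line frequency in Hz (50 in most of the world).
#' @param half_width half-width of the stop band in Hz.
#' @param order Butterworth prototype order (the realized band-stop has
#'   twice this order).
#' @return filtered recording, same dimensions.
#' @export
notch_filter <- function(rec, freq = 50, half_width = 2, order = 2) {
  nyq <- rec$sampling_rate / 2
  if (freq <= 0 || freq >= nyq) {
    stop("notch frequency must lie strictly below Nyquist")
  }
  lo <- max(freq - half_width, 1e-6)
  hi <- min(freq + half_width, nyq * (1 - 1e-6))
  f <- butter_design(order, c(lo, hi) / nyq, "stop")
  .filter_channels(rec, f$b, f$a)
}

#' Band-pass filter
#'
#' Zero-phase Butterworth band-pass retaining `[low, high]` Hz; the
#' default analysis band for this pipeline is 4-80 Hz.
#'
#' @inheritParams notch_filter
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @return filtered recording.
#' @export
bandpass_filter <- function(rec, low = 4, high = 80, order = 4) {
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("need 0 < low < high < Nyquist")
  }
  f <- butter_design(order, c(low, high) / nyq, "pass")
  .filter_channels(rec, f$b, f$a)
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass at 80% of the new Nyquist
#' before decimating. Non-integer decimation ratios are rejected.
#'
#' @inheritParams notch_filter
#' @param target_rate new sampling rate in Hz; must divide the current
#'   rate exactly.
#' @return recording at `target_rate`.
#' @export
downsample <- function(rec, target_rate = 250) {
  q <- rec$sampling_rate / target_rate
  if (abs(q - round(q)) > 1e-9) {
    stop("target_rate must divide sampling_rate (integer decimation only)")
  }
  q <- round(q)
  if (q == 1) return(rec)
  f <- butter_design(8, 0.8 / q, "low")
  rec <- .filter_channels(rec, f$b, f$a)
  rec$data <- rec$data[, seq(1, ncol(rec$data), by = q), drop = FALSE]
  rec$sampling_rate <- target_rate
  rec
}

#' Z-score normalization
#'
#' Standardizes each channel over time to zero mean and unit standard
#' deviation (population convention, divisor `T` not `T - 1`).
#'
#' @inheritParams notch_filter
#' @return standardized recording.
#' @export
zscore <- function(rec) {
  mu <- rowMeans(rec$data)
  centred <- rec$data - mu
  sdev <- sqrt(rowMeans(centred^2))
  if (any(sdev == 0)) stop("zero-variance-channel")
  rec$data <- centred / sdev
  rec
}

#' Split a recording into fixed-length epochs
#'
#' Non-overlapping consecutive windows from t = 0; a trailing partial
#' window is discarded; at most `max_epochs` windows are returned.
#'
#' @inheritParams notch_filter
#' @param epoch_seconds epoch duration in seconds.
#' @param max_epochs maximum number of epochs to keep.
#' @return list of `eeg_epoch` objects, each carrying the parent
#'   recording's subject id, label and domain id plus a 0-based
#'   `epoch_index`.
#' @export
epoch_split <- function(rec, epoch_seconds = 2, max_epochs = 150) {
  t_epoch <- round(epoch_seconds * rec$sampling_rate)
  n <- ncol(rec$data)
  if (n < t_epoch) stop("recording shorter than one epoch")
  n_ep <- min(n %/% t_epoch, max_epochs)
  lapply(seq_len(n_ep) - 1L, function(k) {
    structure(
      list(data = rec$data[, (k * t_epoch + 1):((k + 1) * t_epoch),
                           drop = FALSE],
           sampling_rate = rec$sampling_rate,
           subject_id = rec$subject_id, label = rec$label,
           domain_id = rec$domain_id, epoch_index = k),
      class = "eeg_epoch"
    )
  })
}

#' Flag an epoch as artifactual by amplitude threshold
#'
#' Stand-in for automated artifact rejection: an epoch is flagged when
#' any sample strictly exceeds `threshold` in absolute value.
#'
#' @param epoch an epoch from [epoch_split()].
#' @param threshold amplitude threshold (same units as the data).
#' @return logical scalar.
#' @export
artifact_flag <- function(epoch, threshold = 100) {
  if (threshold <= 0) stop("threshold must be positive")
  any(abs(epoch$data) > threshold)
}

#' Full preprocessing chain
#'
#' Applies, in fixed order: notch -> band-pass -> downsample ->
#' z-score -> epoching, then attaches an `artifact` flag to each epoch.
#' The z-score precedes epoching so epoch statistics stay comparable
#' across the recording.
#'
#' @inheritParams notch_filter
#' @param notch line frequency for the notch (NULL to skip).
#' @param band length-2 band-pass edges in Hz.
#' @param target_rate decimation target in Hz (NULL to skip).
#' @param epoch_seconds,max_epochs epoching parameters.
#' @param artifact_threshold amplitude threshold applied after
#'   z-scoring (units of standard deviations).
#' @return list of epochs, each with an `artifact` logical field.
#' @export
preprocess_recording <- function(rec, notch = 50, band = c(4, 80),
                                 target_rate = 250, epoch_seconds = 2,
                                 max_epochs = 150,
                                 artifact_threshold = 10) {
  if (!is.null(notch)) rec <- notch_filter(rec, notch)
  rec <- bandpass_filter(rec, band[1], band[2])
  if (!is.null(target_rate) && target_rate != rec$sampling_rate) {
    rec <- downsample(rec, target_rate)
  }
  rec <- zscore(rec)
  eps <- epoch_split(rec, epoch_seconds, max_epochs)
  lapply(eps, function(e) {
    e$artifact <- artifact_flag(e, artifact_threshold)
    e
  })
}
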