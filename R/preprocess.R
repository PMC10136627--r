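# Signal chain: band-pass filter -> epoch/baseline -> amplitude rejection ->
# average reference -> resample -> per-condition average ERP.

apply_per_channel <- function(epochs, fun, n_out = NULL) {
  d <- epochs$data
  nt <- dim(d)[1]; nch <- dim(d)[2]
  ns_out <- if (is.null(n_out)) dim(d)[3] else n_out
  out <- array(0, dim = c(nt, nch, ns_out))
  for (tr in seq_len(nt)) for (ch in seq_len(nch)) {
    out[tr, ch, ] <- fun(d[tr, ch, ])
  }
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel (and trial) with a 4th-order Butterworth band-pass
#' applied forward and backward (\code{signal::filtfilt}), so the pass band
#' is imposed with zero phase shift and ERP latencies are untouched. The very
#' low high-pass corner is realised as a cascade of a high-pass and a
#' low-pass section for numerical stability. DC is removed; output length
#' equals input length.
#'
#' @param x an \code{ms_epochs}, a \code{channels x samples} matrix, or a
#'   numeric vector.
#' @param low,high band edges in Hz; requires \code{0 < low < high <}
#'   Nyquist.
#' @param sampling_rate sampling rate in Hz (taken from \code{x} when it is
#'   an \code{ms_epochs}).
#' @return object of the same shape as \code{x}, filtered.
#' @export
bandpass_filter <- function(x, low = 0.1, high = 30, sampling_rate = NULL) {
  if (inherits(x, "ms_epochs")) {
    fs <- x$sampling_rate
    x$data <- apply_per_channel(x, function(v) {
      bandpass_filter(v, low, high, fs)
    })
    return(x)
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1L, bandpass_filter, low = low, high = high,
                   sampling_rate = sampling_rate)))
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("`sampling_rate` required for numeric input",
                        call. = FALSE)
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  hp <- signal::butter(4, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  v <- signal::filtfilt(hp, x - mean(x))
  signal::filtfilt(lp, v)
}

#' Cut epochs from a continuous recording and baseline-correct
#'
#' Extracts half-open windows \code{[window[1], window[2])} ms around each
#' stimulus onset (0 ms = onset sample) and subtracts, per channel, the mean
#' over the baseline window. When \code{x} is already epoched only the
#' baseline correction is applied.
#'
#' @param x continuous \code{channels x samples} matrix, or an
#'   \code{ms_epochs}.
#' @param onsets stimulus onset sample indices (continuous input only).
#' @param window epoch limits in ms.
#' @param baseline baseline limits in ms; must lie inside \code{window}.
#' @param sampling_rate Hz (continuous input only).
#' @param condition trial labels for continuous input.
#' @return an \code{ms_epochs}, baseline-corrected.
#' @export
epoch_and_baseline <- function(x, onsets = NULL, window = c(-200, 5000),
                               baseline = c(-200, 0), sampling_rate = NULL,
                               condition = NULL) {
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stop("baseline window must lie inside the epoch window", call. = FALSE)
  }
  if (inherits(x, "ms_epochs")) {
    bidx <- which(x$times >= baseline[1] & x$times < baseline[2])
    if (length(bidx) == 0L) stop("baseline window contains no samples",
                                 call. = FALSE)
    for (tr in seq_len(dim(x$data)[1])) {
      bl <- apply(x$data[tr, , bidx, drop = FALSE], 2L, mean)
      x$data[tr, , ] <- x$data[tr, , ] - bl
    }
    return(x)
  }
  fs <- sampling_rate
  if (is.null(fs) || is.null(onsets)) {
    stop("continuous input needs `onsets` and `sampling_rate`", call. = FALSE)
  }
  n_ep <- round(diff(window) / 1000 * fs)
  times <- window[1] + (seq_len(n_ep) - 1L) * 1000 / fs
  off0 <- round(window[1] / 1000 * fs)
  dat <- array(0, dim = c(length(onsets), nrow(x), n_ep))
  for (i in seq_along(onsets)) {
    idx <- onsets[i] + off0 + seq_len(n_ep) - 1L
    if (idx[1] < 1L || idx[length(idx)] > ncol(x)) {
      stop(sprintf("epoch %d extends beyond the recording", i), call. = FALSE)
    }
    dat[i, , ] <- x[, idx]
  }
  ep <- new_ms_epochs(dat, fs, times,
                      condition %||% rep(NA_character_, length(onsets)))
  epoch_and_baseline(ep, window = window, baseline = baseline)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reject epochs exceeding an amplitude threshold
#'
#' Stand-in for manual artifact screening: any epoch containing a sample with
#' absolute amplitude above \code{threshold} microvolts is dropped, and the
#' removed trial ids are recorded.
#'
#' @param epochs an \code{ms_epochs}.
#' @param threshold rejection threshold in microvolts (default 100).
#' @return the surviving \code{ms_epochs}, with attribute \code{"rejected"}
#'   holding the removed trial indices.
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  peak <- apply(abs(epochs$data), 1L, max)
  bad <- which(peak > threshold)
  keep <- setdiff(seq_along(peak), bad)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$condition <- epochs$condition[keep]
  attr(out, "rejected") <- bad
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels at every sample, for a
#' matrix, an \code{ms_epochs}, or an \code{ms_erp}. Idempotent; leaves GFP
#' unchanged.
#'
#' @param x matrix (\code{channels x samples}), \code{ms_epochs} or
#'   \code{ms_erp}.
#' @return same shape as \code{x}, average-referenced.
#' @export
rereference_average <- function(x) {
  if (inherits(x, "ms_epochs")) {
    for (tr in seq_len(dim(x$data)[1])) {
      x$data[tr, , ] <- center_columns(x$data[tr, , ])
    }
    return(x)
  }
  if (inherits(x, "ms_erp")) {
    x$data <- center_columns(x$data)
    return(x)
  }
  center_columns(x)
}

# Fourier-domain resampling: truncate or zero-pad the spectrum to the new
# length. Delay-free and exact for band-limited content away from the epoch
# edges.
resample_vec <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  xf <- stats::fft(x)
  yf <- complex(n_out)
  nkeep <- min(n_in, n_out)
  half <- floor(nkeep / 2)
  yf[1] <- xf[1]
  if (half >= 1) {
    yf[2:(half + 1)] <- xf[2:(half + 1)]
    yf[(n_out - half + 1):n_out] <- xf[(n_in - half + 1):n_in]
  }
  if (nkeep %% 2 == 0 && half >= 1) {
    # split/merge the Nyquist bin to keep the output real
    if (n_out < n_in) {
      yf[half + 1] <- xf[half + 1] + xf[n_in - half + 1]
    } else {
      yf[half + 1] <- xf[half + 1] / 2
      yf[n_out - half + 1] <- xf[half + 1] / 2
    }
  }
  Re(stats::fft(yf, inverse = TRUE)) / n_in
}

#' Resample to a target rate
#'
#' Fourier-domain resampling of every channel (spectrum truncation or
#' zero-padding, delay-free); epoch duration is preserved to within one
#' sample and the time axis is rebuilt at the new rate.
#'
#' @param x an \code{ms_epochs} or a \code{channels x samples} matrix.
#' @param target_rate new sampling rate in Hz.
#' @param sampling_rate current rate (matrix input only).
#' @return resampled object with updated \code{sampling_rate} and
#'   \code{times}.
#' @export
resample_epochs <- function(x, target_rate, sampling_rate = NULL) {
  if (inherits(x, "ms_epochs")) {
    fs <- x$sampling_rate
    if (target_rate == fs) return(x)
    n_out <- round(dim(x$data)[3] * target_rate / fs)
    x$data <- apply_per_channel(x, function(v) resample_vec(v, n_out),
                                n_out = n_out)
    x$sampling_rate <- target_rate
    x$times <- x$times[1] + (seq_len(n_out) - 1L) * 1000 / target_rate
    return(x)
  }
  fs <- sampling_rate
  if (is.null(fs)) stop("`sampling_rate` required for matrix input",
                        call. = FALSE)
  if (target_rate == fs) return(x)
  n_out <- round(ncol(x) * target_rate / fs)
  t(apply(x, 1L, resample_vec, n_out = n_out))
}

#' Average epochs of one condition into an ERP
#'
#' @param epochs an \code{ms_epochs}.
#' @param condition condition label to average; errors when no trial carries
#'   it.
#' @return an \code{ms_erp}: list with \code{data} (channels x samples),
#'   \code{sampling_rate}, \code{times}, \code{condition}, \code{n_trials},
#'   participant metadata.
#' @export
average_erp <- function(epochs, condition = NULL) {
  idx <- if (is.null(condition)) seq_along(epochs$condition) else
    which(epochs$condition == condition)
  if (length(idx) == 0L) {
    stop(sprintf("no trials for condition '%s'", condition), call. = FALSE)
  }
  m <- apply(epochs$data[idx, , , drop = FALSE], c(2L, 3L), mean)
  structure(list(data = m, sampling_rate = epochs$sampling_rate,
                 times = epochs$times,
                 condition = condition %||% "all",
                 n_trials = length(idx),
                 participant_id = epochs$participant_id,
                 group = epochs$group),
            class = "ms_erp")
}

#' Run the full preprocessing chain on epoched data
#'
#' Fixed stage order: band-pass filter, baseline correction, amplitude-
#' threshold rejection, average re-referencing, resampling. A per-stage
#' record count report is attached.
#'
#' @param epochs an \code{ms_epochs}.
#' @param band band-pass edges in Hz.
#' @param baseline baseline window in ms.
#' @param reject_threshold rejection threshold in microvolts.
#' @param target_rate output sampling rate in Hz.
#' @return preprocessed \code{ms_epochs} with attribute \code{"report"}
#'   (data.frame of stage, n_in, n_out).
#' @export
preprocess_epochs <- function(epochs, band = c(0.1, 30),
                              baseline = c(-200, 0),
                              reject_threshold = 100, target_rate = 250) {
  stages <- character(); nin <- integer(); nout <- integer()
  log_stage <- function(name, a, b) {
    stages <<- c(stages, name); nin <<- c(nin, a); nout <<- c(nout, b)
  }
  n0 <- dim(epochs$data)[1]
  out <- bandpass_filter(epochs, band[1], band[2])
  log_stage("bandpass_filter", n0, n0)
  out <- epoch_and_baseline(out, baseline = baseline,
                            window = range(out$times) + c(0, 1e-9))
  log_stage("baseline", n0, n0)
  out <- reject_epochs(out, reject_threshold)
  n1 <- dim(out$data)[1]
  log_stage("reject_epochs", n0, n1)
  out <- rereference_average(out)
  log_stage("rereference_average", n1, n1)
  out <- resample_epochs(out, target_rate)
  log_stage("resample", n1, n1)
  attr(out, "report") <- data.frame(stage = stages, n_in = nin, n_out = nout,
                                    stringsAsFactors = FALSE)
  out
}
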