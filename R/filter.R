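# Band-pass and powerline filtering. All filters are zero-phase: a 4th-order
# Butterworth design applied forward and backward over reflection-padded
# signals, so evoked latencies are not shifted and edge transients are
# confined to the padding.

#' Filter specification
#'
#' @param high_pass high-pass corner Hz, or `NULL` for none.
#' @param low_pass low-pass corner Hz, or `NULL` for none.
#' @param mains powerline frequency to notch: 50, 60, or `NULL` for none.
#' @param notch_width full stop-band width in Hz (default 7); applied at
#'   the mains frequency and every harmonic below Nyquist.
#' @param expanded_window if `TRUE`, [filter_for_epoch()] filters a segment
#'   50\% longer than the epoch before cutting, to keep filter edge
#'   artifacts out of the trial.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(high_pass = NULL, low_pass = NULL, mains = NULL,
                        notch_width = 7, expanded_window = TRUE) {
  if (!is.null(high_pass) && high_pass <= 0) stop("high_pass must be > 0")
  if (!is.null(low_pass) && low_pass <= 0) stop("low_pass must be > 0")
  if (!is.null(high_pass) && !is.null(low_pass) && high_pass >= low_pass)
    stop("high_pass must be below low_pass")
  if (!is.null(mains) && !mains %in% c(50, 60))
    stop("mains must be 50 or 60 (Hz)")
  if (notch_width <= 0) stop("notch_width must be > 0")
  structure(list(high_pass = high_pass, low_pass = low_pass, mains = mains,
                 notch_width = notch_width,
                 expanded_window = isTRUE(expanded_window)),
            class = "filter_spec")
}

# Zero-phase filtering of each row with reflection padding. The padding
# length covers several periods of the lowest corner frequency so that
# start-up transients of narrow filters decay inside the padding.
zerophase_rows <- function(data, filt, sfreq, f_corner) {
  ns <- ncol(data)
  pad <- min(ns - 1L, as.integer(ceiling(3 * sfreq / f_corner)))
  t(apply(data, 1, function(x) {
    xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
            2 * x[ns] - rev(x[ns - seq_len(pad)]))
    y <- signal::filtfilt(filt, xp)
    y[(pad + 1L):(pad + ns)]
  }))
}

#' Band-pass filter multichannel data
#'
#' Zero-phase 4th-order Butterworth (applied forward-backward). Pass-band
#' tones are preserved within 2\%; tones at twice the corner or beyond are
#' attenuated by at least 90\%. A pure high- or low-pass is used when only
#' one corner is set; the mains notch in `spec` is applied afterwards when
#' present.
#'
#' @param data channels x samples matrix.
#' @param spec a [filter_spec()].
#' @param sfreq sampling rate, S/s.
#' @return Filtered data, same shape.
#' @export
bandpass <- function(data, spec, sfreq) {
  stopifnot(inherits(spec, "filter_spec"))
  data <- if (is.null(dim(data))) matrix(data, 1) else as.matrix(data)
  nyq <- sfreq / 2
  hp <- spec$high_pass; lp <- spec$low_pass
  if (!is.null(hp) && hp >= nyq) stop("high_pass corner at or above Nyquist")
  if (!is.null(lp) && lp >= nyq) stop("low_pass corner at or above Nyquist")
  out <- data
  if (!is.null(hp) && !is.null(lp)) {
    filt <- signal::butter(4, c(hp, lp) / nyq, type = "pass")
    out <- zerophase_rows(out, filt, sfreq, hp)
  } else if (!is.null(hp)) {
    out <- zerophase_rows(out, signal::butter(4, hp / nyq, type = "high"),
                          sfreq, hp)
  } else if (!is.null(lp)) {
    out <- zerophase_rows(out, signal::butter(4, lp / nyq, type = "low"),
                          sfreq, lp / 4)
  }
  if (!is.null(spec$mains))
    out <- notch_powerline(out, spec$mains, sfreq,
                           notch_width = spec$notch_width)
  out
}

#' Notch the powerline frequency and its harmonics
#'
#' Zero-phase spectral band-stop of width `notch_width` centred at
#' `mains` and every harmonic below Nyquist: the signal is reflection-
#' padded, Fourier-transformed, the stop bands zeroed, and transformed
#' back. Tones at the centres are removed essentially completely; tones
#' 10 Hz or further away are preserved within 2\%, and re-notching
#' already-notched data is a no-op up to edge effects.
#'
#' @param data channels x samples matrix.
#' @param mains 50 or 60 (Hz).
#' @param sfreq sampling rate, S/s.
#' @param notch_width full stop-band width, Hz (default 7).
#' @return Filtered data, same shape.
#' @export
notch_powerline <- function(data, mains, sfreq, notch_width = 7) {
  if (!mains %in% c(50, 60)) stop("mains must be 50 or 60 (Hz)")
  if (notch_width <= 0) stop("notch_width must be > 0")
  data <- if (is.null(dim(data))) matrix(data, 1) else as.matrix(data)
  nyq <- sfreq / 2
  centres <- seq(mains, nyq - 1e-9, by = mains)
  ns <- ncol(data)
  pad <- min(ns - 1L, as.integer(2 * sfreq))
  n_tot <- ns + 2L * pad
  f <- seq(0, n_tot - 1) * sfreq / n_tot
  f <- pmin(f, sfreq - f)            # two-sided frequency axis
  mask <- rep(1, n_tot)
  for (f0 in centres) mask[abs(f - f0) <= notch_width / 2] <- 0
  t(apply(data, 1, function(x) {
    xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
            2 * x[ns] - rev(x[ns - seq_len(pad)]))
    y <- Re(stats::fft(stats::fft(xp) * mask, inverse = TRUE)) / n_tot
    y[(pad + 1L):(pad + ns)]
  }))
}

#' Filter a continuous recording in place
#'
#' Applies [bandpass()] (and any mains notch in `spec`) to the whole
#' continuous data matrix. Filtering the continuous recording once
#' before epoching avoids trial-boundary filter artifacts entirely and
#' is much faster than per-epoch filtering when trials are many.
#'
#' @param rec a [meg_recording()].
#' @param spec a [filter_spec()].
#' @return The recording with filtered data.
#' @export
bandpass_recording <- function(rec, spec) {
  rec$data <- bandpass(rec$data, spec, rec$sfreq)
  rec
}

#' Cut and filter one epoch from a continuous recording
#'
#' With `spec$expanded_window` set, the preprocessing filter is applied to
#' a segment 50\% longer than the epoch (centred on it) and the epoch is
#' then cut from the filtered segment, keeping filter edge artifacts out of
#' the trial. When the expanded segment would extend beyond the recording
#' it is truncated to the available samples and a warning is issued.
#'
#' @param rec a [meg_recording()].
#' @param latency event latency, seconds from recording start.
#' @param window length-2 epoch window relative to the event, seconds.
#' @param spec a [filter_spec()].
#' @param rows optional channel row indices to cut (default all).
#' @return channels x samples matrix holding exactly the epoch window; the
#'   filtered segment length (s) is attached as attribute
#'   `segment_length`.
#' @export
filter_for_epoch <- function(rec, latency, window, spec = filter_spec(),
                             rows = NULL) {
  ns <- ncol(rec$data)
  fs <- rec$sfreq
  if (is.null(rows)) rows <- seq_len(nrow(rec$data))
  i0 <- round((latency + window[1]) * fs) + 1L
  i1 <- round((latency + window[2]) * fs) + 1L
  if (i0 < 1L || i1 > ns)
    stop("epoch window extends beyond the recording (boundary-invalid trial)")
  extra <- if (spec$expanded_window)
    as.integer(round(0.25 * (i1 - i0))) else 0L
  e0 <- i0 - extra; e1 <- i1 + extra
  if (e0 < 1L || e1 > ns) {
    warning("expanded filter segment truncated at the recording boundary")
    e0 <- max(1L, e0); e1 <- min(ns, e1)
  }
  seg <- rec$data[rows, e0:e1, drop = FALSE]
  needs_filter <- !is.null(spec$high_pass) || !is.null(spec$low_pass) ||
    !is.null(spec$mains)
  if (needs_filter) seg <- bandpass(seg, spec, fs)
  out <- seg[, (i0 - e0 + 1L):(i0 - e0 + (i1 - i0) + 1L), drop = FALSE]
  attr(out, "segment_length") <- (e1 - e0) / fs
  out
}
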