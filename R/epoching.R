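# Epoch extraction and the automated rejection chain. The rejection order
# is deterministic and documented: boundary-invalid trials first, then
# peak-to-peak/flat amplitude, then single-sample resets, then noisy-channel
# exclusion with a rescan, then head-motion rejection. Thresholds are
# compared strictly (>): "exceeds" means a tie retains the trial.

#' Epoching specification
#'
#' @param t_start,t_end epoch window relative to the event, seconds
#'   (`t_start < t_end`).
#' @param reject_p2p peak-to-peak amplitude threshold, tesla, or `NULL` to
#'   disable. A trial is rejected when any non-excluded MEG channel has
#'   max-min strictly above the threshold, or exactly zero (flat channel).
#' @param reject_reset single-sample step threshold, tesla, or `NULL`;
#'   detects flux jumps (amplitude steps within one sample).
#' @param channel_exclude_pct exclude a channel when the percentage of
#'   trials it alone would reject is strictly above this (default 90);
#'   trials are then rescanned without the excluded channels.
#' @param reject_motion mean sensor motion threshold, cm (default 0.5), or
#'   `NULL` to disable; requires CHL data.
#' @param use_mean_head_position recompute sensor geometry in the head
#'   frame of the CHL fiducials averaged over retained epochs.
#' @param filter a [filter_spec()] applied when cutting epochs.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(t_start = -2, t_end = 2, reject_p2p = NULL,
                       reject_reset = NULL, channel_exclude_pct = 90,
                       reject_motion = 0.5, use_mean_head_position = FALSE,
                       filter = filter_spec()) {
  if (t_start >= t_end) stop("t_start must be below t_end")
  for (thr in list(reject_p2p, reject_reset, reject_motion))
    if (!is.null(thr) && thr <= 0) stop("rejection thresholds must be positive")
  if (channel_exclude_pct <= 0 || channel_exclude_pct > 100)
    stop("channel_exclude_pct must be in (0, 100]")
  structure(list(t_start = t_start, t_end = t_end, reject_p2p = reject_p2p,
                 reject_reset = reject_reset,
                 channel_exclude_pct = channel_exclude_pct,
                 reject_motion = reject_motion,
                 use_mean_head_position = isTRUE(use_mean_head_position),
                 filter = filter),
            class = "epoch_spec")
}

new_epoched_data <- function(data, sfreq, window, latencies, rejection_log,
                             channels, excluded_channels = character(0),
                             mean_fiducials = NULL) {
  structure(list(data = data, sfreq = sfreq, window = window,
                 latencies = latencies, rejection_log = rejection_log,
                 channels = channels, excluded_channels = excluded_channels,
                 mean_fiducials = mean_fiducials),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  cat(sprintf("<epoched_data> %d trials x %d channels x %d samples @ %g S/s\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$sfreq))
  cat(sprintf("  window [%g, %g] s; %d trials dropped; %d channels excluded\n",
              x$window[1], x$window[2], nrow(x$rejection_log),
              length(x$excluded_channels)))
  invisible(x)
}

#' Epoch time axis
#' @param epochs an `epoched_data` object.
#' @return numeric vector of sample times, seconds relative to the event.
#' @export
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[2]
  epochs$window[1] + (seq_len(n) - 1L) / epochs$sfreq
}

#' Extract fixed-window epochs around event markers
#'
#' Cuts one epoch per event latency via [filter_for_epoch()]. Events whose
#' window would extend beyond the recording are dropped and logged as
#' `boundary` trials. No amplitude/motion rejection is applied here; see
#' [epoch_recording()] for the full chain.
#'
#' @param rec a [meg_recording()].
#' @param event_name marker name (case-sensitive).
#' @param spec an [epoch_spec()].
#' @return An `epoched_data` object with a `rejection_log` data frame
#'   (`latency`, `reason`).
#' @export
extract_epochs <- function(rec, event_name, spec = epoch_spec()) {
  if (!event_name %in% names(rec$markers))
    stop("unknown event name '", event_name, "'; available: ",
         paste(names(rec$markers), collapse = ", "))
  lat <- rec$markers[[event_name]]
  fs <- rec$sfreq; ns <- ncol(rec$data)
  win <- c(spec$t_start, spec$t_end)
  i0 <- round((lat + win[1]) * fs) + 1L
  i1 <- round((lat + win[2]) * fs) + 1L
  ok <- i0 >= 1L & i1 <= ns
  log <- data.frame(latency = lat[!ok],
                    reason = rep("boundary", sum(!ok)),
                    stringsAsFactors = FALSE)
  kept <- lat[ok]
  nsamp <- round((win[2] - win[1]) * fs) + 1L
  nch <- nrow(rec$data)
  if (!length(kept)) {
    warning("no events survive the epoch window for '", event_name, "'")
    return(new_epoched_data(array(0, c(nch, nsamp, 0)), fs, win,
                            numeric(0), log, rec$channels))
  }
  dat <- array(0, c(nch, nsamp, length(kept)))
  for (k in seq_along(kept))
    dat[, , k] <- filter_for_epoch(rec, kept[k], win, spec$filter)
  new_epoched_data(dat, fs, win, kept, log, rec$channels)
}

# Per-trial, per-channel peak-to-peak/flat scan restricted to `use` rows.
p2p_channel_flags <- function(epochs, threshold, use) {
  dat <- epochs$data
  nt <- dim(dat)[3]
  flags <- matrix(FALSE, nt, dim(dat)[1])
  for (k in seq_len(nt)) {
    x <- dat[use, , k, drop = FALSE]
    rng <- apply(x, 1, function(v) max(v) - min(v))
    flags[k, use] <- rng > threshold | rng == 0
  }
  flags
}

#' Flag trials exceeding a peak-to-peak amplitude threshold
#'
#' A trial is flagged when any non-excluded MEG channel has a min-to-max
#' range strictly above `threshold` tesla, or a range of exactly zero
#' (flat channel).
#'
#' @param epochs an `epoched_data` object.
#' @param threshold peak-to-peak threshold, tesla (e.g. `3e-12` for 3 pT).
#' @return Logical per-trial flags (`TRUE` = reject).
#' @export
reject_peak_to_peak <- function(epochs, threshold) {
  stopifnot(threshold > 0)
  use <- active_meg_channels(epochs$channels)
  rowSums(p2p_channel_flags(epochs, threshold, use)) > 0
}

#' Flag trials containing single-sample amplitude steps (resets)
#'
#' Flags a trial iff `|x[t+1] - x[t]| > threshold` for some non-excluded
#' MEG channel and sample — detecting flux jumps while passing smooth
#' drifts of any size.
#'
#' @inheritParams reject_peak_to_peak
#' @param threshold step threshold, tesla.
#' @return Logical per-trial flags.
#' @export
reject_resets <- function(epochs, threshold) {
  stopifnot(threshold > 0)
  use <- active_meg_channels(epochs$channels)
  nt <- dim(epochs$data)[3]
  vapply(seq_len(nt), function(k) {
    x <- epochs$data[use, , k, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    any(abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]) > threshold)
  }, logical(1))
}

#' Exclude channels responsible for excessive trial rejection
#'
#' A channel is excluded when the fraction of trials in which that channel
#' alone trips the amplitude criterion is strictly above `pct`/100. The
#' caller should rescan trial flags with the excluded channels removed
#' (done automatically by [epoch_recording()]).
#'
#' @param epochs an `epoched_data` object.
#' @param channel_flags trials x channels logical matrix of per-channel
#'   amplitude flags (as produced during the peak-to-peak scan).
#' @param pct exclusion threshold, percent (default 90).
#' @return Character vector of channel names to exclude.
#' @export
exclude_noisy_channels <- function(epochs, channel_flags, pct = 90) {
  frac <- colMeans(channel_flags)
  bad <- frac > pct / 100
  epochs$channels$name[bad]
}

#' Epoch a recording with the full automated rejection chain
#'
#' Applies, in order: boundary-invalid removal ([extract_epochs()]),
#' peak-to-peak/flat amplitude rejection, reset (flux-jump) rejection,
#' noisy-channel exclusion with a rescan of the amplitude criterion, and
#' head-motion rejection from CHL. Optionally recomputes the sensor
#' geometry at the mean head position of the retained epochs (and then
#' recalculates it after trial rejection).
#'
#' @param rec a [meg_recording()].
#' @param event_name marker name.
#' @param spec an [epoch_spec()].
#' @return An `epoched_data` object; `rejection_log` holds one row per
#'   dropped trial with its primary reason (`boundary`, `peak_to_peak`,
#'   `reset`, `motion`).
#' @export
epoch_recording <- function(rec, event_name, spec = epoch_spec()) {
  if (spec$use_mean_head_position && is.null(rec$chl))
    stop("use_mean_head_position requires CHL data")
  epochs <- extract_epochs(rec, event_name, spec)
  if (spec$use_mean_head_position && dim(epochs$data)[3] > 0) {
    rec <- apply_mean_head_position(rec, epochs)
    epochs$channels <- rec$channels
    epochs$mean_fiducials <- rec$fiducials_device
  }
  nt <- dim(epochs$data)[3]
  if (nt == 0) return(epochs)
  drop_flags <- rep(FALSE, nt)
  reason <- rep(NA_character_, nt)
  excluded <- character(0)

  if (!is.null(spec$reject_p2p)) {
    use <- active_meg_channels(epochs$channels)
    cf <- p2p_channel_flags(epochs, spec$reject_p2p, use)
    excluded <- exclude_noisy_channels(epochs, cf, spec$channel_exclude_pct)
    if (length(excluded)) {  # rescan without the excluded channels
      epochs$channels$excluded <- epochs$channels$excluded |
        epochs$channels$name %in% excluded
      use <- active_meg_channels(epochs$channels)
      cf <- p2p_channel_flags(epochs, spec$reject_p2p, use)
    }
    hit <- rowSums(cf) > 0
    reason[hit & !drop_flags] <- "peak_to_peak"
    drop_flags <- drop_flags | hit
  }
  if (!is.null(spec$reject_reset)) {
    hit <- reject_resets(epochs, spec$reject_reset)
    reason[hit & !drop_flags] <- "reset"
    drop_flags <- drop_flags | hit
  }
  if (!is.null(spec$reject_motion) && !is.null(rec$chl)) {
    motion <- epoch_head_motion(rec, epochs)
    hit <- motion > spec$reject_motion
    reason[hit & !drop_flags] <- "motion"
    drop_flags <- drop_flags | hit
  }

  if (spec$use_mean_head_position && any(drop_flags)) {
    # head position recalculated following trial rejection
    kept_tmp <- epochs
    kept_tmp$latencies <- epochs$latencies[!drop_flags]
    rec2 <- apply_mean_head_position(rec, kept_tmp)
    epochs$channels <- rec2$channels
    epochs$mean_fiducials <- rec2$fiducials_device
  }

  log <- rbind(epochs$rejection_log,
               data.frame(latency = epochs$latencies[drop_flags],
                          reason = reason[drop_flags],
                          stringsAsFactors = FALSE))
  out <- new_epoched_data(epochs$data[, , !drop_flags, drop = FALSE],
                          epochs$sfreq, epochs$window,
                          epochs$latencies[!drop_flags], log,
                          epochs$channels, excluded,
                          mean_fiducials = epochs$mean_fiducials)
  out
}
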