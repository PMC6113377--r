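# Source-space time courses. A virtual sensor projects every trial through
# one location's beamformer weights (recomputed for the requested band and
# covariance window) and noise-normalizes the result (pseudo-Z). The TFR
# is a per-trial complex Morlet decomposition; "power minus average"
# subtracts the transformed trial average's power to isolate induced
# (non-phase-locked) activity.

#' Virtual sensor at a source location
#'
#' Beamformer weights are recomputed for the virtual-sensor filter band
#' and covariance window (so the band may differ from the one used for
#' imaging); each filtered trial is projected and divided by the
#' projected noise RMS.
#'
#' @param epochs an `epoched_data` object.
#' @param model a [head_model()].
#' @param location source position, cm head frame.
#' @param filter a [filter_spec()] for the virtual-sensor band.
#' @param cov_window covariance window, s (default c(-0.5, 1)).
#' @param reg_ft regularization RMS, fT.
#' @param cov optional precomputed `covariance_set` (common weights).
#' @return A list of class `virtual_sensor`: `trials` (trials x samples,
#'   pseudo-Z), `average`, `times`, `sem` (per-sample standard error
#'   across trials), `location`, `orientation`, `sign` (polarity factor
#'   applied, starts at +1).
#' @export
virtual_sensor <- function(epochs, model, location,
                           filter = filter_spec(1, 30),
                           cov_window = c(-0.5, 1), reg_ft = 10, cov = NULL) {
  if (is.null(cov))
    cov <- compute_covariance(epochs, cov_window, filter, reg_ft)
  lf <- lead_field_at(location, model, epochs$channels,
                      active_rows = cov$channel_rows)
  bw <- scalar_weights(cov, lf)
  dat <- filter_epoch_array(epochs, filter, cov$channel_rows)
  nt <- dim(dat)[3]
  proj <- t(vapply(seq_len(nt), function(k)
    drop(bw$w %*% dat[, , k]), numeric(dim(dat)[2])))
  proj <- proj / sqrt(bw$noise_power)
  structure(list(trials = proj, average = colMeans(proj),
                 times = epoch_times(epochs), sfreq = epochs$sfreq,
                 sem = apply(proj, 2, stats::sd) / sqrt(nt),
                 location = as.numeric(location),
                 orientation = bw$orientation, filter = filter, sign = 1),
            class = "virtual_sensor")
}

#' @export
print.virtual_sensor <- function(x, ...) {
  cat(sprintf("<virtual_sensor> %d trials x %d samples at (%.1f, %.1f, %.1f) cm\n",
              nrow(x$trials), ncol(x$trials), x$location[1], x$location[2],
              x$location[3]))
  invisible(x)
}

#' Force virtual-sensor polarity positive at a latency
#'
#' If the trial-average value at the sample nearest `latency` is
#' negative, all trials and the average are multiplied by -1 (the
#' beamformer orientation sign is arbitrary). An exact zero leaves the
#' sensor unchanged.
#'
#' @param vs a `virtual_sensor`.
#' @param latency time point, s (e.g. -0.05 for a motor field peak).
#' @return The (possibly flipped) `virtual_sensor`.
#' @export
polarity_align <- function(vs, latency) {
  i <- which.min(abs(vs$times - latency))
  if (vs$average[i] < 0) {
    vs$trials <- -vs$trials
    vs$average <- -vs$average
    vs$sign <- -vs$sign
  }
  vs
}

# Complex Morlet wavelet at frequency f: exp(i 2 pi f t) Gaussian with
# sigma_t = cycles / (2 pi f), truncated at +/- 4 sigma_t, L2-normalized.
morlet_wavelet <- function(f, cycles, sfreq) {
  sigma_t <- cycles / (2 * pi * f)
  half <- max(1L, ceiling(4 * sigma_t * sfreq))
  t <- (-half:half) / sfreq
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# FFT-based same-length convolution of each row of x with kernel k.
conv_rows <- function(x, k) {
  n <- ncol(x); m <- length(k)
  nfft <- stats::nextn(n + m - 1L, 2)
  K <- stats::fft(c(k, rep(0, nfft - m)))
  half <- (m - 1L) %/% 2L
  out <- matrix(0i, nrow(x), n)
  for (r in seq_len(nrow(x))) {
    X <- stats::fft(c(x[r, ], rep(0, nfft - n)))
    full <- stats::fft(X * K, inverse = TRUE) / nfft
    out[r, ] <- full[(half + 1L):(half + n)]
  }
  out
}

#' Morlet wavelet time-frequency representation of a virtual sensor
#'
#' Per-trial complex Morlet convolution on a regular frequency grid.
#' Modes: `"power"` is the mean over trials of squared magnitude (total
#' power); `"average"` is the squared magnitude of the transformed trial
#' average (evoked, phase-locked power); `"power_minus_average"` is their
#' difference (induced power). Edge samples where the wavelet support
#' (+/- 4 sigma_t) extends beyond the epoch are flagged in `valid` rather
#' than silently zero-padded.
#'
#' @param vs a `virtual_sensor` (or any list with `trials`, `times`,
#'   `sfreq`).
#' @param f_min,f_max frequency range, Hz.
#' @param bin_hz frequency bin size, Hz (default 1).
#' @param cycles wavelet time-frequency resolution, cycles per wavelet
#'   (default 7).
#' @param mode `"power"`, `"power_minus_average"`, or `"average"`.
#' @return A list of class `tfr`: `power` (freq x time), `freqs`,
#'   `times`, `mode`, `cycles`, `valid` (freq x time logical),
#'   `baseline` (window applied, or NULL).
#' @export
morlet_tfr <- function(vs, f_min, f_max, bin_hz = 1, cycles = 7,
                       mode = c("power", "power_minus_average", "average")) {
  mode <- match.arg(mode)
  nyq <- vs$sfreq / 2
  if (f_max > nyq) stop("f_max exceeds the Nyquist frequency")
  freqs <- seq(f_min, f_max, by = bin_hz)
  nsamp <- ncol(vs$trials)
  epoch_len <- nsamp / vs$sfreq
  min_f <- cycles / (pi * epoch_len)
  if (f_min < min_f)
    warning(sprintf(paste0("lowest frequency %.3g Hz is below the resolvable",
                           " floor ~%.3g Hz for this epoch length"),
                    f_min, min_f))
  nt <- nrow(vs$trials)
  power <- matrix(0, length(freqs), nsamp)
  evoked <- matrix(0, length(freqs), nsamp)
  valid <- matrix(TRUE, length(freqs), nsamp)
  avg <- matrix(colMeans(vs$trials), 1)
  for (i in seq_along(freqs)) {
    k <- morlet_wavelet(freqs[i], cycles, vs$sfreq)
    cv <- conv_rows(vs$trials, k)
    power[i, ] <- colMeans(Mod(cv)^2)
    evoked[i, ] <- Mod(conv_rows(avg, k))^2
    half <- (length(k) - 1L) %/% 2L
    if (half >= 1 && half < nsamp)
      valid[i, c(seq_len(half), (nsamp - half + 1L):nsamp)] <- FALSE
    else if (half >= nsamp) valid[i, ] <- FALSE
  }
  p <- switch(mode, power = power, average = evoked,
              power_minus_average = power - evoked)
  structure(list(power = p, freqs = freqs, times = vs$times, mode = mode,
                 cycles = cycles, bin_hz = bin_hz, valid = valid,
                 baseline = NULL),
            class = "tfr")
}

#' Baseline-correct a TFR
#'
#' Subtracts, per frequency bin, the mean power over the baseline window.
#' Applying the same baseline twice changes nothing.
#'
#' @param tfr a `tfr`.
#' @param window length-2 baseline window, s (e.g. c(-1.5, 0)).
#' @return The baseline-corrected `tfr`.
#' @export
tfr_baseline <- function(tfr, window) {
  idx <- which(tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9)
  if (!length(idx)) stop("baseline window lies outside the epoch")
  base <- rowMeans(tfr$power[, idx, drop = FALSE])
  tfr$power <- tfr$power - base
  tfr$baseline <- window
  tfr
}

#' Narrow-band time course from a TFR
#'
#' Mean power across the frequency bins inside `band`.
#'
#' @param tfr a `tfr`.
#' @param band length-2 frequency band, Hz (inclusive).
#' @return Numeric time series (same length as `tfr$times`).
#' @export
band_timecourse <- function(tfr, band) {
  idx <- which(tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9)
  if (!length(idx)) stop("no frequency bins inside the requested band")
  colMeans(tfr$power[idx, , drop = FALSE])
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d freqs (%g-%g Hz) x %d samples, mode %s, %g cycles\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$power),
              x$mode, x$cycles))
  invisible(x)
}

#' Plot a TFR as a time-frequency heat map
#' @param x a `tfr`.
#' @param ... passed to [graphics::image()].
#' @export
plot.tfr <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$power), xlab = "time (s)",
                  ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Plot a virtual sensor average with standard-error shading
#' @param x a `virtual_sensor`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.virtual_sensor <- function(x, ...) {
  graphics::plot(x$times, x$average, type = "l", xlab = "time (s)",
                 ylab = "source amplitude (pseudo-Z)", ...)
  graphics::polygon(c(x$times, rev(x$times)),
                    c(x$average + x$sem, rev(x$average - x$sem)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  invisible(x)
}
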