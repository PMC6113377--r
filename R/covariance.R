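# Channel covariance over a stated epoch window and bandpass, with
# diagonal regularization expressed as an RMS field value (fT). The
# covariance is the average over trials and samples of the outer product
# of the (filtered) channel vector; regularization adds (reg_fT * 1e-15)^2
# to the diagonal before inversion.

#' Compute a channel covariance matrix from epoched data
#'
#' Samples are taken from the half-open window `[start, end)` on the
#' epoch's sample grid (so window lengths are exact). Only non-excluded
#' MEG channels enter. When `filter` is given, each trial is filtered
#' before accumulation.
#'
#' @param epochs an `epoched_data` object.
#' @param window length-2 covariance window, seconds relative to the
#'   event; defaults to the whole epoch.
#' @param filter optional [filter_spec()] applied per trial.
#' @param reg_ft diagonal regularization RMS, fT (default 10).
#' @param condition label stored with the covariance (e.g. a condition
#'   name; `"common"` marks pooled covariances).
#' @return A list of class `covariance_set`: `C` (regularized, T^2),
#'   `C_raw`, `n_trials`, `window`, `reg_ft`, `channel_rows`,
#'   `channel_names`, `condition`.
#' @export
compute_covariance <- function(epochs, window = NULL, filter = NULL,
                               reg_ft = 10, condition = "single") {
  nt <- dim(epochs$data)[3]
  if (nt == 0) stop("cannot compute covariance from zero trials")
  rows <- active_meg_channels(epochs$channels)
  idx <- covariance_sample_index(epochs, window)
  C <- matrix(0, length(rows), length(rows))
  for (k in seq_len(nt)) {
    x <- epochs$data[rows, , k, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    if (!is.null(filter)) x <- bandpass(x, filter, epochs$sfreq)
    xw <- x[, idx, drop = FALSE]
    C <- C + tcrossprod(xw) / length(idx)
  }
  C_raw <- C / nt
  C <- C_raw + diag((reg_ft * FT_TO_T)^2, length(rows))
  structure(list(C = C, C_raw = C_raw, n_trials = nt,
                 window = if (is.null(window)) epochs$window else window,
                 reg_ft = reg_ft, channel_rows = rows,
                 channel_names = epochs$channels$name[rows],
                 condition = condition),
            class = "covariance_set")
}

# Samples of the half-open window [start, end) on the epoch time grid.
covariance_sample_index <- function(epochs, window = NULL) {
  tt <- epoch_times(epochs)
  if (is.null(window)) return(seq_along(tt))
  if (window[1] < epochs$window[1] - 1e-9 ||
      window[2] > epochs$window[2] + 1e-9)
    stop("covariance window lies outside the epoch")
  idx <- which(tt >= window[1] - 1e-9 & tt < window[2] - 1e-9)
  if (!length(idx)) stop("covariance window contains no samples")
  idx
}

#' Pooled covariance across two conditions (common weights)
#'
#' Accumulates the covariance over the pooled trial set of both
#' conditions, so beamformer weights derived from it are common to the
#' conditions and condition contrasts are not biased by weight
#' differences.
#'
#' @param epochs1,epochs2 `epoched_data` objects with identical channel
#'   sets.
#' @inheritParams compute_covariance
#' @return A `covariance_set` tagged `condition = "common"` with
#'   `n_trials = n1 + n2`.
#' @export
common_covariance <- function(epochs1, epochs2, window = NULL, filter = NULL,
                              reg_ft = 10) {
  r1 <- active_meg_channels(epochs1$channels)
  r2 <- active_meg_channels(epochs2$channels)
  if (!identical(epochs1$channels$name[r1], epochs2$channels$name[r2]))
    stop("conditions have differing channel sets; cannot pool covariance")
  c1 <- compute_covariance(epochs1, window, filter, reg_ft = 0)
  c2 <- compute_covariance(epochs2, window, filter, reg_ft = 0)
  n1 <- c1$n_trials; n2 <- c2$n_trials
  C_raw <- (c1$C_raw * n1 + c2$C_raw * n2) / (n1 + n2)
  C <- C_raw + diag((reg_ft * FT_TO_T)^2, nrow(C_raw))
  structure(list(C = C, C_raw = C_raw, n_trials = n1 + n2,
                 window = c1$window, reg_ft = reg_ft,
                 channel_rows = r1, channel_names = c1$channel_names,
                 condition = "common"),
            class = "covariance_set")
}
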