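# Validation harnesses: end-to-end checks of the imaging chain against
# the simulator's planted ground truth. These run the same public
# pipeline a user would (simulate -> epoch -> image) and score the result
# against the known sources.

#' ERB localization study on randomly planted dipoles
#'
#' For each case, one evoked dipolar source is planted at a random
#' interior position (inside the image bounding box) with a random
#' (tangentially detectable) orientation; a full recording is simulated,
#' epoched, and imaged with the ERB beamformer on the default 4 mm grid;
#' the peak voxel and estimated orientation are scored against the
#' truth. Cases are resampled until the achieved trial-average SNR of
#' the evoked field (peak over post-response baseline RMS) is at least
#' 2, so every scored case meets the stated detectability floor.
#'
#' @param n_cases number of random dipoles (default 20).
#' @param n_trials events per recording (default 100).
#' @param seed RNG seed (one independent recording per case).
#' @param amplitude evoked moment, nA m.
#' @param noise sensor noise density, fT/sqrt(Hz).
#' @param brain_dipoles,brain_amp brain-noise model passed to
#'   [scenario()].
#' @return data frame with one row per case: `loc_error_mm`,
#'   `ori_error_deg`, `snr` (achieved trial-average sensor-space SNR of
#'   the evoked peak).
#' @export
localization_check <- function(n_cases = 20, n_trials = 100, seed = 1,
                               amplitude = 20, noise = 7,
                               brain_dipoles = 10, brain_amp = 5) {
  model <- suppressWarnings(head_model(c(0, 0, 5), 7.5))
  grid <- source_grid(model = model)
  # the grid/sensor lead fields are shared by every case
  lf <- lead_field_matrix(grid$points / 10, model, helmet_layout())
  set.seed(seed)
  case_seeds <- sample.int(1e6, n_cases)
  box_lo <- (grid$box_min + grid$step) / 10   # truth must be imageable, cm
  box_hi <- (grid$box_max - grid$step) / 10
  res <- lapply(seq_len(n_cases), function(i) {
    set.seed(case_seeds[i])
    attempt <- 0
    repeat {  # resample until the planted case meets the SNR floor
      attempt <- attempt + 1
      repeat {  # cortical-shell position under the array, inside the box:
        # eccentricity 3-5.5 cm (tangential lead fields vanish toward the
        # sphere centre) and within the helmet cap coverage
        pos <- stats::runif(3, -1, 1) * 5.5 + model$origin
        v <- pos - model$origin
        d <- vnorm(v)
        polar <- acos(v[3] / max(d, 1e-12)) * 180 / pi
        if (d > 3 && d < 5.5 && polar <= 95 &&
            all(pos > box_lo) && all(pos < box_hi)) break
      }
      repeat {  # orientation with a usable tangential component
        ori <- unit(stats::rnorm(3))
        u <- unit(pos - model$origin)
        tang <- ori - u * sum(ori * u)
        if (vnorm(tang) > 0.4) break
      }
      scn <- scenario(
        sources = list(list(position = pos, orientation = ori, event = "ev",
                            waveform = list(type = "evoked_transient",
                                            peak = -0.05, width = 0.025,
                                            amplitude = amplitude))),
        events = list(ev = list(n = n_trials, iti = 0.8, jitter = 0.05)),
        noise = list(sensor_ft_sqrt_hz = noise, brain_dipoles = brain_dipoles,
                     brain_amp = brain_amp),
        pad = 1.5, seed = case_seeds[i] + attempt)
      sim <- simulate_recording(scn)
      # band-limit the continuous recording once (no per-epoch filtering)
      rec <- bandpass_recording(sim$recording, filter_spec(1, 30))
      ep <- epoch_recording(rec, "ev",
                            epoch_spec(-0.3, 0.3, reject_motion = NULL,
                                       filter = filter_spec()))
      # achieved sensor-space SNR of the trial average: evoked peak over
      # the baseline (post-response) RMS of the same channel
      avg <- rowMeans(ep$data, dims = 2)
      tt <- epoch_times(ep)
      pk <- which(abs(tt + 0.05) <= 0.02)
      bs <- which(tt > 0.1)
      ch_best <- which.max(apply(abs(avg[, pk, drop = FALSE]), 1, max))
      snr <- max(abs(avg[ch_best, pk])) / stats::sd(avg[ch_best, bs])
      if (snr >= 2 || attempt >= 8) break
    }
    img <- erb_image(ep, model, grid, latency_range = c(-0.06, -0.04),
                     step = 0.005, filter = NULL,
                     cov_window = c(-0.3, 0.3), leadfields = lf)
    frame <- which.max(apply(img$values, 2, max))
    peak_idx <- which.max(img$values[, frame])
    loc <- img$grid$points[peak_idx, ]
    loc_err <- vnorm(loc - pos * 10)
    # orientation scored at the voxel nearest the true position
    near <- which.min(row_norms(sweep(img$grid$points, 2, pos * 10)))
    est <- img$meta$orientation[near, ]
    tang <- unit(ori - u * sum(ori * u))
    cosang <- abs(sum(unit(est) * tang))      # axis angle (sign-free)
    ori_err <- acos(pmin(1, cosang)) * 180 / pi
    data.frame(loc_error_mm = loc_err, ori_error_deg = ori_err, snr = snr)
  })
  do.call(rbind, res)
}

#' Full-pipeline recovery of the planted task effects
#'
#' Simulates the [preset_sart()] scenario, epochs both marker streams,
#' and checks that (1) the beta-band (15-30 Hz) SAM pseudo-T image
#' (active 0.4-0.7 s vs baseline -0.7 to -0.4 s, common weights across
#' conditions) peaks at the planted sensorimotor source, and (2) the
#' error-minus-default theta (4-8 Hz) pseudo-T contrast (active -0.5 to
#' 0.5 s, baseline -1.5 to -0.5 s) peaks at the planted frontal source.
#'
#' @param seed RNG seed for the simulated recording.
#' @return List with `beta_error_mm`, `theta_error_mm` (distance of each
#'   image peak from its planted source), the two images, and the epoch
#'   trial counts.
#' @export
sart_recovery_check <- function(seed = 1) {
  scn <- preset_sart(seed = seed)
  sim <- simulate_recording(scn)
  model <- suppressWarnings(head_model(scn$sphere$origin, scn$sphere$radius))
  grid <- source_grid(model = model)
  lf <- lead_field_matrix(grid$points / 10, model, scn$channels)
  spec <- epoch_spec(-2, 2, filter = filter_spec(), reject_motion = NULL)
  # band-limit the continuous recording once per analysis band
  rec_beta <- bandpass_recording(sim$recording, filter_spec(15, 30))
  beta_def <- epoch_recording(rec_beta, "correctDef_4th", spec)
  beta_err <- epoch_recording(rec_beta, "errorWH", spec)
  rec_theta <- bandpass_recording(sim$recording, filter_spec(4, 8))
  theta_def <- epoch_recording(rec_theta, "correctDef_4th", spec)
  theta_err <- epoch_recording(rec_theta, "errorWH", spec)
  beta <- sam_image(beta_def, model, grid, baseline = c(-0.7, -0.4),
                    active = c(0.4, 0.7), mode = "pseudoT", filter = NULL,
                    weights_epochs = list(beta_err), leadfields = lf)
  theta <- contrast_image(theta_err, theta_def, model, grid,
                          baseline = c(-1.5, -0.5), active = c(-0.5, 0.5),
                          filter = NULL, leadfields = lf)
  truth_beta <- scn$sources[[2]]$position * 10
  truth_theta <- scn$sources[[3]]$position * 10
  beta_loc <- grid$points[which.max(beta$values), ]
  theta_loc <- grid$points[which.max(theta$values), ]
  list(beta_error_mm = vnorm(beta_loc - truth_beta),
       theta_error_mm = vnorm(theta_loc - truth_theta),
       beta_image = beta, theta_image = theta,
       n_trials = c(default = dim(beta_def$data)[3],
                    error = dim(beta_err$data)[3]))
}
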