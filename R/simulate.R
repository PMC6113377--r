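# Dipole simulator. Generates complete continuous recordings - a
# helmet-like axial-gradiometer array over a spherical conductor, dipolar
# sources with evoked transients, oscillatory bursts and band-limited
# power modulations, sensor and brain noise, CHL fiducial streams with
# injected head motion, and event marker streams - together with the
# ground truth needed to score every downstream stage.

#' Default helmet sensor layout
#'
#' Axial gradiometers placed quasi-uniformly (Fibonacci lattice) on a
#' spherical cap around the conductor sphere, inner coils at
#' `helmet_radius` from the sphere origin, orientations radial, second
#' coil at `baseline` cm along the orientation.
#'
#' @param n number of gradiometer channels (default 151).
#' @param sphere_origin conductor sphere origin, cm head frame.
#' @param helmet_radius inner-coil distance from the sphere origin, cm.
#' @param baseline gradiometer baseline, cm (default 5).
#' @return A [channel_info()] table.
#' @export
helmet_layout <- function(n = 151, sphere_origin = c(0, 0, 5),
                          helmet_radius = 9.2, baseline = 5) {
  pts <- fibonacci_cap(n, helmet_radius, center = sphere_origin,
                       cap_deg = 100)
  ori <- sweep(pts, 2, sphere_origin)
  ori <- ori / row_norms(ori)
  channel_info(name = sprintf("MEG%03d", seq_len(n)),
               kind = "meg_gradiometer",
               coil1 = pts, coil2 = pts + ori * baseline,
               orientation = ori, baseline = baseline)
}

#' Simulation scenario
#'
#' Describes a synthetic recording: sensor layout, conductor sphere,
#' sources with waveform specifications, noise, event streams, and a head
#' motion schedule for the CHL channels.
#'
#' Waveform specs (one per source, tied to an event stream):
#' \describe{
#'   \item{evoked_transient}{Gaussian pulse of `amplitude` nA m peaking at
#'     `peak` s relative to each event, width `width` s (sd); phase-locked.}
#'   \item{band_burst}{oscillation at a random frequency inside `band`
#'     with random phase per event (induced), Hann envelope over
#'     `window`, `amplitude` nA m.}
#'   \item{oscillation_modulation}{ongoing narrow-band oscillation in
#'     `band` whose envelope is `suppress_gain` inside `suppress` and
#'     `rebound_gain` inside `rebound` around each event (ERD and
#'     rebound), `amplitude` nA m baseline RMS.}
#' }
#'
#' @param channels sensor layout (default [helmet_layout()]).
#' @param sphere list(origin, radius), cm head frame.
#' @param sources list of source specs: each a list with `position` (cm),
#'   `orientation` (moment direction, need not be tangential), `event`
#'   (marker name or NULL for ongoing), and `waveform` (list with `type`
#'   and the parameters above).
#' @param events named list: each entry list(n, iti, jitter) - count,
#'   mean inter-trial interval and uniform jitter (s). Streams are
#'   interleaved randomly on a common timeline.
#' @param noise list(sensor_ft_sqrt_hz, brain_dipoles, brain_amp) -
#'   sensor white-noise density (fT/sqrt(Hz)), number of random brain
#'   noise dipoles and their RMS moment (nA m).
#' @param motion list of segments list(start, end, translation = cm
#'   vector and/or rotation_deg about the z axis) injected into the CHL
#'   stream; NULL for a static head.
#' @param sfreq sampling rate (default 600 S/s).
#' @param pad seconds of quiet recording before the first and after the
#'   last event (default 3).
#' @param seed RNG seed; the seed fully determines the output.
#' @return A list of class `scenario`.
#' @export
scenario <- function(channels = helmet_layout(),
                     sphere = list(origin = c(0, 0, 5), radius = 7.5),
                     sources = list(),
                     events = list(),
                     noise = list(sensor_ft_sqrt_hz = 7, brain_dipoles = 20,
                                  brain_amp = 5),
                     motion = NULL, sfreq = 600, pad = 3, seed = 1) {
  for (s in sources) {
    d <- vnorm(as.numeric(s$position) - sphere$origin)
    if (d >= sphere$radius)
      stop("source at (", paste(s$position, collapse = ", "),
           ") lies outside the conductor sphere")
  }
  structure(list(channels = channels, sphere = sphere, sources = sources,
                 events = events, noise = noise, motion = motion,
                 sfreq = sfreq, pad = pad, seed = seed),
            class = "scenario")
}

# Interleaved event timeline: one press every `iti` +/- jitter seconds,
# stream labels randomly ordered with the requested counts.
build_event_stream <- function(events, pad, sfreq) {
  labels <- unlist(mapply(function(nm, sp) rep(nm, sp$n),
                          names(events), events, SIMPLIFY = FALSE))
  labels <- sample(labels)
  iti <- mean(vapply(events, function(sp) sp$iti, 0))
  jit <- mean(vapply(events, function(sp) sp$jitter %||% 0, 0))
  gaps <- iti + stats::runif(length(labels), -jit, jit)
  lat <- pad + cumsum(gaps)
  lat <- round(lat * sfreq) / sfreq   # align to the sample grid
  split(lat, labels)
}

# Narrow-band unit-RMS noise: white noise band-passed to `band`.
narrowband_noise <- function(n, band, sfreq) {
  x <- stats::rnorm(n + 2 * sfreq)
  spec <- filter_spec(band[1], band[2])
  y <- drop(bandpass(matrix(x, 1), spec, sfreq))
  y <- y[sfreq + seq_len(n)]
  y / stats::sd(y)
}

source_waveform <- function(src, latencies, times, sfreq) {
  wf <- src$waveform
  n <- length(times)
  out <- numeric(n)
  if (wf$type == "evoked_transient") {
    for (lat in latencies)
      out <- out + wf$amplitude *
        exp(-(times - lat - wf$peak)^2 / (2 * wf$width^2))
  } else if (wf$type == "band_burst") {
    for (lat in latencies) {
      f <- stats::runif(1, wf$band[1], wf$band[2])
      ph <- stats::runif(1, 0, 2 * pi)
      t0 <- lat + wf$window[1]; t1 <- lat + wf$window[2]
      idx <- which(times >= t0 & times <= t1)
      env <- 0.5 - 0.5 * cos(2 * pi * (times[idx] - t0) / (t1 - t0))
      out[idx] <- out[idx] + wf$amplitude * env *
        sin(2 * pi * f * (times[idx] - t0) + ph)
    }
  } else if (wf$type == "oscillation_modulation") {
    osc <- narrowband_noise(n, wf$band, sfreq) * wf$amplitude
    env <- rep(1, n)
    for (lat in latencies) {
      sup <- times >= lat + wf$suppress[1] & times <= lat + wf$suppress[2]
      reb <- times >= lat + wf$rebound[1] & times <= lat + wf$rebound[2]
      env[sup] <- wf$suppress_gain
      env[reb] <- wf$rebound_gain
    }
    out <- osc * env
  } else stop("unknown waveform type: ", wf$type)
  out
}

# Device frame used by the simulator: head frame shifted down the z axis.
SIM_DEVICE_SHIFT <- c(0, 0, -20)

sim_fiducials_head <- function() {
  list(nasion = c(9, 0, 0), left_ear = c(0, 6.5, 0),
       right_ear = c(0, -6.5, 0))
}

#' Simulate a continuous MEG recording from a scenario
#'
#' Sensor fields are built source by source through the spherical-
#' conductor forward model; sensor white noise, random brain-noise
#' dipoles, CHL fiducial channels with the scheduled head motion, and the
#' event marker streams are added. The same seed always reproduces the
#' identical recording.
#'
#' @param scn a [scenario()].
#' @return List with `recording` (a [meg_recording()]) and `truth` (a
#'   list: per-source position/orientation/waveform, event latencies,
#'   motion schedule, sphere).
#' @export
simulate_recording <- function(scn) {
  set.seed(scn$seed)
  fs <- scn$sfreq
  latencies <- if (length(scn$events))
    build_event_stream(scn$events, scn$pad, fs) else list()
  t_end <- if (length(latencies)) max(unlist(latencies)) + scn$pad
           else 2 * scn$pad
  ns <- as.integer(round(t_end * fs)) + 1L
  times <- (seq_len(ns) - 1L) / fs
  channels <- scn$channels
  nch <- nrow(channels)
  data <- matrix(0, nch, ns)
  model <- suppressWarnings(head_model(scn$sphere$origin, scn$sphere$radius))
  truth_sources <- list()
  for (src in scn$sources) {
    lat <- if (is.null(src$event)) numeric(0)
           else sort(unlist(latencies[src$event], use.names = FALSE))
    wave <- source_waveform(src, lat, times, fs)   # nA m along orientation
    gain <- forward_channels(src$position, unit(src$orientation), model,
                             channels)             # T per nA m
    data <- data + gain %o% wave
    truth_sources <- c(truth_sources,
                       list(list(position = src$position,
                                 orientation = unit(src$orientation),
                                 event = src$event,
                                 waveform = src$waveform,
                                 waveform_trace = NULL)))
  }
  # brain noise: random interior dipoles with low-passed noise time courses
  nb <- scn$noise$brain_dipoles %||% 0
  if (nb > 0) {
    for (b in seq_len(nb)) {
      repeat {
        pos <- stats::runif(3, -1, 1) * scn$sphere$radius * 0.7 +
          scn$sphere$origin
        if (vnorm(pos - scn$sphere$origin) < 0.8 * scn$sphere$radius &&
            vnorm(pos - scn$sphere$origin) > 1) break
      }
      mom <- unit(stats::rnorm(3))
      wave <- narrowband_noise(ns, c(1, 40), fs) * scn$noise$brain_amp
      gain <- forward_channels(pos, mom, model, channels)
      data <- data + gain %o% wave
    }
  }
  dens <- scn$noise$sensor_ft_sqrt_hz %||% 0
  if (dens > 0) {
    sd_t <- dens * FT_TO_T * sqrt(fs / 2)
    meg <- which(meg_channel_mask(channels))
    data[meg, ] <- data[meg, ] + stats::rnorm(length(meg) * ns, sd = sd_t)
  }
  # CHL stream with scheduled rigid head motion
  fid_head <- sim_fiducials_head()
  H_ref <- structure(list(rotation = diag(3), origin = SIM_DEVICE_SHIFT),
                     class = "rigid_transform")   # head -> device
  fid_dev <- lapply(fid_head, function(p) apply_transform(H_ref, p))
  chl <- array(0, c(ns, 3, 3))
  base <- rbind(fid_dev$nasion, fid_dev$left_ear, fid_dev$right_ear)
  for (i in 1:3) for (j in 1:3) chl[, i, j] <- base[i, j]
  if (!is.null(scn$motion)) {
    for (seg in scn$motion) {
      idx <- which(times >= seg$start & times <= seg$end)
      shift <- seg$translation %||% c(0, 0, 0)
      ang <- (seg$rotation_deg %||% 0) * pi / 180
      Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
                  c(0, 0, 1))
      ctr <- apply_transform(H_ref, c(0, 0, 0))  # head origin in device frame
      for (i in 1:3) {
        p <- base[i, ]
        p_moved <- drop(Rz %*% (p - ctr)) + ctr + shift
        for (j in 1:3) chl[idx, i, j] <- p_moved[j]
      }
    }
  }
  markers <- event_markers(latencies)
  rec <- meg_recording(data, fs, channels, fid_dev, markers, chl = chl)
  list(recording = rec,
       truth = list(sources = truth_sources, events = latencies,
                    motion = scn$motion, sphere = scn$sphere,
                    seed = scn$seed))
}

#' Preset scenario: sustained-attention response task (SART-like)
#'
#' Emulates a button-press paradigm with two marker streams:
#' `correctDef_4th` (every 4th correct default press) and `errorWH`
#' (erroneous presses on withhold trials; fewer events). Planted effects:
#' a left-sensorimotor source with an evoked motor field peaking 50 ms
#' before the press plus beta-band (15-30 Hz) suppression around movement
#' and a rebound 0.4-0.7 s after; and a medial-frontal theta (4-8 Hz)
#' burst around the press on error trials only. Source positions lie on
#' the default 4 mm image lattice so localization can be scored in whole
#' voxel steps.
#'
#' @param seed RNG seed.
#' @param n_default,n_error event counts for the two streams (defaults
#'   48 and 24; the error stream is always the smaller).
#' @return A [scenario()].
#' @export
preset_sart <- function(seed = 1, n_default = 48, n_error = 24) {
  sm_pos <- c(-1.9, 3.2, 5.8)    # left sensorimotor, cm head frame
  th_pos <- c(4.5, 0, 3.0)       # medial frontal
  presses <- c("correctDef_4th", "errorWH")
  sources <- list(
    list(position = sm_pos, orientation = c(0, 1, 1), event = presses,
         waveform = list(type = "evoked_transient", peak = -0.05,
                         width = 0.025, amplitude = 20)),
    list(position = sm_pos, orientation = c(1, 0, 1), event = presses,
         waveform = list(type = "oscillation_modulation", band = c(15, 30),
                         suppress = c(-0.3, 0.3), suppress_gain = 0.4,
                         rebound = c(0.35, 0.75), rebound_gain = 2.2,
                         amplitude = 12)),
    list(position = th_pos, orientation = c(0, 1, 0), event = "errorWH",
         waveform = list(type = "band_burst", band = c(4, 8),
                         window = c(-0.4, 0.4), amplitude = 30)))
  scenario(sources = sources,
           events = list(correctDef_4th = list(n = n_default, iti = 2.4,
                                               jitter = 0.2),
                         errorWH = list(n = n_error, iti = 2.4,
                                        jitter = 0.2)),
           seed = seed)
}
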