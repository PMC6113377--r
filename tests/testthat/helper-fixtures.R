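# Small fixtures built in code. A reduced helmet (fewer channels) keeps
# unit tests fast; full 151-channel runs live in the end-to-end checks.

small_layout <- function(n = 40) helmet_layout(n)

default_model <- function() suppressWarnings(head_model(c(0, 0, 5), 7.5))

# Minimal recording: given channel layout, data matrix and markers.
tiny_recording <- function(data, channels, sfreq = 600,
                           markers = event_markers(), chl = NULL) {
  fid <- list(nasion = c(9, 0, -20), left_ear = c(0, 6.5, -20),
              right_ear = c(0, -6.5, -20))
  meg_recording(data, sfreq, channels, fid, markers, chl = chl)
}

# Static CHL stream matching a recording's fiducials.
static_chl <- function(ns, fid) {
  chl <- array(0, c(ns, 3, 3))
  base <- rbind(fid$nasion, fid$left_ear, fid$right_ear)
  for (i in 1:3) for (j in 1:3) chl[, i, j] <- base[i, j]
  chl
}

# Epoched dataset built directly from an array (channels x samples x trials).
epochs_from_array <- function(dat, channels, sfreq = 600,
                              window = c(-0.5, 0.5)) {
  megbeamer:::new_epoched_data(dat, sfreq, window,
                               latencies = seq_len(dim(dat)[3]),
                               rejection_log = data.frame(
                                 latency = numeric(0), reason = character(0),
                                 stringsAsFactors = FALSE),
                               channels = channels)
}

# Quiet evoked-dipole scenario used by several beamformer tests.
evoked_scenario <- function(pos = c(-1.9, 3.2, 5.8), ori = c(0, 1, 1),
                            n_ev = 30, seed = 7, channels = helmet_layout(),
                            noise = list(sensor_ft_sqrt_hz = 7,
                                         brain_dipoles = 10, brain_amp = 5)) {
  scenario(channels = channels,
           sources = list(list(position = pos, orientation = ori,
                               event = "ev",
                               waveform = list(type = "evoked_transient",
                                               peak = -0.05, width = 0.025,
                                               amplitude = 20))),
           events = list(ev = list(n = n_ev, iti = 1.2, jitter = 0.1)),
           noise = noise, pad = 2, seed = seed)
}

angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

unit_icosahedron_off <- function(path) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
             c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
             c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
             c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  lines <- c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
             apply(v, 1, function(p) sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])),
             apply(f, 1, function(x) sprintf("3 %d %d %d", x[1], x[2], x[3])))
  writeLines(lines, path)
  list(vertices = v, faces = f + 1L)
}
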