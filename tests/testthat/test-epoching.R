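# Epoch extraction, amplitude/reset/channel/motion rejection, mean head
# position. Thresholds are strict (>): ties retain the trial.

quiet_rec <- function(n_ch = 5, dur = 60, sfreq = 600, markers, chl = NULL,
                      noise_sd = 5e-14, seed = 11) {
  set.seed(seed)
  ch <- small_layout(n_ch)
  dat <- matrix(rnorm(n_ch * dur * sfreq, sd = noise_sd), n_ch, dur * sfreq)
  tiny_recording(dat, ch, sfreq, markers, chl = chl)
}

test_that("events too close to the recording bounds are boundary-invalid", {
  rec <- quiet_rec(markers = event_markers(ev = c(1.5, 10, 30, 59.5)))
  spec <- epoch_spec(-2, 2, filter = filter_spec(expanded_window = FALSE))
  ep <- extract_epochs(rec, "ev", spec)
  expect_equal(dim(ep$data)[3], 2)        # 10 s and 30 s survive
  expect_equal(ep$rejection_log$reason, c("boundary", "boundary"))
  expect_equal(ep$rejection_log$latency, c(1.5, 59.5))
  expect_equal(dim(ep$data)[2], 4 * 600 + 1)

  expect_error(extract_epochs(rec, "nope", spec), "unknown event")

  rec2 <- quiet_rec(markers = event_markers(ev = c(0.5)))
  expect_warning(ep0 <- extract_epochs(rec2, "ev", spec), "no events")
  expect_equal(dim(ep0$data)[3], 0)
})

test_that("peak-to-peak rejection flags artifacts and flat trials", {
  ch <- small_layout(4)
  dat <- array(rnorm(4 * 600 * 3, sd = 5e-14), c(4, 600, 3))
  dat[2, 300, 1] <- 4e-12                  # 4 pT spike in trial 1
  dat[, , 3] <- 0                          # flat trial
  ep <- epochs_from_array(dat, ch)
  flags <- reject_peak_to_peak(ep, 3e-12)
  expect_identical(flags, c(TRUE, FALSE, TRUE))
})

test_that("white-noise trials essentially always pass a 3 pT threshold", {
  set.seed(42)
  ch <- small_layout(4)
  n_mc <- 400
  dat <- array(rnorm(4 * 600 * n_mc, sd = 5e-14), c(4, 600, n_mc))
  ep <- epochs_from_array(dat, ch)
  flags <- reject_peak_to_peak(ep, 3e-12)
  expect_equal(mean(!flags), 1)  # pass probability >= 0.999 per trial
})

test_that("reset detection catches single-sample steps only, strict >", {
  ch <- small_layout(2)
  dat <- array(0, c(2, 200, 3))
  dat[1, 100:200, 1] <- 5e-12                       # single-sample 5 pT step
  dat[2, , 2] <- seq(0, 5e-12, length.out = 200)    # smooth ramp
  dat[1, 100:200, 3] <- 3e-12                       # step exactly at threshold
  ep <- epochs_from_array(dat, ch)
  flags <- reject_resets(ep, 3e-12)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
})

test_that("channels bad in >90% of trials are excluded and trials rescanned", {
  set.seed(5)
  sfreq <- 600
  nev <- 20
  markers <- event_markers(ev = seq(3, by = 2, length.out = nev))
  rec <- quiet_rec(n_ch = 5, dur = 2 * nev + 6, markers = markers)
  # channel 3 carries a large artifact in 19/20 trials (95%)
  bad_trials <- 1:19
  for (k in bad_trials) {
    i <- round(markers$ev[k] * sfreq)
    rec$data[3, i] <- rec$data[3, i] + 5e-12
  }
  spec <- epoch_spec(-1, 1, reject_p2p = 3e-12, reject_motion = NULL,
                     channel_exclude_pct = 90,
                     filter = filter_spec(expanded_window = FALSE))
  ep <- epoch_recording(rec, "ev", spec)
  expect_identical(ep$excluded_channels, rec$channels$name[3])
  expect_true(ep$channels$excluded[3])
  # after the rescan without channel 3, all trials survive
  expect_equal(dim(ep$data)[3], nev)

  # a channel bad in only 50% of trials is retained and its trials dropped
  rec2 <- quiet_rec(n_ch = 5, dur = 2 * nev + 6, markers = markers, seed = 6)
  for (k in 1:10) {
    i <- round(markers$ev[k] * sfreq)
    rec2$data[3, i] <- rec2$data[3, i] + 5e-12
  }
  ep2 <- epoch_recording(rec2, "ev", spec)
  expect_length(ep2$excluded_channels, 0)
  expect_equal(dim(ep2$data)[3], nev - 10)
  expect_true(all(ep2$rejection_log$reason == "peak_to_peak"))

  # an all-zero channel trips the flat rule in every trial -> excluded
  rec3 <- quiet_rec(n_ch = 5, dur = 2 * nev + 6, markers = markers, seed = 7)
  rec3$data[2, ] <- 0
  ep3 <- epoch_recording(rec3, "ev", spec)
  expect_identical(ep3$excluded_channels, rec3$channels$name[2])
  expect_equal(dim(ep3$data)[3], nev)
})

test_that("rejection-log count plus retained count equals candidate count", {
  markers <- event_markers(ev = c(0.5, seq(3, 39, by = 2), 59.9))
  rec <- quiet_rec(markers = markers)
  i <- round(markers$ev[5] * 600)
  rec$data[1, i] <- 5e-12
  spec <- epoch_spec(-1, 1, reject_p2p = 3e-12, reject_motion = NULL,
                     filter = filter_spec(expanded_window = FALSE))
  ep <- epoch_recording(rec, "ev", spec)
  expect_equal(dim(ep$data)[3] + nrow(ep$rejection_log), length(markers$ev))
  expect_equal(sum(ep$rejection_log$reason == "boundary"), 2)
  expect_equal(sum(ep$rejection_log$reason == "peak_to_peak"), 1)
})

test_that("head motion metric matches a brute-force oracle and flags 0.6 cm", {
  sfreq <- 100
  markers <- event_markers(ev = c(4, 10, 16))
  ch <- small_layout(6)
  ns <- 20 * sfreq
  fid <- list(nasion = c(9, 0, -20), left_ear = c(0, 6.5, -20),
              right_ear = c(0, -6.5, -20))
  chl <- static_chl(ns, fid)
  # inject a 0.6 cm translation covering the second epoch exactly
  idx <- (9 * sfreq + 1):(11 * sfreq + 1)
  for (i in 1:3) chl[idx, i, 1] <- chl[idx, i, 1] + 0.6
  rec <- tiny_recording(matrix(rnorm(6 * ns, sd = 5e-14), 6, ns), ch,
                        sfreq, markers, chl = chl)
  spec <- epoch_spec(-1, 1, filter = filter_spec(expanded_window = FALSE))
  ep <- extract_epochs(rec, "ev", spec)
  motion <- epoch_head_motion(rec, ep)
  expect_equal(motion[1], 0, tolerance = 1e-12)
  expect_equal(motion[3], 0, tolerance = 1e-12)
  expect_gt(motion[2], 0.5)
  expect_equal(motion[2], 0.6, tolerance = 0.01)

  # full chain flags only the moved epoch
  spec2 <- epoch_spec(-1, 1, reject_motion = 0.5,
                      filter = filter_spec(expanded_window = FALSE))
  ep2 <- epoch_recording(rec, "ev", spec2)
  expect_equal(dim(ep2$data)[3], 2)
  expect_equal(ep2$rejection_log$reason, "motion")

  # pure rotation about the head origin: motion equals mean |R p - p|
  ang <- 5 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  chl3 <- static_chl(ns, fid)
  ctr <- c(0, 0, -20)                      # head origin in device frame
  idx <- (3 * sfreq + 1):(5 * sfreq + 1)   # the epoch samples exactly
  base <- rbind(fid$nasion, fid$left_ear, fid$right_ear)
  for (i in 1:3) {
    p <- drop(Rz %*% (base[i, ] - ctr)) + ctr
    for (j in 1:3) chl3[idx, i, j] <- p[j]
  }
  rec3 <- tiny_recording(matrix(0, 6, ns), ch, sfreq,
                         event_markers(ev = 4), chl = chl3)
  ep3 <- extract_epochs(rec3, "ev", spec)
  motion3 <- epoch_head_motion(rec3, ep3)
  coils <- megbeamer:::sensor_coil_points(ch)
  # oracle: head rotates by Rz, so sensors move by Rz^-1 relative to the head
  moved <- coils %*% Rz                    # = t(t(Rz) %*% t(coils)) = Rz^-1 p
  oracle <- mean(sqrt(rowSums((moved - coils)^2)))
  expect_equal(motion3[1], oracle, tolerance = 1e-9)

  # CHL absent -> instructive error
  rec4 <- tiny_recording(matrix(0, 6, ns), ch, sfreq, event_markers(ev = 4))
  expect_error(epoch_head_motion(rec4, ep3), "motion rejection")
})

test_that("mean head position averages CHL and preserves rigid geometry", {
  sfreq <- 100
  ch <- small_layout(6)
  ns <- 20 * sfreq
  fid <- list(nasion = c(9, 0, -20), left_ear = c(0, 6.5, -20),
              right_ear = c(0, -6.5, -20))
  # static head: mean equals the stored fiducials
  rec <- tiny_recording(matrix(0, 6, ns), ch, sfreq,
                        event_markers(ev = c(4, 10)),
                        chl = static_chl(ns, fid))
  spec <- epoch_spec(-1, 1, filter = filter_spec(expanded_window = FALSE))
  ep <- extract_epochs(rec, "ev", spec)
  mf <- mean_head_position(rec, ep)
  expect_equal(mf$nasion, fid$nasion, tolerance = 1e-12)

  # two-position recording, half the epochs in each -> midpoint
  chl2 <- static_chl(ns, fid)
  shift <- c(0.4, 0, 0)
  half <- (8 * sfreq):ns
  for (i in 1:3) chl2[half, i, ] <- sweep(chl2[half, i, ], 2, -shift)
  rec2 <- tiny_recording(matrix(0, 6, ns), ch, sfreq,
                         event_markers(ev = c(4, 12.005)), chl = chl2)
  ep2 <- extract_epochs(rec2, "ev", spec)
  mf2 <- mean_head_position(rec2, ep2)
  expect_equal(mf2$nasion, fid$nasion + shift / 2, tolerance = 1e-6)

  # geometry re-expression preserves inter-coil distances
  rec3 <- apply_mean_head_position(rec2, ep2)
  d_old <- dist(megbeamer:::sensor_coil_points(rec2$channels))
  d_new <- dist(megbeamer:::sensor_coil_points(rec3$channels))
  expect_equal(as.numeric(d_new), as.numeric(d_old), tolerance = 1e-9)
})
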