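# Covariance, scalar weights (unit gain, optimal orientation), ERB and
# SAM images, contrasts, surface constraint.

# Epochs of pure sensor white noise plus (optionally) a planted dipole.
noise_epochs <- function(ch, n_trials = 20, nsamp = 300, sd = 5e-14,
                         seed = 21) {
  set.seed(seed)
  dat <- array(rnorm(nrow(ch) * nsamp * n_trials, sd = sd),
               c(nrow(ch), nsamp, n_trials))
  epochs_from_array(dat, ch, window = c(-0.25, 0.25 - 1 / 600))
}

test_that("covariance honours window, averaging, and 10 fT regularization", {
  ch <- small_layout(6)
  dat <- array(0, c(6, 300, 4))
  ep <- epochs_from_array(dat, ch, window = c(-0.25, 0.25 - 1 / 600))
  cov <- compute_covariance(ep, reg_ft = 10)
  expect_equal(diag(cov$C), rep((1e-14)^2, 6))
  expect_equal(cov$C - diag(diag(cov$C)), matrix(0, 6, 6), ignore_attr = TRUE)

  # white noise: C approaches sigma^2 I (single trial, long window)
  set.seed(22)
  sd_n <- 1e-13
  big <- array(rnorm(6 * 60000, sd = sd_n), c(6, 60000, 1))
  ep2 <- epochs_from_array(big, ch, window = c(0, 100 - 1 / 600))
  cov2 <- compute_covariance(ep2, reg_ft = 0)
  expect_equal(diag(cov2$C) / sd_n^2, rep(1, 6), tolerance = 0.05)
  off <- cov2$C[upper.tri(cov2$C)]
  expect_lt(max(abs(off)) / sd_n^2, 0.05)

  # half-open window: [0, 0.1) at 600 S/s covers exactly 60 samples
  idx <- megbeamer:::covariance_sample_index(
    epochs_from_array(dat, ch, window = c(-0.25, 0.25 - 1 / 600)), c(0, 0.1))
  expect_length(idx, 60)

  expect_error(compute_covariance(ep, window = c(-1, 1)), "outside")
  ep0 <- epochs_from_array(array(0, c(6, 300, 0)), ch)
  expect_error(compute_covariance(ep0), "zero trials")
})

test_that("rank-deficient covariance without regularization raises an error", {
  ch <- small_layout(6)
  set.seed(23)
  # rank-1 data across channels
  w <- rnorm(6)
  dat <- array(0, c(6, 300, 3))
  for (k in 1:3) dat[, , k] <- w %o% rnorm(300) * 1e-13
  ep <- epochs_from_array(dat, ch, window = c(-0.25, 0.25 - 1 / 600))
  cov <- compute_covariance(ep, reg_ft = 0)
  lf <- lead_field_at(c(2, 1, 7), default_model(), ch)
  expect_error(scalar_weights(cov, lf), "regularization")
})

test_that("common covariance pools trials and requires matching channels", {
  ch <- small_layout(6)
  ep1 <- noise_epochs(ch, n_trials = 5, seed = 24)
  ep2 <- noise_epochs(ch, n_trials = 7, seed = 25)
  cc <- common_covariance(ep1, ep2, reg_ft = 10)
  expect_equal(cc$n_trials, 12)
  expect_identical(cc$condition, "common")

  # identical conditions -> equals the single-condition covariance
  cc_same <- common_covariance(ep1, ep1, reg_ft = 10)
  c1 <- compute_covariance(ep1, reg_ft = 10)
  expect_equal(cc_same$C, c1$C, tolerance = 1e-14)

  ep3 <- noise_epochs(small_layout(5), n_trials = 5)
  expect_error(common_covariance(ep1, ep3), "channel sets")
})

test_that("weights have unit gain and the eigen orientation beats a 1-degree scan", {
  model <- default_model()
  ch <- helmet_layout(60)
  set.seed(26)
  pos <- c(2.0, 1.5, 7.0)
  mom_dir <- megbeamer:::unit(c(0.3, 1, 0.2))
  gain <- megbeamer:::forward_channels(pos, mom_dir, model, ch)
  n_trials <- 30; nsamp <- 300
  dat <- array(rnorm(60 * nsamp * n_trials, sd = 5e-14),
               c(60, nsamp, n_trials))
  src <- sin(2 * pi * 8 * (1:nsamp) / 600) * 15   # nA m
  for (k in seq_len(n_trials)) dat[, , k] <- dat[, , k] + gain %o% src
  ep <- epochs_from_array(dat, ch, window = c(-0.25, 0.25 - 1 / 600))
  cov <- compute_covariance(ep, reg_ft = 10)
  lf <- lead_field_at(pos, model, ch)
  bw <- scalar_weights(cov, lf)

  # unit gain at the chosen orientation
  Lt <- drop(lf$L %*% bw$theta)
  expect_equal(sum(bw$w * Lt), 1, tolerance = 1e-9)

  # orientation aligns with the true tangential moment within 5 degrees
  u <- megbeamer:::unit(pos - model$origin)
  tang <- megbeamer:::unit(mom_dir - u * sum(mom_dir * u))
  expect_lt(angle_deg(bw$orientation, tang), 5)

  # eigen solution's output power >= brute-force 1-degree orientation scan
  Cinv <- megbeamer:::cov_inverse(cov)
  G <- t(lf$L) %*% Cinv %*% lf$L
  scan <- vapply(seq(0, 179, by = 1) * pi / 180, function(a) {
    th <- c(cos(a), sin(a))
    1 / drop(th %*% G %*% th)
  }, numeric(1))
  p_eig <- 1 / drop(bw$theta %*% G %*% bw$theta)
  expect_gte(p_eig, max(scan) - 1e-9 * abs(max(scan)))
})

test_that("ERB images count latencies, rectify, localize, and permute cleanly", {
  model <- default_model()
  grid <- source_grid(box_min = c(-40, -20, 40), box_max = c(0, 60, 76),
                      step = 4, model = model)
  scn <- evoked_scenario(n_ev = 100, channels = helmet_layout(), seed = 27)
  sim <- simulate_recording(scn)
  ep <- epoch_recording(sim$recording, "ev",
                        epoch_spec(-0.5, 0.5, reject_motion = NULL,
                                   filter = filter_spec(1, 30)))
  img <- erb_image(ep, model, grid, latency_range = c(-0.3, 0.3),
                   step = 0.005, cov_window = c(-0.5, 0.5))
  expect_equal(ncol(img$values), 121)
  expect_true(all(img$values >= 0))
  frame <- which.min(abs(img$latencies - (-0.05)))
  peak <- grid$points[which.max(img$values[, frame]), ]
  expect_lte(sqrt(sum((peak - c(-19, 32, 58))^2)), 4 * sqrt(3))
  expect_equal(img$latencies[which.max(apply(img$values, 2, max))], -0.05,
               tolerance = 0.0051)

  # channel permutation invariance
  perm <- sample(nrow(ep$channels))
  ep_p <- ep
  ep_p$data <- ep$data[perm, , , drop = FALSE]
  ep_p$channels <- ep$channels[perm, , drop = FALSE]
  img_p <- erb_image(ep_p, model, grid, latency_range = c(-0.06, -0.04),
                     step = 0.005, cov_window = c(-0.5, 0.5))
  img_r <- erb_image(ep, model, grid, latency_range = c(-0.06, -0.04),
                     step = 0.005, cov_window = c(-0.5, 0.5))
  expect_equal(img_p$values, img_r$values, tolerance = 1e-8)

  # zero averaged data -> all-zero image
  ch <- small_layout(10)
  dat0 <- array(0, c(10, 300, 2))
  dat0[, , 1] <- matrix(rnorm(3000, sd = 1e-13), 10, 300)
  dat0[, , 2] <- -dat0[, , 1]
  ep0 <- epochs_from_array(dat0, ch, window = c(-0.25, 0.25 - 1 / 600))
  g_small <- source_grid(box_min = c(-8, -8, 52), box_max = c(8, 8, 68),
                         step = 8, model = model)
  img0 <- erb_image(ep0, model, g_small, latency_range = c(-0.1, 0.1),
                    step = 0.05, filter = NULL, cov_window = c(-0.25, 0.2))
  expect_equal(max(img0$values), 0, tolerance = 1e-25)
})

test_that("null-steering: weights at one source suppress a second source", {
  model <- default_model()
  ch <- helmet_layout(60)
  set.seed(28)
  p1 <- c(-2, 3, 6); p2 <- c(3, -2.5, 7)
  d1 <- megbeamer:::unit(c(0, 1, 0.3)); d2 <- megbeamer:::unit(c(1, 0, -0.4))
  g1 <- megbeamer:::forward_channels(p1, d1, model, ch)
  g2 <- megbeamer:::forward_channels(p2, d2, model, ch)
  nsamp <- 600; n_trials <- 30
  dat <- array(rnorm(60 * nsamp * n_trials, sd = 3e-14),
               c(60, nsamp, n_trials))
  for (k in seq_len(n_trials)) {
    s1 <- sin(2 * pi * 9 * (1:nsamp) / 600 + runif(1, 0, 2 * pi)) * 20
    s2 <- sin(2 * pi * 13 * (1:nsamp) / 600 + runif(1, 0, 2 * pi)) * 20
    dat[, , k] <- dat[, , k] + g1 %o% s1 + g2 %o% s2
  }
  ep <- epochs_from_array(dat, ch, window = c(-0.5, 0.5 - 1 / 600))
  cov <- compute_covariance(ep, reg_ft = 5)
  bw <- scalar_weights(cov, lead_field_at(p1, model, ch))
  # unit gain on source 1's tangential forward pattern; interference
  # gain from source 2 under 0.1
  u1 <- megbeamer:::unit(p1 - model$origin)
  t1 <- megbeamer:::unit(d1 - u1 * sum(d1 * u1))
  gt1 <- megbeamer:::forward_channels(p1, t1, model, ch)
  expect_gt(abs(sum(bw$w * gt1)), 0.9)
  expect_lt(abs(sum(bw$w * g2)), 0.1)
})

test_that("SAM null case, antisymmetry, and pseudo-F reciprocity hold", {
  model <- default_model()
  ch <- small_layout(30)
  set.seed(29)
  # stationary data with identical statistics in both windows; the noise
  # sd matches the 10 fT regularization so pseudo-T is on its unit scale
  ep <- noise_epochs(ch, n_trials = 40, nsamp = 600, sd = 1e-14, seed = 29)
  ep$window <- c(-0.5, 0.5 - 1 / 600)
  grid <- source_grid(box_min = c(-20, -20, 40), box_max = c(20, 20, 72),
                      step = 8, model = model)
  baseline <- c(-0.45, -0.15); active <- c(0.15, 0.45)
  imgT <- sam_image(ep, model, grid, baseline, active, "pseudoT",
                    filter = NULL)
  expect_lt(max(abs(imgT$values)), 0.2)
  imgF <- sam_image(ep, model, grid, baseline, active, "pseudoF",
                    filter = NULL)
  expect_equal(mean(imgF$values), 1, tolerance = 0.2)

  # swapping windows negates pseudo-T exactly and inverts pseudo-F
  imgT_sw <- sam_image(ep, model, grid, active, baseline, "pseudoT",
                       filter = NULL)
  expect_equal(imgT_sw$values, -imgT$values, tolerance = 1e-12)
  imgF_sw <- sam_image(ep, model, grid, active, baseline, "pseudoF",
                       filter = NULL)
  expect_equal(imgF_sw$values, 1 / imgF$values, tolerance = 1e-12)

  expect_error(sam_image(ep, model, grid, c(-0.3, 0.1), c(0, 0.4)),
               "overlap")
  expect_warning(sam_image(ep, model, grid, c(-0.45, -0.25), c(0.15, 0.45),
                           filter = NULL), "length")
})

test_that("contrast of a condition with itself vanishes; definition holds", {
  model <- default_model()
  ch <- small_layout(30)
  ep <- noise_epochs(ch, n_trials = 10, nsamp = 600, sd = 1e-13, seed = 30)
  ep$window <- c(-0.5, 0.5 - 1 / 600)
  grid <- source_grid(box_min = c(-16, -16, 44), box_max = c(16, 16, 68),
                      step = 8, model = model)
  con <- contrast_image(ep, ep, model, grid, baseline = c(-0.45, -0.15),
                        active = c(0.15, 0.45), filter = NULL)
  expect_equal(max(abs(con$values)), 0, tolerance = 1e-12)
  # contrast equals the difference of the per-condition images it carries
  expect_equal(con$values,
               con$meta$condition1$values - con$meta$condition2$values)
})

test_that("surface beamformer: constrained orientation; vertex equals voxel", {
  model <- default_model()
  ch <- helmet_layout(60)
  scn <- evoked_scenario(n_ev = 15, channels = ch, seed = 31)
  sim <- simulate_recording(scn)
  ep <- epoch_recording(sim$recording, "ev",
                        epoch_spec(-0.5, 0.5, reject_motion = NULL,
                                   filter = filter_spec(1, 30)))
  # tiny "mesh": a patch of vertices including the true source location
  verts <- rbind(c(-1.9, 3.2, 5.8), c(-1.5, 3.0, 5.6), c(-2.3, 3.4, 6.0))
  faces <- matrix(c(1, 2, 3), 1)
  mesh <- megbeamer:::new_mesh(verts, faces)
  sgrid <- surface_grid(mesh)

  img_free <- surface_beamformer(ep, model, sgrid, normal_constraint = FALSE,
                                 type = "erb", latency_range = c(-0.06, -0.04),
                                 step = 0.005, cov_window = c(-0.5, 0.5))
  # unconstrained vertex result equals the volumetric computation at the
  # same coordinates
  vgrid <- structure(list(points = verts * 10, dims = c(3L, 1L, 1L),
                          voxel_index = 1:3, step = 4,
                          box_min = verts[1, ] * 10, type = "volume"),
                     class = "source_grid")
  img_vol <- erb_image(ep, model, vgrid, latency_range = c(-0.06, -0.04),
                       step = 0.005, cov_window = c(-0.5, 0.5))
  expect_equal(img_free$values, img_vol$values, tolerance = 1e-9)

  img_con <- surface_beamformer(ep, model, sgrid, normal_constraint = TRUE,
                                type = "erb", latency_range = c(-0.06, -0.04),
                                step = 0.005, cov_window = c(-0.5, 0.5))
  # constrained orientation is exactly the normal's tangential projection
  for (v in 1:3) {
    u <- megbeamer:::unit(verts[v, ] - model$origin)
    nrm <- mesh$normals[v, ]
    tang <- megbeamer:::unit(nrm - u * sum(nrm * u))
    expect_lt(angle_deg(img_con$meta$orientation[v, ], tang), 1e-6)
  }
})
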