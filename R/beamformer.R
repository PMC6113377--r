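# Minimum-variance scalar beamformer. For a source location with
# tangential lead-field columns L = [l1 l2] and channel covariance C, the
# source orientation is the unit vector t minimizing t' (L' C^-1 L) t
# (equivalently maximizing the unit-gain output power 1 / (t'L'C^-1L t)),
# solved as the 2x2 symmetric eigenproblem. Weights are
#   w = C^-1 L t / (t' L' C^-1 L t),
# giving unit gain w'L t = 1; projected sensor-noise power is w' Sn w with
# Sn = reg^2 I.

MAX_COND <- 1e12

# Inverse of a covariance set with conditioning check.
cov_inverse <- function(cov) {
  ev <- eigen(cov$C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > MAX_COND)
    stop("covariance matrix is ill-conditioned (condition number > 1e12); ",
         "regularization may need to be increased until a stable image ",
         "is obtained")
  chol2inv(chol(cov$C))
}

noise_sigma2 <- function(cov) (cov$reg_ft * FT_TO_T)^2

#' Beamformer weights at one source location
#'
#' @param cov a `covariance_set`.
#' @param leadfield a `lead_field` from [lead_field_at()] (units T per
#'   nA m).
#' @return A list of class `beam_weights`: `w` (channel weights),
#'   `orientation` (3-vector, tangential), `noise_power`
#'   (`w' Sn w`, with Sn the regularization diagonal), `output_power`
#'   (`w' C w`).
#' @export
scalar_weights <- function(cov, leadfield) {
  Cinv <- cov_inverse(cov)
  sw <- weights_from_inverse(Cinv, leadfield$L)
  orientation <- drop(sw$theta %*% leadfield$basis)
  s2 <- noise_sigma2(cov)
  structure(list(w = sw$w, orientation = orientation,
                 theta = sw$theta,
                 noise_power = sum(sw$w^2) * s2,
                 output_power = drop(sw$w %*% cov$C %*% sw$w)),
            class = "beam_weights")
}

# Core 2x2 solve given a precomputed covariance inverse.
weights_from_inverse <- function(Cinv, L) {
  G <- t(L) %*% Cinv %*% L          # 2x2, symmetric positive definite
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  theta <- e$vectors[, 2]           # smallest eigenvalue -> max output power
  # deterministic sign: first nonzero component positive
  k <- which(abs(theta) > 1e-12)[1]
  if (theta[k] < 0) theta <- -theta
  Lt <- drop(L %*% theta)
  CinvL <- drop(Cinv %*% Lt)
  denom <- sum(Lt * CinvL)
  if (denom <= 0) stop("degenerate lead field at source location")
  list(w = CinvL / denom, theta = theta)
}

# Weights for every grid point. Returns W (V x nchan), plus per-point
# orientation (V x 3) and noise/output power vectors. `lf` may carry a
# precomputed lead_field_matrix for the same grid/model/channel set.
grid_weights <- function(cov, grid, model, channels,
                         orientations = NULL, lf = NULL) {
  Cinv <- cov_inverse(cov)
  pts_cm <- grid$points / 10
  if (is.null(lf))
    lf <- lead_field_matrix(pts_cm, model, channels,
                            active_rows = cov$channel_rows)
  V <- nrow(pts_cm)
  L1 <- lf$L1; L2 <- lf$L2
  A1 <- L1 %*% Cinv; A2 <- L2 %*% Cinv
  g11 <- rowSums(A1 * L1); g12 <- rowSums(A1 * L2); g22 <- rowSums(A2 * L2)
  if (is.null(orientations)) {
    # smallest-eigenvalue eigenvector of [[g11 g12],[g12 g22]] per point
    tr2 <- (g11 + g22) / 2
    disc <- sqrt(pmax((g11 - g22)^2 / 4 + g12^2, 0))
    lam_min <- tr2 - disc
    # eigenvector (g12, lam_min - g11) or (lam_min - g22, g12)
    u <- ifelse(abs(g12) > 1e-300, g12, lam_min - g22)
    v <- ifelse(abs(g12) > 1e-300, lam_min - g11, g12)
    nrm <- sqrt(u^2 + v^2)
    degen <- nrm < 1e-300   # isotropic case: orientation arbitrary
    u[degen] <- 1; v[degen] <- 0; nrm[degen] <- 1
    u <- u / nrm; v <- v / nrm
    flip <- (abs(u) > 1e-12 & u < 0) | (abs(u) <= 1e-12 & v < 0)
    u[flip] <- -u[flip]; v[flip] <- -v[flip]
  } else {
    # supplied unit orientation per point, projected onto the tangential basis
    u <- rowSums(orientations * lf$t1)
    v <- rowSums(orientations * lf$t2)
    nrm <- sqrt(u^2 + v^2)
    if (any(nrm < 1e-9))
      stop("a constrained orientation is radial; no tangential component")
    u <- u / nrm; v <- v / nrm
  }
  Lt <- L1 * u + L2 * v               # V x nchan
  CinvLt <- A1 * u + A2 * v
  denom <- rowSums(Lt * CinvLt)
  W <- CinvLt / denom
  ori <- lf$t1 * u + lf$t2 * v
  s2 <- noise_sigma2(cov)
  list(W = W, orientation = ori,
       noise_power = rowSums(W^2) * s2,
       theta = cbind(u, v))
}

filter_epoch_array <- function(epochs, filter, rows) {
  dat <- epochs$data[rows, , , drop = FALSE]
  if (!is.null(filter)) {
    for (k in seq_len(dim(dat)[3])) {
      x <- dat[, , k, drop = FALSE]; dim(x) <- dim(x)[1:2]
      dat[, , k] <- bandpass(x, filter, epochs$sfreq)
    }
  }
  dat
}

#' Event-related beamformer (ERB) image
#'
#' Projects the trial-averaged (phase-locked) sensor data through the
#' minimum-variance weights of every grid point, normalized by projected
#' sensor noise: the image value is `|w' b_avg(t)| / sqrt(w' Sn w)`
#' (rectified pseudo-Z) at each latency on the step grid.
#'
#' @param epochs an `epoched_data` object.
#' @param model a [head_model()].
#' @param grid a [source_grid()].
#' @param latency_range length-2 latency window, s (default c(-0.3, 0.3)).
#' @param step latency step, s (default 0.005).
#' @param filter a [filter_spec()] for the imaging bandpass.
#' @param cov_window covariance window, s (default c(-0.5, 1)).
#' @param reg_ft diagonal regularization RMS, fT (default 10).
#' @param cov optional precomputed `covariance_set` (e.g. pooled across
#'   conditions for common weights); overrides `cov_window`/`reg_ft`.
#' @param leadfields optional precomputed grid lead fields (internal
#'   `lead_field_matrix` result) reused across images on the same grid.
#' @return A `source_image` (units pseudo-Z, rectified).
#' @export
erb_image <- function(epochs, model, grid,
                      latency_range = c(-0.3, 0.3), step = 0.005,
                      filter = filter_spec(1, 30),
                      cov_window = c(-0.5, 1), reg_ft = 10, cov = NULL,
                      leadfields = NULL) {
  if (is.null(cov))
    cov <- compute_covariance(epochs, cov_window, filter, reg_ft)
  gw <- grid_weights(cov, grid, model, epochs$channels, lf = leadfields)
  dat <- filter_epoch_array(epochs, filter, cov$channel_rows)
  avg <- rowMeans(dat, dims = 2)
  lat <- seq(latency_range[1], latency_range[2], by = step)
  tt <- epoch_times(epochs)
  samp <- vapply(lat, function(l) which.min(abs(tt - l)), 0L)
  proj <- gw$W %*% avg[, samp, drop = FALSE]       # V x nlat, A m-ish units
  vals <- abs(proj) / sqrt(gw$noise_power)
  new_source_image(vals, grid, lat, units = "pseudo-Z",
                   polarity = "rectified",
                   meta = list(orientation = gw$orientation,
                               reg_ft = cov$reg_ft,
                               cov_window = cov$window))
}

#' SAM pseudo-T / pseudo-F image
#'
#' Weights are computed from the covariance of the pooled baseline and
#' active window samples only. Source power in each window is
#' `P = w' C_win w`; the image is `(Pa - Pb) / (2 w' Sn w)` (pseudo-T) or
#' `Pa / Pb` (pseudo-F). Images are not rectified: positive and negative
#' values are power increases and decreases relative to baseline.
#'
#' @param epochs an `epoched_data` object.
#' @param model a [head_model()].
#' @param grid a [source_grid()].
#' @param baseline,active length-2 windows, s; must not overlap.
#' @param mode `"pseudoT"` or `"pseudoF"`.
#' @param filter band-limiting [filter_spec()] (e.g. 15-30 Hz for beta).
#' @param reg_ft regularization RMS, fT.
#' @param weights_epochs optional list of `epoched_data` pooled with
#'   `epochs` for the weight covariance (common weights across
#'   conditions).
#' @inheritParams erb_image
#' @return A single-frame `source_image` (units pseudo-T or pseudo-F).
#' @export
sam_image <- function(epochs, model, grid, baseline, active,
                      mode = c("pseudoT", "pseudoF"),
                      filter = filter_spec(15, 30), reg_ft = 10,
                      weights_epochs = NULL, leadfields = NULL) {
  mode <- match.arg(mode)
  if (baseline[1] < active[2] && active[1] < baseline[2])
    stop("baseline and active windows overlap")
  lb <- diff(baseline); la <- diff(active)
  if (abs(lb - la) > 1e-9)
    warning("baseline and active windows differ in length; ",
            "power per unit time is used")
  pool <- c(list(epochs), if (is.null(weights_epochs)) list()
            else weights_epochs)
  covs <- lapply(pool, function(e)
    list(b = compute_covariance(e, baseline, filter, reg_ft = 0),
         a = compute_covariance(e, active, filter, reg_ft = 0)))
  ntot <- sum(vapply(covs, function(x) x$b$n_trials, 0))
  C_raw <- Reduce(`+`, lapply(covs, function(x)
    (x$b$C_raw + x$a$C_raw) / 2 * x$b$n_trials)) / ntot
  rows <- covs[[1]]$b$channel_rows
  cov_w <- structure(list(C = C_raw + diag((reg_ft * FT_TO_T)^2, nrow(C_raw)),
                          C_raw = C_raw, n_trials = ntot,
                          window = c(baseline, active), reg_ft = reg_ft,
                          channel_rows = rows,
                          channel_names = covs[[1]]$b$channel_names,
                          condition = if (length(pool) > 1) "common"
                                      else "single"),
                     class = "covariance_set")
  gw <- grid_weights(cov_w, grid, model, epochs$channels, lf = leadfields)
  Ca <- covs[[1]]$a$C_raw; Cb <- covs[[1]]$b$C_raw
  Pa <- rowSums((gw$W %*% Ca) * gw$W)
  Pb <- rowSums((gw$W %*% Cb) * gw$W)
  vals <- if (mode == "pseudoT") (Pa - Pb) / (2 * gw$noise_power)
          else Pa / Pb
  new_source_image(matrix(vals, ncol = 1), grid, mean(active),
                   units = mode, polarity = "signed",
                   meta = list(baseline = baseline, active = active,
                               reg_ft = reg_ft,
                               orientation = gw$orientation,
                               weights = gw$W,
                               common_weights = length(pool) > 1))
}

#' Condition-contrast SAM image with common weights
#'
#' Computes per-condition pseudo-T images with identical weights (from
#' the covariance pooled over both conditions' baseline and active
#' windows) and returns condition 1 minus condition 2.
#'
#' @param epochs1,epochs2 `epoched_data` for conditions 1 and 2.
#' @inheritParams sam_image
#' @return A `source_image` (pseudo-T difference); per-condition images
#'   are in `meta$condition1` / `meta$condition2`.
#' @export
contrast_image <- function(epochs1, epochs2, model, grid, baseline, active,
                           filter = filter_spec(4, 8), reg_ft = 10,
                           leadfields = NULL) {
  img1 <- sam_image(epochs1, model, grid, baseline, active, "pseudoT",
                    filter, reg_ft, weights_epochs = list(epochs2),
                    leadfields = leadfields)
  img2 <- sam_image(epochs2, model, grid, baseline, active, "pseudoT",
                    filter, reg_ft, weights_epochs = list(epochs1),
                    leadfields = leadfields)
  new_source_image(img1$values - img2$values, grid, img1$latencies,
                   units = "pseudoT", polarity = "signed",
                   meta = list(condition1 = img1, condition2 = img2,
                               baseline = baseline, active = active))
}

#' Surface-constrained beamformer image
#'
#' Sources at mesh vertices. With `normal_constraint`, the source
#' orientation at each vertex is the surface normal projected onto the
#' sphere model's tangential plane and renormalized; otherwise the
#' optimal orientation is computed exactly as for volumetric images.
#'
#' @param epochs an `epoched_data` object.
#' @param model a [head_model()].
#' @param grid a [surface_grid()].
#' @param normal_constraint use the vertex normal orientation.
#' @param type `"erb"` or `"sam"`.
#' @param ... passed to [erb_image()] or [sam_image()]-style parameters
#'   (`latency_range`, `step`, `baseline`, `active`, `mode`, `filter`,
#'   `cov_window`, `reg_ft`).
#' @return A `source_image` on vertices.
#' @export
surface_beamformer <- function(epochs, model, grid, normal_constraint = FALSE,
                               type = c("erb", "sam"), ...) {
  type <- match.arg(type)
  stopifnot(identical(grid$type, "surface"))
  args <- list(...)
  orientations <- if (normal_constraint) grid$normals else NULL
  if (type == "erb") {
    filter <- args$filter %||% filter_spec(1, 30)
    cov_window <- args$cov_window %||% c(-0.5, 1)
    reg_ft <- args$reg_ft %||% 10
    cov <- compute_covariance(epochs, cov_window, filter, reg_ft)
    gw <- grid_weights(cov, grid, model, epochs$channels,
                       orientations = orientations)
    dat <- filter_epoch_array(epochs, filter, cov$channel_rows)
    avg <- rowMeans(dat, dims = 2)
    lr <- args$latency_range %||% c(-0.3, 0.3)
    stp <- args$step %||% 0.005
    lat <- seq(lr[1], lr[2], by = stp)
    tt <- epoch_times(epochs)
    samp <- vapply(lat, function(l) which.min(abs(tt - l)), 0L)
    vals <- abs(gw$W %*% avg[, samp, drop = FALSE]) / sqrt(gw$noise_power)
    new_source_image(vals, grid, lat, units = "pseudo-Z",
                     polarity = "rectified",
                     meta = list(orientation = gw$orientation,
                                 normal_constraint = normal_constraint))
  } else {
    baseline <- args$baseline; active <- args$active
    filter <- args$filter %||% filter_spec(15, 30)
    reg_ft <- args$reg_ft %||% 10
    mode <- args$mode %||% "pseudoT"
    cb <- compute_covariance(epochs, baseline, filter, reg_ft = 0)
    ca <- compute_covariance(epochs, active, filter, reg_ft = 0)
    C_raw <- (cb$C_raw + ca$C_raw) / 2
    cov_w <- cb
    cov_w$C_raw <- C_raw
    cov_w$C <- C_raw + diag((reg_ft * FT_TO_T)^2, nrow(C_raw))
    cov_w$reg_ft <- reg_ft
    gw <- grid_weights(cov_w, grid, model, epochs$channels,
                       orientations = orientations)
    Pa <- rowSums((gw$W %*% ca$C_raw) * gw$W)
    Pb <- rowSums((gw$W %*% cb$C_raw) * gw$W)
    vals <- if (mode == "pseudoT") (Pa - Pb) / (2 * gw$noise_power)
            else Pa / Pb
    new_source_image(matrix(vals, ncol = 1), grid, mean(active),
                     units = mode, polarity = "signed",
                     meta = list(orientation = gw$orientation,
                                 normal_constraint = normal_constraint))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
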