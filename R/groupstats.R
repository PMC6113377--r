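# Group-level operations: grid-matched averaging of subject images, peak
# finding with per-subject refinement, and the omnibus sign-flip
# permutation threshold for signed images (SAM / contrast).

#' Voxelwise group average of subject images
#'
#' All images must share the grid and latency axis exactly.
#'
#' @param images list of `source_image` objects (one per subject).
#' @return A `source_image` with the group mean; subject images kept in
#'   `meta$subjects`.
#' @export
group_average <- function(images) {
  stopifnot(length(images) >= 1)
  ref <- images[[1]]
  for (im in images[-1]) {
    if (!isTRUE(all.equal(im$grid$points, ref$grid$points)) ||
        !isTRUE(all.equal(im$latencies, ref$latencies)))
      stop("subject images are on mismatched grids or latency axes")
  }
  vals <- Reduce(`+`, lapply(images, `[[`, "values")) / length(images)
  new_source_image(vals, ref$grid, ref$latencies, ref$units, ref$polarity,
                   meta = list(subjects = images, n = length(images)))
}

#' Find peaks in one latency frame of a source image
#'
#' Local maxima above `threshold`: a location counts as a peak when its
#' value is the strict maximum among all locations within one grid
#' neighborhood (< 1.8 steps for volumetric grids). Peaks closer together
#' than `min_separation` are greedily pruned keeping the larger; the list
#' is ordered by descending value with exact ties broken by lexicographic
#' coordinate order.
#'
#' @param image a `source_image`.
#' @param frame latency frame index (default 1).
#' @param threshold minimum peak value (same units as the image).
#' @param min_separation minimum distance between reported peaks, mm.
#' @param neighbor_radius neighborhood radius used for the local-maximum
#'   test, mm; defaults to 1.8 grid steps (26-connectivity) for volumes.
#' @return data frame with `value`, `x`, `y`, `z` (mm), `index`.
#' @export
find_peaks <- function(image, frame = 1, threshold = 0,
                       min_separation = 20, neighbor_radius = NULL) {
  v <- image$values[, frame]
  pts <- image$grid$points
  if (is.null(neighbor_radius))
    neighbor_radius <- if (!is.na(image$grid$step)) 1.8 * image$grid$step
                       else 2 * stats::median(stats::dist(pts[
                         seq_len(min(50, nrow(pts))), ]))
  cand <- which(v > threshold)
  cand <- cand[order(-v[cand], pts[cand, 1], pts[cand, 2], pts[cand, 3])]
  peaks <- integer(0)
  for (i in cand) {
    d2 <- rowSums(sweep(pts, 2, pts[i, ])^2)
    nb <- which(d2 > 0 & d2 <= neighbor_radius^2)
    if (all(v[i] >= v[nb])) peaks <- c(peaks, i)
  }
  # greedy min-separation pruning in descending-value order
  kept <- integer(0)
  for (i in peaks) {
    if (!length(kept) ||
        all(rowSums(sweep(pts[kept, , drop = FALSE], 2, pts[i, ])^2) >
              min_separation^2))
      kept <- c(kept, i)
  }
  out <- data.frame(value = v[kept], x = pts[kept, 1], y = pts[kept, 2],
                    z = pts[kept, 3], index = kept)
  rownames(out) <- NULL
  out
}

#' Refine a group peak within a subject image
#'
#' Returns the largest local maximum of the subject image inside a ball
#' of `radius` mm around the group peak; falls back to the group
#' location when the ball contains no local maximum above zero (e.g.
#' when the subject's peak lies outside the search radius).
#'
#' @param group_peak length-3 location, mm.
#' @param subject_image a `source_image`.
#' @param frame latency frame index.
#' @param radius search radius, mm (default 10).
#' @return Length-3 location, mm.
#' @export
subject_peak_search <- function(group_peak, subject_image, frame = 1,
                                radius = 10) {
  pts <- subject_image$grid$points
  v <- subject_image$values[, frame]
  inball <- which(rowSums(sweep(pts, 2, as.numeric(group_peak))^2) <= radius^2)
  if (!length(inball)) return(as.numeric(group_peak))
  nb_r <- if (!is.na(subject_image$grid$step)) 1.8 * subject_image$grid$step
          else radius / 2
  for (i in inball[order(-v[inball])]) {
    if (v[i] <= 0) break
    d2 <- rowSums(sweep(pts, 2, pts[i, ])^2)
    nb <- which(d2 > 0 & d2 <= nb_r^2)
    if (all(v[i] >= v[nb])) return(pts[i, ])  # largest local max in the ball
  }
  as.numeric(group_peak)
}

#' Number of sign-flip permutations for a group size
#'
#' Sign symmetry of the two-sided maximum statistic halves the 2^N flip
#' patterns: the first subject's sign can be fixed, giving 2^(N-1)
#' distinct permutations (2048 for 12 subjects); enumeration is capped at
#' 4096, above which patterns are randomly subsampled.
#'
#' @param n_subjects group size.
#' @param cap enumeration cap (default 4096).
#' @return Integer permutation count.
#' @export
n_permutations <- function(n_subjects, cap = 4096) {
  if (n_subjects < 2) stop("permutation testing requires at least 2 subjects")
  if (n_subjects - 1 >= 31) return(as.integer(cap))
  as.integer(min(2^(n_subjects - 1), cap))
}

#' Omnibus sign-flip permutation threshold for group images
#'
#' Builds the null distribution of the omnibus statistic — the maximum
#' over ROI voxels of the absolute group mean — under per-subject sign
#' flips of the (signed) subject images, and thresholds the observed
#' group mean at the empirical (1 - alpha) quantile. The identity
#' permutation is always a member of the null, so p >= 1/n_permutations.
#'
#' @param images list of subject `source_image`s (signed values: SAM or
#'   contrast images), or a subjects x voxels matrix.
#' @param alpha significance level (default 0.05).
#' @param roi optional ROI as list(min = c(x,y,z), max = c(x,y,z)) in mm;
#'   the statistic is taken over voxels inside it.
#' @param frame latency frame index.
#' @param cap permutation enumeration cap (default 4096).
#' @return A list of class `perm_result`: `threshold`, `alpha`,
#'   `n_permutations`, `null` (sorted null distribution),
#'   `observed`, `thresholded` (group mean with sub-threshold voxels
#'   zeroed), `roi_index`, `n_suprathreshold`.
#' @export
permutation_threshold <- function(images, alpha = 0.05, roi = NULL,
                                  frame = 1, cap = 4096) {
  if (is.matrix(images)) {
    X <- images
    pts <- NULL
  } else {
    n <- length(images)
    if (n < 2) stop("permutation testing requires at least 2 subjects")
    X <- t(vapply(images, function(im) im$values[, frame],
                  numeric(nrow(images[[1]]$values))))
    pts <- images[[1]]$grid$points
  }
  n <- nrow(X)
  if (n < 2) stop("permutation testing requires at least 2 subjects")
  if (n < 8) warning("permutation thresholds are unreliable for groups ",
                     "of fewer than 8 subjects")
  roi_idx <- seq_len(ncol(X))
  if (!is.null(roi)) {
    if (is.null(pts)) stop("ROI selection requires source_image input")
    inroi <- pts[, 1] >= roi$min[1] & pts[, 1] <= roi$max[1] &
      pts[, 2] >= roi$min[2] & pts[, 2] <= roi$max[2] &
      pts[, 3] >= roi$min[3] & pts[, 3] <= roi$max[3]
    if (!any(inroi)) stop("ROI contains no grid voxels")
    roi_idx <- which(inroi)
  }
  nperm <- n_permutations(n, cap)
  full <- n - 1 < 31 && 2^(n - 1) <= cap
  if (full) {
    # enumerate all sign patterns with the first subject's sign fixed
    signs <- matrix(1, nperm, n)
    if (n > 1) {
      grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n - 1L)))
      signs[, 2:n] <- grid
    }
  } else {
    signs <- matrix(sample(c(1, -1), nperm * n, replace = TRUE), nperm, n)
    signs[1, ] <- 1  # keep the identity permutation in the null
  }
  Xr <- X[, roi_idx, drop = FALSE]
  null <- apply(abs((signs %*% Xr) / n), 1, max)
  threshold <- sort(null)[ceiling((1 - alpha) * nperm)]
  gmean <- colMeans(X)
  observed <- max(abs(gmean[roi_idx]))
  thresholded <- gmean
  thresholded[abs(thresholded) < threshold] <- 0
  thresholded[-roi_idx] <- 0
  structure(list(threshold = threshold, alpha = alpha,
                 n_permutations = nperm, null = sort(null),
                 observed = observed, thresholded = thresholded,
                 roi_index = roi_idx,
                 n_suprathreshold = sum(thresholded != 0)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(paste0("<perm_result> %d permutations, alpha %.3g, threshold",
                     " %.4g; observed max |mean| %.4g; %d suprathreshold",
                     " voxels\n"),
              x$n_permutations, x$alpha, x$threshold, x$observed,
              x$n_suprathreshold))
  invisible(x)
}

#' Empirical familywise type-I error of the permutation threshold
#'
#' Repeatedly simulates null groups of spatially smoothed noise images,
#' applies [permutation_threshold()], and reports the fraction of runs
#' with any suprathreshold voxel. Under a valid test this approximates
#' `alpha`.
#'
#' @param n_subjects subjects per simulated group (default 8).
#' @param n_sims number of null simulations (default 200).
#' @param alpha significance level.
#' @param dims image dimensions for the simulated volumes.
#' @param smooth_fwhm smoothing kernel FWHM in voxels.
#' @param seed RNG seed.
#' @return List with `rate` (empirical familywise error), `n_sims`,
#'   `alpha`, `hits`.
#' @export
type1_check <- function(n_subjects = 8, n_sims = 200, alpha = 0.05,
                        dims = c(8, 8, 8), smooth_fwhm = 2, seed = 1) {
  if (n_subjects < 2) stop("permutation testing requires at least 2 subjects")
  set.seed(seed)
  nvox <- prod(dims)
  sm <- smooth_kernel_1d(smooth_fwhm)
  hits <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    X <- t(vapply(seq_len(n_subjects), function(i)
      as.vector(smooth3(array(stats::rnorm(nvox), dims), sm)),
      numeric(nvox)))
    res <- suppressWarnings(permutation_threshold(X, alpha = alpha))
    hits[s] <- res$n_suprathreshold > 0
  }
  list(rate = mean(hits), n_sims = n_sims, alpha = alpha, hits = hits)
}

smooth_kernel_1d <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution with reflection padding, same length as input.
conv1_reflect <- function(x, k) {
  m <- length(k); n <- length(x)
  pad <- min(n - 1L, m)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  full <- stats::convolve(xp, rev(k), type = "open")
  half <- (m - 1L) %/% 2L
  full[(pad + half + 1L):(pad + half + n)]
}

# Separable Gaussian smoothing of a 3-D array.
smooth3 <- function(arr, k) {
  d <- dim(arr)
  out <- apply(arr, c(2, 3), conv1_reflect, k = k)          # (d1, d2, d3)
  out <- apply(array(out, d), c(1, 3), conv1_reflect, k = k) # (d2, d1, d3)
  out <- aperm(array(out, d[c(2, 1, 3)]), c(2, 1, 3))
  out <- apply(out, c(1, 2), conv1_reflect, k = k)           # (d3, d1, d2)
  aperm(array(out, d[c(3, 1, 2)]), c(2, 3, 1))
}
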