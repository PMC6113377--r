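# Head motion metrics from continuous head localization (CHL). The CHL
# stream carries per-sample fiducial coil positions in device coordinates.
# Motion is expressed as the displacement of the MEG sensor coils relative
# to the head: with H_ref the head->device transform of the reference
# fiducials and H_t that of the instantaneous fiducials, a sensor at
# head-frame position p sits, at time t, at H_t^-1 H_ref p in the head
# frame, and its displacement is |H_t^-1 H_ref p - p|.

# Head->device transform from a fiducial triple in device coordinates.
head_to_device <- function(nasion, left_ear, right_ear) {
  invert_transform(head_transform_from_fiducials(nasion, left_ear, right_ear))
}

# All physical MEG coil positions (both gradiometer coils), head frame cm.
sensor_coil_points <- function(channels) {
  use <- meg_channel_mask(channels)
  p1 <- channels$coil1[use, , drop = FALSE]
  p2 <- channels$coil2[use, , drop = FALSE]
  rbind(p1, p2[stats::complete.cases(p2), , drop = FALSE])
}

#' Per-epoch mean MEG sensor motion from CHL
#'
#' For every sample of every epoch, the rigid transform taking the
#' reference fiducials (the recording's stored device-frame fiducials, or
#' the mean head position when one was applied) to the instantaneous CHL
#' fiducials is applied to the MEG sensor coil positions; the motion of an
#' epoch is the mean over coils and samples of the displacement magnitude.
#'
#' @param rec a [meg_recording()] with CHL data.
#' @param epochs an `epoched_data` object for that recording.
#' @param reference_fiducials optional list (`nasion`, `left_ear`,
#'   `right_ear`, device frame cm) overriding the recording's stored
#'   fiducials.
#' @return Numeric vector of per-epoch mean sensor motion, cm.
#' @export
epoch_head_motion <- function(rec, epochs, reference_fiducials = NULL) {
  if (is.null(rec$chl))
    stop("recording has no CHL data; disable motion rejection ",
         "(reject_motion = NULL) or record CHL")
  ref <- if (is.null(reference_fiducials)) rec$fiducials_device
         else reference_fiducials
  H_ref <- head_to_device(ref$nasion, ref$left_ear, ref$right_ear)
  coils <- sensor_coil_points(epochs$channels)
  coils_dev <- apply_transform(H_ref, coils)   # device-frame coil positions
  fs <- rec$sfreq
  vapply(epochs$latencies, function(lat) {
    i0 <- round((lat + epochs$window[1]) * fs) + 1L
    i1 <- round((lat + epochs$window[2]) * fs) + 1L
    idx <- i0:i1
    disp <- vapply(idx, function(i) {
      fid <- rec$chl[i, , ]   # 3 x 3, rows nasion/LE/RE
      D_t <- head_transform_from_fiducials(fid[1, ], fid[2, ], fid[3, ])
      p_t <- apply_transform(D_t, coils_dev)   # back into instantaneous head frame
      mean(row_norms(p_t - coils))
    }, numeric(1))
    mean(disp)
  }, numeric(1))
}

#' Mean head position over retained epochs
#'
#' Averages the CHL fiducial positions (device frame) over all samples of
#' the retained epochs.
#'
#' @inheritParams epoch_head_motion
#' @return List with `nasion`, `left_ear`, `right_ear` (device frame, cm).
#' @export
mean_head_position <- function(rec, epochs) {
  if (is.null(rec$chl)) stop("recording has no CHL data")
  fs <- rec$sfreq
  idx <- unlist(lapply(epochs$latencies, function(lat) {
    (round((lat + epochs$window[1]) * fs) + 1L):
      (round((lat + epochs$window[2]) * fs) + 1L)
  }))
  m <- apply(rec$chl[idx, , , drop = FALSE], c(2, 3), mean)
  list(nasion = m[1, ], left_ear = m[2, ], right_ear = m[3, ])
}

#' Re-express sensor geometry at the mean head position
#'
#' Computes the mean CHL fiducials over the retained epochs and rewrites
#' the channel coil positions/orientations in the head frame defined by
#' those mean fiducials. The rigid re-expression preserves all inter-coil
#' distances.
#'
#' @inheritParams epoch_head_motion
#' @return The recording with updated `channels` and `fiducials_device`.
#' @export
apply_mean_head_position <- function(rec, epochs) {
  mf <- mean_head_position(rec, epochs)
  H_ref <- head_to_device(rec$fiducials_device$nasion,
                          rec$fiducials_device$left_ear,
                          rec$fiducials_device$right_ear)
  D_mean <- head_transform_from_fiducials(mf$nasion, mf$left_ear, mf$right_ear)
  # old head frame -> device -> new (mean) head frame
  move <- compose_transforms(D_mean, H_ref)
  ch <- rec$channels
  ch$coil1 <- apply_transform(move, ch$coil1)
  has2 <- stats::complete.cases(ch$coil2)
  ch$coil2[has2, ] <- apply_transform(move, ch$coil2[has2, , drop = FALSE])
  ch$orientation <- apply_rotation(move, ch$orientation)
  rec$channels <- ch
  rec$fiducials_device <- mf
  rec
}
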