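# Core data containers: channel descriptions, event markers, and the
# continuous recording object shared by the whole pipeline.
# Field values are tesla throughout; geometry is in cm, head frame.

#' Describe a set of MEG channels
#'
#' A channel table holds, per channel: its name, kind, physical coil
#' geometry in head coordinates (cm), and an exclusion flag. Axial
#' gradiometers have two coils separated by `baseline` cm along the coil
#' orientation; magnetometers have one.
#'
#' @param name character vector of unique channel names.
#' @param kind one of `"meg_gradiometer"`, `"meg_magnetometer"`,
#'   `"chl_coil"`, `"other"` (recycled).
#' @param coil1,coil2 n x 3 matrices of coil positions, cm head frame.
#'   `coil2` rows are `NA` for single-coil channels.
#' @param orientation n x 3 matrix of unit coil orientations.
#' @param baseline gradiometer baseline in cm (0 for magnetometers).
#' @param excluded logical exclusion flags.
#' @return A data frame of class `channel_info`.
#' @export
channel_info <- function(name, kind, coil1, coil2 = NULL, orientation,
                         baseline = 0, excluded = FALSE) {
  n <- length(name)
  if (anyDuplicated(name)) stop("channel names must be unique")
  kind <- match.arg(kind, c("meg_gradiometer", "meg_magnetometer",
                            "chl_coil", "other"), several.ok = TRUE)
  kind <- rep_len(kind, n)
  coil1 <- unname(as.matrix(coil1))
  if (is.null(coil2)) coil2 <- matrix(NA_real_, n, 3)
  coil2 <- unname(as.matrix(coil2))
  orientation <- unname(as.matrix(orientation))
  nrm <- row_norms(orientation)
  bad <- is.finite(nrm) & abs(nrm - 1) > 1e-9
  if (any(bad)) stop("coil orientations must be unit-norm (within 1e-9)")
  grad <- kind == "meg_gradiometer"
  if (any(grad & !stats::complete.cases(coil2)))
    stop("gradiometer channels require exactly 2 coil positions")
  df <- data.frame(name = as.character(name), kind = kind,
                   stringsAsFactors = FALSE)
  df$coil1 <- coil1
  df$coil2 <- coil2
  df$orientation <- orientation
  df$baseline <- rep_len(as.numeric(baseline), n)
  df$excluded <- rep_len(as.logical(excluded), n)
  class(df) <- c("channel_info", class(df))
  df
}

meg_channel_mask <- function(channels) {
  channels$kind %in% c("meg_gradiometer", "meg_magnetometer")
}

# Indices of channels that may enter covariance/weight computations.
active_meg_channels <- function(channels) {
  which(meg_channel_mask(channels) & !channels$excluded)
}

#' Event marker set
#'
#' Named list of sorted event latencies (seconds from recording start).
#' Names are unique and case-sensitive.
#'
#' @param ... named numeric vectors of latencies, or a single named list.
#' @param duration optional recording duration used to validate latencies.
#' @return An object of class `event_markers`.
#' @export
event_markers <- function(..., duration = NULL) {
  x <- list(...)
  if (length(x) == 1 && is.list(x[[1]]) && is.null(names(x)[1])) x <- x[[1]]
  if (length(x) && (is.null(names(x)) || any(names(x) == "")))
    stop("every marker stream must be named")
  if (anyDuplicated(names(x))) stop("marker names must be unique")
  x <- lapply(x, function(v) sort(as.numeric(v)))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("marker '", nm, "' has negative or non-finite latencies")
    if (!is.null(duration) && length(v) && max(v) > duration)
      stop("marker '", nm, "' has latencies beyond the recording duration")
  }
  structure(x, class = "event_markers")
}

#' Continuous MEG recording
#'
#' A single continuously recorded trial: a channels x samples matrix of
#' field values (tesla), the channel table, the fiducial coil positions in
#' device coordinates (cm), event markers, and optionally the continuous
#' head localization (CHL) stream of per-sample fiducial positions.
#'
#' @param data channels x samples numeric matrix, tesla.
#' @param sfreq sampling rate, samples/s.
#' @param channels a [channel_info()] table with `nrow == nrow(data)`.
#' @param fiducials_device list with `nasion`, `left_ear`, `right_ear`
#'   (length-3, cm, device frame).
#' @param markers an [event_markers()] set (may be empty).
#' @param chl optional samples x 3 x 3 array of per-sample fiducial
#'   positions (device frame, cm); second dim ordered nasion, left ear,
#'   right ear.
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(data, sfreq, channels, fiducials_device,
                          markers = event_markers(), chl = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(sfreq) || sfreq <= 0) stop("sfreq must be positive")
  if (nrow(data) != nrow(channels))
    stop("data rows and channel table rows disagree")
  req <- c("nasion", "left_ear", "right_ear")
  if (!all(req %in% names(fiducials_device)))
    stop("fiducials_device must name nasion, left_ear, right_ear")
  if (!is.null(chl)) {
    chl <- as.array(chl)
    if (length(dim(chl)) != 3 || dim(chl)[1] != ncol(data) ||
        !all(dim(chl)[2:3] == c(3, 3)))
      stop("chl must be a samples x 3 x 3 array matching the data length")
  }
  rec <- structure(list(data = data, sfreq = sfreq, channels = channels,
                        fiducials_device = fiducials_device[req],
                        markers = markers, chl = chl),
                   class = "meg_recording")
  dur <- duration(rec)
  for (nm in names(markers))
    if (length(markers[[nm]]) && max(markers[[nm]]) > dur)
      stop("marker '", nm, "' extends beyond the recording")
  rec
}

#' @export
duration <- function(rec) UseMethod("duration")

#' @export
duration.meg_recording <- function(rec) ncol(rec$data) / rec$sfreq

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channels x %d samples @ %g S/s (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, duration(x)))
  cat(sprintf("  MEG channels: %d (%d excluded); CHL: %s\n",
              sum(meg_channel_mask(x$channels)), sum(x$channels$excluded),
              if (is.null(x$chl)) "absent" else "present"))
  if (length(x$markers))
    cat("  markers:", paste0(names(x$markers), " (",
                             vapply(x$markers, length, 0L), ")",
                             collapse = ", "), "\n")
  invisible(x)
}
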