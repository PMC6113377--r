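# On-disk dataset container. A recording is stored as an open directory
# `<name>.megds/` holding:
#   header.json   - version, sfreq, dims, channel table, fiducials
#   data.bin      - float64 little-endian, column-major channels x samples
#   markers.json  - {name: [latencies_s]}
#   chl.bin       - optional float64 samples x 3 x 3 CHL stream
# Doubles are stored verbatim, so write/read round-trips are bit-identical.

CONTAINER_VERSION <- 1L

#' Write a continuous recording to a dataset container
#'
#' @param rec a [meg_recording()].
#' @param path directory path (conventionally ending in `.megds`); created
#'   (and overwritten) as needed.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "meg_recording"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create container directory: ", path)
  ch <- rec$channels
  header <- list(
    format = "megds", version = CONTAINER_VERSION,
    sfreq = rec$sfreq,
    n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    channels = list(name = ch$name, kind = ch$kind,
                    baseline = ch$baseline, excluded = ch$excluded),
    marker_names = names(rec$markers),
    marker_counts = vapply(rec$markers, length, 0L),
    fiducials_device = lapply(rec$fiducials_device, as.numeric),
    has_chl = !is.null(rec$chl))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  write_doubles <- function(x, name) {
    con <- file(file.path(path, name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  write_doubles(rec$data, "data.bin")
  # geometry and latencies carried as raw IEEE doubles so round-trips are
  # bit-identical; markers.json duplicates the latencies for external use
  write_doubles(cbind(ch$coil1, ch$coil2, ch$orientation), "geometry.bin")
  write_doubles(unlist(rec$markers, use.names = FALSE), "markers.bin")
  jsonlite::write_json(unclass(rec$markers), file.path(path, "markers.json"),
                       digits = NA)
  if (!is.null(rec$chl)) write_doubles(rec$chl, "chl.bin")
  invisible(path)
}

#' Read a continuous recording from a dataset container
#'
#' @param path container directory written by [write_recording()].
#' @return A [meg_recording()].
#' @export
read_recording <- function(path) {
  hpath <- file.path(path, "header.json")
  if (!file.exists(hpath)) stop("not a dataset container (no header.json): ", path)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$format, "megds"))
    stop("unrecognized container format in ", hpath)
  if (h$version > CONTAINER_VERSION)
    stop("container schema version ", h$version, " not supported")
  if (is.null(h$fiducials_device))
    stop("container missing required group 'fiducials_device'")
  if (is.null(h$channels))
    stop("container missing required group 'channels'")
  nch <- h$n_channels; ns <- h$n_samples
  dat <- readBin(file.path(path, "data.bin"), "double", n = nch * ns,
                 size = 8, endian = "little")
  if (length(dat) != nch * ns) stop("data.bin truncated")
  dim(dat) <- c(nch, ns)
  geo <- readBin(file.path(path, "geometry.bin"), "double", n = nch * 9,
                 size = 8, endian = "little")
  dim(geo) <- c(nch, 9)
  chs <- h$channels
  channels <- channel_info(name = chs$name, kind = chs$kind,
                           coil1 = geo[, 1:3, drop = FALSE],
                           coil2 = geo[, 4:6, drop = FALSE],
                           orientation = geo[, 7:9, drop = FALSE],
                           baseline = chs$baseline, excluded = chs$excluded)
  mk_names <- as.character(unlist(h$marker_names))
  mk_counts <- as.integer(unlist(h$marker_counts))
  lat <- readBin(file.path(path, "markers.bin"), "double",
                 n = sum(mk_counts), size = 8, endian = "little")
  mk <- list()
  if (length(mk_names)) {
    idx <- c(0L, cumsum(mk_counts))
    mk <- lapply(seq_along(mk_names), function(i)
      if (mk_counts[i] == 0) numeric(0) else lat[(idx[i] + 1):idx[i + 1]])
    names(mk) <- mk_names
  }
  chl <- NULL
  if (isTRUE(h$has_chl)) {
    chl <- readBin(file.path(path, "chl.bin"), "double", n = ns * 9,
                   size = 8, endian = "little")
    dim(chl) <- c(ns, 3, 3)
  }
  meg_recording(dat, h$sfreq, channels, h$fiducials_device,
                markers = event_markers(mk), chl = chl)
}
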