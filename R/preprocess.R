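# Five-step preprocessing: exposure normalization, removal of nonspectral
# columns, wavelength trim, per-channel binning, per-channel [0,1] min-max
# normalization, and pad/reshape to the 66 x 66 x 1 fingerprint.

#' Exposure-normalize a raw scan
#'
#' Divides each intensity by its block's `integration_time * brightness`,
#' putting all 12 channels on a common counts-per-unit-exposure scale.
#'
#' @param scan An `hsf_scan` (or a data.frame with the five scan columns).
#' @return The scan with `intensity` replaced by the normalized value.
#' @export
normalize_exposure <- function(scan) {
  validate_scan(scan)
  bad <- scan$integration_time <= 0 | scan$brightness <= 0
  if (any(bad))
    stop("non-positive integration_time or brightness in block(s) led_index ",
         paste(sort(unique(scan$led_index[bad])), collapse = ", "))
  scan$intensity <- scan$intensity / (scan$integration_time * scan$brightness)
  scan
}

#' Strip nonspectral fields into a channel matrix precursor
#'
#' Step (i): after exposure normalization, drops wavelength, integration
#' time and brightness, keeping only the ordered intensity values grouped
#' by channel.
#'
#' @param scan An `hsf_scan`.
#' @return List with `values` (12 x pixels matrix, rows in ascending
#'   `led_index`) and `wavelengths` (the shared emission axis).
#' @export
strip_nonspectral <- function(scan) {
  scan <- normalize_exposure(scan)
  npix <- nrow(scan) / 12L
  ord <- order(scan$led_index, scan$emission_nm)
  scan <- scan[ord, ]
  wl <- scan$emission_nm[seq_len(npix)]
  vals <- matrix(scan$intensity, nrow = 12L, ncol = npix, byrow = TRUE)
  if (any(!is.finite(vals))) stop("non-finite intensities in scan")
  list(values = vals, wavelengths = wl, led_index = 0:11)
}

#' Trim channels to a wavelength window
#'
#' Step (ii): retain only pixels whose wavelength lies in the closed
#' window; the same window is applied to every channel. The default window
#' of 250--655 nm keeps every LED line (>= 255 nm) and all emission
#' structure while discarding the dead region below the shortest LED.
#'
#' @param channels List from [strip_nonspectral()].
#' @param window Two-element numeric window in nm, within \[185, 655\].
#' @return Trimmed channel list.
#' @export
trim_channels <- function(channels, window = c(250, 655)) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing 2-element interval")
  if (window[1] < WAVELENGTH_MIN || window[2] > WAVELENGTH_MAX)
    stop("window outside [", WAVELENGTH_MIN, ", ", WAVELENGTH_MAX, "] nm")
  keep <- channels$wavelengths >= window[1] & channels$wavelengths <= window[2]
  if (!any(keep)) stop("trim window contains no pixels")
  list(values = channels$values[, keep, drop = FALSE],
       wavelengths = channels$wavelengths[keep],
       led_index = channels$led_index)
}

#' Average neighbouring pixels into bins
#'
#' Step (iii): each channel's pixels are partitioned into `n_bins`
#' contiguous near-equal-width index windows (widths differ by at most one
#' pixel when the count does not divide evenly) and averaged; bin centres
#' are the mean wavelength of each window.
#'
#' @param channels Channel list (from [trim_channels()]).
#' @param n_bins Number of bins per channel, 1 <= n_bins <= pixels.
#' @return List with `values` (12 x n_bins), `bin_centers`, `led_index`.
#' @export
bin_average <- function(channels, n_bins = 360L) {
  npix <- ncol(channels$values)
  if (n_bins <= 0) stop("n_bins must be positive")
  if (n_bins > npix)
    stop("n_bins (", n_bins, ") exceeds pixels per channel (", npix, ")")
  edges <- floor(seq(0, npix, length.out = n_bins + 1))
  grp <- rep(seq_len(n_bins), times = diff(edges))
  vals <- t(apply(channels$values, 1L,
                  function(row) tapply(row, grp, mean)))
  centers <- as.numeric(tapply(channels$wavelengths, grp, mean))
  structure(list(values = unname(vals), bin_centers = centers,
                 led_index = channels$led_index),
            class = "hsf_channels")
}

#' Min-max normalize each channel to \[0, 1\]
#'
#' Step (iv): every channel (row) is mapped by `(x - min) / (max - min)`.
#' A constant row (e.g. a dark channel of a blank) maps to all zeros.
#'
#' @param channels An `hsf_channels` (or compatible list).
#' @return Same structure with each row in \[0, 1\].
#' @export
normalize_channels <- function(channels) {
  vals <- channels$values
  if (nrow(vals) != 12L) stop("channel matrix must have 12 rows")
  if (any(!is.finite(vals))) stop("non-finite values in channel matrix")
  for (i in seq_len(nrow(vals))) {
    rng <- range(vals[i, ])
    vals[i, ] <- if (rng[2] > rng[1])
      (vals[i, ] - rng[1]) / (rng[2] - rng[1]) else 0
  }
  channels$values <- vals
  channels
}

#' Pad and reshape a channel matrix into the 66 x 66 x 1 fingerprint
#'
#' Step (v): the 12 x B matrix is flattened row-major (channel by channel,
#' each channel in ascending wavelength), padded with `4356 - 12 B`
#' trailing zeros, and reshaped row-major into 66 x 66 x 1.
#'
#' @param channels An `hsf_channels`.
#' @param provenance Optional source scan identifier.
#' @return Object of class `hsf_matrix`: list with `values`
#'   (66 x 66 x 1 array), `pad_count`, `provenance`.
#' @export
pad_reshape <- function(channels, provenance = NA_character_) {
  vals <- channels$values
  n <- length(vals)
  if (n > 4356L)
    stop("12 x ", ncol(vals), " = ", n, " values exceed 66 x 66 = 4356; ",
         "use a smaller bin count")
  flat <- c(as.vector(t(vals)), rep(0, 4356L - n))
  arr <- array(0, dim = c(66L, 66L, 1L))
  arr[, , 1L] <- matrix(flat, nrow = 66L, ncol = 66L, byrow = TRUE)
  structure(list(values = arr, pad_count = 4356L - n,
                 n_bins = ncol(vals), provenance = provenance),
            class = "hsf_matrix")
}

#' @export
print.hsf_matrix <- function(x, ...) {
  cat(sprintf("<hsf_matrix> 66 x 66 x 1, %d channels x %d bins, pad %d\n",
              12L, x$n_bins, x$pad_count))
  invisible(x)
}

# Inverse of pad_reshape for round-trip checks.
unpad_unreshape <- function(fp) {
  flat <- as.vector(t(fp$values[, , 1L]))
  n <- 4356L - fp$pad_count
  matrix(flat[seq_len(n)], nrow = 12L, byrow = TRUE)
}

#' Full preprocessing pipeline: raw scan to fingerprint
#'
#' Applies, in order: exposure normalization, nonspectral-column removal,
#' wavelength trim, per-channel binning, per-channel \[0,1\] min-max
#' normalization, and pad/reshape to 66 x 66 x 1. Deterministic.
#'
#' @param scan An `hsf_scan`.
#' @param trim_window Wavelength window in nm, default c(250, 655).
#' @param n_bins Bins per channel, default 360 (12 x 360 = 4320 values plus
#'   36 zeros of padding).
#' @return An `hsf_matrix`.
#' @export
#' @examples
#' cfg <- device_config()
#' fp <- preprocess_scan(acquire_scan(make_sample(diazepam = 0.5), cfg, 1))
#' dim(fp$values)  # 66 66 1
preprocess_scan <- function(scan, trim_window = c(250, 655), n_bins = 360L) {
  ch <- strip_nonspectral(scan)
  ch <- trim_channels(ch, trim_window)
  ch <- bin_average(ch, n_bins)
  ch <- normalize_channels(ch)
  pad_reshape(ch, provenance = attr(scan, "sample_id") %||% NA_character_)
}

#' Write / read a fingerprint as delimited text
#'
#' Plain-text container: a `#` comment header carrying `pad_count`,
#' `n_bins` and provenance, followed by the 66 x 66 grid as comma-separated
#' rows.
#'
#' @param fp An `hsf_matrix`.
#' @param path File path.
#' @return `read_fingerprint` returns an `hsf_matrix`.
#' @export
write_fingerprint <- function(fp, path) {
  stopifnot(inherits(fp, "hsf_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  prov <- fp$provenance
  if (is.null(prov) || !length(prov)) prov <- NA_character_
  writeLines(sprintf("# hsf_matrix pad_count=%d n_bins=%d provenance=%s",
                     fp$pad_count, fp$n_bins, prov), con)
  utils::write.table(fp$values[, , 1L], con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# hsf_matrix", hdr)) stop("not a fingerprint file: ", path)
  gv <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", hdr)
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 1L))
  if (!all(dim(m) == c(66L, 66L))) stop("fingerprint grid is not 66 x 66")
  arr <- array(0, dim = c(66L, 66L, 1L))
  arr[, , 1L] <- unname(m)
  structure(list(values = arr, pad_count = as.integer(gv("pad_count")),
                 n_bins = as.integer(gv("n_bins")), provenance = gv("provenance")),
            class = "hsf_matrix")
}
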