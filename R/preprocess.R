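#' Preprocessing configuration
#'
#' @param sd_threshold spike detection threshold in units of each voxel's
#'   temporal SD (default 4).
#' @param extreme_fraction_threshold fraction of extreme voxels above
#'   which a volume is flagged as motion-affected (default 0.02, i.e. 2%).
#' @param highpass_cycles_per_run cutoff of the high-pass filter:
#'   frequencies strictly below this many cycles per run are removed
#'   (default 6).
#' @param remove_linear_trend also project out a linear trend (default
#'   TRUE).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sd_threshold = 4,
                              extreme_fraction_threshold = 0.02,
                              highpass_cycles_per_run = 6L,
                              remove_linear_trend = TRUE) {
  if (sd_threshold <= 0) stop("`sd_threshold` must be > 0")
  if (extreme_fraction_threshold <= 0 || extreme_fraction_threshold >= 1)
    stop("`extreme_fraction_threshold` must be in (0, 1)")
  if (highpass_cycles_per_run < 0)
    stop("`highpass_cycles_per_run` must be >= 0")
  structure(list(sd_threshold = sd_threshold,
                 extreme_fraction_threshold = extreme_fraction_threshold,
                 highpass_cycles_per_run = as.integer(highpass_cycles_per_run),
                 remove_linear_trend = remove_linear_trend),
            class = "preprocess_config")
}

#' High-pass filter an ROI time series
#'
#' Removes, per voxel, the mean, an optional linear trend, and all Fourier
#' components (sine and cosine) at 1 to `highpass_cycles_per_run - 1`
#' cycles per run, by projecting the time course onto that basis and
#' subtracting the projection. Frequencies at or above the cutoff are
#' attenuated by less than 5% in amplitude; the operation is idempotent.
#'
#' @param ts a [roi_timeseries()].
#' @param cfg a [preprocess_config()].
#' @return The filtered [roi_timeseries()].
#' @export
highpass_filter <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- ncol(ts$data)
  k <- cfg$highpass_cycles_per_run
  min_vol <- 2L * k + 1L
  if (n <= 2L * k)
    stop(sprintf("high-pass at %d cycles/run needs more than %d volumes (got %d)",
                 k, 2L * k, n))
  u <- (seq_len(n) - 1) / n
  basis <- matrix(1, n, 1)
  if (cfg$remove_linear_trend) basis <- cbind(basis, u - mean(u))
  if (k >= 2L) for (f in seq_len(k - 1L))
    basis <- cbind(basis, cos(2 * pi * f * u), sin(2 * pi * f * u))
  qx <- qr(basis)
  fitted <- t(qr.fitted(qx, t(ts$data)))
  ts$data <- ts$data - fitted
  ts
}

#' Detect spike ("excessive motion") volumes
#'
#' For each volume, computes the fraction of voxels whose intensity
#' deviates from that voxel's temporal mean by more than
#' `sd_threshold` temporal SDs (two-sided). Volumes where this fraction
#' strictly exceeds `extreme_fraction_threshold` are flagged. Voxels with
#' zero temporal variance are excluded from the denominator.
#'
#' @param ts a [roi_timeseries()].
#' @param cfg a [preprocess_config()].
#' @return Integer vector of flagged volume indices (0-based).
#' @export
detect_spike_volumes <- function(ts, cfg = preprocess_config()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$data
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  ok <- s > 0
  if (!any(ok)) stop("all voxels are constant: spike detection undefined")
  z <- abs(x[ok, , drop = FALSE] - m[ok]) / s[ok]
  frac <- colMeans(z > cfg$sd_threshold)
  which(frac > cfg$extreme_fraction_threshold) - 1L
}

#' Scrub flagged volumes by spline interpolation or edge deletion
#'
#' Interior flagged volumes are replaced, per voxel, by a natural cubic
#' spline through all unflagged volumes. Flagged volumes at either end of
#' the run (including any flagged volumes contiguous with an edge, which
#' have no clean bordering volume on one side) are deleted. The returned
#' kept-volume map re-expresses original volume indices so block onsets
#' can be shifted accordingly.
#'
#' @param ts a [roi_timeseries()].
#' @param flagged integer vector of flagged volume indices (0-based), as
#'   returned by [detect_spike_volumes()].
#' @return A list with `ts` (the scrubbed [roi_timeseries()]) and
#'   `kept_map`, a data frame mapping `original` (0-based index in the
#'   input) to `new` (0-based index in the output) for every retained
#'   volume.
#' @export
scrub_volumes <- function(ts, flagged) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- ncol(ts$data)
  flagged <- sort(unique(as.integer(flagged)))
  if (length(flagged) && (min(flagged) < 0 || max(flagged) >= n))
    stop("flagged indices outside 0..", n - 1L)
  if (length(flagged) >= n - 1L)
    stop("fewer than 2 unflagged volumes remain")
  idx <- seq_len(n) - 1L
  if (!length(flagged)) {
    return(list(ts = ts, kept_map = data.frame(original = idx, new = idx)))
  }
  is_flag <- idx %in% flagged
  # contiguous flagged stretches touching either run edge are deleted
  drop <- rep(FALSE, n)
  i <- 1L
  while (i <= n && is_flag[i]) { drop[i] <- TRUE; i <- i + 1L }
  i <- n
  while (i >= 1L && is_flag[i]) { drop[i] <- TRUE; i <- i - 1L }
  interior <- which(is_flag & !drop)
  if (length(interior)) {
    good <- which(!is_flag)
    for (v in seq_len(nrow(ts$data))) {
      ts$data[v, interior] <- spline(
        x = idx[good], y = ts$data[v, good], xout = idx[interior],
        method = "natural")$y
    }
  }
  keep <- which(!drop)
  ts$data <- ts$data[, keep, drop = FALSE]
  list(ts = ts,
       kept_map = data.frame(original = idx[keep],
                             new = seq_along(keep) - 1L))
}

#' Run the full temporal preprocessing chain on one run
#'
#' Applies [highpass_filter()], [detect_spike_volumes()] and
#' [scrub_volumes()] in that order and shifts block onsets when leading
#' volumes were deleted.
#'
#' @param ts a [roi_timeseries()].
#' @param design the run's [block_design()] (onsets re-expressed if edge
#'   volumes are removed); may be NULL.
#' @param cfg a [preprocess_config()].
#' @return List with `ts`, `design`, `flagged` (0-based flagged volumes)
#'   and `kept_map`.
#' @export
preprocess_run <- function(ts, design = NULL, cfg = preprocess_config()) {
  ts <- highpass_filter(ts, cfg)
  flagged <- detect_spike_volumes(ts, cfg)
  scr <- scrub_volumes(ts, flagged)
  if (!is.null(design)) {
    shift <- scr$kept_map$original[1] * ts$tr
    if (shift > 0) {
      design$onset_s <- design$onset_s - shift
      if (any(design$onset_s < 0))
        warning("block onset precedes run start after edge scrubbing")
    }
    attr(design, "total_duration") <-
      attr(design, "total_duration") - shift
  }
  list(ts = scr$ts, design = design, flagged = flagged,
       kept_map = scr$kept_map)
}
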