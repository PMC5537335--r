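#' Canonical double-gamma HRF parameters
#'
#' The haemodynamic response is modelled as the difference of two
#' gamma-density lobes: a positive peak around 5-6 s and a late negative
#' undershoot around 15-16 s of relative depth `undershoot_ratio`.
#' Defaults are the canonical values used throughout fMRI analysis.
#'
#' @param peak_delay time-to-peak parameter of the positive lobe (s).
#' @param undershoot_delay delay parameter of the undershoot lobe (s).
#' @param peak_dispersion,undershoot_dispersion dispersion (width) of the
#'   two lobes (s).
#' @param undershoot_ratio depth of the undershoot relative to the peak.
#' @param duration support of the HRF kernel (s).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, duration = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, undershoot_ratio, duration)
  if (any(vals <= 0)) stop("all HRF parameters must be positive")
  if (undershoot_delay <= peak_delay)
    stop("`undershoot_delay` must exceed `peak_delay`")
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 duration = duration),
            class = "hrf_params")
}

#' Evaluate the double-gamma HRF
#'
#' Each lobe is a gamma density with shape `delay/dispersion` and rate
#' `1/dispersion`, peak-normalized; the undershoot lobe is subtracted
#' with weight `undershoot_ratio` and the result is rescaled to peak 1.
#' The curve is 0 at t = 0, rises to a single positive peak, and dips into
#' a negative undershoot of relative depth about `undershoot_ratio`.
#'
#' @param t non-negative, increasing time grid (s).
#' @param p an [hrf_params()].
#' @return Numeric vector of HRF amplitudes on `t`.
#' @export
double_gamma_hrf <- function(t, p = hrf_params()) {
  if (any(t < 0)) stop("`t` must be non-negative")
  if (is.unsorted(t)) stop("`t` must be increasing")
  # lobes parameterized by their mode: shape = 1 + delay/dispersion puts
  # the gamma density's peak exactly at `delay`
  lobe <- function(delay, disp) {
    shape <- 1 + delay / disp
    g <- stats::dgamma(t, shape = shape, rate = 1 / disp)
    g / stats::dgamma(delay, shape = shape, rate = 1 / disp)
  }
  h <- lobe(p$peak_delay, p$peak_dispersion) -
    p$undershoot_ratio * lobe(p$undershoot_delay, p$undershoot_dispersion)
  h[t > p$duration] <- 0
  h / max(h)
}

#' Build a block GLM design matrix
#'
#' One regressor per block: a unit boxcar over the block's onset/duration
#' convolved with the double-gamma HRF at 0.1 s resolution, then sampled
#' at volume acquisition times `k * tr` (k = 0-based volume index).
#' Columns are ordered by block onset; an intercept column is appended.
#'
#' @param design a [block_design()].
#' @param n_volumes number of acquired volumes.
#' @param tr repetition time (s).
#' @param p an [hrf_params()].
#' @param intercept append an intercept column (default TRUE).
#' @return `n_volumes` x (B + intercept) numeric matrix; block columns are
#'   named `block_<index>`.
#' @export
build_design_matrix <- function(design, n_volumes, tr, p = hrf_params(),
                                intercept = TRUE) {
  dt <- 0.1
  ends <- design$onset_s + design$duration_s
  run_end <- n_volumes * tr
  if (any(design$onset_s > run_end))
    stop("block onset beyond run end")
  if (nrow(design) > 1) {
    o <- order(design$onset_s)
    if (any(design$onset_s[o][-1] < head(ends[o], -1)))
      stop("overlapping blocks in design")
  }
  grid_len <- ceiling((max(c(ends, run_end)) + p$duration) / dt) + 1L
  tgrid <- (seq_len(grid_len) - 1) * dt
  hrf <- double_gamma_hrf(seq(0, p$duration, by = dt), p)
  vol_idx <- round(seq(0, by = tr, length.out = n_volumes) / dt) + 1L
  B <- nrow(design)
  X <- matrix(0, n_volumes, B)
  if (B > 0) {
    o <- order(design$onset_s)
    for (j in seq_len(B)) {
      b <- o[j]
      box <- as.numeric(tgrid >= design$onset_s[b] & tgrid < ends[b])
      conv <- convolve(box, rev(hrf), type = "open")[seq_len(grid_len)] * dt
      X[, j] <- conv[vol_idx]
    }
    colnames(X) <- paste0("block_", design$block_index[o])
  }
  if (intercept) {
    X <- cbind(X, intercept = 1)
  }
  X
}

#' Estimate per-block response amplitudes (beta series)
#'
#' Fits, per voxel, one joint ordinary-least-squares GLM against the
#' block design matrix (one HRF-convolved regressor per block plus an
#' intercept). The resulting betas form the V x B pattern matrix; block
#' condition labels and run ids are carried from the design.
#'
#' @param ts a (preprocessed) [roi_timeseries()].
#' @param design the run's [block_design()], onsets re-expressed through
#'   the kept-volume map if scrubbing removed edge volumes.
#' @param p an [hrf_params()].
#' @return A [pattern_matrix()] (V x B).
#' @export
estimate_block_betas <- function(ts, design, p = hrf_params()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- build_design_matrix(design, ncol(ts$data), ts$tr, p)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, t(ts$data))            # (B+1) x V
  o <- order(design$onset_s)
  betas <- t(coefs[seq_len(nrow(design)), , drop = FALSE])  # V x B
  pattern_matrix(betas,
                 condition_labels = design$condition[o],
                 run_ids = design$run[o],
                 session_id = ts$session_id, subject_id = ts$subject_id)
}

#' Z-score a pattern matrix across voxels
#'
#' Each block column is independently standardized to mean 0 and SD 1
#' across the ROI's voxels (sample SD, denominator V - 1). Because each
#' pattern is normalized using only its own voxels, the operation cannot
#' leak information across blocks or cross-validation folds.
#'
#' @param pm a [pattern_matrix()] with V >= 2.
#' @return The z-scored [pattern_matrix()].
#' @export
zscore_patterns <- function(pm) {
  stopifnot(inherits(pm, "pattern_matrix"))
  if (nrow(pm$betas) < 2L) stop("z-scoring needs at least 2 voxels")
  s <- apply(pm$betas, 2, sd)
  if (any(s == 0))
    stop("zero variance across voxels in block(s): ",
         paste(which(s == 0), collapse = ", "))
  pm$betas <- scale(pm$betas, center = TRUE, scale = s)
  attr(pm$betas, "scaled:center") <- NULL
  attr(pm$betas, "scaled:scale") <- NULL
  pm
}

#' Combine per-run pattern matrices into one session-level matrix
#'
#' @param pms list of [pattern_matrix()] objects (same voxels, one per run).
#' @return A single [pattern_matrix()] with blocks of all runs.
#' @export
bind_patterns <- function(pms) {
  stopifnot(length(pms) >= 1L)
  pattern_matrix(do.call(cbind, lapply(pms, `[[`, "betas")),
                 condition_labels = unlist(lapply(pms, `[[`,
                                                  "condition_labels")),
                 run_ids = unlist(lapply(pms, `[[`, "run_ids")),
                 roi_id = pms[[1]]$roi_id,
                 session_id = pms[[1]]$session_id,
                 subject_id = pms[[1]]$subject_id)
}
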