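#' Per-voxel localizer GLM with object contrasts
#'
#' Fits, per voxel, an OLS GLM with one HRF-convolved regressor per
#' condition (objects, scrambled) plus an intercept, and returns t
#' statistics for the object-responsive contrast (objects - scrambled)
#' and the object-positive contrast (objects - 0). Voxels with zero
#' residual variance (noiseless degenerate fits) receive a capped
#' sentinel t of +/- 1e6.
#'
#' @param ts a [roi_timeseries()] over the candidate voxel set.
#' @param design the localizer [block_design()] with conditions
#'   `objects` and `scrambled`.
#' @param p an [hrf_params()].
#' @return A list of class `localizer_result` with
#'   `t_objects_gt_scrambled`, `t_objects_gt_baseline` (length-V),
#'   `dof`, and the contrast estimates.
#' @export
localizer_glm <- function(ts, design, p = hrf_params()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  conds <- sort(unique(design$condition))
  if (!identical(conds, c("objects", "scrambled")))
    stop("localizer design must have conditions 'objects' and 'scrambled'")
  n_vol <- ncol(ts$data)
  Xb <- build_design_matrix(design, n_vol, ts$tr, p, intercept = FALSE)
  o <- order(design$onset_s)
  X <- cbind(objects = rowSums(Xb[, design$condition[o] == "objects",
                                  drop = FALSE]),
             scrambled = rowSums(Xb[, design$condition[o] == "scrambled",
                                    drop = FALSE]),
             intercept = 1)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient localizer design")
  coefs <- qr.coef(qx, t(ts$data))              # 3 x V
  resid <- t(ts$data) - X %*% coefs
  dof <- n_vol - ncol(X)
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  tstat <- function(contrast) {
    est <- drop(crossprod(contrast, coefs))
    se <- sqrt(pmax(sigma2, 0) * drop(crossprod(contrast,
                                                XtXinv %*% contrast)))
    tt <- ifelse(se > 0, est / se, sign(est) * 1e6)
    tt <- sign(tt) * pmin(abs(tt), 1e6)   # documented sentinel cap
    list(estimate = est, t = tt)
  }
  c_resp <- tstat(c(1, -1, 0))   # objects > scrambled
  c_pos <- tstat(c(1, 0, 0))     # objects > baseline
  structure(list(t_objects_gt_scrambled = c_resp$t,
                 est_objects_gt_scrambled = c_resp$estimate,
                 t_objects_gt_baseline = c_pos$t,
                 est_objects_gt_baseline = c_pos$estimate,
                 dof = dof),
            class = "localizer_result")
}

#' Conjunction ROI selection with Bonferroni correction
#'
#' A voxel enters the ROI iff both one-sided contrasts (objects >
#' scrambled AND objects > baseline) are individually significant at the
#' Bonferroni-corrected level `alpha / n_tests` (minimum-statistic
#' conjunction under the conjunction null).
#'
#' @param res a `localizer_result` from [localizer_glm()].
#' @param n_tests number of tests corrected for (>= number of voxels).
#' @param alpha family significance level (default 0.05).
#' @return Logical length-V mask.
#' @export
conjunction_roi <- function(res, n_tests = length(res$t_objects_gt_baseline),
                            alpha = 0.05) {
  V <- length(res$t_objects_gt_baseline)
  if (n_tests < V) stop("`n_tests` must be at least the number of voxels")
  thr <- alpha / n_tests
  p1 <- pt(res$t_objects_gt_scrambled, df = res$dof, lower.tail = FALSE)
  p2 <- pt(res$t_objects_gt_baseline, df = res$dof, lower.tail = FALSE)
  (p1 < thr) & (p2 < thr)
}

#' Group-average fallback ROI for subjects without localizer voxels
#'
#' Voxelwise majority vote across the supplied subject masks: a voxel is
#' included iff it appears in strictly more than half of them.
#'
#' @param masks list of logical vectors of equal length (per-subject
#'   masks), at least one of which is non-empty.
#' @return Logical mask of the same length.
#' @export
fallback_roi <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  if (!any(vapply(masks, any, logical(1))))
    stop("all supplied masks are empty")
  prop <- Reduce(`+`, lapply(masks, as.numeric)) / length(masks)
  prop > 0.5
}
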