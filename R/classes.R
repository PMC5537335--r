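#' ROI time-series container
#'
#' Wraps a voxels x volumes numeric matrix for a single acquisition run
#' together with its sampling interval and identity. Volume `k` (0-based)
#' samples time `k * tr` seconds; slice timing is out of scope.
#'
#' @param data numeric matrix, voxels in rows, volumes in columns.
#' @param tr repetition time in seconds (> 0).
#' @param run_id,session_id,subject_id identifiers carried through the
#'   pipeline (any atomic scalar).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr, run_id = 1L, session_id = 1L,
                           subject_id = 1L) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data))
    stop("`data` must be a numeric matrix without missing values")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stop("need at least 1 voxel and 2 volumes")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)")
  structure(list(data = data, tr = tr, run_id = run_id,
                 session_id = session_id, subject_id = subject_id),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "<roi_timeseries> %d voxels x %d volumes, TR = %gs (subject %s, session %s, run %s)\n",
    nrow(x$data), ncol(x$data), x$tr, x$subject_id, x$session_id, x$run_id))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

#' Block-design timing table
#'
#' An ordered data frame of stimulus blocks (one row per block) with
#' columns `run`, `block_index`, `condition`, `onset_s`, `duration_s`.
#' The attribute `total_duration` records the run length in seconds
#' (including trailing rest), used to size simulated runs.
#'
#' @param blocks data frame with the columns listed above.
#' @param total_duration run duration in seconds; defaults to the last
#'   block offset plus 16 s of trailing rest.
#' @return An object of class `block_design` (a data frame).
#' @export
block_design <- function(blocks, total_duration = NULL) {
  need <- c("run", "block_index", "condition", "onset_s", "duration_s")
  if (!all(need %in% names(blocks)))
    stop("design table needs columns: ", paste(need, collapse = ", "))
  blocks <- as.data.frame(blocks)[need]
  if (is.unsorted(blocks$onset_s, strictly = TRUE))
    stop("block onsets must be strictly increasing")
  if (is.null(total_duration))
    total_duration <- max(blocks$onset_s + blocks$duration_s) + 16
  structure(blocks, total_duration = total_duration,
            class = c("block_design", "data.frame"))
}

#' Pattern matrix of block response amplitudes
#'
#' The decoding substrate: a V x B matrix of per-voxel, per-block response
#' amplitudes (betas), with one condition label and one run id per block
#' column.
#'
#' @param betas numeric V x B matrix.
#' @param condition_labels character vector of length B.
#' @param run_ids vector of length B.
#' @param roi_id,session_id,subject_id identifiers.
#' @return An object of class `pattern_matrix`.
#' @export
pattern_matrix <- function(betas, condition_labels, run_ids,
                           roi_id = "roi", session_id = 1L,
                           subject_id = 1L) {
  betas <- as.matrix(betas)
  condition_labels <- as.character(condition_labels)
  if (length(condition_labels) != ncol(betas))
    stop("one condition label per block column required")
  if (length(run_ids) != ncol(betas))
    stop("one run id per block column required")
  structure(list(betas = betas, condition_labels = condition_labels,
                 run_ids = run_ids, roi_id = roi_id,
                 session_id = session_id, subject_id = subject_id),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("<pattern_matrix> %d voxels x %d blocks (%s), runs: %s\n",
              nrow(x$betas), ncol(x$betas),
              paste(unique(x$condition_labels), collapse = "/"),
              paste(unique(x$run_ids), collapse = ",")))
  invisible(x)
}

#' @export
dim.pattern_matrix <- function(x) dim(x$betas)
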