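#' Simulation configuration for synthetic ROI datasets
#'
#' Defines the experimental design and noise model used by all generators:
#' a two-session (deprived/satiated), three-run block design with three
#' stimulus conditions (cigarette, pencil, chair), eight blocks per
#' condition per run, eight 1.5 s stimuli per block with 50 ms
#' inter-stimulus interval (block duration 12.4 s), rest intervals drawn
#' uniformly from {10, 12, 14} s, and TR = 2 s.
#'
#' Multivariate signal strength is controlled by `pattern_separation`: for
#' each session and condition pair, a standardized pattern distance
#' \eqn{d = \lVert\mu_a-\mu_b\rVert / (\sigma\sqrt{V})}, i.e. the
#' root-mean-square per-voxel mean difference in units of the voxel noise
#' SD. `d = 0` makes the conditions identical (null data).
#'
#' @param n_subjects number of simulated participants.
#' @param n_voxels number of ROI voxels V.
#' @param n_runs_per_session runs per scanning session.
#' @param blocks_per_condition_per_run stimulus blocks per condition per run.
#' @param stimuli_per_block,stimulus_duration,isi block composition:
#'   number of stimuli, stimulus duration (s) and inter-stimulus interval
#'   (s); block duration is `stimuli_per_block * (stimulus_duration + isi)`.
#' @param rest_choices rest interval durations (s) sampled uniformly
#'   between consecutive blocks.
#' @param tr repetition time (s).
#' @param conditions condition labels.
#' @param sessions session labels.
#' @param pattern_separation named list, one element per session, each a
#'   named numeric vector of standardized distances `d >= 0` keyed by
#'   condition pair as `"a|b"` (alphabetical order). See
#'   [pair_key()]. Pairs omitted default to 0.
#' @param noise_sd marginal SD of the AR(1) voxel noise (signal units).
#' @param ar1_coef lag-1 autoregressive coefficient in [0, 1).
#' @param drift_amplitude SD of per-voxel low-order polynomial drift
#'   coefficients (signal units).
#' @param spike_rate per-volume probability of a motion spike.
#' @param spike_magnitude spike offset in multiples of `noise_sd`.
#' @param seed base random seed; all subject/session/run streams are
#'   derived deterministically from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 10L, n_voxels = 200L,
                       n_runs_per_session = 3L,
                       blocks_per_condition_per_run = 8L,
                       stimuli_per_block = 8L, stimulus_duration = 1.5,
                       isi = 0.05, rest_choices = c(10, 12, 14), tr = 2,
                       conditions = c("cigarette", "pencil", "chair"),
                       sessions = c("deprived", "satiated"),
                       pattern_separation = NULL,
                       noise_sd = 1, ar1_coef = 0.3, drift_amplitude = 0.5,
                       spike_rate = 0.01, spike_magnitude = 8,
                       seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_voxels = n_voxels,
              n_runs_per_session = n_runs_per_session,
              blocks_per_condition_per_run = blocks_per_condition_per_run,
              stimuli_per_block = stimuli_per_block)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (tr <= 0) stop("`tr` must be > 0")
  if (ar1_coef < 0 || ar1_coef >= 1) stop("`ar1_coef` must be in [0, 1)")
  if (spike_rate < 0 || spike_rate > 1) stop("`spike_rate` must be in [0, 1]")
  if (noise_sd < 0 || drift_amplitude < 0)
    stop("`noise_sd` and `drift_amplitude` must be >= 0")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  if (is.null(pattern_separation))
    pattern_separation <- default_separation(sessions, conditions)
  for (s in sessions) {
    ps <- pattern_separation[[s]]
    if (!is.null(ps) && any(ps < 0)) stop("effect sizes d must be >= 0")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
    n_runs_per_session = as.integer(n_runs_per_session),
    blocks_per_condition_per_run = as.integer(blocks_per_condition_per_run),
    stimuli_per_block = as.integer(stimuli_per_block),
    stimulus_duration = stimulus_duration, isi = isi,
    rest_choices = rest_choices, tr = tr, conditions = conditions,
    sessions = sessions, pattern_separation = pattern_separation,
    noise_sd = noise_sd, ar1_coef = ar1_coef,
    drift_amplitude = drift_amplitude, spike_rate = spike_rate,
    spike_magnitude = spike_magnitude, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects, V=%d, %d runs/session, %d blocks/cond/run, TR=%gs\n",
    x$n_subjects, x$n_voxels, x$n_runs_per_session,
    x$blocks_per_condition_per_run, x$tr))
  invisible(x)
}

#' Canonical key for an unordered condition pair
#'
#' @param a,b condition labels.
#' @return `"a|b"` with the labels in alphabetical order.
#' @export
pair_key <- function(a, b) {
  p <- sort(c(as.character(a), as.character(b)))
  paste(p, collapse = "|")
}

# Default effect sizes: cigarette/pencil weakly separable under deprivation
# and near-null under satiation; the visually distinct chair pairs well
# separable in both sessions. Values are calibrated so cross-validated
# decoding accuracies at V = 200 fall in the 53-80% range typical of
# block-design object decoding; per-voxel d is small because the
# simulator's noise is voxelwise independent, which makes multivariate
# pooling across voxels highly efficient.
default_separation <- function(sessions, conditions) {
  pairs <- utils::combn(sort(conditions), 2)
  keys <- apply(pairs, 2, paste, collapse = "|")
  out <- list()
  for (s in sessions) {
    d <- stats::setNames(rep(0.035, length(keys)), keys)
    cp <- pair_key("cigarette", "pencil")
    if (cp %in% keys) d[cp] <- if (s == "satiated") 0.005 else 0.02
    out[[s]] <- d
  }
  out
}

block_duration <- function(config)
  config$stimuli_per_block * (config$stimulus_duration + config$isi)

#' Generate a randomized block-design timing table for one run
#'
#' Blocks (`blocks_per_condition_per_run` per condition) are placed in
#' random order, separated by rest intervals drawn uniformly from
#' `rest_choices`; the run starts and ends with a rest interval.
#'
#' @param config a [sim_config()].
#' @param run_index run number (recorded in the `run` column).
#' @param seed optional seed for this design.
#' @return A [block_design()] with attribute `total_duration`.
#' @export
generate_block_design <- function(config, run_index = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- rep(config$conditions, each = config$blocks_per_condition_per_run)
  conds <- sample(conds)
  nb <- length(conds)
  dur <- block_duration(config)
  rests <- sample(config$rest_choices, nb + 1L, replace = TRUE)
  gaps <- if (nb > 1L) dur + rests[2:nb] else numeric(0)
  onsets <- rests[1L] + c(0, cumsum(gaps))
  total <- onsets[nb] + dur + rests[nb + 1L]
  block_design(data.frame(run = run_index, block_index = seq_len(nb),
                          condition = conds, onset_s = onsets,
                          duration_s = dur),
               total_duration = total)
}

#' Generate condition mean patterns with calibrated pairwise separation
#'
#' Constructs one length-V mean-amplitude vector per condition such that
#' each pair's standardized pattern distance
#' \eqn{\lVert\mu_a-\mu_b\rVert/(\sigma\sqrt{V})} equals the configured
#' `d` exactly. The target distance matrix is embedded by classical
#' multidimensional scaling and mapped into voxel space along random
#' orthonormal directions, on top of a common baseline response.
#'
#' @param config a [sim_config()].
#' @param session session label (selects the `pattern_separation` entry).
#' @param seed optional seed.
#' @param noise_sd noise SD used for standardization (defaults to
#'   `config$noise_sd`); supplied separately so between-subject noise
#'   jitter keeps `d` calibrated.
#' @return A `ground_truth` list with `condition_mean_patterns` (named
#'   list of length-V vectors), empty `spike_locations`, and `drift_params`.
#' @export
generate_condition_patterns <- function(config, session = config$sessions[1],
                                        seed = NULL,
                                        noise_sd = config$noise_sd) {
  if (!is.null(seed)) set.seed(seed)
  conds <- config$conditions
  k <- length(conds)
  V <- config$n_voxels
  d <- config$pattern_separation[[session]]
  D <- matrix(0, k, k, dimnames = list(conds, conds))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    key <- pair_key(conds[i], conds[j])
    dij <- if (!is.null(d) && key %in% names(d)) d[[key]] else 0
    D[i, j] <- D[j, i] <- dij * noise_sd * sqrt(V)
  }
  coords <- mds_embed(D)                      # k x m, m <= k-1
  base <- rnorm(V, mean = 1, sd = 0.2)        # shared baseline response
  if (ncol(coords) > 0) {
    Q <- qr.Q(qr(matrix(rnorm(V * ncol(coords)), V)))  # orthonormal dirs
    pats <- lapply(seq_len(k), function(i) base + drop(Q %*% coords[i, ]))
  } else {
    pats <- rep(list(base), k)
  }
  names(pats) <- conds
  structure(list(condition_mean_patterns = pats,
                 spike_locations = data.frame(run = integer(),
                                              volume = integer()),
                 drift_params = list()),
            class = "ground_truth")
}

# Classical MDS embedding of a target distance matrix; errors if the
# distances are not Euclidean-realizable (negative Gram eigenvalues).
mds_embed <- function(D) {
  k <- nrow(D)
  if (all(D == 0)) return(matrix(0, k, 0))
  J <- diag(k) - 1 / k
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  if (min(e$values) < -tol)
    stop("infeasible pairwise separations: no point configuration ",
         "realizes the requested distances")
  keep <- which(e$values > tol)
  if (!length(keep)) return(matrix(0, k, 0))
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
}

#' Simulate an ROI time series for one run
#'
#' The voxel x volume matrix is the sum of (i) HRF-convolved block
#' responses with per-voxel condition amplitudes, (ii) stationary AR(1)
#' Gaussian noise with marginal SD `noise_sd`, (iii) per-voxel low-order
#' polynomial drift, and (iv) optional additive motion spikes on a random
#' voxel subset of flagged volumes.
#'
#' @param design a [block_design()] for this run.
#' @param patterns a `ground_truth` from [generate_condition_patterns()]
#'   (or a named list of length-V amplitude vectors).
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @param hrf [hrf_params()] used to build the signal.
#' @return A [roi_timeseries()] with attributes `spike_volumes` (0-based
#'   flagged volume indices), `spike_sign`, and `drift_params`.
#' @export
generate_roi_timeseries <- function(design, patterns, config, seed = NULL,
                                    hrf = hrf_params()) {
  if (!is.null(seed)) set.seed(seed)
  pats <- if (inherits(patterns, "ground_truth"))
    patterns$condition_mean_patterns else patterns
  V <- length(pats[[1]])
  total <- attr(design, "total_duration")
  n_vol <- floor(total / config$tr)
  if (max(design$onset_s + design$duration_s) > total)
    stop("design extends beyond the requested run duration")
  X <- build_design_matrix(design, n_vol, config$tr, hrf,
                           intercept = FALSE)
  amp <- vapply(design$condition, function(cc) pats[[cc]],
                numeric(V))                         # V x B
  signal <- amp %*% t(X)                            # V x T

  noise <- matrix(0, V, n_vol)
  if (config$noise_sd > 0) {
    burn <- 50L
    innov <- matrix(rnorm(V * (n_vol + burn),
                          sd = config$noise_sd *
                            sqrt(1 - config$ar1_coef^2)),
                    nrow = n_vol + burn)
    ar <- stats::filter(innov, config$ar1_coef, method = "recursive")
    noise <- t(ar[(burn + 1):(n_vol + burn), , drop = FALSE])
  }

  drift <- matrix(0, V, n_vol)
  drift_coef <- matrix(0, V, 2)
  if (config$drift_amplitude > 0) {
    u <- seq(-1, 1, length.out = n_vol)
    basis <- cbind(u, 2 * u^2 - 1)                  # linear + quadratic
    drift_coef <- matrix(rnorm(V * 2, sd = config$drift_amplitude), V)
    drift <- drift_coef %*% t(basis)
  }

  dat <- signal + noise + drift
  spike_vols <- integer(0)
  spike_sign <- integer(0)
  if (config$spike_rate > 0) {
    spike_vols <- which(runif(n_vol) < config$spike_rate) - 1L
    spike_sign <- sample(c(-1L, 1L), length(spike_vols), replace = TRUE)
    for (i in seq_along(spike_vols)) {
      frac <- runif(1, 0.03, 0.08)
      vox <- sample.int(V, max(2L, round(frac * V)))
      dat[vox, spike_vols[i] + 1L] <- dat[vox, spike_vols[i] + 1L] +
        spike_sign[i] * config$spike_magnitude * config$noise_sd
    }
  }
  ts <- roi_timeseries(dat, tr = config$tr, run_id = design$run[1])
  attr(ts, "spike_volumes") <- spike_vols
  attr(ts, "spike_sign") <- spike_sign
  attr(ts, "drift_params") <- drift_coef
  ts
}

#' Generate a full multi-subject, two-session cohort
#'
#' Deterministic given `config$seed`: subject-, session- and run-level
#' random streams are derived from it. Between-subject variability is a
#' subject-specific +/-20% jitter of the noise SD and independently drawn
#' pattern directions per subject (the configured standardized distances
#' `d` are preserved exactly for every subject).
#'
#' @param config a [sim_config()].
#' @return An object of class `mvpa_cohort`: a list with `config` and
#'   `subjects`, where `subjects[[i]]$sessions[[s]]` holds `runs` (list of
#'   [roi_timeseries()]), `designs` (list of [block_design()]) and `truth`
#'   (a `ground_truth` including spike locations per run).
#' @export
generate_cohort <- function(config) {
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, 1L, i))
    subj_noise <- config$noise_sd * runif(1, 0.8, 1.2)
    cfg_i <- config
    cfg_i$noise_sd <- subj_noise
    sess <- list()
    for (s in seq_along(config$sessions)) {
      sname <- config$sessions[s]
      truth <- generate_condition_patterns(
        config, sname, seed = derive_seed(config$seed, 2L, i, s),
        noise_sd = subj_noise)
      runs <- designs <- vector("list", config$n_runs_per_session)
      spikes <- data.frame(run = integer(), volume = integer())
      for (r in seq_len(config$n_runs_per_session)) {
        rs <- derive_seed(config$seed, 3L, i, s, r)
        designs[[r]] <- generate_block_design(cfg_i, run_index = r,
                                              seed = rs)
        ts <- generate_roi_timeseries(designs[[r]], truth, cfg_i,
                                      seed = rs + 1L)
        ts$subject_id <- i; ts$session_id <- sname
        sv <- attr(ts, "spike_volumes")
        if (length(sv))
          spikes <- rbind(spikes, data.frame(run = r, volume = sv))
        truth$drift_params[[r]] <- attr(ts, "drift_params")
        runs[[r]] <- ts
      }
      truth$spike_locations <- spikes
      sess[[sname]] <- list(runs = runs, designs = designs, truth = truth)
    }
    subjects[[i]] <- list(subject_id = i, noise_sd = subj_noise,
                          sessions = sess)
  }
  structure(list(config = config, subjects = subjects),
            class = "mvpa_cohort")
}

#' @export
print.mvpa_cohort <- function(x, ...) {
  cat(sprintf("<mvpa_cohort> %d subjects x %d sessions x %d runs (V=%d)\n",
              length(x$subjects), length(x$config$sessions),
              x$config$n_runs_per_session, x$config$n_voxels))
  invisible(x)
}

#' Simulate an object localizer run
#'
#' Two-condition (objects vs scrambled objects) block design: 12 blocks
#' per condition of 10 stimuli each (1.2 s + 0.6 s ISI, block duration
#' 21.6 s), interleaved with 12.6 s fixation, TR 1.8 s. A configurable
#' fraction of voxels is object-selective (responds to both conditions,
#' more strongly to intact objects); the rest respond to neither.
#'
#' @param n_voxels candidate voxel count.
#' @param selective_fraction fraction of truly object-selective voxels,
#'   in (0, 1).
#' @param n_blocks_per_condition blocks per condition.
#' @param stimuli_per_block,stimulus_duration,isi block composition (s).
#' @param fixation_duration fixation interval between blocks (s).
#' @param tr repetition time (s).
#' @param amp_objects,amp_scrambled response amplitudes of selective
#'   voxels to the two conditions (`amp_objects > amp_scrambled > 0`).
#' @param noise_sd,ar1_coef noise model as in [sim_config()].
#' @param seed optional seed.
#' @return A list with `ts` ([roi_timeseries()]), `design`
#'   ([block_design()]) and `truth_mask` (logical length-V vector of
#'   selective voxels).
#' @export
generate_localizer <- function(n_voxels = 100L, selective_fraction = 0.3,
                               n_blocks_per_condition = 12L,
                               stimuli_per_block = 12L,
                               stimulus_duration = 1.2, isi = 0.6,
                               fixation_duration = 12.6, tr = 1.8,
                               amp_objects = 1, amp_scrambled = 0.5,
                               noise_sd = 1, ar1_coef = 0.3,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (selective_fraction < 0 || selective_fraction >= 1)
    stop("`selective_fraction` must be in [0, 1)")
  conds <- sample(rep(c("objects", "scrambled"), n_blocks_per_condition))
  nb <- length(conds)
  dur <- stimuli_per_block * (stimulus_duration + isi)
  onsets <- fixation_duration +
    (seq_len(nb) - 1L) * (dur + fixation_duration)
  total <- onsets[nb] + dur + fixation_duration
  design <- block_design(
    data.frame(run = 1L, block_index = seq_len(nb), condition = conds,
               onset_s = onsets, duration_s = dur),
    total_duration = total)

  n_sel <- round(selective_fraction * n_voxels)
  mask <- rep(FALSE, n_voxels)
  if (n_sel > 0) mask[sample.int(n_voxels, n_sel)] <- TRUE
  pats <- list(
    objects = ifelse(mask, amp_objects, 0),
    scrambled = ifelse(mask, amp_scrambled, 0))
  cfg <- sim_config(n_voxels = n_voxels, tr = tr, noise_sd = noise_sd,
                    ar1_coef = ar1_coef, drift_amplitude = 0,
                    spike_rate = 0)
  ts <- generate_roi_timeseries(design, pats, cfg)
  list(ts = ts, design = design, truth_mask = mask)
}
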