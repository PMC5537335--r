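#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end analysis. Every
#' stochastic stage receives a seed derived deterministically from
#' `seed`, so a given configuration always reproduces the same results.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param preprocess a [preprocess_config()].
#' @param hrf an [hrf_params()].
#' @param decoder a [decoder_config()] (its `seed` is overridden by
#'   derived per-subject seeds).
#' @param q FDR level for the group tables (default 0.05).
#' @param n_interaction_perm permutations for the interaction F test
#'   (default 10000).
#' @param roi_variants named list of logical voxel masks defining the ROI
#'   variants to analyse (default: one variant, `bilateral`, spanning all
#'   simulated voxels).
#' @param seed global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            preprocess = preprocess_config(),
                            hrf = hrf_params(),
                            decoder = decoder_config(),
                            q = 0.05, n_interaction_perm = 10000L,
                            roi_variants = NULL, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(preprocess, "preprocess_config"),
            inherits(hrf, "hrf_params"),
            inherits(decoder, "decoder_config"))
  if (is.null(roi_variants))
    roi_variants <- list(bilateral = rep(TRUE, sim$n_voxels))
  structure(list(sim = sim, preprocess = preprocess, hrf = hrf,
                 decoder = decoder, q = q,
                 n_interaction_perm = as.integer(n_interaction_perm),
                 roi_variants = roi_variants, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Compute z-scored session pattern matrices for one subject
#'
#' Preprocesses each run (high-pass, spike scrubbing), estimates block
#' betas, concatenates runs and z-scores each block pattern across
#' voxels.
#'
#' @param session_data a cohort session entry (`runs` + `designs`).
#' @param cfg a [pipeline_config()].
#' @return A [pattern_matrix()] for the session.
#' @export
session_patterns <- function(session_data, cfg) {
  pms <- lapply(seq_along(session_data$runs), function(r) {
    pre <- preprocess_run(session_data$runs[[r]],
                          session_data$designs[[r]], cfg$preprocess)
    estimate_block_betas(pre$ts, pre$design, cfg$hrf)
  })
  zscore_patterns(bind_patterns(pms))
}

condition_pairs <- function(conditions) {
  cp <- utils::combn(sort(conditions), 2)
  lapply(seq_len(ncol(cp)), function(i) cp[, i])
}

#' Run the full simulate-preprocess-decode-test analysis
#'
#' Generates (or accepts) a synthetic cohort, preprocesses every run,
#' estimates z-scored block patterns, decodes every condition pair in
#' every session and ROI variant with leave-one-run-out SVM
#' cross-validation plus a run-wise permutation null, and performs the
#' group-level tests: per pair x session, accuracy vs empirical chance;
#' per pair, the deprived-minus-satiated difference; BH-FDR within each
#' ROI variant's family of p-values; and the permutation
#' repeated-measures interaction F test (deprivation state x stimulus
#' pair).
#'
#' @param cfg a [pipeline_config()].
#' @param cohort optionally, a pre-generated `mvpa_cohort` (defaults to
#'   `generate_cohort(cfg$sim)`).
#' @return A list of class `mvpa_results` with `subject_table` (one row
#'   per subject x session x pair x ROI), `group_table`,
#'   `interaction_tests`, `null_distributions`, and `config`.
#' @export
run_full_analysis <- function(cfg = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(cfg$sim)
  sim <- cohort$config
  pairs <- condition_pairs(sim$conditions)
  sessions <- sim$sessions
  subj_rows <- list()
  records <- list()    # records[[roi]][[pair]][[session]][[subject]]
  nulls <- list()

  for (i in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[i]]
    for (sname in sessions) {
      pm_full <- session_patterns(subj$sessions[[sname]], cfg)
      for (roi in names(cfg$roi_variants)) {
        mask <- cfg$roi_variants[[roi]]
        pm <- pm_full
        pm$betas <- pm$betas[mask, , drop = FALSE]
        pm$roi_id <- roi
        for (pp in pairs) {
          key <- paste(pp, collapse = "|")
          ds <- assemble_pair(pm, pp[1], pp[2])
          dcfg <- cfg$decoder
          dcfg$seed <- derive_seed(cfg$seed, 4L, i,
                                   match(sname, sessions),
                                   match(key, vapply(pairs, paste,
                                                     "", collapse = "|")),
                                   match(roi, names(cfg$roi_variants)))
          res <- loro_cv(ds, dcfg)
          nul <- permutation_null(ds, dcfg)
          records[[roi]][[key]][[sname]][[i]] <-
            list(result = res, null = nul)
          nulls[[length(nulls) + 1L]] <- data.frame(
            subject = i, session = sname, pair = key, roi = roi,
            permutation = seq_along(nul$accuracies),
            accuracy = nul$accuracies)
          subj_rows[[length(subj_rows) + 1L]] <- data.frame(
            subject = i, session = sname, pair = key, roi = roi,
            mean_accuracy = res$mean_accuracy,
            null_mean = nul$mean_accuracy,
            t(stats::setNames(res$fold_accuracies,
                              paste0("fold_", names(res$fold_accuracies)))),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  subject_table <- do.call(rbind, subj_rows)

  group_rows <- list()
  interaction_tests <- list()
  for (roi in names(cfg$roi_variants)) {
    fam <- list()
    for (pp in pairs) {
      key <- paste(pp, collapse = "|")
      for (sname in sessions) {
        gt <- test_accuracy_vs_null(
          records[[roi]][[key]][[sname]],
          contrast_id = sprintf("%s:%s:%s", roi, key, sname))
        fam[[length(fam) + 1L]] <- cbind(gt, roi = roi, pair = key,
                                         session = sname,
                                         test = "accuracy_vs_null")
      }
      if (length(sessions) == 2L) {
        diffs <- lapply(seq_along(cohort$subjects), function(i)
          session_difference(records[[roi]][[key]][[sessions[1]]][[i]],
                             records[[roi]][[key]][[sessions[2]]][[i]]))
        gt <- test_session_difference_group(
          diffs, contrast_id = sprintf("%s:%s:D-S", roi, key))
        fam[[length(fam) + 1L]] <- cbind(gt, roi = roi, pair = key,
                                         session = "D-S",
                                         test = "session_difference")
      }
    }
    fam <- do.call(rbind, fam)
    fdr <- fdr_correct(fam$p_uncorrected, cfg$q)
    fam$p_fdr <- fdr$p_adjusted
    fam$significant_fdr <- fdr$significant
    group_rows[[roi]] <- fam

    if (length(sessions) == 2L && length(pairs) >= 2L) {
      tab <- array(NA_real_,
                   c(length(cohort$subjects), length(sessions),
                     length(pairs)))
      for (i in seq_along(cohort$subjects))
        for (s in seq_along(sessions))
          for (p in seq_along(pairs)) {
            key <- paste(pairs[[p]], collapse = "|")
            tab[i, s, p] <-
              records[[roi]][[key]][[sessions[s]]][[i]]$result$mean_accuracy
          }
      interaction_tests[[roi]] <- permutation_interaction_test(
        tab, n_perm = cfg$n_interaction_perm,
        seed = derive_seed(cfg$seed, 5L,
                           match(roi, names(cfg$roi_variants))))
    }
  }
  structure(list(subject_table = subject_table,
                 group_table = do.call(rbind, group_rows),
                 interaction_tests = interaction_tests,
                 null_distributions = do.call(rbind, nulls),
                 config = cfg),
            class = "mvpa_results")
}

#' @export
print.mvpa_results <- function(x, ...) {
  cat(sprintf("<mvpa_results> %d subject-level rows, %d group tests, %d interaction test(s)\n",
              nrow(x$subject_table), nrow(x$group_table),
              length(x$interaction_tests)))
  invisible(x)
}

#' Write an analysis results bundle to disk
#'
#' Writes the per-subject decoding table, the group test table, the
#' archived permutation-null distributions, a JSON echo of the
#' configuration (including all seeds), and a plain-text log, all as
#' delimited/JSON text files with documented headers.
#'
#' @param bundle an `mvpa_results` from [run_full_analysis()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, the named character vector of files written.
#' @export
write_results <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "mvpa_results"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- c(subject_table = file.path(outdir, "subject_decoding.csv"),
             group_table = file.path(outdir, "group_tests.csv"),
             nulls = file.path(outdir, "null_distributions.csv"),
             config = file.path(outdir, "config.json"),
             log = file.path(outdir, "run_log.txt"))
  write.csv(bundle$subject_table, files["subject_table"], row.names = FALSE)
  write.csv(bundle$group_table, files["group_table"], row.names = FALSE)
  write.csv(bundle$null_distributions, files["nulls"], row.names = FALSE)
  cfg <- bundle$config
  cfg_list <- list(sim = unclass(cfg$sim),
                   preprocess = unclass(cfg$preprocess),
                   hrf = unclass(cfg$hrf), decoder = unclass(cfg$decoder),
                   q = cfg$q, n_interaction_perm = cfg$n_interaction_perm,
                   roi_variants = lapply(cfg$roi_variants, sum),
                   seed = cfg$seed)
  jsonlite::write_json(cfg_list, files["config"], auto_unbox = TRUE,
                       digits = NA)
  inter <- vapply(bundle$interaction_tests, function(t)
    sprintf("F = %.4f, p = %.4g (%d perms)", t$f_observed, t$p_perm,
            t$n_perm), character(1))
  writeLines(c(sprintf("blockmvpa results written %s",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("global seed: %d", cfg$seed),
               sprintf("subject rows: %d; group tests: %d",
                       nrow(bundle$subject_table),
                       nrow(bundle$group_table)),
               sprintf("interaction [%s]: %s", names(inter), inter)),
             files["log"])
  invisible(files)
}

#' Ingest a 4D volumetric image, ROI mask and design table
#'
#' Extracts the masked voxel time series from a NIfTI-1 4D image using a
#' fixed linear voxel order (x fastest, then y, then z), and reads the
#' block-design table (columns `run`, `block_index`, `condition`,
#' `onset_s`, `duration_s`; onsets in seconds from run start).
#'
#' @param image_path path to the 4D NIfTI image (one run).
#' @param mask_path path to a 3D binary mask on the identical grid.
#' @param design_path path to the delimited design table.
#' @param tr repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header.
#' @return A list with `ts` (a [roi_timeseries()]) and `design`
#'   (a [block_design()]).
#' @export
ingest_volumetric <- function(image_path, mask_path, design_path,
                              tr = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("package 'RNifti' is required for volumetric ingestion")
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(img)) != 4L) stop("image must be 4D (x, y, z, time)")
  if (!identical(dim(img)[1:3], dim(msk)[1:3]))
    stop("mask grid does not match image grid")
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else
      stop("TR not recoverable from header; pass `tr` explicitly")
  }
  vox <- which(msk != 0)             # linear order: x fastest, then y, z
  if (!length(vox)) stop("mask selects no voxels")
  n_vol <- dim(img)[4]
  mat <- matrix(vapply(seq_len(n_vol),
                       function(k) as.numeric(img[, , , k])[vox],
                       numeric(length(vox))),
                nrow = length(vox))               # voxels x volumes
  design_df <- read.csv(design_path)
  run_dur <- n_vol * tr
  if (any(design_df$onset_s + design_df$duration_s > run_dur))
    stop("design extends beyond the acquired run (", run_dur, " s)")
  design <- block_design(design_df, total_duration = run_dur)
  list(ts = roi_timeseries(mat, tr = tr,
                           run_id = design_df$run[1]),
       design = design)
}
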