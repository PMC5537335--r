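test_that("block designs have the right counts, durations and rest structure", {
  cfg <- sim_config()
  des <- generate_block_design(cfg, run_index = 1L, seed = 11)
  expect_equal(nrow(des), 24L)
  expect_equal(as.integer(table(des$condition)), rep(8L, 3))
  expect_true(all(des$duration_s == 12.4))
  expect_true(all(diff(des$onset_s) > 0))
  gaps <- round(diff(des$onset_s) - 12.4, 9)
  expect_true(all(gaps %in% c(10, 12, 14)))
  expect_gt(attr(des, "total_duration"),
            max(des$onset_s + des$duration_s))

  # minimal design: one condition, one block
  cfg1 <- sim_config(blocks_per_condition_per_run = 1, conditions = "a",
                     pattern_separation = list(deprived = numeric(),
                                               satiated = numeric()))
  d1 <- generate_block_design(cfg1, seed = 2)
  expect_equal(nrow(d1), 1L)
  expect_true(d1$onset_s %in% c(10, 12, 14))
})

test_that("rest intervals are drawn uniformly from the configured choices", {
  cfg <- sim_config()
  set.seed(20240901)
  gaps <- unlist(lapply(seq_len(10000), function(i) {
    d <- generate_block_design(cfg)
    round(diff(d$onset_s) - d$duration_s[1], 9)
  }))
  freq <- table(factor(gaps, levels = c(10, 12, 14))) / length(gaps)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("condition patterns realize the configured standardized distances", {
  cfg <- sim_config(n_voxels = 200, pattern_separation = list(
    deprived = c("cigarette|pencil" = 0.5, "chair|cigarette" = 2,
                 "chair|pencil" = 2),
    satiated = c("cigarette|pencil" = 0.5, "chair|cigarette" = 2,
                 "chair|pencil" = 2)))
  gt <- generate_condition_patterns(cfg, "deprived", seed = 5)
  pats <- gt$condition_mean_patterns
  sdist <- function(a, b)
    sqrt(sum((pats[[a]] - pats[[b]])^2)) / (cfg$noise_sd * sqrt(200))
  expect_equal(sdist("cigarette", "pencil"), 0.5, tolerance = 0.1)
  expect_equal(sdist("chair", "cigarette"), 2, tolerance = 0.1)
  expect_equal(sdist("chair", "pencil"), 2, tolerance = 0.1)

  # all d = 0: identical patterns
  cfg0 <- sim_config(n_voxels = 50)
  cfg0$pattern_separation <- list(
    deprived = stats::setNames(rep(0, 3), names(cfg0$pattern_separation$deprived)),
    satiated = cfg0$pattern_separation$satiated)
  g0 <- generate_condition_patterns(cfg0, "deprived", seed = 5)
  expect_identical(g0$condition_mean_patterns$cigarette,
                   g0$condition_mean_patterns$chair)

  # doubling d doubles all pairwise distances
  cfg2 <- cfg
  cfg2$pattern_separation <- lapply(cfg$pattern_separation, `*`, 2)
  g1 <- generate_condition_patterns(cfg, "deprived", seed = 9)
  g2 <- generate_condition_patterns(cfg2, "deprived", seed = 9)
  d1 <- sqrt(sum((g1$condition_mean_patterns$cigarette -
                  g1$condition_mean_patterns$pencil)^2))
  d2 <- sqrt(sum((g2$condition_mean_patterns$cigarette -
                  g2$condition_mean_patterns$pencil)^2))
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
})

test_that("infeasible pairwise separations are rejected", {
  cfg <- sim_config(pattern_separation = list(
    deprived = c("cigarette|pencil" = 3, "chair|cigarette" = 0.5,
                 "chair|pencil" = 0.5),
    satiated = c("cigarette|pencil" = 0, "chair|cigarette" = 0,
                 "chair|pencil" = 0)))
  expect_error(generate_condition_patterns(cfg, "deprived", seed = 1),
               "infeasible")
})

test_that("noiseless time series equal the HRF-convolved design exactly", {
  cfg <- two_cond_config(d = 0, V = 1, noise_sd = 0, drift_amplitude = 0)
  cfg$spike_rate <- 0
  des <- generate_block_design(
    sim_config(blocks_per_condition_per_run = 1, conditions = "a",
               pattern_separation = list(deprived = numeric(),
                                         satiated = numeric())),
    seed = 3)
  pats <- list(a = 1)
  ts <- generate_roi_timeseries(des, pats, cfg, seed = 4)
  X <- build_design_matrix(des, ncol(ts$data), cfg$tr, hrf_params(),
                           intercept = FALSE)
  expect_equal(drop(ts$data), drop(X[, 1]), tolerance = 1e-12)
  expect_length(attr(ts, "spike_volumes"), 0)
})

test_that("AR(1) noise has the configured marginal moments and autocorrelation", {
  cfg <- sim_config(n_voxels = 2, conditions = "a",
                    pattern_separation = list(deprived = numeric(),
                                              satiated = numeric()),
                    noise_sd = 1.5, ar1_coef = 0.4, drift_amplitude = 0,
                    spike_rate = 0)
  des <- block_design(data.frame(run = 1, block_index = 1, condition = "a",
                                 onset_s = 10, duration_s = 12.4),
                      total_duration = 20000)
  pats <- list(a = c(0, 0))
  ts <- generate_roi_timeseries(des, pats, cfg, seed = 8)
  x <- ts$data[1, ]
  expect_equal(mean(x), 0, tolerance = 0.1)
  expect_equal(sd(x), 1.5, tolerance = 0.1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, 0.4, tolerance = 0.05)
})

test_that("cohort generation is deterministic and has the study geometry", {
  cfg <- sim_config(n_subjects = 3, n_voxels = 20, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(c1$subjects, 3L)
  s1 <- c1$subjects[[1]]
  expect_setequal(names(s1$sessions), c("deprived", "satiated"))
  expect_length(s1$sessions$deprived$runs, 3L)
  expect_equal(dim(s1$sessions$deprived$runs[[1]]$data)[1], 20L)
  # different subjects get different noise realizations
  expect_false(identical(c1$subjects[[1]]$sessions$deprived$runs[[1]]$data,
                         c1$subjects[[2]]$sessions$deprived$runs[[1]]$data))
  # spike bookkeeping: spike_rate = 0 leaves no recorded spikes
  cfg0 <- sim_config(n_subjects = 1, n_voxels = 10, spike_rate = 0)
  c0 <- generate_cohort(cfg0)
  expect_equal(nrow(c0$subjects[[1]]$sessions$deprived$truth$spike_locations),
               0L)
})

test_that("localizer simulation has the quoted timing and truth mask", {
  loc <- generate_localizer(n_voxels = 100, selective_fraction = 0.3,
                            noise_sd = 0, seed = 21)
  expect_equal(nrow(loc$design), 24L)
  expect_equal(as.integer(table(loc$design$condition)), c(12L, 12L))
  expect_true(all(abs(loc$design$duration_s - 21.6) < 1e-9))
  gaps <- diff(loc$design$onset_s) - 21.6
  expect_true(all(abs(gaps - 12.6) < 1e-9))
  expect_equal(sum(loc$truth_mask), 30L)
  expect_equal(loc$ts$tr, 1.8)

  loc0 <- generate_localizer(n_voxels = 50, selective_fraction = 0,
                             seed = 3)
  expect_equal(sum(loc0$truth_mask), 0L)
})
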