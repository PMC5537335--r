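test_that("pair assembly keeps labels, balance and run structure", {
  set.seed(2)
  pm <- make_null_patterns(V = 10)
  ds <- assemble_pair(pm, "a", "b")
  expect_equal(nrow(ds$X), 48L)
  expect_equal(as.integer(table(ds$y)), c(24L, 24L))
  for (r in 1:3)
    expect_equal(as.integer(table(ds$y[ds$runs == r])), c(8L, 8L))
  expect_identical(levels(ds$y), c("a", "b"))
  expect_error(assemble_pair(pm, "a", "a"), "differ")
  expect_error(assemble_pair(pm, "a", "zebra"), "not present")
})

test_that("the linear SVM matches libsvm and a QP oracle", {
  # separable clouds: perfect training accuracy
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 3), 20, 2), matrix(rnorm(40, -3), 20, 2))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- train_linear_classifier(X, y, 1)
  expect_equal(mean(predict(fit, X) == y), 1)

  # toy problem against the dual QP oracle
  Xt <- rbind(c(-1, 0), c(1, 0), c(0, 1), c(0, -1), c(2, 2))
  yt <- factor(c("A", "A", "B", "B", "B"))
  ft <- train_linear_classifier(Xt, yt, 1)
  qp <- oracle_svm_qp(Xt, yt, 1)
  expect_lt(max(abs(ft$weights - qp$weights)), 1e-4)
  expect_lt(abs(ft$bias - qp$bias), 1e-4)

  # random problems against libsvm (e1071)
  for (i in 1:5) {
    set.seed(100 + i)
    Xr <- matrix(rnorm(30 * 6), 30)
    yr <- factor(rep(c("a", "b"), 15))
    Xr[yr == "a", 1] <- Xr[yr == "a", 1] + 1
    fr <- train_linear_classifier(Xr, yr, 1)
    m <- e1071::svm(Xr, yr, kernel = "linear", cost = 1, scale = FALSE)
    expect_lt(max(abs(fr$weights - drop(t(m$coefs) %*% m$SV))), 5e-3)
    expect_lt(abs(fr$bias - (-m$rho)), 5e-3)
  }

  # duplicating every example leaves the boundary unchanged at large C
  set.seed(11)
  Xd <- matrix(rnorm(20 * 3), 20)
  yd <- factor(rep(c("a", "b"), 10))
  Xd[yd == "a", 1] <- Xd[yd == "a", 1] + 3
  f1 <- train_linear_classifier(Xd, yd, 100)
  f2 <- train_linear_classifier(rbind(Xd, Xd), c(yd, yd), 100)
  expect_lt(max(abs(f1$weights - f2$weights)) / max(abs(f1$weights)),
            1e-3)

  expect_error(train_linear_classifier(Xd, factor(rep("a", 20)), 1),
               "2 classes")
})

test_that("leave-one-run-out folds are bookkept correctly", {
  set.seed(3)
  pm <- make_signal_patterns(V = 20, delta = 3)
  ds <- assemble_pair(pm, "a", "b")
  res <- loro_cv(ds)
  expect_length(res$fold_accuracies, 3L)
  expect_identical(sort(names(res$fold_accuracies)), c("1", "2", "3"))
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies) * 100)
  # strong separation: ceiling accuracy
  expect_equal(res$mean_accuracy, 100)
  # test-set order invariance (no leakage through example order)
  perm <- order(ds$runs, rev(seq_along(ds$runs)))
  ds2 <- ds; ds2$X <- ds$X[perm, ]; ds2$y <- ds$y[perm]
  ds2$runs <- ds$runs[perm]
  expect_equal(loro_cv(ds2)$mean_accuracy, res$mean_accuracy)
})

test_that("null decoding accuracy is centred on 50%", {
  set.seed(202)
  accs <- vapply(seq_len(100), function(i)
    loro_cv(assemble_pair(make_null_patterns(V = 30), "a", "b"))$mean_accuracy,
    numeric(1))
  expect_lt(abs(mean(accs) - 50), 3)
})

test_that("run-wise permutation null is centred, seeded and scope-aware", {
  set.seed(4)
  pm <- make_signal_patterns(V = 25, delta = 1.5)
  ds <- assemble_pair(pm, "a", "b")
  cfg <- decoder_config(n_permutations = 1000, seed = 77)
  nd <- permutation_null(ds, cfg)
  expect_length(nd$accuracies, 1000L)
  expect_lt(abs(nd$mean_accuracy - 50), 2)
  # determinism under the same seed
  nd2 <- permutation_null(ds, cfg)
  expect_identical(nd$accuracies, nd2$accuracies)
  # train_and_test scope also yields a centred null
  cfg2 <- decoder_config(n_permutations = 400, seed = 78,
                         permutation_scope = "train_and_test")
  expect_lt(abs(permutation_null(ds, cfg2)$mean_accuracy - 50), 3)
})

test_that("sampled permutation null matches exhaustive enumeration on a toy", {
  set.seed(6)
  pm <- make_null_patterns(V = 8, n_runs = 2, blocks_per_cond = 2)
  pm$betas[, pm$condition_labels == "b"] <- pm$betas[, pm$condition_labels == "b"] + 0.8
  pm <- zscore_patterns(pm)
  ds <- assemble_pair(pm, "a", "b")
  runs <- unique(ds$runs)
  # exhaustive: within-run label assignments of the training run determine
  # each fold; average fold accuracy over all distinct assignments
  fold_means <- vapply(runs, function(r) {
    tr <- which(ds$runs != r); te <- which(ds$runs == r)
    labelings <- unique(enumerate_run_labelings(as.character(ds$y[tr])))
    accs <- vapply(labelings, function(lab) {
      fit <- train_linear_classifier(ds$X[tr, ], factor(lab, levels(ds$y)), 1)
      mean(as.character(predict(fit, ds$X[te, ])) ==
             as.character(ds$y[te]))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  exact_mean <- mean(fold_means) * 100
  nd <- permutation_null(ds, decoder_config(n_permutations = 2000,
                                            seed = 123))
  expect_lt(abs(nd$mean_accuracy - exact_mean), 1)
})

test_that("session differences are antisymmetric and correctly paired", {
  set.seed(8)
  pm <- make_signal_patterns(V = 15, delta = 1)
  ds <- assemble_pair(pm, "a", "b")
  rec <- list(result = loro_cv(ds),
              null = permutation_null(ds, decoder_config(n_permutations = 50)))
  # identical sessions: zero differences
  d0 <- session_difference(rec, rec)
  expect_equal(d0$accuracy_diff, 0)
  expect_equal(d0$null_mean_diff, 0)
  # constructed values reproduce a known D-S difference
  dep <- rec; sat <- rec
  dep$result$mean_accuracy <- 61.0
  sat$result$mean_accuracy <- 53.5
  expect_equal(session_difference(dep, sat)$accuracy_diff, 7.5)
  # antisymmetry
  d1 <- session_difference(dep, sat)
  d2 <- session_difference(sat, dep)
  expect_equal(d1$accuracy_diff, -d2$accuracy_diff)
  expect_equal(d1$null_mean_diff, -d2$null_mean_diff)
  # mismatched pair is an error
  pm2 <- make_null_patterns(V = 15, conditions = c("a", "c"))
  rec2 <- list(result = loro_cv(assemble_pair(pm2, "a", "c")),
               null = rec$null)
  expect_error(session_difference(rec, rec2), "different condition pairs")
})
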