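#' Decoder configuration
#'
#' @param svm_c soft-margin penalty C of the linear SVM (default 1).
#' @param n_permutations number of run-wise label permutations used to
#'   estimate the empirical chance distribution (default 1000).
#' @param permutation_scope `"train_only"` (default): labels are shuffled
#'   within each training run and accuracy is scored against the true
#'   test labels; `"train_and_test"`: labels are shuffled within every
#'   run and accuracy is scored against the permuted test labels. Both
#'   destroy the label-pattern association and yield a valid null.
#' @param seed seed for the permutation stream.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(svm_c = 1, n_permutations = 1000L,
                           permutation_scope = c("train_only",
                                                 "train_and_test"),
                           seed = 1L) {
  if (svm_c <= 0) stop("`svm_c` must be > 0")
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  structure(list(svm_c = svm_c,
                 n_permutations = as.integer(n_permutations),
                 permutation_scope = match.arg(permutation_scope),
                 seed = as.integer(seed)),
            class = "decoder_config")
}

#' Extract a two-condition labelled dataset from a pattern matrix
#'
#' @param pm a [pattern_matrix()] (typically z-scored).
#' @param a,b the two condition labels to decode.
#' @return A list of class `pair_dataset` with `X` (examples x voxels),
#'   `y` (factor with levels sorted alphabetically), `runs`, `pair`,
#'   and identifiers carried from `pm`.
#' @export
assemble_pair <- function(pm, a, b) {
  stopifnot(inherits(pm, "pattern_matrix"))
  a <- as.character(a); b <- as.character(b)
  if (a == b) stop("the two conditions must differ")
  for (cc in c(a, b))
    if (!cc %in% pm$condition_labels)
      stop("condition not present in pattern matrix: ", cc)
  keep <- pm$condition_labels %in% c(a, b)
  structure(list(X = t(pm$betas[, keep, drop = FALSE]),
                 y = factor(pm$condition_labels[keep],
                            levels = sort(c(a, b))),
                 runs = pm$run_ids[keep],
                 pair = sort(c(a, b)), roi_id = pm$roi_id,
                 session_id = pm$session_id, subject_id = pm$subject_id),
            class = "pair_dataset")
}

#' Train a soft-margin linear SVM
#'
#' Solves the standard C-SVC dual by sequential minimal optimization on
#' the linear kernel. Predictions are `sign(w . x + b)`; a decision value
#' of exactly 0 is assigned to the alphabetically first class label
#' (deterministic tie rule).
#'
#' @param X numeric examples x features matrix.
#' @param y two-level factor (or vector coercible to one).
#' @param c penalty parameter C (> 0).
#' @return A list of class `linear_svm` with `weights`, `bias`, `levels`
#'   (class labels; first level is the positive class), and `alpha`.
#' @export
train_linear_classifier <- function(X, y, c = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("need examples from exactly 2 classes, got ", nlevels(y))
  K <- tcrossprod(X)
  fit <- svm_fit_kernel(K, y, c)
  w <- drop(crossprod(X, fit$coef))
  structure(list(weights = w, bias = fit$b, levels = levels(y),
                 alpha = fit$alpha, svm_c = c),
            class = "linear_svm")
}

# Kernel-level SVM fit: y a 2-level factor aligned with rows of K.
# First factor level is coded +1. Returns alpha, signed coefficients
# (alpha_i * y_i) and intercept b.
svm_fit_kernel <- function(K, y, c) {
  ysign <- ifelse(as.integer(y) == 1L, 1, -1)
  if (length(unique(ysign)) < 2L)
    stop("need examples from exactly 2 classes")
  sol <- .smo_solve(K, ysign, c)
  list(alpha = sol$alpha, coef = sol$alpha * ysign, b = sol$b,
       ysign = ysign)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  # f >= 0 -> first (alphabetically first) level
  factor(ifelse(f >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

# decision values for test rows given a precomputed cross-Gram block
# Ktest (n_test x n_train) and a kernel-level fit
decision_from_kernel <- function(Ktest, fit) {
  drop(Ktest %*% fit$coef) + fit$b
}

#' Leave-one-run-out cross-validated decoding
#'
#' For each run r, trains the linear SVM on all other runs and scores the
#' proportion of correctly labelled blocks in run r. The mean over folds
#' is reported in percent.
#'
#' @param dataset a `pair_dataset` from [assemble_pair()].
#' @param cfg a [decoder_config()].
#' @return A list of class `decoding_result` with `pair`, `session_id`,
#'   `roi_id`, `subject_id`, `fold_accuracies` (one proportion per
#'   left-out run, named by run) and `mean_accuracy` (percent).
#' @export
loro_cv <- function(dataset, cfg = decoder_config()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  runs <- unique(dataset$runs)
  if (length(runs) < 2L) stop("leave-one-run-out needs at least 2 runs")
  K <- tcrossprod(dataset$X)
  acc <- vapply(runs, function(r) {
    tr <- dataset$runs != r
    if (length(unique(dataset$y[tr])) < 2L)
      stop("training folds must contain both classes (left-out run ", r, ")")
    fit <- svm_fit_kernel(K[tr, tr, drop = FALSE], dataset$y[tr], cfg$svm_c)
    f <- decision_from_kernel(K[!tr, tr, drop = FALSE], fit)
    pred <- ifelse(f >= 0, levels(dataset$y)[1], levels(dataset$y)[2])
    mean(pred == as.character(dataset$y[!tr]))
  }, numeric(1))
  structure(list(pair = dataset$pair, session_id = dataset$session_id,
                 roi_id = dataset$roi_id, subject_id = dataset$subject_id,
                 fold_accuracies = stats::setNames(acc, runs),
                 mean_accuracy = mean(acc) * 100),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s vs %s (session %s): %.1f%% (folds: %s)\n",
              x$pair[1], x$pair[2], x$session_id, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracies), collapse = ", ")))
  invisible(x)
}

#' Run-wise label-permutation empirical chance distribution
#'
#' Per iteration, condition labels are shuffled independently within each
#' run (preserving each run's label counts), the classifier is retrained
#' for every leave-one-run-out fold, and the cross-validated accuracy is
#' recorded. The resulting distribution estimates the empirical chance
#' level of the decoder under the null hypothesis of no label-pattern
#' association.
#'
#' @param dataset a `pair_dataset` from [assemble_pair()].
#' @param cfg a [decoder_config()]; `n_permutations`, `permutation_scope`
#'   and `seed` control the procedure.
#' @return A list of class `null_distribution` with `accuracies`
#'   (percent, length `n_permutations`) and `mean_accuracy`.
#' @export
permutation_null <- function(dataset, cfg = decoder_config()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  runs <- unique(dataset$runs)
  if (length(runs) < 2L) stop("leave-one-run-out needs at least 2 runs")
  set.seed(cfg$seed)
  K <- tcrossprod(dataset$X)
  run_idx <- lapply(runs, function(r) which(dataset$runs == r))
  names(run_idx) <- as.character(runs)
  lev <- levels(dataset$y)
  y_true <- as.character(dataset$y)
  shuffle_all <- cfg$permutation_scope == "train_and_test"
  acc <- numeric(cfg$n_permutations)
  for (it in seq_len(cfg$n_permutations)) {
    y_perm <- y_true
    for (ri in run_idx) y_perm[ri] <- sample(y_true[ri])
    fold_acc <- vapply(seq_along(runs), function(k) {
      te <- run_idx[[k]]
      tr <- setdiff(seq_along(y_true), te)
      y_tr <- factor(y_perm[tr], levels = lev)
      fit <- svm_fit_kernel(K[tr, tr, drop = FALSE], y_tr, cfg$svm_c)
      f <- decision_from_kernel(K[te, tr, drop = FALSE], fit)
      pred <- ifelse(f >= 0, lev[1], lev[2])
      ref <- if (shuffle_all) y_perm[te] else y_true[te]
      mean(pred == ref)
    }, numeric(1))
    acc[it] <- mean(fold_acc) * 100
  }
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 pair = dataset$pair, session_id = dataset$session_id,
                 roi_id = dataset$roi_id, subject_id = dataset$subject_id,
                 scope = cfg$permutation_scope),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d permutations, mean = %.2f%% (sd %.2f)\n",
    length(x$accuracies), x$mean_accuracy, sd(x$accuracies)))
  invisible(x)
}

#' Deprived-minus-satiated session difference for one subject
#'
#' Computes the per-subject inputs to the group-level D-S test: the
#' difference of true cross-validated accuracies between the two sessions
#' and the matching difference of permutation-null means.
#'
#' @param dep,sat lists with elements `result` (a `decoding_result`) and
#'   `null` (a `null_distribution`) for the deprived and satiated session
#'   of the same subject, condition pair and ROI.
#' @return A list with `accuracy_diff` and `null_mean_diff` (percentage
#'   points) plus identifiers.
#' @export
session_difference <- function(dep, sat) {
  if (!identical(dep$result$pair, sat$result$pair))
    stop("session records decode different condition pairs")
  if (!identical(dep$result$roi_id, sat$result$roi_id))
    stop("session records come from different ROIs")
  list(pair = dep$result$pair, roi_id = dep$result$roi_id,
       subject_id = dep$result$subject_id,
       accuracy_diff = dep$result$mean_accuracy - sat$result$mean_accuracy,
       null_mean_diff = dep$null$mean_accuracy - sat$null$mean_accuracy)
}
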