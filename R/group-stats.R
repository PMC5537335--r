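#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original treatment), ties
#' receive midranks, and W is the smaller of the positive- and
#' negative-signed rank sums. For n <= `exact_limit` retained pairs the
#' two-sided p-value is exact, computed by enumerating all 2^n sign
#' assignments (valid under ties); above that, a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @param exact_limit largest n for which full enumeration is used
#'   (default 15).
#' @return A list of class `wilcoxon_result` with `statistic` (W),
#'   `p_value` (two-sided), `n` (pairs retained after zero removal),
#'   `method` (`"exact"` or `"normal"`), and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 15L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (anyNA(d)) stop("missing values in paired differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = 0, p_value = 1, n = 0L,
                          method = "degenerate", all_zero = TRUE),
                     class = "wilcoxon_result"))
  r <- rank(abs(d))                      # midranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  if (n <= exact_limit) {
    # all 2^n sign assignments; smaller signed-rank sum per assignment
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- signs %*% r
    tot <- sum(r)
    wmin <- pmin(sums, tot - sums)
    p <- mean(wmin <= W + 1e-9)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu + 0.5) / sqrt(sigma2)   # continuity-corrected
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  structure(list(statistic = W, p_value = p, n = n, method = method,
                 all_zero = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' Group test of decoding accuracy against the empirical chance level
#'
#' Paired Wilcoxon signed-rank test of per-subject cross-validated
#' accuracy against the per-subject mean of the permutation null
#' distribution.
#'
#' @param results list over subjects, each with elements `result` (a
#'   `decoding_result`) and `null` (a `null_distribution`).
#' @param contrast_id identifier recorded in the output.
#' @return A one-row data frame of class `group_test_result` with
#'   `contrast_id`, `statistic`, `p_uncorrected`, `n_subjects`,
#'   `mean_accuracy` and `mean_null`.
#' @export
test_accuracy_vs_null <- function(results, contrast_id = "accuracy_vs_null") {
  if (length(results) < 2L) stop("need at least 2 subjects")
  acc <- vapply(results, function(r) {
    if (is.null(r$result$mean_accuracy) || is.null(r$null$mean_accuracy))
      stop("each subject needs a decoding result and a null distribution")
    r$result$mean_accuracy
  }, numeric(1))
  nul <- vapply(results, function(r) r$null$mean_accuracy, numeric(1))
  wt <- wilcoxon_signed_rank(acc, nul)
  structure(data.frame(contrast_id = contrast_id,
                       statistic = wt$statistic,
                       p_uncorrected = wt$p_value,
                       n_subjects = wt$n,
                       mean_accuracy = mean(acc), mean_null = mean(nul),
                       stringsAsFactors = FALSE),
            class = c("group_test_result", "data.frame"))
}

#' Group test of the deprived-minus-satiated accuracy difference
#'
#' Paired Wilcoxon signed-rank test of per-subject session accuracy
#' differences against the matching differences of permutation-null
#' means.
#'
#' @param diffs list over subjects of [session_difference()] records.
#' @param contrast_id identifier recorded in the output.
#' @return A one-row `group_test_result` data frame (columns as in
#'   [test_accuracy_vs_null()], with `mean_accuracy`/`mean_null` holding
#'   the mean D-S differences).
#' @export
test_session_difference_group <- function(diffs,
                                          contrast_id = "session_difference") {
  if (length(diffs) < 2L) stop("need at least 2 subjects")
  ad <- vapply(diffs, `[[`, numeric(1), "accuracy_diff")
  nd <- vapply(diffs, `[[`, numeric(1), "null_mean_diff")
  wt <- wilcoxon_signed_rank(ad, nd)
  structure(data.frame(contrast_id = contrast_id,
                       statistic = wt$statistic,
                       p_uncorrected = wt$p_value,
                       n_subjects = wt$n,
                       mean_accuracy = mean(ad), mean_null = mean(nd),
                       stringsAsFactors = FALSE),
            class = c("group_test_result", "data.frame"))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values (monotone-enforced) with significance flags
#' at level `q`.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return A list with `p_adjusted` and logical `significant`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj < q)
}

#' Repeated-measures two-way interaction F statistic
#'
#' Computes the interaction F for a complete within-subject
#' subjects x A x B design (one observation per cell) from the standard
#' sum-of-squares decomposition, with the A x B x subject term as the
#' error:
#' \eqn{F = MS_{AB} / MS_{AB \times S}}.
#'
#' @param table numeric 3-d array, subjects x levels(A) x levels(B);
#'   here A is deprivation state (2) and B is stimulus pair (3).
#' @return The interaction F statistic (scalar).
#' @export
rm_anova_interaction_F <- function(table) {
  if (length(dim(table)) != 3L)
    stop("`table` must be a subjects x A x B array")
  if (anyNA(table)) stop("missing cells in the repeated-measures table")
  n <- dim(table)[1]; a <- dim(table)[2]; b <- dim(table)[3]
  if (n < 2L) stop("need at least 2 subjects")
  # flatten to subjects x cells; cell (i, j) maps to column i + (j-1)*a
  flat <- matrix(table, n, a * b)
  icol <- rep(seq_len(a), b)
  jcol <- rep(seq_len(b), each = a)
  m <- mean(flat)
  cm <- colMeans(flat)                          # cell means m_ij
  m_i <- vapply(seq_len(a), function(i) mean(cm[icol == i]), numeric(1))
  m_j <- vapply(seq_len(b), function(j) mean(cm[jcol == j]), numeric(1))
  m_s <- rowMeans(flat)
  m_si <- vapply(seq_len(a),
                 function(i) rowMeans(flat[, icol == i, drop = FALSE]),
                 numeric(n))
  m_sj <- vapply(seq_len(b),
                 function(j) rowMeans(flat[, jcol == j, drop = FALSE]),
                 numeric(n))
  if (n == 1L) { m_si <- matrix(m_si, 1L); m_sj <- matrix(m_sj, 1L) }
  ss_ab <- n * sum((cm - m_i[icol] - m_j[jcol] + m)^2)
  resid <- flat - matrix(cm - m_i[icol] - m_j[jcol], n, a * b,
                         byrow = TRUE) -
    m_si[, icol, drop = FALSE] - m_sj[, jcol, drop = FALSE] +
    (m_s - m)
  ss_abs <- sum(resid^2)
  df_ab <- (a - 1) * (b - 1)
  df_abs <- df_ab * (n - 1)
  ms_abs <- ss_abs / df_abs
  if (ms_abs < 1e-12) ms_abs <- 1e-12           # MS floor for exact-zero error
  (ss_ab / df_ab) / ms_abs
}

#' Permutation test of the repeated-measures interaction
#'
#' Per iteration, the A x B cell values are shuffled independently within
#' each participant (exchangeable under the null of no condition
#' effects), the interaction F is recomputed, and the p-value is the
#' smoothed proportion \eqn{(1 + \#\{F_{null} \ge F_{obs}\}) / (1 + m)}.
#' With `scope = "between"` whole cell vectors are instead permuted
#' across participants.
#'
#' @param table numeric subjects x 2 x 3 array of accuracies.
#' @param n_perm number of permutations (default 10000).
#' @param seed seed for the permutation stream.
#' @param scope `"within"` (default) or `"between"` participant shuffling.
#' @return A list of class `interaction_test_result` with `f_observed`,
#'   `f_null`, `p_perm`, `n_perm`.
#' @export
permutation_interaction_test <- function(table, n_perm = 10000L,
                                         seed = 1L,
                                         scope = c("within", "between")) {
  scope <- match.arg(scope)
  f_obs <- rm_anova_interaction_F(table)
  set.seed(seed)
  n <- dim(table)[1]; ncell <- dim(table)[2] * dim(table)[3]
  flat <- matrix(table, n, ncell)               # subjects x cells
  f_null <- numeric(n_perm)
  for (it in seq_len(n_perm)) {
    perm <- flat
    if (scope == "within") {
      for (s in seq_len(n)) perm[s, ] <- flat[s, sample.int(ncell)]
    } else {
      perm <- flat[sample.int(n), ]
    }
    dim(perm) <- dim(table)
    f_null[it] <- rm_anova_interaction_F(perm)
  }
  p <- (1 + sum(f_null >= f_obs)) / (1 + n_perm)
  structure(list(f_observed = f_obs, f_null = f_null, p_perm = p,
                 n_perm = as.integer(n_perm), scope = scope),
            class = "interaction_test_result")
}

#' @export
print.interaction_test_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_test_result> F = %.3f, p = %.4g (%d permutations, %s-subject)\n",
    x$f_observed, x$p_perm, x$n_perm, x$scope))
  invisible(x)
}
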