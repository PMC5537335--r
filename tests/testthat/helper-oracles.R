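# Independent oracles and fast fixtures used across the suite.

# --- fixtures ---------------------------------------------------------------

# Null pattern matrix: iid Gaussian betas, z-scored per block, with the
# experiment's run/block structure. Used for calibration tests where the
# time-series/GLM path would only add runtime, not information.
make_null_patterns <- function(V = 30, n_runs = 3, blocks_per_cond = 8,
                               conditions = c("a", "b")) {
  B <- n_runs * blocks_per_cond * length(conditions)
  labels <- rep(rep(conditions, each = blocks_per_cond), n_runs)
  runs <- rep(seq_len(n_runs), each = blocks_per_cond * length(conditions))
  zscore_patterns(pattern_matrix(matrix(rnorm(V * B), V), labels, runs))
}

# Pattern matrix with a fixed mean shift `delta` on half the voxels for
# condition "b" (separable signal injected directly at the beta level).
make_signal_patterns <- function(V = 30, n_runs = 3, blocks_per_cond = 8,
                                 delta = 1) {
  pm <- make_null_patterns(V, n_runs, blocks_per_cond)
  shift <- c(rep(delta, V %/% 2), rep(-delta, V - V %/% 2))
  pm$betas[, pm$condition_labels == "b"] <-
    pm$betas[, pm$condition_labels == "b"] + shift
  pm
}

# Minimal two-condition sim config with explicit uniform separation d.
two_cond_config <- function(d, V = 60, seed = 1, noise_sd = 1,
                            spike_rate = 0, drift_amplitude = 0.3) {
  sim_config(n_subjects = 1, n_voxels = V, conditions = c("a", "b"),
             sessions = "deprived",
             pattern_separation = list(
               deprived = stats::setNames(d, pair_key("a", "b"))),
             noise_sd = noise_sd, spike_rate = spike_rate,
             drift_amplitude = drift_amplitude, seed = seed)
}

# Simulate one subject-session and return the z-scored pattern matrix.
simulate_session_patterns <- function(cfg, session = "deprived") {
  cohort <- generate_cohort(cfg)
  session_patterns(cohort$subjects[[1]]$sessions[[session]],
                   pipeline_config(sim = cfg))
}

# --- oracles ----------------------------------------------------------------

# Brute-force Wilcoxon signed-rank: enumerate all 2^n sign assignments.
# Independent re-derivation (loop-based) of the exact two-sided p.
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  W_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  count <- 0L
  total <- 2^n
  for (m in 0:(total - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    w_pos <- sum(r[bits == 1L])
    if (min(w_pos, sum(r) - w_pos) <= W_obs + 1e-9) count <- count + 1L
  }
  list(W = W_obs, p = count / total)
}

# Direct implementation of the Benjamini-Hochberg step-up definition:
# adjusted p_(i) = min over j >= i of min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) min(1, m * p[o[j]] / j))
    adj_sorted[i] <- min(vals)
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Dual QP oracle for the soft-margin linear SVM via kernlab::ipop:
#   min 1/2 a'Qa - e'a  s.t. y'a = 0, 0 <= a <= C,  Q = (yy') * (XX')
oracle_svm_qp <- function(X, y01, C = 1) {
  y <- ifelse(y01 == levels(factor(y01))[1], 1, -1)
  K <- tcrossprod(as.matrix(X))
  H <- (y %o% y) * K
  n <- length(y)
  # tiny ridge keeps the interior-point solver away from exact singularity;
  # it perturbs alpha by O(1e-8)
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-8, n),
                       A = matrix(y, 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n),
                       sigf = 9, maxiter = 400)
  alpha <- kernlab::primal(sol)
  w <- drop(crossprod(as.matrix(X), alpha * y))
  free <- alpha > 1e-6 * C & alpha < C * (1 - 1e-6)
  b <- if (any(free))
    mean(y[free] - as.matrix(X)[free, , drop = FALSE] %*% w)
  else NA_real_
  list(alpha = alpha, weights = w, bias = b)
}

# All distinct within-run label assignments of a run's label multiset.
enumerate_run_labelings <- function(labels) {
  perms <- unique(combinat_permn(labels))
  perms
}

# Minimal permutation generator (avoids extra dependencies).
combinat_permn <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_permn(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

# Interaction F via stats::aov with a within-subject error stratum.
oracle_interaction_F_aov <- function(tab) {
  n <- dim(tab)[1]; a <- dim(tab)[2]; b <- dim(tab)[3]
  df <- expand.grid(subject = factor(seq_len(n)), A = factor(seq_len(a)),
                    B = factor(seq_len(b)))
  df$y <- as.vector(tab)
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = df)
  s <- summary(fit)
  fv <- s[["Error: subject:A:B"]][[1]]["A:B", "F value"]
  as.numeric(fv)
}
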