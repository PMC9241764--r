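# Shared fixtures and independent oracles used across the suite.

# Small count matrix with named samples/taxa.
make_counts <- function(m, samples = NULL, taxa = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- taxa %||% sprintf("t%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid metadata for a set of subjects; visits at orders 0..(k-1).
make_meta <- function(subjects, n_visits, group = "AS") {
  if (length(group) == 1) group <- rep(group, length(subjects))
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    k <- if (length(n_visits) == 1) n_visits else n_visits[i]
    data.frame(
      sample_id = sprintf("%s_T%d", subjects[i], seq_len(k) - 1),
      subject_id = subjects[i], collection_order = seq_len(k) - 1,
      time_point = seq_len(k) - 1, group = group[i],
      sample_type = c("baseline", rep("nonexacerbation", k - 1))[seq_len(k)],
      age = 10, stringsAsFactors = FALSE)
  }))
}

# Assignment table from a named vector sample_id -> mpg.
make_assign <- function(labels) {
  data.frame(sample_id = names(labels), mpg = unname(labels),
             dominant_fraction = 0.9, stringsAsFactors = FALSE)
}

# --- independent oracles ----------------------------------------------------

# Two-sided Fisher exact p by exhaustive enumeration over the support of the
# hypergeometric table distribution at fixed margins.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact signed-rank p by enumeration of all 2^n sign patterns.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs + 1e-9), mean(v_all >= v_obs - 1e-9)))
}

# All permutations of 1:n (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# One-factor PERMANOVA pseudo-F via the Gower-centred inner-product matrix.
gower_F <- function(d, groups) {
  n <- nrow(d)
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (d^2) %*% J
  X <- stats::model.matrix(~groups)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ssg <- sum(diag(H %*% G))
  sst <- sum(diag(G))
  dfg <- ncol(X) - 1
  (ssg / dfg) / ((sst - ssg) / (n - ncol(X)))
}

permanova_enum_p <- function(d, groups) {
  perms <- all_perms(nrow(d))
  f_obs <- gower_F(d, groups)
  f_all <- apply(perms, 1, function(ord) gower_F(d, groups[ord]))
  mean(f_all >= f_obs - 1e-12)
}

# --- simulator regimes used by several files -------------------------------

null_regime <- function(seed, n_subjects = 24)
  sim_config(n_subjects_AE = 0, n_subjects_AS = n_subjects, n_controls = 0,
             state_self_prob = npmdyn:::MPG_BASE_FREQ,
             trend_slope = stats::setNames(rep(0, 6), npmdyn:::MPG_GENERA),
             seed = seed)

power_regime <- function(seed, n_subjects = 24)
  sim_config(n_subjects_AE = 0, n_subjects_AS = n_subjects, n_controls = 0,
             base_freq = rep(1 / 6, 6),
             state_self_prob = stats::setNames(
               c(0.9, 1 / 6, 0.9, 1 / 6, 1 / 6, 1 / 6), npmdyn:::MPG_GENERA),
             trend_slope = stats::setNames(rep(0, 6), npmdyn:::MPG_GENERA),
             seed = seed)
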