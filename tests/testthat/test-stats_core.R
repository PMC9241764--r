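test_that("PERMANOVA separates maximally distinct groups and is order-invariant", {
  # two groups of identical samples at between-group distance 1
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  ids <- sprintf("s%d", 1:6); dimnames(d) <- list(ids, ids)
  design <- data.frame(grp = rep(c("a", "b"), each = 3))
  fit <- permanova(d, design, "grp", n_perm = 99, seed = 1)
  expect_equal(fit$R2[1], 1, tolerance = 1e-9)
  expect_equal(fit$p_value[1], 1 / 100)
  # R2 column sums to 1 over terms + residual
  expect_equal(sum(fit$R2[1:2]), 1, tolerance = 1e-9)
  # reordering rows with matched labels leaves p unchanged
  ord <- c(4, 1, 5, 2, 6, 3)
  fit2 <- permanova(d[ord, ord], design[ord, , drop = FALSE], "grp",
                    n_perm = 99, seed = 1)
  expect_equal(fit2$p_value[1], fit$p_value[1])
  expect_error(permanova(d, data.frame(grp = rep("a", 6)), "grp"),
               "fewer than 2 levels")
})

test_that("PERMANOVA p matches full permutation enumeration at n = 4", {
  set.seed(5)
  for (rep in 1:3) {
    x <- matrix(rpois(12, 20), 4, 3)
    rownames(x) <- sprintf("s%d", 1:4); colnames(x) <- sprintf("t%d", 1:3)
    d <- bray_curtis(x)
    g <- c("a", "a", "b", "b")
    p_enum <- permanova_enum_p(d, factor(g))
    perms <- all_perms(4)
    perms <- perms[rowSums(perms != rep(1:4, each = nrow(perms))) > 0, ]
    fit <- permanova(d, data.frame(g = g), "g", permutations = perms)
    expect_equal(fit$p_value[1], p_enum, tolerance = 1e-12)
  }
})

test_that("PERMANOVA type-I error is nominal when labels are independent", {
  set.seed(11)
  hits <- vapply(1:200, function(i) {
    x <- matrix(rpois(30, 30), 10, 3)
    rownames(x) <- sprintf("s%d", 1:10); colnames(x) <- sprintf("t%d", 1:3)
    d <- bray_curtis(x)
    g <- sample(rep(c("a", "b"), each = 5))
    permanova(d, data.frame(g = g), "g", n_perm = 99)$p_value[1] <= 0.05
  }, logical(1))
  bounds <- qbinom(c(0.025, 0.975), 200, 0.05) / 200
  expect_gte(mean(hits), bounds[1])
  expect_lte(mean(hits), bounds[2])
})

test_that("pairwise PERMANOVA tests every level pair with BH adjustment", {
  set.seed(13)
  x <- matrix(rpois(45, 25), 15, 3)
  rownames(x) <- sprintf("s%d", 1:15); colnames(x) <- sprintf("t%d", 1:3)
  d <- bray_curtis(x)
  design <- data.frame(g = rep(c("a", "b", "c"), each = 5))
  res <- pairwise_permanova(d, design, "g", n_perm = 49, seed = 2)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_value))
  # a level with one sample is skipped with a warning
  design2 <- data.frame(g = c(rep(c("a", "b"), each = 7), "z"))
  expect_warning(res2 <- pairwise_permanova(d, design2, "g", n_perm = 49, seed = 2),
                 "skipped.*z")
  expect_equal(nrow(res2), 1)
})

test_that("Fisher exact matches exhaustive enumeration over all small tables", {
  for (r1 in 0:12) for (r2 in 0:12) {
    if (r1 + r2 == 0) next
    for (a in 0:r1) for (c in 0:r2) {
      tab <- matrix(c(a, c, r1 - a, r2 - c), 2)
      expect_equal(fisher_exact_2x2(tab)$p_value,
                   fisher_enum_p(a, r1 - a, c, r2 - c), tolerance = 1e-12)
    }
  }
})

test_that("Fisher exact handles the degenerate all-one-outcome table", {
  expect_equal(fisher_exact_2x2(rbind(c(0, 10), c(0, 10)))$p_value, 1)
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(0, 0))), "positive")
})

test_that("Kruskal-Wallis with Dunn post hoc matches rank arithmetic", {
  res <- kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                      rep(c("a", "b", "c"), each = 3))
  # fully separated groups: KW significant
  expect_lt(res$kw$p_value, 0.05)
  expect_equal(nrow(res$pairwise), 3)
  # mean ranks 2, 5, 8; s2 = N(N+1)/12 = 7.5 (no ties)
  z_ab <- (2 - 5) / sqrt(7.5 * (2 / 3))
  expect_equal(res$pairwise$z[1], z_ab)
  expect_equal(res$pairwise$p_value[1], 2 * pnorm(-abs(z_ab)))
  # all-identical values: flat p = 1, no division by zero
  flat <- kruskal_dunn(rep(3, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$kw$p_value, 1)
  # KW statistic is invariant under label permutation of the pooled data
  set.seed(3)
  v <- rnorm(12); g <- rep(c("a", "b", "c"), 4)
  k1 <- kruskal_dunn(v, g)$kw$statistic
  idx <- sample(12)
  k2 <- kruskal_dunn(v[idx], g[idx])$kw$statistic
  expect_equal(k1, k2)
})

test_that("Kruskal-Wallis type-I error is near nominal", {
  set.seed(17)
  hits <- vapply(1:500, function(i) {
    v <- rnorm(30)
    kruskal_dunn(v, rep(c("a", "b", "c"), each = 10))$kw$p_value <= 0.05
  }, logical(1))
  bounds <- qbinom(c(0.025, 0.975), 500, 0.05) / 500
  expect_gte(mean(hits), bounds[1])
  expect_lte(mean(hits), bounds[2])
})

test_that("signed-rank test matches sign-flip enumeration and edge cases", {
  # n = 8, all differences one sign: two-sided exact p = 2/256
  x <- 1:8; y <- x + 1
  expect_equal(wilcoxon_signed_rank(y, x)$p_value, 2 / 256)
  # all-zero differences
  expect_equal(wilcoxon_signed_rank(rep(2, 5), rep(2, 5))$p_value, 1)
  # enumeration oracle over 2^n sign patterns, n = 4..10, untied data
  set.seed(19)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 3)
      d <- d[d != 0]
      if (any(duplicated(abs(d)))) next
      expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enum_p(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("Spearman correlation handles monotone and independent data", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(x, rep(1, 6)), "constant")
  set.seed(23)
  rhos <- vapply(1:200, function(i)
    spearman_cor(rnorm(20), rnorm(20))$rho, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(200))
})

test_that("BH adjustment follows the step-up rule and its guarantees", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(29)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in rank order
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  # BH rejections are a superset of Bonferroni rejections
  q <- 0.1
  expect_true(all(which(p.adjust(p, "bonferroni") <= q) %in% which(adj <= q)))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("percentile bootstrap is deterministic with calibrated coverage", {
  ci1 <- bootstrap_ci(c(2, 2, 2, 2), mean, B = 100, seed = 5)
  expect_equal(ci1$lower, 2)
  expect_equal(ci1$upper, 2)
  x <- rnorm(30)
  expect_identical(bootstrap_ci(x, mean, B = 200, seed = 7),
                   bootstrap_ci(x, mean, B = 200, seed = 7))
  # coverage of the mean of N(0,1) samples
  set.seed(31)
  cover <- vapply(1:200, function(i) {
    v <- rnorm(40)
    ci <- bootstrap_ci(v, mean, B = 400)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  expect_gt(mean(cover), 0.88)  # nominal 0.95 minus Monte-Carlo + small-n slack
  expect_error(bootstrap_ci(numeric(0), mean), "at least one")
})
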