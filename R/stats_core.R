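# Resampling and classical tests shared across the pipeline.
#
# Standard tests delegate to their canonical implementations (vegan::adonis2,
# stats::fisher.test, stats::kruskal.test, stats::wilcox.test,
# stats::cor.test, stats::p.adjust); this module fixes the conventions the
# pipeline relies on (sequential term entry, +1 permutation correction,
# explicit seeds) and adds the pieces base R lacks (Dunn's post hoc z-tests,
# percentile bootstrap).

#' PERMANOVA on a distance matrix
#'
#' Sequential (order-of-entry) decomposition of the distance-based sum of
#' squares via the Gower-centred inner-product matrix, with significance from
#' whole-sample-row permutations: p = (1 + #\{permuted F >= observed F\}) /
#' (1 + n_perm). Covariates to adjust for should be listed before the factor
#' of interest in `terms`.
#'
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param data data.frame of factors/covariates, one row per sample, in the
#'   same order as `rownames(d)`.
#' @param terms character vector of column names of `data`, in entry order.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param permutations optional explicit permutation matrix (rows =
#'   permutations of `1:n`); overrides `n_perm`, e.g. for exhaustive
#'   enumeration on small n.
#' @return data.frame with one row per term plus Residual and Total: `term`,
#'   `df`, `sum_sq`, `R2`, `F`, `p_value`.
#' @export
permanova <- function(d, data, terms, n_perm = 1000, seed = NULL,
                      permutations = NULL) {
  d <- as.matrix(d)
  if (nrow(data) != nrow(d)) stop("design rows must align with distance rows")
  for (term in terms) {
    if (!term %in% colnames(data)) stop("unknown design column: ", term)
    v <- data[[term]]
    if ((is.character(v) || is.factor(v)) &&
        length(unique(v[!is.na(v)])) < 2)
      stop("factor '", term, "' has fewer than 2 levels present")
    if (is.numeric(v) && stats::var(v, na.rm = TRUE) == 0)
      stop("covariate '", term, "' is constant")
  }
  if (is.null(permutations)) {
    if (!is.null(seed)) set.seed(seed)
    permutations <- n_perm
  }
  df <- data[, terms, drop = FALSE]
  .d <- stats::as.dist(d)   # adonis2 resolves the response in this frame
  fml <- stats::as.formula(
    paste(".d ~", paste(terms, collapse = " + ")), env = environment())
  fit <- vegan::adonis2(fml, data = df, permutations = permutations,
                        by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df, sum_sq = fit$SumOfSqs,
                    R2 = fit$R2, F = fit$F, p_value = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- if (is.matrix(permutations)) nrow(permutations) else n_perm
  attr(out, "seed") <- seed
  out
}

#' Pairwise PERMANOVA over the levels of one factor
#'
#' One test per level pair on the corresponding sub-matrix, with
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param d symmetric distance matrix.
#' @param data design data.frame aligned with `rownames(d)`.
#' @param factor_name column of `data` with >= 2 levels.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @return data.frame: `level1`, `level2`, `R2`, `F`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, data, factor_name, n_perm = 1000, seed = NULL) {
  d <- as.matrix(d)
  f <- as.character(data[[factor_name]])
  tab <- table(f)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("level(s) with < 2 samples skipped: ", paste(small, collapse = ", "))
    keep <- !f %in% small
    d <- d[keep, keep, drop = FALSE]
    data <- data[keep, , drop = FALSE]
    f <- f[keep]
  }
  levs <- sort(unique(f))
  if (length(levs) < 2) stop("factor '", factor_name, "' has fewer than 2 usable levels")
  pairs <- utils::combn(levs, 2)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- f %in% pairs[, i]
    sub <- permanova(d[sel, sel, drop = FALSE],
                     data[sel, , drop = FALSE], factor_name, n_perm = n_perm)
    data.frame(level1 = pairs[1, i], level2 = pairs[2, i],
               R2 = sub$R2[1], F = sub$F[1], p_value = sub$p_value[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_fdr(out$p_value)
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = group,
#'   columns = outcome).
#' @return data.frame with `method`, `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("table total must be positive")
  ft <- stats::fisher.test(tab)
  data.frame(method = "fisher_exact", odds_ratio = unname(ft$estimate),
             p_value = ft$p.value, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis test followed by Dunn's pairwise z-tests on
#' mean ranks with Benjamini-Hochberg adjustment across pairs.
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector of the same length, >= 3 groups for the
#'   post hoc stage to be meaningful.
#' @return list with `kw` (data.frame: `statistic`, `df`, `p_value`) and
#'   `pairwise` (data.frame: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  if (length(values) < 3) stop("at least 3 observations required")
  if (length(unique(values)) == 1) {
    kw <- data.frame(statistic = 0, df = length(unique(groups)) - 1, p_value = 1)
  } else {
    fit <- stats::kruskal.test(values, factor(groups))
    kw <- data.frame(statistic = unname(fit$statistic),
                     df = unname(fit$parameter), p_value = fit$p.value)
  }
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  levs <- sort(unique(groups))
  pw <- NULL
  if (length(levs) >= 2) {
    pairs <- utils::combn(levs, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      na <- sum(groups == a); nb <- sum(groups == b)
      z <- if (s2 <= 0) 0 else
        (mean(r[groups == a]) - mean(r[groups == b])) /
          sqrt(s2 * (1 / na + 1 / nb))
      data.frame(group1 = a, group2 = b, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    }))
    pw$p_adjusted <- bh_fdr(pw$p_value)
  }
  list(kw = kw, pairwise = pw)
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test. Zero differences are dropped. The exact
#' null distribution is used for n <= 25: via the signed-rank distribution
#' when the absolute differences are untied, and by direct enumeration of the
#' 2^n sign patterns on the average ranks when ties are present (enumeration
#' is capped at n <= 14 for tied data). Larger samples use the normal
#' approximation with tie correction.
#'
#' @param x first member of each pair (or the differences if `y` is `NULL`).
#' @param y optional second member of each pair.
#' @return data.frame with `statistic` (V), `n_used`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(data.frame(statistic = NA_real_, n_used = 0L, p_value = 1,
                      method = "wilcoxon_signed_rank", stringsAsFactors = FALSE))
  ties <- any(duplicated(abs(d)))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25 && !ties) {
    ht <- stats::wilcox.test(d, exact = TRUE)
    p <- ht$p.value
  } else if (n <= 14) {
    # exact two-sided p over all sign patterns, valid under ties
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(v_all <= v + 1e-9), mean(v_all >= v - 1e-9)))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    p <- ht$p.value
  }
  data.frame(statistic = v, n_used = n, p_value = p,
             method = "wilcoxon_signed_rank", stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling; two-sided p-value from
#' the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return data.frame with `rho`, `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(rho = unname(ht$estimate), p_value = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return step-up adjusted p-values, monotone and capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Percentile bootstrap confidence interval
#'
#' @param x vector (or list) of items to resample with replacement.
#' @param statistic function mapping a resampled set of items to a scalar.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed; same seed gives the identical interval.
#' @return list with `lower`, `upper`, `level`, `B`.
#' @export
bootstrap_ci <- function(x, statistic, B = 1000, level = 0.95, seed = NULL) {
  n <- length(x)
  if (n < 1) stop("at least one item required")
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    statistic(x[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2], level = level, B = B)
}
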