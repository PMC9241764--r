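# Linear mixed-effects trends in diversity, consecutive-pair dissimilarity
# and genus abundances, contrasting exacerbating (AE) and stable (AS)
# asthmatic subjects.

#' Restrict metadata to the longitudinal analysis set
#'
#' Keeps asthmatic (AE/AS) samples at baseline and scheduled visits (integer
#' `time_point`; extra illness visits lack one) from subjects with at least
#' `min_samples` such samples.
#'
#' @param meta validated metadata.
#' @param min_samples minimum samples per subject (default 3).
#' @param scheduled_only drop extra-visit samples without a scheduled index.
#' @return metadata subset.
#' @export
eligible_longitudinal <- function(meta, min_samples = 3, scheduled_only = TRUE) {
  m <- meta[meta$group %in% c("AE", "AS"), , drop = FALSE]
  if (scheduled_only && "time_point" %in% colnames(m))
    m <- m[!is.na(m$time_point), , drop = FALSE]
  keep <- names(which(table(m$subject_id) >= min_samples))
  m[m$subject_id %in% keep, , drop = FALSE]
}

#' Build a longitudinal series of an alpha-diversity metric
#'
#' @param alpha result of [alpha_diversity()].
#' @param meta validated metadata.
#' @param metric one of the columns of `alpha` (`"shannon"`, `"pielou"`,
#'   `"observed"`).
#' @param min_samples eligibility threshold per subject.
#' @return data.frame: `subject_id`, `time`, `group`, `value`, `label`.
#' @export
build_alpha_series <- function(alpha, meta, metric = "shannon", min_samples = 3) {
  if (!metric %in% colnames(alpha)) stop("unknown metric: ", metric)
  m <- eligible_longitudinal(meta, min_samples = min_samples)
  if (nrow(m) == 0) stop("no eligible subjects")
  v <- stats::setNames(alpha[[metric]], alpha$sample_id)
  data.frame(subject_id = m$subject_id, time = m$time_point,
             group = m$group, value = unname(v[m$sample_id]),
             label = metric, stringsAsFactors = FALSE, row.names = NULL)
}

#' Consecutive same-subject distances as a longitudinal series
#'
#' One observation per adjacent same-subject pair among eligible samples;
#' the observation's time is the later sample's (the transition "arrives"
#' there), or the pair midpoint under `time_at = "midpoint"`.
#'
#' @param d distance matrix covering the eligible samples.
#' @param meta validated metadata.
#' @param label response label for the series.
#' @param min_samples eligibility threshold per subject.
#' @param time_at `"later"` (default) or `"midpoint"`.
#' @return data.frame: `subject_id`, `time`, `group`, `value`, `label`.
#' @export
consecutive_distances <- function(d, meta, label = "bray_curtis",
                                  min_samples = 3,
                                  time_at = c("later", "midpoint")) {
  time_at <- match.arg(time_at)
  d <- as.matrix(d)
  m <- eligible_longitudinal(meta, min_samples = min_samples)
  m <- m[order(m$subject_id, m$collection_order), , drop = FALSE]
  missing <- setdiff(m$sample_id, rownames(d))
  if (length(missing))
    stop("distance matrix lacks sample(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(m, m$subject_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    i <- seq_len(nrow(s) - 1)
    tp <- if (time_at == "later") s$time_point[i + 1] else
      (s$time_point[i] + s$time_point[i + 1]) / 2
    data.frame(subject_id = s$subject_id[i], time = tp, group = s$group[i],
               value = d[cbind(s$sample_id[i], s$sample_id[i + 1])],
               label = label, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the longitudinal mixed model to a series
#'
#' Fits `value ~ time * group` with per-subject random intercepts and time
#' slopes by REML, and derives term p-values from the sequential (type-1)
#' ANOVA with Satterthwaite denominator degrees of freedom. On failure the
#' model falls back to random intercepts only, then to a fixed-effects
#' linear model; the `model` field records which fit is reported.
#'
#' @param series data.frame with `subject_id`, `time`, `group`, `value`
#'   (and optionally `label`).
#' @param random `"slope"` (default, random intercept + time slope) or
#'   `"intercept"`.
#' @return one-row data.frame: `label`, `p_time`, `p_group`,
#'   `p_interaction`, `est_time`, `se_time`, `est_interaction`,
#'   `se_interaction`, `model`, `converged`.
#' @export
fit_lme <- function(series, random = c("slope", "intercept")) {
  random <- match.arg(random)
  s <- series[!is.na(series$value), , drop = FALSE]
  label <- if ("label" %in% colnames(s) && nrow(s)) s$label[1] else "response"
  if (length(unique(s$group)) < 2) stop("both AE and AS groups are required")
  if (length(unique(s$time)) < 2) stop("at least two distinct time values required")
  if (stats::var(s$value) == 0)
    return(data.frame(label = label, p_time = NA_real_, p_group = NA_real_,
                      p_interaction = NA_real_, est_time = 0, se_time = NA_real_,
                      est_interaction = 0, se_interaction = NA_real_,
                      model = "degenerate", converged = FALSE,
                      stringsAsFactors = FALSE))
  s$group <- factor(s$group)
  fits <- list(
    slope = function() lmerTest::lmer(
      value ~ time * group + (1 + time | subject_id), data = s, REML = TRUE),
    intercept = function() lmerTest::lmer(
      value ~ time * group + (1 | subject_id), data = s, REML = TRUE),
    fixed = function() stats::lm(value ~ time * group, data = s))
  order <- if (random == "slope") c("slope", "intercept", "fixed") else
    c("intercept", "fixed")
  fit <- NULL; used <- NA_character_
  for (nm in order) {
    fit <- tryCatch(suppressMessages(suppressWarnings(fits[[nm]]())),
                    error = function(e) NULL)
    if (!is.null(fit)) { used <- nm; break }
  }
  if (is.null(fit)) stop("all model fits failed for response '", label, "'")
  if (used == "fixed") {
    a <- stats::anova(fit)   # sequential by construction
    p <- a[["Pr(>F)"]][1:3]
    cf <- summary(fit)$coefficients
  } else {
    a <- stats::anova(fit, type = 1)
    p <- a[["Pr(>F)"]]
    cf <- summary(fit)$coefficients
  }
  inter_row <- grep("^time:", rownames(cf))
  data.frame(label = label,
             p_time = p[1], p_group = p[2], p_interaction = p[3],
             est_time = cf["time", "Estimate"],
             se_time = cf["time", "Std. Error"],
             est_interaction = if (length(inter_row)) cf[inter_row[1], "Estimate"] else NA_real_,
             se_interaction = if (length(inter_row)) cf[inter_row[1], "Std. Error"] else NA_real_,
             model = used, converged = !is.na(p[1]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Most abundant genera by cohort mean relative abundance
#'
#' @param comp composition matrix, samples x genera.
#' @param k maximum number of genera to keep.
#' @param min_mean minimum cohort mean relative abundance.
#' @return character vector of genus labels, most abundant first.
#' @export
top_genera <- function(comp, k = 8, min_mean = 0.01) {
  means <- sort(colMeans(comp), decreasing = TRUE)
  names(means)[means > min_mean][seq_len(min(k, sum(means > min_mean)))]
}

#' Mixed-model trends of genus relative abundances
#'
#' One [fit_lme()] per genus with the genus relative abundance as response
#' (untransformed by default; arcsine-square-root available as a variance-
#' stabilising sensitivity option). A genus whose fit fails contributes a
#' flagged row instead of aborting the remainder.
#'
#' @param comp composition matrix, samples x genera.
#' @param meta validated metadata.
#' @param genera genus labels to model.
#' @param transform `"none"` or `"arcsine_sqrt"`.
#' @param min_samples eligibility threshold per subject.
#' @return data.frame with one row per genus, columns as in [fit_lme()].
#' @export
fit_taxa_trends <- function(comp, meta, genera, transform = c("none", "arcsine_sqrt"),
                            min_samples = 3) {
  transform <- match.arg(transform)
  missing <- setdiff(genera, colnames(comp))
  if (length(missing)) stop("genera not in table: ", paste(missing, collapse = ", "))
  m <- eligible_longitudinal(meta, min_samples = min_samples)
  out <- lapply(genera, function(g) {
    v <- comp[m$sample_id, g]
    if (transform == "arcsine_sqrt") v <- asin(sqrt(v))
    s <- data.frame(subject_id = m$subject_id, time = m$time_point,
                    group = m$group, value = as.numeric(v), label = g,
                    stringsAsFactors = FALSE)
    tryCatch(fit_lme(s), error = function(e)
      data.frame(label = g, p_time = NA_real_, p_group = NA_real_,
                 p_interaction = NA_real_, est_time = NA_real_,
                 se_time = NA_real_, est_interaction = NA_real_,
                 se_interaction = NA_real_, model = "failed",
                 converged = FALSE, stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a Gaussian longitudinal series with known fixed effects
#'
#' Generator used to calibrate the mixed model: per-subject random
#' intercepts and time slopes plus residual noise around
#' `intercept + slope_time * time + effect_group * [group == AE] +
#' effect_interaction * time * [group == AE]`.
#'
#' @param n_per_group subjects per group (AE and AS).
#' @param timepoints time values observed for every subject.
#' @param intercept,slope_time,effect_group,effect_interaction fixed effects.
#' @param sd_intercept,sd_slope,sd_resid variance components (SD scale).
#' @param seed integer seed.
#' @return data.frame usable by [fit_lme()].
#' @export
simulate_lme_series <- function(n_per_group = 12, timepoints = 0:5,
                                intercept = 2, slope_time = 0,
                                effect_group = 0, effect_interaction = 0,
                                sd_intercept = 0.5, sd_slope = 0.1,
                                sd_resid = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- sprintf("S%03d", seq_len(2 * n_per_group))
  grp <- rep(c("AE", "AS"), each = n_per_group)
  b0 <- stats::rnorm(length(subj), 0, sd_intercept)
  b1 <- stats::rnorm(length(subj), 0, sd_slope)
  out <- lapply(seq_along(subj), function(i) {
    mu <- intercept + b0[i] + (slope_time + b1[i]) * timepoints +
      (grp[i] == "AE") * (effect_group + effect_interaction * timepoints)
    data.frame(subject_id = subj[i], time = timepoints, group = grp[i],
               value = mu + stats::rnorm(length(timepoints), 0, sd_resid),
               label = "simulated", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
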