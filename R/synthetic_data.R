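# Dirichlet-multinomial simulator of longitudinal nasopharyngeal cohorts.
#
# The generative model mirrors the structure the downstream analyses assume:
# each asthmatic subject carries a latent dominant-genus state that evolves as
# a first-order Markov chain over the six profile-defining genera; at every
# visit a genus composition is drawn from a Dirichlet centred on the state's
# template (with per-genus multiplicative trends over time), counts are drawn
# multinomially at a negative-binomial sequencing depth, and exacerbation
# events transiently multiply the pathogen-analog genus before renormalisation.

MPG_GENERA <- c("Moraxella", "Corynebacterium_1", "Dolosigranulum",
                "Staphylococcus", "Streptococcus", "Anoxybacillus")

# Cohort-level MPG sample frequencies used as the base state distribution
# (34%, 28.5%, 22.2%, 6.9%, 3.5%, 4.9%, normalised).
MPG_BASE_FREQ <- c(0.340, 0.285, 0.222, 0.069, 0.035, 0.049) /
  sum(c(0.340, 0.285, 0.222, 0.069, 0.035, 0.049))

#' Simulation configuration
#'
#' Builds and validates the parameter set of the longitudinal cohort
#' simulator. Defaults reproduce the structure of a typical school-age
#' asthma surveillance cohort: 11 exacerbating (AE) and 13 stable (AS)
#' asthmatics followed over six visits at regular intervals, nine one-off
#' non-asthmatic controls, six dominant genera plus a residual pool, and
#' sequencing depths comfortably above a 22,201-read rarefaction floor.
#'
#' @param n_subjects_AE,n_subjects_AS,n_controls cohort sizes.
#' @param n_timepoints scheduled visits per asthmatic subject (>= 3).
#' @param genus_names the profile-defining (MPG) genera; a residual
#'   `"Other"` pool is always appended.
#' @param base_freq base frequency of each latent state; also shapes the
#'   off-diagonal transition mass.
#' @param state_self_prob per-genus probability that the latent state repeats
#'   at the next visit. Defaults keep Moraxella and Dolosigranulum highly
#'   persistent (0.9) and leave the remaining states at their base frequency,
#'   i.e. at the random-transition null.
#' @param dominant_frac template relative abundance of the dominant genus.
#' @param residual_frac template share of the residual pool.
#' @param precision Dirichlet precision (sum of concentrations); larger
#'   values mean tighter within-state compositional noise.
#' @param trend_slope named per-genus log-scale slope per visit applied to
#'   the template mean (positive = steady increase).
#' @param exacerbation_rate per-interior-visit probability of an event for an
#'   AE subject; every AE subject is guaranteed at least one event.
#' @param bloom_genus genus multiplied at exacerbation.
#' @param bloom_multiplier multiplicative bloom factor (> 1) applied to
#'   `bloom_genus` before renormalisation at event visits.
#' @param recovery if `TRUE` the bloom is transient and the latent state is
#'   untouched (post-event samples revert); if `FALSE` the latent state
#'   switches to `bloom_genus` at the event.
#' @param depth_mean,depth_dispersion negative-binomial sequencing-depth
#'   model (mu / size parameterisation).
#' @param depth_floor lower bound applied to drawn depths so rarefaction at
#'   this depth never drops samples.
#' @param n_asv_per_genus when > 1, genus counts are split over this many
#'   pseudo-ASVs and a taxonomy map is emitted, exercising the aggregation
#'   path.
#' @param age_range uniform age range (years) for subject ages.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_subjects_AE = 11,
                       n_subjects_AS = 13,
                       n_controls = 9,
                       n_timepoints = 6,
                       genus_names = MPG_GENERA,
                       base_freq = MPG_BASE_FREQ,
                       state_self_prob = NULL,
                       dominant_frac = 0.65,
                       residual_frac = 0.10,
                       precision = 30,
                       trend_slope = NULL,
                       exacerbation_rate = 0.25,
                       bloom_genus = "Moraxella",
                       bloom_multiplier = 3,
                       recovery = TRUE,
                       depth_mean = 60000,
                       depth_dispersion = 10,
                       depth_floor = 22201,
                       n_asv_per_genus = 1,
                       age_range = c(6, 17),
                       seed = 1L) {
  k <- length(genus_names)
  base_freq <- base_freq / sum(base_freq)
  names(base_freq) <- genus_names
  if (is.null(state_self_prob)) {
    state_self_prob <- base_freq
    for (g in intersect(c("Moraxella", "Dolosigranulum"), genus_names))
      state_self_prob[g] <- 0.9
  }
  if (is.null(names(state_self_prob))) names(state_self_prob) <- genus_names
  if (is.null(trend_slope)) {
    trend_slope <- stats::setNames(rep(0, k), genus_names)
    for (g in intersect("Moraxella", genus_names)) trend_slope[g] <- 0.15
    for (g in intersect(c("Corynebacterium_1", "Anoxybacillus"), genus_names))
      trend_slope[g] <- -0.10
  }
  if (is.null(names(trend_slope))) names(trend_slope) <- genus_names
  cfg <- list(n_subjects_AE = n_subjects_AE, n_subjects_AS = n_subjects_AS,
              n_controls = n_controls, n_timepoints = n_timepoints,
              genus_names = genus_names, base_freq = base_freq,
              state_self_prob = state_self_prob[genus_names],
              dominant_frac = dominant_frac, residual_frac = residual_frac,
              precision = precision, trend_slope = trend_slope[genus_names],
              exacerbation_rate = exacerbation_rate, bloom_genus = bloom_genus,
              bloom_multiplier = bloom_multiplier, recovery = recovery,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              depth_floor = depth_floor, n_asv_per_genus = n_asv_per_genus,
              age_range = age_range, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_timepoints < 3) stop("n_timepoints must be >= 3")
    if (any(state_self_prob <= 0 | state_self_prob >= 1))
      stop("state_self_prob values must lie strictly in (0, 1)")
    if (any(base_freq <= 0)) stop("base_freq values must be positive")
    if (dominant_frac <= 0 || dominant_frac >= 1 || residual_frac < 0 ||
        dominant_frac + residual_frac >= 1)
      stop("dominant_frac and residual_frac must leave positive mass for the rest")
    if (precision <= 0) stop("precision must be positive")
    if (exacerbation_rate < 0 || exacerbation_rate > 1)
      stop("exacerbation_rate must be in [0, 1]")
    if (bloom_multiplier <= 0) stop("bloom_multiplier must be positive")
    if (!bloom_genus %in% genus_names) stop("bloom_genus not among genus_names")
    if (depth_floor < 1 || depth_mean < depth_floor)
      stop("depth_mean must be >= depth_floor >= 1")
  })
  invisible(cfg)
}

# Template mean composition (over genera + residual pool) for latent state g.
state_template <- function(cfg, g) {
  gn <- cfg$genus_names
  m <- numeric(length(gn) + 1)
  names(m) <- c(gn, "Other")
  m[g] <- cfg$dominant_frac
  m["Other"] <- cfg$residual_frac
  others <- setdiff(gn, g)
  w <- cfg$base_freq[others]
  m[others] <- (1 - cfg$dominant_frac - cfg$residual_frac) * w / sum(w)
  m
}

# One Dirichlet draw centred on mean m with the configured precision.
rdirichlet1 <- function(m, precision) {
  a <- m * precision
  x <- stats::rgamma(length(a), shape = a, rate = 1)
  x[a == 0] <- 0
  x / sum(x)
}

next_state <- function(cfg, g) {
  s <- cfg$state_self_prob[g]
  if (stats::runif(1) < s) return(g)
  others <- setdiff(cfg$genus_names, g)
  w <- cfg$base_freq[others]
  sample(others, 1, prob = w / sum(w))
}

draw_depth <- function(cfg) {
  max(cfg$depth_floor,
      stats::rnbinom(1, mu = cfg$depth_mean, size = cfg$depth_dispersion))
}

#' Simulate a longitudinal cohort
#'
#' Generates a genus-level count table, sample metadata passing
#' [validate_metadata()], and a ground-truth record (latent states, event
#' schedule, true parameters) for recovery tests. Exacerbation events are
#' placed at interior scheduled visits of AE subjects so pre- and
#' post-event neighbours always exist in the design.
#'
#' @param cfg a [sim_config()] object.
#' @return list with elements `counts` (matrix), `metadata` (data.frame),
#'   `truth` (list), and, when `n_asv_per_genus > 1`, `taxonomy` (named
#'   vector) with `counts` at ASV level.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gn <- cfg$genus_names
  taxa <- c(gn, "Other")
  counts <- list(); meta <- list(); states <- list(); events <- list()
  subjects <- c(sprintf("AE%02d", seq_len(cfg$n_subjects_AE)),
                sprintf("AS%02d", seq_len(cfg$n_subjects_AS)))
  groups <- rep(c("AE", "AS"), c(cfg$n_subjects_AE, cfg$n_subjects_AS))
  interior <- seq(1, cfg$n_timepoints - 2)
  for (i in seq_along(subjects)) {
    sub <- subjects[i]
    age <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
    ev <- integer(0)
    if (groups[i] == "AE") {
      ev <- interior[stats::runif(length(interior)) < cfg$exacerbation_rate]
      if (!length(ev)) ev <- sample(interior, 1)
    }
    g <- sample(gn, 1, prob = cfg$base_freq)
    for (t in seq_len(cfg$n_timepoints) - 1) {
      is_event <- t %in% ev
      m <- state_template(cfg, g)
      m[gn] <- m[gn] * exp(cfg$trend_slope * t)
      m <- m / sum(m)
      if (is_event) {
        m[cfg$bloom_genus] <- m[cfg$bloom_genus] * cfg$bloom_multiplier
        m <- m / sum(m)
      }
      p <- rdirichlet1(m, cfg$precision)
      depth <- draw_depth(cfg)
      y <- as.integer(stats::rmultinom(1, depth, p))
      sid <- sprintf("%s_T%d", sub, t)
      counts[[sid]] <- y
      meta[[sid]] <- data.frame(
        sample_id = sid, subject_id = sub, collection_order = t,
        time_point = t, group = groups[i],
        sample_type = if (is_event) "exacerbation"
                      else if (t == 0) "baseline" else "nonexacerbation",
        age = round(age, 1), stringsAsFactors = FALSE)
      states[[sid]] <- data.frame(sample_id = sid, state = g,
                                  stringsAsFactors = FALSE)
      if (is_event) {
        events[[length(events) + 1]] <-
          data.frame(subject_id = sub, time_point = t, stringsAsFactors = FALSE)
        if (!cfg$recovery) g <- cfg$bloom_genus
      }
      g <- next_state(cfg, g)
    }
  }
  for (j in seq_len(cfg$n_controls)) {
    sub <- sprintf("C%02d", j)
    g <- sample(gn, 1, prob = cfg$base_freq)
    p <- rdirichlet1(state_template(cfg, g), cfg$precision)
    y <- as.integer(stats::rmultinom(1, draw_depth(cfg), p))
    sid <- sprintf("%s_T0", sub)
    counts[[sid]] <- y
    meta[[sid]] <- data.frame(
      sample_id = sid, subject_id = sub, collection_order = 0,
      time_point = 0, group = "control", sample_type = "control",
      age = round(stats::runif(1, cfg$age_range[1], cfg$age_range[2]), 1),
      stringsAsFactors = FALSE)
    states[[sid]] <- data.frame(sample_id = sid, state = g,
                                stringsAsFactors = FALSE)
  }
  x <- do.call(rbind, counts)
  colnames(x) <- taxa
  storage.mode(x) <- "integer"
  metadata <- validate_metadata(do.call(rbind, meta))
  x <- x[metadata$sample_id, , drop = FALSE]
  states_df <- do.call(rbind, states)
  rownames(states_df) <- NULL
  truth <- list(
    states = states_df,
    events = if (length(events)) do.call(rbind, events) else
      data.frame(subject_id = character(0), time_point = integer(0)),
    params = list(genus_names = gn, base_freq = cfg$base_freq,
                  state_self_prob = cfg$state_self_prob,
                  trend_slope = cfg$trend_slope,
                  bloom_genus = cfg$bloom_genus,
                  bloom_multiplier = cfg$bloom_multiplier,
                  recovery = cfg$recovery, seed = cfg$seed))
  out <- list(counts = x, metadata = metadata, truth = truth)
  if (cfg$n_asv_per_genus > 1) {
    split <- split_to_asvs(x, cfg$n_asv_per_genus)
    out$counts <- split$counts
    out$taxonomy <- split$taxonomy
    out$genus_counts <- x
  }
  class(out) <- "npm_sim"
  out
}

# Split genus-level counts over pseudo-ASVs with fixed per-genus weights.
split_to_asvs <- function(x, n_per_genus) {
  pieces <- list(); tax <- character(0)
  for (g in colnames(x)) {
    ids <- sprintf("%s_ASV%d", g, seq_len(n_per_genus))
    w <- rdirichlet1(rep(1 / n_per_genus, n_per_genus), 10)
    m <- t(vapply(x[, g], function(n) {
      as.integer(stats::rmultinom(1, n, w))
    }, integer(n_per_genus)))
    colnames(m) <- ids
    pieces[[g]] <- m
    tax <- c(tax, stats::setNames(rep(g, n_per_genus), ids))
  }
  counts <- do.call(cbind, pieces)
  rownames(counts) <- rownames(x)
  storage.mode(counts) <- "integer"
  list(counts = counts, taxonomy = tax)
}

#' Summarise the ground truth of a simulated cohort
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @return list of data.frames: `genus_params` (per-genus base frequency,
#'   self-transition probability and trend slope) and `events` (per-subject
#'   exacerbation schedule).
#' @export
truth_report <- function(truth) {
  p <- truth$params
  genus_params <- data.frame(
    genus = p$genus_names,
    base_freq = as.numeric(p$base_freq[p$genus_names]),
    self_prob = as.numeric(p$state_self_prob[p$genus_names]),
    trend_slope = as.numeric(p$trend_slope[p$genus_names]),
    stringsAsFactors = FALSE)
  list(genus_params = genus_params, events = truth$events,
       n_samples = nrow(truth$states),
       n_events = nrow(truth$events))
}

#' Write a simulated cohort to disk as TSV files
#'
#' Emits `counts.tsv`, `metadata.tsv`, `ground_truth_states.tsv`,
#' `ground_truth_events.tsv`, `ground_truth_params.tsv` and, for ASV-level
#' simulations, `taxonomy.tsv`.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  utils::write.table(sim$truth$states, file.path(dir, "ground_truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(dir, "ground_truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_report(sim$truth)$genus_params,
                     file.path(dir, "ground_truth_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$taxonomy)) {
    utils::write.table(
      data.frame(asv_id = names(sim$taxonomy), genus = unname(sim$taxonomy)),
      file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
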