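# Microbiome profile groups (MPGs): dominant-genus assignment, transition
# analysis against a random-transition null, and stable-colonization calls.
#
# This is the analytical core of the package. Each sample is labelled by its
# most abundant genus; the label sequence of every subject defines a set of
# consecutive-pair transitions. The temporal stability of each MPG is judged
# by comparing the observed frequency of its stable transitions (same label
# at both ends, counted over ALL transitions) against the frequency expected
# under random transitions at constant state frequencies, which is the square
# of the MPG's frequency among transition starting points. The observed
# frequency must use the all-transitions denominator: conditioning on the
# starting state would pair with an expected value of p, not p^2.

#' Assign samples to microbiome profile groups
#'
#' Labels each sample with its most abundant (dominant) genus. Exact ties are
#' broken in favour of the genus with the higher cohort-wide mean abundance,
#' then lexicographically; tie events are recorded in the `ties` attribute
#' and reported via a message.
#'
#' @param comp composition matrix, samples x genera (rows sum to 1).
#' @return data.frame with `sample_id`, `mpg`, `dominant_fraction`; tie
#'   sample ids in `attr(, "ties")`.
#' @export
assign_mpg <- function(comp) {
  validate_composition(comp)
  cohort_mean <- colMeans(comp)
  genera <- colnames(comp)
  pref <- order(-cohort_mean, genera)   # tie-break preference order
  ties <- character(0)
  lab <- character(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    row <- comp[i, ]
    mx <- max(row)
    cand <- which(row == mx)
    if (length(cand) > 1) {
      ties <- c(ties, rownames(comp)[i])
      cand <- cand[order(match(cand, pref))]
    }
    lab[i] <- genera[cand[1]]
  }
  if (length(ties))
    message("assign_mpg: dominance tie(s) broken by cohort mean for: ",
            paste(ties, collapse = ", "))
  out <- data.frame(sample_id = rownames(comp), mpg = lab,
                    dominant_fraction = apply(comp, 1, max),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ties") <- ties
  out
}

#' Hierarchical clustering of MPG-genus profiles
#'
#' Complete-linkage agglomeration on Bray-Curtis distances of the composition
#' restricted to (and renormalised over) the profile-defining genera. Used
#' for heatmap ordering only; MPG labels are never altered by clustering.
#'
#' @param comp composition matrix, samples x genera.
#' @param mpg_genera subset of genera to cluster on.
#' @return an [stats::hclust] object.
#' @export
hcluster_profiles <- function(comp, mpg_genera) {
  if (nrow(comp) < 2) stop("at least 2 samples required")
  missing <- setdiff(mpg_genera, colnames(comp))
  if (length(missing)) stop("genera not in table: ", paste(missing, collapse = ", "))
  sub <- comp[, mpg_genera, drop = FALSE]
  tot <- rowSums(sub)
  if (any(tot == 0)) {
    warning("dropping sample(s) with no abundance over the selected genera: ",
            paste(rownames(sub)[tot == 0], collapse = ", "))
    sub <- sub[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sub <- sub / tot
  stats::hclust(vegan::vegdist(sub, method = "bray"), method = "complete")
}

#' Build consecutive-pair MPG transitions
#'
#' For every non-control subject with at least two in-scope samples, emits
#' one record per adjacent pair in collection order (extra illness visits
#' participate at their fractional positions). With
#' `scope = "nonexacerbation"` exacerbation samples are removed before
#' adjacency is formed, giving the sensitivity series.
#'
#' @param assignments result of [assign_mpg()].
#' @param meta validated sample metadata.
#' @param scope `"all"` (default) or `"nonexacerbation"`.
#' @return data.frame: `subject_id`, `sample_t1`, `sample_t2`, `mpg_t1`,
#'   `mpg_t2`, `order_t1`, `order_t2`, `stable`.
#' @export
build_transitions <- function(assignments, meta, scope = c("all", "nonexacerbation")) {
  scope <- match.arg(scope)
  m <- meta[meta$group != "control", , drop = FALSE]
  if (scope == "nonexacerbation")
    m <- m[m$sample_type != "exacerbation", , drop = FALSE]
  lab <- stats::setNames(assignments$mpg, assignments$sample_id)
  missing <- setdiff(m$sample_id, names(lab))
  if (length(missing))
    stop("sample(s) without MPG assignment: ", paste(missing, collapse = ", "))
  m <- m[order(m$subject_id, m$collection_order), , drop = FALSE]
  out <- lapply(split(m, m$subject_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    i <- seq_len(nrow(s) - 1)
    data.frame(subject_id = s$subject_id[i],
               sample_t1 = s$sample_id[i], sample_t2 = s$sample_id[i + 1],
               mpg_t1 = unname(lab[s$sample_id[i]]),
               mpg_t2 = unname(lab[s$sample_id[i + 1]]),
               order_t1 = s$collection_order[i],
               order_t2 = s$collection_order[i + 1],
               stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, out)
  if (is.null(tr))
    tr <- data.frame(subject_id = character(0), sample_t1 = character(0),
                     sample_t2 = character(0), mpg_t1 = character(0),
                     mpg_t2 = character(0), order_t1 = numeric(0),
                     order_t2 = numeric(0), stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  tr$stable <- tr$mpg_t1 == tr$mpg_t2
  tr
}

#' Transition count matrix with row proportions
#'
#' @param transitions result of [build_transitions()].
#' @return list with `counts` (K x K matrix, rows = state at T1, columns =
#'   state at T2) and `proportions` (rows of non-empty states sum to 1).
#' @export
transition_matrix <- function(transitions) {
  if (nrow(transitions) < 1) stop("at least one transition record required")
  labs <- sort(unique(c(transitions$mpg_t1, transitions$mpg_t2)))
  counts <- table(factor(transitions$mpg_t1, levels = labs),
                  factor(transitions$mpg_t2, levels = labs))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("T1", "T2")
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, proportions = props)
}

#' MPG stability analysis against the random-transition null
#'
#' For each MPG g, the observed stable-transition frequency is the share of
#' all transition records that go g -> g, with a percentile bootstrap
#' confidence interval over the transition records. The expected frequency
#' under constant state frequencies and random transitions is p^2, where p is
#' the proportion of transition starting points (T1 endpoints) in state g.
#' An MPG is called `more_stable` when the expected frequency falls below the
#' lower CI limit, `less_stable` when it exceeds the upper limit, and
#' `compatible` otherwise.
#'
#' @param transitions result of [build_transitions()].
#' @param B bootstrap replicates.
#' @param level confidence level of the percentile interval.
#' @param seed integer seed for the bootstrap.
#' @param resample `"transition"` (default: resample individual transition
#'   records, the units whose proportion is estimated) or `"subject"`
#'   (block bootstrap over subjects).
#' @return data.frame, one row per MPG: `mpg`, `n_transitions`, `n_stable`,
#'   `observed_freq`, `ci_low`, `ci_high`, `expected_freq`, `verdict`.
#' @export
stability_analysis <- function(transitions, B = 1000, level = 0.95,
                               seed = NULL,
                               resample = c("transition", "subject")) {
  resample <- match.arg(resample)
  if (nrow(transitions) < 1) stop("at least one transition record required")
  if (B < 1) stop("B must be >= 1")
  n <- nrow(transitions)
  labs <- sort(unique(c(transitions$mpg_t1, transitions$mpg_t2)))
  stable_for <- vapply(labs, function(g)
    transitions$mpg_t1 == g & transitions$mpg_t2 == g, logical(n))
  if (is.null(dim(stable_for))) stable_for <- matrix(stable_for, nrow = n)
  observed <- colSums(stable_for) / n
  p_t1 <- vapply(labs, function(g) mean(transitions$mpg_t1 == g), numeric(1))
  expected <- p_t1^2
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, B, length(labs))
  if (resample == "transition") {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot[b, ] <- colMeans(stable_for[idx, , drop = FALSE])
    }
  } else {
    by_subject <- split(seq_len(n), transitions$subject_id)
    ns <- length(by_subject)
    for (b in seq_len(B)) {
      idx <- unlist(by_subject[sample.int(ns, ns, replace = TRUE)],
                    use.names = FALSE)
      boot[b, ] <- colMeans(stable_for[idx, , drop = FALSE])
    }
  }
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  verdict <- ifelse(expected < ci[1, ], "more_stable",
                    ifelse(expected > ci[2, ], "less_stable", "compatible"))
  data.frame(mpg = labs, n_transitions = n,
             n_stable = as.integer(colSums(stable_for)),
             observed_freq = as.numeric(observed),
             ci_low = ci[1, ], ci_high = ci[2, ],
             expected_freq = as.numeric(expected), verdict = verdict,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stable-colonization calls and per-genus group association
#'
#' A subject is stably colonized by a genus when strictly more than
#' `threshold` (default 50%) of the subject's longitudinal samples belong to
#' that genus's MPG. For every observed MPG genus, a 2x2 table (AE/AS x
#' colonized yes/no) is tested with the two-sided Fisher exact test.
#'
#' @param assignments result of [assign_mpg()].
#' @param meta validated sample metadata; control subjects are excluded.
#' @param threshold colonization fraction threshold (strict inequality).
#' @return list with `calls` (subject x genus fractions and calls),
#'   `tables` (named list of 2x2 matrices) and `tests` (data.frame `genus`,
#'   `n_colonized_AE`, `n_AE`, `n_colonized_AS`, `n_AS`, `p_value`).
#' @export
stable_colonization <- function(assignments, meta, threshold = 0.5) {
  m <- meta[meta$group %in% c("AE", "AS"), , drop = FALSE]
  lab <- stats::setNames(assignments$mpg, assignments$sample_id)
  m$mpg <- lab[m$sample_id]
  if (any(is.na(m$mpg)))
    stop("sample(s) without MPG assignment: ",
         paste(m$sample_id[is.na(m$mpg)], collapse = ", "))
  genera <- sort(unique(assignments$mpg))
  subjects <- unique(m[, c("subject_id", "group")])
  calls <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    s <- m[m$subject_id == subjects$subject_id[i], , drop = FALSE]
    frac <- vapply(genera, function(g) mean(s$mpg == g), numeric(1))
    data.frame(subject_id = subjects$subject_id[i], group = subjects$group[i],
               genus = genera, n_samples = nrow(s),
               fraction = as.numeric(frac),
               colonized = as.numeric(frac) > threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  tables <- list(); tests <- list()
  for (g in genera) {
    cg <- calls[calls$genus == g, , drop = FALSE]
    tab <- rbind(AE = c(colonized = sum(cg$colonized[cg$group == "AE"]),
                        not = sum(!cg$colonized[cg$group == "AE"])),
                 AS = c(colonized = sum(cg$colonized[cg$group == "AS"]),
                        not = sum(!cg$colonized[cg$group == "AS"])))
    tables[[g]] <- tab
    tests[[g]] <- data.frame(
      genus = g,
      n_colonized_AE = tab["AE", "colonized"], n_AE = sum(tab["AE", ]),
      n_colonized_AS = tab["AS", "colonized"], n_AS = sum(tab["AS", ]),
      p_value = fisher_exact_2x2(tab)$p_value, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(calls = calls, tables = tables, tests = tests)
}
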