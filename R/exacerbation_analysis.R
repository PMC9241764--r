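# Three-phase exacerbation analyses: each exacerbation event is framed by
# its nearest earlier (PreE) and later (PostE) non-exacerbation samples from
# the same subject, giving paired alpha-diversity contrasts, per-phase genus
# abundance summaries with fold changes, and two-stage MPG switch counts.

#' Identify pre / exacerbation / post phase triplets
#'
#' One triplet per exacerbation sample. PreE and PostE are the nearest
#' non-exacerbation samples of the same subject by collection order, within
#' an optional maximum gap. Events with neither neighbour are excluded and
#' reported via a message.
#'
#' @param meta validated metadata containing at least one exacerbation
#'   sample.
#' @param max_gap maximum |collection_order| difference allowed between the
#'   event and a neighbour (default `Inf`).
#' @return data.frame: `event_id`, `subject_id`, `pre_sample`, `exa_sample`,
#'   `post_sample` (`NA` where absent).
#' @export
identify_phases <- function(meta, max_gap = Inf) {
  ev <- meta[meta$sample_type == "exacerbation", , drop = FALSE]
  if (nrow(ev) == 0) stop("metadata contains no exacerbation samples")
  ev <- ev[order(ev$subject_id, ev$collection_order), , drop = FALSE]
  dropped <- character(0)
  out <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    s <- meta[meta$subject_id == e$subject_id &
                meta$sample_type != "exacerbation", , drop = FALSE]
    pre <- s[s$collection_order < e$collection_order &
               e$collection_order - s$collection_order <= max_gap, , drop = FALSE]
    post <- s[s$collection_order > e$collection_order &
                s$collection_order - e$collection_order <= max_gap, , drop = FALSE]
    pre_id <- if (nrow(pre)) pre$sample_id[which.max(pre$collection_order)] else NA_character_
    post_id <- if (nrow(post)) post$sample_id[which.min(post$collection_order)] else NA_character_
    if (is.na(pre_id) && is.na(post_id)) {
      dropped <<- c(dropped, e$sample_id)
      return(NULL)
    }
    data.frame(event_id = sprintf("%s_E%d", e$subject_id,
                                  sum(ev$subject_id[seq_len(i)] == e$subject_id)),
               subject_id = e$subject_id, pre_sample = pre_id,
               exa_sample = e$sample_id, post_sample = post_id,
               stringsAsFactors = FALSE)
  })
  if (length(dropped))
    message("identify_phases: excluded event(s) with no non-exacerbation ",
            "neighbour: ", paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("no exacerbation event has a usable neighbour")
  rownames(res) <- NULL
  res
}

#' Per-phase genus abundance summary with fold changes
#'
#' Mean relative abundance of each genus over the PreE, exacerbation and
#' PostE sample sets, plus exacerbation/PreE and exacerbation/PostE fold
#' changes (undefined where the denominator is zero).
#'
#' @param comp composition matrix, samples x genera.
#' @param triplets result of [identify_phases()].
#' @param genera genus labels to summarise.
#' @return data.frame: `genus`, `mean_pre`, `mean_exa`, `mean_post`,
#'   `fc_exa_pre`, `fc_exa_post`.
#' @export
phase_abundance_summary <- function(comp, triplets, genera) {
  missing <- setdiff(genera, colnames(comp))
  if (length(missing)) stop("genera not in table: ", paste(missing, collapse = ", "))
  sets <- list(pre = unique(stats::na.omit(triplets$pre_sample)),
               exa = unique(stats::na.omit(triplets$exa_sample)),
               post = unique(stats::na.omit(triplets$post_sample)))
  if (length(sets$exa) == 0) stop("no exacerbation samples in triplets")
  phase_mean <- function(ids, g)
    if (length(ids)) mean(comp[ids, g]) else NA_real_
  out <- do.call(rbind, lapply(genera, function(g) {
    mp <- phase_mean(sets$pre, g)
    me <- phase_mean(sets$exa, g)
    mq <- phase_mean(sets$post, g)
    data.frame(genus = g, mean_pre = mp, mean_exa = me, mean_post = mq,
               fc_exa_pre = if (!is.na(mp) && mp > 0) me / mp else NA_real_,
               fc_exa_post = if (!is.na(mq) && mq > 0) me / mq else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired alpha-diversity contrasts across exacerbation phases
#'
#' Wilcoxon signed-rank tests of exacerbation versus PreE and exacerbation
#' versus PostE over events with both members present. Each event is one
#' observation. A contrast without complete pairs is skipped with a warning.
#'
#' @param alpha result of [alpha_diversity()].
#' @param triplets result of [identify_phases()].
#' @param metric alpha metric column to compare.
#' @return data.frame: `contrast`, `n_pairs`, `statistic`, `p_value`.
#' @export
phase_alpha_comparison <- function(alpha, triplets, metric = "shannon") {
  v <- stats::setNames(alpha[[metric]], alpha$sample_id)
  res <- list()
  for (ctr in c("pre", "post")) {
    other <- triplets[[paste0(ctr, "_sample")]]
    ok <- !is.na(other)
    if (!any(ok)) {
      warning("no complete pairs for contrast exacerbation vs ", ctr)
      next
    }
    ht <- wilcoxon_signed_rank(unname(v[triplets$exa_sample[ok]]),
                               unname(v[other[ok]]))
    res[[ctr]] <- data.frame(contrast = paste0("exa_vs_", ctr),
                             n_pairs = sum(ok), statistic = ht$statistic,
                             p_value = ht$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-stage MPG transitions across exacerbation phases
#'
#' Counts MPG label pairs for the PreE -> exacerbation and exacerbation ->
#' PostE stages over triplets with both members present, plus a three-column
#' edge list suitable for Sankey-style reporting.
#'
#' @param assignments result of [assign_mpg()].
#' @param triplets result of [identify_phases()].
#' @return list with `stage1` and `stage2` count matrices and `edges`
#'   (data.frame `from`, `to`, `count`, `stage`).
#' @export
phase_mpg_transitions <- function(assignments, triplets) {
  lab <- stats::setNames(assignments$mpg, assignments$sample_id)
  stage_counts <- function(from_ids, to_ids) {
    ok <- !is.na(from_ids) & !is.na(to_ids)
    if (!any(ok)) return(NULL)
    f <- unname(lab[from_ids[ok]]); t2 <- unname(lab[to_ids[ok]])
    labs <- sort(unique(c(f, t2)))
    unclass(table(factor(f, levels = labs), factor(t2, levels = labs)))
  }
  s1 <- stage_counts(triplets$pre_sample, triplets$exa_sample)
  s2 <- stage_counts(triplets$exa_sample, triplets$post_sample)
  edge_rows <- function(m, stage) {
    if (is.null(m)) return(NULL)
    idx <- which(m > 0, arr.ind = TRUE)
    data.frame(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
               count = m[idx], stage = stage, stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_rows(s1, "pre_to_exa"), edge_rows(s2, "exa_to_post"))
  if (!is.null(edges)) rownames(edges) <- NULL
  list(stage1 = s1, stage2 = s2, edges = edges)
}
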