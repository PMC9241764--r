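# End-to-end orchestration: filter -> rarefy -> aggregate -> diversity ->
# MPG -> stability -> colonization -> mixed models -> exacerbation phases,
# with per-stage seed derivation, TSV outputs and a reproducibility manifest.

#' Derive a stage seed from the master seed
#'
#' Deterministic polynomial hash of the stage name folded into the master
#' seed, kept below 2^31 so it is a valid R integer seed. Adding stages never
#' perturbs the seeds of existing ones.
#'
#' @param master master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Run the full longitudinal microbiome analysis
#'
#' Orchestrates every stage of the pipeline on a count table and metadata
#' (optionally aggregating an ASV-level table through a taxonomy map first)
#' and writes each stage's table plus a machine-readable manifest into
#' `outdir`. Optional stages that cannot run on the given cohort (e.g. the
#' exacerbation-phase analyses when no exacerbation samples exist) are
#' recorded as skipped and the run continues.
#'
#' @param counts count matrix (samples x taxa) or path to a TSV file.
#' @param metadata metadata data.frame or path to a TSV file.
#' @param taxonomy optional taxonomy map (named vector or TSV path) for
#'   ASV-level input.
#' @param outdir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param min_total rare-taxon filter threshold.
#' @param depth rarefaction depth, or `"min"` for the minimum sample total.
#' @param bootstrap_B bootstrap replicates for the stability analysis.
#' @param colonization_threshold stable-colonization fraction threshold.
#' @param transition_scope `"all"` or `"nonexacerbation"`.
#' @param top_k,min_mean selection of genera for the trend models.
#' @param lme_min_samples per-subject eligibility for the mixed models.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(counts, metadata, taxonomy = NULL, outdir, seed,
                         min_total = 2, depth = "min", bootstrap_B = 1000,
                         colonization_threshold = 0.5,
                         transition_scope = "all", top_k = 8,
                         min_mean = 0.01, lme_min_samples = 3) {
  if (missing(seed)) stop("a master seed is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(counts)) counts <- read_count_table(counts)
  validate_count_table(counts)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- validate_metadata(metadata)
  if (is.character(taxonomy) && length(taxonomy) == 1 && file.exists(taxonomy))
    taxonomy <- read_taxonomy_map(taxonomy)
  missing_meta <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing_meta))
    stop("sample(s) missing from metadata: ", paste(missing_meta, collapse = ", "))
  counts <- counts[metadata$sample_id, , drop = FALSE]

  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  res <- list()

  # -- core table processing ------------------------------------------------
  filtered <- filter_rare_taxa(counts, min_total = min_total)
  used_depth <- if (identical(depth, "min")) min(rowSums(filtered)) else as.integer(depth)
  rarefied <- rarefy_counts(filtered, depth = used_depth,
                            seed = derive_seed(seed, "rarefy"))
  genus_tab <- if (!is.null(taxonomy)) aggregate_to_genus(rarefied, taxonomy) else rarefied
  comp <- to_relative(genus_tab)
  write_count_table(rarefied, file.path(outdir, "rarefied_counts.tsv"))
  write_count_table(genus_tab, file.path(outdir, "genus_counts.tsv"))
  write_count_table(comp, file.path(outdir, "relative_abundance.tsv"))

  # -- diversity ------------------------------------------------------------
  alpha <- alpha_diversity(genus_tab)
  bc <- bray_curtis(genus_tab)
  jac <- jaccard_distance(genus_tab)
  ord <- pcoa_ordination(bc, k = min(2, nrow(bc) - 1))
  utils::write.table(alpha, file.path(outdir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_matrix(bc, file.path(outdir, "bray_curtis.tsv"))
  write_distance_matrix(jac, file.path(outdir, "jaccard.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
    file.path(outdir, "pcoa_coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  res$alpha <- alpha; res$bray_curtis <- bc; res$jaccard <- jac

  # -- MPG assignment, transitions, stability, colonization -----------------
  assignments <- assign_mpg(comp)
  transitions <- build_transitions(assignments, metadata, scope = transition_scope)
  res$assignments <- assignments; res$transitions <- transitions
  utils::write.table(assignments, file.path(outdir, "mpg_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(transitions, file.path(outdir, "mpg_transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(transitions)) {
    tm <- transition_matrix(transitions)
    write_distance_matrix(tm$counts, file.path(outdir, "transition_counts.tsv"))
    stability <- stability_analysis(transitions, B = bootstrap_B,
                                    seed = derive_seed(seed, "stability"))
    utils::write.table(stability, file.path(outdir, "mpg_stability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$stability <- stability
  } else note("stability stage skipped: no transitions")
  colonization <- stable_colonization(assignments, metadata,
                                      threshold = colonization_threshold)
  utils::write.table(colonization$tests, file.path(outdir, "colonization_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(colonization$calls, file.path(outdir, "colonization_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$colonization <- colonization

  # -- longitudinal mixed models -------------------------------------------
  lme_rows <- list()
  for (metric in c("shannon", "pielou", "observed")) {
    lme_rows[[metric]] <- tryCatch({
      fit_lme(build_alpha_series(alpha, metadata, metric = metric,
                                 min_samples = lme_min_samples))
    }, error = function(e) { note("lme ", metric, " skipped: ", conditionMessage(e)); NULL })
  }
  for (dn in c("bray_curtis", "jaccard")) {
    dmat <- if (dn == "bray_curtis") bc else jac
    lme_rows[[dn]] <- tryCatch({
      fit_lme(consecutive_distances(dmat, metadata, label = dn,
                                    min_samples = lme_min_samples))
    }, error = function(e) { note("lme ", dn, " skipped: ", conditionMessage(e)); NULL })
  }
  genera <- top_genera(comp, k = top_k, min_mean = min_mean)
  taxa_trends <- tryCatch(
    fit_taxa_trends(comp, metadata, genera, min_samples = lme_min_samples),
    error = function(e) { note("taxa trends skipped: ", conditionMessage(e)); NULL })
  lme_table <- do.call(rbind, c(lme_rows, list(taxa_trends)))
  if (!is.null(lme_table)) {
    rownames(lme_table) <- NULL
    utils::write.table(lme_table, file.path(outdir, "lme_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$lme <- lme_table
  }

  # -- exacerbation phases --------------------------------------------------
  if (any(metadata$sample_type == "exacerbation")) {
    phase <- tryCatch({
      triplets <- identify_phases(metadata)
      summ <- phase_abundance_summary(comp, triplets,
                                      intersect(genera, colnames(comp)))
      cmp_alpha <- phase_alpha_comparison(alpha, triplets)
      trans <- phase_mpg_transitions(assignments, triplets)
      utils::write.table(triplets, file.path(outdir, "phase_triplets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summ, file.path(outdir, "phase_abundance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cmp_alpha, file.path(outdir, "phase_alpha_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(trans$edges))
        utils::write.table(trans$edges, file.path(outdir, "phase_mpg_edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(triplets = triplets, abundance = summ, alpha_tests = cmp_alpha,
           transitions = trans)
    }, error = function(e) { note("phase stage skipped: ", conditionMessage(e)); NULL })
    res$phases <- phase
  } else note("phase stage skipped: no exacerbation samples")

  manifest <- list(
    package_version = as.character(utils::packageVersion("npmdyn")),
    master_seed = seed,
    stage_seeds = list(rarefy = derive_seed(seed, "rarefy"),
                       stability = derive_seed(seed, "stability")),
    config = list(min_total = min_total, depth = used_depth,
                  bootstrap_B = bootstrap_B,
                  colonization_threshold = colonization_threshold,
                  transition_scope = transition_scope, top_k = top_k,
                  min_mean = min_mean, lme_min_samples = lme_min_samples),
    n_samples = nrow(counts), n_taxa_input = ncol(counts),
    n_taxa_filtered = ncol(filtered), n_transitions = nrow(transitions),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Write a human-readable run report
#'
#' Summarises a completed [run_pipeline()] output directory: MPG frequencies,
#' stability verdicts, colonization tests, the mixed-model p-value grid and
#' the exacerbation-phase summary. Regeneration is idempotent. Missing stage
#' files are listed rather than failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file report filename within `run_dir`.
#' @return path of the report, invisibly.
#' @export
write_report <- function(run_dir, file = "report.txt") {
  p <- function(...) file.path(run_dir, ...)
  lines <- c("Longitudinal nasopharyngeal microbiome analysis report",
             strrep("=", 54), "")
  missing <- character(0)
  fmt_df <- function(df) utils::capture.output(print(df, row.names = FALSE))
  if (file.exists(p("mpg_assignments.tsv"))) {
    a <- utils::read.delim(p("mpg_assignments.tsv"))
    freq <- sort(table(a$mpg), decreasing = TRUE)
    lines <- c(lines, "MPG sample frequencies:",
               sprintf("  %-20s %4d (%.1f%%)", names(freq), as.integer(freq),
                       100 * as.integer(freq) / sum(freq)), "")
  } else missing <- c(missing, "mpg_assignments.tsv")
  if (file.exists(p("mpg_stability.tsv"))) {
    s <- utils::read.delim(p("mpg_stability.tsv"))
    lines <- c(lines, "MPG transition stability (observed vs p^2 expected):",
               fmt_df(s[, c("mpg", "observed_freq", "ci_low", "ci_high",
                            "expected_freq", "verdict")]), "")
  } else missing <- c(missing, "mpg_stability.tsv")
  if (file.exists(p("colonization_tests.tsv"))) {
    ct <- utils::read.delim(p("colonization_tests.tsv"))
    lines <- c(lines, "Stable colonization by group (Fisher exact):",
               fmt_df(ct), "")
  } else missing <- c(missing, "colonization_tests.tsv")
  if (file.exists(p("lme_results.tsv"))) {
    lt <- utils::read.delim(p("lme_results.tsv"))
    lines <- c(lines, "Mixed-model p-values (time, group, time x group):",
               fmt_df(lt[, c("label", "p_time", "p_group", "p_interaction")]), "")
  } else missing <- c(missing, "lme_results.tsv")
  if (file.exists(p("phase_abundance.tsv"))) {
    pa <- utils::read.delim(p("phase_abundance.tsv"))
    lines <- c(lines, "Exacerbation-phase mean relative abundances:",
               fmt_df(pa), "")
  } else missing <- c(missing, "phase_abundance.tsv")
  if (length(missing))
    lines <- c(lines, "Missing stage output(s):",
               paste0("  ", missing), "")
  writeLines(lines, p(file))
  invisible(p(file))
}
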