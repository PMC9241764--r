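#!/usr/bin/env Rscript
# Diversity structure of the cohort: rare-taxon filtering, rarefaction to an
# even depth, alpha diversity, Bray-Curtis/Jaccard distances, PCoA, baseline
# PERMANOVA (age-adjusted asthma-group effect) and the cross-sectional
# control / baseline / exacerbation comparison of Shannon diversity.

suppressMessages(library(npmdyn))
dir.create("results/diversity", recursive = TRUE, showWarnings = FALSE)
seed <- 20170901

counts <- read_count_table("results/simulated/counts.tsv")
meta <- read_metadata("results/simulated/metadata.tsv")

filtered <- filter_rare_taxa(counts, min_total = 2)
depth <- min(rowSums(filtered))
rarefied <- rarefy_counts(filtered, depth = depth, seed = derive_seed(seed, "rarefy"))
cat(sprintf("Rarefied %d samples to an even depth of %d reads\n",
            nrow(rarefied), depth))

alpha <- alpha_diversity(rarefied)
write.table(alpha, "results/diversity/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
bc <- bray_curtis(rarefied)
write_distance_matrix(bc, "results/diversity/bray_curtis.tsv")
write_distance_matrix(jaccard_distance(rarefied), "results/diversity/jaccard.tsv")

ord <- pcoa_ordination(bc, k = 2)
write.table(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
            "results/diversity/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA axes 1-2 explain %.1f%% and %.1f%% of positive inertia\n",
            100 * ord$proportion_explained[1], 100 * ord$proportion_explained[2]))

# Baseline beta diversity vs clinical factors: age entered first, then the
# asthma group, so the group effect is conditioned on age.
base <- meta[meta$sample_type == "baseline", ]
pm <- permanova(bc[base$sample_id, base$sample_id], base, c("age", "group"),
                n_perm = 1000, seed = derive_seed(seed, "permanova"))
write.table(pm, "results/diversity/baseline_permanova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nBaseline PERMANOVA on Bray-Curtis (age first, then asthma group):\n")
print(pm, row.names = FALSE)

# Shannon diversity across the three cross-sectional sample categories.
cross <- meta[meta$sample_type %in% c("control", "baseline", "exacerbation"), ]
sdi <- setNames(alpha$shannon, alpha$sample_id)[cross$sample_id]
kd <- kruskal_dunn(sdi, cross$sample_type)
write.table(kd$pairwise, "results/diversity/sdi_dunn_pairwise.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nKruskal-Wallis on Shannon diversity across categories: p = %.4g\n",
            kd$kw$p_value))
cat("Geometric mean SDI by category:\n")
for (ct in unique(cross$sample_type)) {
  v <- sdi[cross$sample_type == ct]
  cat(sprintf("  %-15s %.2f (n = %d)\n", ct, geometric_mean(v[v > 0]), length(v)))
}
print(kd$pairwise, row.names = FALSE)
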