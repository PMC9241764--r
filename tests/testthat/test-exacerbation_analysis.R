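make_event_meta <- function() {
  # subject A: N E N; subject B: E N (no pre); subject C: only E (excluded)
  meta <- rbind(
    data.frame(sample_id = c("A_T0", "A_T1", "A_T2"), subject_id = "A",
               collection_order = 0:2, time_point = 0:2, group = "AE",
               sample_type = c("baseline", "exacerbation", "nonexacerbation"),
               age = 10),
    data.frame(sample_id = c("B_T0", "B_T1"), subject_id = "B",
               collection_order = 0:1, time_point = 0:1, group = "AE",
               sample_type = c("exacerbation", "nonexacerbation"), age = 11),
    data.frame(sample_id = "C_T0", subject_id = "C", collection_order = 0,
               time_point = 0, group = "AE", sample_type = "exacerbation",
               age = 12))
  validate_metadata(meta)
}

test_that("phase triplets pick nearest neighbours and drop isolated events", {
  meta <- make_event_meta()
  expect_message(tri <- identify_phases(meta), "C_T0")
  expect_equal(nrow(tri), 2)
  a <- tri[tri$subject_id == "A", ]
  expect_equal(a[, c("pre_sample", "exa_sample", "post_sample")],
               data.frame(pre_sample = "A_T0", exa_sample = "A_T1",
                          post_sample = "A_T2"), ignore_attr = TRUE)
  b <- tri[tri$subject_id == "B", ]
  expect_true(is.na(b$pre_sample))    # event at first sample: kept via post
  expect_equal(b$post_sample, "B_T1")
  # a max_gap below the spacing removes distant neighbours
  expect_error(suppressMessages(identify_phases(meta, max_gap = 0.5)),
               "no exacerbation event")
  expect_error(identify_phases(meta[meta$sample_type != "exacerbation", ]),
               "no exacerbation samples")
})

test_that("phase abundance summary computes per-phase means and fold changes", {
  meta <- make_event_meta()
  tri <- suppressMessages(identify_phases(meta))
  comp <- matrix(0.25, 6, 4,
                 dimnames = list(meta$sample_id, c("g1", "g2", "g3", "g4")))
  # all samples identical: every defined fold change is 1
  s <- phase_abundance_summary(comp, tri, c("g1", "g2"))
  expect_equal(s$fc_exa_pre, c(1, 1))
  expect_equal(s$fc_exa_post, c(1, 1))
  # a genus absent everywhere: mean 0, fold change undefined
  comp2 <- comp; comp2[, "g4"] <- 0; comp2 <- comp2 / rowSums(comp2)
  s2 <- phase_abundance_summary(comp2, tri, "g4")
  expect_equal(s2$mean_exa, 0)
  expect_true(is.na(s2$fc_exa_pre))
})

test_that("phase alpha contrasts delegate to the signed-rank test", {
  meta <- make_event_meta()
  tri <- suppressMessages(identify_phases(meta))
  alpha <- data.frame(sample_id = meta$sample_id,
                      shannon = c(2.5, 1.2, 2.4, 1.0, 2.2, 0.5))
  res <- phase_alpha_comparison(alpha, tri)
  expect_setequal(res$contrast, c("exa_vs_pre", "exa_vs_post"))
  # identical to calling the test directly on the same pairs
  v <- setNames(alpha$shannon, alpha$sample_id)
  ok <- !is.na(tri$post_sample)
  direct <- wilcoxon_signed_rank(unname(v[tri$exa_sample[ok]]),
                                 unname(v[tri$post_sample[ok]]))
  expect_equal(res$p_value[res$contrast == "exa_vs_post"], direct$p_value)
  # identical paired values give p = 1
  alpha2 <- transform(alpha, shannon = 1)
  expect_equal(phase_alpha_comparison(alpha2, tri)$p_value, c(1, 1))
  # n = 8 pairs all one direction: exact p = 2/256
  meta8 <- validate_metadata(do.call(rbind, lapply(1:8, function(i)
    data.frame(sample_id = sprintf("S%d_T%d", i, 0:2), subject_id = sprintf("S%d", i),
               collection_order = 0:2, time_point = 0:2, group = "AE",
               sample_type = c("baseline", "exacerbation", "nonexacerbation"),
               age = 9))))
  tri8 <- identify_phases(meta8)
  alpha8 <- data.frame(sample_id = meta8$sample_id,
                       shannon = rep(c(2, 1, 2.5), 8) + rep(1:8 / 100, each = 3))
  res8 <- phase_alpha_comparison(alpha8, tri8)
  expect_equal(res8$p_value[res8$contrast == "exa_vs_pre"], 2 / 256)
})

test_that("two-stage MPG transition counts conserve the triplet totals", {
  meta <- make_event_meta()
  tri <- suppressMessages(identify_phases(meta))
  lab <- setNames(c("Dolosigranulum", "Moraxella", "Dolosigranulum",
                    "Moraxella", "Moraxella", "Moraxella"), meta$sample_id)
  pt <- phase_mpg_transitions(make_assign(lab), tri)
  # stage-1 total = triplets with both pre and exa present
  expect_equal(sum(pt$stage1), sum(!is.na(tri$pre_sample)))
  expect_equal(sum(pt$stage2), sum(!is.na(tri$post_sample)))
  # forced switch concentrates on a single cell and returns after the event
  expect_equal(unname(pt$stage1["Dolosigranulum", "Moraxella"]), 1)
  expect_equal(unname(pt$stage2["Moraxella", "Dolosigranulum"]), 1)
  expect_true(all(c("from", "to", "count", "stage") %in% colnames(pt$edges)))
  # unchanged labels give purely diagonal counts
  lab2 <- setNames(rep("Moraxella", 6), meta$sample_id)
  pt2 <- phase_mpg_transitions(make_assign(lab2), tri)
  expect_equal(sum(pt2$stage1) + sum(pt2$stage2),
               sum(diag(pt2$stage1)) + sum(diag(pt2$stage2)))
})

test_that("with recovery the bloom genus returns toward its pre-event level", {
  ok <- vapply(1:20, function(i) {
    sim <- simulate_cohort(sim_config(seed = 700 + i))
    comp <- to_relative(sim$counts)
    tri <- suppressMessages(identify_phases(sim$metadata))
    s <- phase_abundance_summary(comp, tri, "Moraxella")
    abs(s$mean_post - s$mean_pre) < abs(s$mean_exa - s$mean_pre)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
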