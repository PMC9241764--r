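test_that("MPG assignment picks the dominant genus with the stated tie rule", {
  comp <- rbind(c(0.6, 0.25, 0.15), c(0.2, 0.5, 0.3))
  rownames(comp) <- c("s1", "s2")
  colnames(comp) <- c("Moraxella", "Dolosigranulum", "Streptococcus")
  a <- assign_mpg(comp)
  expect_equal(a$mpg, c("Moraxella", "Dolosigranulum"))
  expect_equal(a$dominant_fraction, c(0.6, 0.5))
  # exact tie: the genus with the higher cohort mean wins, and is logged
  tied <- rbind(c(0.4, 0.4, 0.2), c(0.1, 0.8, 0.1))
  rownames(tied) <- c("s1", "s2"); colnames(tied) <- colnames(comp)
  expect_message(at <- assign_mpg(tied), "tie")
  expect_equal(at$mpg[1], "Dolosigranulum")   # higher cohort mean
  expect_identical(attr(at, "ties"), "s1")
  # labels are invariant to count scaling (argmax property)
  x <- make_counts(rbind(c(30, 20, 10), c(5, 45, 10)),
                   taxa = colnames(comp))
  a1 <- assign_mpg(to_relative(x))
  a2 <- assign_mpg(to_relative(x * 7L))
  expect_equal(a1$mpg, a2$mpg)
})

test_that("profile clustering is complete-linkage on Bray-Curtis", {
  comp <- rbind(c(0.7, 0.3), c(0.7, 0.3), c(0.2, 0.8), c(0.45, 0.55))
  rownames(comp) <- sprintf("s%d", 1:4); colnames(comp) <- c("gA", "gB")
  hc <- hcluster_profiles(comp, c("gA", "gB"))
  expect_s3_class(hc, "hclust")
  expect_equal(min(hc$height), 0)               # identical samples merge first
  expect_true(all(diff(hc$height) >= -1e-12))   # monotone agglomeration
  # hand-computed complete-linkage tree: d12=0, d34=0.25, final merge at
  # max pairwise BC = 0.5
  expect_equal(hc$height, c(0, 0.25, 0.5))
  expect_error(hcluster_profiles(comp[1, , drop = FALSE], "gA"), "2 samples")
})

test_that("transition building pairs consecutive in-scope samples per subject", {
  meta <- validate_metadata(rbind(make_meta(c("A", "B"), c(3, 1)),
                                  make_meta("C", 1, group = "control")))
  meta$sample_type[meta$sample_id == "C_T0"] <- "control"
  lab <- setNames(rep("Moraxella", nrow(meta)), meta$sample_id)
  lab["A_T1"] <- "Dolosigranulum"
  tr <- build_transitions(make_assign(lab), meta)
  expect_equal(nrow(tr), 2)            # A contributes 2, B has 1 sample, C control
  expect_equal(tr$stable, c(FALSE, FALSE))
  expect_equal(tr$sample_t1, c("A_T0", "A_T1"))
  # full 6-point series: 5 transitions per subject
  meta6 <- validate_metadata(make_meta(c("X", "Y", "Z"), 6))
  lab6 <- setNames(rep("Moraxella", nrow(meta6)), meta6$sample_id)
  expect_equal(nrow(build_transitions(make_assign(lab6), meta6)), 15)
  # extra visits participate at fractional orders
  extra <- make_meta("E", 3, group = "AE")
  extra <- rbind(extra, data.frame(sample_id = "E_X1", subject_id = "E",
                                   collection_order = 1.5, time_point = NA,
                                   group = "AE", sample_type = "exacerbation",
                                   age = 10))
  extra <- validate_metadata(extra)
  labx <- setNames(rep("Moraxella", 4), extra$sample_id)
  trx <- build_transitions(make_assign(labx), extra)
  expect_equal(trx$sample_t2[2], "E_X1")
  expect_equal(nrow(trx), 3)
  # nonexacerbation scope removes the extra visit before pairing
  trn <- build_transitions(make_assign(labx), extra, scope = "nonexacerbation")
  expect_equal(nrow(trn), 2)
  expect_false("E_X1" %in% c(trn$sample_t1, trn$sample_t2))
})

test_that("transition matrices conserve counts with unit row proportions", {
  meta <- validate_metadata(make_meta(c("A", "B"), 4))
  lab <- setNames(c("g1", "g1", "g2", "g2", "g1", "g1", "g1", "g1"),
                  meta$sample_id)
  tm <- transition_matrix(build_transitions(make_assign(lab), meta))
  expect_equal(sum(tm$counts), 6)
  nonempty <- rowSums(tm$counts) > 0
  expect_true(all(abs(rowSums(tm$proportions)[nonempty] - 1) < 1e-12))
  # all-stable records give a diagonal matrix
  lab2 <- setNames(rep("g1", 8), meta$sample_id)
  tm2 <- transition_matrix(build_transitions(make_assign(lab2), meta))
  expect_equal(unname(tm2$counts["g1", "g1"]), 6)
})

test_that("stability analysis follows the observed/expected/CI verdict rule", {
  meta <- validate_metadata(make_meta("A", 5))
  lab <- setNames(rep("g1", 5), meta$sample_id)
  st <- stability_analysis(build_transitions(make_assign(lab), meta),
                           B = 200, seed = 1)
  # single MPG everywhere: observed = expected = 1, verdict compatible
  expect_equal(st$observed_freq, 1)
  expect_equal(st$expected_freq, 1)
  expect_equal(st$verdict, "compatible")
  # sum over MPGs of observed = overall stable proportion; sum expected <= 1
  sim <- simulate_cohort(power_regime(71))
  tr <- build_transitions(assign_mpg(to_relative(sim$counts)), sim$metadata)
  st2 <- stability_analysis(tr, B = 200, seed = 2)
  expect_equal(sum(st2$observed_freq), mean(tr$stable))
  expect_lte(sum(st2$expected_freq), 1)
  expect_true(all(st2$ci_low <= st2$observed_freq &
                    st2$observed_freq <= st2$ci_high))
  # same seed reproduces the bootstrap exactly
  expect_identical(st2, stability_analysis(tr, B = 200, seed = 2))
})

test_that("stability analysis is equivariant under MPG relabelling", {
  sim <- simulate_cohort(power_regime(73))
  tr <- build_transitions(assign_mpg(to_relative(sim$counts)), sim$metadata)
  st <- stability_analysis(tr, B = 300, seed = 5)
  # bijective rename of the labels permutes the rows, nothing else
  rename <- function(v) paste0("x_", v)
  tr2 <- transform(tr, mpg_t1 = rename(mpg_t1), mpg_t2 = rename(mpg_t2))
  st2 <- stability_analysis(tr2, B = 300, seed = 5)
  st2$mpg <- sub("^x_", "", st2$mpg)
  st2 <- st2[order(st2$mpg), ]; rownames(st2) <- NULL
  expect_equal(st2, st[order(st$mpg), ], ignore_attr = TRUE)
})

test_that("bootstrap CI width shrinks like 1/sqrt(N)", {
  widths <- vapply(c(6, 24, 96), function(n_subj) {
    sim <- simulate_cohort(null_regime(79, n_subjects = n_subj))
    tr <- build_transitions(assign_mpg(to_relative(sim$counts)), sim$metadata)
    st <- stability_analysis(tr, B = 500, seed = 11)
    i <- which.max(st$observed_freq)
    st$ci_high[i] - st$ci_low[i]
  }, numeric(1))
  n <- c(6, 24, 96) * 5
  slope <- coef(lm(log(widths) ~ log(n)))[2]
  expect_lt(abs(slope - (-0.5)), 0.3 * 0.5 + 0.15)  # slope ~ -0.5 within 30%ish
})

test_that("subject-block bootstrap is available and seed-stable", {
  sim <- simulate_cohort(power_regime(83))
  tr <- build_transitions(assign_mpg(to_relative(sim$counts)), sim$metadata)
  st <- stability_analysis(tr, B = 200, seed = 3, resample = "subject")
  expect_true(all(st$ci_low <= st$ci_high))
  expect_identical(st, stability_analysis(tr, B = 200, seed = 3,
                                          resample = "subject"))
})

test_that("stable colonization uses a strict >50% rule and Fisher grouping", {
  # subject with 3/6 samples in a genus is NOT colonized; 4/6 is
  meta <- validate_metadata(make_meta(c("A", "B"), 6, group = c("AS", "AS")))
  lab <- setNames(c(rep("g1", 3), rep("g2", 3),      # A: 3/6 g1
                    rep("g1", 4), rep("g2", 2)),     # B: 4/6 g1
                  meta$sample_id)
  res <- stable_colonization(make_assign(lab), meta)
  calls <- res$calls[res$calls$genus == "g1", ]
  expect_equal(setNames(calls$colonized, calls$subject_id),
               c(A = FALSE, B = TRUE))
  # the printed worked example: 4/13 AS vs 0/11 AE colonized -> p ~ 0.098
  subjects <- c(sprintf("AE%02d", 1:11), sprintf("AS%02d", 1:13))
  groups <- rep(c("AE", "AS"), c(11, 13))
  meta2 <- validate_metadata(make_meta(subjects, 6, group = groups))
  lab2 <- setNames(rep("Moraxella", nrow(meta2)), meta2$sample_id)
  for (s in sprintf("AS%02d", 1:4))
    lab2[meta2$sample_id[meta2$subject_id == s][1:4]] <- "Corynebacterium_1"
  res2 <- stable_colonization(make_assign(lab2), meta2)
  row <- res2$tests[res2$tests$genus == "Corynebacterium_1", ]
  expect_equal(row$n_colonized_AS, 4)
  expect_equal(row$n_colonized_AE, 0)
  expect_equal(round(row$p_value, 3), 0.098)
})
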