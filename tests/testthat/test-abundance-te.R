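test_that("relative abundance normalises per sample over the gene universe", {
  df <- tibble::tibble(sample = "s1", gene_id = c("g1", "g2", "g3"),
                       abundance = c(10, 30, 60))
  expect_equal(relative_abundance(df)$rel_abundance, c(0.1, 0.3, 0.6))

  one <- relative_abundance(df, gene_universe = "g2")
  expect_equal(one$rel_abundance, 1)

  # excluding an indeterminate gene renormalises over the rest
  sub <- relative_abundance(df, gene_universe = c("g1", "g2"))
  expect_equal(sub$rel_abundance, c(0.25, 0.75))
  expect_false("g3" %in% sub$gene_id)

  zero <- tibble::tibble(sample = c("s1", "s2"), gene_id = "g1",
                         abundance = c(1, 0))
  expect_error(relative_abundance(zero), "s2")
})

test_that("relative-abundance rows sum to one and are scale invariant", {
  sim <- sim_abundance(tibble::tibble(
    gene_id = paste0("g", 1:20),
    label = rep(c("glucose_tolerant", "non_tolerant"), 10)), seed = 5)
  rel <- relative_abundance(sim$dna)
  sums <- tapply(rel$rel_abundance, rel$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  scaled <- sim$dna
  scaled$abundance <- scaled$abundance * ifelse(scaled$sample == "CK", 1000, 1)
  rel2 <- relative_abundance(scaled)
  expect_equal(rel2$rel_abundance, rel$rel_abundance)
})

test_that("replicate aggregation takes arithmetic means and reports CV", {
  df <- tibble::tibble(
    sample = c("CK_r1", "CK_r2", "T_r1"),
    treatment = c("CK", "CK", "T"),
    gene_id = "g1",
    abundance = c(4, 6, 7))
  agg <- aggregate_replicates(df)
  expect_equal(agg$abundance[agg$treatment == "CK"], 5)
  expect_equal(agg$abundance[agg$treatment == "T"], 7)
  expect_equal(agg$n_replicates, c(2L, 1L))

  zeros <- tibble::tibble(sample = paste0("CK_r", 1:3), treatment = "CK",
                          gene_id = "g1", abundance = 0)
  aggz <- aggregate_replicates(zeros)
  expect_equal(aggz$abundance, 0)
  expect_true(is.na(aggz$cv))
})

test_that("transcription efficiency is the RNA/DNA ratio with guards", {
  dna <- tibble::tibble(treatment = "T", gene_id = c("g1", "g2", "g3"),
                        rel_abundance = c(0.1, 0.1, 0))
  rna <- tibble::tibble(treatment = "T", gene_id = c("g1", "g2", "g3"),
                        rel_abundance = c(0.2, 0, 0.5))
  te <- transcription_efficiency(dna, rna)
  expect_equal(te$te, c(2, 0, NA_real_))

  flipped <- transcription_efficiency(dna, rna, direction = "dna_rna")
  expect_equal(flipped$te[1], 0.5)

  rna_bad <- rna[rna$gene_id != "g3", ]
  expect_error(transcription_efficiency(dna, rna_bad), "g3")
})

test_that("relative TE follows the control-normalised fractional change", {
  te <- tibble::tibble(
    treatment = rep(c("CK", "T1", "T2"), each = 2),
    gene_id = rep(c("g1", "g2"), 3),
    te = c(1, 2, 1, 2, 2, 1))
  rel <- relative_te(te, ck = "CK")
  expect_equal(rel$rel_te[rel$treatment == "CK"], c(0, 0))
  expect_equal(rel$rel_te[rel$treatment == "T2"], c(1, -0.5))

  # control TE of zero excludes the gene with a log entry
  te0 <- dplyr::bind_rows(te, tibble::tibble(
    treatment = c("CK", "T1", "T2"), gene_id = "g3", te = c(0, 5, 5)))
  expect_message(rel0 <- relative_te(te0, ck = "CK"), "excluded")
  expect_false("g3" %in% rel0$gene_id)
  expect_equal(attr(rel0, "excluded"), "g3")

  expect_error(relative_te(te, ck = "missing"), "absent")
})

test_that("group summaries average per gene and report the signed gap", {
  calls <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    call = c("glucose_tolerant", "glucose_tolerant", "non_tolerant",
             "non_tolerant", "indeterminate"))
  rel <- tibble::tibble(treatment = "T", gene_id = c("a", "b", "c", "d", "e"),
                        rel_te = c(0.5, 1.5, -0.2, -0.8, 99))
  gs <- group_summary(rel, calls)
  gt <- gs[gs$group == "glucose_tolerant", ]
  expect_equal(gt$mean, 1)
  expect_equal(gt$n_genes, 2L)
  expect_equal(unique(gs$gt_minus_nongt), 1 - (-0.5))
  # indeterminate gene never enters
  expect_equal(sum(gs$n_genes), 4L)

  # a treatment where one group is empty still yields a row with n = 0
  solo <- group_summary(rel, calls[calls$call == "glucose_tolerant", ])
  expect_equal(solo$n_genes[solo$group == "non_tolerant"], 0L)
})

test_that("tolerant ratio counts decided genes, optionally weighted", {
  calls <- tibble::tibble(
    gene_id = paste0("g", 1:31),
    call = rep(c("glucose_tolerant", "non_tolerant"), c(17, 14)))
  expect_equal(tolerant_ratio(calls), 17 / 31, tolerance = 1e-12)

  all_gt <- tibble::tibble(gene_id = "g", call = "glucose_tolerant")
  expect_equal(tolerant_ratio(all_gt), 1)

  # indeterminate genes leave numerator and denominator
  with_ind <- dplyr::bind_rows(calls, tibble::tibble(
    gene_id = "g99", call = "indeterminate"))
  expect_equal(tolerant_ratio(with_ind), 17 / 31)

  w <- c(setNames(rep(0.9 / 17, 17), paste0("g", 1:17)),
         setNames(rep(0.1 / 14, 14), paste0("g", 18:31)))
  expect_equal(tolerant_ratio(calls, w), 0.9, tolerance = 1e-12)

  expect_error(tolerant_ratio(calls, setNames(rep(0, 31), calls$gene_id)), "zero")
  expect_error(tolerant_ratio(tibble::tibble(gene_id = "g", call = "indeterminate")),
               "decided")
})

test_that("relative activity is a percentage with a monotonicity flag", {
  out <- relative_activity(50, 100)
  expect_equal(out$relative_activity_pct, 50)
  expect_equal(relative_activity(7, 7)$relative_activity_pct, 100)
  expect_warning(flagged <- relative_activity(c(80, 60, 70), 100,
                                              conc = c(50, 100, 200)),
                 "monotone")
  expect_true(attr(flagged, "non_monotone"))
  expect_error(relative_activity(10, 0), "positive")
})

test_that("qPCR replicate tables summarise the same before or after averaging", {
  truth <- tibble::tibble(gene_id = paste0("g", 1:10),
                          label = rep(c("glucose_tolerant", "non_tolerant"), 5))
  sim <- sim_qpcr(truth, noise_cv = 0.15, seed = 9)
  agg <- aggregate_replicates(sim$dna)
  # manual mean over replicates, base R route
  man <- aggregate(abundance ~ treatment + gene_id, data = sim$dna, FUN = mean)
  joined <- merge(agg, man, by = c("treatment", "gene_id"))
  expect_equal(joined$abundance.x, joined$abundance.y)

  te <- transcription_efficiency(aggregate_replicates(sim$dna),
                                 aggregate_replicates(sim$rna),
                                 value_col = "abundance")
  rel <- relative_te(te)
  gs <- group_summary(rel, dplyr::rename(truth, call = label))
  # recompute one cell from scratch
  gt_ids <- truth$gene_id[truth$label == "glucose_tolerant"]
  cell <- rel$rel_te[rel$treatment == "G_H_C_H" & rel$gene_id %in% gt_ids]
  expect_equal(gs$mean[gs$treatment == "G_H_C_H" & gs$group == "glucose_tolerant"],
               mean(cell))
})
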