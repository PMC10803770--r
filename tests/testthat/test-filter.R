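test_that("the reference ratio takes the smaller bait/cofactor ratio", {
  psm <- reference_psm(sel1l = c(wt = 10L, hko = 30L),
                       os9 = c(wt = 10L, hko = 20L))
  expect_equal(reference_ratio(psm, "expt1"), 2)

  all_ratios <- reference_ratio(psm)
  expect_equal(all_ratios$ref_ratio, 2)

  only_os9 <- psm_row("OS9", wt = 0L, hko = 8L)
  expect_warning(r <- reference_ratio(only_os9, "expt1"), "OS9")
  expect_equal(r, 8)  # denominator floored at 1

  none <- psm_row("SOMETHING", wt = 5L, hko = 5L)
  expect_error(reference_ratio(none, "expt1"), class = "erad_stage_error")
})

cascade_verdict <- function(row, annot, score = 1, cutoff = 0,
                            ref_ratio = 2) {
  rr <- data.frame(experiment_id = row$experiment_id, ref_ratio = ref_ratio)
  scores <- flat_scores(row, score)
  apply_filter_cascade(row, annot, scores, cutoff, rr)
}

test_that("each cascade rule fires on its documented boundary", {
  er <- annot_row("P1", localizations = "ER")

  keratin <- cascade_verdict(psm_row(hko = 50L, wt = 2L),
                             annot_row("P1", keratin = TRUE))
  expect_false(keratin$passed)
  expect_equal(keratin$failure_reasons, "KERATIN")

  below <- cascade_verdict(psm_row(hko = 50L, wt = 2L), er,
                           score = 0.3, cutoff = 0.4)
  expect_equal(below$failure_reasons, "SCORE_BELOW_CUTOFF")

  # IgG at exactly one tenth of HRD1-KO is allowed (inclusive reading)
  igg_edge <- cascade_verdict(psm_row(igg = 1L, hko = 10L, wt = 1L), er)
  expect_true(igg_edge$passed)
  igg_over <- cascade_verdict(psm_row(igg = 2L, hko = 10L, wt = 1L), er)
  expect_equal(igg_over$failure_reasons, "IGG_TOO_HIGH")

  # SEL1L-KO exemption: sko >= wt tolerated while sko <= 1
  exempt <- cascade_verdict(psm_row(wt = 0L, sko = 1L, hko = 6L), er)
  expect_true(exempt$passed)
  sko_fail <- cascade_verdict(psm_row(wt = 2L, sko = 2L, hko = 30L), er)
  expect_equal(sko_fail$failure_reasons, "SKO_NOT_BELOW_WT")

  # HRD1-KO must strictly exceed SEL1L-KO
  tie <- cascade_verdict(psm_row(hko = 5L, sko = 5L, wt = 6L), er)
  expect_true(grepl("HKO_NOT_ABOVE_SKO", tie$failure_reasons))

  # ratio must strictly exceed the reference
  at_ref <- cascade_verdict(psm_row(hko = 4L, wt = 2L), er, ref_ratio = 2)
  expect_equal(at_ref$failure_reasons, "RATIO_VS_REFERENCE")

  # nucleus-only featureless proteins are removed, a single TM rescues
  bare_nuc <- annot_row("P1", localizations = "nucleus",
                        signal_peptide = FALSE, n_glyc = 0L, n_tm = 0L)
  nuc <- cascade_verdict(psm_row(hko = 50L, wt = 2L), bare_nuc)
  expect_equal(nuc$failure_reasons, "NUCLEUS_ONLY")
  tm_nuc <- bare_nuc; tm_nuc$n_tm_domains <- 1L
  expect_true(cascade_verdict(psm_row(hko = 50L, wt = 2L), tm_nuc)$passed)
})

test_that("failing rows report every violated rule in cascade order", {
  row <- psm_row(igg = 9L, sko = 9L, wt = 3L, hko = 1L)
  v <- cascade_verdict(row, annot_row("P1", keratin = TRUE),
                       score = 0.1, cutoff = 0.5)
  expect_equal(v$failure_reasons,
               paste("KERATIN", "SCORE_BELOW_CUTOFF", "RATIO_VS_REFERENCE",
                     "SKO_NOT_BELOW_WT", "HKO_NOT_ABOVE_SKO", "IGG_TOO_HIGH",
                     sep = ";"))
  expect_false(v$passed)
})

test_that("raising hko never converts a pass into a fail", {
  er <- annot_row("P1", localizations = "ER")
  set.seed(8)
  for (i in 1:40) {
    igg <- sample(0:3, 1); sko <- sample(0:4, 1); wt <- sample(0:6, 1)
    hko <- sample(0:12, 1)
    v0 <- cascade_verdict(psm_row(igg = igg, sko = sko, wt = wt, hko = hko), er)
    v1 <- cascade_verdict(psm_row(igg = igg, sko = sko, wt = wt,
                                  hko = hko + sample(1:5, 1)), er)
    if (v0$passed) expect_true(v1$passed)
  }
})

test_that("candidates need two passing experiments; groups track WT detection", {
  psm <- psm_table(
    psm_row("A", "expt1", wt = 1L, hko = 20L),
    psm_row("A", "expt2", wt = 0L, hko = 18L),
    psm_row("A", "expt3", wt = 0L, hko = 0L),
    psm_row("B", "expt1", wt = 0L, hko = 15L),
    psm_row("B", "expt2", wt = 0L, hko = 12L),
    psm_row("B", "expt3", wt = 0L, hko = 0L),
    psm_row("C", "expt1", wt = 0L, hko = 9L),
    psm_row("C", "expt2", wt = 5L, hko = 0L),
    psm_row("C", "expt3", wt = 5L, hko = 0L)
  )
  verdicts <- data.frame(
    protein_id = psm$protein_id, experiment_id = psm$experiment_id,
    passed = c(TRUE, TRUE, FALSE,  TRUE, TRUE, FALSE,  TRUE, FALSE, FALSE),
    failure_reasons = "", stringsAsFactors = FALSE
  )
  scores <- flat_scores(psm, 0.9)
  calls <- call_candidates(verdicts, psm, scores)
  row <- function(id) calls[calls$protein_id == id, ]
  expect_true(row("A")$final_candidate); expect_equal(row("A")$group, "A")
  expect_true(row("B")$final_candidate); expect_equal(row("B")$group, "B")
  expect_false(row("C")$final_candidate); expect_equal(row("C")$group, "none")
  expect_equal(row("A")$n_experiments_passed, 2L)
})

test_that("mean scores average HRD1-KO-detected experiments only", {
  psm <- psm_table(psm_row("A", "expt1", hko = 20L),
                   psm_row("A", "expt2", hko = 0L))
  verdicts <- data.frame(protein_id = "A",
                         experiment_id = c("expt1", "expt2"),
                         passed = c(TRUE, TRUE), failure_reasons = "")
  scores <- data.frame(protein_id = "A", experiment_id = c("expt1", "expt2"),
                       score = c(0.8, 0.2))
  calls <- call_candidates(verdicts, psm, scores)
  expect_equal(calls$mean_score, 0.8)
})

test_that("transcriptional upregulation strips candidate status", {
  calls <- data.frame(
    protein_id = c("DECOY", "STABLE", "UNKNOWN"),
    n_experiments_passed = 3L, group = "A", mean_score = 0.9,
    rna_excluded = FALSE, final_candidate = TRUE, stringsAsFactors = FALSE
  )
  annot <- annot_table(annot_row("DECOY"), annot_row("STABLE"),
                       annot_row("UNKNOWN"))
  de <- data.frame(
    gene_symbol = c("DECOY", "STABLE"), contrast = "HRD1KO_vs_WT",
    log2fc = c(2.5, 0.1), padj = c(1e-6, 0.9), stringsAsFactors = FALSE
  )
  expect_warning(out <- rna_exclusion(calls, de, annot), "retained")
  expect_true(out$rna_excluded[out$protein_id == "DECOY"])
  expect_false(out$final_candidate[out$protein_id == "DECOY"])
  expect_equal(out$group[out$protein_id == "DECOY"], "none")
  expect_true(out$final_candidate[out$protein_id == "STABLE"])
  expect_true(out$final_candidate[out$protein_id == "UNKNOWN"])

  # below-threshold fold change is never excluded however significant
  de2 <- data.frame(gene_symbol = "STABLE", contrast = "HRD1KO_vs_WT",
                    log2fc = 0.9, padj = 1e-9)
  out2 <- suppressWarnings(rna_exclusion(calls, de2, annot))
  expect_false(out2$rna_excluded[out2$protein_id == "STABLE"])
})
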