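#!/usr/bin/env Rscript
# Apply the hard-filter cascade per experiment, require passing in at
# least two experiments, assign Group A/B by WT detectability, remove
# transcriptionally upregulated hits with the RNA-seq DE table, and
# evaluate recovery of the planted substrates.

suppressPackageStartupMessages(library(eradscreen))

dir.create("results/candidates", recursive = TRUE, showWarnings = FALSE)

refs <- list(human = c("SEL1L", "OS9"), mouse = c("Sel1l", "Os9"))

for (name in c("human", "mouse")) {
  psm <- complete_psm_table(
    read_psm_table(sprintf("results/sim/%s_psm.tsv", name)))
  annot <- read_annotation_table(sprintf("results/sim/%s_annotation.tsv", name))
  de <- read_de_table(sprintf("results/sim/%s_de.tsv", name))
  truth <- read_tsv_table(sprintf("results/sim/%s_truth.tsv", name))
  scores <- read_tsv_table(sprintf("results/scoring/%s_scores.tsv", name))
  model <- jsonlite::read_json(sprintf("results/scoring/%s_model.json", name))

  rr <- reference_ratio(psm, NULL, refs[[name]])
  verdicts <- apply_filter_cascade(psm, annot, scores, model$cutoff, rr)
  calls <- call_candidates(verdicts, psm, scores)
  calls <- rna_exclusion(calls, de, annot)

  write_tsv_table(verdicts, sprintf("results/candidates/%s_verdicts.tsv", name))
  write_tsv_table(calls, sprintf("results/candidates/%s_candidates.tsv", name))

  called <- calls$protein_id[calls$final_candidate]
  cc <- truth_confusion(called, truth)
  cat(sprintf(
    "%s screen: %d candidates (Group A %d, Group B %d); RNA-excluded %d; sensitivity %.2f, precision %.2f\n",
    name, length(called), sum(calls$group == "A"), sum(calls$group == "B"),
    sum(calls$rna_excluded),
    cc$tp / (cc$tp + cc$fn), cc$tp / (cc$tp + cc$fp)))
}
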