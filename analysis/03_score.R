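#!/usr/bin/env Rscript
# Fit the logistic confidence score for each screen: PSM enrichment
# features, training labels from annotations plus the known-substrate
# list, MCC-maximizing fit, per-experiment scores, and the score cutoff
# anchored on hits detected exclusively in HRD1-KO with 2 PSMs.

suppressPackageStartupMessages(library(eradscreen))

dir.create("results/scoring", recursive = TRUE, showWarnings = FALSE)

for (name in c("human", "mouse")) {
  psm <- complete_psm_table(
    read_psm_table(sprintf("results/sim/%s_psm.tsv", name)))
  annot <- read_annotation_table(sprintf("results/sim/%s_annotation.tsv", name))
  known <- readLines(sprintf("results/sim/%s_known_positives.txt", name))

  features <- compute_features(psm)
  mf <- mean_features(features)
  labels <- derive_labels(annot, known)
  model <- suppressWarnings(fit_confidence_model(
    mf$x1, mf$x2, labels$label[match(mf$protein_id, labels$protein_id)]))

  scores <- data.frame(protein_id = features$protein_id,
                       experiment_id = features$experiment_id,
                       score = score_confidence(model, features$x1, features$x2))
  mean_scores <- data.frame(protein_id = mf$protein_id,
                            score = score_confidence(model, mf$x1, mf$x2))
  cutoff <- select_cutoff(mean_scores, psm)

  write_tsv_table(scores, sprintf("results/scoring/%s_scores.tsv", name))
  write_tsv_table(mean_scores, sprintf("results/scoring/%s_mean_scores.tsv", name))
  jsonlite::write_json(
    list(weights = as.list(model$weights), achieved_mcc = model$achieved_mcc,
         n_pos = model$n_pos, n_neg = model$n_neg,
         cutoff = as.numeric(cutoff),
         n_anchor_proteins = length(attr(cutoff, "anchors"))),
    sprintf("results/scoring/%s_model.json", name),
    auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s screen: trained on %d pos / %d neg; hard MCC %.3f; cutoff %.2g from %d anchor proteins\n",
              name, model$n_pos, model$n_neg, model$achieved_mcc,
              as.numeric(cutoff), length(attr(cutoff, "anchors"))))
}
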