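#!/usr/bin/env Rscript
# Simulate two SEL1L IP-MS screens with planted ground truth: a human
# cell-line-like screen and a mouse adipocyte-like screen (3 replicate
# experiments each, 2000 proteins, four pulldown genotypes). Writes the
# PSM, annotation, DE and truth tables that the later steps consume.

suppressPackageStartupMessages(library(eradscreen))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

screens <- list(
  human = sim_config(n_proteins = 2000, species = "human", seed = 101),
  mouse = sim_config(n_proteins = 2000, species = "mouse", seed = 102)
)

for (name in names(screens)) {
  d <- generate_dataset(screens[[name]])
  prefix <- file.path(out, name)
  write_tsv_table(d$psm, paste0(prefix, "_psm.tsv"))
  write_tsv_table(d$annotation, paste0(prefix, "_annotation.tsv"))
  write_tsv_table(d$de, paste0(prefix, "_de.tsv"))
  write_tsv_table(d$truth, paste0(prefix, "_truth.tsv"))
  writeLines(d$known_positives, paste0(prefix, "_known_positives.txt"))
  cat(sprintf(
    "%s screen: %d proteins x %d experiments; %d planted substrates, %d decoys, %d known positives\n",
    name, length(unique(d$psm$protein_id)),
    length(unique(d$psm$experiment_id)),
    sum(d$truth$role == "substrate"),
    sum(d$truth$role == "transcriptional_decoy"),
    length(d$known_positives)))
}
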