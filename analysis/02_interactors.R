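#!/usr/bin/env Rscript
# Select SEL1L-interacting proteins from the WT vs SEL1L-KO columns of
# each simulated screen: ER-resident or membrane proteins whose SEL1L-KO
# PSMs are below one tenth of their WT PSMs.

suppressPackageStartupMessages(library(eradscreen))

dir.create("results/interactors", recursive = TRUE, showWarnings = FALSE)

for (name in c("human", "mouse")) {
  psm <- read_psm_table(sprintf("results/sim/%s_psm.tsv", name))
  annot <- read_annotation_table(sprintf("results/sim/%s_annotation.tsv", name))
  calls <- select_interactors(psm, annot)
  write_tsv_table(calls, sprintf("results/interactors/%s_interactors.tsv", name))
  cat(sprintf("%s screen: %d of %d proteins called SEL1L interactors (%d ER/membrane-eligible)\n",
              name, sum(calls$selected), nrow(calls),
              sum(calls$eligible_localization)))
}
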