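# In-code fixtures shared across test files.

# One PSM row; defaults make a clean HRD1-KO-enriched hit.
psm_row <- function(protein_id = "P1", experiment_id = "expt1",
                    igg = 0L, sko = 0L, wt = 2L, hko = 20L) {
  data.frame(protein_id = protein_id, experiment_id = experiment_id,
             psm_igg = igg, psm_sko = sko, psm_wt = wt, psm_hko = hko,
             stringsAsFactors = FALSE)
}

# Stack several psm_row() calls.
psm_table <- function(...) do.call(rbind, list(...))

# Minimal annotation row; defaults describe an ER client protein.
annot_row <- function(protein_id = "P1", gene_symbol = protein_id,
                      species = "human", localizations = "ER",
                      signal_peptide = TRUE, n_glyc = 2L,
                      disulfide = FALSE, n_tm = 1L, keratin = FALSE) {
  data.frame(protein_id = protein_id, gene_symbol = gene_symbol,
             species = species, localizations = localizations,
             has_signal_peptide = signal_peptide,
             n_glycosylation_sites = n_glyc, has_disulfide = disulfide,
             n_tm_domains = n_tm, is_keratin_family = keratin,
             stringsAsFactors = FALSE)
}

annot_table <- function(...) do.call(rbind, list(...))

# Reference rows (bait + cofactor) every cascade test needs.
reference_psm <- function(experiment_id = "expt1",
                          sel1l = c(wt = 10L, hko = 30L),
                          os9 = c(wt = 10L, hko = 20L)) {
  psm_table(
    psm_row("SEL1L", experiment_id, wt = sel1l[["wt"]], hko = sel1l[["hko"]]),
    psm_row("OS9", experiment_id, wt = os9[["wt"]], hko = os9[["hko"]])
  )
}

reference_annot <- function() {
  annot_table(
    annot_row("SEL1L", localizations = "ER;membrane"),
    annot_row("OS9", localizations = "ER")
  )
}

# Uniform per-experiment scores covering a PSM table.
flat_scores <- function(psm, score = 1) {
  data.frame(protein_id = psm$protein_id, experiment_id = psm$experiment_id,
             score = score, stringsAsFactors = FALSE)
}

# Independently coded scalar predicate for the filter cascade: a literal,
# rule-by-rule transcription used as the brute-force oracle. Returns the
# ordered reason codes (empty character vector = pass).
brute_force_reasons <- function(igg, sko, wt, hko, score, cutoff, ref_ratio,
                                keratin, nucleus_only, signal_peptide,
                                n_glyc, disulfide, n_tm) {
  reasons <- character(0)
  if (keratin) reasons <- c(reasons, "KERATIN")
  if (score < cutoff) reasons <- c(reasons, "SCORE_BELOW_CUTOFF")
  wt_floor <- if (wt > 1) wt else 1
  if (!(hko / wt_floor > ref_ratio)) reasons <- c(reasons, "RATIO_VS_REFERENCE")
  sko_ok <- (sko < wt) || (sko <= 1)
  if (!sko_ok) reasons <- c(reasons, "SKO_NOT_BELOW_WT")
  if (!(hko > sko)) reasons <- c(reasons, "HKO_NOT_ABOVE_SKO")
  igg_ok <- (igg == 0) || (igg <= hko / 10)
  if (!igg_ok) reasons <- c(reasons, "IGG_TOO_HIGH")
  featureless <- !signal_peptide && n_glyc == 0 && !disulfide && n_tm == 0
  if (nucleus_only && featureless) reasons <- c(reasons, "NUCLEUS_ONLY")
  reasons
}

# Hard MCC of thresholded logistic predictions for a weight vector; used by
# the lattice oracle for the model fit.
hard_mcc_at <- function(w, x1, x2, pos) {
  pred <- (w[1] + w[2] * x1 + w[3] * x2) >= 0
  mcc(sum(pred & pos), sum(!pred & !pos), sum(pred & !pos), sum(!pred & pos))
}
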