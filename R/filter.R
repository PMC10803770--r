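# Hard-filter cascade, replicate consensus, Group A/B assignment and
# RNA-seq-based transcriptional exclusion.
#
# Boundary readings of the selection rules, each applied exactly as stated:
#   - IgG "zero or no greater than one-tenth of HRD1-KO"  -> igg <= hko/10 (inclusive)
#   - SEL1L-KO "must be smaller than WT"                   -> sko <  wt (strict)
#   - SEL1L-KO exemption "no > 1"                          -> sko <= 1
#   - HRD1-KO "must be greater than SEL1L-KO"              -> hko >  sko (strict)
#   - enrichment "greater than the smaller reference ratio"-> ratio > ref (strict)

FILTER_REASONS <- c("KERATIN", "SCORE_BELOW_CUTOFF", "RATIO_VS_REFERENCE",
                    "SKO_NOT_BELOW_WT", "HKO_NOT_ABOVE_SKO", "IGG_TOO_HIGH",
                    "NUCLEUS_ONLY")

#' Reference enrichment ratio per experiment
#'
#' The candidate enrichment filter compares each hit's HRD1-KO:WT PSM ratio
#' against the smaller of the same ratio for the bait (SEL1L) and its
#' cofactor (OS9) in the same experiment. Denominators are floored at 1.
#' If one reference protein is absent from an experiment the other is used
#' with a warning; if both are absent the stage fails naming the
#' experiment.
#'
#' @param psm PSM table.
#' @param experiment_id experiment to evaluate; `NULL` computes all.
#' @param reference_proteins protein ids of bait and cofactor.
#' @return a single ratio, or (for `NULL`) a data frame
#'   `experiment_id`, `ref_ratio`.
#' @export
reference_ratio <- function(psm, experiment_id = NULL,
                            reference_proteins = c("SEL1L", "OS9")) {
  psm <- validate_psm_table(psm)
  if (is.null(experiment_id)) {
    expts <- sort(unique(psm$experiment_id))
    ratios <- vapply(expts, function(e)
      reference_ratio(psm, e, reference_proteins), numeric(1))
    return(data.frame(experiment_id = expts, ref_ratio = unname(ratios),
                      stringsAsFactors = FALSE))
  }
  rows <- psm[psm$experiment_id == experiment_id &
                psm$protein_id %in% reference_proteins, , drop = FALSE]
  rows <- rows[rows$psm_hko > 0 | rows$psm_wt > 0, , drop = FALSE]
  if (nrow(rows) == 0L) {
    erad_stage_error(paste0("no reference protein (",
                            paste(reference_proteins, collapse = ", "),
                            ") detected in experiment ", experiment_id))
  }
  if (nrow(rows) < length(reference_proteins)) {
    warning("experiment ", experiment_id, ": only ",
            paste(rows$protein_id, collapse = ", "),
            " available as enrichment reference", call. = FALSE)
  }
  min(rows$psm_hko / pmax(rows$psm_wt, 1))
}

#' Apply the hard-filter cascade to every (protein, experiment) row
#'
#' Evaluates, without short-circuiting so all failing reasons are recorded:
#' keratin-family removal; confidence score at or above the cutoff;
#' HRD1-KO:WT ratio strictly above the reference ratio of the same
#' experiment; SEL1L-KO below WT unless SEL1L-KO is at most 1; HRD1-KO
#' strictly above SEL1L-KO; IgG zero or at most one tenth of HRD1-KO; and
#' exclusion of proteins localized only to the nucleus unless they carry a
#' signal peptide, N-glycosylation, disulfide bond or transmembrane domain.
#'
#' @param psm PSM table.
#' @param annot annotation table covering the proteins in `psm`.
#' @param scores data frame `protein_id`, `experiment_id`, `score`
#'   (per-experiment confidence scores).
#' @param cutoff global score cutoff from [select_cutoff()].
#' @param ref_ratios data frame `experiment_id`, `ref_ratio` from
#'   [reference_ratio()].
#' @return verdict data frame: `protein_id`, `experiment_id`, `passed`,
#'   `failure_reasons` (`;`-joined, in cascade order, empty iff passed).
#' @export
apply_filter_cascade <- function(psm, annot, scores, cutoff, ref_ratios) {
  psm <- validate_psm_table(psm)
  annot <- validate_annotation_table(annot)

  i_annot <- match(psm$protein_id, annot$protein_id)
  if (anyNA(i_annot)) {
    erad_stage_error(paste0("protein(s) missing from annotation: ",
                            paste(utils::head(unique(
                              psm$protein_id[is.na(i_annot)]), 5),
                              collapse = ", ")))
  }
  key <- paste(psm$protein_id, psm$experiment_id, sep = "\r")
  skey <- paste(scores$protein_id, scores$experiment_id, sep = "\r")
  score <- scores$score[match(key, skey)]
  if (anyNA(score)) {
    erad_stage_error("scores must cover every (protein, experiment) row")
  }
  rr <- ref_ratios$ref_ratio[match(psm$experiment_id, ref_ratios$experiment_id)]
  if (anyNA(rr)) {
    erad_stage_error("reference ratio missing for some experiment")
  }

  loc <- split_localizations(annot$localizations)[i_annot]
  nucleus_only <- vapply(loc, function(l) all(l == "nucleus"), logical(1))
  featureless <- !annot$has_signal_peptide[i_annot] &
    annot$n_glycosylation_sites[i_annot] == 0L &
    !annot$has_disulfide[i_annot] &
    annot$n_tm_domains[i_annot] == 0L

  fails <- cbind(
    KERATIN            = annot$is_keratin_family[i_annot],
    SCORE_BELOW_CUTOFF = score < cutoff,
    RATIO_VS_REFERENCE = !(psm$psm_hko / pmax(psm$psm_wt, 1) > rr),
    SKO_NOT_BELOW_WT   = !(psm$psm_sko < psm$psm_wt | psm$psm_sko <= 1),
    HKO_NOT_ABOVE_SKO  = !(psm$psm_hko > psm$psm_sko),
    IGG_TOO_HIGH       = !(psm$psm_igg == 0 | psm$psm_igg <= psm$psm_hko / 10),
    NUCLEUS_ONLY       = nucleus_only & featureless
  )
  reasons <- apply(fails, 1L, function(f)
    paste(FILTER_REASONS[f], collapse = ";"))
  data.frame(protein_id = psm$protein_id, experiment_id = psm$experiment_id,
             passed = !apply(fails, 1L, any), failure_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Call substrate candidates from per-experiment verdicts
#'
#' A protein becomes a candidate when it passes the cascade in at least
#' `min_experiments` independent experiments. Candidates detected in the WT
#' pulldown (`psm_wt > 0` in any experiment) form Group A; candidates never
#' detected in WT form Group B. The reported score is the mean of
#' per-experiment scores over experiments with HRD1-KO detection.
#'
#' @param verdicts output of [apply_filter_cascade()].
#' @param psm PSM table.
#' @param scores per-experiment scores (`protein_id`, `experiment_id`,
#'   `score`).
#' @param min_experiments consensus threshold.
#' @return data frame `protein_id`, `n_experiments_passed`, `group`
#'   (A/B/none), `mean_score`, `rna_excluded`, `final_candidate`.
#' @export
call_candidates <- function(verdicts, psm, scores, min_experiments = 2L) {
  psm <- validate_psm_table(psm)
  n_passed <- tapply(verdicts$passed, verdicts$protein_id, sum)
  proteins <- sort(unique(psm$protein_id))
  if (!all(proteins %in% names(n_passed))) {
    erad_stage_error("verdicts must cover every protein in the PSM table")
  }
  n_passed <- n_passed[proteins]

  wt_detected <- tapply(psm$psm_wt > 0, psm$protein_id, any)[proteins]

  det <- psm$psm_hko > 0
  skey <- paste(scores$protein_id, scores$experiment_id, sep = "\r")
  key <- paste(psm$protein_id, psm$experiment_id, sep = "\r")
  sc <- scores$score[match(key, skey)]
  ms <- tapply(ifelse(det, sc, NA_real_), psm$protein_id,
               function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  mean_score <- unname(ms[proteins])

  candidate <- unname(n_passed) >= min_experiments
  group <- ifelse(candidate, ifelse(unname(wt_detected), "A", "B"), "none")
  out <- data.frame(protein_id = proteins,
                    n_experiments_passed = as.integer(n_passed),
                    group = group, mean_score = mean_score,
                    rna_excluded = FALSE, final_candidate = candidate,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclude candidates with transcriptional upregulation
#'
#' Enrichment in HRD1-KO pulldowns can reflect increased expression rather
#' than stabilized protein. Candidates whose gene shows significant mRNA
#' upregulation in HRD1-KO vs WT (`padj < alpha` and `log2fc > min_log2fc`)
#' are excluded. Candidates absent from the DE table are retained with a
#' warning.
#'
#' @param calls candidate table from [call_candidates()].
#' @param de differential-expression table.
#' @param annot annotation table, used to map protein ids to gene symbols.
#' @param alpha adjusted-p significance level.
#' @param min_log2fc log2 fold-change threshold defining upregulation.
#' @param contrast DE contrast to use.
#' @return `calls` with `rna_excluded` set, `final_candidate` and `group`
#'   downgraded for excluded proteins.
#' @export
rna_exclusion <- function(calls, de, annot, alpha = 0.05, min_log2fc = 1,
                          contrast = "HRD1KO_vs_WT") {
  de <- validate_de_table(de)
  annot <- validate_annotation_table(annot)
  de <- de[de$contrast == contrast, , drop = FALSE]
  gene <- annot$gene_symbol[match(calls$protein_id, annot$protein_id)]
  i_de <- match(gene, de$gene_symbol)

  up <- !is.na(i_de) & !is.na(de$padj[i_de]) & de$padj[i_de] < alpha &
    de$log2fc[i_de] > min_log2fc

  missing_cand <- calls$final_candidate & is.na(i_de)
  if (any(missing_cand)) {
    warning(sum(missing_cand),
            " candidate(s) absent from the DE table were retained",
            call. = FALSE)
  }

  calls$rna_excluded <- calls$final_candidate & up
  calls$final_candidate <- calls$final_candidate & !calls$rna_excluded
  calls$group[!calls$final_candidate] <- "none"
  calls
}
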