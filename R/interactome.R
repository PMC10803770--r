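# SEL1L-interactor selection from WT vs SEL1L-KO pulldowns.

#' Select SEL1L-interacting proteins
#'
#' A protein is called a SEL1L interactor when it is ER-resident or a
#' membrane protein and its PSM signal in the SEL1L-KO negative control is
#' smaller than one tenth of its PSM signal in WT pulldowns (strict
#' inequality). PSMs are summed across replicate experiments before the
#' one-tenth test by default; `per_experiment = TRUE` instead requires the
#' rule to hold in every experiment where the protein was detected.
#' Proteins without an annotation row are ineligible and reported via a
#' warning. The IgG and HRD1-KO columns play no part in this call.
#'
#' @param psm PSM table (see [validate_psm_table()]).
#' @param annot protein annotation table.
#' @param per_experiment apply the rule per experiment instead of to pooled
#'   PSMs.
#' @return data frame with one row per protein: `protein_id`, `wt_psm`,
#'   `sko_psm` (pooled counts), `eligible_localization`, `selected`.
#' @export
select_interactors <- function(psm, annot, per_experiment = FALSE) {
  psm <- validate_psm_table(psm)
  annot <- validate_annotation_table(annot)

  wt <- tapply(psm$psm_wt, psm$protein_id, sum)
  sko <- tapply(psm$psm_sko, psm$protein_id, sum)
  proteins <- names(wt)

  loc <- split_localizations(annot$localizations)
  eligible_by_id <- vapply(loc, function(l) any(l %in% c("ER", "membrane")),
                           logical(1))
  names(eligible_by_id) <- annot$protein_id
  eligible <- unname(eligible_by_id[proteins])
  unannotated <- is.na(eligible)
  if (any(unannotated)) {
    warning(sum(unannotated),
            " protein(s) lack annotation and were treated as ineligible",
            call. = FALSE)
    eligible[unannotated] <- FALSE
  }

  if (per_experiment) {
    rule <- tapply(psm$psm_sko < psm$psm_wt / 10, psm$protein_id, all)
    passes_ratio <- unname(rule[proteins])
  } else {
    passes_ratio <- unname(sko < wt / 10)
  }

  out <- data.frame(protein_id = proteins,
                    wt_psm = as.integer(wt), sko_psm = as.integer(sko),
                    eligible_localization = eligible,
                    selected = eligible & passes_ratio,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
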