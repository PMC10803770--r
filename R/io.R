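# All tables move through the pipeline as plain data frames in a fixed TSV
# dialect: UTF-8, tab-separated, header row, no quoting of identifiers —
# the supplementary-table conventions of proteomics papers. Every
# intermediate the pipeline writes is re-readable by the same readers.

PSM_COLUMNS <- c("psm_igg", "psm_sko", "psm_wt", "psm_hko")
GENOTYPES <- c(igg = "psm_igg", sko = "psm_sko", wt = "psm_wt", hko = "psm_hko")

LOCALIZATION_LEVELS <- c("ER", "Golgi", "lysosome", "membrane", "nucleus",
                         "mitochondrion", "secreted", "cytosol")

#' Validate a PSM count table
#'
#' A PSM table holds one row per (protein, experiment) with non-negative
#' integer peptide-spectrum-match counts for the four pulldown genotypes:
#' IgG control (`psm_igg`), SEL1L knockout (`psm_sko`), wild type (`psm_wt`)
#' and HRD1 knockout (`psm_hko`).
#'
#' @param psm data frame with columns `protein_id`, `experiment_id`,
#'   `psm_igg`, `psm_sko`, `psm_wt`, `psm_hko`.
#' @return The validated data frame, counts coerced to integer.
#' @export
validate_psm_table <- function(psm) {
  required <- c("protein_id", "experiment_id", PSM_COLUMNS)
  missing <- setdiff(required, names(psm))
  if (length(missing) > 0L) {
    erad_schema_error(paste0("PSM table is missing column(s): ",
                             paste(missing, collapse = ", ")))
  }
  for (col in PSM_COLUMNS) {
    v <- psm[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      erad_value_error(paste0("column ", col, " must be numeric with no NA"))
    }
    if (any(v < 0) || any(v != floor(v))) {
      erad_value_error(paste0("column ", col,
                              " must contain non-negative integers"))
    }
    psm[[col]] <- as.integer(v)
  }
  key <- paste(psm$protein_id, psm$experiment_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- psm[duplicated(key), , drop = FALSE][1L, ]
    erad_integrity_error(paste0("duplicate (protein, experiment) row: (",
                                dup$protein_id, ", ", dup$experiment_id, ")"))
  }
  psm$protein_id <- as.character(psm$protein_id)
  psm$experiment_id <- as.character(psm$experiment_id)
  psm
}

#' Read a PSM count table from TSV
#'
#' @param path path to a tab-separated file with header
#'   `protein_id experiment_id psm_igg psm_sko psm_wt psm_hko`.
#' @return validated PSM data frame.
#' @export
read_psm_table <- function(path) {
  validate_psm_table(read_tsv_table(path))
}

#' Materialize missing (protein, experiment) entries as zero counts
#'
#' Proteins absent from an experiment's search results were simply not
#' detected; the screen treats absence as zero signal.
#'
#' @param psm validated PSM table.
#' @param experiments experiment ids to complete against; defaults to those
#'   present in `psm`.
#' @return PSM table covering every protein x experiment combination.
#' @export
complete_psm_table <- function(psm, experiments = NULL) {
  psm <- validate_psm_table(psm)
  if (is.null(experiments)) experiments <- sort(unique(psm$experiment_id))
  proteins <- sort(unique(psm$protein_id))
  full <- expand.grid(protein_id = proteins, experiment_id = experiments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(full, psm, by = c("protein_id", "experiment_id"),
               all.x = TRUE, sort = FALSE)
  for (col in PSM_COLUMNS) out[[col]][is.na(out[[col]])] <- 0L
  out <- out[order(out$protein_id, out$experiment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a protein annotation table
#'
#' Annotations carry the sequence/topology features used for training labels
#' and the filter cascade: subcellular localizations (semicolon-separated),
#' signal peptide, N-glycosylation site count, disulfide bonds,
#' transmembrane domain count, and a keratin-family flag (gene symbols with
#' prefix KRT or KRTAP, the dominant IP-MS contaminant family).
#'
#' @param annot data frame with columns `protein_id`, `gene_symbol`,
#'   `species`, `localizations`, `has_signal_peptide`,
#'   `n_glycosylation_sites`, `has_disulfide`, `n_tm_domains`,
#'   `is_keratin_family`.
#' @return validated data frame.
#' @export
validate_annotation_table <- function(annot) {
  required <- c("protein_id", "gene_symbol", "species", "localizations",
                "has_signal_peptide", "n_glycosylation_sites",
                "has_disulfide", "n_tm_domains", "is_keratin_family")
  missing <- setdiff(required, names(annot))
  if (length(missing) > 0L) {
    erad_schema_error(paste0("annotation table is missing column(s): ",
                             paste(missing, collapse = ", ")))
  }
  if (!all(annot$species %in% c("human", "mouse"))) {
    erad_value_error("species must be 'human' or 'mouse'")
  }
  if (any(!nzchar(annot$localizations)) || anyNA(annot$localizations)) {
    erad_value_error("localizations must be non-empty")
  }
  bad <- setdiff(unlist(strsplit(annot$localizations, ";", fixed = TRUE)),
                 LOCALIZATION_LEVELS)
  if (length(bad) > 0L) {
    erad_value_error(paste0("unknown localization(s): ",
                            paste(unique(bad), collapse = ", ")))
  }
  for (col in c("has_signal_peptide", "has_disulfide", "is_keratin_family")) {
    annot[[col]] <- as.logical(annot[[col]])
    if (anyNA(annot[[col]])) erad_value_error(paste0(col, " must be boolean"))
  }
  for (col in c("n_glycosylation_sites", "n_tm_domains")) {
    v <- annot[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
      erad_value_error(paste0(col, " must be a non-negative integer"))
    }
    annot[[col]] <- as.integer(v)
  }
  if (anyDuplicated(annot$protein_id)) {
    erad_integrity_error("duplicate protein_id in annotation table")
  }
  annot$protein_id <- as.character(annot$protein_id)
  annot$gene_symbol <- as.character(annot$gene_symbol)
  annot
}

#' Read a protein annotation table from TSV
#' @param path path to a tab-separated annotation file.
#' @return validated annotation data frame.
#' @export
read_annotation_table <- function(path) {
  validate_annotation_table(read_tsv_table(path))
}

#' Validate a differential-expression table
#'
#' One row per (gene, contrast) from a precomputed RNA-seq analysis of
#' knockout vs wild type; used only to exclude candidates whose IP-MS
#' enrichment is explained by transcriptional upregulation.
#'
#' @param de data frame with columns `gene_symbol`, `contrast`
#'   (`HRD1KO_vs_WT` or `SEL1LKO_vs_WT`), `log2fc`, `padj`.
#' @return validated data frame.
#' @export
validate_de_table <- function(de) {
  required <- c("gene_symbol", "contrast", "log2fc", "padj")
  missing <- setdiff(required, names(de))
  if (length(missing) > 0L) {
    erad_schema_error(paste0("DE table is missing column(s): ",
                             paste(missing, collapse = ", ")))
  }
  if (!all(de$contrast %in% c("HRD1KO_vs_WT", "SEL1LKO_vs_WT"))) {
    erad_value_error("contrast must be HRD1KO_vs_WT or SEL1LKO_vs_WT")
  }
  ok <- is.na(de$padj) | (de$padj >= 0 & de$padj <= 1)
  if (!all(ok)) erad_value_error("padj must lie in [0, 1] when present")
  de$gene_symbol <- as.character(de$gene_symbol)
  de
}

#' Read a differential-expression table from TSV
#' @param path path to a tab-separated DE file.
#' @return validated DE data frame.
#' @export
read_de_table <- function(path) {
  validate_de_table(read_tsv_table(path))
}

#' Read a mouse-to-human ortholog symbol map from TSV
#'
#' Expects two columns, `mouse_symbol` and `human_symbol`, e.g. extracted
#' from the Alliance of Genome Resources homology report. The map must be a
#' function: one human symbol per mouse symbol.
#'
#' @param path path to a tab-separated two-column file.
#' @return data frame with `mouse_symbol`, `human_symbol`.
#' @export
read_ortholog_map <- function(path) {
  map <- read_tsv_table(path)
  missing <- setdiff(c("mouse_symbol", "human_symbol"), names(map))
  if (length(missing) > 0L) {
    erad_schema_error(paste0("ortholog map is missing column(s): ",
                             paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(map$mouse_symbol)) {
    erad_integrity_error("ortholog map must give one human symbol per mouse symbol")
  }
  map$mouse_symbol <- as.character(map$mouse_symbol)
  map$human_symbol <- as.character(map$human_symbol)
  map
}

#' Read a pathway assignment table from TSV
#'
#' Curated (symbol, pathway) assignments; a symbol may appear under several
#' pathways, and symbols with no assignment simply do not appear.
#'
#' @param path path to a tab-separated file with columns `symbol`, `pathway`.
#' @return data frame with `symbol`, `pathway`.
#' @export
read_pathway_table <- function(path) {
  pw <- read_tsv_table(path)
  missing <- setdiff(c("symbol", "pathway"), names(pw))
  if (length(missing) > 0L) {
    erad_schema_error(paste0("pathway table is missing column(s): ",
                             paste(missing, collapse = ", ")))
  }
  pw$symbol <- as.character(pw$symbol)
  pw$pathway <- as.character(pw$pathway)
  pw
}

#' Read any pipeline TSV table
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) erad_schema_error(paste0("file not found: ", path))
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write a pipeline table as TSV
#' @param x data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# Split a ";"-joined localization field into a character vector.
split_localizations <- function(x) strsplit(x, ";", fixed = TRUE)
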