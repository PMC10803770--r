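# End-to-end orchestration: features -> labels -> model -> cutoff ->
# cascade -> consensus -> RNA exclusion, with optional TSV/manifest output.

#' Default pipeline configuration
#'
#' @return named list of tunable parameters: `known_positives` (gene
#'   symbols treated as training positives), `default_cutoff` and
#'   `anchor_psm` (score-cutoff search), `reference_proteins` (enrichment
#'   ratio), `min_experiments` (consensus), `rna_filter`, `alpha`,
#'   `min_log2fc` (transcriptional exclusion), `learning_rate`,
#'   `max_iter`, `tol` (model fit).
#' @export
pipeline_config <- function() {
  list(known_positives = NULL,
       default_cutoff = 0.5,
       anchor_psm = 2L,
       reference_proteins = c("SEL1L", "OS9"),
       min_experiments = 2L,
       rna_filter = TRUE,
       alpha = 0.05,
       min_log2fc = 1,
       learning_rate = 0.05,
       max_iter = 5000L,
       tol = 1e-8)
}

#' Run the full substrate-discovery pipeline
#'
#' Completes the PSM table (absence = 0), computes per-experiment
#' enrichment features and per-protein mean features, derives training
#' labels, fits the logistic confidence model, scores every (protein,
#' experiment), selects the score cutoff from exclusive HRD1-KO anchors,
#' computes per-experiment reference ratios, applies the filter cascade,
#' calls candidates by replicate consensus with Group A/B assignment, and
#' (when enabled) removes transcriptionally upregulated candidates using
#' the DE table. The run is fully deterministic given its inputs.
#'
#' @param psm PSM table.
#' @param annot annotation table.
#' @param de differential-expression table; required when
#'   `config$rna_filter` is `TRUE`.
#' @param config list as from [pipeline_config()]; entries you supply
#'   override the defaults. `known_positives` must be set.
#' @param out_dir optional directory; when given, all result tables, a log
#'   and a JSON manifest are written there.
#' @return list with `interactors`, `features`, `labels`, `model`,
#'   `scores` (per experiment), `mean_scores`, `cutoff`, `ref_ratios`,
#'   `verdicts`, `calls`, and `config`.
#' @export
run_pipeline <- function(psm, annot, de = NULL, config = list(),
                         out_dir = NULL) {
  cfg <- utils::modifyList(pipeline_config(), config)
  if (is.null(cfg$known_positives) || length(cfg$known_positives) == 0L) {
    erad_config_error("config$known_positives must list known substrate gene symbols")
  }
  if (isTRUE(cfg$rna_filter) && is.null(de)) {
    erad_config_error("rna_filter is enabled but no DE table was supplied")
  }
  psm <- complete_psm_table(psm)
  annot <- validate_annotation_table(annot)

  interactors <- select_interactors(psm, annot)

  features <- compute_features(psm)
  mf <- mean_features(features)
  labels <- derive_labels(annot, cfg$known_positives)

  i <- match(mf$protein_id, labels$protein_id)
  model <- fit_confidence_model(mf$x1, mf$x2, labels$label[i],
                                learning_rate = cfg$learning_rate,
                                max_iter = cfg$max_iter, tol = cfg$tol)

  scores <- data.frame(protein_id = features$protein_id,
                       experiment_id = features$experiment_id,
                       score = score_confidence(model, features$x1, features$x2),
                       stringsAsFactors = FALSE)
  mean_scores <- data.frame(protein_id = mf$protein_id,
                            score = score_confidence(model, mf$x1, mf$x2),
                            stringsAsFactors = FALSE)

  cutoff <- select_cutoff(mean_scores, psm,
                          default_cutoff = cfg$default_cutoff,
                          anchor_psm = cfg$anchor_psm)
  ref_ratios <- reference_ratio(psm, NULL, cfg$reference_proteins)

  verdicts <- apply_filter_cascade(psm, annot, scores, cutoff, ref_ratios)
  calls <- call_candidates(verdicts, psm, scores,
                           min_experiments = cfg$min_experiments)
  if (isTRUE(cfg$rna_filter)) {
    calls <- rna_exclusion(calls, de, annot, alpha = cfg$alpha,
                           min_log2fc = cfg$min_log2fc)
  }

  result <- list(interactors = interactors, features = features,
                 labels = labels, model = model, scores = scores,
                 mean_scores = mean_scores, cutoff = cutoff,
                 ref_ratios = ref_ratios, verdicts = verdicts,
                 calls = calls, config = cfg)
  if (!is.null(out_dir)) write_run_dir(result, psm, out_dir)
  result
}

# Serialize a pipeline run: candidate/verdict/score/interactor TSVs, a
# model JSON, a plain-text log, and a manifest with a config hash so a run
# directory is self-describing.
write_run_dir <- function(result, psm, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_table(result$interactors, file.path(out_dir, "interactors.tsv"))
  write_tsv_table(result$scores, file.path(out_dir, "scores.tsv"))
  write_tsv_table(result$verdicts, file.path(out_dir, "verdicts.tsv"))
  write_tsv_table(result$calls, file.path(out_dir, "candidates.tsv"))
  final <- result$calls[result$calls$final_candidate, , drop = FALSE]
  write_tsv_table(final, file.path(out_dir, "final_candidates.tsv"))

  model_json <- list(weights = as.list(result$model$weights),
                     achieved_mcc = result$model$achieved_mcc,
                     n_pos = result$model$n_pos, n_neg = result$model$n_neg,
                     iterations = result$model$iterations,
                     cutoff = as.numeric(result$cutoff))
  jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- result$config
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "eradscreen",
    version = as.character(utils::packageVersion("eradscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_proteins = length(unique(psm$protein_id)),
    n_experiments = length(unique(psm$experiment_id)),
    config = cfg,
    config_hash = config_hash(cfg_json)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(
    sprintf("proteins: %d; experiments: %d",
            manifest$n_proteins, manifest$n_experiments),
    sprintf("training: %d positive, %d negative; hard MCC %.4f",
            result$model$n_pos, result$model$n_neg,
            result$model$achieved_mcc),
    sprintf("score cutoff: %.6f (%d anchor proteins)",
            as.numeric(result$cutoff),
            length(attr(result$cutoff, "anchors"))),
    sprintf("final candidates: %d (Group A %d, Group B %d; RNA-excluded %d)",
            sum(result$calls$final_candidate),
            sum(result$calls$group == "A"), sum(result$calls$group == "B"),
            sum(result$calls$rna_excluded))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

# Stable content hash of the serialized config (no external digest
# dependency): md5 of the JSON bytes via a temp file.
config_hash <- function(json) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}
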