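# Cross-cell-type cataloging: ortholog harmonization with MHC-I grouping,
# shared vs cell-type-specific classification, and pathway
# overrepresentation by normalized group counts.

MHC_TOKEN <- "MHC-I"

is_mhc_symbol <- function(symbols) {
  grepl("^(HLA-|H2-)", symbols, ignore.case = TRUE)
}

#' Harmonize candidate gene symbols across species
#'
#' Mouse symbols are converted to human ortholog symbols via a supplied
#' map (e.g. from the Alliance of Genome Resources homology report);
#' unmapped symbols are dropped with a warning and recorded in the
#' `unmapped` attribute. Class-I MHC heavy-chain genes (human `HLA-*`,
#' mouse `H2-*`, case-insensitive) cannot be put in one-to-one orthology
#' and are collapsed to the single token `MHC-I`, counted once per cell
#' type; the number of symbols collapsed is recorded in the
#' `mhc_raw_count` attribute for downstream raw-count substitution.
#'
#' @param symbols candidate gene symbols of one cell type.
#' @param species `"human"` or `"mouse"`.
#' @param ortholog_map data frame `mouse_symbol`, `human_symbol`; required
#'   for mouse input.
#' @return unique harmonized symbol vector with attributes `unmapped` and
#'   `mhc_raw_count`.
#' @export
harmonize_symbols <- function(symbols, species = c("human", "mouse"),
                              ortholog_map = NULL) {
  species <- match.arg(species)
  symbols <- unique(as.character(symbols))
  mhc <- is_mhc_symbol(symbols)
  unmapped <- character(0)
  out <- symbols
  if (species == "mouse") {
    if (is.null(ortholog_map) || nrow(ortholog_map) == 0L) {
      erad_config_error("mouse symbols require a non-empty ortholog map")
    }
    # case-normalized lookup; MHC symbols bypass orthology entirely
    i <- match(toupper(symbols), toupper(ortholog_map$mouse_symbol))
    out <- ortholog_map$human_symbol[i]
    unmapped <- symbols[is.na(i) & !mhc]
    if (length(unmapped) > 0L) {
      warning(length(unmapped), " mouse symbol(s) without human ortholog ",
              "were dropped", call. = FALSE)
    }
    keep <- !is.na(i) | mhc
    out[mhc] <- MHC_TOKEN
    out <- out[keep]
  } else {
    out[mhc] <- MHC_TOKEN
  }
  out <- unique(out)
  structure(out, unmapped = unmapped, mhc_raw_count = sum(mhc))
}

#' Classify candidates as shared or cell-type-specific
#'
#' @param set1,set2 harmonized symbol vectors for the two cell types.
#' @param names labels for the two cell types.
#' @return an `erad_catalog` list: `shared`, `specific` (named list),
#'   `counts`, `shared_pct` (per cell type, nearest integer),
#'   `specific_pct_overall`, `total` (size of the union).
#' @export
classify_shared <- function(set1, set2,
                            names = c("celltype1", "celltype2")) {
  set1 <- unique(as.character(set1)); set2 <- unique(as.character(set2))
  shared <- sort(intersect(set1, set2))
  spec1 <- sort(setdiff(set1, set2)); spec2 <- sort(setdiff(set2, set1))
  n_sh <- length(shared)
  shared_pct <- c(round(100 * n_sh / max(n_sh + length(spec1), 1)),
                  round(100 * n_sh / max(n_sh + length(spec2), 1)))
  names(shared_pct) <- names
  total <- n_sh + length(spec1) + length(spec2)
  specific <- stats::setNames(list(spec1, spec2), names)
  structure(list(shared = shared, specific = specific,
                 counts = stats::setNames(
                   c(n_sh, length(spec1), length(spec2)),
                   c("shared", paste0(names, "_specific"))),
                 shared_pct = shared_pct,
                 specific_pct_overall =
                   round(100 * (length(spec1) + length(spec2)) / max(total, 1)),
                 total = total),
            class = "erad_catalog")
}

#' @export
print.erad_catalog <- function(x, ...) {
  nm <- names(x$specific)
  cat(sprintf("Comparative catalog: %d hits total\n", x$total))
  cat(sprintf("  shared: %d (%d%% of %s, %d%% of %s)\n",
              x$counts[["shared"]], x$shared_pct[[1]], nm[1],
              x$shared_pct[[2]], nm[2]))
  cat(sprintf("  %s-specific: %d; %s-specific: %d (%d%% specific overall)\n",
              nm[1], length(x$specific[[1]]), nm[2], length(x$specific[[2]]),
              x$specific_pct_overall))
  invisible(x)
}

#' Pathway overrepresentation by normalized group counts
#'
#' For each pathway, the number of catalogued hits in the shared and the
#' two cell-type-specific groups is normalized to the total number of hits
#' in that group. A pathway is called overrepresented in a group when that
#' group's normalized count exceeds 50% of the sum of the three normalized
#' counts; otherwise it is shared across groups. At most one group can
#' exceed half the sum, so verdicts are unique. A group with zero
#' catalogued hits contributes zero and cannot be called enriched. For the
#' collapsed `MHC-I` token in the shared group, the larger of the actual
#' per-cell-type MHC hit counts is substituted for the single token before
#' normalization (`mhc_common_count`).
#'
#' @param assignments data frame `symbol`, `pathway` (a symbol may carry
#'   several pathways).
#' @param catalog an `erad_catalog` from [classify_shared()].
#' @param mhc_common_count raw MHC hit count to substitute for the `MHC-I`
#'   token in the shared group; `NULL` keeps the token's count of 1.
#' @return data frame per pathway: counts, normalized counts
#'   (`norm_shared`, `norm_specific1`, `norm_specific2`), ternary
#'   coordinates (`tern_*`, normalized to sum to 1), and `verdict`.
#' @export
pathway_overrepresentation <- function(assignments, catalog,
                                       mhc_common_count = NULL) {
  stopifnot(inherits(catalog, "erad_catalog"))
  groups <- list(shared = catalog$shared,
                 specific1 = catalog$specific[[1]],
                 specific2 = catalog$specific[[2]])
  totals <- vapply(groups, length, integer(1))
  pathways <- sort(unique(assignments$pathway))

  count_in <- function(members, pw) {
    syms <- assignments$symbol[assignments$pathway == pw]
    n <- sum(members %in% syms)
    n
  }
  counts <- sapply(pathways, function(pw) {
    n <- vapply(groups, count_in, numeric(1), pw = pw)
    if (!is.null(mhc_common_count) && MHC_TOKEN %in% catalog$shared &&
        MHC_TOKEN %in% assignments$symbol[assignments$pathway == pw]) {
      n[["shared"]] <- n[["shared"]] - 1 + mhc_common_count
    }
    n
  })
  counts <- if (length(pathways)) t(counts) else
    matrix(numeric(0), 0, 3, dimnames = list(NULL, names(groups)))

  norm <- sweep(counts, 2, pmax(totals, 1), "/")
  norm[, totals == 0] <- 0
  sums <- rowSums(norm)
  verdict <- rep("shared_across_groups", length(pathways))
  lab <- c(shared = "enriched_in_shared",
           specific1 = paste0("enriched_in_", names(catalog$specific)[1]),
           specific2 = paste0("enriched_in_", names(catalog$specific)[2]))
  for (g in seq_along(groups)) {
    hit <- sums > 0 & norm[, g] > 0.5 * sums & totals[g] > 0
    verdict[hit] <- lab[[g]]
  }
  tern <- norm / ifelse(sums == 0, 1, sums)
  out <- data.frame(pathway = pathways,
                    count_shared = counts[, 1], count_specific1 = counts[, 2],
                    count_specific2 = counts[, 3],
                    norm_shared = norm[, 1], norm_specific1 = norm[, 2],
                    norm_specific2 = norm[, 3],
                    tern_shared = tern[, 1], tern_specific1 = tern[, 2],
                    tern_specific2 = tern[, 3],
                    verdict = verdict, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
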