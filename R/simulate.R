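# Seeded synthetic IP-MS screens with planted ground truth.
#
# The simulator emulates the structure of a four-genotype anti-SEL1L
# pulldown screen: replicate experiments, non-negative integer PSM counts
# per genotype column, bait/machinery proteins always present, keratin
# contaminants, true substrates enriched only in the HRD1-KO column, and
# transcriptional decoys whose enrichment is mirrored by an mRNA increase.
# Counts are negative-binomial: PSM counts are overdispersed integers, and
# the NB covers the Poisson as dispersion grows.

SIM_ROLES <- c("substrate", "machinery", "contaminant",
               "transcriptional_decoy", "background")

default_mean_psm <- function() {
  # rows: role; cols: genotype means of the NB count model (per experiment).
  # Substrates/decoys: strong HRD1-KO enrichment over low WT/SEL1L-KO/IgG.
  # Contaminants: flat across all columns including IgG (non-specific).
  # Background: weak non-specific binders. Machinery: co-purifies with the
  # bait in WT and HRD1-KO, absent without the bait (SEL1L-KO) or in IgG.
  m <- rbind(
    substrate             = c(igg = 0.2, sko = 1.0, wt = 2.0,  hko = 20),
    transcriptional_decoy = c(igg = 0.2, sko = 1.0, wt = 2.0,  hko = 20),
    contaminant           = c(igg = 15,  sko = 15,  wt = 15,   hko = 15),
    background            = c(igg = 0.3, sko = 0.3, wt = 0.3,  hko = 0.5),
    machinery             = c(igg = 0.5, sko = 0.5, wt = 30,   hko = 30)
  )
  m
}

# Fixed counts for the bait and its obligate partners. Emitted
# deterministically so the reference-ratio filter (SEL1L/OS9 HRD1-KO:WT
# ratio) is always computable. SEL1L cannot appear in its own knockout
# pulldown and HRD1 cannot appear in the HRD1-KO pulldown.
BAIT_COUNTS <- list(
  SEL1L = c(igg = 0, sko = 0, wt = 50, hko = 75),
  HRD1  = c(igg = 0, sko = 0, wt = 45, hko = 0),
  OS9   = c(igg = 0, sko = 0, wt = 40, hko = 60)
)

#' Simulation configuration for a synthetic SEL1L IP-MS screen
#'
#' @param n_proteins number of simulated proteins (baits SEL1L/HRD1/OS9 are
#'   included in this total).
#' @param n_experiments number of replicate pulldown experiments (>= 2).
#' @param role_fractions named fractions over
#'   `substrate`, `machinery`, `contaminant`, `transcriptional_decoy`,
#'   `background`; must sum to 1.
#' @param mean_psm role-by-genotype matrix of negative-binomial means
#'   (columns `igg`, `sko`, `wt`, `hko`); see `default_mean_psm` in the
#'   source for the defaults and their rationale.
#' @param dispersion negative-binomial size parameter; larger means closer
#'   to Poisson.
#' @param de_effect_log2fc minimum mRNA log2 fold change (HRD1-KO vs WT)
#'   planted for transcriptional decoys.
#' @param known_positive_fraction fraction of planted substrates treated as
#'   literature-known ERAD substrates (training positives).
#' @param species `"human"` or `"mouse"`; controls gene-symbol style
#'   (keratins `KRT*`/`Krt*`, MHC-I `HLA-*`/`H2-*`).
#' @param seed integer RNG seed; identical configurations (including seed)
#'   reproduce byte-identical tables.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_experiments = 3,
                       role_fractions = c(background = 0.80,
                                          substrate = 0.08,
                                          contaminant = 0.05,
                                          transcriptional_decoy = 0.04,
                                          machinery = 0.03),
                       mean_psm = default_mean_psm(),
                       dispersion = 8,
                       de_effect_log2fc = 2.5,
                       known_positive_fraction = 0.25,
                       species = c("human", "mouse"),
                       seed = 1L) {
  species <- match.arg(species)
  if (length(n_proteins) != 1L || n_proteins < 10 || n_proteins != floor(n_proteins)) {
    erad_config_error("n_proteins must be a single integer >= 10")
  }
  if (length(n_experiments) != 1L || n_experiments < 2 ||
      n_experiments != floor(n_experiments)) {
    erad_config_error("n_experiments must be an integer >= 2")
  }
  if (!setequal(names(role_fractions), SIM_ROLES)) {
    erad_config_error(paste0("role_fractions must name exactly: ",
                             paste(SIM_ROLES, collapse = ", ")))
  }
  if (abs(sum(role_fractions) - 1) > 1e-9 || any(role_fractions < 0)) {
    erad_config_error("role_fractions must be non-negative and sum to 1")
  }
  if (!setequal(rownames(mean_psm), SIM_ROLES) ||
      !setequal(colnames(mean_psm), names(GENOTYPES))) {
    erad_config_error("mean_psm must be a role x genotype (igg/sko/wt/hko) matrix")
  }
  if (any(mean_psm < 0)) erad_config_error("mean_psm means must be >= 0")
  if (length(dispersion) != 1L || dispersion <= 0) {
    erad_config_error("dispersion must be a positive real")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_experiments = as.integer(n_experiments),
                 role_fractions = role_fractions[SIM_ROLES],
                 mean_psm = mean_psm[SIM_ROLES, names(GENOTYPES), drop = FALSE],
                 dispersion = dispersion,
                 de_effect_log2fc = de_effect_log2fc,
                 known_positive_fraction = known_positive_fraction,
                 species = species,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic role assignment honouring the configured fractions exactly
# (largest-remainder apportionment), with the three baits always present.
assign_roles <- function(config) {
  n_free <- config$n_proteins - 3L  # baits occupy three machinery slots
  quota <- config$role_fractions * config$n_proteins
  quota["machinery"] <- max(quota["machinery"] - 3, 0)
  base <- floor(quota)
  rem <- quota - base
  short <- n_free - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  } else if (short < 0) {
    drop_from <- order(rem)[seq_len(-short)]
    base[drop_from] <- pmax(base[drop_from] - 1, 0)
  }
  rep(names(base), times = base)
}

sim_symbols <- function(roles, species) {
  n <- length(roles)
  idx <- stats::ave(seq_len(n), roles, FUN = seq_along)
  prefix <- c(substrate = "SUB", machinery = "MCH", contaminant = "KRT",
              transcriptional_decoy = "TDE", background = "BGD")
  sym <- sprintf("%s%04d", prefix[roles], idx)
  if (species == "mouse") {
    # mouse-style capitalisation (Krt..., Sub...); flags stay authoritative
    sym <- paste0(substr(sym, 1, 1), tolower(substr(sym, 2, nchar(sym))))
  }
  sym
}

#' Generate a synthetic IP-MS screen with planted ground truth
#'
#' Draws per-(protein, experiment, genotype) PSM counts from a negative
#' binomial with role- and genotype-specific means, emits bait proteins
#' (SEL1L, HRD1, OS9) deterministically with genotype-consistent counts,
#' plants keratin-family contaminants, HRD1-KO-enriched substrates,
#' transcriptional decoys with matching upregulated mRNA, and weak
#' non-specific background. Annotation features for substrate-like proteins
#' match prevalences typical of ERAD substrate sets (roughly 60%
#' transmembrane, 70% glycosylated, 30% with disulfide bonds).
#'
#' @param config a [sim_config()].
#' @return list with elements `psm` (PSM table), `annotation`, `de`
#'   (differential expression, HRD1KO_vs_WT), `truth` (protein roles), and
#'   `known_positives` (gene symbols usable as training positives).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  roles <- assign_roles(config)
  symbols <- sim_symbols(roles, config$species)
  # baits appended last so free-protein draws are unaffected by their presence
  bait_names <- names(BAIT_COUNTS)
  if (config$species == "mouse") {
    bait_display <- c(SEL1L = "Sel1l", HRD1 = "Hrd1", OS9 = "Os9")
  } else {
    bait_display <- c(SEL1L = "SEL1L", HRD1 = "HRD1", OS9 = "OS9")
  }

  n_free <- length(roles)
  expts <- sprintf("expt%d", seq_len(config$n_experiments))

  # --- PSM counts -----------------------------------------------------------
  mu <- config$mean_psm[roles, , drop = FALSE]
  draw <- function(genotype) {
    m <- rep(mu[, genotype], times = config$n_experiments)
    stats::rnbinom(length(m), size = config$dispersion, mu = m)
  }
  psm <- data.frame(
    protein_id = rep(symbols, times = config$n_experiments),
    experiment_id = rep(expts, each = n_free),
    psm_igg = draw("igg"), psm_sko = draw("sko"),
    psm_wt = draw("wt"), psm_hko = draw("hko"),
    stringsAsFactors = FALSE
  )
  bait_psm <- do.call(rbind, lapply(bait_names, function(b) {
    data.frame(protein_id = bait_display[[b]], experiment_id = expts,
               psm_igg = BAIT_COUNTS[[b]][["igg"]],
               psm_sko = BAIT_COUNTS[[b]][["sko"]],
               psm_wt = BAIT_COUNTS[[b]][["wt"]],
               psm_hko = BAIT_COUNTS[[b]][["hko"]],
               stringsAsFactors = FALSE)
  }))
  psm <- rbind(psm, bait_psm)
  psm <- psm[order(psm$protein_id, psm$experiment_id), , drop = FALSE]
  rownames(psm) <- NULL
  psm <- validate_psm_table(psm)

  # --- annotations ----------------------------------------------------------
  annot <- sim_annotations(roles, symbols, config$species)
  bait_annot <- data.frame(
    protein_id = unname(bait_display), gene_symbol = unname(bait_display),
    species = config$species,
    localizations = c("ER;membrane", "ER;membrane", "ER"),
    has_signal_peptide = c(TRUE, FALSE, TRUE),
    n_glycosylation_sites = c(5L, 0L, 1L),
    has_disulfide = c(TRUE, FALSE, TRUE),
    n_tm_domains = c(1L, 6L, 0L),
    is_keratin_family = FALSE,
    stringsAsFactors = FALSE
  )
  annot <- validate_annotation_table(rbind(annot, bait_annot))

  # --- differential expression ---------------------------------------------
  all_syms <- annot$gene_symbol
  is_decoy <- all_syms %in% symbols[roles == "transcriptional_decoy"]
  log2fc <- stats::rnorm(length(all_syms), mean = 0, sd = 0.3)
  padj <- stats::runif(length(all_syms))
  log2fc[is_decoy] <- config$de_effect_log2fc +
    abs(stats::rnorm(sum(is_decoy), 0, 0.25))
  padj[is_decoy] <- 10^(-stats::runif(sum(is_decoy), 4, 8))
  de <- validate_de_table(data.frame(
    gene_symbol = all_syms, contrast = "HRD1KO_vs_WT",
    log2fc = log2fc, padj = padj, stringsAsFactors = FALSE
  ))

  # --- truth and known positives -------------------------------------------
  truth <- data.frame(
    protein_id = c(symbols, unname(bait_display)),
    role = c(roles, rep("machinery", 3L)),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$protein_id), , drop = FALSE]
  rownames(truth) <- NULL
  sub_syms <- symbols[roles == "substrate"]
  n_known <- round(config$known_positive_fraction * length(sub_syms))
  known <- character(0)
  if (n_known > 0) known <- sort(sample(sub_syms, n_known))
  known_positives <- c(known, bait_display[["OS9"]])

  list(psm = psm, annotation = annot, de = de, truth = truth,
       known_positives = known_positives, config = config)
}

sim_annotations <- function(roles, symbols, species) {
  n <- length(roles)
  sp <- logical(n); glyc <- integer(n); dis <- logical(n); tm <- integer(n)
  loc <- character(n)
  substrate_like <- roles %in% c("substrate", "transcriptional_decoy")
  k <- sum(substrate_like)
  if (k > 0) {
    # feature prevalences typical of secretory-pathway ERAD clients
    tm[substrate_like] <- ifelse(stats::runif(k) < 0.60,
                                 1L + stats::rpois(k, 1), 0L)
    glyc[substrate_like] <- ifelse(stats::runif(k) < 0.70,
                                   1L + stats::rpois(k, 2), 0L)
    dis[substrate_like] <- stats::runif(k) < 0.30
    sp[substrate_like] <- stats::runif(k) < 0.70
    loc[substrate_like] <- sample(c("ER", "ER;membrane", "membrane", "Golgi"),
                                  k, replace = TRUE,
                                  prob = c(0.35, 0.35, 0.2, 0.1))
  }
  mach <- roles == "machinery"
  if (any(mach)) {
    m <- sum(mach)
    sp[mach] <- TRUE
    glyc[mach] <- stats::rpois(m, 1)
    dis[mach] <- stats::runif(m) < 0.5
    tm[mach] <- ifelse(stats::runif(m) < 0.5, 1L, 0L)
    loc[mach] <- "ER"
  }
  contam <- roles == "contaminant"
  loc[contam] <- "cytosol"
  bg <- roles == "background"
  if (any(bg)) {
    loc[bg] <- sample(c("cytosol", "nucleus", "mitochondrion"),
                      sum(bg), replace = TRUE, prob = c(0.4, 0.4, 0.2))
  }
  data.frame(protein_id = symbols, gene_symbol = symbols, species = species,
             localizations = loc, has_signal_peptide = sp,
             n_glycosylation_sites = glyc, has_disulfide = dis,
             n_tm_domains = tm, is_keratin_family = contam,
             stringsAsFactors = FALSE)
}

#' Confusion counts of substrate calls against planted truth
#'
#' @param called_ids protein ids called as final substrate candidates.
#' @param truth truth table from [generate_dataset()] (`protein_id`, `role`).
#' @return list with integer `tp`, `fp`, `tn`, `fn` (positives are planted
#'   substrates).
#' @export
truth_confusion <- function(called_ids, truth) {
  called_ids <- unique(as.character(called_ids))
  unknown <- setdiff(called_ids, truth$protein_id)
  if (length(unknown) > 0L) {
    erad_reference_error(paste0("called protein(s) absent from truth: ",
                                paste(utils::head(unknown, 5), collapse = ", ")))
  }
  is_sub <- truth$role == "substrate"
  called <- truth$protein_id %in% called_ids
  list(tp = sum(called & is_sub), fp = sum(called & !is_sub),
       tn = sum(!called & !is_sub), fn = sum(!called & is_sub))
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' File fields mirror the [sim_config()] arguments; `role_fractions` is a
#' named mapping and `mean_psm` a nested mapping role -> genotype -> mean.
#' Omitted fields keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  if (!file.exists(path)) erad_schema_error(paste0("file not found: ", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$role_fractions)) {
    cfg$role_fractions <- unlist(cfg$role_fractions)
  }
  if (!is.null(cfg$mean_psm)) {
    rows <- lapply(cfg$mean_psm, function(r) unlist(r)[names(GENOTYPES)])
    m <- do.call(rbind, rows)
    rownames(m) <- names(cfg$mean_psm)
    cfg$mean_psm <- m
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    erad_config_error(paste0("unknown configuration field(s): ",
                             paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, cfg)
}
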