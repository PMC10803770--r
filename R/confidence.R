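# Logistic confidence score for substrate vs non-substrate, fitted by
# gradient ascent on a smooth Matthews-correlation surrogate.
#
# The score for one protein in one experiment is
#   y = 1 / (1 + exp(-(w0 + w1*x1 + w2*x2)))
# with enrichment features
#   x1 = hko / max(wt, igg, 1)    (HRD1-KO vs wild type / IgG)
#   x2 = hko / max(sko, igg, 1)   (HRD1-KO vs SEL1L-KO / IgG)
# Denominators are floored at 1: PSM counts are integers, and absence from
# both control columns is maximal enrichment, which must stay finite.

#' Compute PSM enrichment features
#'
#' @param psm PSM table.
#' @return data frame `protein_id`, `experiment_id`, `psm_hko`, `x1`, `x2`.
#'   Features are always finite and non-negative; scaling all four counts of
#'   a row by a positive integer leaves them unchanged while the floored
#'   denominators stay above 1.
#' @export
compute_features <- function(psm) {
  psm <- validate_psm_table(psm)
  data.frame(protein_id = psm$protein_id, experiment_id = psm$experiment_id,
             psm_hko = psm$psm_hko,
             x1 = psm$psm_hko / pmax(psm$psm_wt, psm$psm_igg, 1),
             x2 = psm$psm_hko / pmax(psm$psm_sko, psm$psm_igg, 1),
             stringsAsFactors = FALSE)
}

#' Aggregate per-experiment features to one vector per protein
#'
#' Training and ranking use one feature vector per protein: the mean of the
#' per-experiment features over experiments in which the protein was
#' detected in the HRD1-KO pulldown (`hko > 0`). Proteins never detected in
#' HRD1-KO get `NA` features (they can never be candidates anyway).
#'
#' @param features output of [compute_features()].
#' @return data frame `protein_id`, `x1`, `x2`, `n_detected`.
#' @export
mean_features <- function(features) {
  det <- features[features$psm_hko > 0, , drop = FALSE]
  proteins <- sort(unique(features$protein_id))
  x1 <- tapply(det$x1, det$protein_id, mean)
  x2 <- tapply(det$x2, det$protein_id, mean)
  n <- tapply(det$psm_hko, det$protein_id, length)
  out <- data.frame(protein_id = proteins,
                    x1 = unname(x1[proteins]), x2 = unname(x2[proteins]),
                    n_detected = as.integer(ifelse(is.na(n[proteins]), 0L,
                                                   n[proteins])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Derive training labels from annotations and known substrates
#'
#' Positives are proteins whose gene symbol appears in a curated list of
#' known ERAD substrates (e.g. SIGMAR1, HLA class I, OS9). Negatives are
#' proteins that carry none of the hallmarks of a secretory-pathway client
#' (no signal peptide, no transmembrane domain, no N-glycosylation, no
#' disulfide bonds) or are not localized to ER, Golgi, lysosome or
#' membrane. Everything else is unlabeled.
#'
#' @param annot annotation table.
#' @param known_positives character vector of gene symbols.
#' @return data frame `protein_id`, `gene_symbol`, `label`
#'   (positive/negative/unlabeled), `source`.
#' @export
derive_labels <- function(annot, known_positives) {
  annot <- validate_annotation_table(annot)
  if (length(known_positives) == 0L) {
    erad_training_error("known_positives must be non-empty")
  }
  loc <- split_localizations(annot$localizations)
  secretory <- vapply(loc, function(l)
    any(l %in% c("ER", "Golgi", "lysosome", "membrane")), logical(1))
  featureless <- !annot$has_signal_peptide & annot$n_tm_domains == 0L &
    annot$n_glycosylation_sites == 0L & !annot$has_disulfide
  pos <- annot$gene_symbol %in% known_positives
  neg <- !pos & (featureless | !secretory)
  label <- ifelse(pos, "positive", ifelse(neg, "negative", "unlabeled"))
  source <- ifelse(pos, "known substrate",
                   ifelse(neg, "no client hallmark or non-secretory", ""))
  data.frame(protein_id = annot$protein_id, gene_symbol = annot$gene_symbol,
             label = label, source = source, stringsAsFactors = FALSE)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), ranging over
#' \[-1, 1\]; by convention 0 when any factor of the denominator is zero.
#'
#' @param tp,tn,fp,fn non-negative counts (vectorised).
#' @return numeric MCC.
#' @export
mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  if (any(c(tp, tn, fp, fn) < 0)) erad_value_error("confusion counts must be >= 0")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  num <- tp * tn - fp * fn
  ifelse(denom == 0, 0, num / denom)
}

#' Logistic confidence score
#'
#' @param model a fitted model from [fit_confidence_model()] or a numeric
#'   weight vector `c(w0, w1, w2)`.
#' @param x1,x2 feature vectors.
#' @return scores in (0, 1); overflow-safe via [stats::plogis()].
#' @export
score_confidence <- function(model, x1, x2) {
  w <- if (inherits(model, "erad_confidence_model")) model$weights else model
  stats::plogis(w[[1]] + w[[2]] * x1 + w[[3]] * x2)
}

# Soft confusion counts: replacing indicator predictions with predicted
# probabilities makes MCC smooth in the weights. Since TP+FN = n_pos and
# TN+FP = n_neg are fixed, the surrogate reduces to a function of
# (soft TP, soft FP) only.
soft_mcc <- function(tp_soft, fp_soft, n_pos, n_neg) {
  s <- tp_soft + fp_soft
  t <- n_pos + n_neg
  d2 <- n_pos * n_neg * s * (t - s)
  if (d2 <= 0) return(0)
  (tp_soft * n_neg - fp_soft * n_pos) / sqrt(d2)
}

# Exact hard-MCC intercept search for a fixed linear score s = w1*x1 +
# w2*x2: with predictions "s + w0 >= 0", only the n+1 threshold positions
# between sorted score values matter, and all of them are evaluated by
# cumulative sums. Returns the best intercept and its hard MCC.
best_intercept <- function(s, pos) {
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  pos_sorted <- pos[ord]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tp <- c(0, cumsum(pos_sorted))        # predict positive for top k scores
  fp <- c(0, cumsum(!pos_sorted))
  m <- mcc(tp, n_neg - fp, fp, n_pos - tp)
  # thresholds: above the max, between distinct values, below the min
  cuts <- c(s_sorted[1] + 1,
            (s_sorted[-1] + s_sorted[-length(s_sorted)]) / 2,
            s_sorted[length(s_sorted)] - 1)
  valid <- c(TRUE, s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  m[!valid] <- -Inf
  k <- which.max(m)
  list(w0 = -cuts[k], mcc = m[k])
}

hard_mcc <- function(w, x1, x2, pos) {
  pred <- (w[1] + w[2] * x1 + w[3] * x2) >= 0
  mcc(sum(pred & pos), sum(!pred & !pos), sum(pred & !pos), sum(!pred & pos))
}

#' Fit the confidence model by maximizing the Matthews correlation
#'
#' The hard MCC of thresholded predictions is piecewise constant in the
#' weights, so the fit proceeds in two deterministic stages. First,
#' gradient ascent on a smooth MCC surrogate — confusion counts built from
#' predicted probabilities (soft TP = sum of scores over positives, soft
#' FP = sum over negatives) — from fixed starts, with an analytic gradient
#' and backtracking step halving. Second, an exact refinement of the
#' decision boundary in the two-dimensional feature plane: every boundary
#' orientation on a fine angular grid is paired with its exactly
#' MCC-optimal intercept (a threshold sweep), and the ascent solution
#' itself is intercept-calibrated the same way. The returned weights are
#' whichever candidate attains the highest hard MCC at probability
#' threshold 0.5 (never below the zero-weight model); score dispersion is
#' preserved by scaling refined directions to the ascent's weight norm.
#'
#' @param x1,x2 per-protein features (one value per labeled protein).
#' @param label character vector: `"positive"` / `"negative"` (other values
#'   are dropped).
#' @param learning_rate base step size of the ascent.
#' @param max_iter iteration budget per ascent start.
#' @param tol convergence tolerance on the surrogate increase.
#' @param n_angles resolution of the boundary-orientation scan.
#' @return an `erad_confidence_model`: `weights` (w0, w1, w2),
#'   `achieved_mcc` (hard, at threshold 0.5), `surrogate_mcc`, `n_pos`,
#'   `n_neg`, `iterations`, `converged`.
#' @export
fit_confidence_model <- function(x1, x2, label, learning_rate = 0.05,
                                 max_iter = 5000L, tol = 1e-8,
                                 n_angles = 360L) {
  keep <- label %in% c("positive", "negative")
  x1 <- x1[keep]; x2 <- x2[keep]; label <- label[keep]
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]; label <- label[ok]
  pos <- label == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    erad_training_error("need at least one positive and one negative labeled protein")
  }
  X <- cbind(1, x1, x2)
  t_tot <- n_pos + n_neg

  surrogate <- function(w) {
    y <- stats::plogis(drop(X %*% w))
    soft_mcc(sum(y[pos]), sum(y[!pos]), n_pos, n_neg)
  }
  gradient <- function(w) {
    y <- stats::plogis(drop(X %*% w))
    tp <- sum(y[pos]); fp <- sum(y[!pos])
    s <- tp + fp
    d2 <- n_pos * n_neg * s * (t_tot - s)
    if (d2 <= 0) return(rep(0, 3))
    d <- sqrt(d2)
    u <- tp * n_neg - fp * n_pos
    dd_ds <- n_pos * n_neg * (t_tot - 2 * s) / (2 * d)
    dm_dtp <- n_neg / d - u * dd_ds / d2
    dm_dfp <- -n_pos / d - u * dd_ds / d2
    gy <- y * (1 - y)
    g_tp <- colSums(X[pos, , drop = FALSE] * gy[pos])
    g_fp <- colSums(X[!pos, , drop = FALSE] * gy[!pos])
    dm_dtp * g_tp + dm_dfp * g_fp
  }
  ascend <- function(w) {
    m_cur <- surrogate(w)
    iterations <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- it
      g <- gradient(w)
      if (sqrt(sum(g^2)) < 1e-14) { converged <- TRUE; break }
      step <- learning_rate
      improved <- FALSE
      for (h in 1:40) {
        w_new <- w + step * g
        m_new <- surrogate(w_new)
        if (m_new > m_cur) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      gain <- m_new - m_cur
      w <- w_new
      m_cur <- m_new
      if (gain < tol) { converged <- TRUE; break }
    }
    list(w = w, m = m_cur, iterations = iterations, converged = converged)
  }

  # stage 1: surrogate ascent from fixed starts (zero plus the two
  # enrichment-aligned diagonals); best surrogate wins
  starts <- list(c(0, 0, 0), c(0, 1, 1), c(0, -1, -1))
  asc <- NULL
  iterations <- 0L
  for (w0 in starts) {
    a <- ascend(w0)
    iterations <- iterations + a$iterations
    if (is.null(asc) || a$m > asc$m + 1e-12) asc <- a
  }
  if (!asc$converged) {
    warning("confidence-model fit did not converge within ", max_iter,
            " iterations; using best iterate", call. = FALSE)
  }

  # stage 2: exact hard-MCC refinement of the decision boundary
  scale <- max(sqrt(sum(asc$w[2:3]^2)), 1)
  candidates <- list(asc$w)
  cal <- best_intercept(asc$w[2] * x1 + asc$w[3] * x2, pos)
  candidates <- c(candidates, list(c(cal$w0, asc$w[2], asc$w[3])))
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  for (th in theta) {
    d <- c(cos(th), sin(th)) * scale
    bi <- best_intercept(d[1] * x1 + d[2] * x2, pos)
    candidates <- c(candidates, list(c(bi$w0, d[1], d[2])))
  }
  hm <- vapply(candidates, hard_mcc, numeric(1), x1 = x1, x2 = x2, pos = pos)
  w <- candidates[[which.max(hm)]]

  structure(list(weights = c(w0 = w[[1]], w1 = w[[2]], w2 = w[[3]]),
                 achieved_mcc = max(hm), surrogate_mcc = asc$m,
                 n_pos = n_pos, n_neg = n_neg,
                 iterations = iterations, converged = asc$converged),
            class = "erad_confidence_model")
}

#' @export
print.erad_confidence_model <- function(x, ...) {
  cat("Logistic confidence model (soft-MCC gradient ascent)\n")
  cat(sprintf("  weights: w0 = %.4f, w1 = %.4f, w2 = %.4f\n",
              x$weights[[1]], x$weights[[2]], x$weights[[3]]))
  cat(sprintf("  hard MCC at 0.5: %.4f (surrogate %.4f)\n",
              x$achieved_mcc, x$surrogate_mcc))
  cat(sprintf("  training set: %d positive, %d negative; %d iterations%s\n",
              x$n_pos, x$n_neg, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Select the confidence-score cutoff from exclusive HRD1-KO hits
#'
#' The cutoff is anchored on marginal detections: proteins identified only
#' in the HRD1-KO pulldown with 2 PSMs — i.e. `psm_hko == 2` in at least
#' one experiment and `psm_wt`, `psm_sko`, `psm_igg` all zero in every
#' experiment. The cutoff is the lowest per-protein score among these
#' anchors; proteins scoring at or above it are score-eligible. When no
#' protein matches the anchor condition the configured default is used with
#' a warning.
#'
#' @param scores data frame `protein_id`, `score` (one score per protein,
#'   typically the mean over HRD1-KO-detected experiments).
#' @param psm PSM table.
#' @param default_cutoff fallback when no anchor protein exists.
#' @param anchor_psm PSM count defining a marginal exclusive detection.
#' @return numeric cutoff, with attribute `anchors` (anchor protein ids).
#' @export
select_cutoff <- function(scores, psm, default_cutoff = 0.5, anchor_psm = 2L) {
  psm <- validate_psm_table(psm)
  exclusive <- tapply(psm$psm_wt == 0 & psm$psm_sko == 0 & psm$psm_igg == 0,
                      psm$protein_id, all)
  has_anchor_count <- tapply(psm$psm_hko == anchor_psm, psm$protein_id, any)
  anchor_ids <- names(exclusive)[exclusive & has_anchor_count]
  anchor_scores <- scores$score[scores$protein_id %in% anchor_ids]
  anchor_scores <- anchor_scores[is.finite(anchor_scores)]
  if (length(anchor_scores) == 0L) {
    warning("no protein detected exclusively in HRD1-KO with ", anchor_psm,
            " PSMs; using default cutoff ", default_cutoff, call. = FALSE)
    return(structure(default_cutoff, anchors = character(0)))
  }
  structure(min(anchor_scores), anchors = anchor_ids)
}
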