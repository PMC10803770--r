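test_that("enrichment features follow the floored-denominator rule", {
  f <- compute_features(psm_row(igg = 1L, sko = 0L, wt = 2L, hko = 10L))
  expect_equal(f$x1, 5)   # 10 / max(2, 1, 1)
  expect_equal(f$x2, 10)  # 10 / max(0, 1, 1)

  zero_num <- compute_features(psm_row(igg = 3L, sko = 4L, wt = 5L, hko = 0L))
  expect_equal(c(zero_num$x1, zero_num$x2), c(0, 0))

  floored <- compute_features(psm_row(igg = 0L, sko = 0L, wt = 0L, hko = 4L))
  expect_equal(c(floored$x1, floored$x2), c(4, 4))
})

test_that("features are invariant to integer scaling above the floor", {
  base <- psm_row(igg = 2L, sko = 3L, wt = 4L, hko = 12L)
  f1 <- compute_features(base)
  for (k in c(2L, 5L, 11L)) {
    scaled <- base
    for (col in c("psm_igg", "psm_sko", "psm_wt", "psm_hko")) {
      scaled[[col]] <- scaled[[col]] * k
    }
    fk <- compute_features(scaled)
    expect_equal(c(fk$x1, fk$x2), c(f1$x1, f1$x2))
  }
})

test_that("mean features average only HRD1-KO-detected experiments", {
  psm <- psm_table(
    psm_row("A", "expt1", wt = 2L, hko = 10L),   # x1 = 5
    psm_row("A", "expt2", wt = 1L, hko = 1L),    # x1 = 1
    psm_row("A", "expt3", wt = 9L, hko = 0L),    # undetected, ignored
    psm_row("B", "expt1", wt = 9L, hko = 0L)     # never detected
  )
  mf <- mean_features(compute_features(psm))
  expect_equal(mf$x1[mf$protein_id == "A"], 3)
  expect_equal(mf$n_detected[mf$protein_id == "A"], 2L)
  expect_true(is.na(mf$x1[mf$protein_id == "B"]))
})

test_that("training labels implement the positive/negative/unlabeled rules", {
  annot <- annot_table(
    annot_row("OS9", localizations = "ER"),
    annot_row("CLIENT", localizations = "ER", signal_peptide = TRUE,
              n_glyc = 2L),
    annot_row("CYTO", localizations = "cytosol", signal_peptide = FALSE,
              n_glyc = 0L, disulfide = FALSE, n_tm = 0L),
    annot_row("ODDBALL", localizations = "cytosol", signal_peptide = FALSE,
              n_glyc = 1L, n_tm = 0L)  # non-secretory -> negative anyway
  )
  labels <- derive_labels(annot, known_positives = "OS9")
  lab <- function(id) labels$label[labels$protein_id == id]
  expect_equal(lab("OS9"), "positive")
  expect_equal(lab("CLIENT"), "unlabeled")
  expect_equal(lab("CYTO"), "negative")
  expect_equal(lab("ODDBALL"), "negative")
  expect_error(derive_labels(annot, character(0)),
               class = "erad_training_error")
})

test_that("MCC closed forms, zero convention and symmetry hold", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(0, 0, 5, 5), -1)
  expect_equal(mcc(1, 1, 1, 1), 0)
  expect_equal(mcc(0, 10, 0, 5), 0)  # zero denominator factor
  expect_error(mcc(-1, 0, 0, 0), class = "erad_value_error")

  set.seed(1)
  for (i in 1:25) {
    c4 <- sample(0:20, 4, replace = TRUE)
    m <- mcc(c4[1], c4[2], c4[3], c4[4])
    expect_gte(m, -1); expect_lte(m, 1)
    expect_equal(m, mcc(c4[2], c4[1], c4[4], c4[3]))  # class-swap symmetry
  }
})

test_that("the logistic score is bounded, symmetric and monotone", {
  expect_equal(score_confidence(c(0, 0, 0), 3, 7), 0.5)
  expect_equal(score_confidence(c(-1, 1, 1), 1, 0), 0.5)
  w <- c(0.3, 0.8, -0.2)
  x1 <- c(0, 1, 50); x2 <- c(2, 0, 10)
  expect_equal(score_confidence(w, x1, x2) + score_confidence(-w, x1, x2),
               rep(1, 3))
  # extreme features stay finite and inside [0, 1]
  s <- score_confidence(c(0, 10, 10), 1e6, 1e6)
  expect_true(is.finite(s) && s <= 1)
  # monotone in each feature under positive weights
  grid <- seq(0, 20, by = 2)
  s1 <- score_confidence(c(-1, 0.5, 0.2), grid, 1)
  expect_true(all(diff(s1) > 0))
})

test_that("linearly separable labels are fit to a perfect hard MCC", {
  x1 <- c(5, 6, 8, 12, 0.2, 0.5, 1, 0.8, 0.1)
  x2 <- c(4, 9, 7, 10, 0.3, 0.2, 0.9, 1, 0.4)
  label <- c(rep("positive", 4), rep("negative", 5))
  # the surrogate approaches 1 only as the weights diverge, so the
  # iteration budget is exhausted by design on separable data
  fit <- suppressWarnings(fit_confidence_model(x1, x2, label))
  expect_equal(fit$achieved_mcc, 1)
  expect_gte(fit$achieved_mcc, 0)  # never worse than the null weights
})

test_that("permuted labels leave only small-sample optimism, no real signal", {
  # the fit never scores below the zero-weight model, so its null value is
  # a non-negative optimism term: it must stay far below genuine signal
  # and shrink as the training set grows
  null_mean <- function(n, reps = 10) {
    set.seed(99)
    x1 <- rexp(n, 1 / 3); x2 <- rexp(n, 1 / 3)
    mean(replicate(reps, {
      label <- sample(c(rep("positive", n / 5), rep("negative", 4 * n / 5)))
      suppressWarnings(fit_confidence_model(x1, x2, label))$achieved_mcc
    }))
  }
  m200 <- null_mean(200, reps = 20)
  expect_gte(m200, 0)
  expect_lt(m200, 0.35)

  m800 <- null_mean(800)
  expect_lt(m800, m200)

  # genuine signal under the same conditions scores far higher
  set.seed(99)
  n <- 200
  pos <- c(rep(TRUE, 40), rep(FALSE, 160))
  x1 <- rexp(n, 1 / 3) + 8 * pos; x2 <- rexp(n, 1 / 3) + 8 * pos
  fit <- suppressWarnings(
    fit_confidence_model(x1, x2, ifelse(pos, "positive", "negative")))
  expect_gt(fit$achieved_mcc, m200 + 0.5)
})

test_that("single-class training sets raise a training error", {
  expect_error(fit_confidence_model(1:5, 1:5, rep("positive", 5)),
               class = "erad_training_error")
})

test_that("the fit agrees with an independent logistic fit on direction", {
  # cross-check: glm's logistic regression must rank the same clearly
  # separated classes in the same direction as the MCC-surrogate fit
  set.seed(7)
  n <- 120
  pos <- c(rep(TRUE, 30), rep(FALSE, 90))
  x1 <- ifelse(pos, rgamma(n, 8, 1), rgamma(n, 1, 1))
  x2 <- ifelse(pos, rgamma(n, 10, 1), rgamma(n, 1.5, 1))
  fit <- suppressWarnings(
    fit_confidence_model(x1, x2, ifelse(pos, "positive", "negative")))
  ref <- suppressWarnings(
    glm(pos ~ x1 + x2, family = binomial()))
  expect_gt(fit$weights[["w1"]] * coef(ref)[["x1"]], 0)
  expect_gt(fit$achieved_mcc, 0.8)
})

test_that("the cutoff anchors on exclusive HRD1-KO hits with 2 PSMs", {
  psm <- psm_table(
    psm_row("AN1", "expt1", hko = 2L, wt = 0L),           # anchor
    psm_row("AN1", "expt2", hko = 0L, wt = 0L),
    psm_row("AN2", "expt1", hko = 2L, wt = 0L),           # anchor
    psm_row("AN2", "expt2", hko = 3L, wt = 0L),
    psm_row("NO1", "expt1", hko = 2L, wt = 1L),           # wt detected
    psm_row("NO1", "expt2", hko = 2L, wt = 0L),
    psm_row("NO2", "expt1", hko = 4L, wt = 0L),           # never exactly 2
    psm_row("NO2", "expt2", hko = 0L, wt = 0L)
  )
  scores <- data.frame(protein_id = c("AN1", "AN2", "NO1", "NO2"),
                       score = c(0.63, 0.41, 0.10, 0.05))
  cutoff <- select_cutoff(scores, psm)
  expect_equal(as.numeric(cutoff), 0.41)
  expect_setequal(attr(cutoff, "anchors"), c("AN1", "AN2"))

  no_anchor <- psm_table(psm_row("NO1", hko = 5L, wt = 1L))
  expect_warning(
    fallback <- select_cutoff(data.frame(protein_id = "NO1", score = 0.9),
                              no_anchor, default_cutoff = 0.5),
    "default cutoff")
  expect_equal(as.numeric(fallback), 0.5)
})
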