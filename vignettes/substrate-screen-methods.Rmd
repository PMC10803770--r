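---
title: "Methods: scoring and filtering a label-free SEL1L IP-MS substrate screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and filtering a label-free SEL1L IP-MS substrate screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eradscreen)
```

## The screen and its assumptions

SEL1L is the substrate-recruiting scaffold of the SEL1L–HRD1 ERAD complex.
When the HRD1 ligase is knocked out, substrates that would normally be
retrotranslocated and degraded instead accumulate on SEL1L, so an
anti-SEL1L pulldown from HRD1-KO cells is enriched for substrates relative
to the same pulldown from wild-type cells. Four pulldown genotypes are
measured per replicate experiment, each yielding a peptide-spectrum-match
(PSM) count per protein:

* **IgG** — mock IP; non-specific background and contaminants;
* **SEL1L-KO** — no bait; anything present is bait-independent;
* **WT** — the steady-state SEL1L interactome;
* **HRD1-KO** — the substrate-trapped interactome.

PSM counts are semi-quantitative: integer, non-negative, overdispersed,
and only comparable within an experiment. Every rule in the pipeline
respects those properties — ratios are taken within an experiment,
denominators are floored rather than smoothed, and absence is treated as a
count of zero.

## The confidence score

Each (protein, experiment) row is summarized by two enrichment features,

$$x_1 = \frac{hko}{\max(wt,\ IgG,\ 1)}, \qquad
  x_2 = \frac{hko}{\max(sko,\ IgG,\ 1)},$$

where $hko$, $wt$, $sko$ and $IgG$ are the four PSM counts. The floor of 1
in the denominators is a deliberate policy: counts are integers, so a
protein absent from both control columns is maximally enriched and the
feature must stay finite; flooring at 1 reports the raw HRD1-KO count in
that case. The features are invariant to scaling all four counts while
the controls stay above the floor, which makes scores comparable across
experiments of different depth.

The confidence score is a three-parameter logistic model,

$$y = \frac{1}{1 + \exp\left[-(w_0 + w_1 x_1 + w_2 x_2)\right]},$$

trained on labeled proteins: positives are literature-known ERAD
substrates observed in the screen; negatives are proteins with none of the
hallmarks of a secretory-pathway client (no signal peptide, no
transmembrane domain, no N-glycosylation, no disulfide bond) or localized
outside the ER/Golgi/lysosome/membrane compartments. Everything else is
unlabeled and plays no part in training. Training uses one feature vector
per protein: the mean of per-experiment features over experiments with
HRD1-KO detection.

### Fitting by MCC maximization

The fit maximizes the Matthews correlation coefficient (MCC) of the
thresholded predictions,

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with the convention that a zero factor in the denominator yields 0. MCC is
the right objective for this problem because the classes are extremely
unbalanced (tens of positives against a thousand negatives) and MCC
penalizes trivial all-negative solutions that accuracy would reward.

Hard MCC is piecewise constant in the weights, so it has no useful
gradient. The fitter therefore works in two deterministic stages:

1. **Surrogate gradient ascent.** Confusion counts are softened by
   replacing indicator predictions with predicted probabilities
   ($\widetilde{TP} = \sum_{i \in pos} y_i$,
   $\widetilde{FP} = \sum_{i \in neg} y_i$; the complementary counts are
   fixed by the class sizes). The resulting surrogate is smooth, and an
   analytic gradient with backtracking step halving ascends it from three
   fixed starts ($w = 0$ and the two enrichment-aligned diagonals).
   Defaults: learning rate 0.05, at most 5000 iterations per start,
   tolerance $10^{-8}$ on the surrogate increase. On separable data the
   surrogate approaches 1 only as $\lVert w\rVert \to \infty$, so
   exhausting the iteration budget there is expected and harmless.
2. **Exact boundary refinement.** With two features, the decision boundary
   at probability threshold 0.5 is a line in the $(x_1, x_2)$ plane. For a
   fixed orientation, the MCC-optimal intercept can be found exactly by a
   threshold sweep over the $n+1$ relevant positions (cumulative-sum
   confusion counts). The fitter sweeps a fine grid of orientations (360
   by default, $O(n \log n)$ each), intercept-calibrates the ascent
   solution the same way, and returns whichever candidate attains the
   highest hard MCC — never below the zero-weight model. Refined
   directions are rescaled to the ascent's weight norm so score dispersion
   is preserved.

The refinement stage exists because the smooth surrogate optimizes a
different (smoothed) objective: on small or weakly separated training
sets, its hard MCC at threshold 0.5 can sit well below the best achievable
linear rule, which matters both for honest reporting of `achieved_mcc` and
for reproducibility against exhaustive search. With only two features the
exact scan is cheap at any training-set size, so there is no reason to
accept the gap. A consequence worth knowing: on label-permuted data the
reported MCC is a non-negative small-sample optimism term (it cannot be
negative, because the zero-weight model is always a candidate); it shrinks
as the training set grows and carries no signal.

### The score cutoff

Rather than fixing an arbitrary probability threshold, the cutoff is
anchored on the weakest credible detections: proteins observed exclusively
in the HRD1-KO pulldown with exactly 2 PSMs in at least one experiment and
zero PSMs in every other column of every experiment. The cutoff is the
lowest per-protein mean score among these anchors. "Exactly 2 in at least
one experiment" is one of several defensible readings of a marginal
exclusive detection (alternatives: exactly 2 summed, or at least 2);
`anchor_psm` keeps it configurable. When no anchor exists the configured
default (0.5) is used with a warning.

## The filter cascade

Each (protein, experiment) row is then tested against seven rules,
evaluated without short-circuiting so a failing row records every violated
rule:

1. **KERATIN** — keratin and keratin-associated proteins (gene symbols
   `KRT*`/`KRTAP*`) are the dominant IP-MS contaminant family and are
   removed outright.
2. **SCORE_BELOW_CUTOFF** — the per-experiment score must reach the global
   cutoff.
3. **RATIO_VS_REFERENCE** — $hko/\max(wt, 1)$ must strictly exceed the
   smaller of the same ratio for SEL1L and OS9 in the same experiment.
   The bait and its lectin cofactor accumulate on the stalled complex too,
   so their enrichment is the natural lower bar for a substrate.
4. **SKO_NOT_BELOW_WT** — SEL1L-KO PSMs must be below WT, unless SEL1L-KO
   is at most 1 (a single PSM in a no-bait control is noise, not
   bait-independent binding).
5. **HKO_NOT_ABOVE_SKO** — HRD1-KO PSMs must strictly exceed SEL1L-KO.
6. **IGG_TOO_HIGH** — IgG must be zero or at most one tenth of HRD1-KO
   (inclusive: "no greater than one tenth").
7. **NUCLEUS_ONLY** — proteins localized only to the nucleus are excluded
   unless they carry a signal peptide, N-glycosylation, a disulfide bond
   or a transmembrane domain (which would mark them as mis-annotated
   secretory clients).

The strict/inclusive readings in rules 3–6 are each a one-line constant in
the implementation and are pinned by boundary tests (e.g. $igg = 1$,
$hko = 10$ passes rule 6; $sko = 3$, $wt = 30$ fails the interactor
one-tenth rule).

A protein becomes a candidate when it passes the cascade in at least two
independent experiments. Candidates detected in WT in any experiment form
Group A (steady-state interactors that accumulate further); candidates
never detected in WT form Group B (transient or low-abundance clients).
Group membership uses detection in *any* experiment, not only passing
ones — the simplest reading of "detectable in WT samples".

Finally, candidates whose transcript is significantly upregulated in
HRD1-KO vs WT (adjusted $p < 0.05$ and $\log_2\mathrm{FC} > 1$ by default;
both configurable and recorded in the run manifest) are excluded: their
enrichment is explained by expression, not by stabilization. Candidates
missing from the DE table are retained with a warning rather than silently
dropped.

## Interactor selection

The SEL1L interactome itself (independent of substrate trapping) is called
from the WT vs SEL1L-KO columns: ER-resident or membrane proteins with
pooled SEL1L-KO PSMs strictly below one tenth of pooled WT PSMs. Pooling
across replicates is the default because the rule is stated against "WT
samples" collectively; a per-experiment mode is available. A protein with
$wt = 0$ can never be selected (strict inequality against 0).

## Comparative cataloging

To compare screens across species, mouse gene symbols are converted to
human ortholog symbols via a user-supplied map (the Alliance of Genome
Resources report format); unmapped symbols are dropped and reported.
Class-I MHC heavy-chain genes are collapsed to a single `MHC-I` token
before comparison because human `HLA-*` and mouse `H2-*` genes have no
one-to-one orthology. Shared candidates are the intersection of the
harmonized sets; percentages are rounded to the nearest integer, the
convention that reproduces published pie-chart values exactly (29 shared
of 116 harmonized human hits → 25%; of 151 mouse hits → 19%; 238 total).

Pathway overrepresentation normalizes per-pathway hit counts by each
group's total (shared, cell-type-1-specific, cell-type-2-specific); a
pathway is called enriched in a group when that group holds more than 50%
of the sum of the three normalized counts — at most one group can, so
verdicts are unique — and shared otherwise. For the `MHC-I` token in the
shared group, the larger of the actual per-species MHC hit counts can be
substituted for the token's count of 1 before normalization
(`mhc_common_count`); group totals keep counting the token as one hit,
which is one reading of a rule whose normalization basis is not fully
specified.

## The synthetic-data generator

Real screens of this design are deposited as raw spectra; nothing at
protein level can be regenerated from them on a desktop. The simulator
therefore stands in with data carrying the statistical structure the
pipeline assumes, plus planted ground truth:

* counts are negative-binomial (`dispersion` is the NB size parameter,
  default 8 — overdispersed but not wildly so; Poisson is the large-size
  limit), with role-by-genotype means;
* default roles over 2000 proteins: 80% background (weak flat binders,
  40% of them nucleus-localized), 8% substrates (HRD1-KO mean 20 vs WT 2,
  SEL1L-KO 1, IgG 0.2), 5% keratin contaminants (flat mean 15 in all four
  columns), 4% transcriptional decoys (substrate-like counts plus a
  planted DE row with $\log_2\mathrm{FC} \ge 2.5$ and tiny adjusted $p$),
  3% machinery (WT and HRD1-KO mean 30, near-zero without bait);
* the baits SEL1L, HRD1 and OS9 are emitted deterministically
  (SEL1L 50/75, OS9 40/60 in WT/HRD1-KO — reference ratio 1.5 — and HRD1
  absent from the HRD1-KO column, SEL1L absent from SEL1L-KO), so the
  reference-ratio filter is always computable;
* substrate-like annotation features match prevalences reported for ERAD
  client sets (~60% transmembrane, ~70% glycosylated, ~30% disulfide);
* a quarter of planted substrates are marked "known" and serve as
  training positives, alongside OS9.

Everything is drawn under one seed; identical configurations reproduce
byte-identical tables. What the simulator does **not** emulate: peptide-
to-protein inference artifacts, shared peptides, batch effects between
experiments, abundance-dependent detection dropout, or any correlation
structure between replicates beyond shared means. Passing recovery tests
on this generator therefore demonstrates that the selection logic is
implemented correctly and is well-behaved under realistic count noise —
not that the biological screen has any particular sensitivity.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on 2000-protein,
3-experiment screens (about a second each), checks the filter cascade
against an exhaustively enumerated brute-force predicate (all count
combinations in 0–6 across the four genotypes times annotation-flag
combinations), and compares the fitter against a coarse weight-lattice
search ($\{-5,\dots,5\}^3$, step 0.5) on 50 seeded instances of at most 50
labeled points. Planted-substrate recovery on the default simulation at
five seeds achieves sensitivity and precision above 0.8, with every
surviving transcriptional decoy removed by the RNA filter. Degenerate
inputs have defined behavior throughout: empty anchor sets fall back to a
default cutoff with a warning, a missing reference protein falls back to
the remaining one, single-class training sets raise a typed error, and
proteins never detected in HRD1-KO carry undefined mean scores but can
never pass the cascade.

## Known limitations

* The confidence model is deliberately the three-parameter logistic the
  screen design calls for; no regularization or cross-validation is
  offered, so `achieved_mcc` is an in-sample quantity.
* The per-protein score aggregates experiments by a plain mean; a
  weighted mean is sometimes mentioned for ranking in screens of this
  kind, but with no defined weighting, the plain mean is used everywhere.
* Filters are applied to per-experiment scores against a global cutoff
  (a mean-score mode is intentionally not the default: the cascade is
  stated per experiment).
* Ortholog mapping is whatever the supplied table says; no sequence-based
  orthology is attempted.
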