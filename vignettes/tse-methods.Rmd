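---
title: "The TSE score: model, implementation choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TSE score: model, implementation choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsescore)
```

## The problem and the model

Response to immune-checkpoint inhibition in urothelial cancer tracks two
opposing features of the tumor microenvironment: infiltration by T cells and
the abundance of stromal resident cells (fibroblasts, TGF-β-driven EMT
programs) whose products impede those T cells. The TSE score condenses both
into one number per sample:

$$\mathrm{TSE}_j = \underbrace{\frac{1}{|M_T|}\sum_{s \in M_T} z_{sj}}_{\text{global T}}
\;-\; \underbrace{\frac{1}{|M_S|}\sum_{s \in M_S} z_{sj}}_{\text{global stromal}},
\qquad z_{sj} = \frac{1}{|G_s|}\sum_{g \in G_s} \tilde x_{gj},$$

where $\tilde x_{gj}$ is log-scale normalized expression centered on the
gene's cohort median, $G_s$ the gene list of signature $s$, and $M_T$, $M_S$
the seven T-cell and five stromal member signatures. Samples with
$\mathrm{TSE} \ge 0.5$ are positive, $\le -0.5$ negative, otherwise neutral;
both boundaries are closed, exactly as published.

Assumptions worth stating plainly:

* **Median centering is per gene, across the cohort's samples.** The source
  description is ambiguous on the centering axis; per-gene centering is the
  only reading under which "enrichment" across samples is meaningful, and it
  makes the score *cohort-relative*: scoring a sample inside a different
  cohort changes its TSE value. This is documented rather than "fixed" —
  single-sample use requires a frozen reference cohort, out of scope here.
* **Equal weights everywhere.** Genes within a signature, and signatures
  within a global group, are unweighted means. No gene re-standardization is
  applied beyond median centering, so high-variance genes carry more weight
  implicitly; this mirrors the published construction.
* **Tumor purity is not modeled.** The difference of two within-sample
  enrichments partially cancels purity effects; the generator does not
  simulate purity gradients.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 0.5 | category boundary on the TSE scale (log-expression units); closed on both sides |
| `min_coverage` | 0.5 | fraction of a signature's genes that must be present; below it the signature is dropped with a warning (missing-gene handling is unstated in the source; dropping is transparent and order-independent) |
| `auc_threshold` | 0.7 | screening threshold when re-deriving memberships (`rescreen = TRUE`) |
| `q` (Hill order) | 1 | "true diversity" named no order; q = 1 (exponential Shannon) is the conventional default, configurable |
| TMB threshold | 10 mut/Mb | closed lower bound (`>= 10` is high) |
| APOBEC classes | E ≥ 3 / [2, 3) / < 2 | gated by an explicit `detected` flag: the class thresholds define low/medium/high only, while cohorts also carry a "no enrichment" state; the detection criterion belongs to the upstream WGS pipeline |
| clonality | VCN > 0.75 | strict inequality |
| TCR filter | > 100 reads | strict: exactly 100 total reads is excluded |

Clonotype classes partition all (reads, R): `rare` (a single supporting
read) takes precedence — in any filtered sample a singleton also satisfies
R < 1%, so without precedence `rare` would be empty; `frequent` is closed at
both ends ([1%, 10%]) so the three R-classes tile (0, 1] with
`hyper-frequent` strictly above 10%.

The protein score sums (not averages) the two log-transformed markers per
compartment — the literal reading of the published transform; a mean would
rescale the score by ½ and leave ranks, AUC and the sign-based category
unchanged. Densities (cells/mm²) and area percentages enter `log10(1+·)` in
their native, incommensurate units; this mirrors the source and is flagged
as a caveat, not harmonized away. The protein category cutoff of 0 is this
package's choice — no numeric cutoff is published.

## The synthetic cohort: what it emulates, and what it does not

`simulation_config()` states the world once; its defaults are not tuned to
tests. Three latent groups (T-cell-high / mixed / stroma-high) are drawn
with probabilities (15, 14, 12)/41 — the category proportions observed in
the discovery cohort. Expression is homoskedastic Gaussian noise (SD 1,
VST-like) around per-gene baselines N(8, 2), with +1.5 log-units planted on
T-signature genes of group 1 and stromal-signature genes of group 3.
Response is Bernoulli per group with probabilities (0.67, 0.21, 0) — the
published response rates, used here as the *generative target*, so recovered
rates must match them only up to binomial error and category
misassignment. Survival is exponential with group hazard ratios (1, 2.5, 6)
around a baseline of 0.0667/month (anchored to ~67% six-month survival in
the positive group) under independent exponential censoring (rate 0.05,
~30% censored — the censoring structure is this package's convention; none
is described for the real cohort). Repertoires are Dirichlet-multinomial
with symmetric concentration (2, 1, 0.5) over 150 clonotypes and 1000 reads
— most even in the T-cell-high group; marker levels are log-normal with
group means concordant with the planted expression shifts.

Deliberate simplifications: gene sets are disjoint (real signatures overlap;
`overlap_frac` re-introduces overlap when wanted, but disjointness keeps
recovery tests interpretable); genes are independent given the group (no
co-expression structure); there are no batch effects, no purity gradients,
no library-size artifacts; TMB and APOBEC E are only weakly linked to
response (log-normal shifts of 0.3 and 0.2 on responders) so that the TSE
score should dominate them, as planted. A green recovery test therefore
establishes that the implementation recovers structure *of the kind the
model assumes* — it says nothing about robustness to correlated genes,
overlapping signatures or cohort composition shift.

Determinism: one seed drives everything; per-modality sub-seeds are derived
arithmetically (kept below 2³¹) so that regenerating a cohort is
bit-identical and adding a modality does not reshuffle the others.

## Numerical and inferential choices

* **AUC** is the Mann–Whitney midrank estimator — exactly the all-pairs
  concordance count with ties counted ½ — and the reported ROC curve has one
  operating point per unique threshold so its trapezoidal area reproduces
  the AUC including tie diagonals. Screening reports `max(AUC, 1−AUC)` with
  the direction recorded, since discriminatory power is signless there.
* **DeLong** uses the standard structural-components formulation (V10/V01
  placement values); the variance of a single AUC is `var(V10)/m +
  var(V01)/n`, the paired test uses the 2×2 component covariance with a
  two-sided normal reference. Comparing a classifier against itself returns
  z = 0, p = 1 by construction (degenerate zero variance short-circuits).
* **Fisher's exact test** is two-sided by the probability-mass method
  (summing hypergeometric masses ≤ the observed table's); Wilcoxon uses the
  normal approximation with midrank tie correction and no continuity
  correction; BH is the standard step-up capped at 1. These delegate to R's
  reference implementations; the test suite checks each against an
  independent oracle (direct `dhyper` enumeration, hand step-up) rather than
  trusting the delegation.
* **Survival**: product-limit KM, observed-vs-expected log-rank, Cox partial
  likelihood with the **Efron** tie correction (unstated in the source;
  Efron is the less biased default) and Wald intervals.
* **Logistic regression** is IRLS with convergence at deviance change
  < 1e-8; complete/quasi-separation is detected (non-convergence or
  |linear predictor| > 20) and surfaced as a classed warning plus a
  `separation` flag rather than silently returning huge coefficients.
* Re-deriving global memberships from the evaluated cohort's own labels
  (`rescreen = TRUE`) is circular by construction; the flag replicates the
  published screening route but the fixed membership lists are the default,
  as used for validation cohorts.

## Limitations

* The score is cohort-relative; cross-cohort transfer of the ±0.5 cutoff
  assumes comparable normalization and cohort composition.
* Signature gene identifiers are matched exactly and case-sensitively — no
  alias resolution; users must pre-harmonize annotations.
* The generator's realism limits are listed above; in particular the
  additivity result (TSE AUC ≥ either global AUC in ≥ 95% of seeds) is a
  property of the planted two-sided structure and should not be read as a
  theorem about arbitrary cohorts.
* Upstream quantities — VST normalization, APOBEC enrichment E, variant
  copy numbers, image segmentation — are consumed, not computed; published
  pipelines own them.
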