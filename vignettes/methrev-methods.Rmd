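---
title: "Methods: promoter-tile differential methylation and treatment reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-tile differential methylation and treatment reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrev)
```

# The analysis model

`methrev` analyses targeted bisulfite sequencing of a four-group,
two-factor design: a chronic condition (e.g. nerve injury vs sham) crossed
with an intervention (e.g. a methyl-donor supplement vs vehicle). The raw
observation is, per CpG site and sample, a pair of counts
(methylated reads, total reads). Inference happens not at single CpGs but
on *tiles* — fixed 250 bp windows sliding in 125 bp steps — because single
CpGs at 10–50x coverage carry too little information and neighbouring CpGs
are strongly co-methylated. Counts within a tile are summed per sample.

## The tile test

For one tile and two groups, the model is a binomial logistic regression
with a single group indicator,

$$\mathrm{logit}(\pi_i) = \beta_0 + \beta_1\,g_i,$$

where sample $i$ contributes ($m_i$ methylated of $t_i$ total) reads and
$g_i \in \{0, 1\}$ codes control vs experimental. $\beta_1 = 0$ is tested
by likelihood ratio against $\chi^2_1$. Because the only covariate is a
two-level factor, the maximum-likelihood fit is available in closed form —
the fitted group proportions are the pooled proportions
$\hat p_g = \sum_{i \in g} m_i / \sum_{i \in g} t_i$ — and the package
computes the deviance difference directly from pooled counts, vectorised
over all tiles. The test suite cross-checks this closed form against
`stats::glm` on the per-sample observations.

Three quantities are reported per tile: the *methylation difference*
$100(\hat p_{exp} - \hat p_{ctl})$ in percentage points with the control
group as the reference, the *log odds ratio* $\hat\beta_1 =
\mathrm{logit}(\hat p_{exp}) - \mathrm{logit}(\hat p_{ctl})$, and the LRT
p-value. Tiles where a pooled proportion is exactly 0 or 1 would have an
infinite log odds ratio; the package clamps each pooled proportion away
from the boundary by half a read ($0.5/t$) before taking logits, which
keeps the estimate finite without affecting the LRT. Tiles identical in
both groups at a boundary (all 0% or all 100%) short-circuit to p = 1 and
log OR = 0.

The model assumes binomial sampling within each group's pooled counts: it
accounts for coverage but not for *replicate-level* overdispersion
(biological variation between animals beyond counting noise). This is the
standard behaviour of tile-based logistic DM testing without an
overdispersion correction, and it is the main caveat when interpreting
q-values on real data (see Limitations).

## Multiple testing: SLIM

P-values across tiles are converted to q-values by scaling the
Benjamini–Hochberg step-up adjustment with an estimate of $\pi_0$, the
proportion of truly null tiles, in the spirit of the sliding-linear-model
(SLIM) family of estimators. The estimator in `slimPi0()` works on the
empirical CDF of the p-values: above the signal-bearing region the CDF is
approximately linear with slope $\pi_0$, so the range $[0.1, 1]$ is split
into 10 consecutive lambda segments, a least-squares line is fitted to the
CDF inside each, and the slope of the most *stable* segment — the one whose
slope changes least from its left neighbour, ties resolved towards larger
lambda — is taken as $\hat\pi_0$, clipped to $(0, 1]$. Degenerate p-value
distributions (point masses) leave the stable region flat at slope 0; the
estimator then falls back to the steepest segment, which holds the
remaining mass, so that e.g. all-p-equal-1 input yields $\hat\pi_0 = 1$
and q = 1 everywhere. With $\pi_0$ forced to 1 the adjustment *is*
Benjamini–Hochberg, exactly; `adjust = "BH"` selects that directly. The
exact segment geometry (10 segments, 11 CDF points each, lambda from 0.1)
is a package default, documented rather than hidden, since published
descriptions of SLIM leave room for implementation choices.

## Calling and reversal

A tile is *hypermethylated* when $q < 0.1$ and the difference exceeds
+5 percentage points, *hypomethylated* below −5 points — both inequalities
strict, with the control group as reference. The permissive 0.1 threshold
suits exploratory screens; tiles with $q < 10^{-7}$ carry an additional
`robust` flag. Volcano-plot tables label the remaining tiles as
non-significant-but-large, significant-but-small, or neither.

The reversal step pairs tiles called DM in *both* the injury contrast
(injured-vehicle vs sham-vehicle) and the treatment contrast
(injured-treated vs injured-vehicle), matching by exact tile coordinates —
correct whenever both contrasts came from one tiling, and enforced by a
hard error when zero exact matches coexist with many partial overlaps
(a sign of mismatched tiling parameters). Each pair falls in exactly one
class by the sign rule: hyper→hypo is a reversal of hypermethylation,
hypo→hyper a reversal of hypomethylation, same-direction is no reversal.
Under exact matching the sign rule is exhaustive, so no "unclear" class
can arise; an optional overlap-based matching mode
(`overlapContrasts(..., mode = "overlap")`) also pairs an injury tile with
partially overlapping treatment tiles and labels *conflicting* evidence
(overlapping treatment tiles of opposite direction) as `unclear`. That
mode is an interpretation — exact matching is the default and the
recommended analysis path. Reversal requires only an opposite DM sign,
not magnitude parity: the pairing step has already demanded $|diff| > 5\%$
in both contrasts.

Gene-level summaries average the methylation difference over a gene's
tiles per contrast, with the between-tile standard error when a gene has
two or more tiles; a tile spanning two promoters contributes to both
genes. Gene counts per reversal class use any-tile membership.

## Enrichment

Over-representation of a curated gene set among DM or reversing genes is
tested with the upper-tail hypergeometric probability
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, computed by exact
summation of the mass function. The population $N$ is the set of genes
with at least one analysable promoter tile — enrichment must condition on
what was measurable, not on a genome-wide list. Set members absent from
the population are dropped (and reported) before testing; matching is
exact and case-sensitive; only enrichment (upper tail) is tested. Across
several sets, p-values get a BH-adjusted q column.

# The synthetic-data generator

`simParams()` + `simulateExperiment()` generate the full study shape so
that calibration and recovery are testable without any external data:

* a single toy chromosome with `nGenes` genes on equal slots, random
  strand, and CpGs at exponential spacing (mean `cpgSpacingMean`, default
  50 bp) inside each promoter (TSS −2000/+200, strand-aware);
* four groups sized 3, 3, 4, 4 by default (reference, treated reference,
  injured, injured-treated);
* coverage per CpG and sample from a negative binomial
  (`coverageMean` 30, `coverageDispersion` 5), multiplied by a per-sample
  log-normal depth factor ($\sigma = 0.2$) so the median-scaling
  normalisation has real work to do;
* effects planted on disjoint 250 bp *units* aligned to the tiling grid —
  all CpGs of a unit share their group mean, making the tile the natural
  recovery scale. A fraction `fracInjuryTiles` of units receives an injury
  shift with magnitude uniform in `injuryEffectRange` (default 15–30
  points, above the 5-point calling threshold) and sign positive with
  probability `hyperFraction` (default 0.6, reflecting the hyper-skew
  typical of cortical injury signatures). Of the injured units,
  `reversalFraction` (default 0.927) move back past the baseline in the
  treated-injured group (overshoot 0.3 x effect, so the treatment
  contrast changes sign decisively); the rest keep drifting in the injury
  direction;
* methylation counts are binomial at the CpG's group mean, where each
  CpG's own mean is a single Beta draw (correlation parameter
  `methOverdispersion`, default 0.05) around its unit's group mean,
  *shared across samples*. Tile counts are therefore beta-binomially
  overdispersed relative to a binomial at the tile mean — intra-tile CpG
  heterogeneity — while group contrasts remain calibrated, because the
  CpG-level deviations are common to all groups. The generator
  deliberately does **not** add independent per-replicate overdispersion:
  the analysis model has no overdispersion correction, so replicate noise
  at realistic magnitudes would make every null q-value anticonservative
  and no FDR statement testable. Passing tests consequently demonstrate
  correctness of the machinery and calibration under the stated noise
  model — not robustness to between-animal variance on real data.

Baseline unit methylation comes from Beta(`baselineMethAlpha` = 2,
`baselineMethBeta` = 5) (promoters skew lowly methylated), truncated to
the interval where all planted shifts stay inside (0.01, 0.99); if a
user-chosen effect range makes that interval empty, the generator falls
back to untruncated draws, clamps group means to [0.01, 0.99], records the
clamping in the ground truth, and relabels units from their *achieved*
effects so that ground-truth labels always satisfy the sign invariants.
One RNG stream is keyed per (seed, sample) plus one for the genome and one
for the ground truth, so identical seeds give byte-identical files.
Coverage distribution and CpG density of real capture panels are not
published for the motivating study; the defaults are explicit stand-ins
exposed in `simParams()`.

# Numerical and design choices

* **Coordinates.** Internally everything is a `GRanges` (1-based,
  closed), the Bioconductor convention; BED input/output converts at the
  boundary via `rtracklayer`. Bismark coverage positions (1-based) map
  directly.
* **Filter order.** Depth filter → blacklist → normalisation → tiling →
  promoter restriction, the methylKit-style order (filter before
  normalising, so scale factors come from analysable sites).
* **Rounding.** Normalised counts round half *away from zero* (not
  banker's rounding) and floor at 1 read where coverage was nonzero;
  methylated counts rescale to preserve each site's proportion and clamp
  to coverage. Counts stay integral for the count-based GLM.
* **Window anchoring.** Tile grids anchor at position 0 of each
  chromosome, not at the first covered base, so tiling is stable under
  filtering.
* **Promoter assignment.** A tile keeps *all* overlapping promoters'
  gene symbols (not nearest-gene-only), and promoter restriction is
  tile-level overlap; a stricter CpG-level pre-filter would only matter if
  effects were not promoter-local.
* **minCpgs.** Default 1 CpG per tile; exposed in `tilingParams()`.
* **Problem sizes in the checks.** The null-calibration suite uses ~320
  genes (≈5,500 promoter tiles), the recovery suite ~1,000 genes with a
  quarter of units injured (≈2,200 planted units); both sizes give stable
  percentages while keeping a full test run in tens of seconds.

# Limitations

* No replicate-level overdispersion correction (beta-binomial regression
  and F-tests are out of scope); q-values on real between-animal data are
  likely anticonservative.
* No covariate adjustment or paired designs.
* Strand collapsing of symmetric CpGs is assumed done upstream; positions
  are taken as given.
* Gene symbols match exactly and case-sensitively; cross-species homology
  mapping is the user's responsibility.
* The `unclear` reversal class only arises in the optional overlap
  matching mode; exact matching cannot produce it by construction.
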