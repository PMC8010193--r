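---
title: "Methods: voxel-wise lesion-label mapping and downstream radiogenomic comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise lesion-label mapping and downstream radiogenomic comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlsmap)
```

`vlsmap` asks a spatial question about a binary molecular label: across a
cohort of binary tumor masks registered to one template grid, which voxels
are lesioned significantly more often in label-positive samples? This
vignette documents the statistical model, the parameters that matter, the
numerical conventions, and what the built-in simulator does and does not
emulate.

## The voxel-wise model

Masks are assumed *pre-registered*: spatial normalization is upstream and
out of scope. The package never resamples silently — grids must agree to
1e-4 mm per affine element, otherwise `resample_to_grid()` (nearest
neighbour through the composed world transform, binarity-preserving) must
be called explicitly. The rationale is that a silent resample can hide a
registration error that would invalidate every voxel-wise count downstream.

At a voxel lesioned in more than `min_lesion_fraction` of the cohort
(default 0.05, strict inequality — with 125 samples, 7 lesions keep a voxel
and 6 do not), lesion status × label forms a 2×2 table (a, b; c, d). The
test is the **Liebermeister quasi-exact measure**: augment the concordant
cells, (a+1, b; c, d+1) for the positive direction, and evaluate the
one-sided hypergeometric tail P(X ≥ a+1) with population n+2, column margin
a+c+1 and row margin a+b+1 (the negative direction augments the discordant
cells and takes the lower tail). Compared with Fisher's exact test on the
unaugmented table the measure is less conservative while remaining
quasi-exact; the test suite verifies, by exhaustive enumeration of every
2×2 table with n ≤ 12, both equality with a direct
binomial-coefficient-summation oracle (to 1e-12) and the Fisher upper
bound. Only the test's name is conventionally fixed; its standard
quasi-exact formulation is what non-parametric mapping software implements,
and we verified our closed form against enumeration rather than against any
external binary.

One-sided p-values are mapped to signed z-scores, z = Φ⁻¹(1 − p) ×
direction sign; p of exactly 0 or 1 (possible only through floating-point
underflow) is clamped at |z| = 8 with a warning so maps remain storable in
finite-precision NIfTI volumes.

### Multiplicity

FDR control uses the Benjamini–Hochberg step-up rule *across analyzed
voxels only* — voxels failing the coverage filter are never tested, so they
do not dilute the correction. The step-up constant is BH by default;
Benjamini–Yekutieli is available (`fdr_method = "BY"`) for users worried
about the positive-dependence assumption, which voxel-wise lesion data
(spatially correlated, one-sided) generally satisfies in practice. The two
subtype maps (positive class = proneural, then = mesenchymal) are
independent runs with opposite label polarity, each corrected on its own —
matching how separate subtype predilection maps are conventionally
reported.

### Clusters

Significant voxels are grouped by connected-component labeling (default
26-neighbour connectivity; 6 and 18 available). Components are computed on
a voxel-adjacency graph via `igraph`; the suite cross-checks the labeling
against a breadth-first flood-fill oracle. Clusters are ordered by voxel
count, ties by peak z then lowest linear index, so output is fully
deterministic. No minimum cluster extent is imposed by default, since
correction is at the voxel level.

## Membership, reporting, survival

"In the determined area" means the tumor overlaps the significant region by
at least `min_overlap_voxels` (default 1 — the most permissive reading; the
overlap fraction of each tumor is recorded so stricter rules can be
re-applied without recomputation, and `classify_membership()` is monotone
in the threshold). The 2×2 region-by-subtype report recomputes margins and
both row and column percentage families from the cells, rounding
percentages to integers as narrative reports conventionally do; the
lobe-level location summary keeps two decimals.

Rater agreement uses Cohen's κ with grades: κ > 0.8 excellent, 0.6 ≤ κ ≤
0.8 good, below 0.6 poor. The boundary 0.8 itself is graded *good*: the
convention quoted for "excellent" is a strict inequality, and we document
rather than hide the boundary choice. The inter-observer VOI volume rule
flags a pair for recheck when |V₁ − V₂| / min(V₁, V₂) > 0.05; the published
phrasing ("ratio of VOI … > 0.05") is ambiguous between this and
|V₁ − V₂| / V̄, and we chose the more sensitive denominator.

Survival is Kaplan–Meier plus the standard unweighted two-group log-rank
(ties pooled in the hypergeometric term; censoring at an event time stays
at risk through that time), delegated to the `survival` package behind the
module interface, with hand product-limit and event-table oracles in the
tests. No Cox modeling: the analysis this package supports is a two-group
contrast. The treatment/VASARI-filtered survival subset (resection +
radiation + pharmaceutical flags, F5 ≥ 7 i.e. > 95 % enhancing, temporal
involvement) is reported alongside the unfiltered one, because the
filtered n depends on the cohort and should be logged, not assumed.

## Expression scoring

`ssgsea_score()` implements the rank-based running-sum form of
single-sample GSEA: per sample, genes are ranked by expression descending;
the score is the sum over rank positions of the difference between the
weighted in-set empirical distribution (weight = rank position from the
bottom, raised to α) and the unweighted out-of-set distribution. α = 0.25
by default — the conventional single-sample choice; α = 0 gives the
unweighted cumulative-difference sum. Ties share average rank weight by
default (`ties = "first"` breaks them by row order). Because the score
depends on ranks only, it is invariant to per-sample monotone transforms —
a property the suite asserts — so the input scale (RSEM, microarray, log or
not) need only be monotone-comparable within a sample.

The tumor-purity proxy is −(z(immune ES) + z(stromal ES))/2 across samples.
This is deliberately *not* a published purity polynomial: it is a
signature-combination score that orders samples and supports group
contrasts, and it is documented as such. Immune-cell infiltration is
likewise approximated by per-cell-type marker-set scoring (one ssGSEA score
per marker set) rather than support-vector deconvolution; with desk-scale
synthetic marker sets this captures directionality of infiltration shifts,
which is what the group comparison consumes.

Differential expression between the groups is a genewise pooled-variance
Student's t (cross-checked against `t.test(var.equal = TRUE)`), with fold
change defined as mean(out) − mean(in) on the (assumed log-scale) values —
positive = higher outside the area, matching the orientation in which
out-of-region up-regulation of EMT genes is described. The top-k report
filters at p < 0.05 and sorts by |log2 FC| (ties: smaller p, then gene id).

## What the simulator emulates — and what it does not

`sim_config()` defaults *are* the study conditions the package is tested
under: 52 positive / 73 negative samples on a 48 × 56 × 48 grid (4 mm
voxels — a cohort-scale template resolution), a spherical hotspot of radius
7 voxels centered at (15, 20, 17) (left-hemisphere, inferior-posterior),
positive-class lesions centered in the hotspot with probability π = 0.7,
ellipsoidal lesions with semi-axes 3–6 voxels (1.2–2.4 cm — realistic
glioblastoma scale relative to a 4 mm grid, and comparable to the hotspot
so the recovered region tracks the planted one), exponential survival with
median 400 days in-region and hazard ratio 2 outside with 20 % independent
censoring (censoring times exponential with rate chosen so the censoring
probability is exactly the configured rate per sample), and a 2000-gene
standard-normal expression matrix with a 141-gene EMT set of which 16 genes
are shifted up by 1 SD in out-of-region samples, 80-gene immune and stromal
signatures shifted by 0.5 SD, and two depleted cell-type marker sets
(CD8 and follicular-helper T cells, −0.5 SD). Survival and expression
depend on *true* region membership (does the lesion touch the hotspot), not
on the class label, so classification error propagates realistically.
Each stage (lesions, survival, expression, clinical) draws from its own
seed derived from the master seed, keeping stages individually
reproducible.

What it does not emulate: tumor shape (ellipsoids, not infiltrative
margins), registration error, multifocal disease, intensity data of any
kind, correlated gene-gene structure, or realistic marker-set biology.
Passing recovery tests therefore demonstrates that the *statistical
machinery* recovers planted spatial, survival and expression effects at
realistic sizes — not that the pipeline is robust to segmentation or
normalization artifacts in real MRI.

## Test problem sizes and determinism

The suite exercises: exhaustive 2×2 enumeration to n = 12 (1 819 tables);
null calibration with 200 simulated cohorts (32³ grid, 30 + 30 samples,
no spatial effect) asserting the family-wise chance of any FDR-significant
voxel stays within Monte-Carlo error of q = 0.05; hotspot recovery at the
full default conditions (Dice ≥ 0.5 against truth, peak inside the
hotspot); log-rank power ≥ 80 % over 100 seeds at hazard ratio 2 with the
default cohort's group sizes (40 in / 85 out); and planted-gene recovery
(≥ 80 % of the 16 planted genes significant with positive fold change, in
≥ 80 % of 50 seeds, at δ = 1 SD and n = 30/30). These sizes were chosen to
make Monte-Carlo error small relative to the margins being asserted while
keeping the suite desk-scale. Every stochastic test fixes its seeds;
`run_vlsm()` itself is deterministic and order-invariant, which the suite
asserts by permuting samples.

## Degenerate inputs and numerical conventions

- Empty masks are representable (`read_mask()` flags them) but rejected at
  cohort assembly: every included sample has a tumor.
- Single-class labels, empty coverage, zero-margin 2×2 tables, all-censored
  survival and whole-matrix gene sets are errors, not silent results.
- Both-raters-constant κ is undefined (p_e = 1) and reported as 1 with a
  warning; both-groups-constant t-tests warn and return p of 0 or 1.
- Voxel indexing is 0-based through the affine, 1-based in R arrays; world
  coordinates are obtained only via the affine, never assumed.
- Internal matrices are samples × voxels logicals, so every voxel-wise
  quantity is a vectorized column operation; p-values for all analyzed
  voxels are computed in one `phyper()` call.

## Known limitations

Voxels are tested independently — spatial correlation enters only through
FDR and cluster reporting, not through the test statistic. The anatomical
naming of clusters (which gyrus a peak sits in) is outside the package:
cluster peaks are reported in voxel and world coordinates for lookup in the
user's atlas. Real cohort sizes near one hundred samples give the
Liebermeister test limited power at voxels with marginal coverage, which is
why the coverage filter is part of the model rather than an optimization.
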