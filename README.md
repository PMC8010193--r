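# vlsmap

Voxel-based lesion-symptom mapping (VLSM) for radiogenomic cohorts, in R.

Glioblastoma (and lesion-mapping studies generally) often ask where in the
brain a tumor must sit for the patient to carry a given molecular label —
for example, whether the proneural transcriptomic subtype has a spatial
predilection site distinct from the mesenchymal subtype. `vlsmap` implements
that analysis end to end for cohorts of binary tumor masks (VOIs) on a
shared template grid, together with the downstream comparisons the question
motivates: do samples inside the mapped region survive longer, and do their
expression profiles show less epithelial–mesenchymal transition (EMT), higher
tumor purity, and different immune infiltration?

The package is aimed at neuro-oncology imaging researchers who have
pre-registered binary lesion masks (e.g. in MNI space), a per-sample
clinical/VASARI table, and a gene-by-sample expression matrix.

## The statistics at the core

At every voxel *v* lesioned in more than 5 % of the cohort, lesion status is
crossed with the binary label into a 2×2 table (a, b; c, d), with
a = lesioned ∧ label-positive. The **Liebermeister quasi-exact test**
augments the concordant cells by one and evaluates a hypergeometric tail on
the augmented table: for the positive direction

> p(v) = P(X ≥ a + 1),  X ~ Hypergeom(N = n + 2, K = a + c + 1, m = a + b + 1),

which is less conservative than Fisher's exact test on the unaugmented
table (verified exhaustively in the test suite). One-sided p-values are
mapped to signed z-scores via z = Φ⁻¹(1 − p), the false discovery rate is
controlled with the Benjamini–Hochberg step-up rule across analyzed voxels
only, and surviving voxels are grouped into 26-connected clusters.

Samples are then classified *in* or *outside* the significant region
(≥ 1 overlapping voxel by default), and the groups are compared by:

- Kaplan–Meier / log-rank on overall survival (`survival` package);
- single-sample GSEA (ssGSEA, rank-based running-sum with exponent
  α = 0.25) for EMT, immune, stromal and per-cell-type signatures;
- a signature-combination tumor-purity proxy,
  −(z(immune ES) + z(stromal ES))/2;
- per-gene pooled-variance t-tests with log-scale fold changes and a
  top-k report.

A coupled simulator (`simulate_cohort()`) generates imaging + clinical +
expression cohorts with a planted spatial hotspot, a doubled out-of-region
hazard and planted expression shifts, so every stage can be tested against
known ground truth.

## Worked example

```r
library(vlsmap)

sim <- simulate_cohort(sim_config(seed = 1))   # 52 + 73 samples, 48x56x48 grid
res <- run_vlsm(sim$lesions, sim$truth$labels)
res
#> vlsm_result: 783 voxels analyzed (52+/73- samples), 702 significant in 1 cluster(s) at q = 0.05 (BH)
#>   FDR p-threshold: 0.0319
res$clusters[1, ]
#>   label n_voxels peak_z peak_i peak_j peak_k
#> 1     1      702 4.3833     13     19     15

mem <- classify_membership(sim$lesions, res$sig_mask)
contingency_report(mem, sim$truth$labels)
#>         label+ label- total
#> in area     39      6    45
#> outside     13     67    80
#> total       52     73   125
#> odds ratio: 33.50

sv <- compare_survival(mem, sim$samples)
sv$test$p
#> 0.00082      # in-area samples survive longer (hazard ratio 2 outside)

emt <- ssgsea_score(sim$expression, sim$gene_sets$EMT)
diff_by_group(emt, mem$in_area)$p
#> 0.0017       # EMT score higher outside the mapped region

dice_coefficient(res$sig_mask, sim$truth$hotspot)
#> 0.60         # recovered region vs planted truth
```

The mapped cluster (peak at voxel 13/19/15) sits inside the planted hotspot
(center 15/20/17, radius 7): the pipeline recovers the simulated
predilection site, the survival disadvantage outside it, and the planted
EMT shift.

For shell use, a thin wrapper ships in `inst/cli/vlsm.R`
(`Rscript vlsm.R simulate|run-all --config cfg.yaml --out DIR`).

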