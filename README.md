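# screenkit

Analysis of pooled single-cell CRISPRi screens read out by droplet
RNA-seq along a differentiation trajectory — the experimental design in
which dCas9-KRAB silences candidate enhancers or promoters, each cell
carries one or a few sgRNAs delivered at low MOI, and the phenotype of a
perturbation is a shift in the distribution of its cells across
trajectory states (e.g. progenitor → early → mid → late cardiomyocytes)
rather than a change in a single readout.

The package is aimed at analysts of CROP-seq / Perturb-seq style screens
and covers the full path from raw UMI triplets to per-target statistics:

* **Guide and hashing-tag assignment** by the saturation-curve method:
  for each sgRNA, cells are ranked by UMI count and the knee of the
  normalized cumulative curve — the rank maximizing the perpendicular
  distance to the chord between the curve's endpoints — separates true
  carriers from ambient background; UMIs past the knee are zeroed and a
  guide is called wherever the adjusted count exceeds 0. Cells with
  exactly one called hashing antibody are retained as singlets.
* **Cell and gene filtering**: cells above 20% mitochondrial content and
  zero-count genes are removed; clusters under 1% of cells are dropped;
  the expression matrix is kept as raw / `ln(1+x)` / per-gene
  standardized layers.
* **Two-stage sgRNA quality filtration**: (1) non-targeting (NT) control
  guides whose own cell-state distribution biases the pooled NT
  background are removed iteratively (hypergeometric tests, Bonferroni
  over clusters × tails × guides); (2) for each target, all `2^k − 1`
  guide combinations are tested against the NT background per cluster
  and direction, each of the `2 × |clusters|` p-value lists is cut at
  `2^(k−1)`, and a guide over-represented left of the cutoff
  (hypergeometric count test, with a per-list correction and a signal
  gate on the underlying p-values) is removed — unless more than half of
  a target's guides would be removed, in which case all are kept.
* **Perturbation statistics**: per (target, cluster) enrichment and
  depletion from the hypergeometric tails `P(X ≥ k)` and `P(X ≤ k)` on
  the pooled target + NT urn; Mann–Whitney pseudotime-shift tests
  (exact for small groups); per-gene Mann–Whitney differential
  expression; state gene-set definition by pairwise rank-sum with BH
  correction; a resampling Z-test that compares mean gene-set expression
  in perturbed cells with a null built by repeatedly sampling
  equally-sized NT cell sets; pseudotime expression profiles and bulk
  RPKM time-course fold changes for validation.
* **Enhancer prioritization**: ATAC peaks are merged and extended to
  500 bp, H3K27ac counts are input-normalized
  (`log2((RPKM_chip + c)/(RPKM_input + c))`), and regions pass if their
  maximum enrichment exceeds `log2(1.5)`, lie within 1 kb of a disease
  variant and within 100 kb of a relevant gene.
* **A synthetic-screen generator** (`simulateScreen()`) producing
  expression, guide-UMI and hashing matrices with ground truth (Poisson
  MOI 0.3 carriage, ambient background, state-odds effects, marker
  genes, target-gene repression, mito content, hashing doublets), so
  every stage is testable without sequencing data.

## Worked example

Simulate a screen in which enhancer `ENH01` carries a 3-fold odds
depletion of the late state, call guides, filter them, and test the
target's state distribution and pseudotime shift against the NT
background:

```r
library(screenkit)

cfg <- simulationConfig(nCells = 6000, seed = 42,
                        effectTable = list(ENH01 = c(late = 1/3)))
scr <- simulateScreen(cfg)
ga  <- assignGuides(scr@guideUmis, scr@library)
ga
#> GuideAssignment: 11 guides over 6000 cells (1603 cells with >=1 call)

cells  <- dropUnassignedCells(ga)
labels <- setNames(scr@truthStates, barcodes(scr@expression))[cells]
qc     <- qcGuides(ga, labels, scr@library)

nt  <- setdiff(intersect(cellsWithGuide(ga, qc$ntBackgroundGuides), cells),
               cellsWithGuide(ga, setdiff(guideIds(scr@library),
                                          ntGuides(scr@library))))
tgt <- intersect(cellsWithGuide(ga, guidesForTarget(scr@library, "ENH01")),
                 cells)
hypergeomClusterTest(tgt, nt, labels)[, c("cluster", "k", "n", "K", "N",
                                          "p_enrich", "p_deplete")]
#>      cluster   k   n   K    N p_enrich p_deplete
#> 1      early 177 487 359 1139  0.00154  9.99e-01
#> 2       late  31 487 174 1139  1.00000  4.50e-14
#> 3        mid 154 487 309 1139  0.00204  9.99e-01
#> 4 progenitor 125 487 297 1139  0.63229  4.20e-01

pt <- setNames(scr@truthPseudotime, barcodes(scr@expression))
sh <- pseudotimeShiftTest(pt[tgt], pt[nt])
#> pseudotime shift: U = 141727, p = 0.00193, median diff = -368
```

Of the 6000 simulated cells, 1603 carry a callable guide; the 487
ENH01 cells are strongly depleted from the late state
(31 observed where the urn expects ~74; `p_deplete = 4.5e-14`), with the
displaced cells appearing as mild enrichment of the earlier states, and
their median pseudotime sits 368 ranks below the NT cells — the
signature of a perturbation that delays lineage commitment.

The same analysis runs end to end from a single config via
`runPipeline()` (or `Rscript inst/scripts/screenkit.R --config
config.yaml --out DIR`), which writes assignment, QC and statistics
tables plus a deterministic `report.json`.

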