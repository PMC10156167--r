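---
title: "Statistical methods and design choices in screenkit"
author: "screenkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in screenkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenkit)
```

# The screen model

screenkit analyzes pooled CRISPRi screens in which each cell of a
differentiating population carries a small number of sgRNAs (lentiviral
delivery at MOI ≈ 0.3, so most carrier cells hold exactly one guide),
and the phenotype of silencing a regulatory element is read out as a
change in where the perturbed cells sit along a trajectory of states
(progenitor < early < mid < late in the cardiomyocyte design the
package emulates). Three observations make this setting statistically
distinctive:

1. Guide capture is contaminated by ambient sgRNA molecules, so
   per-guide UMI counts mix a high-count carrier population with a
   low-count background and must be thresholded per guide.
2. The control population is defined by non-targeting (NT) guides, and
   both the NT background and the targeting guides themselves need
   quality filtration before any inference.
3. Effects are distributional: a perturbed element shifts its cells'
   state proportions and pseudotime ranks, so the core tests are urn
   (hypergeometric) and rank (Mann–Whitney) statistics, plus a
   resampling test for gene-set expression.

# Guide assignment: the saturation-curve knee

For one guide, let $u_{(1)} \ge u_{(2)} \ge \dots$ be the per-cell UMI
counts in decreasing order (ties broken by lexicographic barcode order
so runs are reproducible across platforms). Only cells with $u > 0$
enter the curve. With $m$ positive cells, the normalized cumulative
curve is $x_r = r/m$, $y_r = \sum_{i \le r} u_{(i)} / \sum_i u_{(i)}$,
and the knee is the rank maximizing the perpendicular distance from
$(x_r, y_r)$ to the chord joining the curve's first and last points.
UMIs of cells past the knee are set to zero and a guide is called
wherever the adjusted count is positive. The same procedure assigns
hashing antibodies; only cells with exactly one called tag (singlets)
are kept when hashing data exist.

Numerical choices: distances within $10^{-9}$ of the maximum are
treated as tied and the earliest rank wins, so mathematically flat
curves (e.g. all counts equal) are not split by floating-point noise;
all-zero guides yield no knee and no calls. The knee is parameter-free
and scale-invariant — multiplying a guide's counts by any positive
constant leaves the call set unchanged.

The knee separates carriers cleanly only when carrier cells hold an
appreciable share of the guide's total UMI mass. With carrier mean
$\mu_c$, ambient rate $\lambda$ per (cell, guide) and $n$ cells, the
cumulative curve's ambient section has slope proportional to
$c \cdot m/\mathrm{total}$ at ambient count $c$; when the largest
ambient counts exceed the chord slope the knee slides into the
background. In practice this means carriers-per-guide of roughly 50 or
more at ambient rate 0.5 — which is why the simulator's default library
is small (see below).

# Preprocessing

Cells with mitochondrial fraction strictly above 0.20 are removed (a
cell at exactly 20% is retained); genes with total count below 1 —
i.e. all-zero genes — are dropped; clusters holding strictly fewer than
1% of cells are discarded. Both cell and gene filters are computed on
the input matrix, so their application order is immaterial. Three
layers are kept: raw counts; $\ln(1 + x)$; and a per-gene standardized
layer with zero mean and unit *population* variance (divide by $n$),
constant genes set to all-zero. No library-size normalization is
applied by default — the procedure operates on the counts as given —
but `makeLayers(..., normalize = "median")` provides the common
median-total scaling for users who want it.

# sgRNA quality filtration

**Stage 1 — NT debiasing.** Each NT guide's cluster distribution is
tested against the pool of cells carrying any retained NT guide
(hypergeometric, both tails, every cluster). P-values are Bonferroni
corrected over clusters × 2 tails × number of NT guides; the most
significant flagged guide is removed and the pool retested, stopping
when nothing is flagged or only two NT guides remain.

**Stage 2 — combination filter.** For a target with $k \ge 2$ guides,
every non-empty guide subset (ordered by size, then lexicographic guide
ids) is pooled and tested against the NT background per cluster, giving
$2 \times |\mathrm{clusters}|$ p-value lists, each sorted ascending
(ties keep enumeration order; subsets with no cells get $p = 1$ so they
cannot sort left). A cutoff is drawn at $2^{k-1}$ — the number of
subsets containing any fixed guide — and each guide's membership count
among the top-cutoff subsets is scored with the tail
$P(X \ge \mathrm{count})$, $X \sim \mathrm{Hypergeom}(2^k - 1, 2^{k-1},
2^{k-1})$. A guide is flagged by a list only if it is the *only*
significant guide there; the union of flags forms the removal set
unless it exceeds half the guides, in which case all are kept.

**Why the default applies a correction.** The subset p-values of one
target are strongly dependent — every subset containing a guide shares
that guide's cells — so under pure exchangeability the guide with the
largest random deviation tends to monopolize the top of a list even
though its underlying p-values are unremarkable: empirically the
per-list maximum membership count equals its ceiling $2^{k-1}$ about
20% of the time at $k = 4$ with 200 cells per guide, orders of
magnitude above the urn model's prediction. An unadjusted per-list
threshold therefore strips guides from a large fraction of perfectly
healthy targets. The default (`method = "corrected"`) does two things:
it Bonferroni-corrects the count test across the lists, and it requires
the flagged guide's most significant subset in that list to pass
$\alpha / (n_\mathrm{lists} \cdot n_\mathrm{combos})$ — i.e. genuine
distributional signal, not a noise-ordered monopoly. With four
clusters this keeps the null removal rate at the percent level while
removing a genuinely biased guide (3-fold state-odds shift, 200 cells)
essentially always. The literal unadjusted reading remains available
as `method = "literal"`. A corollary of the correction: with eight
lists a $k = 3$ target cannot clear the bar (its smallest attainable
count-test p is $1/35$), so three-guide targets are effectively exempt
from stage 2; the filter is designed for $k \ge 4$, and screens
typically carry 4–16 guides per element.

# Perturbation statistics

**State enrichment/depletion.** For a target with cell set $T$ and NT
background $B$ (cells carrying both a targeting and an NT guide count
as target cells and are excluded from $B$, so the urn never
double-counts), the urn is $N = |T| + |B|$ with $K$ cells in the
cluster, of which $k$ are target cells out of $n = |T|$. Depletion is
$P(X \le k)$ and enrichment the inclusive tail $P(X \ge k)$, so
$p_\mathrm{enrich} + p_\mathrm{deplete} = 1 + P(X = k)$ exactly. The
exclusive tail $P(X > k)$ — the literal survival function, which
understates enrichment evidence at the observed count — is also emitted
as `p_enrich_exclusive`. Screen-level reports carry unadjusted
p-values plus a BH-adjusted column.

**Pseudotime shift.** Mann–Whitney U on pseudotime ranks, exact
enumeration when both groups have ≤ 8 tie-free observations and the
continuity- and tie-corrected normal approximation otherwise, reported
with the median rank difference. Two-sided is the default; directional
power analyses use `alternative = "less"`. The worst-case disagreement
between the corrected normal approximation and the exact distribution
at $n_1 = n_2 = 8$ is 0.011 in p-value units.

**Gene sets and the resampling Z-test.** State signatures are defined
by pairwise Wilcoxon rank-sum between two states with BH control at
0.05, split by sign of the mean log-layer difference; per-cluster
marker lists take the top 100 one-vs-rest genes and drop genes shared
between clusters' lists. For a perturbation's effect on a signature,
the observed statistic is the mean over perturbed cells of the per-cell
signature mean (log layer); the null resamples, without replacement,
equally many cells from the NT pool `nIter = 1000` times;
$z = (\mathrm{obs} - \hat\mu_0)/\hat\sigma_0$ with
$p_\mathrm{deplete} = \Phi(z)$ — the coherent direction mapping (low
expression ⇒ negative z ⇒ small depletion p). A zero null sd is
reported as degenerate rather than inventing a p-value. The test is
calibrated when the perturbed set is drawn from the pool itself; note
that resampling from a *disjoint* pool slightly overdisperses z (the
finite-population correction differs), which is inherent to the
original design of sampling controls from a fixed NT population.

**Bulk validation.** Time-course fold changes use
$(\mathrm{RPKM}_t + \varepsilon)/(\mathrm{RPKM}_0 + \varepsilon)$ with
$\varepsilon = 0.1$ RPKM (configurable), averaged over a gene set per
time point.

# Enhancer prioritization

ATAC peaks are merged (overlapping or bookended) and each merged
interval is replaced by a 500 bp window centered on the floor of its
midpoint, clipped at coordinate 0 (and flagged when clipped).
H3K27ac enrichment is
$\log_2((\mathrm{RPKM}_\mathrm{chip} + c)/(\mathrm{RPKM}_\mathrm{input}
+ c))$ with $c = 0.5$ RPKM by default, RPKM being
count/(width$_\mathrm{kb}$ × library$_\mathrm{millions}$). The gates
are: maximum enrichment across time points strictly greater than
$\log_2 1.5$; base-to-base distance (0 when overlapping) to the nearest
variant at most 1 kb; distance to the nearest gene *body* at most
100 kb. Strict ">" at the activity gate versus inclusive "≤" at the
distance windows mirrors the respective "greater than" and "within"
conventions. Coordinates are 0-based half-open at file boundaries
(BED) and 1-based inclusive internally (GenomicRanges); distances
reported to the user are base-to-base, i.e. GenomicRanges gaps plus one
for disjoint ranges.

# The synthetic generator

`simulateScreen()` draws, per cell: Poisson(MOI = 0.3) carried guides
(cells with none are later dropped by assignment, as in a real screen);
a state from baseline proportions (0.25, 0.30, 0.25, 0.20 across
progenitor/early/mid/late — a mid-differentiation snapshot in which no
state dominates) with odds multiplied by the effect-table entries of
carried targets; unique integer pseudotime ranks ordered by state with
uniform jitter inside each state; guide UMIs as negative binomial
(mean 50, size 10) for carriers plus Poisson(0.5) ambient background in
every cell; negative-binomial expression (size 2) with 5× elevated
state markers, target genes repressed by 80% in carrier cells,
mitochondrial counts matching a clipped-normal per-cell fraction
(mean 0.05, sd 0.03); and hashing tags with one dominant tag per cell
plus a 5% doublet rate. Identical config and seed give bit-identical
output.

Two deliberate scaling choices. First, the default library is 2
targets × 3 guides + 5 NT: what the knee caller experiences is
carriers-per-guide, so a desk-scale screen must preserve that ratio
(~55 carriers/guide at 2000 cells, versus roughly 200 in a full-size
screen) rather than the guide count. Second, the ambient rate 0.5 per
(cell, guide) is a deliberately heavy background that forces a visible
knee; real CROP-seq libraries are usually cleaner.

What the generator does *not* emulate — and hence what green tests do
not establish about real data: no barcode sequencing errors or
guide-identity swapping, no cell-cycle or batch structure, no
doublet transcriptomes (hashing doublets get two tags but one
expression profile), independent ambient counts rather than a shared
ambient pool, and state labels drawn from the true model rather than
inferred by clustering (so label noise is absent). Results on real
screens depend on upstream clustering/pseudotime quality in ways these
tests cannot probe.

# Validation suite sizes

The test suite and `scripts/acceptance.R` exercise: exhaustive
hypergeometric enumeration for all urns up to $N = 30$ (tests) /
$N = 18$ (script); 10,000 (tests) / 3,000 (script) random knee curves
against a brute-force chord search; guide-call recovery on a
2000-cell screen; 500 null targets for flag-rate calibration; 2000
(tests) / 500 (script) null replicates for Z-test uniformity; 100
replicates each for depletion power and guide-QC operating
characteristics; a 2000–3000-region random genome against an all-pairs
distance scan; and byte-identity of two 500-cell pipeline runs. These
sizes were chosen so the whole suite completes in a couple of minutes
on one CPU while keeping Monte-Carlo error well inside the asserted
margins.

# Known limitations

* The combination filter has no resolution below $k = 4$ under the
  corrected default, and at $k = 4$ its retention of unbiased guides is
  bounded by the dependence structure of the subsets, not by sample
  size.
* The resampling Z-test inherits the finite-pool overdispersion noted
  above when the perturbed set is disjoint from the control pool.
* Pseudotime is consumed as given (ranks); the package neither infers
  trajectories nor propagates pseudotime uncertainty.
* The enhancer chain stops at the automated gates; literature-based
  curation of candidate lists is out of scope.
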