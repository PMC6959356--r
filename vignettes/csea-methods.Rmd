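---
title: "Cell set enrichment analysis: model, null models, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell set enrichment analysis: model, null models, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cluster-based differential abundance testing asks whether a *cluster* changes
in frequency between conditions. Many disease-associated shifts do not
respect cluster boundaries: a transcriptional program (say, a T follicular
helper signature) can rise in a *subset* of cells that is scattered across
clusters. CSEA (cell set enrichment analysis) addresses this directly. Cells
are ranked by a per-cell signature score, and the test asks whether the cells
of one condition (the set $S$, e.g. the disease group) concentrate at one
extreme of that ranking. No clustering is involved, and the test
simultaneously reports *which* cells drive the enrichment (the leading-edge
subset).

## Per-cell signature scores

Scores are computed from a library-normalized log expression matrix. Each
cell profile is first centered and scaled across genes (z-scored); for a
signature with positive gene set $G^+$ and optional negative set $G^-$, the
score of cell $j$ is

$$ r_j \;=\; \frac{\sum_{g \in G^+} z_{jg} \;-\; \sum_{g \in G^-} z_{jg}}
              {|G^+| + |G^-|}. $$

Two conventions are ours to fix and are therefore worth stating:

* **Population SD.** Per-cell scaling uses the divide-by-$n$ standard
  deviation. Downstream properties only need self-consistency; the
  population form makes the all-genes signature score identically zero,
  which is a convenient internal check. A zero-variance cell profile is an
  error naming the cell, not a silent NaN.
* **Present-gene denominator.** The denominator counts only signature genes
  present in the matrix, not the nominal signature size, so scores remain
  comparable across datasets with different gene coverage. Dropped genes are
  reported in a warning so heavy attrition is visible.

Because of per-cell centering and scaling, scores are invariant to any
per-cell affine transform $a x + b$ ($a > 0$) of the input, and swapping
$G^+$ and $G^-$ negates every score. `score_signatures()` computes per-cell
moments over *all* genes but z-scores only the union of signature genes, so
sparse inputs are never fully densified.

## The enrichment score

Let cells be ranked $r_1 \ge r_2 \ge \dots \ge r_N$ (descending for the high
tail; the low tail is tested by re-ranking ascending, via
`direction = "low"`). With $N_H = |S|$ and weight exponent $p \ge 0$, define

$$ P_{\mathrm{hit}}(i) = \frac{\sum_{j \le i,\, j \in S} |r_j|^p}
        {\sum_{j \in S} |r_j|^p}, \qquad
   P_{\mathrm{miss}}(i) = \frac{\#\{j \le i : j \notin S\}}{N - N_H}, $$

$$ \mathrm{ES} = \max_i \left( P_{\mathrm{hit}}(i) - P_{\mathrm{miss}}(i) \right). $$

The difference is zero at $i = N$, so $0 \le \mathrm{ES} \le 1$, with
$\mathrm{ES} = 1$ exactly when all of $S$ precedes its complement. At
$p = 0$ the ES is the one-sided Kolmogorov–Smirnov statistic comparing the
two groups' rank distributions (`ks_statistic()` recomputes this
independently by direct CDF counting, and the equivalence is exercised
exhaustively in the tests). At $p = 1$ (the default) set members are weighted
by score magnitude, down-weighting low-magnitude cells in $S$ while all
non-members count equally.

Numerical conventions:

* **Ties in scores** are broken by ascending cell identifier, making the
  ranking — and hence the ES — deterministic. With heavy ties the ES depends
  on the arrangement only through this deterministic tie-break; this is a
  documented caveat rather than a hidden source of variation. Weights always
  use the cell's own $|r_j|^p$.
* **Ties in the running maximum** resolve to the smallest rank, giving the
  most conservative (smallest) leading edge.
* $|r_j|$ is used as written, so negative scores contribute positive weight.
* If every member of $S$ scores exactly zero and $p > 0$, the hit
  normalization is degenerate and the function errors rather than returning
  0/0.

The **leading edge** is the set of cells at ranks $1..i^*$ where $i^*$
attains the maximum; the **leading-edge subset** is its intersection with
$S$ — the core cells driving the enrichment, and the quantity bounded in the
screening filter below.

## Null models and screening

**Label permutation.** Condition labels are shuffled across cells 100 times
(group sizes preserved) and

$$ p = \frac{\#\{b : \mathrm{ES}_b \ge \mathrm{ES}_{\mathrm{obs}}\}}{B}. $$

The raw fraction can be exactly zero; `pseudo_count = TRUE` switches to
$(k+1)/(B+1)$ when a strictly positive estimate is preferred. We use the
standard exceedance convention (large observed ES relative to the null is
significant); under the null the p-value is uniform up to the $1/B$
permutation-grid discreteness, which the calibration tests verify.

**Expression-matched control genesets.** A signature can rank cells merely
because its genes are highly expressed. The control replaces each signature
gene with one of its `pool_size = 20` nearest neighbors in mean expression
(computed on the normalized log matrix over all cells), sampled uniformly,
*without replacement* across the output set — a multiset geneset would be
ill-defined for scoring — and mirroring the positive/negative structure.
Original signature genes are excluded by default. Screening uses one matched
set per signature; `geneset_null_pvalue()` runs the 1000-set validation
version, reporting the fraction of control ES at least as large as the true
ES. `match_sensitivity()` quantifies how much the matching stringency
matters: tight pools give the least variable control ES, fully random sets
the most.

**Screening filter.** Across a signature collection, Benjamini–Hochberg
correction is applied separately within the true-signature and
control-geneset p-value families, and a signature is retained when all three
hold: corrected true $p < 0.05$, corrected control $p > 0.05$, and leading
edge $< 1000$ cells (all strict). The last condition discards diffuse
enrichments involving most of the dataset, which are better captured by
cluster-level composition tests.

## Simulation scheme A: Gaussian-mixture cell states

`simulate_gaussian()` draws control-cell states from $N(5, 1)$ and each case
cell, independently with probability `outlier_frac`, from an outlier
component $N(\mathrm{mean2}, 1)$ (otherwise from the control component).
Because the component SD is 1, `mean2 - 5` is the separation in SD units.
Per-cell Bernoulli mixing is the default reading of "a proportion drawn
from"; `fixed_outlier_count = TRUE` provides the fixed-count alternative,
and the realized outlier count is recorded per replicate either way.

## Simulation scheme B: counts driven by a latent state

`simulate_counts()` emulates a continuous-trajectory single-cell experiment
with an explicit negative-binomial model rather than wrapping an external
simulator, so every parameter is visible in `count_sim_spec`:

* each cell's latent state $z$ is a draw from the scheme-A mixture (these
  draws double as the rank-matching reference);
* gene $g$ has $\log \mu_{jg} = b_g + \ell_g (z_j - 5)$ with baseline
  $b_g \sim N(1, 0.5)$ — mean counts around 3, typical of shallow
  droplet-based data — loading $\ell_g = 0.5$ for the 10% of genes that are
  differentially expressed along the trajectory and 0 otherwise, and
  counts $\sim \mathrm{NB}(\mu_{jg}, \text{size} = 10)$;
* counts are normalized to the median library size and log1p-transformed;
* each cell is scored on the DE-gene signature (after per-cell z-scoring),
  and case/control labels are transferred from the reference by rank:
  the $i$-th ranked count cell inherits the label of the $i$-th ranked
  reference cell (`rank_match_labels()`).

With these defaults the DE-gene score recovers the latent state at Spearman
correlation above 0.9, which the tests check before any power claims are
made. The generator deliberately omits batch effects, zero inflation beyond
NB sampling, and multi-lineage structure: passing power and calibration
tests under this model shows the *statistic* behaves as designed when a
recoverable continuous state exists, not that any real dataset satisfies
those assumptions.

## Power evaluation and detection thresholds

`power_grid()` scans mean separation × outlier fraction, running each
replicate through the full scoring → ranking → ES → permutation pipeline and
recording rejection at raw $p < 0.05$ (one signature at a time, so no
multiplicity correction). Conventions we fixed where the design was open:

* **Fraction axis units.** Detection limits are quoted as the outlier share
  of the **total** population (both groups pooled) — the scale on which such
  limits are naturally compared; with equal group sizes a total share $f$
  corresponds to a per-case-cell outlier probability $2f$.
  `fraction_of = "case"` passes the case-group proportion directly.
* **Detection criterion.** A grid cell "detects" when more than 50% of its
  replicates reject; the threshold along an axis is the smallest scanned
  value that detects *and* keeps detecting at every larger scanned value
  (`Inf` when never stably reached; isolated interior detections trigger a
  warning).
* **Seeding.** Replicate $r$ of grid cell $(i, j)$ uses a seed derived
  deterministically from the master seed and $(i, j, r)$, so cells are
  independently reproducible and the whole table replays exactly.
* **Problem sizes.** The validation runs use 1000 cells per group for the
  Gaussian scheme, 300 cells per group × 500 genes for the count scheme,
  20 replicates per grid cell, 100 permutations, fractions
  $\{1,2,3,4,5,6,8,10,12\}\%$ and separations $\{0, 0.5, 1, 1.5, 2, 3\}$ SD.
* **Null calibration** uses `mean2 = mean1` (scheme A) or zero DE loadings
  (scheme B) and compares the p-value ECDF to uniform with an allowance of
  $1/B$ (permutation discreteness) plus $1.36/\sqrt{R}$ (KS sampling noise
  at $R$ replicates).

```{r example}
library(csea)
grid <- power_grid(separations = 2,
                   fractions = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06),
                   replicates = 20, scheme = "gaussian", seed = 1)
grid$power
detection_threshold(grid, "fraction")
```

## Known limitations

* The ES tests one tail per run; signatures enriched at the low extreme need
  a second run with `direction = "low"`. No signed or normalized ES across
  signatures is defined.
* Permutation resolution is $1/B$; with $B = 100$ the smallest nonzero
  p-value is 0.01, which matters when screening large signature collections
  at strict FDR levels.
* Heavy score ties make the leading edge depend on the identifier tie-break.
* The matched-geneset control conditions on mean expression only; variance
  or detection-rate matching is not implemented.
* The count simulator's NB model is a deliberate simplification of real
  droplet data (no ambient RNA, doublets, or batch structure); thresholds
  estimated under it transfer to real data only to the extent those effects
  are secondary.
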