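---
title: "Detecting pivot genes in co-expression networks on a PPI scaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pivot genes in co-expression networks on a PPI scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivotnet)
```

## The procedure

`pivotnet` implements a network-based definition of *pivot genes*:
genes that are not members of any co-expression module themselves but
whose interaction partners concentrate inside one or more modules, so
that they plausibly mediate crosstalk between functional programmes.
The pipeline runs in five stages.

1. **Expression preparation.** Counts are normalised to transcripts
   per million, $\mathrm{TPM}_i = 10^6 \cdot (c_i/\ell_i) \big/ \sum_j
   (c_j/\ell_j)$, and a gene counts as *expressed* if its TPM is
   strictly above 1 in strictly more than 50% of the replicates of at
   least one developmental stage.  For array data the package also
   provides detection-p filtering, quantile normalisation and
   collapsing of multi-probe genes to the probe with the highest mean
   intensity.
2. **Co-expression network.** For every protein--protein interaction
   $(g_1, g_2)$ whose genes are expressed, the Pearson correlation $r$
   of the two expression profiles is computed across *all* samples,
   with the exact two-sided p-value from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom.
   Benjamini--Hochberg adjustment runs over all tested interactions and
   edges with $q \le 0.01$ are kept, each annotated as correlated or
   anti-correlated.
3. **Modules.** The retained graph is clustered with a native
   implementation of the Markov cluster algorithm (expansion 2,
   inflation 2, self-loops of weight 1, pruning at $10^{-5}$).
   Clusters of at least 10 genes with at least one GO biological
   process enriched at BH $q \le 0.05$ (one-sided hypergeometric test)
   become *functional modules*.
4. **Hubs and pivots.** Genes outside every functional module with
   degree $\ge 10$ in the co-expression network are *inter-modular
   hubs*.  For each hub with degree $d$ and each module of size $K$ in
   a network of $N$ nodes, the probability that $k$ or more of its $d$
   neighbours fall inside the module under neighbour sampling without
   replacement is $P(X \ge k)$ with
   $X \sim \mathrm{Hypergeom}(N - 1, K, d)$; hubs with $p \le 0.05$
   for at least one module are reported as pivots, together with the
   correlated/anti-correlated breakdown of their edges into each
   module.
5. **Differential expression and overlap.** Stage contrasts use a
   two-sample t-test (Welch by default) with the dual MAQC-style rule:
   significant iff BH $q < 0.05$ *and* linear fold change $> 1.4$,
   both strict.  Gene lists from several conditions are summarised by
   exact Venn set algebra, cross-dataset overlaps rank shared
   significant genes by their worse adjusted p-value, and small
   validation statistics (ddCt relative expression, two-group
   chi-square on abnormality proportions) round out the toolkit.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| TPM threshold / replicate fraction | 1 / 0.5 | expressed-gene rule, both strict inequalities |
| edge `q_cutoff` | 0.01 | BH-adjusted PCC significance for network edges |
| MCL inflation / expansion / loop weight / pruning | 2 / 2 / 1 / $10^{-5}$ | canonical defaults of the original algorithm |
| `min_module_size` / enrichment `q_cutoff` | 10 / 0.05 | functional-module rule |
| hub `min_degree` | 10 | "interacts with at least ten genes" |
| pivot `p_cutoff` | 0.05 | raw hypergeometric p (a BH option exists, off by default) |
| DE `q_cutoff` / `fc_cutoff` | 0.05 / 1.4 | dual significance rule, both strict |

Design choices where the procedure was genuinely open:

* **Correlation scope.** PCC is computed across all samples pooled
  over stages, not per stage: modules are meant to capture genes that
  co-vary across the developmental trajectory, and pooling is what
  makes stage-covarying modules cohere.
* **Correlation scale.** The network stage correlates the expression
  matrix exactly as supplied (the pipeline feeds TPM); no internal log
  transform is applied there.  The DE t-test, in contrast, runs on
  `log2(x + 1)` for variance stabilisation while fold changes stay on
  the linear scale, where the 1.4 rule is defined.
* **Pivot test universe.** The hypergeometric universe for pivots is
  the whole network minus the hub itself (sampling neighbours without
  replacement), not the union of module members; neighbours, not
  edges, are counted, and the test is one-sided upper tail
  ("significantly *more* interactions").
* **Multiplicity for pivots.** Raw $p \le 0.05$ per hub--module pair
  is the default, matching the stated selection rule; BH adjustment
  across all pairs is available behind a flag.
* **Detection-filter polarity.** Array QC descriptions of the form
  "exclude unexpressed probes if detection $p \le 0.05$" are
  internally contradictory; the package defaults to the conventional
  Illumina reading (keep probes *detected* at $p < 0.05$ in at least
  one sample) and exposes the literal polarity behind
  `keep_detected = FALSE`, without guessing intent.
* **t-test variant.** Welch is the default everywhere (robust to
  unequal variances at tiny $n$); Student's pooled-variance test is
  available where a protocol prescribes it.
* **MCL edge weights.** Clustering runs on the unweighted retained
  graph by default; the significance threshold already selects edges,
  and $|r|$ weighting is available behind a flag.

## The synthetic generator

All tests run against `generate_stage_expression()` and its
companions, which emulate a seven-stage preimplantation design
(oocyte, zygote, 2-cell, 4-cell, 8-cell, morula, blastocyst; three
replicates per stage).  The generative model is deliberately minimal:
each planted module has one latent per-stage profile (Gaussian, shared
by replicates of a stage); member genes are the profile scaled by the
module's strength plus i.i.d. log-scale noise, exponentiated to
non-negative abundances.  This makes the within-module correlation
structure controllable in closed form -- at zero noise the pairwise
PCC is exactly 1 -- while background genes carry independent private
profiles.  Planted pivots are background genes coupled (with
alternating sign, mirroring correlated and anti-correlated crosstalk)
to one target module's profile; planted DE genes have their own latent
difference between the contrast stages removed before the requested
log2 fold change is added, so the planted effect is the only
systematic difference.  The PPI generator wires module cliques at
probability 0.9, pivots as degree-12 hubs with 10 edges into their
target module, and background pairs at probability 0.01; the GO
generator interpolates linearly between exact module annotation and
module-independent noise.

What the generator does *not* emulate: probe-level array structure,
sequencing depth and count dispersion, correlated noise between
samples, GO-term hierarchy (annotations are flat), or the scale of a
genome-wide PPI (hundreds of genes, not tens of thousands).  Passing
tests therefore demonstrate the correctness and calibration of the
machinery under a known truth, not performance on genome-scale data.

Default problem sizes -- 200 genes, 21 samples, two 20-gene modules,
three pivots, 20-gene DE plant; the statistical-calibration
simulations use 2,000 null edges and 5,000 null contingency tables --
were chosen so the planted structure is comfortably identifiable
while the whole suite stays interactive on a laptop.

## Numerical choices and degenerate inputs

* $|r| = 1$ maps to $p = 0$ rather than through the $t$ transform
  (which would divide by zero); constant-profile genes are skipped and
  counted, not errors.
* Hypergeometric tails use `phyper` directly; tests verify it against
  an exact integer-arithmetic convolution sum exhaustively for all
  instances with $N \le 30$ (about 87,000 cases; every intermediate
  quantity is an exactly representable integer below $2^{53}$).
* The BH step-up is delegated to `p.adjust` and verified against the
  definition on random vectors.
* A two-sample test with both groups constant returns $t = 0, p = 1$
  when the means agree and $p = 0$ with a warning otherwise; a
  chi-square table with a zero margin is defined as
  $\chi^2 = 0, p = 1$ with a warning.  The continuity correction is
  off by default so the statistic follows its nominal reference
  distribution (the calibration tests check a 5% type-I rate), and a
  flag restores Yates' correction.
* MCL always emits a partition: attractor systems are merged when
  attractors flow into one another, overlap is resolved towards the
  system receiving most of a node's column mass (ties towards the
  cluster with the lexicographically smallest member), fully pruned
  columns are re-anchored on their own node, and non-convergence
  within the iteration cap is a warning.
* Venn arithmetic treats pairwise intersections as *inclusive* of the
  higher-order regions, the convention under which
  $|A \cup B \cup C| = \sum|A_i| - \sum|A_i \cap A_j| + |A \cap B \cap C|$,
  and the fixture generator refuses infeasible requests naming the
  offending region.

## Known limitations

* **Module granularity versus hub attachment.**  At the default
  inflation, MCL assigns every node to the cluster receiving most of
  its random-walk flow.  A hub that sends the majority of its edges
  into a single dense module is therefore absorbed *into* that module
  and, being a member, can no longer qualify as an inter-modular hub.
  Pivots are detectable only in the regime typical of genome-scale
  networks -- sparse attachment relative to module-internal density,
  with a hub's neighbourhood spread over several clusters.  The
  bundled dense synthetic conditions (10 of 12 hub edges into one
  20-gene near-clique) sit squarely in the absorbing regime and
  illustrate this boundary; the unit tests therefore exercise the
  hub/pivot statistics on explicitly constructed topologies where the
  hub genuinely sits outside the modules.
* The pivot statistics assume a simple graph (neighbour counts, not
  edge multiplicities) and take GO annotations as flat labels.
* DE power at three replicates per group is modest and seed-variable:
  under the default noise the planted fold-change-3 genes essentially
  all pass the fold-change arm of the rule, but the BH q < 0.05 arm
  recovers only roughly a quarter to two thirds of them depending on
  the realised replicate noise, with direction always correct -- an
  honest reflection of tiny-n designs rather than a defect.
* The ranking that defines "top" overlapping genes across datasets is
  a documented package choice (worse-of-the-two adjusted p); other
  conventions are exposed via `rank_by`.
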