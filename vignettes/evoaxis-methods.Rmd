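---
title: "Methods: quantifying cell-state position on the evodevo axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell-state position on the evodevo axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoaxis)
```

## The question and the model

Cancer cell populations — in particular polyploid giant cancer cells
(PGCC) and their progeny — can move along a combined ontogenetic
(stemness) and phylogenetic (unicellularity) gradient, the *evodevo
axis*. `evoaxis` quantifies where a cell state sits on that axis from
processed transcriptomes, using gene-level evolutionary annotations:

* the **phylostratum** (ordinal gene age, 1 = cellular organisms …
  17 = Hominidae; strata 1–3 predate multicellularity and define the
  unicellular, UC, gene class; 4–17 the multicellular, MC, class);
* the **multicellularity gene index** (MGI), a family-level deep
  dating: MGI = 1 marks families found only in MC organisms, MGI < 1 a
  deep UC family origin;
* stemness compendium counts (`multi_score`, `pluri_score`,
  `stem_score`; 0 means non-stemness);
* Gene Ontology memberships, closed over `is_a` ancestry so that a gene
  annotated to any subcategory counts for the parent category.

All comparative inference runs on the **per-sample standardized
scale**: each sample column is expressed in standard deviations around
zero (sample SD, denominator $n-1$). This removes between-sample
location and spread differences and makes the per-gene *fold*

$$f_g = \bar z_{g,\text{test}} - \bar z_{g,\text{ref}}$$

a difference of state means in SD units. A difference, not a ratio:
standardized values are negative half the time, and the profile
figures are signed curves around zero. Absolute-level questions (the
per-gene oncofetal comparisons, UC/MC expression ratios, TAI) instead
use multiplicative whole-transcriptome mean normalization, which
preserves relative within-sample expression.

## Analysis of means

The estimator underneath every profile is the analysis of means
(ANOM): each group mean is compared against the grand mean
$\mu = \sum n_i \bar x_i / \sum n_i$ with simultaneous decision limits

$$\mu \pm h \; s \; \sqrt{\frac{k-1}{k\,n_i}},$$

where $s$ is the pooled SD on $\sum(n_i - 1)$ degrees of freedom and
$h$ the two-sided Student-$t$ critical value at $\alpha/(2k)$. The
Bonferroni-adjusted $t$ stands in for Nelson's exact $h$: exact tables
cover a limited range of $k$ and degrees of freedom, the Bonferroni
variant is standard, conservative, and its family-wise error is
verified by Monte-Carlo in the test suite (with $k = 17$, $n = 200$
and $\alpha = 0.05$ the simulated family-wise flag rate sits near
0.045, inside the 0.03–0.07 calibration band the suite asserts).
Groups of size one receive limits but contribute no degrees of
freedom; empty groups are skipped with $k$ reduced accordingly; a
zero pooled variance yields all-`ns` flags with a warning.

## Evolutionary profiles and the three-phase readout

`evolutionary_profile()` bins standardized folds by phylostratum and
fits one ANOM across the occupied bins. `classify_three_phase()` reads
the flag pattern: a **UC shift** needs at least one UC bin (1–3) up
*and* one late-MC bin suppressed (down), with no contradictory flags in
those two zones; an **MC shift** is the mirror; no zone flags at all is
`NONE`, anything else `AMBIGUOUS`. The late zone defaults to strata
12–17 (with 4–11 as the roughly unchanged middle phase, the boundary
chosen from the characteristic three-phase shape of such profiles) and
is configurable.

Two consequences of the standardized scale are worth stating
explicitly:

* Flags are *relative to the grand mean of folds*. When a large gene
  class moves, the unaffected middle strata sit on the other side of
  the grand mean and may be flagged in the opposite direction. The
  classification therefore only inspects the two zones, by design.
* Because standardization subtracts the column mean, a planted shift
  $\delta$ on ~half the genes is recentred: the UC-bin mean fold does
  not equal $\delta_{uc}$ absolutely. The identified estimand is the
  contrast against the unaffected middle strata,
  $\bar f_{ps \le 3} - \bar f_{4 \le ps \le 11} \approx \delta_{uc}$,
  and that is what the recovery tests assert (to ±0.05 over 50
  simulated datasets). A small residual shrinkage (~3% under the
  default conditions) remains because planted effects inflate the
  column SD slightly.

The proliferation control removes the mitotic cell-cycle programme
(propagated GO:0000278 members) before binning; removing genes from a
fixture with no such members leaves the profile bit-identical.

## Signatures, score bins, oncofetal genes

Signature analyses (`signature_fold()`) are two-group ANOMs of member
versus complement within the same fold universe. This realizes an
internal complementary normalization: both sides share the grand mean,
so on the standardized scale a significant rise of a signature forces
a fall of its complement. Shipped signatures: MGI classes (deep-UC
families vs MC-only families), stemness (`stem_score > 0`), and the GO
compartments/functions nucleus, cytoplasm, plasma membrane, signaling
receptor activity, channel activity, gap junction — each resolved by
DAG propagation.

`score_bin_profile()` runs the ANOM across integer stemness-score bins
(bin 0 = non-stemness; scores above the top bin are pooled into it,
default 5).

`oncofetal_compare()` tests each oncofetal gene individually on the
mean-normalized absolute scale with a per-gene Welch $t$ and Bonferroni
correction over the tested set. The per-gene test is a package choice
(any test producing per-gene up/down/ns flags would fit the design)
and is recorded in the result metadata. Requested genes absent from
the data are reported as missing, not failed.

## Interactome centrality, hubs, shells

The protein interactome is an undirected confidence-weighted graph
(self-loops dropped, duplicate edges keep the maximum confidence; the
STRING 0–1000 integer score dialect is auto-detected and divided by
1000). Edge filters are strict: the top-half filter keeps confidence
> 0.5. Shortest paths are unweighted — confidence filters edges, it is
not a distance — and each unordered pair is counted once:

* degree — direct interactants (local);
* stress — $\sum_{s<t} \sigma_{st}(v)$, the raw count of shortest
  paths through $v$ (load);
* betweenness — $\sum_{s<t} \sigma_{st}(v)/\sigma_{st}$ (brokerage);
  betweenness never exceeds stress.

Both global measures come from a single Brandes-style BFS sweep; the
test suite checks them against an exhaustive shortest-path enumerator
on 50 random graphs and cross-checks betweenness against igraph.

`centrality_by_class()` stratifies the upregulated genes into
UC∩pluripotent, UC-only, pluripotent-only and neither
(pluripotent means `pluri_score > 0`) and fits an ANOM per measure;
empty classes are skipped with a warning and $k$ reduced.

A **hub** has more than five interactants — read strictly as degree
≥ 6 — in the network filtered at confidence > 0.7, plus a fold beyond
twofold. On the ratio scale the down rule is the reciprocal
(fold < 1/2); on the standardized scale, where no reciprocal exists,
the down rule is the negated threshold. Hub modules are found by
K-means on each hub's connectivity profile (its row of the
confidence-weighted hub-subnetwork adjacency); the feature space is a
package choice recorded in the output, the seed fixes the assignment,
and the default cluster counts (4 up, 2 down) are configurable. The
**shell** of a seed set is the seeds plus their first neighbors — the
one-step network-propagation neighborhood; shells are expansive
(`shell(shell(S)) ⊇ shell(S)`).

## PCA and the age correlation

`pca_genes()` performs covariance PCA with *genes as observations* and
samples as variables, because the dominant component of processed
expression matrices — the shared between-gene expression hierarchy —
is common to all cell states and is the object whose correlation with
gene age is of interest. Columns are centered, not rescaled; the PC1
sign is fixed so its gene scores correlate non-negatively with mean
expression; both the mean-normalized (default) and standardized input
scales are supported since either is defensible for processed data.
`pc1_age_correlation()` uses Spearman rank correlation — gene age is
ordinal, so only a rank statistic is justified.

## The synthetic study conditions

`synth_config()` defaults emulate a four-state PGCC experiment:
`initial`, `pgcc`, `early_progeny`, `late_progeny`, three replicates
each, 10,000 genes.

* Phylostratum weights follow a decreasing age histogram with the
  three UC strata holding roughly half the genes, matching the shape
  of human shallow gene dating (exact human counts are not
  reproduced).
* Baseline expression is Gaussian on a log2-like scale (mean 8, SD 3 —
  a realistic between-gene spread for processed log-intensity data)
  with a linear age trend of −0.2 per stratum, so older genes are
  expressed higher; replicate noise SD is 1.
* Planted state effects are pairs (δ_uc, δ_mc) in standardized SD
  units: (−0.3, +0.3) for PGCC, (−0.45, +0.45) for the early progeny
  (the multicellularity activation is stronger there), (−0.1, +0.1)
  for the late progeny (partial backward movement). Internally the
  generator multiplies δ by `sqrt(baseline_sd² + noise_sd²)` so that
  the standardized fold recovers δ directly.
* The probability of a deep-UC family (MGI < 1) decreases with the
  stratum; pluripotency scores are Poisson with a 3× enriched mean in
  UC genes; `stem = multi + pluri`; 33 genes are flagged oncofetal.
* The interactome is a core–periphery Bernoulli graph over a 300-gene
  subset: UC–UC pairs connect with `p_core = 0.15`, MC–MC with
  `p_periph = 0.02`, cross pairs with `p_cross = 0.05`, confidence
  uniform on (0.4, 1) — a dense ancient UC center.
* Everything is reproducible bit-identically from the seed, and
  generation restores the session RNG state.

A strictly positive copy (`2^values`) is returned for ratio-scale
paths. The generator does **not** emulate read counts, library-size or
batch effects, dropout, mapping ambiguity, real GO topology, or the
degree distribution of the real interactome — passing recovery tests
demonstrates the statistical machinery under the stated Gaussian
conditions, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Standardization requires length ≥ 2 and positive variance; it is
  idempotent to 1e-12.
* Mean normalization requires positive matrix means (non-negative
  processed values assumed); ratio folds drop zero-reference genes
  with a warning.
* All inequality thresholds (confidence, fold, interactant count,
  flag limits) are strict, matching their definitions.
* Gene identifiers are whitespace-stripped and case-folded; duplicate
  annotation rows keep the first with a warning; genes missing the
  relevant annotation are excluded from that analysis and tallied.
* GO input is either a child/parent TSV or a minimal OBO parse
  (`id`/`is_a` only; other relationship types are ignored); cycles are
  a load error naming an involved term.
* K-means uses 25 random starts under the caller's seed;
  ties elsewhere (e.g. a mean exactly on a decision limit) resolve to
  `ns` because flags require strict exceedance.

The test suite runs the Monte-Carlo checks at fixed sizes chosen to
make sampling error negligible relative to the asserted bands: 2000
null simulations for the ANOM calibration, 100 seeds per recovery
direction (10,000 genes each), 50 seeds for effect-size recovery, 50
random graphs for the centrality oracle.

## Known limitations

* The ANOM variant is Bonferroni-conservative; with many groups its
  realized family-wise error runs slightly below nominal α.
* The three-phase zones (1–3 / 4–11 / 12–17) are a fixed default;
  datasets with different phase boundaries need the configurable
  zones.
* `uc_mc_ratio()` averages per-sample ratios by default; the
  ratio-of-state-means alternative is exposed as an option since
  either averaging order is defensible.
* Phylostratigraphy construction, GO term obsolescence handling,
  enrichment statistics and count-level normalization are out of
  scope; annotations and processed matrices are consumed as given.
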