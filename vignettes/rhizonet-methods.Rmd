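---
title: "Methods: co-occurrence networks, complexity indices and path models for halophyte rhizospheres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, complexity indices and path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the
numerical decisions a reader would otherwise have to reverse-engineer
from the code.

## The study system

Three halophytes of a desert-steppe salt marsh — *Kalidium cuspidatum*
(KC), *Nitraria tangutorum* (NT) and *Reaumuria soongarica* (RS) — shape
chemically distinct rhizospheres: KC concentrates salt (pH, Na⁺, K⁺)
while RS accumulates carbon, available nitrogen and microbial biomass.
The analysis chain asks how these microenvironments structure bacterial
(16S) and fungal (ITS) communities, whether bacterial–fungal
co-occurrence networks differ in complexity across hosts, and how soil
properties, diversity, dominant taxa and network complexity relate
causally. Sample sizes are small by design: six composite samples per
plant, which drives most of the statistical choices below.

## Soil metrics

Microbial biomass C/N/P comes from chloroform fumigation–extraction:
`(fumigated − non-fumigated) / k`, with efficiency coefficients
k\_C = 0.45, k\_N = 0.54, k\_P = 0.40 (the fractions of microbial C, N, P
rendered extractable by fumigation). Negative differences are physically
questionable but real data contain them; they are returned with a
warning, never truncated, so downstream summaries see the data as
measured.

Group comparisons use one-way ANOVA with Tukey HSD and a compact letter
display at α = 0.05 (the conventional companion of letter displays; the
letters are assigned by the insert–absorb algorithm, ordered so the
largest mean is always "a"). The display satisfies, and the tests check,
the two-way consistency property: groups share a letter **iff** their
Tukey p exceeds α.

## Diversity

* **Shannon** uses natural log (nats) by default, with a `base` switch,
  since conventions differ between toolchains.
* **ACE** splits species at the canonical rare threshold of 10,
  extrapolates the rare group through its sample coverage
  C = 1 − F₁/N_rare and a coefficient-of-variation term floored at 0.
  When every rare individual is a singleton, C = 0 and the estimator is
  undefined; we fall back to bias-corrected Chao1 and flag the switch in
  the output rather than returning infinity.
* **No rarefaction by default.** Whether tables should be rarefied before
  diversity and network analysis is an unsettled question in amplicon
  work; `rarefyTable()` (seeded, without replacement) is provided for
  users who want it, and all downstream functions are agnostic.
* **NMDS** wraps vegan's monoMDS/metaMDS machinery (Kruskal stress-1,
  monotone regression, random restarts, centred coordinates). The
  dissimilarity is Bray–Curtis — not dictated by any single convention,
  but the standard companion of NMDS for community data — and the output
  records it. An all-tied dissimilarity matrix carries no rank
  information: under primary tie treatment any configuration fits, so
  the function flags the input as degenerate and returns a zero-stress
  placeholder instead of pretending to optimise.
* **Ordination significance.** Stress itself has no p-value; group
  separation is tested by a PERMANOVA-style pseudo-F (vegan::adonis2,
  999 permutations by default) and reported alongside the stress.
* **Mantel tests** are implemented directly (rank correlation of
  lower-triangle vectors, rows/columns of the second matrix permuted
  jointly, one-sided p = (1 + #{r\* ≥ r}) / (n_perm + 1)), with an
  `exact = TRUE` mode that enumerates all n! relabelings — used both for
  small designs and as its own verification path. Spearman is the
  default correlation, matching the package-wide reliance on rank
  statistics.

## Small-sample Spearman inference

Almost every inferential step in the chain is a Spearman correlation at
n = 6. The t-approximation for Spearman's ρ is poor there, so
`spearmanTest()` enumerates all n! rank permutations whenever n ≤ 7
(720–5040 arrangements) and reports the exact two-sided p — the fraction
of permutations whose |ρ| reaches the observed one, observed arrangement
included, so p ≥ 1/n!. Above n = 7 it switches to the t-approximation
with tie-corrected ρ (Pearson correlation of mid-ranks).

One consequence worth knowing: the exact two-sided test at n = 6 is
discrete, and its largest attainable level below 0.05 is 24/720 ≈ 0.033.
A perfectly calibrated analysis therefore rejects at ~3.3%, not 5%, at
this sample size; calibration checks should (and ours do) treat that as
correct behaviour, not miscalibration.

## Driver attribution

* **Dominant taxa**: phyla with mean relative abundance > 1%; the ten
  most abundant genera, ties at rank ten broken lexicographically and
  recorded in the output for provenance.
* **Random forest**: the ambiguity of "taxa explain physicochemical
  variation" is resolved by modelling each dominant taxon's abundance as
  the response and the environment as predictors — the construction that
  yields one percent-explained value per taxon. Percent explained is the
  out-of-bag pseudo-R² × 100 floored at 0 (the output records the
  unfloored value too); significance comes from refitting under response
  permutation. The reverse direction is available by swapping arguments.
* **Variation partitioning** Hellinger-transforms the (compositional)
  abundance matrix before redundancy analysis, then decomposes adjusted
  (Ezekiel) R² into unique and shared fractions of the physical
  {pH, SWC, EC, Na, K}, chemical {TC, TOC, TN, TP, AN, OP} and biomass
  {MBC, MBN, MBP} sets. The membership is a configurable default — no
  universal definition exists. Individual fractions may legitimately be
  negative; all seven plus the residual sum to 1.
* **Heatmaps** report raw Spearman p by default (significance stars on
  such figures conventionally reflect unadjusted p); Benjamini–Hochberg
  is a flag away.

## Co-occurrence networks

Edges require |ρ| > 0.9 **and** p < 0.01 over all OTU pairs, within and
between kingdoms, computed on relative abundances (counts and rarefied
counts are accepted and converted; which scale the correlations "should"
use is genuinely underdetermined, and Spearman is only invariant to
within-sample monotone rescaling). A prevalence filter (present in ≥ 3
samples, configurable) precedes testing: with six samples, pairs
dominated by zeros otherwise produce spurious perfect correlations.
Isolated nodes are dropped.

Topology follows the conventions that make the metrics comparable to
published network tables:

* **Edge lengths** default to 1 − |ρ| so stronger correlations are
  shorter; published non-integer network diameters imply weighted path
  computations. Unit and 1/|ρ| schemes are selectable.
* **Average path length / diameter** are computed over connected pairs
  only (disconnected pairs are excluded, not infinite).
* **Modularity** uses greedy agglomerative (CNM) maximisation on the
  unweighted graph — deterministic, no seed. The reported Q is evaluated
  on the partition actually returned (igraph's stored optimum can
  disagree with its returned membership on small graphs; we report the
  partition's Q so the number is verifiable against the membership).
* **Betweenness centralization** is Freeman's index on unweighted
  betweenness, normalised by the star-graph maximum (a star scores 1).
* Density and transitivity are unweighted.

Every metric is verified in the test suite against independent
brute-force oracles (Floyd–Warshall distances, shortest-path enumeration
for betweenness, triple counting for transitivity, direct evaluation of
Q) on hundreds of random graphs of ≤ 15 nodes.

**Subnetworks.** A sample's subnetwork is the induced subgraph on the
OTUs present (count ≥ 1 by default) in that sample, edges inherited from
the parent network built on the sample's group. Networks are built per
plant group over that group's six samples.

## Network complexity index

The NCI is the first principal component of the per-sample subnetwork
parameter matrix {nodes, edges, density, transitivity, diameter, average
path length}: columns z-scored, PCA by SVD, all samples of all groups
pooled into a single decomposition (one ordination, not one per group —
scores must be comparable across groups). Constant columns are dropped
with a warning; samples with missing parameters (e.g. an empty
subnetwork has no diameter) are dropped with a warning. PC1's sign is
arbitrary, so it is reflected to correlate positively with the edge
count: "higher NCI = more complex" is then stable across runs and
machines. Group comparisons reuse the ANOVA letter display; dominant
phyla are regressed on the NCI by OLS with a two-sided slope test.

## PLS path modeling

`fitPlspm()` is a from-scratch Lohmöller estimator. Indicators are
standardized; outer weights start equal; each iteration (i) forms every
latent as the weighted sum of its indicators, standardized to unit
variance, (ii) computes inner weights under the chosen scheme — centroid
(default, the long-standing convention): sign of the correlation between
connected latents; factorial: the correlation; path: regression
coefficients for predecessors, correlations for successors — and
(iii) updates outer weights in mode A (reflective blocks),
weight = cor(indicator, inner proxy). Convergence is declared when the
largest outer-weight change falls below 10⁻⁷ (maximum 300 iterations;
non-convergence is an error carrying the last delta, not a silent
result). Isolated blocks use their own latent as proxy, which turns the
mode-A update into a power iteration towards the block's first principal
axis. After convergence each latent is oriented so the sum of its
loadings is positive — making the solution invariant to sign flips of a
minority of indicators (with two near-equal indicators the majority is
undefined and the orientation is a coin decided by the data). Structural
coefficients are then OLS of each endogenous latent on its predecessors,
with per-block R².

The bootstrap resamples rows, refits, aligns each replicate's latent
orientations to the full-sample solution by the sign of the loading
inner product (otherwise sign-flipped replicates create artifactual
bimodality), and reports percentile CIs plus a two-sided normal p from
the full-sample coefficient over the bootstrap SE. More than 20% failed
replicates is an error.

**Attenuation.** Mode-A composites are not the latents: paths are
attenuated by roughly the block reliability. With loadings of 0.9,
three-indicator blocks leave ≈ 8% downward bias on a path of 0.6; six
indicators shrink the bias to ≈ 4%. The parameter-recovery benchmarks
use six indicators per block for this reason, and users comparing fitted
paths to a structural model simulated on true latents should expect the
same shrinkage.

**Default inner model.** Blocks: physical {pH, SWC, Na, K}, chemical
{TC, TOC, TN, TP, AN, OP}, biomass {MBC, MBN, MBP}, diversity (bacterial
and fungal Shannon + ACE), dominant phyla (caller-chosen abundance
columns), network complexity (NCI). Nine arrows: physical → chemical,
biomass, diversity; chemical → biomass, diversity; biomass → complexity;
diversity → dominant phyla, complexity; dominant phyla → complexity. The
exact arrow set of any particular study cannot be recovered from prose;
the spec object, not the code, is the source of truth, and
`plspmSpec()` accepts any acyclic alternative.

## Synthetic data: what it emulates, what it does not

* **Soil.** Each variable is drawn per group from
  Normal(mean, SE·√6) truncated at zero *by resampling* (clipping would
  pile mass at zero), with the bundled reference means ± SE of the three
  halophyte rhizospheres as defaults and n = 6 per group. Fumigation
  extract pairs are constructed as baseline + k·biomass so the biomass
  formulas recover the drawn MBC/MBN/MBP exactly — the generator is
  invertible by design. The original field design pooled three cores per
  composite sample; that compositing is emulated only through the SE
  convention, not explicitly.
* **OTU tables.** Latent log-abundance = per-OTU baseline + planted
  block signal + Gaussian noise; counts are multinomial per sample and
  kingdom on the softmax of the latent row, with log-normal library
  sizes (median 3 × 10⁴). A block is a set of OTUs sharing one standard
  normal factor with per-member signs and a strength in [0, 1];
  same-sign members co-vary positively, opposite-sign negatively, and
  the truth table lists exactly the within-block pairs with product
  signs. Defaults: 120 bacterial + 60 fungal OTUs with baseline spread
  2.5 log units — wide enough that low-baseline OTUs drop in and out of
  individual samples. That sparsity is essential: with a narrow baseline
  every OTU is present in every sample, all subnetworks equal the parent
  network, and the complexity index degenerates.
* **Recovery benchmarks** use a moderate baseline spread (0.5) and low
  latent noise (0.05) instead: they measure association detection, and
  under the wide sparsity default planted members can be censored by
  absence while compositional closure around dominant OTUs creates
  spurious strong correlations at desk scale (a handful of OTUs standing
  in for thousands). Both regimes are single `networkSimParams()` calls;
  neither is hidden.
* **Path-model data** generate latents recursively along the acyclic
  path equations with disturbances scaled to keep each latent near unit
  variance, then indicators as loading × latent + noise (default noise
  √(1 − λ²), giving unit-variance indicators).
* **Not emulated:** sequencing reads, chimeras, taxonomy misassignment,
  phylogenetic structure, overdispersion beyond the multinomial, or any
  spatial/temporal correlation. Passing tests on these generators
  demonstrates correctness of the statistical machinery under a known
  model — not robustness to the full messiness of real amplicon data.

## Problem sizes and runtime envelope

The test suite and acceptance script run at desk scale, chosen so the
full chain (including 200 brute-force graph oracles, 1000-replicate
calibration loops, 100-seed ordering checks and 50-seed path-model
recovery at n = 500) completes in a few minutes on one core: 18 samples
(3 × 6) for pipeline runs, ≤ 15-node graphs for oracle equivalence,
n = 20 samples for edge recovery, 99–199 permutations for permutation
tests in pipeline defaults, 200–500 bootstrap replicates. All are
parameters, not constants.

## Known limitations

* Correlation-threshold networks on relative abundances inherit
  compositional-closure artefacts; SparCC-style compositionality-aware
  inference is out of scope by design.
* The exact-permutation route is factorial in n and capped at n ≤ 7;
  beyond that the t-approximation is used even though it is only
  asymptotically exact.
* PLS-PM path coefficients are attenuated composites (see above), and
  the bootstrap p assumes approximate normality of the replicate
  distribution.
* With n = 6 per group, the random-forest percent-explained values and
  variation-partitioning fractions are high-variance descriptors;
  the package reports them faithfully but they should be read as
  effect-size screens, not precise estimates.
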