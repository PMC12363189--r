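---
title: "Models and methods behind kcsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kcsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kcsnet` implements a longitudinal microbiome–metabolome association
analysis for paired genus-level 16S count tables and targeted metabolomics
panels, ending in a composite **Keystone Candidate Score (KCS)** that ranks
genera by how disproportionately they sit in the association network. This
vignette documents the models, the tunable parameters, the synthetic-data
generator, and the numerical and design choices, in the order the pipeline
runs them.

## Preprocessing contracts

**Metabolites.** Features with *strictly more than* 70% missing cells are
removed (a feature missing in exactly 70% of samples is kept — the rule is
read literally). Zeros are observed values; only explicitly missing cells
count as missing and are later imputed. Each remaining feature is imputed
with its observed median and divided by that same median, so the median of
every feature's non-imputed cells is exactly 1 (enforced to 1e-12 in the
tests). Even-length medians use the usual midpoint convention. Ahead of
ordination, metabolites are additionally *panel-normalized*: within each
sample, every metabolite is divided by the mean of its panel (SCFA, BA or
AA), making each sample's per-panel mean 1. Ahead of differential and
correlation analysis they are instead transformed as `log2(x + 1)`.

**Microbiome.** Features present (count > 0) in fewer than 2 samples are
removed, then samples with strictly fewer than 1,000 total reads are removed
(a sample with exactly 1,000 reads is kept). Counts are converted to
relative abundances (rows sum to 1) and arcsine-square-root transformed for
the correlation stage. Low-depth samples are excluded from the correlation
and network stages, but the untransformed tables keep them available for
ordination, where balanced designs matter for restricted permutation tests.

## Ordination, omnibus and differential statistics

Bray–Curtis dissimilarity and PERMANOVA are delegated to `vegan`
(`vegdist`, `adonis2` with `by = "margin"`, so each term is tested
conditionally on all others); restricted permutations shuffle labels only
within strata via `permute::how(blocks = ...)`. We construct strata as the
interaction cells of the requested metadata columns (e.g. subject x
treatment group); since each subject belongs to one group this reduces to
within-subject permutation — the natural reading of a subject-and-group
restricted scheme, recorded here as an assumption. Permutation p-values use
the add-one convention `(1 + #{F* >= F}) / (1 + n_perm)` and are never
exactly zero. PCoA is classical metric scaling (`stats::cmdscale`); axes
with non-positive eigenvalues are dropped and no negative-eigenvalue
correction is applied, since none is needed for the bounded dissimilarities
used here.

Differential metabolite abundance is assessed per metabolite with the mixed
model `value ~ Treatment_Condition + (1 | Subject)` fitted by
`lmerTest::lmer` on median-scaled, `log2(x+1)` data; the package reports
each condition's contrast against the Control reference as a log2 fold
change with a Satterthwaite coefficient test. Benjamini–Hochberg correction
is applied over the pooled metabolite x condition p-vector and metabolites
with q < 0.05 form the *differentially abundant* (DA) set used by the KCS.
The estimator itself is not the contract — acceptance is via parameter
recovery (a planted log2FC of 1.0 is recovered to ±0.1 over replicates).

## Residualization and association testing

Subject effects dominate between-sample variance in longitudinal microbiome
studies, so each feature is residualized on subject before correlation:
the saturated one-factor linear model `value ~ subject` has Pearson
residuals equal to its raw residuals, so residualization is exact
subject-mean centering, and per-subject residual means vanish to machine
precision. Subjects observed once contribute residual 0 (with a warning).

All-against-all Spearman correlations are computed as Pearson correlations
of mid-ranks (average ranks under ties), with two-sided p-values from the
`t = rho * sqrt((n-2)/(1-rho^2))` approximation on `n - 2` degrees of
freedom — standard at this study's n of about 38 samples. Constant features
have undefined rho; they are recorded as missing and excluded from FDR.
Within-dataset matrices are symmetric, so each unordered pair is stored
once (upper triangle). BH correction runs *separately per family*
(metabolite–metabolite, bacteria–bacteria, bacteria–metabolite), mirroring
testing per dataset pair; whether the original workflow pooled families is
not documented, and separate families match per-dataset-pair testing tools.

Block ranking over the q-matrix is a deliberately simplified, deterministic
surrogate for hierarchical all-against-all testing: starting at the root
pair of the two feature dendrograms, a rectangular block is reported when
its fraction of significant cells reaches a density parameter (default 0.5,
configurable), otherwise the larger-side clade is split and the descent
recurses. Blocks are disjoint, scored by their minimum q, and ranked
ascending. The full hierarchical-testing machinery (permutation block
p-values, Gini-based cutting) is intentionally out of scope.

## A/B labels and feature clustering

Each within-dataset Spearman correlation matrix is eigendecomposed; features
are labeled **A** (non-negative entry) or **B** (negative entry) by their
sign in the leading eigenvector. An eigenvector is defined only up to a
global sign, so the package fixes the sum of entries to be non-negative
(first entry non-negative if the sum is zero); exact zeros are labeled A.
Labels are therefore meaningful up to a global A/B swap, and all tests
compare partitions, not names. The full (unthresholded) rho matrix is used.
Hierarchical clustering uses the correlation distance between rows of the
correlation matrix (`1 - cor`) with average linkage — the default of the
common clustermap tools that only document the metric.

## Networks, MCODE, and degree diagnostics

Significant associations (q < 0.05) become an undirected typed graph: one
node per participating feature, one rho-weighted signed edge per record,
partitioned into met–met, bact–met (bipartite) and bact–bact subgraphs.
Degree is the raw incident-edge count (the score table reports integers).
Betweenness is computed on each subgraph's largest connected component with
unweighted paths and normalized by `(n-1)(n-2)/2`; closeness is the inverse
mean shortest-path distance within a node's component.

**MCODE.** The molecular-complex detection algorithm is reimplemented
deterministically: (1) each vertex of degree ≥ 2 is weighted by
`k * density` of its closed-neighborhood subgraph, where `k` is that
subgraph's highest k-core level; (2) complexes grow breadth-first from the
highest-weight unused vertex, admitting neighbors whose weight is at least
`(1 - 0.2)` of the seed's; (3) complexes lacking a 2-core are discarded and
the haircut strips singly-connected periphery. Ties in weight break by
lexicographic node name, so the output is invariant to insertion order, and
clusters are node-disjoint (no fluff). Using the density of the *whole*
closed neighborhood — rather than of its top core alone — penalizes
vertices that sit at the periphery of a dense region; this is what lets a
single bridge between two dense complexes break the expansion into two
clusters rather than one. The flip side is that a pendant vertex attached
to a member of a small dense region slightly lowers that member's weight,
which can exclude it from a seed's complex; for the graph sizes and
densities this pipeline produces, the separation behavior was judged the
more important property. MCODE runs on the bact–bact and bact–met
subgraphs only.

**Power-law diagnostics.** Degree distributions are fitted with a discrete
power law `p(k) ∝ k^(-alpha)`, `k ≥ xmin`, by numerical maximum likelihood
with Hurwitz-zeta normalization (finite sum of 1,000 terms plus an
Euler–Maclaurin tail; accurate to about 1e-10 for alpha ≤ 20). `xmin` is
scanned over the observed unique degrees (at most 40 quantile-spaced
candidates, tails of at least 2 points) to minimize the Kolmogorov–Smirnov
distance between tail and model. Goodness of fit uses a semi-parametric
bootstrap: each replicate resamples the body empirically and the tail from
the fitted law, refits both `xmin` and `alpha`, and records its KS
statistic; the p-value is the fraction of replicate statistics at or above
the observed one, so *small p rejects the power law*. Model comparison
fits discrete lognormal, exponential (shifted geometric) and truncated
Poisson alternatives to the same tail `k ≥ xmin` (likelihoods must be
pointwise comparable) and reports Vuong's normalized statistic; positive
values favor the power law, and identical pointwise likelihoods yield
statistic 0 with p 1.

## The Keystone Candidate Score

Per genus, six integer subcomponents are summed:

1. **MCODE status** — 10 for a cluster seed, 5 for a non-seed member, 0
   otherwise (maximum across the two subgraphs if a genus clusters in both;
   that situation does not arise in the motivating study).
2. **Diff. Metab** — the number of *distinct* DA metabolites adjacent to
   the genus in the significant bact–met edge list.
3.–4. **Degree** in the bact–bact and bact–met subgraphs (raw counts).
5.–6. **HiLo betweenness** — 3 points for being among the three highest
   *or* three lowest betweenness nodes of a subgraph's LCC (reading
   "highest/lowest" as both triples, which matches the six genera carrying
   the bonus in the motivating study's table); ties break by higher
   degree, then higher closeness, then lexicographic name. Metabolite
   nodes compete for bact–met slots but never receive score records. When
   the LCC has ≤ 6 nodes every LCC node qualifies, and the condition is
   flagged.

Ranking is by KCS descending with ties broken by total degree descending,
then genus name. The published score table's order *within* tied scores is
not reproducible from any stated rule (its within-tie order contradicts
both degree-descending and lexicographic ordering), so the package treats
within-tie print order as arbitrary and guarantees only the score sequence
and the membership of each score level.

## The synthetic study generator

`simulate_study()` emulates the structure of the motivating study — 10
subjects in a two-group crossover, 4 samples each (Pre/Iso/Post plus a
Control collected roughly 3–4 weeks away), 54 genera, and 5 SCFA + 16 BA +
26 AA metabolites — with planted, exportable ground truth:

* **Microbiome latent model.** Per genus: log-abundance = genus mean +
  subject intercept (SD 1) + an AR(1) temporal signal of marginal SD 1
  (coefficient 0.3, a weak drift) + Gaussian noise (SD 0.35); counts are
  multinomial draws from the per-sample softmax at a negative-binomial
  library size (mean 20,000). One genus is dominant (fixed mean giving
  roughly a quarter of reads, like the dominant genus of the motivating
  study); the keystone genus is kept rare (about 1% on average). Exactly 2
  samples are forced below 1,000 reads, reproducing the study's two
  excluded samples and its n = 38 correlation stage.
* **Planted structure.** The keystone genus's temporal signal is coupled
  into 15 metabolites with coefficient 2 latent-SD; a hub genus shares a
  latent factor (loading 0.75) with 8 other genera; a separate 3-genus
  clique shares its own factor (loading 0.8), giving the bacteria–bacteria
  graph a second dense region; one extra genus follows the keystone weakly
  (loading 0.5), mirroring the single bacteria partner the motivating
  keystone had without duplicating its metabolite profile.
* **Metabolome.** Per metabolite: log2 abundance = baseline + subject
  intercept + keystone coupling (planted links) + condition shift + noise,
  exponentiated to a positive scale; cells go missing completely at random
  (rate 0.05 — no mechanism is documented for the real data). Ten metabolites (7 of them
  keystone-linked, the overlap of the motivating study) receive −2.2 log2
  Pre shifts, two of them also −1.2 in Iso. In addition the keystone latent
  itself sits 0.8 latent-SD lower in Pre samples, so linked metabolites
  inherit part of their contrast *through the coupling* — the way the
  motivating study's differentially abundant metabolites were
  overwhelmingly keystone partners whose change over time the keystone
  plausibly drove. Because the keystone coupling acts as residual variance
  in the mixed model, only a subset of the linked DA metabolites reaches
  q < 0.05 in any one replicate — the recovered DA partner count is
  typically far smaller than the planted seven, as in any finite study.

Coupling strengths were calibrated once, before any acceptance measurement,
to the study's *observable* statistics: significant associations at n = 38
imply residual |rho| of roughly 0.55 and above, so defaults were chosen to
place planted links at |rho| ≈ 0.6–0.8 after the attenuation introduced by
subject-mean centering (which removes about a third of the temporal
variance at 4 time points), multinomial counting noise, and compositional
closure. What the generator does **not** emulate: phylogenetic structure,
realistic absolute concentrations, below-LOD censoring, batch effects, or
read-level sequencing error. Passing tests therefore demonstrate that the
pipeline recovers structure of the planted kind at study scale — not that
it is robust to every artifact of real data.

## Problem sizes and tolerances

The test suite runs the statistical calibrations at desk scale: type-I
calibration of PERMANOVA over 500 replicates at 199/99 permutations;
mixed-model recovery over 100 replicates; association-stage FDR calibration
over 50 structure-free studies (20 genera, 21 metabolites); power-law
calibration on 1,000 draws with 500-iteration bootstraps over 20
meta-replicates; and keystone recovery over 25 full-pipeline replicates.
Production settings default to 9,999 permutations and 5,000 bootstrap
iterations. Numerical tolerances: symmetry and median contracts at 1e-12;
residual means at 1e-10; the Hurwitz-zeta tail correction at ~1e-10.

## Known limitations

* Correlation on compositional data remains compositional: closure induces
  weak spurious dependence which the pipeline does not correct (no CLR or
  similar transform, matching the upstream workflow it operationalizes).
* The block-ranking stage is a surrogate, not a reimplementation, of
  hierarchical all-against-all testing.
* KCS is a ranking heuristic; its weights (10/5/0, 3-point bonuses) are
  inherited as-is and have no probabilistic calibration.
* The A/B labels are defined up to a global swap and depend on the sign
  structure of the leading eigenvector only.
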