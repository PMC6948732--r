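---
title: "Methods: multi-omics analysis of myeloma plasma cells with mmomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics analysis of myeloma plasma cells with mmomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmomics)
```

# Scope and model

`mmomics` implements a complete analysis chain for two-group comparisons of
multiple myeloma plasma-cell cohorts across three molecular layers —
targeted/untargeted lipidomics, shotgun proteomics and microarray
transcriptomics — together with a metabolic-network stage that mines
reaction paths whose gene expression is coherently correlated in one
patient group but not the other (for example relapsed/refractory, RRMM,
versus newly diagnosed, NDMM). Every stage is also exercised by a
synthetic-data module that generates cohorts with known ground truth, so
the statistical machinery can be validated by parameter recovery rather
than by eyeballing.

## Intensity model and preprocessing

Feature intensities are modelled log-normally: on the log2 scale a feature
has a baseline drawn around a grand mean, additive residual noise, and a
per-sample dilution offset applied multiplicatively on the raw scale.
Preprocessing follows the conventions of the field:

* **Presence filtering** retains a feature if it is observed in at least
  75% of the samples of one or more comparison groups (inclusive
  boundary). Proteins are additionally required to have at least 2 unique
  peptides (inclusive) and an identification score strictly greater
  than 5.
* **Quantile normalization** forces all samples onto the mean quantile
  profile. Missing cells are excluded from rank pooling: each column's
  observed values are ranked (mean ranks on ties) and mapped onto the
  reference profile by interpolation, so complete columns share sorted
  values exactly and partially observed columns are placed consistently.
* **Probabilistic quotient normalization (PQN)** divides each sample by
  the median of its feature-wise quotients to the median reference
  spectrum, computed on the raw scale. PQN presumes spectra that are
  near-proportional across samples (its job is injection-volume
  correction); its accuracy therefore degrades with biological residual
  variance and improves with panel size. The package verifies 2% recovery
  of planted dilution factors on a targeted-panel-sized catalog
  (310 lipids) with small residual noise, the setting the method is
  designed for.
* **Imputation.** Untargeted lipidomics uses matrix-minimum imputation, a
  deliberate left-censoring assumption. Proteomics splits proteins by
  missing fraction: below 25% (strict) the values are treated as missing
  at random and imputed by localized least-squares (LLS) regression on
  the `k = 10` most-correlated complete proteins (Pearson similarity,
  regression over the samples where the target is observed); at or above
  25% the protein is treated as left-censored and imputed from
  `Normal(min observed intensity, (0.3 * global sd)^2)`. The exactly-25%
  case goes to the censored branch — the conservative, low-information
  choice. When fewer complete proteins than `k` exist, LLS falls back to
  row means with a warning.

The targeted-lipidomics chain runs PQN then log2; the untargeted chain
runs presence filter, quantile normalization, log2, then minimum
imputation. Chain order is configurable.

## Moderated differential analysis

Both comparisons use an empirical-Bayes moderated t. For each feature the
two-group fit gives the log2 fold change (numerator minus denominator
group mean), the pooled residual variance `s^2` and residual degrees of
freedom `d`. Under the scaled-F model `s^2 ~ s0^2 F(d, d0)`, the prior
degrees of freedom `d0` and prior variance `s0^2` are estimated by method
of moments on `log s^2` (digamma/trigamma moment equations, trigamma
inverted by Newton iteration). The posterior variance
`(d0 s0^2 + d s^2)/(d0 + d)` yields a t-statistic on `d0 + d` degrees of
freedom; p-values are two-sided and Benjamini–Hochberg adjusted across
features. The implementation is validated against the established
empirical-Bayes reference implementation in the test suite, and reduces
exactly to the ordinary pooled t when `d0 = 0`.

Significance is reported under two rules, mirroring common practice in
small pilot cohorts: raw `p < 0.05` and adjusted `p < 0.05`; up/down
regulation tallies additionally require `|logFC| > 1.5` (strict) under
the raw rule. Features with fewer than two observations in a group are
flagged and carry missing statistics rather than disappearing silently.

## Lipid nomenclature and set enrichment

The lipid shorthand parser understands `CLASS C:DB` forms
(`"PC 34:4"`), subclass brackets and per-chain compositions
(`"Cer[NS](d18:1/16:0)"`, sphingoid `d` prefix), plasmalogen/plasmanyl
prefixes (`"Plasmenyl-PE 40:6"` maps to `PE-P`), ether-lipid forms
(`"PC(O-38:6)"`), unresolved O-/P- alternatives (kept with the O- form
primary, the P- form as a recorded alternative) and trailing adducts
(`"; [M+H]+"`), which are stripped. Anything else is an error naming the
offending token — never a silent guess. Lipid sets are built by class, by
total chain length and by total unsaturation, so each species lands in
exactly three sets.

Set enrichment is GSEA-preranked style: features sorted by decreasing
logFC (ties broken by feature id for determinism), a weighted
Kolmogorov–Smirnov running sum with weight `|logFC|^1`, and the extreme
excursion as the enrichment score. When the positive and negative
excursions tie to within 1e-12 the score is defined as 0, which keeps the
score antisymmetric under ranking negation. The null permutes feature
labels; when `choose(N, m)` does not exceed the permutation budget the
null is enumerated exhaustively and p-values are exact (the test suite
checks them against an independent enumeration oracle to 1e-12). NES
divides the score by the mean |null score| of matching sign; p-values are
sign-matched tails with BH adjustment across sets. Label permutation
(rather than sample permutation) is the only option consistent with
having a ranking as the sole input.

## Cross-omics concordance

Gene-level and pathway-level agreement between two differential analyses
is scored on the shared tested universe: the overlap of significant ids
with an upper-tail hypergeometric probability, and directional agreement
among overlapping ids with a one-sided sign test at probability 1/2. Both
match brute-force enumeration on small universes in the tests. Probe sets
are collapsed to protein ids by keeping the highest-mean-expression probe
per target, the common microarray convention.

## Reaction-graph path mining

A metabolic network (reactions with substrates, products and gene
annotations; metabolites flagged ubiquitous) is converted to a directed
reaction graph: an edge runs from a producing to a consuming reaction for
every shared non-ubiquitous metabolite. Removing water-like compounds and
co-factors before edge formation prevents the over-connectivity they
would cause. Per group, each edge is weighted by the maximum Pearson
correlation over all gene pairs of its two reactions, computed on that
group's samples (mean aggregation is available); edges with unmeasured
genes receive the group median weight and an `unmeasured` flag so
connectivity is preserved but the provenance is visible.

Path extraction enumerates simple paths between source-like (zero
in-degree) and sink-like (zero out-degree) reactions, scores each path by
its mean edge weight, and returns the top `k` with at least `minLength`
edges, ordered by score and then lexicographically for determinism. The
phrase "minimum path length of 6 reactions" is ambiguous between nodes
and edges in common usage; the package counts **edges** (`minLength = 6`
means at least 7 reactions), the stricter reading, and the parameter is
configurable. Exhaustive enumeration was chosen over k-shortest-path
search because mean-weight scoring is not monotone in path cost and the
graphs in scope are small; enumeration matches a brute-force oracle
exactly in the tests.

## Path classification

Association of extracted paths with disease condition is assessed by a
two-component mixture of first-order Markov chains over reaction
sequences, fitted by EM with Laplace (add-1) smoothing. Training is
semi-supervised: each path carries a fixed prior of 0.85 on the component
matching its own condition. This anchors component 1 to condition 1,
prevents the component-starvation degeneracy that unconstrained mixtures
exhibit when the two conditions' paths are similar, and leaves the
likelihood free to dominate when the conditions genuinely differ. With
smoothing the procedure is MAP-EM: the penalized objective is guaranteed
non-decreasing and is used for convergence (tolerance 1e-6, at most 200
iterations); the raw log-likelihood trace is recorded alongside.
Classification reports the posterior of the condition-1 component, a
threshold-sweep ROC with trapezoid AUC, and per-component ROC curves (the
component tied to the other condition shows AUC below 0.5, mirroring the
M1/M2 reading of mixture classifiers).

Subnetworks take the union of the two conditions' top-path edges and
label each edge exclusive to one condition or shared; differential
results are projected onto reaction nodes through the gene map, taking
the largest-|logFC| significant feature per node and reporting coverage.

# Synthetic cohorts: what they emulate and what they do not

The generators reproduce the statistical structure the pipeline assumes:
two-group designs, planted lipid-class log2 effects (e.g. PC down by 2 in
RRMM), log-normal per-sample dilution, left-censored (MNAR) missingness
below a global intensity quantile plus uniform (MAR) dropout, proteins
with sub-threshold peptide counts and scores to exercise the filters, and
expression matrices in which the genes along designated network paths are
exchangeably correlated (shared-factor construction) within one group's
samples only. Truth tables are first-class outputs — effects, dilution
factors and the exact MAR/MNAR partition — because every acceptance check
is parameter recovery.

The toy metabolic network arranges reactions as one or two parallel
backbone chains (sharing endpoints) plus short forward bypasses within a
chain, giving a directed acyclic graph whose simple-path space grows
combinatorially (roughly 70–100 qualifying paths at the default 30
reactions) while guaranteeing at least one path of 6 or more edges. Genes
are dedicated per reaction so planted co-expression stays path-specific.

What the generators do **not** emulate: raw spectra, chromatography,
isotopes, adduct ambiguity at the signal level, batch effects, or
realistic biological correlation among background features. Passing tests
therefore demonstrate that the statistical machinery is correct under its
stated model, not that the model captures every property of real
acquisitions. In particular the real missingness mechanism of
instrument data is unknown; MNAR-by-global-censoring is an explicit
assumption.

# Default parameters and problem sizes

| parameter | default | meaning |
|---|---|---|
| presence threshold | 0.75 | min non-missing fraction in some group |
| peptide / score filters | >= 2, > 5 | protein identification quality |
| MAR cutoff | 0.25 | missing fraction below which LLS applies |
| LLS neighbors | 10 | complete proteins per regression |
| MNAR sd factor | 0.3 | censored-draw width as fraction of global sd |
| p / logFC thresholds | 0.05, 1.5 | significance and regulation rules |
| permutations | 10000 (2000 in the pipeline) | enrichment null |
| min set size | 3 | enrichment set floor |
| top-k paths | 50 (15 in the pipeline) | paths kept per condition |
| min path length | 6 edges | path qualification |
| EM smoothing / tol / iters | 1, 1e-6, 200 | classifier fitting |
| label prior weight | 0.85 | semi-supervised anchoring |

The bundled pipeline and the verification experiments run at reduced
sizes chosen to keep a full run on one CPU in seconds while leaving every
statistical property measurable: cohorts of 10–20 samples per group for
lipidomics/proteomics, 60 per group for expression (correlation estimates
need the larger n), 120 proteins, a 30-reaction network, top-15 paths per
condition, and 2000 permutations. The classifier and overlap checks run
over 10 generator seeds, the class-enrichment check over 20.

# Numerical choices and degenerate inputs

* Quantile normalization errors on all-missing columns; PQN requires at
  least 3 shared features with the reference; log2 refuses non-positive
  values rather than adding a silent pseudo-count.
* The enrichment score of a set equal to the whole universe is undefined
  (empty complement); such sets are skipped with a warning, as are sets
  with no members in the universe. Permutation counts below 100 are
  refused.
* With fewer than 10 positive-variance features the moderation falls back
  to ordinary t with a warning; all-zero variances are an error.
* Tie-breaks are deterministic everywhere: enrichment sorts by statistic
  then feature id; path ranking sorts by score then node sequence.
* All stochastic steps (generators, permutation nulls, censored-draw
  imputation, EM) take explicit integer seeds, and the pipeline derives
  every stage seed from the single configuration seed, so a full run is
  bit-reproducible.

# Known limitations

* The moderated-t and enrichment machinery assume independent features;
  correlated lipids within a class make the label-permutation null
  slightly liberal, as it does for every preranked method.
* LLS imputation assumes linear relations among co-expressed proteins and
  degrades gracefully (to row means) when complete proteins are scarce.
* Path extraction by exhaustive enumeration is exponential in the worst
  case; it is intended for pathway-scale graphs (up to a few hundred
  reactions), not genome-scale networks, and it caps enumeration with an
  explicit error.
* The path classifier's per-component ROC interpretation assumes two
  conditions; multi-condition designs are out of scope, as are paired or
  covariate-adjusted differential designs.
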