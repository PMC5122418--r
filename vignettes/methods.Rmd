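---
title: "Functional-similarity association inference: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-similarity association inference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smirnet)
```

`smirnet` scores candidate small molecule–miRNA associations by asking
whether the two perturbations disturb the same biological processes. This
vignette explains each model in the chain, the parameters that matter, the
choices we made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate.

## 1. Differential-expression signatures

Three callers cover the three experimental designs the pipeline accepts.

**SAM-style caller** (`call_de_sam`), for single-channel designs with at
least two replicates per class. The per-gene statistic is the unpaired
moderated difference `d = (mean_t − mean_c)/(s + s0)`, where `s` is the
pooled standard error and the exchangeability constant `s0` is the median
of all gene-wise standard errors — a deliberately simple member of the SAM
family that keeps the mechanism (variance moderation plus permutation FDR)
without the full quantile-search machinery. The FDR at a candidate
threshold is the mean number of permuted `|d|` values exceeding it, over
label permutations that include the identity, divided by the observed
count. Including the identity permutation makes the estimated FDR strictly
positive whenever anything is called, so `fdr_cutoff = 0` always returns an
empty signature. Testing is done on the log2 scale (`log2(x + 1)` applied
to linear input). Default `fdr_cutoff = 0.05`, `n_perm = 100`.

**Fold-change caller** (`call_de_foldchange`), for singleton-class or
double-channel designs: per treatment sample a gene is up when the ratio to
the mean control is ≥ 2 and down when ≤ 1/2 (double-channel columns are
taken as ready-made ratios), and a call requires the same direction in
strictly more than half of the evaluable samples — ties fail. Samples with
a non-positive control value are not evaluable for that gene.

**Amplitude caller** (`call_de_amplitude`), the Connectivity-Map statistic
`A = (t − c)/((t + c)/2)` with `t` a treatment sample's value and `c` the
mean of its matched controls. `A` is bounded in (−2, 2) and `|A| = 2/3` is
algebraically an exact 2-fold change; calls use the strict inequality
`A > 2/3`, so the ratio-2 boundary itself does not qualify — note this
differs at the exact boundary from the fold-change caller's closed ≥ 2
rule, which follows its own stated convention. Probes with `t = c = 0` are
skipped.

All callers operate on linear-scale expression by default; profiles built
with `log2_scale = TRUE` are unlogged (`2^x`) before the ratio rules. All
signature operations discard conflict genes, so `up ∩ down = ∅` is an
invariant throughout.

**Cross-dataset combination** (`combine_signatures`): a gene keeps a
direction when called that way in at least `min_support` datasets
(default 2; the two descriptions of the combination rule we follow differ
between miRNA and small-molecule passages, so the threshold is exposed as
a parameter rather than hard-wired).

## 2. Enrichment profiles

Gene annotations are propagated up the ontology (each term's gene set is
the union over its descendants), and each signature's genes are tested
term by term with the one-sided hypergeometric tail — exactly the
one-sided Fisher exact test. The *elim* refinement processes terms from
most to least specific (decreasing longest-path depth, ties broken
lexicographically; only child-before-parent matters for the result) and,
whenever a term's p-value falls below `alpha`, removes its current genes
from all ancestors before those are tested. The elimination threshold
equals the reporting threshold (`alpha = 0.01` by default) — one
significance level governs the whole enrichment stage, and no
multiple-testing correction is applied within it. The background universe
defaults to all annotated genes and is overridable. A useful exactness
property, asserted in the tests: any term with no significant descendant
gets exactly its classic Fisher p-value.

## 3. Structural information content and Lin/BMA similarity

The term probability is structural: `p(t) = n_t / N` with `n_t` the number
of distinct descendants of `t` plus itself and `N` the ontology size, and
`IC(t) = −log p(t)`. "Descendants" is the transitive closure — with direct
children only, the root's probability would not be 1 and its IC not 0.
Counting descendants rather than annotation frequencies makes the IC a
property of the ontology alone, which is what the similarity definition
here calls for. The logarithm is natural; only IC *ratios* enter the Lin
score, so the base cancels and the choice is cosmetic.

Lin similarity is `2·IC(MICA)/(IC(t1) + IC(t2))`, where the MICA is the
common ancestor (terms count as their own ancestors) with maximal IC. Ties
in IC cannot change the score; the reported MICA breaks them by the
lexicographically smallest identifier for determinism. The 0/0 case —
both ICs zero — is defined as 1 for the identity pair and 0 otherwise.
Only `is_a` edges are used when reading OBO files; other relation types
are dropped as the conservative core of the hierarchy.

Term-set similarity is the best-match average of the pairwise Lin matrix:
`(Σ row maxima + Σ column maxima)/(|S1| + |S2|)`, symmetric and in [0, 1].
Empty sets are an error — entities with empty enrichment profiles are
dropped (and logged) before the similarity matrix is built, rather than
silently scored 0.

## 4. Threshold and network

The pair scores are moment-matched to a normal distribution (sample mean,
sample SD) and the association cutoff is the upper one-sided quantile
`μ + z(1−α)·σ`, default `alpha = 0.01`. The reported full-scale fit
(mean 0.4882, SD 0.0965) gives 0.7127 under exactly this one-sided
convention, which is why we fixed it. Edges use the closed rule
`score ≥ cutoff`, so a score exactly at the cutoff qualifies. Note the
consequence of a quantile cutoff: on pure-noise inputs about `α` of the
pairs will exceed it by construction, so an empty network is *not* the
null expectation — the tests assert alpha-level spillover (≈ 1 % of
pairs), not emptiness.

## 5. Permutation ROC

Each gold-standard pair contributes its true score as a positive and
`n_perm = 99` "fake" scores as negatives: random term sets of the same
size as the miRNA's profile, drawn without replacement from the union of
all enriched terms (configurable to the whole ontology; the appropriate
pool is genuinely ambiguous, and the enriched-term union is the more
conservative null because it matches the marginal term usage). 110 gold
pairs therefore yield 10 890 negatives among 11 000 scored instances. The
AUC comes from a threshold sweep with trapezoidal integration; ties get
half credit, making it exactly the Mann–Whitney U statistic — the tests
assert that identity on tied data.

## 6. Repurposing and survival

Drug–disease pairs are scored by the hypergeometric upper tail on shared
miRNAs; the universe defaults to the union of the network's and the
disease map's miRNAs (overridable — the choice changes the p-values and
should be stated with any result). Pairs sharing no miRNA are untestable
non-candidates and are excluded from the BH family by default
(`include_zero` flips this; it changes the family size m and hence the
FDR). FDR control is Benjamini–Hochberg at 0.1.

Survival stratification clusters patients with K-means (K = 2, Euclidean,
best of 10 seeded restarts) on the selected miRNAs' expression after
`log2(x + 1)` and per-miRNA z-scoring — unscaled expression would let one
high-abundance miRNA dominate the distance; `preprocess = FALSE` restores
raw clustering. Because cluster indices are arbitrary, the "good"
prognosis label goes to the cluster with the higher Kaplan–Meier survival
at the last time both groups remain under observation. Group differences
use the standard 1-df log-rank test and per-miRNA fold changes are ratios
of raw group means, good over poor. Log-rank, Kaplan–Meier and the
clustering itself are delegated to the `survival` and `stats` packages;
the tests verify them against hand tabulations of the observed/expected
event tables and the product-limit form. The module is agnostic about
time units and assumes standard right-censoring.

## 7. Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline reads, with planted truth:

- `make_dag(n_terms, branching, seed, p_extra_parent)` — single-root DAG
  with a balanced-tree backbone and optional extra parents; written as
  valid OBO on request.
- `make_expression(...)` — log-normal two-class matrices; planted genes
  shift by `effect × noise_sd` log2 units in treatment. Defaults (220
  genes, 5 v 5, effect 3, noise SD 0.5) model a clean small microarray
  with a strong perturbation: 20 planted genes are recalled at ≥ 90 % at
  FDR 0.05 while pure-null runs call essentially nothing.
- `make_association_scenario(...)` — 20 small molecules × 10 miRNAs, each
  with 8 enriched terms drawn from the deep half of a 200-term DAG; the 5
  planted pairs share 80 % of their terms. These sizes keep the whole
  scenario (including 99 permutations per gold pair) in seconds while
  giving background scores a tight unimodal distribution around 0.46,
  cleanly below the fitted 1 % cutoff.
- `make_survival(...)` — exponential event times (baseline rate 0.1),
  exponential censoring at a rate hitting the nominal censoring fraction
  for the baseline group, and group-shifted Gaussian miRNA expression
  (good-prognosis group up-regulated).

Every generator is a pure function of its parameters and seed, and the
truth record serialises to JSON next to the outputs.

What passing these benchmarks shows: the statistics are implemented
correctly (they match independent brute-force oracles), the pipeline
recovers planted signal at realistic effect sizes, and its error rates are
calibrated under the null. What it does not show: performance on real
perturbation compendia, where probe effects, batch structure, correlated
genes, annotation bias and incomplete gold standards all degrade the
idealised behaviour. Published full-scale figures (AUC ≈ 0.985 on a
curated gold standard; a 538-edge network) depend on those external data
and are deliberately not asserted by this package's tests.

## 8. Numerical and interface choices

- Degenerate inputs: zero-variance score vectors refuse a threshold fit;
  an all-identical expression submatrix refuses clustering; cohorts with
  no events return a flagged NA rather than a fabricated p-value; genes
  with `t = c = 0` are excluded from amplitude calls.
- Determinism: every stochastic routine takes a seed; pipeline outputs
  are byte-stable under a fixed seed (asserted in the tests), and the
  provenance record deliberately contains no timestamp so that reruns are
  comparable byte for byte.
- Tie-breaks are lexicographic everywhere a deterministic report is
  needed (MICA, elim processing order among equal-depth siblings).
- The command-line surface is deliberately thin: `simulate` and `run`
  subcommands over `pipeline_config()`/`run_pipeline()`; the individual
  stages are the exported R functions, which compose better in scripts
  than a long list of single-purpose subcommands.

## Session info

```{r}
sessionInfo()
```
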