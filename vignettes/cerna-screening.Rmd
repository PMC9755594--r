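---
title: "Screening mRNA–miRNA–mRNA ceRNA axes: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mRNA–miRNA–mRNA ceRNA axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAtriad)
```

## The screening model

A competing-endogenous-RNA (ceRNA) axis is a triple (mRNA A, miRNA m,
mRNA B) in which both mRNAs carry response elements for the same miRNA and
therefore compete for it. Competition leaves a characteristic footprint in
bulk expression data: the two mRNAs rise and fall together (positive
co-expression), while each moves opposite to the shared miRNA (negative
co-expression). `ceRNAtriad` screens for that footprint among genes already
dysregulated in a two-group (case vs control) design, in four stages.

**Differential expression.** Per dataset, each gene's log2 fold change is
the difference of group means on log2 scale and its p-value comes from a
two-sided Welch two-sample t-test. A gene is significant iff
`p < p_max` **and** `|log2FC| > lfc_min`, both inequalities strict
(defaults 0.05 and 1; a value exactly at either cutoff never passes).
We deliberately use a plain Welch test rather than an empirical-Bayes
moderated statistic: the contribution of this package is the screening
chain, not the DE engine, and with ≥ 30 samples per group (the reference
design below) moderation changes almost nothing. The DE stage is a single
pluggable function, and no multiple-testing correction is applied to the
significance call — filtering is on the raw p, with a Benjamini–Hochberg
column carried along for information.

**Consensus.** Only genes significant with the *same direction* in every
dataset survive (the Venn step). Genes measured in one dataset only are
excluded.

**Candidate pairs and the hypergeometric condition.** For every unordered
pair of consensus DEGs sharing at least `min_shared` targeting miRNAs
(default 1), the shared count `k` is tested against the hypergeometric
upper tail: with `K` miRNAs targeting A, `n` targeting B, and a universe
of `N` miRNAs, `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) /
C(N,n)`. The universe `N` defaults to the full miRNA universe of the
supplied target map — the test concerns the targeting relation, which
lives in the map, not in what happened to be measured — with
`universe = "expressed"` as the configurable alternative that restricts
both the map and `N` to measured miRNAs.

**Signed correlation screens.** Each surviving pair is expanded into one
triplet per shared miRNA with measured expression, and a triplet is
accepted iff additionally `r_AB > 0` with `p < alpha`, and `r_mA < 0`,
`r_mB < 0` each with `p < alpha`. Three choices here were genuinely open
and are resolved as follows:

* *Which samples feed the correlations.* The two cohorts of a
  multi-dataset study are disjoint, so correlations are computed within
  ONE designated dataset (`corr_dataset`), never by pooling across
  cohorts. Case and control samples of that dataset are pooled: the
  disease shift is part of the co-expression signal being screened.
* *Sign plus two-sided p, not a one-sided test.* "Positive/negative
  correlation (p < 0.05)" is read as a sign constraint on r combined with
  the ordinary two-sided p — the common practice with a symmetric alpha.
  `one_sided = TRUE` switches to the matching one-sided tail.
* *Both endpoints.* The negative-correlation condition applies to both
  mRNAs of the axis; `either_endpoint = TRUE` relaxes it to at least one.

A pair that is significant through several shared miRNAs yields several
triplets — axes, not pairs, are the unit of the result. The screen writes
an audit table containing **every** tested triplet with all statistics and
the first failed condition, so acceptance is exactly its stated
inequalities and can be re-verified post hoc; BH-adjusted companions of
each p-value family are included for information only. Candidates whose
mapped gene or miRNA lacks expression are dropped and counted in the log,
never imputed.

**Downstream.** Over-representation analysis reuses the same
hypergeometric kernel (overlap k, set size K, query size n, universe N).
The ORA universe defaults to the measured gene set of the analyzed
expression matrix — the standard correction for detection bias — and
significance is called on the raw p to mirror common screening practice,
with BH values reported alongside. Hub ranking takes an undirected edge
list, drops self-loops, deduplicates edges in either orientation, and
flags the top `top_k` nodes by degree, breaking boundary ties
lexicographically (and logging that a tie occurred).

## What the generator emulates

`simulate_paired_datasets()` draws, for each of `n_datasets` cohorts, a
genes-by-samples log2 expression matrix for mRNAs and one for miRNAs:

* per-gene baselines `N(8, 1)` and residual noise `N(0, noise_sd^2)` —
  microarray-like continuous log2 expression, *not* counts, matching how
  mixed microarray/RNA-seq studies analyze both platforms as continuous;
* a fraction `de_fraction` of mRNAs receives a `±de_effect` shift in the
  case group;
* each of `n_planted_triplets` modules has a latent per-sample miRNA
  activity `u ~ N(0, 1)` added to its miRNA and subtracted, scaled by
  `sponge_strength`, from both of its mRNAs. This single-latent-factor
  sponge model is the minimal structure that makes all three screening
  conditions true in expectation for planted axes. The two mRNAs of a
  module are DE genes with same-direction shifts (otherwise the consensus
  step would remove them by construction).

The target map is the union of the planted edges and uniform Bernoulli
(`decoy_edge_prob`) decoys. Decoys are drawn over all miRNAs but **not**
onto the planted modules' mRNAs: a planted pair's targeting evidence is
exactly its true regulator (`k = K = n = 1`, upper-tail p `= 1/N`). This
is a deliberate design choice, not an accident. If decoys also land on
planted mRNAs, the planted pair still shares only its one true miRNA
while its marginal target counts grow to `K, n ≈ 1 + ρN`, and the
expected upper-tail p, roughly `1/N + 2ρ + ρ²N`, exceeds 0.05 for *every*
universe size once `ρ = 0.02` — the planted signal would be
hypergeometrically invisible and recovery would measure luck, not the
screen. Keeping planted targeting clean makes recovery interpretable
while decoys on all other genes and miRNAs preserve a realistic null
topology (decoy-driven candidate pairs, false-positive pressure on the
correlation conditions).

`simulate_null()` runs the identical pipeline with `sponge_strength` and
`de_fraction` forced to zero; the planted edges stay in the map as inert
topology, truth is empty, and the null screen is run with all mRNAs as
the candidate set (with no DE genes the screen would otherwise have
nothing to test).

### Reference conditions and parameter defaults

| parameter | default | units / meaning |
|---|---|---|
| `n_case`, `n_control` | 30, 30 | samples per group, each cohort |
| `n_mrna`, `n_mirna` | 400, 80 | genes and miRNAs |
| `n_planted_triplets` | 20 | true ceRNA modules |
| `sponge_strength` | 1.2 | loading of miRNA activity on its targets (log2 units per sd of activity) |
| `de_fraction`, `de_effect` | 0.25, 2 | fraction of shifted mRNAs; log2 shift |
| `noise_sd` | 0.5 | residual sd, log2 scale |
| `decoy_edge_prob` | 0.02 | per-pair decoy probability in the target map |
| `n_datasets` | 2 | paired cohorts |

The sample sizes, effect size, sponge loading, noise level, planting
count and decoy rate are the package's reference validation conditions.
`n_mrna = 400` and `n_mirna = 80` are a desk-scale stand-in for
genome-wide panels: large enough that the consensus step, the candidate
enumeration (hundreds of pairs) and the decoy-driven false-positive
pressure behave as in larger data, small enough that a 10-simulation
recovery batch and a 50-simulation null batch run in seconds.
`de_fraction = 0.25` keeps 100 DE genes per cohort, comfortably above the
40 genes consumed by planted modules.

With these values a planted pair has pooled correlation ≈ 0.9 (sponge
plus shared DE shift), each miRNA–target correlation ≈ −0.65, and DE
genes have |log2FC| estimates tightly around 2 — all three conditions
pass with large margins, which is what makes ≥ 0.9 recall/precision a
meaningful bar rather than a knife-edge.

### What the generator does *not* emulate

Count-based (negative-binomial) noise, batch effects, dropout,
degree-matched decoy maps, correlated miRNA activities, and lncRNA or
circRNA sponges. Passing recovery on this generator shows the chain is
implemented correctly and calibrated on its own assumptions; it does not
show that real tissue data satisfy those assumptions, and real target
maps are far denser and more structured than Bernoulli decoys.

## Numerical and degenerate-input choices

* Hypergeometric tails are computed with `phyper` (upper tail,
  `P(X >= k)`, so `k = 0` gives exactly 1); tests verify it against
  exhaustive subset enumeration to 1e-12 for all parameters with N ≤ 12.
* Pearson p uses `t = r sqrt((n-2)/(1-r^2))` on `n − 2` df, with `p = 0`
  at `|r| = 1` and a guard against floating-point `1 - r^2 < 0`. Constant
  vectors raise a distinct condition (`cerna_constant_input`); the screen
  drops such candidates and logs the count.
* Genes with zero variance in both groups get DE p-value 1 when the group
  means are equal, 0 when they differ (exact separation).
* All writers sort rows and columns lexicographically (C collation) and
  print doubles with 17 significant digits, so equal seeds/configs give
  byte-identical files and read/write pairs are exact inverses.
* Ties in hub ranking break lexicographically; duplicate edges and
  self-loops are removed before degree counting.

### A calibration caveat worth knowing

The analytic Pearson p and a permutation p computed from the same data
are *not* the same quantity: the t distribution is the unconditional
normal-theory null, while permutation conditions on the observed margins.
They coincide only to O(1/n). Empirically (exact enumeration at n = 6;
10,000-permutation estimates above), the median absolute gap at n = 6 is
≈ 0.011 with outliers up to ≈ 0.19 — far beyond Monte-Carlo noise — and
the gap falls below Monte-Carlo noise only around n ≥ 25. The test suite
therefore asserts permutation agreement at moderate n, where the
assertion is statistically meaningful, and treats small-n disagreement as
a property of the statistics, not an implementation defect. At the
reference conditions (n = 60 pooled samples) the distinction is
immaterial.

## Validation problem sizes

The shipped validation (unit + acceptance tests, and
`scripts/acceptance.R`) uses: the full hypergeometric enumeration sweep
(N ≤ 12, 3,184 tuples); 100 vector pairs with 10,000 permutations each
for correlation calibration; a 10-simulation batch at the reference
conditions for recovery (recall, precision, consensus DE recall, all
≥ 0.9 required); and a 50-simulation null batch for the false-positive
rates (≤ 0.05 required). These sizes were chosen so each block completes
in seconds while keeping Monte-Carlo error well below the margins being
asserted.

## Known limitations

* The screen is marginal-correlation-based; it does not attempt partial
  correlation or conditional-independence refinements, so strong
  disease-driven co-expression can create decoy-supported false axes (the
  generator reproduces exactly this failure mode — precision < 1 at some
  seeds comes from DE-correlated gene pairs sharing a decoy miRNA edge).
* Raw-p filtering at every condition mirrors common screening practice
  but has no family-wise guarantee; the audit table's BH columns are the
  place to look when stricter control is wanted.
* Identifiers are opaque case-sensitive strings: no probe-to-symbol
  mapping, no cross-resource id reconciliation.
* Single-cell evidence enters only as precomputed marker lists; the
  package does not process single-cell matrices.
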