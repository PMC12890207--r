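---
title: "Why naive diversification and ancestral-trait estimators mislead under incomplete sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why naive diversification and ancestral-trait estimators mislead under incomplete sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divbias)
```

## The problem

Comparative studies sometimes estimate diversification rates and ancestral
trait values directly from a time-calibrated phylogeny of extant species,
using procedures that look down the tree: a species "originates" at the age
of its parent node, a clade's diversification rate is `log(n)/t` for `n`
tips and stem age `t`, a speciation rate is the Kendall–Moran `(n − 2)/S`
for total branch length `S`, and the "ancestral" trait value of a past time
interval is the median trait of the extant species that originated in it.

All of these read the reconstructed tree as if it recorded the complete
evolutionary process. It does not. Extinct lineages leave no trace, and —
more damaging in practice — most described species are absent from any
given phylogeny. When a species' true sister is unsampled, its parent node
in the analyzed tree is an older node, so its apparent origin age is
inflated by an unpredictable amount; apparent `n` is a fraction of true
richness, so richness-based rates are understated; and interval medians
reshuffle wholesale when a single species drops out of the tree.

`divbias` makes these failure modes measurable. It simulates birth–death
trees with known rates, trait histories and sampling schemes, applies the
naive estimators exactly as described above, and reports their bias against
the simulation's ground truth. It also provides the constructive
alternative used for tip-level questions: the DR (inverse equal-splits)
tip-rate statistic with permutation tests of trait–rate association,
including a regime-level (STRAPP-style) null.

## Time and interval conventions

Time is measured backward from the present in millions of years (My):
age 0 is the present, the crown (root) age is the maximum root-to-tip path
length, and the stem age — the split from the clade's sister lineage — is
carried separately (simulated trees record their true stem age; for
user-supplied trees the crown age is used as a fallback, with a warning,
since Newick files rarely carry stem information).

Interval grids are half-open in age, `[b_k, b_{k+1})`, starting at 0, with
an open-ended oldest interval so every age belongs to exactly one bin; an
age exactly on a boundary belongs to the interval whose young edge it is.
The default width is 5 My, the conventional bin for Cenozoic-scale
analyses. When counting the lineages alive at an age `T`
(`lineage_count_at()`), a node exactly at `T` counts as already split, so
its daughter branches are the counted units; the same convention is used
when averaging trait states over live branches. Ultrametricity is judged at
a tolerance of 1e-9 My; complete trees retaining extinct lineages are
legitimately non-ultrametric and are handled as such.

## The simulator and what it emulates

`simulate_birth_death()` is an exact Gillespie simulation of a constant-rate
birth–death process started from a crown pair (two lineages at the crown).
Extinct lineages are retained as tips at their death times, so
`reconstruct_extant()` can derive the reconstructed (extant-only) tree that
an empiricist would actually see, and `apply_sampling()` the tree they
would actually analyze. Whole-clade extinction in fixed-duration mode is
returned as an explicit `extinct_clade` outcome, not an error. The stem age
is drawn as the crown age plus an Exponential(λ) stem branch.

Two stopping rules are available. Fixed duration (`t_max`) is the default
and is used for all calibration work in this package; stopping at a target
tip count (`n_target`) uses simple first-passage stopping, which is known
to distort the tree-age distribution relative to generalized sampling
approaches (the estimator consequences are visible directly: first-passage
stopping makes `(n − 2)/S` biased upward by about `λ/(n − 3)`), so it is
provided for convenience rather than calibration.

Two sampling schemes emulate how real trees are assembled: `uniform` keeps
exactly `round(f · n)` tips chosen without replacement (deterministic test
sizes; a per-tip Bernoulli would make them random), and `one_per_clade`
keeps one random tip from each maximal clade younger than a cutoff age,
mimicking one-species-per-genus sampling of genus-level trees.

Trait evolution is Brownian motion: each child state is its parent's state
plus Normal(0, σ² × branch length). An optional cladogenetic jump adds an
independent Normal(0, jump_sd²) to each daughter lineage at its origin —
"once per branching event" is implemented symmetrically, one jump per
branch, rather than privileging one daughter. With `log_trait = TRUE` the
states live on log scale and tip traits are exponentiated, giving positive,
Vcmax-like values suitable for log-scale association tests. Every
generator takes an explicit integer seed and restores the caller's RNG
state; nothing draws from an implicit stream.

What the simulator does not emulate: fossilized birth–death sampling,
protracted speciation, time-varying or state-dependent rates, measurement
error in branch lengths, and non-random taxon selection beyond the
one-per-clade scheme. Passing bias checks on these simulations therefore
demonstrates the *mechanism* of the estimators' failure, not a calibrated
forecast of its magnitude in any particular empirical tree.

## The naive estimators, taken literally

* `naive_origin_ages()` — a tip's origin is its parent-node age in the
  analyzed tree.
* `interval_median_states()` — per-interval median over contributing tips;
  even counts use the mean of the two middle values; empty intervals are
  reported absent (`NA`), never zero, and are excluded from downstream
  comparisons rather than imputed.
* `magallon_sanderson_rate()` — `log(n)/t` with the natural logarithm
  (recorded in output manifests) and the stem age as `t`.
* `kendall_moran_rate()` — `(n − 2)/S`, the crown-conditioned pure-birth
  maximum-likelihood rate; the recovery of λ on complete Yule simulations
  (and agreement with `ape::yule()`) is the correctness check.
* `naive_rate_through_time()` — "pruning tips and branches younger than
  each interval" is operationalized as slicing: the lineages crossing the
  interval's young boundary `T` are the counted units and the rate is
  `log(n_T)/(stem age − T)`. This is the one reading that yields a
  well-defined count per interval; the per-interval elapsed time is
  `stem age − T`. Both interpretations are recorded in run manifests.

## Ground truth and the bias reports

The true origin age of an extant tip is its parent-node age in the fully
sampled reconstructed tree. Even this is an analysis convention — any real
tree undersamples, so "truth" here means truth within the simulation.
`origin_age_bias()` reports the mean percent inflation as the mean of
per-tip ratios, with the ratio-of-means aggregation reported alongside
(the two differ materially because the ratio distribution is heavy-tailed:
a tip whose true sister split very recently can show a four-digit percent
inflation), and the squared Pearson correlation of log naive vs log true
ages.

The true ancestral trait per interval is the mean over all complete-tree
branches alive at the interval midpoint of the linearly interpolated state
between the branch's endpoints — linear interpolation is the Brownian
bridge mean, and the midpoint makes the interpolation unbiased for the
interval. `asr_bias()` pairs this with the naive medians and also reports
the drop-one-tip sensitivity of the naive series.

## Reference study conditions

The package's calibration suite runs at fixed, package-chosen conditions:
pure-birth trees with λ = 0.1 per lineage per My and crown durations of
40–50 My (expected sizes roughly 100–300 extant tips, the scale of
genus-level comparative datasets), uniform sampling fractions
{0.05, 0.2, 0.5, 1}, 150–500 tree replicates per experiment, and 400
replicates × 999 permutations for test calibration. Trees are conditioned
on at least 40 extant tips so that even the 5% sampling fraction retains
the two tips a bias report needs.

Because single subsample draws of the mean-percent-older statistic are
dominated by whether a near-zero true-age tip happens to be included, the
ensemble means across sampling fractions are estimated by averaging 40
independent subsample draws per tree per fraction (Rao–Blackwellization
over the sampling stage). This reduces Monte-Carlo noise without changing
the estimand; the monotone decrease of inflation with increasing `f`, and
its nonnegativity in every single draw, are exact consequences of pruning
monotonicity and are asserted as such.

One calibration caveat is worth stating because the package measures it:
over an ensemble of fixed-duration crown Yule trees, the *mean of per-tree*
Kendall–Moran estimates sits slightly below λ (about 1–1.5% at these tree
sizes) even though the estimator is consistent on any single growing tree.
This is a Jensen-type effect of averaging ratios whose numerator and
denominator are jointly random, shrinks only slowly with tree size, and is
itself a small instance of the package's broader theme: ensemble summaries
of ratio estimators are not automatically unbiased.

## The association test

`dr_statistic()` implements the inverse equal-splits tip rate
(`ES_i = Σ_j l_j (1/2)^(j−1)` over root-ward branches, `DR_i = 1/ES_i`), a
deliberate substitution for model-based (BAMM-style) rate regimes: tip
rates have fewer identifiability problems and need no MCMC.
`permutation_test()` computes Pearson correlation on logs (or Spearman) and
a permutation p-value by the add-one rule, ties counted as extreme, so
`p ≥ 1/(B+1)` and the test is valid at finite B. The `tip_shuffle` null
permutes traits across tips and is calibrated under exchangeable traits;
it is anticonservative when rates and traits share phylogenetic signal,
which is exactly why regime-level permutation (STRAPP) exists —
`regime_shuffle` permutes regime rates across regimes and lets tips
inherit them. Two-tailed testing on |r| is the default, one-tailed is an
option.

## Numerical choices and degenerate inputs

Branch lengths must be finite and non-negative; duplicate or empty tip
labels are parse errors naming the offending label. Pruning to one tip
yields a single-branch tree carrying the tip's full root-to-tip path.
Single-lineage rate series are identically zero (`log 1`). Zero-variance
traits make correlations undefined and raise errors rather than returning
`NA`. Permutation ties are resolved conservatively (counted as extreme,
with a 1e-12 comparison tolerance). Inflation sign assertions use a 1e-9
tolerance because pruned parent ages are re-summed floating-point branch
lengths; the inequality is exact in real arithmetic.

## Interfaces

Everything is plain text: Newick in and out (unquoted labels, decimal
branch lengths — the smallest interoperable dialect), CSV tables for
traits, origin tables, ancestral series, rate series and bias reports, and
key=value manifests recording seeds, parameters and the interpretation
choices above. `run_pipeline()` wires the stages together under a single
master seed from which all stage seeds are derived; every stage can also be
re-run standalone from the previous stage's files. The package is used from
R; `run_four_taxon_demo()` reproduces the four-taxon worked example, and
`scripts/acceptance.R` in the source repository re-derives the headline
numbers from scratch.

## Known limitations

Bias magnitudes reported on simulations transfer only qualitatively to
empirical trees, whose sampling is neither uniform nor one-per-clade and
whose branch lengths carry estimation error. The mean-of-ratios inflation
summary is heavy-tailed and should be read alongside the ratio-of-means
variant. The exchangeable-null calibration of `tip_shuffle` says nothing
about its behaviour under phylogenetic signal, where only the regime-level
null is appropriate. And the simulator's constant-rate assumption means
rate-through-time curves here isolate sampling artifacts; they cannot
separate them from genuine rate variation, which is the point of the
exercise rather than a defect.
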