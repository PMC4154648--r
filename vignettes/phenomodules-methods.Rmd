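---
title: "Methods: integrating multi-profile screens with gene sets and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating multi-profile screens with gene sets and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Data model and assumptions

The input is a `P × N` matrix `D` of phenotypic profiles: one row per
perturbation experiment, `N` quantitative parameters per row, with a gene
label per row. A gene may have any number of profiles `m_i ≥ 1`, and the
counts may differ between genes; the parameter set must be identical for
all. Profiles are compared with the Pearson correlation, which is scale-
and offset-free per profile, but the parameters must still be normalized
so that no single readout dominates the correlation: `znormalize()`
standardizes every column to mean 0 and unit *sample* standard deviation
(denominator `P − 1`; for screen-sized `P` the distinction from the
population estimator is immaterial, and the sample form matches common
screen-analysis practice). A constant column is an error rather than a
silent NaN — the caller decides whether to drop the parameter.

Missing values are not imputed: a profile containing any missing
parameter is excluded from similarity computations. A profile with zero
variance yields an undefined correlation, which every consumer treats as
"not similar"; a single flat well therefore cannot abort a run.

Both algorithms assume that functionally related genes share a phenotype
*up to sign* in the module search (a complex member may act as an
activator or inhibitor, inverting the profile) and *with positive sign*
in the set search, where complex members are expected to co-vary.

## The gene-set search

Within a set, all profiles are cross-correlated and each profile is
tested as an *anchor*: it covers every gene owning at least one profile
with `r ≥ T` to it (itself included). The anchor covering the most genes
wins — counting *genes*, not profiles, so a gene with many oligos cannot
dominate the pattern. Ties are broken by the larger sum of correlation
values of the selected profiles, remaining ties by the lexicographically
smallest (gene, oligo) label, which makes the search deterministic and
invariant to input row order. The threshold is closed (`r = T` passes).
All passing profiles of every covered gene are selected; their
per-parameter median is the reference profile (even counts: midpoint of
the central pair). The median is deliberate: selected profiles still
contain off-target outliers, and the median is robust to them where a
mean is not.

Significance is a structure-preserving permutation test. Pseudo-sets
replicate the observed set's per-gene profile counts, moving whole
per-gene bundles so the within-gene correlation structure survives in the
background. Genes are matched on their exact profile count when at least
five candidate genes carry that count (so the draw is not degenerate),
otherwise on the count's bin (see binning below); sampling is without
replacement within one pseudo-set. The p-value is the plain fraction of
pseudo-sets whose statistic reaches the observed one. Two statistics are
exposed because the natural description ("the same or more profiles are
selected") differs from the search criterion (gene coverage): the default
compares the number of *selected profiles*, `statistic = "genes"` compares
the covered gene count. A zero count is reported as p = 0 with resolution
`1/n_rand` attached; a `(count + 1)/(n_rand + 1)` estimator is available
(`laplace = TRUE`) for consumers that need strictly positive values.

## The network-module search

**Seeds.** Every node with at least `k_s` profiles is tested by running
the enriched-pattern search over the node plus its direct neighbors, in
absolute-similarity mode at threshold `T_s`. The node is kept as a seed
when the winning anchor belongs to the node itself and at least one
neighbor profile is selected. The anchor condition deserves a note, since
a looser reading — keep the node whenever the neighborhood holds an
enriched pattern anywhere — is also defensible. We implemented both
(`module_params(seed_rule =)`) and made "center-anchor" the default: under
the looser rule a gene's own profiles can anchor a *neighbor's* seed, so
every strong-phenotype gene drags a module into existence wherever it
sits, and randomizing the network no longer destroys the signal. The
stricter rule ties every seed to similarity between the node and its
neighbours and restores the expected collapse under randomization (the
package's randomization tests exercise exactly this). The seed profile is
the median of the selected profiles after swapping anti-correlated ones;
a node whose passing profiles split in sign keeps the orientation with
the larger sum of absolute correlations (ties: positive), dropping the
minority profiles.

**Expansion.** Growth is greedy against the *fixed* seed profile — the
profile is never updated, so the module cannot drift away from the
phenotype that seeded it. At each state, every non-member gene adjacent
to the module qualifies if at least `k` of its profiles pass `|r| ≥ T`
against the seed profile with a consistent orientation (minority-sign
passing profiles are dropped first; the retained, same-orientation set
must still reach `k`). All qualifying neighbors join simultaneously.
With `k_is_fraction = TRUE`, `k` is read as a fraction of the gene's
profiles, `ceiling(k · m_i)`, at least 1. Expansion halts when no
neighbor qualifies or after `max_steps = 50` states. The terminal state
with zero qualifiers is recorded and scored — observing "no further
growth" is part of the observed trajectory; a seed whose first
neighborhood is empty yields no Bernoulli trials and a p-value of 1.
Rejected neighbors stay in later states' trial sets while still adjacent
and unjoined; since the seed profile is fixed they can never qualify
later, which makes consecutive states statistically dependent — the
p-value below inherits the independence assumption regardless.

**Backgrounds.** The probability that a random gene would join is not
uniform: some phenotype patterns are frequent in a screen, and genes with
more profiles have more chances to pass. Both effects are absorbed into
profile-specific empirical backgrounds: for each seed profile and each
profiles-per-gene bin, `p̂_i` is the fraction of `n_rand_bg` genes drawn
(with replacement) from the bin that would qualify under the same
orientation-aware rule the expansion applies. We use the expansion's own
rule rather than the plain "≥ k profiles with `|r| ≥ T`" so that the
Bernoulli success probability estimates exactly the event whose
occurrences it prices. Binning defaults to one bin per exact count 1..7
plus a pooled "8+" bin — screens rarely have many genes with more than 7
oligos, so exact bins above that would be empty; `n_bin` switches to
quantile bins. Empty bins fall back to the nearest non-empty bin. The
default `n_rand_bg = 1000` bounds the Monte-Carlo error of each `p̂` at
about 0.016; `n_rand_bg = Inf` computes the exhaustive fraction over the
bin, which the test suite uses when it checks the probability engine so
that background sampling error does not blur the comparison.

**Assessment.** A state with `n` neighbor trials and `k_obs` qualifiers
has probability given by the Poisson-binomial mass at `k_obs` over the
per-neighbor `p̂` values, computed with the `O(n·k)` dynamic-programming
convolution. This is the default of three implemented readings: it
reduces exactly to the homogeneous binomial mass when all `p̂` coincide;
`"config"` is the literal product over the observed per-neighbor outcome
(which lacks the combinatorial factor), `"tail"` is the upper-tail
probability. The module p-value multiplies the state probabilities over
the trajectory in log space (50 states of 0.9 evaluate without
underflow). Finite-draw `p̂` values are clamped half a count away from 0
and 1 before entering a state probability, so a Monte-Carlo zero cannot
zero out a module; exhaustive backgrounds need no clamp (a qualifying
neighbor proves its bin fraction is positive).

Modules with identical member sets are deduplicated keeping the smallest
p-value; seeds are enumerated in ascending gene order, so results do not
depend on input file order. Seed-only modules — seeds whose expansion
never grew — are reported and flagged, but excluded from the gene ranking
by default (`gene_scores(include_seed_only = FALSE)`): they carry no
network support, and counting them would rank genes by bare phenotype
consistency, which also keeps ranking signal alive under network
randomization where the method's value should vanish.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `T` | 0.7 | similarity threshold (Pearson r) for selection/expansion |
| `mode` | sets: positive; modules: absolute | whether anti-correlated profiles count |
| `k` | 3 | profiles of a gene that must pass for module membership (2 = discovery setting) |
| `T_s`, `k_s` | 0.8, 2 | seed-selection threshold and minimal profile count |
| `max_steps` | 50 | expansion cap in states |
| `n_rand` | 5000 | pseudo-sets per gene set |
| `n_rand_bg` | 1000 | background draws per profile-count bin |

All thresholds are in correlation units; raising `T` never increases the
number of covered genes (monotonicity is property-tested).

## The simulator, and what it does not emulate

`generate_screen()` emulates the structure of a large image-based RNAi
screen: 40 parameters, on average 7 oligos per gene (`1 + Poisson(6)`,
minimum 1), z-normalized output. True phenotypes are drawn from a pool of
archetypal profile shapes — random unit-norm vectors kept pairwise
dissimilar (|r| < 0.3) by rejection sampling — assigned to planted,
connectedly wired gene groups; all other genes are null. Each oligo
reports its gene's true profile plus `N(0, σ_w)` parameter noise, except
with probability `ote_rate` it is off-target and reports a random
archetype instead. Off-target profiles draw from the same archetype pool,
*not* white noise, precisely so that frequent patterns exist and the
profile-specific background correction has something to correct; an
optional `archetype_skew` sharpens that frequency bias.

Two features of real screens are deliberately not modeled, and they bound
what passing tests demonstrate. First, real off-target phenotypes have
reagent-specific structure (seed-sequence-driven, correlated with the
reagent, occasionally shared between reagents); the simulator draws each
off-target archetype independently per oligo. A consequence measured by
the acceptance suite: per-gene *averaging* largely cancels this
independent contamination, so a single-average analysis is genuinely
competitive on simulated data, whereas on real screens collapsing
replicates is reported to cost substantial accuracy. The corresponding
acceptance check is therefore expected to fail on this generator, and its
failure is informative about the generator, not the algorithms. Second,
image-derived parameters are mutually correlated in blocks; simulated
parameters are independent given the archetype, so effective
dimensionality is higher than in real data and null correlations are
milder.

## Calibration and numerical choices

Null calibration is checked on signal-free screens. The operating point
`T = 0.7` is unusable there — two 40-dimensional noise profiles
essentially never reach r = 0.7, every statistic degenerates and nothing
can be learned — so the calibration studies run at thresholds chosen at a
non-degenerate quantile of the null correlation distribution (`T = 0.2`
for sets, `T = 0.35` with `T_s = 0.3` for modules). Set-level p-values
are exactly calibrated at their achievable values by construction
(observed and pseudo-sets are exchangeable); because the selection
statistic is integer-valued the p-values are discrete, and the
Kolmogorov–Smirnov comparison against a continuous uniform is sensitive
to the largest atom — the calibration design therefore uses set sizes
6–12, which spread the statistic widely enough for the test.

Module-level p-values are *not* uniform under the null, and cannot be:
the product of per-state trajectory probabilities is a semi-analytic
probability of the observed expansion path, not a probability-integral
transform of a test statistic. Under the null it spans many orders of
magnitude with a non-uniform shape. The acceptance suite measures this
honestly (the uniformity check for modules fails by a wide margin); for
practice this means module p-values order modules well and separate
planted from null structure, but their absolute scale should be read as a
score, not as a frequentist tail probability — a limitation the
independence assumption across states already signals.

Other numerical conventions: correlations are computed from
row-standardized matrices via `tcrossprod` and clipped to `[-1, 1]`;
zero-variance rows propagate as "not similar"; tie-breaks (anchor
selection, orientation, reference-profile majority) resolve
deterministically as described above, with the positive orientation and
the seed orientation as the final defaults; all stochastic steps accept
an explicit seed and two runs with the same seed are bitwise identical.

## Problem sizes used by the test suite

Unit tests run on screens of up to a few hundred profiles with
brute-force oracles (anchor-loop pattern search, 2^n Poisson-binomial
enumeration, exhaustive pseudo-set enumeration, Mann–Whitney AUC). The
end-to-end acceptance studies use: a 500-gene scale-free screen with
three planted 8-gene modules (σ_w = 0.1, 30% off-target, ~7 oligos/gene)
for recovery, degradation and baseline comparisons, with three repeats
per noise/randomization condition and five simulation seeds for the
averaging comparison; a 300-gene null screen with 200 random sets
(1000 pseudo-sets each) and five 800-gene null screens (pooling over 200
modules) for calibration; 10^5-draw Monte-Carlo oracles per expansion
state for the probability engine. These sizes keep the full suite within
a few minutes on one CPU while leaving every estimate's Monte-Carlo error
well below the tested tolerances.

## Known limitations

- Greedy expansion is order-free within a state but cannot revisit a
  rejection; exact search formulations are out of scope.
- The module p-value assumes independent states (see above) and is best
  treated as a ranking score; sets use raw permutation p-values with no
  multiplicity correction by default (Benjamini–Hochberg is available
  behind a flag in the CLI).
- Gene identifiers are opaque case-sensitive strings; no ortholog or
  symbol mapping is performed.
- The simulator's independent off-target model understates the advantage
  of multi-profile analysis over replicate averaging; conclusions about
  that comparison require real screen data.
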