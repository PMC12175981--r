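---
title: "Modeling olfactory attractiveness from volatile proportion profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling olfactory attractiveness from volatile proportion profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volatrank)
```

## The problem

Gravid female flesh flies choose larviposition substrates by smell. Given a
set of benchmark products whose relative attractiveness has been measured
behaviorally, and GC-MS volatile profiles for both the benchmarks and new,
untested products, we want to (i) identify which odorants carry the
attractiveness signal, and (ii) predict where an untested product falls in
the attractiveness order — without running a new bioassay for every product.

All chemistry enters as *proportions*: a compound's peak area as a
percentage of the product's total peak area. This is compositional data —
each product row sums to 100 — which has two consequences used throughout
this vignette: absolute emission rates are invisible, and no subset of
compounds can vary while the rest stay exactly fixed.

## Behavioral ranking

A two-choice trial releases `n_flies`; some respond and walk to one arm.
The *choosing ratio* of an arm is its share of responders (default) or of
all flies (`denominator = "all"`). Responders is the default because
participation in these assays is characteristically low, and non-responders
carry no preference information under the model below.

`rank_products()` aggregates trials two ways:

* **pooled** — a product's mean choosing ratio over every trial it appears
  in; order-invariant, the default.
* **calibrator** — rounds are processed in order; each round designates one
  calibrator whose accumulated mean is frozen at the end of its round, after
  which it may not reappear. The behavioral literature that motivates this
  scheme describes the design (one calibrator per round, excluded from
  subsequent rounds) but not the aggregation arithmetic, so the freezing
  semantics here are this package's own choice, made for determinism and
  because they reduce to the pooled mean when every product calibrates last.

The numeric response passed downstream is the *attractiveness score*
`n + 1 − rank`, so a compound enriched in attractive products has a
*positive* correlation — matching the field's sign convention (ethanol
positive, known repellents such as sorbic acid negative).

Ties in mean ratio are broken lexicographically by product id and flagged
in the `"ties"` attribute; deterministic output was preferred over random
tie-breaking.

## Screening and panel selection

`correlate_with_ranking()` computes Pearson r between each compound and the
score, with the p-value from the exact t transform
`t = r sqrt((n−2)/(1−r²))`. With only ~9 products, power is limited and no
multiple-testing correction is applied by default (`p_adjust = "BH"` is
available); this mirrors the screening practice the package reimplements,
where raw significance at alpha = 0.05 selected a handful of seeds.
Constant compounds have undefined r and are flagged `skipped`.

`pattern_search()` expands seeds into a panel: every other compound is
correlated against the seed's proportion vector, the `top_k` (default 25)
best under the sign rule are kept above `min_r`, and the panel is the union
of seeds and kept correlates, ordered by descending mean proportion.
Because the data are closed, a block of compounds driven by one shared
factor necessarily contains members moving in opposite relative directions;
`sign_rule = "absolute"` captures both sides of such a block, while the
default `positive_only` matches the narrower "co-varying biomarkers"
reading. The exact filter that a published 21-member panel implies is not
recoverable from panel membership alone, so `top_k` and `min_r` are exposed
rather than hard-coded.

## The chem-index

For a blind product's panel proportions `y` against a benchmark's `x`,
`origin_least_squares()` fits `y = m·x` with the spreadsheet no-intercept
conventions: residual df `n − 1`, `se_m = sqrt((Σe²/(n−1))/Σx²)`, and the
*uncentered* `R² = 1 − Σe²/Σy²`. Then

```
chem_index = |m − 1| + |R² − 1| + se_m
```

is 0 exactly when `y = x` and penalizes, respectively, systematic scaling,
scatter around proportionality, and noise in the fitted slope. The three
statistics are read as slope, its standard error, and uncentered R² — the
row order of the spreadsheet least-squares statistics array the original
formula indexes; this is the only reading under which a self-match scores 0,
which the index's use as a similarity score requires.

Design choices worth stating:

* the blind vector is the regressand and the benchmark the regressor
  (the formula's argument order is known-y, known-x);
* one simple regression per benchmark, not one multiple regression on all
  benchmarks — the index consumes exactly one slope, SE and R²;
* `estimate_rank()` takes the argmin over benchmarks; ties go to the more
  attractive rank and are flagged (conservative for screening use);
* a degenerate all-zero blind panel yields `m = 0`, `R² = 0` by convention
  and is flagged, rather than erroring, since a blind product genuinely may
  lack every panel compound.

An estimated rank is a nearest-benchmark label, not an interpolation: it
brackets the blind product within the known set and makes no claim between
ranks.

## Trap-arena validation

`trap_index()` is the trap-side analogue of the choosing ratio.
`pair_chem_value()` reduces a pair's model results to one coordinate;
`score_difference` (default) compares the estimated-rank scores of the two
products, because the validation narrative compares *rankings* between
trapping results and model estimates; `index_difference` and
`sample1_similarity_to_top` are retained for sensitivity analysis since the
published pairing rule is not machine-readable. `validate_traps()` fits a
simple linear regression *with* intercept (unlike the chem-index's internal
fits) and reports `R²`, `F = R²(n−2)/(1−R²)` on (1, n−2) df, and its
upper-tail p — the arithmetic identity the acceptance suite checks at the
published operating point (R² = 0.4999, n = 9 → F₁,₇ ≈ 6.997, p ≈ 0.033).

## What the synthetic generator emulates

`generate_profiles()` builds a world with the same shape as the motivating
study: 9 benchmark products (10 in the T-maze configuration), 110
compounds, 10 positively and 4 negatively loaded odorants, and a
21-compound correlated block. Latent attractiveness `a` is evenly spaced
then jittered (SD = a quarter of the spacing); abundances are
`baseline · exp(loading·a + ε)` with lognormal noise `ε` (default SD 0.25,
a typical GC-MS proportion CV) and the rows are closed to 100%.

Two constructions deserve explanation:

* **Balanced groups.** Closure means planted variation would leak into
  every unloaded compound (all would co-vary with 1/total and acquire
  spurious correlations of magnitude up to 1 in the noiseless limit). The
  loaded group and the block are therefore each rescaled to a constant
  per-product total before closure, so unloaded compounds are exactly
  constant at zero noise. The cost is mild: noise within a group is slightly
  redistributed.
* **The block factor.** The 21-compound block loads on a second latent
  factor generated orthogonal to the attractiveness axis, so the screening
  structure (10+4) and the pattern-search structure (21) are separable; and
  because of closure, roughly half the block members anti-correlate with
  the rest — which is why block recovery uses `sign_rule = "absolute"` with
  a high floor (`min_r = 0.9`; at zero noise within-block |r| = 1 while any
  cross-structure correlation is an n = 9 sampling accident).

Behavioral sampling: each fly independently no-chooses with `p_nochoice`
(default 0.4 — participation is low in this system), otherwise picks an arm
with odds `exp(choice_beta · a)` (default β = 3: an extreme pair splits
roughly 95:5, adjacent products ~58:42, consistent with the spread of
observed choosing ratios). Trap counts are one multinomial draw per pair.
`noise_sd = 0` selects the fully noiseless world: behavioral sampling also
becomes deterministic (every responder takes the better arm), which is the
limit in which exact-recovery tests are meaningful. The calibrator design
runs worst-first (next calibrator = least attractive remaining product);
this is the simple sequential design under which noiseless trials recover
the planted order exactly.

What the generator does **not** emulate: chemically realistic co-occurrence
(compound identities are anonymous), absolute emission rates, arena spatial
structure, day effects, or sex/physiological-state variation. A green test
therefore establishes algorithmic correctness against planted structure,
not field validity of any particular biological claim.

## Calibration of "low noise" rank recovery

The rank estimate degrades gracefully with profile noise. For a blind
product planted midway between the 4th- and 5th-ranked benchmarks
(adjacent-benchmark compositional gap ≈ 6%), the probability of estimating
rank 4 or 5 across 200 seeds is:

| noise_sd | 0.10 | 0.05 | 0.02 | 0.01 | 0 |
|----------|------|------|------|------|---|
| P(rank ∈ {4,5}) | 0.60 | 0.80 | 0.95 | 0.995 | 1.00 |

(misses land on the flanking ranks 3/6). The test suite's "low noise"
operating point is `noise_sd = 0.01` — measurement noise an order of
magnitude below the between-benchmark signal. At the default noise (0.25)
the estimated rank is a coarse bracket only; the ranking-recovery and
slope-sign validation tests, not rank pinpointing, are the meaningful
checks at that level.

## Numerical choices

* Proportions live on the 0–100 scale end to end; the chem-index consumes
  the same scale (no rescaling to fractions).
* Compound/product name matching is exact after whitespace trimming and
  case folding; no synonym resolution.
* A compound absent from a product's table is 0% (undetected), not missing:
  proportion-of-total semantics make absence a statement, not a gap.
* `origin_least_squares` uses `sum(x * x)` rather than `sum(x^2)` so a
  self-match yields slope exactly 1 in floating point.
* Row normalization tolerance: sums equal 100 within 1e-6; idempotence is
  exact up to one rounding of the renormalization factor (~1e-15 relative).
* Whether the 100% denominator covers all detected peaks or only identified
  compounds is a property of the upstream table; `normalize_proportions()`
  is only applied when the supplied compounds are meant to be exhaustive,
  and the CLI leaves the choice to the user.

## Known limitations

* With ~9 products, every screen is underpowered and unadjusted p-values
  are a ranking device more than an inference; the BH option exists but
  changes selection little at these sample sizes.
* The chem-index weights its three terms equally on incommensurable scales;
  it is a published operational definition, reproduced as such, not an
  optimized metric.
* Calibrator-mode semantics are this package's reconstruction of an
  under-specified sequential design; pooled mode is the default for that
  reason.
* The estimated rank cannot extrapolate beyond the benchmark set's
  attractiveness range.
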