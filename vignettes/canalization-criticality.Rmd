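---
title: "Canalization and the critical dynamics of Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canalization and the critical dynamics of Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Boolean networks (BNs) are the canonical discrete model of biochemical
regulation: each node is a binary automaton updated synchronously by a
logical rule of its `k` inputs. A BN operates in an *ordered* regime
(perturbations die out), a *chaotic* regime (perturbations spread), or near
the *critical* boundary between them, where biological networks are widely
believed to sit. The classical structural theory places the critical surface

    2 k p (1 - p) = 1

in terms of in-degree `k` and rule bias `p` (the fraction of ON entries in
the rule's look-up table). This package implements, end to end, the
competing *canalization* account: that what determines the regime is not how
many inputs a node has, but how many it *effectively needs* once the
redundancy in its logic is accounted for — its effective connectivity
`k_e` — and that a boundary of the form `c * <k_e> * p(1 - p) = 1` predicts
the regime of a network far better than the structural surface.

The package provides four layers, each usable on its own:

1. **Automata and canalization** — look-up-table rules
   (`boolean_rule()`), wildcard-schema redescription
   (`prime_schemata()`), effective connectivity
   (`effective_connectivity()`), average sensitivity.
2. **Controlled ensembles** — catalogues of rules indexed by
   `(k, p, k_e bin)` (`build_catalogue()`, `ga_fill_bins()`) and random
   BN ensembles homogeneous in all three parameters
   (`ensemble_spec()`, `generate_ensemble()`).
3. **Regime measurement** — Derrida divergence curves and the Derrida
   parameter ζ (`derrida_curve()`, `derrida_zeta()`,
   `classify_regime()`).
4. **Criticality models** — six logistic model classes in both the
   structural (`k`) and canalization (`<k_e>`) instances, boundary
   rearrangement, MCC / AUC / McFadden R² scoring, nested fourfold
   cross-validation, Pareto model selection and paired fold tests
   (`fit_model()`, `nested_cv()`, `run_pipeline()`).

## Effective connectivity

A rule's LUT can be redescribed as *wildcard schemata*: patterns over
`{0, 1, #}` in which `#` marks an input whose state cannot matter. The
maximal schemata are exactly the prime implicants of the rule's ON-set and
OFF-set, computed here by Quine–McCluskey-style merging, per output class.
For the 2-input OR rule the ON schemata are `1#` and `#1` and the OFF schema
is `00`: three of the four LUT entries are settled by a single input, one
needs both, so

```{r}
library(canalcrit)
effective_connectivity(or_rule(2))   # (3*1 + 1*2)/4
prime_schemata(or_rule(2))
```

Formally, the *enput* count of a LUT entry is `k` minus the wildcard count
of the most compressed schema covering it — equivalently the size of the
smallest input subset whose fixation forces the output — and `k_e` is the
mean enput count over all `2^k` entries. `k_e = 0` only for constant rules;
`k_e = k` only for the two parity rules (the only functions with no
redundancy at all). Average sensitivity, by contrast, sums each input's
*independent* activity and misses collective canalization:
`s(AND2) = s(COPY) = 1` although `k_e(AND2) = 1.25 > k_e(COPY) = 1`.

Two implementation notes. The hot path (catalogue construction evaluates
`k_e` for tens of thousands of rules) runs in compiled code as a dynamic
programme over monochromatic subcubes; the prime-implicant route is kept as
an independent second implementation, used for arities above 12 and
cross-checked against the kernel in the tests, alongside a brute-force
minimal-subset oracle. Only single-symbol (wildcard) schemata are needed:
`k_e` derives from the upper bound on input redundancy, which two-symbol
(input-permutation) redescription does not change.

## Rule catalogues and the GA

Ensembles need rules at prescribed `(k, p, k_e)`. Bias is realized exactly
as an integer ON count `round(p 2^k)`; `k_e` is binned into half-open
intervals `[c - 0.25, c + 0.25)` on multiples of 0.5 (a rule with
`k_e = 1.25` belongs to bin 1.5). Catalogues are exhaustive for `k <= 4`
(and whenever `choose(2^k, ones)` is below the cap), and otherwise hold
10^4 distinct uniformly sampled rules per `(k, p)` — the cap is a
compute/coverage compromise kept configurable.

Random sampling concentrates `k_e` in a narrow band (roughly `k - 2` at
`p = 0.5`), so remote bins — strongly canalized rules, or parity-like rules
— are populated by a bias-preserving genetic algorithm: fitness
`-|k_e - target|`, tournament selection (size 3) with elitism, mutation
that swaps one ON with one OFF entry so the ON count is invariant, no
crossover (it would break the count), at most 500 generations with an
early stop after 100 stagnant generations. Plain random initialization
provably stalls on this landscape: `k_e` jumps discontinuously near highly
canalized rules (one swap away from "copy the first input" the value leaps
from 1 toward 2), so the initial population is seeded with canalization
templates — rules whose ON entries are confined to a random subcube
(low `k_e`), parities over random input subsets (`k_e` equal to the subset
size, available when `ones = 2^(k-1)`), and lightly perturbed full
parities (`k_e ~ k`) — alongside random individuals. With this seeding
every representable bin we know of is reached within the generation
budget, and a bin the search cannot populate is reported as unreachable
and the ensemble cell skipped, never fabricated. Genuine examples exist:
at `k = 2, p = 0.25` all four rules have `k_e = 1.25`, and at `p = 0.5`
no rule we could find has `k_e` strictly between the copy-like value 1 and
the parity-pair value 2, so bin 1.5 is honestly empty there.

## Ensembles

An ensemble cell `(k, p, <k_e> bin)` holds networks of `N` nodes, every
node with `k` distinct random inputs (self-inputs permitted — external
input nodes are conventionally self-loop copies) and a rule drawn with
replacement from the cell's catalogue bin. The default sweep follows the
homogeneous design: `N = 100`, `k in {2, 3, 4, 6, 8}`, bias grid with step
`1/2^k` clipped to `[0.01, 0.5]` (the lower edge is a clipping bound —
small biases are unattainable at small `k`; only `p <= 0.5` is swept
because of the `p <-> 1 - p` duality of Boolean logic), `<k_e>` bins from 1
to `k` in steps of 0.5, and 10 replicates per viable cell (a configurable
default: the full-scale study reports a total ensemble size, not a
per-cell count). Tautologies and contradictions never enter ensembles:
their bins lie below 0.75 and they force `k_e = 0` and degenerate
dynamics. Seeds are derived hierarchically (master → catalogue → cell), so
any cell can be regenerated independently of the rest of the sweep.

## Derrida parameter and regime labels

For each network we draw `I` random configuration pairs differing in `m`
node states (`m` uniform on `1..floor(N/10)`; "N/10" is taken as a floor),
advance both one synchronous step, and record the Hamming distance. ζ is
the least-squares slope through the origin of mean divergence against `m`
— at `t = 1` the Derrida map is near-linear in `m`, making this the
natural discrete estimate of the slope at the origin; the regression is
unweighted over the observed `m` values. A network is *chaotic* iff
`ζ > 1` strictly; ζ = 1 (criticality) is grouped with the stable side.
Perturbations may hit any node, including self-loop input nodes, since
damage anywhere can propagate downstream. An optional stratified mode
(equal pairs per `m`) is available for variance control but is off by
default, matching the random-`m` design.

## Criticality models

Each network contributes a record `(k, p, <k_e>, ζ, R)` with
`R = 1(ζ > 1)`. Six nested model classes are fitted by maximum-likelihood
logistic regression, each in two instances (`κ = k` structural, or
`κ = <k_e>` canalization), with `p(1-p)` as the single bias term:

    1. c1 κ              4. c1 κ + c2 κ p(1-p)
    2. c1 κ p(1-p)       5. c1 κ p(1-p) + c2 p(1-p)
    3. c1 κ + c2 p(1-p)  6. c1 κ + c2 κ p(1-p) + c3 p(1-p)

The fitted 0.5-probability locus is rearranged into the boundary form
`sum c_i term_i = 1` via `c_i = -b_i / b0` (the intercept is always
included and absorbed by the division). No regularization is applied —
the coefficients are read as theory constants; quasi-separation, which a
crisp boundary makes likely, is handled by the iteration cap and surfaced
in the fit diagnostics rather than shrunk away. Predictions threshold the
probability at τ = 0.5, with ties predicted chaotic (mirroring the strict
`ζ > 1` on the label side). A `k × <k_e>` interaction fit
(`fit_interaction_model()`) tests whether in-degree adds anything beyond
effective connectivity.

Generalization is measured by nested fourfold cross-validation: 4 outer
75/25 splits; each outer training split is again split 4-fold, training on
three quarters and scoring on the held-out quarter — 16 train/test pairs,
averaged. The wording "repeated four times" is ambiguous; this reading
matches the printed total of 16 pairs. Fold assignment depends only on the
seed and the number of records, so models evaluated under one seed share
folds, enabling the one-sided paired t-test of the canalization class-2
model against the structural one. The t statistic is computed directly so
that degenerate inputs are defined (identical fold scores give p = 0.5; a
zero-variance positive shift gives p = 0, flagged); it agrees with
`t.test(..., paired = TRUE)` on regular input. McFadden's R² on a test
fold uses the intercept-only probability fitted on the corresponding
training split. MCC is computed by the confusion-count formula and defined
as 0 when a denominator factor vanishes; AUC is the normalized
Mann–Whitney rank statistic. Pareto selection returns the
lowest-complexity class within δ = 0.01 of the best mean metric.

## The synthetic generator as a study design

`run_pipeline()` chains the stages deterministically from one master seed.
The generator's defaults emulate the homogeneous ensemble design above;
what it deliberately does **not** emulate is real biochemical networks:
degree heterogeneity, correlated wiring, rule classes selected by
evolution, and asynchronous update are all absent. Passing tests on these
ensembles therefore validates the machinery and the homogeneous-ensemble
conclusions, not field performance on arbitrary biological models; for
those, `analyze_model_collection()` applies the same per-network measures
(means of `k`, `p`, `k_e` over nodes, ζ, and class-2 refits in both
parameter spaces) to user-supplied networks read from logical-expression
(.bnet dialect) or truth-table files.

The package's own test and acceptance studies run a reduced sweep chosen
to fit a desktop: `N = 50` nodes, 10 replicates per viable cell, bias
step `max(1/2^k, 1/16)` and `I = 100` Derrida pairs — about 1 800
networks, where the full grid implies hundreds of thousands. At this
scale the fitted canalization boundary constant and the overall regime
balance are stable across master seeds, while classification scores
carry the extra regime-label noise of small networks: about one network in ten has
ζ within 0.1 of the critical value, and those labels are intrinsically
uncertain, which caps the attainable MCC of *any* boundary classifier on
such data (an exhaustive threshold scan on the canalization axis peaks
near 0.89 at this scale). The cross-validated scores reported by the
reduced study should be read with that ceiling in mind.

## Numerical choices and edge cases

* LUT rows are ordered lexicographically with the **first** listed input
  most significant; all parsers and writers share this convention.
* Requested biases are rounded to the nearest attainable ON count;
  `k = 0` rules are representable but may not appear in networks
  (minimum arity 1; constants are written as 1-input self-loops).
* Empirical filtering removes constant rules first, then single-input
  rules (`k_e = k = 1` carries no canalization signal); quartiles use the
  median-of-halves rule and the IQR is reported as the `(Q3, Q1)` pair;
  skewness is the Pearson moment coefficient and kurtosis is excess
  (normal = 0).
* `derrida_coefficient()` rejects tables with zero total weight;
  `ga_fill_bins()` validates targets against `[0.75, k + 0.25]`;
  single-label record sets are rejected by all fitting functions.
* Heterogeneous networks reuse the homogeneous Derrida procedure
  unchanged; their records use per-node means.

## Known limitations

* The state-transition-graph side of BN analysis (attractors, basins) is
  out of scope, as are asynchronous update policies and
  heterogeneous-degree ensemble designs.
* Catalogues above `k = 15` are unsupported; the compiled `k_e` kernel
  covers `k <= 12`, with the prime-implicant route (efficient for
  canalized rules, exponential in the worst case) beyond that.
* GA bin coverage is a search result, not a guarantee: a reported
  unreachable bin means the search failed, which for some cells is a
  genuine non-existence (verified exhaustively for small `k`) and for
  others merely very hard.
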