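---
title: "Modelling bystander selectivity of cytosine base editors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bystander selectivity of cytosine base editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beselect)
```

## The problem

Cytosine base editors (CBEs) fuse a nickase Cas9 to a cytidine deaminase and
convert C to T within a short activity window. When that window contains a
second cytidine — a *bystander* — the deaminase edits it too, degrading
precision. Deaminase point mutations that weaken ssDNA binding can suppress
bystander editing, but the effect is non-monotone: weaken too little and
nothing changes, weaken too much and on-target activity collapses. `beselect`
implements a discrete-state stochastic model of this trade-off, quantifies
it as a selectivity landscape, and turns it into a screening rule for
candidate mutations.

## The model

Editing is a continuous-time Markov chain with 15 states and four absorbing
products: CTC (no edit), CTT (target only), TTC (bystander only) and TTT
(both). The transient states track Cas9 binding (`u0`, dissociation `w0`),
competing commitment to an unproductive state (`u4`), engagement of either
cytidine by the catalytic site (`u1`, `u2`), unbinding of the engaged
cytidine (`w1`, `w2`) and chemistry (`u3`). After an edit, Cas9 release lets
DNA repair fix the outcome; rebinding is attenuated by a factor `m` in
[0, 1] because the edited protospacer no longer matches the sgRNA.

The splitting probabilities of the chain have closed forms obtained by
first-step analysis; the package evaluates them directly
(`outcomes_from_rates()`) and also exposes the chain itself
(`build_editing_network()`, `splitting_probabilities()`,
`simulate_gillespie()`), so every analytical result is checked against an
independent linear solve and a stochastic simulation in the test suite.

Only rate *ratios* matter for outcome probabilities. Six dimensionless
quantities determine everything (`reduced_params()`):

| parameter | meaning | A3A-BE3 calibration |
|---|---|---|
| `gamma1 = u4/u0` | unproductive vs productive initiation | 2.1 |
| `gamma2 = w1_wt/u3` | site unbinding vs chemistry | 11.4 |
| `gamma3 = w0/u1` | Cas9 dissociation vs engagement | 2.9e-5 |
| `m` | rebinding attenuation | 0 |
| `ddE0` (k~B~T) | bystander-vs-target context penalty | 6 |
| `ddEm` (k~B~T) | mutation-induced binding perturbation | design variable |

Binding free energies act on unbinding rates through Boltzmann factors:
`w1 = gamma2 * u3 * exp(ddEm)` and `w2 = w1 * exp(ddE0)`. Engagement is
taken to be diffusion controlled and context blind (`u2 = u1`). `gamma2`
comes from Michaelis–Menten constants via `infer_site_kinetics()`:
`kon = kcat/(KM − Kd)`, `w1_wt = Kd * kon`, `u3 = kcat` — for A3A
(Kd = 57 µM, KM = 62 µM, kcat = 1.1/s) this gives `w1_wt = 12.54`/s and
`gamma2 = 11.4`.

```{r calibration}
p <- a3a_calibration()
pt_pb_reduced(p)       # overall target / bystander editing probabilities
ratio_r1(p)            # target-first vs bystander-first engagement odds
ratio_r2(p)            # post-target-edit CTT : TTT odds
```

`R2 < 1` at the calibration says the wild-type enzyme usually goes on to
edit the bystander; increasing `ddEm` by a few k~B~T flips the dominant
product to CTT. Note a subtlety: the `R2` formula describes the
no-rebinding chain. With `m > 0` the realised CTT:TTT odds on the network
carry an extra factor `u4/(u4 + m*u0)`; the tests verify both forms.

## Selectivity landscape and screening

Selectivity is `S = P_t − P_b`. Sweeping `ddEm` produces a single-peaked
landscape: moderate destabilisation blocks the bystander (whose engagement
already pays the `ddE0` context penalty) while barely affecting the target;
strong destabilisation blocks both.

```{r screen}
curve <- selectivity_scan(p, ddEm = seq(-2, 12, by = 0.05))
(pk <- find_peak(curve))

screen_candidates(p, data.frame(
  name = c("mutA", "mutB", "mutC"),
  ddEm = c(2.0, 5.2, 10)))
```

`find_peak()` refines the grid argmax by golden-section search (tolerance
1e-4 k~B~T, ties toward the least destabilising `ddEm`) and reports a design
window — the contiguous interval with `S` at or above a configurable
fraction (default 0.9) of the peak; the threshold is a presentation choice,
not a model quantity, and is recorded in the output. Screening flags
candidates inside the window and ranks by predicted `S` with the candidate
name as a deterministic tiebreaker.

Sensitivity scans (`sensitivity_scan()`) reproduce the standard
diagnostics: dividing `gamma1` by 5 raises the attainable peak selectivity
while moving `S` at `ddEm = 0` by under 0.05 (numerically it moves ~0.045,
so "unchanged" is qualitative, not exact); dividing `gamma3` by 5
right-shifts the peak without changing its height (within 0.01); and `m`
in {0, 1} changes predicted probabilities by under 1e-4 at the calibration,
which is why fixing `m = 0` is safe.

## Fitting

`fit_gammas()` calibrates `gamma1` and `gamma3` (optionally `m`) to
observed per-variant `(P_t, P_b)` pairs by unweighted least squares, with
`gamma2`, `ddE0` and `m` fixed from independent information. The search
runs in `log10` space over `[-8, 3]` with a 5x5 multi-start grid and
L-BFGS-B refinement — the surface is smooth but spans decades, and the
procedure is fully deterministic. Weighting by reported s.e.m. is available
(`fit_options(weight_by_sem = TRUE)`) but off by default, since published
target and bystander curves appear to be treated equally. `ddEm`
measurement uncertainty is not propagated in the default fit; observations
carry it for reporting only.

## Synthetic data: what it does and does not establish

`generate_synthetic()` draws, per variant, `n_cells` independent outcomes
from the exact four-way outcome distribution at known true parameters and
summarises them as observed fractions — the stated world for
parameter-recovery tests (defaults: the A3A calibration, a five-variant
panel with `ddEm` in [0, 4.5] spanning wild type to a strongly
destabilising mutant, and 1e4 cells per variant, a typical effective depth
for amplicon sequencing). It emulates multinomial counting noise only: real
data additionally carry locus-to-locus context effects, replicate-level
overdispersion, and error in the `ddEm` estimates themselves (which come
from alchemical free-energy calculations, outside this package's scope). A
green recovery test therefore establishes identifiability and correctness
of the estimator under the model, not robustness to model misspecification.

## Numerical choices

* The reduced closed forms are evaluated after dividing numerator and
  denominator by the dominant Boltzmann factors, so they are stable for
  energies up to ±300 k~B~T (validation warns above |50|, errors above
  |300|).
* The first-step denominators, as usually written, are differences of large
  products; the implementation uses their algebraically equivalent
  positive-sum forms, which removes catastrophic cancellation when
  unbinding rates span many decades.
* The linear-solve oracle agrees with the closed forms to 1e-10 over random
  rate sets; beyond `|ddEm| ~ 12` k~B~T the solve itself loses precision
  (its `(I - Q)^{-1}` amplifies rounding by the expected loop count
  `~ gamma2 * exp(ddEm)`), so agreement there is asserted at 1e-8.
* Degenerate inputs (zero-exit states, e.g. `u4 = 0` with `m = 0`, or
  `gamma3 = 0` networks) raise typed errors; no function returns NaN.
* `gamma3 = 0` is admitted in `reduced_params()` as the no-dissociation
  boundary used by the diagnostic ratios, although the corresponding
  network is singular.
* All simulation randomness flows through an explicit per-call seed and the
  caller's RNG stream is restored afterwards.

## Limitations

The model handles exactly two editable cytidines and consumes `ddE0`/`ddEm`
as numbers — estimating them (MD, scoring functions) and any sequence-level
analysis of editing outcomes are out of scope. Absolute time scales are
unidentifiable from outcome probabilities, so all rates are reported in an
arbitrary common unit with `u0 = u1 = u3 = 1` by default. Published
per-variant outcome ratios computed from exact source-data energies can
differ from values recomputed at the rounded narrative energies (a ~0.2
k~B~T shift in `ddE0` moves `R2` by ~25%); the package reproduces the
printed values only to the precision of the energy inputs it is given.
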