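# beselect

Chemical-kinetic modelling of bystander editing by cytosine base editors
(CBEs), for protein engineers and computational biologists designing
deaminase variants with improved precision.

A CBE (nickase Cas9 fused to a cytidine deaminase) converting C→T inside a
4–10 nt activity window will often edit a second, *bystander* cytidine next
to the intended target. `beselect` implements a discrete-state stochastic
model of this process: a 15-state absorbing Markov chain whose four
absorbing products are the sequence outcomes **CTC** (no edit), **CTT**
(target only), **TTC** (bystander only) and **TTT** (both edited). Outcome
probabilities have closed forms in six dimensionless parameters

* γ₁ = u₄/u₀ (unproductive vs productive initiation),
* γ₂ = w₁,WT/u₃ (cytidine unbinding vs deamination chemistry),
* γ₃ = w₀/u₁ (Cas9 dissociation vs cytidine engagement),
* m ∈ [0, 1] (Cas9 rebinding attenuation after an edit),
* ΔΔE₀ (bystander-vs-target binding context penalty, k_BT),
* ΔΔEm (mutation-induced binding perturbation, k_BT — the design variable),

with binding free energies acting on unbinding rates through Boltzmann
factors: w₁ = γ₂·u₃·e^ΔΔEm, w₂ = w₁·e^ΔΔE₀. The package computes outcome
probabilities (closed form, exact linear solve on the chain, and Gillespie
simulation), the diagnostic ratios R₁ (target-first vs bystander-first
editing) and R₂ (CTT:TTT odds after the target edit), fits γ₁/γ₃ to
observed editing fractions, scans the selectivity landscape
S(ΔΔEm) = Pt − Pb, and screens candidate mutations by proximity to the
selectivity peak.

## Worked example

```r
library(beselect)

# Site kinetics from Michaelis-Menten constants (A3A on ssDNA)
infer_site_kinetics(enzyme_kinetics(Kd = 57, KM = 62, kcat = 1.1))
#> Site kinetics: kon = 0.22, w1_wt = 12.54 /s, u3 = 1.1 /s, gamma2 = 11.4

# Outcome probabilities at the A3A-BE3 calibration
# (gamma1 = 2.1, gamma2 = 11.4, gamma3 = 2.9e-5, m = 0, ddE0 = 6)
p <- a3a_calibration()
outcomes_from_rates(rates_from_reduced(p))
#> Editing outcome probabilities:
#>   CTC = 0.6775  CTT = 0.0379  TTC = 0.0000  TTT = 0.2846
#>   P_t = 0.3225  P_b = 0.2846
```

The wild type edits target and bystander almost equally (Pt ≈ 0.32,
Pb ≈ 0.28; the dominant edited product is the double edit TTT) — that is
the bystander problem. The post-target-edit odds ratio quantifies it:
`ratio_r2(p)` gives **0.133** (TTT dominates), while a mutation that adds
ΔΔEm = 4.5 k_BT gives `ratio_r2(a3a_calibration(4.5))` = **12.0** — the
single-edit product CTT now dominates by an order of magnitude.

```r
find_peak(selectivity_scan(p))
#> Selectivity peak: ddEm_peak = 5.2088 k_B*T, S_max = 0.2969
#>   window (S >= 0.90 * S_max): [3.6559, 6.7619]

screen_candidates(p, data.frame(name = c("mutA", "mutB", "mutC"),
                                ddEm = c(2.0, 5.2, 10)))
#>   name ddEm    p_t      p_b      S in_window rank
#> 1 mutB  5.2 0.3100 0.013050 0.2969      TRUE    1
#> 2 mutA  2.0 0.3220 0.162594 0.1594     FALSE    2
#> 3 mutC 10.0 0.0544 0.000153 0.0542     FALSE    3
```

Selectivity is maximal near ΔΔEm ≈ 5.2 k_BT: `mutB` sits in the design
window and keeps high on-target editing (Pt = 0.31) with 20-fold reduced
bystander editing; `mutA` destabilises too little, `mutC` so much that
on-target activity collapses (Pt = 0.05) — the characteristic
non-monotonicity that makes pre-screening by ΔΔEm worthwhile.

A command-line interface wraps the same operations
(`exec/beselect <solve|scan|fit|screen|simulate|synth> --config model.json ...`);
every run writes a provenance record (config hash, seed, package version)
next to its output.

## Documentation

`vignettes/base-editor-selectivity.Rmd` describes the model and its
assumptions, the synthetic-data generator and what a green test does and
does not establish, numerical choices (stability rescaling,
cancellation-free denominators, golden-section peak refinement) and known
limitations.
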