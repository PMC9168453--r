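---
title: "Modeling Krebs-cycle citrate secretion from 13C labeling patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Krebs-cycle citrate secretion from 13C labeling patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citrateflux)
```

## The scientific problem

Prostate epithelial cells secrete citrate drawn out of the Krebs cycle, a
cataplerotic drain that must be balanced by anaplerotic carbon entry. When
such cells are incubated with a position-specifically ¹³C-labeled substrate,
the citrate accumulating in the medium carries a positional labeling pattern
that reflects (i) how many cycle turns its carbons completed before
divergence and (ii) whether pyruvate carbons entered via the pyruvate
dehydrogenase complex (PDC, into acetyl-CoA, citrate C1/C2) or via pyruvate
carboxylase (PC, into oxaloacetate, citrate C3–C6). `citrateflux` turns
measured citrate carbon integrals into two interpretable parameters: the
apparent per-turn secretion fraction `d` and the PC fraction `p`.

## The positional model and its assumptions

The model tracks *expected positional enrichments* — a vector over citrate
carbons C1..C6 — rather than full isotopomer (bond-pattern) distributions.
This is sufficient because both diagnostic ratios are linear in positional
integrals. The assumptions are:

* **Fresh-entry pattern.** Each citrate generation receives labeled carbon
  with weight `(1 − p)·f_a` at the PDC entry position (C2 for
  [1,6-¹³C₂]glucose, which is glycolysed to [3-¹³C]pyruvate; C1 for
  [2-¹³C]pyruvate) and `p·f_p` split equally over C3 and C4. `f_p` and
  `f_a` are the fractional ¹³C enrichments of the pyruvate and acetyl-CoA
  pools; PDC entries are scaled by `f_a`, PC entries by `f_p`.
* **Complete scrambling.** Exchange through the symmetric
  succinate/fumarate stage is fast, so PC-derived label loses positional
  identity completely (50/50) before condensation. No partial-scrambling
  parameter is offered. A direct consequence, asserted exactly in the
  tests, is `s3 = s4` and `s5 = s6` at all parameter values.
* **Turn transition.** One full turn maps C1 → ½C5 + ½C6,
  C2 → ½C3 + ½C4, C3 → ½C3 + ½C4, C4 → ½C5 + ½C6, while C5 and C6 leave as
  CO₂. CO₂ refixed by PC is treated as unlabeled (dilution into a large
  bicarbonate pool), so PC introduces label only through pyruvate carbons.
* **Geometric divergence.** A fraction `d ∈ (0, 1]` of citrate diverges
  every turn; the medium accumulates `s = Σₖ d(1−d)ᵏ Tᵏ(L₀)`. The
  isotopic steady state is identified with the 48-h accumulated secretion.
  `d = 0` is rejected rather than special-cased (nothing is secreted and
  the accumulated distribution is undefined); small-`d` limits are
  evaluated explicitly.
* **Upper bound.** Any other cataplerotic efflux (glutamate exchange,
  PEPCK, malic enzyme) contributes to the apparent divergence, so `d`
  bounds the true citrate secretion fraction from above. The PC fraction
  is unaffected by additional effluxes.

The ratios are `R1 = ((C2+C4) − C3)/(C2+C4)` from the glucose tracer
(0.5 at extensive recycling, 1 when everything diverges at the first turn;
a PC contribution lowers the small-`d` end) and `R2 = (C1+C5)/C3` from the
pyruvate tracer (C3 is reachable only via PC, so R2 → ∞ as p → 0).

Both an iterative evaluation (the defining sum, truncated when the largest
positional increment falls below `tol = 1e-12`, cap 200 turns) and an
analytic geometric closed form are implemented; they agree to 1e-10 over a
(d, p) grid, which the tests assert against a brute-force generation
enumeration coded independently.

## Inversion

`fit_citrate_flux(r1, r2)` solves the two ratio equations jointly: a coarse
0.01-step grid scan over (d, p) locates candidate basins, damped Newton
iteration refines each to a residual below 1e-8, and distinct refined roots
trigger an explicit multiple-root error (none occur in the admissible
region; R1 is strictly increasing in `d` at fixed `p` and R2 strictly
decreasing in `p` at fixed `d`, which the tests verify numerically). Ratio
pairs outside the attainable envelope fail loudly with the envelope rather
than clamping. R1 values at or below 0.5 are admissible in principle (large
PC fractions push R1 below the p = 0 floor of 0.5), but are only accepted
when a joint root with the supplied R2 exists.

**Enrichment convention.** The glucose experiment fixes `f_p = 0.80` and
`f_a = 0.56` (LNCaP). The pyruvate experiment's acetyl-CoA enrichment is
not directly measurable from media spectra; the package adopts, as a
documented default, the same acetyl-CoA/pyruvate enrichment *ratio* as in
the glucose experiment (0.56/0.80 = 0.70) applied to the measured pyruvate
enrichment of 0.83. Only the ratio `f_a/f_p` enters R2, and the default is
overridable through `tracer_spec()`. Under this convention the measured
(R1, R2) = (0.75, 5.2) invert to (d, p) = (0.791, 0.214).

`simulate()` on a fit re-inverts under Gaussian ratio noise (defaults
σ(R1) = 0.02, σ(R2) = 0.5) to give an empirical parameter spread;
`pc_vs_d_curves()` and `plot()` reproduce the standard diagnostic curves.

## NMR quantification chain

The citrate ¹³C resonances are fitted with constrained Lorentzian
multiplets in the prior-knowledge style: fixed offsets from the one-bond
C2–C3 coupling (¹J = 38 Hz; satellites at ±19 Hz, and for C3 also ±38 Hz),
linewidths bounded in [4, 20] Hz, a single shared phase (fixed at 0 by
default), and analytic integrals `amplitude × π × FWHM/2` rather than
point sums. The C2–C4 coupling is below the ¹³C linewidth and neglected.
Three further constraints stabilize low-SNR fits and are defaults:

* one shared linewidth per multiplet (the lines differ only in J-coupling
  state, not relaxation);
* symmetric multiplet halves tied to one amplitude parameter;
* optional transfer of the linewidth fitted on the strong C2/4 multiplet
  to the weak C3 multiplet of the same molecule (`lw_fixed_hz`), used by
  the end-to-end pipeline.

Baselines in fit windows are assumed flat and zero (a linear-baseline
option exists, default off). The noise standard deviation of a window is
estimated as the minimum of a truncation-corrected quiet-point estimate
(sd of the 20% of points with smallest |intensity|) and a robust
first-difference estimate `mad(diff)/√2`; each overestimates precisely
where the other is reliable. ¹³C integral comparisons across resonances
assume equal per-carbon response (no NOE/T1 correction) — a documented
limitation consistent with ratio-based use.

Proton-side quantification references multiplet integrals per proton to
the TSP singlet (0.2 mM, nine protons):
`conc = (I/n_H)/(I_TSP/9) × 0.2 mM`, and converts end-point concentrations
to rates via
`rate = conc × volume × 1000/(incubation_h × cells/10⁶)`. The medium
volume has deliberately **no default** — only aliquot volumes are fixed by
the sample protocol, and a silent default would invite unit errors.
Fractional ¹³C enrichments come from satellite fractions
`f = satellite/(satellite + centerband)`; the lactate methyl doublet at
1.33 ppm with its ¹J_CH ≈ 127 Hz satellites estimates the pyruvate-pool
enrichment. Because the upfield satellite falls at ~1.46 ppm, it overlaps
the alanine doublet at 1.48 ppm; the two are therefore fitted jointly in
one window. Glucose consumption anchors the ¹³C glucose integral to the
¹³C-lactate concentration; the doubly labeled glucose carries two ¹³C
carbons per molecule against one for [3-¹³C]lactate, so the glucose
integral is divided by 2 (configurable, since the correction depends on
the tracer).

## Glutamine split

[5-¹³C]glutamine labels citrate C1 via reductive carboxylation and C5/C6
via the oxidative route (equally, before any exchange loss). HMBC
detection bias per carbon pair is absorbed by a single multiplicative
factor calibrated on unlabeled citrate, whose true C1/5:C6 ratio is 2:1:
`factor = 2/observed`, so `factor × observed = 2` exactly. With corrected
ratio `ρ = (C1+C5):C6` and C6 retention `λ ∈ (0, 1]` (`λ = 1`: C5 and C6
equally labeled), the reductive fraction is
`f_red = (λρ − 1)/(λρ + λ)`, i.e. `(ρ−1)/(ρ+1)` at `λ = 1`; `ρ` below the
purely oxidative floor `1/λ` signals inconsistent integrals and errors.

A point worth noting on the λ sensitivity: once ρ is *measured*, the
observed labeled C1+C5+C6 total is `c15·(1 + 1/ρ)` independently of λ —
the attenuation cancels because the observed C6 is `c15/ρ` by definition
of ρ. λ therefore moves the reductive/oxidative split but not the percent
contribution computed from observed label. Counting back the label
inferred to have been *lost* from C6 (option `include_lost_c6 = TRUE`)
gives `c15·(1 + 1/(λρ))`, which increases the percentage for λ < 1. The
cytosolic and mitochondrial reductive routes are not distinguished (the
data cannot separate them).

## Synthetic data: what it emulates and what it does not

`generate_experiment()` renders seeded ¹H (−0.5–10 ppm, 16k points) and
¹³C (−5–200 ppm, 32k points) media spectra from ground-truth parameters:
citrate multiplets whose group integrals follow the forward model, the TSP
references (0 ppm ¹H; −2 ppm ¹³C), lactate with ¹³C satellites consistent
with `f_p`, alanine, ¹³C lactate, and optionally remaining labeled
glucose. Gaussian i.i.d. frequency-domain noise is added at a configurable
SNR, defined as the tallest citrate line height over the per-point noise
σ. Identical seeds give bit-identical spectra, and the generator restores
the caller's RNG stream.

The default ground truth represents a confluent LNCaP flask after 48 h:
d = 0.79, p = 0.21, f_p = 0.80, f_a = 0.56, 5×10⁶ cells in 10 mL, citrate
0.134 mM (the 5.6 nmol/h per 10⁶ cells production rate accumulated over
the incubation), lactate 9 mM, alanine 0.6 mM, TSP 0.2 mM, ¹³C linewidth
8 Hz, ¹H linewidth 1.2 Hz, SNR 100.

Two deliberate simplifications: the C2/4 singlet/doublet split
(`doublet_fraction_c2`, default 0.3) and the five-line C3 pattern are free
generator parameters, *not* derived from (d, p) — multiplet fine structure
reflects pairwise ¹³C–¹³C co-labeling, which a first-moment model does not
track. Passing tests therefore validate integral and ratio recovery, not
fine-structure prediction. Also absent are lineshape imperfections
(shimming artifacts, baseline roll) and time-domain effects; real spectra
are harsher than the generator in these respects, so recovery bounds
measured here are best-case.

## Numerical choices and test scale

* Model engine: `tol = 1e-12`, `max_turns = 200`.
* Solver: grid step 0.01, Newton stop at 1e-8 (1e-10 in round-trip
  tests), damping by step halving, ties broken by smallest residual.
* Fits: Levenberg–Marquardt (box constraints via `minpack.lm`), maximum
  400 iterations; amplitudes bounded below by 0; multiplet shift bounded
  by a third of the window.
* Test scale, chosen to exercise every stage at full fidelity while
  keeping the suite quick: parameter-recovery grids of 30 (d, p) points,
  200 noise replicates for the ratio-noise study, 50 seeded spectra
  (SNR 50–200) for fit recovery, one paired end-to-end recovery at
  SNR 100. The full suite runs in well under a minute.

## Known limitations

* The recovery of the weak C3 multiplet at the low end of the SNR range
  sits at the estimator's statistical floor: at SNR 50 (defined on the
  tallest citrate line) the relative error of the C3 group integral has a
  standard deviation of ≈4% even with all prior-knowledge constraints
  applied — essentially the information limit of the data — so individual
  low-SNR spectra can miss a 5% recovery bound while the estimate remains
  unbiased. The corresponding test documents this; R1 recovery (within
  0.03) is unaffected because C2/4 dominates it.
* `d` is an apparent, upper-bound secretion fraction; separating citrate
  secretion from other effluxes needs additional measurements outside
  this model's scope.
* Kinetic (time-resolved) modeling, compartmentation of cytosolic vs
  mitochondrial citrate, and full isotopomer simulation are out of scope.
* JCAMP-DX support covers plain AFFN `(X++(Y..Y))` tables only;
  compressed ordinate forms are rejected with a clear error.
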