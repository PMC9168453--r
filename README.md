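# citrateflux

Quantitative analysis of the ¹³C positional labeling of citrate secreted by
prostate (cancer) cells.

Healthy prostate epithelium — and the still-differentiated prostate cancer
lines LNCaP and VCaP — divert citrate out of the Krebs cycle and secrete it.
When cells are incubated with a ¹³C-labeled substrate
([1,6-¹³C₂]glucose, [2-¹³C]pyruvate, or [5-¹³C]glutamine), the citrate that
accumulates in the medium carries a position-specific ¹³C pattern that
encodes how many Krebs-cycle turns its carbons completed before divergence
and which entry route (pyruvate dehydrogenase vs pyruvate carboxylase) fed
them in. `citrateflux` implements the model that reads this pattern, plus
the NMR quantification chain that produces its inputs from 1D ¹H/¹³C media
spectra. It is intended for metabolism researchers working with ¹³C tracer
NMR of cell incubation media.

## The model

Citrate carbons are tracked as expected positional enrichments C1..C6.
Per citrate generation, label enters with weight `(1 − p)·f_a` at the
acetyl-CoA (PDC) position (C2 for the glucose tracer, C1 for the pyruvate
tracer) and with weight `p·f_p` split equally over C3/C4 (PC-derived
oxaloacetate, fully scrambled over the malate/fumarate/OAA pool), where
`f_p` and `f_a` are the ¹³C enrichments of the pyruvate and acetyl-CoA
pools. One Krebs-cycle turn maps

    C1 → ½C5 + ½C6    C2 → ½C3 + ½C4    C3 → ½C3 + ½C4
    C4 → ½C5 + ½C6    C5, C6 → lost as CO₂

A fraction `d` of citrate diverges from the cycle each turn, so the medium
accumulates `s = Σₖ d(1−d)ᵏ Tᵏ(L₀)`. Two integral ratios summarize the
pattern:

    R1 = ((C2 + C4) − C3) / (C2 + C4)     (glucose tracer)
    R2 = (C1 + C5) / C3                   (pyruvate tracer)

R1 runs from 0.5 (extensive recycling) to 1 (all divergence at the first
turn); C3 can only be labeled via PC, so R2 measures the PDC:PC balance.
Solving `R1(d, p) = R1_obs` and `R2(d, p) = R2_obs` jointly yields the
apparent per-turn secretion fraction `d` (an upper bound on the true
citrate secretion fraction when other cataplerotic effluxes exist) and the
PC fraction `p`, and `(1 − d)/d` is the mean number of turns a label
completes before leaving.

## Worked example

The measured LNCaP ratios are R1 = 0.75 (two replicates, 0.74 and 0.76) and
R2 = 5.2, with pyruvate-pool enrichment 0.80 and acetyl-CoA enrichment 0.56
in the glucose experiment:

```r
library(citrateflux)
fit <- fit_citrate_flux(0.75, 5.2)
summary(fit)
#> Citrate secretion model fit
#>   observed ratios: R1 = 0.750, R2 = 5.200
#>   apparent secretion fraction d = 0.7912
#>   PC fraction                 p = 0.2137
#>   expected Krebs-cycle turns before secretion: 0.26
#>   max |ratio residual|: 2.48e-13 (converged)
#>   enrichments: glucose f_p = 0.80, f_a = 0.56; pyruvate f_p = 0.83, f_a = 0.58
#>   note: d is an upper bound on the true citrate secretion fraction c;
#>   other cataplerotic effluxes inflate the apparent per-turn divergence.
```

About 79% of citrate-equivalents leave the cycle each turn (0.26 turns on
average before secretion) and 21% of labeled carbon entry proceeds via
pyruvate carboxylase. Applied to an oxidative triose consumption of
250 nmol/h per 10⁶ cells, that PC fraction corresponds to

```r
pc_anaplerotic_rate(250, coef(fit)[["p"]])
#> [1] 53.42082
```

nmol/h per 10⁶ cells of anaplerotic flux — far above the citrate secretion
rate of ~5.6 nmol/h per 10⁶ cells, so PC alone can cover the carbon drain.
`plot(fit)` draws the R1-versus-d curve and the two PC-fraction-versus-d
curves whose intersection is the fitted pair.

The full chain from spectra to parameters can be exercised on synthetic
data:

```r
rep <- end_to_end_recovery(ground_truth(d = 0.79, p = 0.21, snr = 100, seed = 7))
print(rep)
#> End-to-end synthetic recovery
#>               R1     R2 f_p       d      p
#> truth     0.7522 5.3136 0.8  0.7900 0.2100
#> estimate  0.7460 5.1220 0.8  0.7862 0.2163
#> error    -0.0062 -0.1916 0.0 -0.0038 0.0063
```

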