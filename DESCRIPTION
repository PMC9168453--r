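Package: citrateflux
Title: Krebs-Cycle Flux Ratios from 13C Labeling of Secreted Citrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative modeling of the 13C positional labeling of citrate
    secreted by prostate (cancer) cells. Implements a forward positional
    isotopomer model of citrate through repeated Krebs-cycle turns with
    per-turn divergence, inversion of the citrate carbon integral ratios R1
    and R2 for the apparent per-turn secretion fraction d and the pyruvate
    carboxylase (PC) fraction p, constrained Lorentzian multiplet fitting of
    citrate 13C NMR resonances, TSP-referenced metabolite quantification and
    rate estimation, fractional 13C enrichment from proton satellite signals,
    the reductive/oxidative split of glutamine-derived citrate label, and a
    seeded synthetic spectrum generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
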