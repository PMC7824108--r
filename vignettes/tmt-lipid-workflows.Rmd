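---
title: "Sixplex TMT workflows for carboxy- and phosphate-containing lipids"
author: "lipidTMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sixplex TMT workflows for carboxy- and phosphate-containing lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidTMT)
```

## The method

Isobaric tandem mass tags (TMT), long standard in quantitative proteomics,
can be extended to lipids that carry a free carboxy group (fatty acids,
eicosanoids and other oxylipins) or a phosphate monoester (lysophosphatidic
acid, LPA; phosphatidic acid, PA).  With carbodiimide/DMTMM activation the
aminoxyTMT reagent derivatizes both site types in one pot; phosphate
*diesters* (phosphatidylcholine and -ethanolamine and their lyso-forms) do
not react and stay on a conventional, underivatized SRM method.  Six
samples, each labeled with one of the six reporters (channels 126–131),
are mixed and measured in a single LC/MS run on a triple quadrupole.

Because the tags are isobaric, all six samples give the **same precursor
m/z**; they are distinguished only by the channel-specific reporter ions
released on fragmentation.  The sixplex acquisition therefore monitors,
per labeled species, one transition per channel:

* precursor: `[M − kH + k·303.25]^(k+)`, where `M` is the monoisotopic
  mass and `k` the number of tags attached (one per labelable site).  For
  `k = 1` this is the singly labeled `[M−H+303.25]+` rule; species with two
  carboxy groups (e.g. 20-carboxy-LTB4, tetranor-PGDM) take two tags and
  appear as divalent (2+) ions.
* products: the reporters at 126.15, 127.15, …, 131.15 (unit spacing at
  triple-quadrupole resolution), collision energy 46 eV, positive mode.

One channel of every set carries a **bridging sample**: the same pooled QC
specimen in every set.  All quantities are expressed as the ratio to this
bridge within the (set, species, replicate) group, which removes any
per-set multiplicative factor — injection amount, source drift, overall
derivatization yield — exactly, with no internal standards.

## Package design

`lipidTMT` is organized in Bioconductor style around validated S4 objects:

* `ChemicalFormula` — an element→count map with monoisotopic/average mass
  evaluation and `+`/`-` arithmetic.  Element masses are IUPAC values
  hard-coded to 6 decimals (monoisotopic) / 3 decimals (average) for
  dependency-free reproducibility.
* `LipidSpecies` — name, class, shorthand composition, formula and
  labelable-site counts.  `parseLipidShorthand()` implements the
  composition rules for FA, LPA, PA, LPC, LPE and DAG, accepting both
  total-composition (`PA(36:2)`) and per-chain (`PA(18:1/18:1)`) notation;
  per-chain forms are summed, since sn-position and double-bond position
  are not mass-resolved on this platform.  Named eicosanoids come from an
  extensible formula registry (`oxylipinRegistry()`, `readRegistry()`).
* `TransitionList` — the SRM method table.  `buildSixplexTransitions()`
  emits the TMT method; `buildNativeTransitions()` the underivatized one.
* `AreaTable` — long-format reporter areas keyed by
  (set, species, channel, replicate) with condition/time annotations.
* `QCReport` — CV and dilution-linearity tables with pass/fail flags.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| tag offset | 303.25 Da/tag | nominal per-label precursor offset as printed in the acquisition method (`rule_mode = "paper_nominal"`); an `exact_tag` mode takes a user-supplied exact tag mass and never substitutes one silently |
| reporters | 126.15–131.15 | unit-resolution reporter targets; exact-mass reporters can be passed to `tmtChannels()` |
| collision energy | 46 eV | positive-mode CE for TMT-derivatized compounds; exposed as a per-list override because product-ion scans in the source method also quote −45 eV |
| bridging channel | `"126"` | design choice; any channel may be the bridge, exactly one per set |
| CV threshold | 30 % | QC flag level, slightly above the 28.4 % worst case observed in the original validation |
| linearity threshold | r ≥ 0.94 | the observed floor of the original dilution-series correlations |

Numerical conventions: emitted TMT m/z are rounded to 2 decimals; the six
stored native transitions (LPC(16:0) 496.35→184.1, LPE(18:1) 480.3→339.3,
DAG(18:1/18:1) 636.6→339.3 positive; LPA(16:0) 409.4→153.1, LPA(18:1)
435.4→153.1, PA(36:2) 699.6→153.1 negative) are kept verbatim as
instrument-tuned method defaults.  Novel LPC/LPE species are computed from
formulas: Q1 = [M+H]+, Q3 = the phosphocholine fragment cation (184.07)
for LPC or the 141.0191 Da phosphoethanolamine neutral loss for LPE.
`validateTransitions()` recomputes every precursor from the formula and
flags deviations above a tolerance; the stored DAG precursor differs from
the computed [M+NH4]+ (638.57) by ~2 m/z and is deliberately reported, not
"fixed" — it matches no common adduct of C39H72O5 and is retained exactly
as the instrument method specifies.

## Quantification model

`bridgeNormalize()` computes `ratio = area / area(bridge)` per
(set, species, replicate); groups with a missing or zero bridge area
become missing (never imputed — imputing the denominator would break the
method's core guarantee).  Ratios are computed per replicate, not on
replicate means, because each LC/MS run carries its own bridge.

`relativeToReference()` rescales to a reference condition/time (e.g. the
pooled QC at 0 h).  Two modes exist because linking runs acquired at
different times is genuinely ambiguous: `"bridge"` mode (default) divides
bridge ratios and stays invariant to per-set scales; `"raw"` mode divides
raw areas, reproducing a relative-to-0 h construction across separate
runs, and is only valid under cross-run response stability — it emits a
caveat.  Ratios stay in linear space (log display is a reporting choice).

Replicate summaries use mean ± SEM (sample sd / √n; SEM is missing at
n = 1).

## QC statistics

`cvPercent()` is `100·sd/mean` with the sample (n−1) sd — the spreadsheet
convention.  `dilutionLinearity()` correlates per-level mean areas with
the **relative concentration** `1/fold` by default: a serial dilution read
against the raw fold-dilution number would correlate negatively, so the
positive near-unity correlations of a validation table are only
reproducible on the reciprocal axis; the literal fold-dilution axis is
kept as an option and recorded in the report metadata.  Correlations use
per-level replicate means (a 5-point correlation), with pooled raw points
available via `level_means = FALSE`.

## The simulator and what it does (not) show

`simulateSixplex()` draws areas from a multiplicative lognormal model

    area[s, i, c, r] = T[i, c, t] · S[s] · B[c] · R[i] · ε

with per-set scale `S ~ LN(0, σ_set)` (default σ = 0.5), per-channel
labeling bias `B ~ LN(0, σ_channel)` fixed across sets (default 0.1),
per-species response `R` (lognormal around a median area of 1e5), and
per-measurement noise `ε ~ LN(0, σ_noise)` (default 0.1, which gives CVs
near 10 %, inside the 1.8–28.4 % envelope reported for the real assay).
The bridge channel's true abundance is 1 by construction.  The default
design mirrors the validation study: 6 channels (5 disease pools + QC
bridge), 0 h and 20 h incubation, 3 replicate runs; the dilution simulator
uses 5 levels (×1–×16) with 3–4 replicates.  All randomness flows from a
single seed and reruns are bit-identical.

The lognormal form is the standard choice for MS peak areas (positive,
roughly scale-free CVs); the generator does not attempt chromatographic
peak shapes, isotopic impurity leakage between reporter channels, or
enzymatic kinetics of lipid degradation — serum-stability trends are
emulated only as configurable true fold changes.  Passing recovery tests
therefore demonstrate the algebra of the normalization, not instrument
behavior.

Two deliberate modeling points:

* **Channel bias is not removed by bridging.** `B[c]` multiplies every
  set identically, so it divides out only for the bridge channel itself.
  This is the method's real limitation (a reagent-lot labeling-efficiency
  difference biases all sets the same way), and the simulator exposes it:
  exact-recovery tests set `channel_bias_sigma = 0`.
* **Unbiasedness is assessed on the relative scale.** With true folds
  spanning 0.25–4×, both the deterministic lognormal-ratio bias
  (E[ε_c/ε_bridge] = e^{σ²}) and the replicate-sampling error scale with
  the true fold, so `recoveryMetrics()` reports the absolute `bias`
  alongside the scale-free `rel_bias`; the package's tests bound the
  median |rel_bias| (≈ 0.03 at σ_noise = 0.1 with 3 replicates).

`recoveryMetrics()` joins estimates to ground truth and per species
reports bias, relative bias, RMSE and maximum absolute error.  With
σ_noise = 0 the bridge-mode pipeline recovers the configured truth to
machine precision for set effects of any magnitude, while raw mode
inherits the set effects — the contrast the bridging strategy exists to
demonstrate.

## Worked example

```{r example}
## method generation
tl <- buildSixplexTransitions(c("FA(20:4)", "20-carboxy-LTB4"))
transitionTable(tl)

## simulate the stability design and quantify
tf <- data.frame(species = "TXB2", condition = "Schizophrenia",
                 time_h = 20, fold = 0.5)
cfg <- simulationConfig(c("TXB2", "FA(20:4)"), true_fold = tf,
                        channel_bias_sigma = 0, noise_sigma = 0, seed = 7)
sim <- simulateSixplex(cfg)
fc <- relativeToReference(bridgeNormalize(sim$areas, cfg$channels),
                          list(condition = "QC", time_h = 0))
subset(aggregateReplicates(fc), condition == "Schizophrenia")
```

## Problem sizes and determinism

The test suite and examples run on deliberately small designs: property
tests use tens of random cases, the Monte-Carlo unbiasedness check uses
200 species × 6 channels × 3 replicates, and the analytic-CV check uses
200 replicates per level — sizes chosen so every check completes in
seconds while keeping Monte-Carlo error well below the asserted bounds.
Every stochastic component is seeded explicitly.

## Known limitations

* No isotopic-impurity correction between reporter channels (not part of
  the modeled acquisition method).
* Positional isomers sharing a formula (12- vs 20-HETE) are distinguished
  only by name and retention-time metadata.
* Peaks absent from the pooled QC bridge cannot be quantified relative to
  it; the package propagates them as missing rather than rescuing them.
* No limit-of-detection estimation or calibration-curve fitting: the
  method is internal-standard-free by design, and absolute concentrations
  are out of scope.
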