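---
title: "Methods: hemp cell-wall and stem-morphometry phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemp cell-wall and stem-morphometry phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hempcw)
```

hempcw converts the raw measurements of a hemp (*Cannabis sativa*) stem
phenotyping campaign — chromatography concentrations, gravimetric residue
masses, cross-section radii — into the derived fibre-quality traits used to
compare accessions: cell-wall composition, lignin and cell-wall content,
polysaccharide crystallinity, and stem morphometry, together with the
repeatability and between-accession statistics a breeding programme needs.
This vignette explains the models behind each stage, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
choices made where the underlying protocol left the computation open.

## Composition: from hydrolysate concentrations to percent of cell wall

The total cell-wall fraction is prepared as an alcohol-insoluble residue
(AIR). A nominal 20 mg of AIR is hydrolysed in two steps (72 % H₂SO₄ at
30 °C, then dilution to 4 % and autoclaving at 121 °C), and the eight
monosaccharides (arabinose, galactose, galacturonic acid, glucose,
glucuronic acid, mannose, rhamnose, xylose) are quantified by HPAEC-PAD in
the diluted hydrolysate. The forward calculation per analyte is

```
mass in hydrolysate = concentration × dilution factor × hydrolysate volume
corrected mass      = mass / recovery
percent of cell wall = corrected mass / AIR mass × 100
```

with concentrations in mg/ml, volumes in ml and masses in mg (the unit
convention is enforced through the run configuration; the detector's native
units are not standardised, so the package requires them to be declared).
The *recovery* is estimated from sugar recovery standards (SRS): known
sugar mixtures carried through the same hydrolysis. `recovery_factors()`
takes the ratio of mean hydrolysed to mean control concentration per
analyte — per batch when batch labels are present, since SRS tubes are
hydrolysed within each batch — and clips ratios above 1 to 1 with a
warning, because a correction for degradation must never amplify a
measurement. Glucose is quantified from the 10× dilution record (its
concentration saturates the detector at 1×) and all other sugars from the
1× record; a lone record of either dilution is used as-is.

Klason lignin is gravimetric: the acid-insoluble residue collected on a
pre-washed, pre-dried glass-fibre filter, expressed on the AIR basis as
`(gross − tare) / AIR mass × 100`. A gross mass below tare violates the
purpose of the pre-wash and is treated as an error, not a zero. Cell-wall
content of the biomass (AIR % of dry matter) is
`residue / (initial × dm fraction) × 100`.

Composition percentages are reported on the AIR basis as primary output.
A per-dry-matter basis can be derived by multiplying by AIR%dm / 100; the
package keeps the AIR basis as the canonical column because that is the
basis on which the mass balance is interpretable. The mass-balance check
sums the eight sugars and Klason lignin per sample and warns outside a
configurable 80–105 % band; on the reference panel this total reaches
93.8 % (bast) and 92.5 % (stem), so totals in the low nineties are the
expected healthy regime. Furfural/HMF degradation products are not
modelled: under this hydrolysis they were not detectable.

## Crystallinity: sequential-hydrolysis accounting

Crystallinity of cellulose and mannan in bast fibre is estimated
biochemically by three consecutive hydrolyses: trifluoroacetic acid (TFA)
releases non-crystalline polysaccharides and amorphous cellulose/mannan;
the Updegraff reagent (acetic acid:nitric acid:water 8:1:2) strips the
remaining non-crystalline material — its supernatant is discarded, so this
step contributes no quantified sugars; and the two-step sulfuric acid
hydrolysis breaks down the crystalline polymers. Hence

```
total polymer      = monosaccharide released by TFA + by H₂SO₄
crystalline amount = monosaccharide released by H₂SO₄ only
% crystalline      = crystalline / total × 100
```

applied to glucose (cellulose) and mannose (mannan). The same arithmetic
applied to xylose, galacturonic acid and rhamnose is interpreted
differently: these co-monomers are not crystalline themselves, but a
fraction of xylan and pectin survives into the crystalline residue,
presumably entrapped by the crystalline polymers. The package keeps
`percent_crystalline()` and `entrapped_fraction()` as distinct named
operations with identical arithmetic, and the per-sample stage labels each
analyte's measure accordingly. The crystalline-fraction amounts are
expressed per total cell wall, the basis consistent with the
fraction-of-total arithmetic of the reference panel.

A crystalline amount slightly above the total can arise from measurement
noise between the two chromatography runs; within a 0.5 % relative
tolerance it is clamped to the total (100 % crystalline), beyond that the
inputs are inconsistent and the stage errors. A zero total leaves the
percentage undefined (`NA` with a warning) rather than zero. Summary
ranges are computed on unrounded values, so they can differ in the last
digit from ranges recomputed off displayed (rounded) tables.

## Morphometry: the annulus model

A stem cross-section is modelled as concentric rings around the lumen:
lumen, woody hemp core (WHC), and bast fibre. With ring radii
*r*ₗ, *r*𝓌, *r*ᵦ (bast = primary + secondary):

* *A*ₗ = π *r*ₗ²
* *A*𝓌 = π (*r*ₗ + *r*𝓌)² − *A*ₗ
* *A*ᵦ = π (*r*ₗ + *r*𝓌 + *r*ᵦ)² − *A*ₗ − *A*𝓌

These sum exactly to the disc of the summed radii (an identity the test
suite asserts to machine precision). Bast share is
*A*ᵦ / (*A*𝓌 + *A*ᵦ) × 100 and the bast/WHC ratio is *A*ᵦ / *A*𝓌 — the
source equation for the latter carries a ×100 factor, but every published
per-accession value (0.161–0.274) is plainly the unmultiplied ratio, so
the factor is treated as a typographical error and the plain ratio
reported. Primary and secondary bast fibre are the outermost two rings
referenced to the overall stem radius:

* *A*PF = π (*r*ₛ² − (*r*ₛ − *r*PF)²)
* *A*SF = π ((*r*ₛ − *r*PF)² − (*r*ₛ − *r*PF − *r*SF)²)
* ratio = *A*PF / *A*SF

The stem radius *r*ₛ comes from the separately measured stem diameter
(cm × 10⁴ / 2 µm), not from the sum of the structure radii: the structure
radii are measured locally on a wedge of the section and their sum is far
below half the measured diameter, so the two are deliberately decoupled.
Radii are stored in micrometres; the reference radius table is headed
"mm" but its magnitudes (a WHC radius of 3934.62 for a 2.1 cm stem) are
only consistent with micrometres, and the package documents rather than
silently repairs that discrepancy.

`derive_traits()` offers two modes. The default *mean-radius* mode
averages the nine replicate radii (3 cross-sections × 3 technical
replicates) per accession and structure and applies the geometry once;
this mode reproduces four of the six published primary/secondary ratios
(CRA412 1.17, CRA420 2.62, FNPC243 1.19, WU101 0.84) to two decimals and
is therefore the tabulation convention of record. The *per-replicate*
mode applies the geometry per replicate and then averages, providing a
spread (sd) for uncertainty. The two coincide for a single replicate.
A lumen radius of zero (a fully closed pith, as in CRA412) is valid
input, not missing data. The published bast-area % and bast/WHC ratios
are *not* reproducible from the published radii under either mode (the
basis radii behind those two published columns are unclear); the package
implements the printed equations and leaves the discrepancy flagged
rather than tuned away. The remaining two primary/secondary ratios
(CRA410, CRA416) also differ slightly from print under all averaging
modes tried; they are documented as known discrepancies.

## Repeatability and between-accession statistics

Repeatability is summarised by the coefficient of variation across
technical replicates, CV % = sd / mean × 100 with the *sample* (n − 1)
standard deviation — the convention validated by exact reproduction of
the published radius-table CVs (20.01, 7.11, 150.78, …). CV is
scale-invariant and undefined at zero mean (reported `NA`, never a
division artefact). One published CV cell (38.09) differs in the last
digit from the value computed off the published replicates (38.08),
which is what rounding the inputs to display precision does; the package
computes from the data it is given.

Between-accession differences use classical fixed-effects one-way ANOVA
with technical replicates as the error stratum (no nesting of
cross-sections — the simplest model consistent with the design). Groups
with fewer than two observations are excluded with a warning; an
all-constant response makes F a 0/0 and is reported missing. The star
code mapping defaults to * p < 0.1, ** p < 0.01, *** p < 0.001 —
unconventional at the 0.1 level but kept as the reference convention and
configurable. No multiple-testing correction is applied, matching the
reference analysis; users scanning many traits should interpret stars
accordingly.

Trait association uses Pearson correlation with two-sided t-tests and
pairwise-complete observations; pairs with p above 1 − confidence
(default 0.95) are flagged masked, to be rendered blank. Correlations
can be computed at replicate level or between accession means — with six
accessions the two differ noticeably (e.g. diameter vs primary/secondary
ratio gives −0.99 on the published means while the reference analysis
reports −0.97, consistent with replicate-level source data that is not
published). Both modes are provided; neither is asserted against the
published matrix.

## The synthetic-data generator

`generate_study()` draws a complete study — sample metadata, both
chromatography dilutions, SRS records, Klason and AIR residue masses,
hydrolysis fractions, radius and diameter tables — around a
`synth_truth()`. Its defaults *are* the study conditions of the
reference panel: six accessions × two tissues × three technical
replicates; composition truths at the published tissue means, summing
with Klason lignin to 92.5 % (stem) and 93.8 % (bast) of the cell wall
(arabinose and galactose close the totals, as their per-accession values
are only published graphically); AIR%dm 92 (stem) and 98 (bast);
crystallinity 94 % (cellulose) and 65 % (mannan); technical CV 3 % for
biochemistry (the published CVs are mostly below 10 %) and 20 % for
radii (the magnitude of the published radius CVs); between-accession
effects at 5 % CV, drawn once per study and recorded in the returned
realised truth. SRS control concentrations default to values resembling
hemp hydrolysates (the exact reference concentrations are supplementary
material and configurable). One accession's lumen is closed in two of
three cross-sections, mimicking CRA412.

Noise is multiplicative Gaussian per technical replicate
(value = truth × (1 + CV/100 × z), truncated at zero, with a warning if
more than 1 % of draws truncate), matching CV-based repeatability
reporting; additive noise is available by flag. Concentrations are
back-computed through the inverse of the composition equations, so the
pipeline's forward pass recovers the recorded truth exactly at zero
noise — the round-trip identity the test suite asserts to 10+ significant
digits — and unbiasedly under noise within Monte-Carlo error. The
generator emulates magnitudes and design, not chromatography physics: no
peak shapes, no retention drift, no correlated batch effects, no image
data. Passing tests therefore demonstrate the correctness of the
*computation*, not the behaviour of instruments on real extracts.

## Numerical choices and problem sizes

* Validation happens at parse time with row-addressed errors; tables
  round-trip through delimited text at full stored precision (shortest
  round-trippable decimal representation).
* Pipeline outputs are a pure function of inputs and configuration;
  reruns are byte-identical, and the run log records config, seed and
  package version without timestamps for that reason.
* Monte-Carlo checks in the test suite use 200 replicates for noisy
  truth-recovery (tolerance 0.5 percentage points at 3 % CV), 300
  simulated studies for the small-sample CV bias check (expected
  E[CV̂] ≈ CV(1 − 1/(4n))), and 1000 null traits for the ANOVA type-I
  error check (binomial tolerance), sizes chosen to keep the whole suite
  under a minute on a laptop while leaving comfortable statistical
  margins.
* The acceptance script recomputes the primary/secondary bast ratios
  from the 9-replicate reference radius tables; its n is the replicate
  count behind each mean.

## Known limitations

* The package computes from printed-precision inputs; summary statistics
  published from unrounded source data can differ in the last digit.
* The published bast-area % / bast-WHC ratio columns are not derivable
  from the published radii; the annulus equations are implemented as
  printed and the mismatch surfaced, not calibrated away.
* The ANOVA treats technical replicates as independent errors; a nested
  or mixed model (cross-section within accession) is out of scope.
* No chromatogram peak integration, image segmentation or NIRS
  prediction: concentrations and radii enter as numbers.
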