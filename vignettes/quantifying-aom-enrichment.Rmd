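---
title: "Quantifying biomass growth in AOM enrichments: methods and design"
author: "aomquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biomass growth in AOM enrichments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aomquant)
```

## The quantification problem

Anaerobic methanotrophic archaea (ANME) and their sulphate-reducing
partners (SRB) double on the scale of months, so growth in enrichment
cultures is demonstrated by microscopy rather than by turbidity or dry
mass. The observation unit is a field of view on a polycarbonate filter:
DAPI staining gives counts of all single cells and of multicellular
aggregates binned by eyepiece-measured diameter; CARD-FISH gives, on
separate filter pieces, counts of probe-labelled objects paired with DAPI
counts over the same fields. `aomquant` turns those counts into
concentrations, biovolumes, taxon fractions, and two-timepoint growth
statistics, with uncertainty carried through every step.

## Model and assumptions

**Counting model.** For a homogenized slurry diluted $D$-fold, with $V$ ml
filtered over an effective area $A_{filter}$ and counted in fields of area
$A_{field}$, an object concentration $C$ (per ml of undiluted slurry)
implies a mean per-field count $\lambda = C\,V\,(A_{field}/A_{filter})/D$.
The estimator inverts this: $\hat C = \bar n \cdot
(A_{filter}/A_{field})/V \cdot D$. Each staining replicate is reduced to
its own $\hat C$ first; the reported mean and standard error (sample SD
over $\sqrt k$) are computed across the $k$ replicates, not across
fields. Averaging per replicate before summarizing matches the design in
which each staining is an independent preparation; pooling fields instead
would shrink the SE by ignoring between-staining variability.

**Spheres.** Both cells and aggregates are treated as solid spheres,
$v(d) = \frac{\pi}{6}d^3$. The integer class label (2–15 µm) is used as
the sphere diameter — the reporting convention of the underlying counts —
and single cells use 0.45 µm, the literature average cell size for ANME
and SRB. No porosity or packing correction is applied to aggregates; the
dry-weight conversion below is calibrated on the same assumption, so the
two are consistent and errors partially cancel.

**Probe fractions.** A probe's fraction of a category is
$\sum \text{positive} / \sum \text{DAPI}$ over the fields of a replicate
block (volume-weighted by $v(d)$ for the biovolume category), summarized
across blocks. Because numerator and denominator share every field, the
geometry factor cancels: fractions are invariant to dilution, filtration
volume and optics, which is also why losses during the washing steps do
not bias them provided all object types wash out at the same rate (the
equal-washout assumption). Probes observed zero times are reported as
*below detection* with the concentration a single object over all examined
fields would have implied; a Poisson 95 % bound (3 objects) is available
via `criterion = "poisson95"`.

**Growth.** Group biovolume is total biovolume × biovolume fraction.
"Increased $x$ times" is implemented as the relative increase
$(V_2-V_1)/V_1$; the fold change $V_2/V_1$ is always exposed alongside
because the two conventions differ by exactly 1 and are easily confused.
The relative-increase reading is the only one under which the
reference dataset's printed 2.5×, 12.5× and 8.4× are simultaneously
consistent with its printed biovolumes. Doubling time assumes exponential
growth between the two points: $t_d = \Delta t \ln 2 / \ln(V_2/V_1)$,
with months of 30.44 days (mean Gregorian month; configurable). Dry
weight uses 0.2 g cell dry weight per ml biovolume, a published value for
small marine sediment microorganisms — likely the least certain constant
in the chain (see Limitations).

**Uncertainty.** SEs of derived quantities use the first-order delta
method assuming independent errors at the two timepoints: for the ratio
$R = V_2/V_1$, $\mathrm{se}(R) = R\sqrt{cv_1^2 + cv_2^2}$, and for the
doubling time $\mathrm{se}(t_d) = t_d\,\sqrt{cv_1^2+cv_2^2}/\ln R$. A
seeded parametric bootstrap (`method = "bootstrap"`, normal resampling)
is provided as a cross-check; the two agree within a few percent for
coefficients of variation up to ~0.1, which covers the data this package
targets.

## Reproduction versus full-precision mode

The reference report rounds group biovolumes to 2 significant figures
before deriving increases from them, but derives the SRB increase from
full-precision products; its dry weights are printed at 1 significant
figure. Since no single rounding rule reproduces every printed number,
`estimate_growth()` exposes both conventions: `mode = "reproduce"` rounds
group biovolumes to 2 s.f. before any derived quantity and reports dry
weights at 1 s.f.; `mode = "full"` keeps full precision. Under
"reproduce" the ANME-2 increase is 12.5 and under "full" the SRB increase
is 8.4 and the total 2.5 — together recovering all printed values. The
doubling time is 2.5 months under either mode.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `dilution_factor` | 2000 (S1) / 5600 (S2) | – | dilutions used for the two reference samples |
| `filtered_volume_ml` | 10 | ml | puts per-field counts in a countable range (~13 cells/field) |
| `filter_effective_area_um2` | $\pi (10^4)^2$ | µm² | 2.5 cm filter with ~2 cm effective diameter |
| `field_area_um2` | $10^4$ | µm² | 100 µm × 100 µm field at 1000× |
| `single_cell_diameter_um` | 0.45 | µm | literature average ANME/SRB cell size |
| diameter classes | 2–15 | µm | reporting range of aggregate sizes; class label = sphere diameter |
| `n_replicates`, `n_fields` | 4, 50 | – | the counting design of the reference experiment |
| dry-weight factor | 0.2 | g/ml | published biovolume→dry-mass conversion |
| days per month | 30.44 | d | mean Gregorian month |

Filtered volume, field area and effective filter area were not reported
for the reference experiment; absolute concentrations therefore depend on
these configurable defaults, while every fraction, share, increase and
doubling time is invariant to them (a property the test suite asserts).

## The synthetic-data generator

`truth_model()` declares true concentrations per class, per-probe marginal
labelling probabilities, clone-library compositions, and an exponential
growth law; from it the package draws

* field counts — independent Poisson per field and class, with an
  optional negative-binomial overdispersion knob for aggregate clumping
  (the default is Poisson, appropriate for a manually homogenized
  slurry);
* probe counts — binomial thinning of each field's DAPI count at the
  class-specific fraction, optionally preceded by a common binomial
  washing loss, which lets tests verify that fractions are invariant
  under equal washout;
* clone libraries — multinomial draws from the community composition.

All streams derive from one seed by stable sub-seeding, so adding a stage
never perturbs earlier draws and fixed seeds give byte-identical tables.

`reference_truth()` encodes the reference scenario. Its per-class
concentrations are constructed, not copied: single cells carry 0.3 % of
total biovolume (aggregates 99.7 %); classes 2–5 µm hold 73.35 % /
73.28 % of aggregate counts (uniform within the group); the 11–15 µm
shape is solved (geometric within-group weights) so that S1's big-class
count and biovolume share are met simultaneously; the 6–10 µm shape
absorbs the remaining count and biovolume budget. For S2 the printed
big-class concentration, big-class biovolume share and total are mutually
infeasible for spheres ≤ 15 µm (they imply a mean aggregate volume larger
than a 15 µm sphere), so the preset keeps the total and the shares exact,
reuses S1's within-group shape, and derives the S2 big-class
concentration (~9.7×10⁵/ml, about 3 SEs above the printed point value).
Two-tier per-probe fractions (one level for 2–5 µm, one for 6–15 µm) are
solved per probe from the observed aggregate-count and biovolume
fractions. The published composition tables overlap (single-probe
hybridizations; aggregates host ANME-2 and SRB together — their S2
biovolume fractions sum to over 110 %), so no disjoint all-probe growth
partition exists; the growth truth instead tracks the disjoint pair
{ANME-2, everything else}, whose doubling times (~2.5 and ~9.3 months)
are implied by the two reference states over 286 days. `evolve()` applies
the mixture factor per class and updates the ANME-2 marginals
consistently; other probes' marginals are held fixed, a documented
approximation.

What the generator does **not** emulate: spatial consortium architecture
(shell/core arrangements), diameter-measurement error, between-staining
preparation effects beyond Poisson noise, mis-hybridization, and
extracellular polymeric substances. Passing recovery tests therefore
demonstrate correctness of the estimators under the declared sampling
model, not robustness to these real-data complications.

## Numerical choices and degenerate inputs

* Totals are conserved exactly (single-cell + per-class biovolume); the
  suite asserts this to 1e-9 relative tolerance.
* A sample with zero total biovolume gets aggregate share 0 (with a
  warning) rather than 0/0.
* One replicate: means are reported, SEs are `NA` (flagged undefined),
  never silently 0.
* Probe counts exceeding their paired DAPI counts, negative counts,
  unknown classes and duplicate keys are hard errors naming the row;
  writers are atomic so invalid input never leaves partial files.
* The shape-ratio solver brackets the geometric ratio in log space
  (`uniroot`, tolerance 1e-12) and refuses targets outside the attainable
  volume range instead of extrapolating.
* Probe fractions solved outside [0, 1] (possible only through rounding
  of the published inputs) are clamped to the boundary.

## Test problem sizes

The suite exercises the pipeline at the reference design (4 × 50 fields)
for end-to-end recovery — averaging five seeded runs, since a single
4 × 50 experiment carries ~10 % sampling error on the doubling time — and
at 4 × 5000 fields / 10 000 fields for consistency checks, where
estimator bias must fall within 3 Monte-Carlo SEs. The acceptance script
uses 4 × 2000 fields, at which the recovered doubling time is stable to a
few percent across seeds. These sizes were chosen as the smallest designs
at which the statistical assertions have comfortable power.

## Limitations

* Absolute concentrations are only as good as the geometry config;
  without the true filtration parameters they are defined up to a common
  constant (all ratios are unaffected).
* The 0.45 µm cell diameter and the 0.2 g/ml dry-weight factor are
  literature values, not measured here; dry weights inherit their
  (unquantified) systematic uncertainty, and comparisons with volatile
  suspended solids can disagree by an order of magnitude.
* Two timepoints cannot distinguish exponential from other monotone
  growth; the doubling time is conditional on the exponential assumption.
* Single-probe CARD-FISH fractions are marginal, not additive; summing
  them over probes double-counts mixed consortia.
* The concordance probability $(1-f)^n$ assumes clones are independent
  draws at the FISH-estimated frequency, ignoring PCR and cloning bias.
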