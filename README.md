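# aomquant

Quantification of microbial biomass growth in anaerobic methane-oxidizing
(AOM) enrichment cultures from microscopy count data.

Communities that couple the anaerobic oxidation of methane to sulphate
reduction — anaerobic methanotrophic archaea (ANME) and their
sulphate-reducing bacterial partners (SRB) — grow so slowly (doubling times
of months) that their enrichment can rarely be followed by optical density
or gravimetry. The practical alternative is microscopy: count
DAPI-stained single cells and size-classed cell aggregates in fields of
view on a filter, convert counts to concentrations, convert diameters to
spherical biovolume, attribute biovolume to taxa with CARD-FISH probes,
and compare two sampling timepoints. `aomquant` implements that entire
quantification chain for microbial ecologists running slow-growing
enrichments (bioreactors, sediment slurries), together with a
synthetic-data generator that makes every stage testable against known
parameters.

## The model

**Counts to concentrations.** Objects counted in fields of view on a
filter of effective area *A*<sub>filter</sub>, after filtering
*V* ml of sample diluted *D*-fold, have concentration

> *C* = (mean count per field) × (*A*<sub>filter</sub>/*A*<sub>field</sub>) / *V* × *D*  [objects/ml slurry]

Each staining replicate (default 4, with 50 fields each) is reduced to one
value; means and standard errors (n−1 SD / √k) are taken across
replicates.

**Biovolume.** Cells and aggregates are modelled as solid spheres:
*v*(*d*) = (π/6)·*d*³ μm³, with the integer diameter-class label (2–15 μm)
as the aggregate diameter and 0.45 μm for single cells. Class biovolume is
concentration × *v*(*d*); the total is the single-cell plus per-class sum.

**CARD-FISH composition.** A probe's fraction of cells, aggregates, or
biovolume is the ratio of probe-positive to DAPI counts over the same
fields (volume-weighted for biovolume). Geometry cancels in the ratio, and
under the equal-washout assumption the fraction is unbiased for the
community before filter washing. Probes with zero positives are reported
as below detection with the concentration bound implied by one object over
all examined fields.

**Growth.** For group biovolumes *V*₁, *V*₂ at two timepoints Δt apart:

> relative increase = (*V*₂ − *V*₁)/*V*₁, fold change = *V*₂/*V*₁
> doubling time *t*<sub>d</sub> = Δt · ln 2 / ln(*V*₂/*V*₁)  (months at 30.44 d/month)
> dry weight [g/l] = biovolume [μm³/ml] × 10⁻¹² × 0.2 g/ml × 10³

Standard errors propagate by the first-order delta method, with a seeded
parametric bootstrap as a cross-check. Clone-library percentages
(100 × clones in group / clones sequenced) and a FISH-vs-library
concordance report with (1 − *f*)ⁿ absence probabilities complete the
pipeline.

## Worked example

The package ships the summary observations of a 286-day high-pressure
bioreactor enrichment (samples S1 before and S2 after incubation) as its
reference dataset. Reproducing the growth analysis from those inputs:

```r
library(aomquant)
g <- reference_growth(delta_t_days = 286)
print(g$reproduce)
#> Growth estimate over 286 days (reproduce mode)
#>   total    V1 (1.30 ± 0.06)*10^9, V2 (4.50 ± 0.51)*10^9 um^3/ml
#>            increase 2.5x (fold 3.5), doubling time 5.2 months
#>            dry weight 0.3 -> 0.9 g/l slurry
#>   ANME-1   below detection limit
#>   ANME-2   V1 (1.70 ± 0.54)*10^8, V2 (2.30 ± 0.76)*10^9 um^3/ml
#>            increase 12.5x (fold 13.5), doubling time 2.5 months
#>            dry weight 0.03 -> 0.5 g/l slurry
#>   ANME-3   V1 (1.90 ± 1.92)*10^7, V2 (1.10 ± 0.82)*10^8 um^3/ml
#>            increase 4.8x (fold 5.8), doubling time 3.7 months
#>            dry weight 0.004 -> 0.02 g/l slurry
#>   SRB      V1 (2.90 ± 0.69)*10^8, V2 (2.70 ± 0.40)*10^9 um^3/ml
#>            increase 8.3x (fold 9.3), doubling time 2.9 months
#>            dry weight 0.06 -> 0.5 g/l slurry
```

Reading: the total biovolume grew 2.5×, ANME-2 12.5× and SRB ~8×, i.e.
the methane-oxidizing consortia were selectively enriched; under
exponential growth the ANME-2 population doubled every 2.5 months; the
community amounts to 0.3 → 0.9 g cell dry weight per litre of slurry.
(`g$full` holds the same table without the report-style 2-significant-
figure intermediate rounding.)

The same estimates can be computed from raw count tables. Here from a
simulated dataset whose generating truth matches the reference scenario:

```r
tr     <- reference_truth("S1", seed = 1)       # declared truth
counts <- simulate_counts(tr)                   # Poisson field counts, 4 x 50
bv     <- quantify_sample(counts, tr$geometry)  # concentrations + biovolume
print(bv)
#> Sample biovolume: S1 (4 replicates x 50 fields)
#>   total biovolume    : (1.11 ± 0.03)*10^9 um^3/ml slurry
#>   single cells       : (8.10 ± 0.19)*10^7 cells/ml
#>   aggregate biovolume share: 99.7%

probes <- simulate_probe_counts(tr, simulate_counts(tr, seed = 2), seed = 3)
fish_composition(probes, tr$geometry)
#> CARD-FISH group composition (sample S1)
#> Group       % of cell count       % of aggregate count  % of biovolume
#> ANME-1      Below detection limit Below detection limit Below detection limit
#> ANME-2      7.6 ± 0.7            40.8 ± 2.9           13.7 ± 1.9
#> ANME-3      0.2 ± 0.1            2.3 ± 0.4            1.8 ± 0.7
#> SRB         3.2 ± 0.2            31.2 ± 2.3           24.1 ± 5.1
```

A thin command-line interface (`exec/aomquant`) exposes the same steps as
`simulate`, `quantify`, `fish`, `growth`, `clones` and `report`
subcommands over TSV/YAML files.

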