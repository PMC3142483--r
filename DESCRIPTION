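Package: aomquant
Title: Biovolume and Growth Quantification for Methane-Oxidizing Enrichments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies microbial community growth in anaerobic
    methane-oxidizing (ANME/SRB) enrichment cultures from microscope count
    data. Converts per-field DAPI counts of single cells and size-classed
    aggregates into per-ml concentrations and spherical biovolumes with
    replicate-based standard errors, estimates group composition from
    CARD-FISH probe counts with detection-limit reporting, combines two
    sampling timepoints into relative-increase factors, exponential doubling
    times and dry-weight biomass with delta-method or bootstrap uncertainty,
    computes 16S clone-library composition and its concordance with FISH,
    and generates statistically faithful synthetic datasets (Poisson field
    counts, binomial probe labelling, multinomial clone libraries) for
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
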