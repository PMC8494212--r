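Package: umnvar
Title: Tumor-Only Somatic Variant Filtering with Unmatched Normal Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates and filters tumor variant calls made against a panel
    of unmatched normal controls. Normal-sample allele fractions are
    classified with a binomial mixture model fit by EM, pooled across
    controls and segmented to detect hard-to-map (H2M) regions on the fly.
    Variants in germline equilibrium are scored with a two-component
    posterior against the local B-allele-fraction band, and oxoG, FFPE and
    strand-bias sequencing artifacts are flagged from tumor allele-fraction
    clusters and stranded read counts. A cumulative filter ladder with a
    cross-normal consensus rule and a COSMIC recurrence rescue produces a
    per-variant verdict table, and benchmarking utilities score call sets
    against a gold standard. A synthetic-cohort generator with known truth
    labels supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    tidyr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
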