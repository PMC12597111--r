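Package: famclust
Title: Familial Clustering Analysis in Population Genealogies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing familial clustering of a rare phenotype in
    multigenerational genealogies linked to case records. Implements exact
    Malecot kinship coefficients and meiotic genetic distances over arbitrary
    pedigrees (with a gene-dropping Monte Carlo oracle), the Genealogical
    Index of Familiality (GIF) and its distant variant (dGIF) with matched
    control resampling and empirical significance, per-genetic-distance
    contribution decompositions, cohort-specific incidence rates, relative
    risks for first- through third-degree relatives with small-sample
    Poisson-inversion confidence intervals, founder-pedigree excess-case
    scans for high-risk families, and a forward-time genealogy simulator
    with null and familially clustered phenotype models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
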