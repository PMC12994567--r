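Package: wildtcr
Title: T-Cell Receptor Repertoire Analysis for Wild Rodent Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk T-cell receptor (TCR) repertoires of
    CD4+ and CD8+ alpha/beta chains across a cohort of mice: clonotype table
    ingestion (AIRR Rearrangement TSV and a minimal TSV dialect), CDR3
    translation and productive-sequence filtering, collapse of
    nucleotide-defined clones to amino-acid-defined clonotypes, molecule-count
    quality control, rarefaction by multivariate hypergeometric down-sampling,
    Shannon and Simpson diversity, discrete power-law fits of clone-size
    distributions with Kolmogorov-Smirnov bootstrap goodness of fit,
    pairwise clonotype-sharing matrices with public-clonotype detection,
    dendrogram and principal-coordinates ordination of repertoire
    dissimilarity, and gamma/Gaussian generalized linear models of richness,
    diversity and sharing with estimated-marginal-mean post-hoc contrasts.
    Includes a seeded synthetic-cohort generator with power-law clone sizes,
    a public clonotype pool, and age- and sex-linked clonal expansion, so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    withr,
    ape,
    vegan,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
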