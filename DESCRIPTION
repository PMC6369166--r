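Package: mvftest
Title: Univariate and Multivariate Mixed-Model F-Tests for Genome-Wide
    Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association tests based on F statistics for
    univariate and multivariate linear mixed models with polygenic effects.
    Variance components are estimated by EM-REML, including the
    Kronecker-structured genetic and residual covariances of multi-variate
    models with arbitrarily missing phenotype records.  The package also
    provides a self-contained simulation engine for inbred genotypes with
    linkage disequilibrium, correlated QTL architectures at fixed
    heritability, structured phenotype missingness, replicate power grids
    comparing the multivariate and univariate tests, and the closed-form
    power factor relating the relative QTL effect and the phenotypic
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
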