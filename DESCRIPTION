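Package: ramsolve
Title: Reduced Animal Models Restricted to Phenotyped Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves Henderson's mixed-model equations for
    pedigree and genomic animal models, and reduces them to the equations
    of phenotyped animals by Schur-complement absorption of the
    non-phenotyped animals' equations.  The absorbed kernel equals the
    inverse of the phenotyped block of the numerator relationship matrix,
    so the reduced system reproduces the full-model breeding values
    exactly; solutions for absorbed animals are recovered by sparse
    back-solving.  Supports basic, multiple-trait, repeatability,
    maternal (correlated and uncorrelated), unknown-parent genetic group
    (Quaas-Pollak), GBLUP and single-step GBLUP model families, with a
    seeded simulator for pedigrees, phenotypes and gene-dropped marker
    genotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
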