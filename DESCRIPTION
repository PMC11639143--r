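Package: admixgeom
Title: Geometric f-Statistics for Population Admixture Proportions
Version: 0.1.0
Authors@R:
    person("admixgeom", "developers", email = "admixgeom@example.org",
           role = c("aut", "cre"))
Description: Estimates 2-way and 3-way population-admixture proportions from
    allele-frequency panels using the f-statistics framework interpreted
    geometrically. Provides f2, f3, f4 and renormalized f4 statistics computed
    as scalar products in allele-frequency space, mixing-coefficient
    estimators both in the full phase space and in the low-dimensional
    subspace spanned by auxiliary-population pair directions (a
    Johnson-Lindenstrauss random projection that depletes post-admixture
    drift), admixture angles before and after projection, a tetrahedron
    flatness index for 3-way fits, readers for delimited frequency tables and
    EIGENSTRAT genotype triples, and a tree-structured Brownian drift
    simulator with a bounded uniform post-admixture noise model for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
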