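Package: epiwalsh
Title: High-Order Epistasis in Nonlinear Genotype-Phenotype Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes combinatorially complete genotype-phenotype maps into
    high-order epistatic coefficients on a Walsh-Hadamard basis, after
    estimating and removing an arbitrary monotone nonlinear phenotypic scale
    with a power transform. Propagates phenotype measurement uncertainty into
    coefficient uncertainty by bootstrap pseudoreplicates, with z-score and
    Bonferroni-corrected significance calls, and partitions phenotypic
    variance by interaction order. Includes a simulator of epistatic maps
    with known coefficients, saturating or power-law scales, and replicate
    noise, plus command-line entry points for fitting, simulation, and
    variance partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
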