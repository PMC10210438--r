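Package: gsdsim
Title: Individual-Based Simulation of Sex-Determination Evolution Along
    Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulation of the evolution
    of genetic sex determination in a metapopulation arranged along a linear
    temperature gradient. Sex is set by a threshold model in which a
    feminizing locus with temperature-dependent, evolvable expression is
    antagonized by Y-linked and autosomal masculinizing loci. The package
    models mutation (including irreversible null mutations), de novo
    activation of autosomal masculinizers, Y-chromosomal viability and
    sexually antagonistic fitness effects, and nearest-neighbour dispersal
    between demes. An analysis layer classifies the evolved
    sex-determination systems from recurrent genotype pairs, extracts
    allele-frequency clines, and detects housefly-like joint polymorphisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
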