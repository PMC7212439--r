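Package: gocsim
Title: Stochastic Simulation of Genomic Optimum-Contribution Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-in-time stochastic simulation of closed breeding schemes
    under genomic optimum-contribution selection (GOCS). A Wright-Fisher
    founder simulator with mutation, recombination, drift and mild directional
    selection generates a population at mutation-drift equilibrium; a base
    population carrying identity-by-descent (IBD) tracer loci seeds an
    11-generation breeding scheme in which genomic breeding values are
    predicted by G-BLUP and parental contributions are optimized by
    maximizing genetic gain under a quadratic coancestry penalty. The
    genomic relationship matrix (VanRaden method 2) used for prediction may
    be built from markers, QTL, or both, and may differ from the matrix used
    to control coancestry. Outputs are rates of genetic gain, rates of true
    (IBD-based) and pedigree inbreeding, and prediction accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'genome.R'
    'meiosis.R'
    'founder.R'
    'trait.R'
    'population.R'
    'metrics.R'
    'grm.R'
    'gblup.R'
    'ocs.R'
    'scheme.R'
    'experiment.R'
    'io.R'
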