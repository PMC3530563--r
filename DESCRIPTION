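Package: fecalpop
Title: Population Genetics from Non-Invasive Faecal Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the full inference chain used in non-invasive
    (faecal DNA) population studies of large mammals: multiple-tubes
    consensus genotyping with maximum-likelihood reliability scores,
    probability-of-identity statistics and recapture matching, molecular
    sex assignment, per-population diversity indices, Weir-Cockerham
    F_ST and AMOVA Phi_ST with permutation tests, Kimura two-parameter
    and HKY distances with neighbour-joining trees and bootstrap
    support, a Bayesian admixture (Gibbs) clustering model with an
    optional location-informed prior and Evanno Delta-K model choice,
    and likelihood-based source-population assignment. A synthetic-data
    module simulates metapopulations with strong mitochondrial but weak
    nuclear structure (female philopatry with male-mediated gene flow),
    genotyping errors and recaptures, so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
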