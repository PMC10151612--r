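Package: endofba
Title: Metabolic Compatibility of Host-Endosymbiont Pairs by Flux Balance
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether two prokaryotic metabolisms could form a
    viable endosymbiosis. Genome-scale metabolic models are harmonized onto a
    shared compound namespace, exchange reactions are replaced by equivalent
    bounds on compound derivatives, and a nested host-endosymbiont linear
    program (the endosymbiont's extracellular compartment is the host's
    cytoplasm) is solved for joint growth. Nonviable pairs are diagnosed and
    repaired with minimal sets of host transport reactions; viable pairs are
    competed against their ancestral metabolisms under single-compound
    environmental degradation, in growth-rate comparisons, and in a shared
    two-step community linear program; evolvability is scored by systematic
    relaxation of single reaction flux bounds. Includes a seeded generator of
    synthetic metabolic networks with closed-form ground truth, a
    bounded-variable simplex solver, and survey pipelines with batched
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    boot,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
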