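Package: nrprof
Title: Protein Function Prediction with Neural-Response Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns Gene Ontology (GO) terms to query proteins by remote
    homology, using a two-layer neural-response representation: proteins are
    encoded as vectors of maximal motif-template hit scores over a fixed
    template library, protein pairs are encoded as response differences, and
    a kernel mapping engine (regularized kernel least squares or a support
    vector machine, with linear or Gaussian derived kernels) is trained on
    same-GO-term versus different-GO-term pairs. Query proteins inherit the
    leaf GO terms of their highest-scoring base-set neighbours. Includes
    readers for OBO 1.2 ontologies, HMMER3 per-domain tables, FASTA and TSV
    hit/annotation tables, positive-definiteness validation and repair of
    template similarity matrices, GO-motif association scoring, pair-dataset
    construction with stratified cross-validation, and a synthetic fixture
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    kernlab,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
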