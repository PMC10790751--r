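Package: anigap
Title: Intra-Species ANI Gap Detection and Genomovar Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Detects the discontinuity around 99.2-99.8% average nucleotide
  identity (ANI) observed within bacterial species and delineates the nested
  intra-species units it supports: genomospecies (95% ANI), genomovars
  (99.5%) and strains (99.99%). Provides fragment-based ANI estimation
  between genome assemblies, uniform-null deficit statistics, kernel-density
  valley detection, an exact Hartigan dip statistic with Monte-Carlo
  p-values, single-linkage threshold clustering, MLST-style sequence typing
  with concordance metrics against ANI clusters, a two-proportion enrichment
  test for mobile gene categories among non-shared genes, and a synthetic
  species generator with planted unit structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
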