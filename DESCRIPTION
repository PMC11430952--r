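Package: gyrits
Title: Motif-Anchored Annotation and Partitioned Distance Analysis of
    Gyrodactylid ITS rDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ITS1-5.8S-ITS2 ribosomal DNA marker of
    viviparous gyrodactylid monogeneans. Locates the conserved boundary
    motifs at the 3' end of 18S (ATCATTA), both ends of the 157-bp 5.8S
    gene (CAACTC, GTCGGCT) and the 5' end of 28S (CCTGACC) with
    single-substitution tolerance, excises flanks, partitions records
    into ITS1/5.8S/ITS2 with quality flags and diagnosis strings.
    Computes pairwise p-distances and maximum-likelihood distances under
    partitioned GTR-family models (TVM+F+G4, SYM+G4) with discrete-gamma
    rate heterogeneity, summarizes intra- and inter-group distances,
    evaluates monophyly and support of proposed genera on input trees,
    and delimits candidate species by a single-linkage distance
    threshold. Includes a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
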