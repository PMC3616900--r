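Package: regulonr
Title: Comparative-Genomics Reconstruction of Bacterial Transcription-Factor Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Reconstruction and comparison of transcription-factor (TF) regulons
  across groups of related bacterial genomes. Provides bidirectional-best-hit
  ortholog clustering of proteomes with paralog attachment, symmetry-constrained
  expectation-maximization discovery of TF-binding-site motifs, position weight
  matrix scanning of operon upstream regions with a training-set-minimum score
  threshold, cross-genome consistency filtering of candidate sites, regulon
  projection/expansion workflows, and comparative statistics of the resulting
  regulatory networks (TF census, motif and regulon-content conservation,
  non-orthologous displacement, autoregulation, cascades and co-regulation).
  A seeded synthetic genome generator with planted regulatory sites supplies
  ground truth for benchmarking precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
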