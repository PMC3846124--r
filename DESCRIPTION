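Package: bacscreen
Title: Multidimensional Pooled Screening of BAC Libraries with Multiplex SNP Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening large bacterial artificial chromosome (BAC)
    libraries with combinatorial pools and multiplexed SNP genotyping assays.
    Builds multidimensional pooling designs (plate, row, column, diagonal,
    side and face pools of a conceptual clone cube, plus superpool and
    single-plate dimensions), simulates pooled GoldenGate-style signals
    (normalized R intensity and normalized Theta allele frequency) for
    planted loci including homoeologous locus pairs of a polyploid genome,
    scores pools with a threshold rule tailored to BAC pools, deconvolves
    positive pools into putative clone coordinates, and audits screening
    results against known clone coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
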