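Package: genimage
Title: Genetic Images from Barcode Proteins: Encoding, Neural Recognition,
    and Uncovering of Evolutionary Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes DNA-barcode protein sequences (cytochrome b and
    cytochrome c oxidase subunit I) as fixed-length five-bit binary "genetic
    images", recognizes them with ensembles of three-layer sigmoid networks
    trained by online backpropagation with momentum, and iteratively
    "uncovers" evolutionarily related organisms by removing recognized
    organisms from the teaching set and retraining.  Relationships are
    corroborated by a semihomologous position classifier that types aligned
    amino-acid positions as homologous, transition-type or transversion-type
    one-point codon mutations over a genetic-code table.  A codon-level
    substitution simulator with a controllable transition/transversion ratio
    generates panels with known ancestry so the whole pipeline runs without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
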