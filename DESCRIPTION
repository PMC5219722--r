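Package: overko
Title: Design of Gene Knockouts in Overlapping (Overprinted) Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Finds minimal nucleotide substitutions that knock out a target
    gene -- by inserting a premature stop codon or destroying the start
    codon -- while leaving the amino acid sequence of a gene overlapping it
    in another reading frame or on the opposite strand exactly unchanged.
    Candidate mutations are annotated with restriction-enzyme recognition
    sites gained or lost, usable as cloning tracers, and can be generated in
    batch from FASTA input. Includes a seeded generator of synthetic
    overlapping gene pairs with planted geometry and a survey routine that
    summarises where the first reachable premature stop codon falls along
    the gene.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
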