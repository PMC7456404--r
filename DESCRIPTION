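Package: SeroB15
Title: Serological Split Assignment of HLA-B*15 Alleles from Amino Acid Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts DNA-based HLA-B*15 typing results into their serological
    split equivalents (B62, B62-Bw4, B63, B71, B71-Bw4, B72, B75, B76, B77)
    using a rule table over fifteen diagnostic amino acid positions of the
    mature class I heavy chain, together with the Bw4/Bw6 public-epitope call
    from residues 77 and 80-83. Includes a parser for WHO colon-delimited
    allele nomenclature, mature-protein coordinate mapping for precursor or
    mature input sequences, batch classification of protein FASTA files with
    TSV/JSON reports, and the pattern-discovery procedure that derives
    subtype-specific motifs from serologically labelled allele sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
biocViews: Sequencing, Classification, Transplantation, ImmunoOncology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
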