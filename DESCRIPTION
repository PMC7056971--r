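Package: strainseq
Title: Strain-Specific Gene, mRNA and Protein Sequence Prediction from Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts strain-specific gene, mRNA and protein sequences for
    inbred laboratory mouse strains (or any homozygous genome) from a
    reference gene sequence, a reference transcript and per-strain SNP/indel
    tables. Variants are imputed into the reference gene through an
    index-preserving edit map; the reference mRNA is then spliced-aligned to
    the imputed gene (unique k-mer seeding, shortest-path exon chaining,
    GT/AG splice-boundary refinement and affine-gap Gotoh fill) and the
    predicted transcript is translated under two open-reading-frame
    selection policies. Includes a synthetic gene/variant simulator with
    ground truths for end-to-end validation, pairwise identity reporting,
    and a batch pipeline over many strains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
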