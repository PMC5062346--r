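Package: coiscan
Title: Site-Wise Conservation, Structure Context and Selection Profiling of
    Protein-Coding DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for site-wise molecular-evolution analysis of aligned
    protein-coding marker sequences, with the 658-bp COI DNA barcode as the
    canonical case. Reads gapped nucleotide alignments, filters by sequence
    quality, collapses haplotypes, translates under NCBI (mitochondrial)
    genetic codes, and profiles every amino acid column by Shannon entropy,
    biochemical-group variation, consensus conservation and internal
    deletions. Columns can be annotated with secondary-structure segments
    (transmembrane helix versus loop) and with minimum heavy-atom distances
    to enzyme ligands read from a reference PDB structure. Statistical
    machinery includes the Williams-corrected G-test of independence, a
    tie-corrected Wilcoxon rank-sum test, Nei-Gojobori (1986) counting
    estimates of codon-wise dN/dS with Jukes-Cantor correction, and an
    empirical directional nucleotide substitution matrix. A seeded codon
    alignment simulator with per-site selective constraints, AT-biased
    composition, damage-type transition excess and parasite-restricted
    deletions provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
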