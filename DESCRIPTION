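Package: protpage
Title: Static Supplementary Web Pages for Protein Bioinformatics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds self-contained static HTML pages for protein
    bioinformatics supplementary results from a declarative JSON page
    specification. Pages may combine markdown text, paginated and
    searchable tables, sequence views with per-residue numeric tracks,
    multiple sequence alignments, 3D structure and network viewers
    embedded from pinned CDN assets, and pairwise protein alignments
    colored by secondary structure. Sequences are extracted from PDB
    coordinate files, secondary structure is assigned on the fly from
    alpha-carbon distance templates, and global pairwise alignment uses
    affine gap penalties under a configurable substitution matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    commonmark,
    curl,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'secstruct.R'
    'pairalign.R'
    'pagespec.R'
    'sitegen.R'
    'cli.R'
    'pdbio.R'
    'fixtures.R'
    'protpage-package.R'
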