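# protpage

Static, self-contained supplementary web pages for protein bioinformatics.

Sharing the integrated results of a protein study — sequences, alignments,
structures, interaction networks, large tables — usually ends up as Excel
supplementary files, because the purpose-built viewers each need their own
programming and hosting. `protpage` removes that step: a researcher writes a
single **declarative JSON page specification** in whatever language they
like, and the package turns it into one static `index.html` that needs no
server, no install, and embeds its data inline (only the pinned third-party
viewer scripts load from CDN URLs).

It is aimed at bioinformaticians publishing supplementary material: the
page can mix markdown text, paginated/searchable/sortable/filterable
tables, sequence views with per-residue numeric tracks (e.g. predictor
confidences), multiple sequence alignments, embedded 3D structures and
networks, interactive plots — and, the protein-specific core, **pairwise
alignments of related proteins color-coded by secondary structure**, with
everything computed on the fly from plain PDB files.

## What is computed natively

- **PDB parsing** (`parsePDB`, `chainSequence`, `caTrace`): fixed-column
  ATOM/HETATM records → per-chain one-letter sequences and CA traces
  (MODEL 1 only; first altloc wins; MSE-style residues mapped, unknowns →
  `X`).
- **Secondary structure from CA geometry** (`assignSecondaryStructure`):
  for each interior residue *i*, the six pairwise CA distances of the
  5-residue window (d13, d14, d15, d24, d25, d35) are compared to ideal
  templates; the state is

  - `H` if all six are within 2.1 Å of the helix targets
    (5.45, 5.18, 6.37, 5.45, 5.18, 5.45 Å),
  - else `E` if all six are within 1.42 Å of the strand targets
    (6.1, 10.4, 13.0, 6.1, 10.4, 6.1 Å),
  - else `T` if d15 < 8 Å, else `C`.

  Constants are data (`distanceTemplates()`), not code.
- **Global pairwise alignment** (`globalAlign`): Needleman–Wunsch with the
  Gotoh three-state recurrence for affine gaps, maximizing
  `Σ s(aᵢ, bⱼ) − Σ_gaps (open + extend·L)` under a configurable
  substitution matrix (bundled NCBI BLOSUM62; any NCBI-layout file,
  e.g. ProtSub, can be supplied). Deterministic traceback; optional
  free-end-gap (semi-global) mode; `percentIdentity` over shared columns.
- **Validation** (`parsePageSpec`): eager, total validation of the JSON
  document against the shipped schema; every diagnostic names the JSON
  path of the offending key (`components[3].rows[1]`), unknown component
  kinds are hard errors.

## Worked example

Everything below is generated by the package itself — `makeDemoSpec()`
writes two toy PDB chains (an ideal α-helix and a mixed helix/coil chain)
and a spec exercising all eight component kinds:

```r
library(protpage)

json <- makeDemoSpec(tempdir())          # writes toy_helix.pdb, toy_mixed.pdb
spec <- parsePageSpec(json)
spec
#> PageSpec "Demo: paired toy proteins" (8 components)
#>   [1] markdown
#>   [2] table
#>   [3] sequence
#>   [4] msa
#>   [5] pair_alignment
#>   [6] structure
#>   [7] network
#>   [8] plot

tr <- makeTrace(geometryRecipe("ideal_helix", 12))
assignSecondaryStructure(tr)
#> [1] "CCHHHHHHHHCC"

r <- globalAlign("HEAGAWGHEE", "PAWHEAE")
alignedSeqs(r)
#>            a            b
#> "HEAGAWGHEE" "---PAWHEAE"
alignmentScore(r)
#> [1] 1
```

The helix assignment shows the 5-residue window rule: the first and last
two residues have no complete window and stay `C`; every interior position
of an ideal helix matches the helix template. The alignment score is the
BLOSUM62 column sum minus one affine gap charge (open 11 + 3·extend 1).

Building the page:

```r
specPath <- file.path(tempdir(), "demo.json")
writeLines(json, specPath)
buildSite(specPath, "site")
#> ok=true
#> components=8
#> kinds=markdown,table,sequence,msa,pair_alignment,structure,network,plot
#> warnings=0
#> output=site/index.html
```

`site/index.html` is the whole deliverable: open it in a browser. Local
PDB files are copied to `site/data/` and referenced relatively, so the
directory is portable. The same build is available from a shell:

```sh
Rscript inst/scripts/buildpage.R --json demo.json --out site
```

`--json` also accepts a public http(s) URL (30 s timeout, 50 MB cap);
private resources fail with an explicit message.

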