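---
title: "protpage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protpage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpage)
```

`protpage` builds static supplementary pages for protein bioinformatics
from a declarative JSON specification. Most of the package is plumbing
with firm contracts (validation, rendering, the build pipeline); two parts
are genuinely scientific — secondary structure assignment from CA
geometry, and affine-gap pairwise alignment — and this vignette explains
the model behind each, the tunable parameters, the numerical choices, and
what the synthetic test data does and does not establish.

## The page model

One JSON file describes one page: a `title` and an ordered `components`
array. Eight component kinds exist (`markdown`, `table`, `sequence`,
`msa`, `pair_alignment`, `structure`, `network`, `plot`); the schema
shipped at `inst/extdata/page-schema.json` (returned by `specSchema()`) is
the canonical description and is consulted by the validator itself for
the kind vocabulary and key types. Validation is **eager and total**:
`parsePageSpec()` either returns a fully validated `PageSpec` or raises a
diagnostic naming the JSON path of the offending key. Unknown *keys* are
ignored with a logged note (a page written for a future version still
builds), but unknown component *kinds* are hard errors — the alternative,
silently rendering nothing, is how supplementary pages lose sections
without anyone noticing. One file is one page; multi-page sites with
navigation are out of scope.

Because spec files may be fetched from third-party URLs, all
author-supplied text is sanitized: markdown is rendered as CommonMark
(via the `commonmark` reference implementation) after entity-escaping
`&` and `<`, so raw HTML — `<script>` included — appears as literal text.
The one CommonMark feature this disables is the `<url>` autolink form;
explicit `[text](url)` links are unaffected.

## Secondary structure from CA distances

For presentation purposes the package needs secondary structure without
hydrogen-bond analysis (the files may be CA-only models), so it uses the
distance-template rule over a 5-residue window. For interior residue $i$
with neighbours $i\pm1, i\pm2$ present, the six pairwise CA distances

$$d_{13}, d_{14}, d_{15}, d_{24}, d_{25}, d_{35}$$

(indices 1..5 across the window) are compared against ideal helix targets
$(5.45, 5.18, 6.37, 5.45, 5.18, 5.45)\,\text{Å}$ with tolerance
$\delta_H = 2.1$ Å and ideal strand targets
$(6.1, 10.4, 13.0, 6.1, 10.4, 6.1)\,\text{Å}$ with tolerance
$\delta_E = 1.42$ Å. All six inside the helix band → `H`; else all six
inside the strand band → `E`; else `T` (turn) when $d_{15} < 8$ Å; else
`C`. The first and last two residues of a trace have no complete window
and are `C` by construction. The constants are data, not code: they live
in a `DistanceTemplates` object with a key=value config loader
(`loadDistanceTemplates()`, example file `inst/extdata/ss-templates.cfg`),
so alternative calibrations are a file edit, not a patch. Note
$\delta_H > \delta_E$: the helix band is the looser one, which is why the
helix test runs first.

Two consequences of the rule are worth spelling out. It depends only on
internal distances, so it is exactly invariant under rigid-body motion
(tested on random traces). And it is deliberately conservative at chain
breaks: a residue without a CA atom yields `C` itself *and* poisons every
window that spans it (`chainSecondaryStructure()`), so structure is never
asserted across unknown geometry.

For display, `T` renders with the coil color — only helices and strands
are highlighted (`H` red, `E` yellow on dark text by default; the palette
is a page-level `colors` key, see `colorScheme()`).

## Pairwise alignment

`globalAlign()` is a from-scratch Gotoh three-state dynamic program:
states $M$ (residue column), $X$ (gap in `b`), $Y$ (gap in `a`), with

$$\text{cost of a gap of length } L = \text{open} + \text{extend} \cdot L.$$

That convention (opening charge *in addition to* every column's extension
charge) is stated once and used everywhere — recurrence, rescoring
function, test oracle — because affine-gap implementations disagree on it
silently otherwise. Direct $X\!\to\!Y$ and $Y\!\to\!X$ transitions are
allowed and start a new gap run (paying `open` again), matching the
maximal-run definition of the rescorer. Defaults are the BLAST protein
values, open 11 / extend 1, exposed via `gapPenalties()`.

Traceback tie-breaking is fixed — prefer $M$, then $X$, then $Y$ — so the
emitted alignment (not just its score) is deterministic and pages rebuild
byte-identically. Alignment is true global (Needleman–Wunsch ends) by
default; `endGapFree = TRUE` gives the semi-global variant for
domain-versus-full-length pairs, with leading/trailing runs free.

The substitution matrix is pluggable. The bundle ships the canonical NCBI
BLOSUM62 file and any matrix in NCBI text layout can be loaded from a
file — including ProtSub, which this package does not redistribute (its
values are published with the PROST homology-search tool, not here);
`loadMatrix()` validates symmetry and totality and names the offending
cell otherwise. Of note for cross-checking: the two BLOSUM62 variants in
circulation agree on all 20 standard residues and differ only in the
B/Z/X ambiguity rows; the bundled file is the NCBI FTP (matblas) variant.

**Verification strategy.** The DP is checked against an *independent*
exhaustive enumeration of every global alignment (feasible for lengths
≤ 6): 200 seeded random pairs over a 4-letter alphabet with random
symmetric matrices and random penalties must agree exactly, and the
emitted alignment must achieve its reported score under the oracle's own
scorer. Structural invariants (de-gapping recovers inputs, no double-gap
columns, score symmetry) are tested separately at realistic lengths under
BLOSUM62.

## PDB input

`parsePDB()` reads fixed-column ATOM/HETATM records (wwPDB v3.3 columns)
and nothing else. Policies, chosen for determinism: only `MODEL 1` of
multi-model files (the display use case needs one conformer); the
first-encountered altloc of a residue's CA wins; HETATM records are
accepted only for residues in the nonstandard mapping (MSE → M and
similar), so waters and ligands never enter a chain; unmapped residues
become `X`. Author numbering (`resSeq`) is preserved for display —
alignment line starts are annotated with it — while algorithms use dense
0-based indices. mmCIF is not parsed.

## Rendering and determinism

`renderPage()` emits one self-contained HTML5 document: data inline,
component containers anchored `component-1 … component-n` **derived from
the component index** (no timestamps, no random ids), so the same spec
renders byte-identically — a property the test suite asserts on whole
builds. Tables embed their data twice: as static rows (readable without
JavaScript) and as JSON driving a small embedded widget for pagination,
search, sort and filter. Those client-side semantics have a server-side
twin in R (`tableSearch()`, `tableSort()`, `tableFilter()`) — the twins
are the tested specification of what the embedded script does:
case-insensitive substring search over stringified cells, and numeric
ordering for columns whose non-empty cells all parse as numbers (so "10"
sorts after "2").

Third-party engines are not reimplemented: 3D structures, networks and
plots are handed to NGL, cytoscape.js and plotly.js loaded from pinned,
versioned CDN URLs recorded in `inst/extdata/assets.json`. Local PDB
sources referenced by a spec are copied into the output directory and
referenced relatively, so no absolute local path ever appears in a page;
the `offline` build flag governs this data-copying behaviour, but viewer
JavaScript itself stays on the CDN — vendoring it would require a network
fetch at build time, so a fully network-free *viewing* experience is a
documented limitation, not a switch. Whether two displayed structures are
superimposed is the author's responsibility: coordinates are shown as
given.

Failure policy: a component that cannot be resolved (unreachable or
unparsable PDB, unknown chain) renders as a visible error panel and the
page still builds; `buildSite()` reports such panels as warnings and
keeps exit status 0, while an invalid *spec* is a hard, nonzero-exit
failure before anything is written.

## Synthetic test data

All test inputs are generated in code (`makeTrace()`, `writeToyPDB()`,
`makeDemoSpec()`); nothing is downloaded. The geometries emulate three
regimes:

- `ideal_helix`: the parametric CA helix, radius 2.3 Å, rise 1.5 Å per
  residue, twist 100°/residue — the textbook α-helix trace, which lands
  inside the helix template by construction (the tests verify the six
  distances before asserting the assignment).
- `strand_zigzag`: points $(ia, (-1)^i b, 0)$ with $(a, b)$ solved by
  least squares against the strand targets (the closed forms are
  $d_{13}=2a$, $d_{14}=\sqrt{9a^2+4b^2}$, $d_{15}=4a$). The solver errors
  loudly if the optimum misses the tolerance — never a silent fallback.
  The *fully extended* 3.8 Å collinear chain is kept as a negative
  control: its $d_{13}=7.6$ Å falls outside the strand band, so a correct
  implementation must not call it `E`.
- `random_coil`: seeded 3.8 Å steps in random directions, with rejection
  of any step completing a window that matches either template.

The demo page's chains are toy-scale (24 and 24 residues) and its
confidence track is a seeded smooth random walk clipped to $[0,1]$
standing in for a per-residue predictor's output. What passing tests
show, therefore, is that the geometry rule, the alignment and the
renderer meet their contracts on controlled geometry; they do not
validate the template constants against experimental structures, model
real predictor confidence distributions, or exercise full-backbone PDB
files with ligands and anisotropic records (only CA-relevant records are
parsed). Problem sizes throughout (200 oracle pairs at length ≤ 6,
50-point invariance sweeps, ~25-residue round trips) were chosen so the
whole suite settles in seconds while every property still has room to
fail.

## Known limitations

- Secondary structure is the CA-distance rule, not DSSP; on real,
  irregular structures the two disagree at element boundaries.
- Local (Smith–Waterman) alignment and MSA *computation* are out of
  scope; MSAs are display-only inputs.
- The ProtSub matrix must be supplied by the user as a file; only
  BLOSUM62 ships in the bundle.
- One JSON file produces one page; no navigation, no live-reload server,
  no hosted service.
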