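#' @import methods
NULL

#' ComponentSpec: one renderable unit of a page
#'
#' A validated component of a page specification: a `kind` drawn from the
#' supported component vocabulary and a kind-specific `payload` holding the
#' component's data exactly as supplied in the JSON document (after
#' validation and type normalisation).
#'
#' @slot kind single character string, one of
#'   `"markdown"`, `"table"`, `"sequence"`, `"msa"`, `"pair_alignment"`,
#'   `"structure"`, `"network"`, `"plot"`.
#' @slot payload named list with kind-specific fields; see [parsePageSpec()]
#'   for the schema of each kind.
#' @seealso [parsePageSpec()], [specSchema()]
#' @exportClass ComponentSpec
setClass("ComponentSpec",
  representation(kind = "character", payload = "list"))

setValidity("ComponentSpec", function(object) {
  if (length(object@kind) != 1L || is.na(object@kind))
    return("'kind' must be a single non-NA string")
  if (!object@kind %in% componentKinds())
    return(sprintf("unknown component kind '%s'", object@kind))
  TRUE
})

#' PageSpec: a parsed, validated page specification
#'
#' The in-memory form of a JSON page-specification document: a page title
#' and an ordered list of [ComponentSpec-class] objects, in source-file
#' order.
#'
#' @slot title single non-empty character string.
#' @slot components list of [ComponentSpec-class] objects, in the order they
#'   appear in the source document.
#' @slot colors named character vector overriding the default secondary
#'   structure color scheme (may be empty).
#' @slot source character string recording where the document came from
#'   (path, URL or `"inline"`); informational only.
#' @seealso [parsePageSpec()], [renderPage()]
#' @exportClass PageSpec
setClass("PageSpec",
  representation(title = "character", components = "list",
                 colors = "character", source = "character"))

setValidity("PageSpec", function(object) {
  if (length(object@title) != 1L || is.na(object@title) ||
      !nzchar(object@title))
    return("'title' must be a single non-empty string")
  ok <- vapply(object@components, is, logical(1), class2 = "ComponentSpec")
  if (!all(ok))
    return("all components must be ComponentSpec objects")
  TRUE
})

#' ChainModel: one polymer chain read from a PDB file
#'
#' Residue identities and alpha-carbon coordinates of a single chain, in
#' file order. Residues that have no CA atom carry `NA` coordinates.
#'
#' @slot chainID single character chain identifier.
#' @slot resNames character vector of 3-letter residue names.
#' @slot resSeq integer vector of author residue numbers (PDB `resSeq`).
#' @slot iCode character vector of insertion codes (`""` when absent).
#' @slot ca numeric matrix with one row per residue and columns x, y, z in
#'   Angstrom; rows are all-`NA` for residues without a CA atom.
#' @seealso [parsePDB()], [chainSequence()], [caTrace()]
#' @exportClass ChainModel
setClass("ChainModel",
  representation(chainID = "character", resNames = "character",
                 resSeq = "integer", iCode = "character", ca = "matrix"))

setValidity("ChainModel", function(object) {
  n <- length(object@resNames)
  if (length(object@chainID) != 1L)
    return("'chainID' must be a single character")
  if (length(object@resSeq) != n || length(object@iCode) != n)
    return("residue field lengths disagree")
  if (n > 0L && (nrow(object@ca) != n || ncol(object@ca) != 3L))
    return("'ca' must be an n x 3 matrix")
  key <- paste(object@resSeq, object@iCode)
  if (anyDuplicated(key))
    return("(resSeq, iCode) pairs must be unique within a chain")
  TRUE
})

#' CaTrace: the alpha-carbon trace of a chain
#'
#' Ordered CA coordinates of the residues that possess a CA atom, plus the
#' (1-based) indices of residues that were dropped for lacking one.
#'
#' @slot coords numeric matrix, one row per retained residue, columns
#'   x, y, z in Angstrom.
#' @slot dropped integer vector of 1-based residue indices (into the source
#'   chain) that had no CA coordinate.
#' @slot residueIndex integer vector mapping each trace row to its 1-based
#'   position in the source chain.
#' @seealso [caTrace()], [assignSecondaryStructure()]
#' @exportClass CaTrace
setClass("CaTrace",
  representation(coords = "matrix", dropped = "integer",
                 residueIndex = "integer"))

setValidity("CaTrace", function(object) {
  if (nrow(object@coords) > 0L && ncol(object@coords) != 3L)
    return("'coords' must have 3 columns")
  if (length(object@residueIndex) != nrow(object@coords))
    return("'residueIndex' must map every trace row")
  if (anyNA(object@coords))
    return("trace coordinates must be finite")
  TRUE
})

#' DistanceTemplates: CA distance targets for secondary structure assignment
#'
#' The six pairwise CA-distance targets of a 5-residue window for ideal
#' helix and ideal strand geometry, the per-class tolerances, and the turn
#' threshold on the i to i+4 distance. All values in Angstrom. Defaults are
#' the published TM-align assignment constants; see [distanceTemplates()].
#'
#' @slot helix named numeric vector of the six helix targets
#'   (`d13`, `d14`, `d15`, `d24`, `d25`, `d35`).
#' @slot strand named numeric vector of the six strand targets.
#' @slot deltaHelix numeric tolerance around the helix targets.
#' @slot deltaStrand numeric tolerance around the strand targets.
#' @slot turnD15 numeric: positions with `d15` below this are turns.
#' @seealso [distanceTemplates()], [assignSecondaryStructure()]
#' @exportClass DistanceTemplates
setClass("DistanceTemplates",
  representation(helix = "numeric", strand = "numeric",
                 deltaHelix = "numeric", deltaStrand = "numeric",
                 turnD15 = "numeric"))

.distNames <- c("d13", "d14", "d15", "d24", "d25", "d35")

setValidity("DistanceTemplates", function(object) {
  for (s in c("helix", "strand")) {
    v <- slot(object, s)
    if (!identical(names(v), .distNames))
      return(sprintf("'%s' must be named %s", s,
                     paste(.distNames, collapse = ", ")))
    if (any(!is.finite(v)) || any(v <= 0))
      return(sprintf("'%s' targets must be strictly positive", s))
  }
  for (s in c("deltaHelix", "deltaStrand", "turnD15")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("'%s' must be a single positive number", s))
  }
  TRUE
})

#' SubstitutionMatrix: residue-pair scoring table
#'
#' A symmetric, total scoring table over a residue alphabet, as used for
#' global pairwise alignment.
#'
#' @slot name character name of the matrix (e.g. `"blosum62"`).
#' @slot alphabet character vector of single-character residue codes, in
#'   table order.
#' @slot scores integer matrix, `length(alphabet)` square, with `dimnames`
#'   equal to the alphabet; symmetric.
#' @seealso [loadMatrix()], [globalAlign()]
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
  representation(name = "character", alphabet = "character",
                 scores = "matrix"))

setValidity("SubstitutionMatrix", function(object) {
  a <- object@alphabet
  s <- object@scores
  if (length(a) < 1L || any(nchar(a) != 1L))
    return("'alphabet' must be single characters")
  if (anyDuplicated(a))
    return("'alphabet' must not contain duplicates")
  if (!identical(dim(s), c(length(a), length(a))))
    return("'scores' must be square over the alphabet")
  if (!identical(rownames(s), a) || !identical(colnames(s), a))
    return("'scores' dimnames must equal the alphabet")
  if (anyNA(s))
    return("'scores' must be a total table (no missing cells)")
  bad <- which(s != t(s), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    return(sprintf("scores are asymmetric at (%s, %s)",
                   a[bad[1L, 1L]], a[bad[1L, 2L]]))
  TRUE
})

#' GapPenalties: affine gap costs
#'
#' Affine gap penalties under the convention that a gap of length L costs
#' `open + extend * L` (the opening charge is in addition to the per-column
#' extension charge).
#'
#' @slot open non-negative gap opening cost.
#' @slot extend non-negative per-column gap extension cost.
#' @seealso [gapPenalties()], [globalAlign()]
#' @exportClass GapPenalties
setClass("GapPenalties",
  representation(open = "numeric", extend = "numeric"))

setValidity("GapPenalties", function(object) {
  if (length(object@open) != 1L || length(object@extend) != 1L ||
      object@open < 0 || object@extend < 0)
    return("'open' and 'extend' must be single non-negative numbers")
  if (object@open == 0 && object@extend == 0)
    return("'open' and 'extend' must not both be zero")
  TRUE
})

#' AlignmentResult: a scored global pairwise alignment
#'
#' Equal-length gapped sequences, the optimal score, and a per-column map
#' back to the 0-based residue indices of each input.
#'
#' @slot alignedA,alignedB gapped sequences (characters plus `"-"`),
#'   equal length.
#' @slot score numeric alignment score.
#' @slot columnMap integer matrix with one row per alignment column and
#'   columns `a`, `b` giving the 0-based residue index on each side or `NA`
#'   at a gap.
#' @seealso [globalAlign()], [percentIdentity()], [alignedSSTracks()]
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", columnMap = "matrix"))

setValidity("AlignmentResult", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("gapped sequences must have equal length")
  ca <- strsplit(object@alignedA, "")[[1]]
  cb <- strsplit(object@alignedB, "")[[1]]
  if (any(ca == "-" & cb == "-"))
    return("no column may be a gap on both sides")
  if (nrow(object@columnMap) != length(ca))
    return("'columnMap' must have one row per column")
  TRUE
})

#' RenderedPage: a self-contained static HTML page
#'
#' @slot html single character string: a complete HTML5 document.
#' @slot assets character vector of pinned third-party asset URLs referenced
#'   by the document's script tags.
#' @seealso [renderPage()], [buildSite()]
#' @exportClass RenderedPage
setClass("RenderedPage",
  representation(html = "character", assets = "character"))

setValidity("RenderedPage", function(object) {
  if (length(object@html) != 1L)
    return("'html' must be a single string")
  TRUE
})

#' BuildConfig: configuration of one site build
#'
#' @slot source path or http(s) URL of the JSON page specification.
#' @slot outputDir output directory; created if absent.
#' @slot matrixName substitution matrix used for PDB-backed pair alignments.
#' @slot offline logical: rewrite third-party asset URLs to local copies.
#' @slot force logical: allow writing into a non-empty output directory.
#' @slot logLevel one of `"quiet"`, `"info"`, `"debug"`.
#' @seealso [buildConfig()], [buildSite()]
#' @exportClass BuildConfig
setClass("BuildConfig",
  representation(source = "character", outputDir = "character",
                 matrixName = "character", offline = "logical",
                 force = "logical", logLevel = "character"))

setValidity("BuildConfig", function(object) {
  for (s in c("source", "outputDir", "matrixName", "logLevel"))
    if (length(slot(object, s)) != 1L)
      return(sprintf("'%s' must be a single value", s))
  if (!object@logLevel %in% c("quiet", "info", "debug"))
    return("'logLevel' must be one of quiet, info, debug")
  TRUE
})
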