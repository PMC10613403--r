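#' @include AllClasses.R
NULL

#' Extract the one-letter sequence of a chain
#'
#' @param chain a [ChainModel-class].
#' @return single character string, one letter per residue. Standard
#'   residues use the 20-residue code table, selected nonstandard residues
#'   (e.g. MSE) map to their parent residue, everything else becomes `"X"`.
#' @examples
#' ch <- parsePDB(writeToyPDB(list(list(
#'   chainID = "A", sequence = "AG",
#'   trace = makeTrace(geometryRecipe("ideal_helix", 2))))))[[1]]
#' chainSequence(ch)
#' @export
setGeneric("chainSequence", function(chain) standardGeneric("chainSequence"))

#' Extract the CA trace of a chain
#'
#' @param chain a [ChainModel-class].
#' @return a [CaTrace-class] holding the coordinates of residues that have
#'   a CA atom, in residue order; indices of residues without one are
#'   recorded in the `dropped` slot.
#' @export
setGeneric("caTrace", function(chain) standardGeneric("caTrace"))

#' Percent identity of an alignment
#'
#' The fraction of identical-residue columns among columns that carry a
#' residue on both sides; 0 when the alignment has no such column.
#'
#' @param r an [AlignmentResult-class].
#' @return numeric fraction in `[0, 1]`.
#' @export
setGeneric("percentIdentity", function(r) standardGeneric("percentIdentity"))

#' Gapped sequences of an alignment
#'
#' @param r an [AlignmentResult-class].
#' @return named character vector with elements `a` and `b`.
#' @export
setGeneric("alignedSeqs", function(r) standardGeneric("alignedSeqs"))

#' Alignment score
#'
#' @param r an [AlignmentResult-class].
#' @return numeric optimal score.
#' @export
setGeneric("alignmentScore", function(r) standardGeneric("alignmentScore"))

#' Render a page specification to a self-contained HTML document
#'
#' @param spec a validated [PageSpec-class].
#' @param ... options passed on to the renderer; see the method
#'   documentation.
#' @return a [RenderedPage-class].
#' @export
setGeneric("renderPage", function(spec, ...) standardGeneric("renderPage"))
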