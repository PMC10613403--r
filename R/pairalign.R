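#' @include AllClasses.R AllGenerics.R utils.R
#' @useDynLib protpage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.bundledMatrices <- c(blosum62 = "blosum62.mat")

#' Load a substitution matrix
#'
#' Loads a residue-pair scoring table either by bundled name or from a file
#' in NCBI matrix text layout (comment lines starting with `#`, a header
#' row of residue characters, then one scored row per residue). The bundled
#' set currently holds `"blosum62"` (the canonical NCBI BLOSUM62 table,
#' half-bit units), the package default for pairwise alignment; any other
#' matrix — including ProtSub, which is distributed with the PROST homology
#' search tool rather than here — can be supplied as a file in the same
#' layout.
#'
#' @param source a bundled matrix name or a path to an NCBI-layout matrix
#'   file.
#' @return a validated [SubstitutionMatrix-class].
#' @section Errors: an unknown bundled name raises an error listing the
#'   bundled names; an asymmetric or incomplete file raises a validation
#'   error naming the offending cell.
#' @examples
#' m <- loadMatrix("blosum62")
#' matrixScore(m, "W", "W")
#' @export
loadMatrix <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  name <- tolower(source)
  if (name %in% names(.bundledMatrices)) {
    path <- system.file("extdata", .bundledMatrices[[name]],
                        package = "protpage", mustWork = TRUE)
    return(readMatrixFile(path, name = name))
  }
  if (!file.exists(source))
    stop(sprintf(
      "unknown matrix '%s': not a bundled name (%s) and not a readable file",
      source, paste(names(.bundledMatrices), collapse = ", ")))
  readMatrixFile(source, name = basename(source))
}

#' Read an NCBI-layout substitution matrix file
#'
#' @param path path to the matrix file.
#' @param name name to record on the result.
#' @return a validated [SubstitutionMatrix-class].
#' @export
readMatrixFile <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("matrix file '%s': no header and score rows found", path))
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (any(nchar(header) != 1L))
    stop(sprintf("matrix file '%s': header must list single residue characters",
                 path))
  k <- length(header)
  scores <- matrix(NA_integer_, k, k, dimnames = list(header, header))
  for (ln in lines[-1L]) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    res <- fields[1L]
    if (!res %in% header)
      stop(sprintf("row residue '%s' does not appear in the header", res))
    if (length(fields) != k + 1L)
      stop(sprintf("row '%s' has %d scores for %d alphabet characters",
                   res, length(fields) - 1L, k))
    vals <- suppressWarnings(as.integer(fields[-1L]))
    if (anyNA(vals))
      stop(sprintf("row '%s': non-integer score in cell (%s, %s)", res, res,
                   header[which(is.na(vals))[1L]]))
    scores[res, ] <- vals
  }
  missing <- which(is.na(scores), arr.ind = TRUE)
  if (nrow(missing) > 0L)
    stop(sprintf("incomplete matrix: no score for cell (%s, %s)",
                 header[missing[1L, 1L]], header[missing[1L, 2L]]))
  bad <- which(scores != t(scores), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("asymmetric matrix: cell (%s, %s) is %d but (%s, %s) is %d",
                 header[bad[1L, 1L]], header[bad[1L, 2L]],
                 scores[bad[1L, 1L], bad[1L, 2L]],
                 header[bad[1L, 2L]], header[bad[1L, 1L]],
                 scores[bad[1L, 2L], bad[1L, 1L]]))
  new("SubstitutionMatrix", name = name, alphabet = header, scores = scores)
}

#' Build a substitution matrix from a score table
#'
#' @param scores symmetric integer matrix with identical row and column
#'   names (the alphabet).
#' @param name name to record on the result.
#' @return a [SubstitutionMatrix-class].
#' @export
substitutionMatrix <- function(scores, name = "custom") {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  new("SubstitutionMatrix", name = name, alphabet = rownames(scores),
      scores = scores)
}

#' Score of one residue pair
#'
#' @param m a [SubstitutionMatrix-class].
#' @param a,b single residue characters.
#' @return integer score.
#' @export
matrixScore <- function(m, a, b) m@scores[a, b]

#' Affine gap penalties
#'
#' A gap of length L costs `open + extend * L`: the opening charge is paid
#' once per maximal gap run on top of the per-column extension charge. The
#' defaults are the BLAST protein defaults (open 11, extend 1).
#'
#' @param open non-negative opening cost.
#' @param extend non-negative per-column extension cost.
#' @return a [GapPenalties-class].
#' @export
gapPenalties <- function(open = 11, extend = 1) {
  new("GapPenalties", open = open, extend = extend)
}

#' Global pairwise alignment with affine gaps
#'
#' Maximum-score global alignment of two residue sequences under a
#' substitution matrix and affine gap penalties, by the Gotoh three-state
#' recurrence. The emitted alignment is deterministic: score ties in the
#' traceback prefer a match/mismatch column, then a gap in `b`, then a gap
#' in `a`. With `endGapFree = TRUE` the alignment is semi-global (leading
#' and trailing gap runs are free), for aligning a domain against a
#' full-length sequence.
#'
#' @param a,b non-empty sequences whose characters all occur in the
#'   matrix's alphabet.
#' @param m a [SubstitutionMatrix-class]; default the bundled BLOSUM62.
#' @param g a [GapPenalties-class]; default open 11, extend 1.
#' @param endGapFree logical: free end gaps (semi-global mode).
#' @return an [AlignmentResult-class].
#' @section Errors: a character outside the matrix alphabet raises an error
#'   naming the position and the character.
#' @examples
#' r <- globalAlign("HEAGAWGHEE", "PAWHEAE")
#' alignedSeqs(r)
#' alignmentScore(r)
#' @export
globalAlign <- function(a, b, m = loadMatrix("blosum62"),
                        g = gapPenalties(), endGapFree = FALSE) {
  stopifnot(is(m, "SubstitutionMatrix"), is(g, "GapPenalties"))
  if (!nzchar(a) || !nzchar(b))
    stop("both sequences must be non-empty")
  ai <- encodeSeq(a, m, "a")
  bi <- encodeSeq(b, m, "b")
  res <- .gotohAlign(ai, bi, m@scores, g@open, g@extend, endGapFree)
  columnMap <- cbind(a = ifelse(res$a < 0L, NA_integer_, res$a),
                     b = ifelse(res$b < 0L, NA_integer_, res$b))
  ca <- chars(a); cb <- chars(b)
  gappedA <- ifelse(is.na(columnMap[, "a"]), "-", ca[columnMap[, "a"] + 1L])
  gappedB <- ifelse(is.na(columnMap[, "b"]), "-", cb[columnMap[, "b"] + 1L])
  new("AlignmentResult",
      alignedA = paste(gappedA, collapse = ""),
      alignedB = paste(gappedB, collapse = ""),
      score = res$score, columnMap = columnMap)
}

encodeSeq <- function(x, m, label) {
  cc <- chars(x)
  idx <- match(cc, m@alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf(
      "sequence %s: character '%s' at position %d is not in the '%s' alphabet",
      label, cc[bad], bad, m@name))
  }
  idx - 1L
}

#' Rescore a gapped alignment
#'
#' Recomputes the score of an emitted alignment directly from its gapped
#' sequences: substitution scores summed over residue columns, and each
#' maximal gap run charged `open + extend * length`. Used to check the
#' score invariant of [AlignmentResult-class].
#'
#' @param r an [AlignmentResult-class].
#' @param m a [SubstitutionMatrix-class].
#' @param g a [GapPenalties-class].
#' @param endGapFree logical: if `TRUE`, leading and trailing gap runs are
#'   not charged.
#' @return numeric score.
#' @export
rescoreAlignment <- function(r, m, g, endGapFree = FALSE) {
  ca <- chars(r@alignedA)
  cb <- chars(r@alignedB)
  n <- length(ca)
  if (n == 0L) return(0)
  gap <- ca == "-" | cb == "-"
  score <- 0
  for (i in which(!gap)) score <- score + m@scores[ca[i], cb[i]]
  # charge maximal gap runs per side
  for (side in list(ca == "-", cb == "-")) {
    r0 <- rle(side)
    ends <- cumsum(r0$lengths)
    starts <- ends - r0$lengths + 1L
    for (k in which(r0$values)) {
      if (endGapFree && (starts[k] == 1L || ends[k] == n)) next
      score <- score - g@open - g@extend * r0$lengths[k]
    }
  }
  score
}

#' @describeIn percentIdentity fraction of identical residue columns among
#'   columns carrying a residue on both sides.
#' @export
setMethod("percentIdentity", "AlignmentResult", function(r) {
  ca <- chars(r@alignedA)
  cb <- chars(r@alignedB)
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  sum(ca[both] == cb[both]) / sum(both)
})

#' @rdname alignedSeqs
#' @export
setMethod("alignedSeqs", "AlignmentResult", function(r) {
  c(a = r@alignedA, b = r@alignedB)
})

#' @rdname alignmentScore
#' @export
setMethod("alignmentScore", "AlignmentResult", function(r) r@score)

setMethod("show", "AlignmentResult", function(object) {
  ncol <- nchar(object@alignedA)
  cat(sprintf("AlignmentResult: %d columns, score %g, identity %.1f%%\n",
              ncol, object@score, 100 * percentIdentity(object)))
  if (ncol > 0L && ncol <= 70L) {
    cat(" ", object@alignedA, "\n ", object@alignedB, "\n", sep = "")
  }
})

setMethod("show", "SubstitutionMatrix", function(object) {
  cat(sprintf("SubstitutionMatrix '%s': %d-character alphabet (%s...)\n",
              object@name, length(object@alphabet),
              paste(utils::head(object@alphabet, 6), collapse = "")))
})
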