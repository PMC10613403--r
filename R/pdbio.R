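#' @include AllClasses.R AllGenerics.R utils.R
NULL

# 3-letter -> 1-letter residue code table: the 20 standard amino acids plus
# common nonstandard residues mapped to their parent (MSE selenomethionine,
# SEC/PYL the 21st/22nd amino acids, and frequent modified residues)
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", KCX = "K", MLY = "K")

# HETATM records are accepted only for residues in the nonstandard mapping
.hetatmAllowed <- setdiff(names(.aa3to1),
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"))

#' Parse a PDB-format coordinate file
#'
#' Reads fixed-column ATOM/HETATM records (wwPDB format v3.3) and returns
#' one [ChainModel-class] per chain, in order of first appearance. Only CA
#' atoms populate coordinates; for multi-model files only `MODEL 1` is
#' read; when a residue's CA carries alternate locations, the first
#' encountered altloc is kept. HETATM records are accepted only for
#' residues in the nonstandard-residue mapping (e.g. MSE). All records
#' other than ATOM/HETATM/MODEL/ENDMDL/TER are ignored.
#'
#' @param text either the PDB file content as a single string (or character
#'   vector of lines), or a path to a PDB file.
#' @return named list of [ChainModel-class] objects, one per chain id.
#' @section Errors: a file without any parsable ATOM/HETATM record raises
#'   an empty-structure error; a malformed fixed-column numeric field
#'   raises an error naming the line number.
#' @examples
#' tr <- makeTrace(geometryRecipe("ideal_helix", 12))
#' pdb <- writeToyPDB(list(list(chainID = "A",
#'   sequence = "AGKLMNPQRSTV", trace = tr)))
#' chains <- parsePDB(pdb)
#' chainSequence(chains[["A"]])
#' @export
parsePDB <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  rec <- substr(lines, 1, 6)
  inModel <- 0L   # 0 = no MODEL seen yet (whole file), k = inside MODEL k
  rows <- list()
  for (ln in seq_along(lines)) {
    r <- rec[ln]
    if (r == "MODEL ") {
      inModel <- suppressWarnings(
        as.integer(trimws(substr(lines[ln], 11, 14))))
      if (is.na(inModel)) inModel <- length(rows) + 1L  # tolerate bare MODEL
      next
    }
    if (r == "ENDMDL") { inModel <- -1L; next }   # between models
    if (inModel > 1L || inModel == -1L && any(rec == "MODEL ")) next
    if (r != "ATOM  " && r != "HETATM") next
    line <- lines[ln]
    if (nchar(line) < 54)
      stop(sprintf("line %d: ATOM/HETATM record shorter than 54 columns", ln))
    atomName <- trimws(substr(line, 13, 16))
    resName <- trimws(substr(line, 18, 20))
    if (r == "HETATM" && !resName %in% .hetatmAllowed) next
    altLoc <- substr(line, 17, 17)
    chainID <- substr(line, 22, 22)
    resSeq <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
    if (is.na(resSeq))
      stop(sprintf("line %d: malformed residue number '%s'", ln,
                   trimws(substr(line, 23, 26))))
    iCode <- sub(" ", "", substr(line, 27, 27), fixed = TRUE)
    xyz <- suppressWarnings(as.numeric(c(
      substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("line %d: malformed coordinate field", ln))
    rows[[length(rows) + 1L]] <- list(
      chainID = chainID, resName = resName, resSeq = resSeq, iCode = iCode,
      atomName = atomName, altLoc = altLoc, xyz = xyz)
  }
  if (length(rows) == 0L)
    stop("empty structure: no parsable ATOM/HETATM records found")

  chainIDs <- vapply(rows, `[[`, character(1), "chainID")
  out <- list()
  for (cid in unique(chainIDs)) {
    sel <- rows[chainIDs == cid]
    key <- vapply(sel, function(a) paste(a$resSeq, a$iCode), character(1))
    resKeys <- unique(key)
    n <- length(resKeys)
    resNames <- character(n); resSeq <- integer(n); iCode <- character(n)
    ca <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
    caAlt <- rep(NA_character_, n)
    for (a in sel) {
      i <- match(paste(a$resSeq, a$iCode), resKeys)
      resNames[i] <- a$resName; resSeq[i] <- a$resSeq; iCode[i] <- a$iCode
      if (a$atomName == "CA") {
        # keep the first-encountered altloc, skip others
        if (is.na(caAlt[i])) {
          ca[i, ] <- a$xyz
          caAlt[i] <- a$altLoc
        }
      }
    }
    out[[cid]] <- new("ChainModel", chainID = cid, resNames = resNames,
                      resSeq = resSeq, iCode = iCode, ca = ca)
  }
  out
}

#' @describeIn chainSequence one letter per residue; residues outside the
#'   code table become `"X"`.
#' @export
setMethod("chainSequence", "ChainModel", function(chain) {
  if (length(chain@resNames) == 0L)
    stop("chain is empty")
  one <- .aa3to1[chain@resNames]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
})

#' @describeIn caTrace residues without a CA atom are dropped and their
#'   1-based indices recorded in the `dropped` slot.
#' @export
setMethod("caTrace", "ChainModel", function(chain) {
  has <- !is.na(chain@ca[, 1L])
  new("CaTrace",
      coords = chain@ca[has, , drop = FALSE],
      dropped = which(!has),
      residueIndex = which(has))
})

#' Number of residues in a chain
#'
#' @param chain a [ChainModel-class].
#' @return integer residue count.
#' @export
chainLength <- function(chain) length(chain@resNames)

#' Author residue numbers of a chain
#'
#' @param chain a [ChainModel-class].
#' @return integer vector of PDB `resSeq` values, in residue order.
#' @export
residueNumbers <- function(chain) chain@resSeq

#' Coordinates of a CA trace
#'
#' @param trace a [CaTrace-class].
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
traceCoords <- function(trace) trace@coords

setMethod("show", "ChainModel", function(object) {
  nca <- sum(!is.na(object@ca[, 1L]))
  cat(sprintf("ChainModel chain %s: %d residues (%d with CA)\n",
              object@chainID, length(object@resNames), nca))
})

setMethod("show", "CaTrace", function(object) {
  cat(sprintf("CaTrace: %d points%s\n", nrow(object@coords),
              if (length(object@dropped) > 0L)
                sprintf(" (%d residues without CA dropped)",
                        length(object@dropped))
              else ""))
})

setMethod("length", "CaTrace", function(x) nrow(x@coords))
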