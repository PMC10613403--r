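#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' CA distance templates for secondary structure assignment
#'
#' Constructs a [DistanceTemplates-class]. The defaults are the published
#' TM-align assignment constants: within a 5-residue window centred on
#' position i, the six pairwise CA distances are compared to ideal helix
#' targets (d13 = d24 = d35 = 5.45, d14 = d25 = 5.18, d15 = 6.37 Angstrom,
#' tolerance 2.1) and ideal strand targets (d13 = d24 = d35 = 6.1,
#' d14 = d25 = 10.4, d15 = 13.0 Angstrom, tolerance 1.42); positions
#' matching neither template are turns when d15 < 8 Angstrom, else coil.
#' The constants are data, not code: pass alternatives here or load them
#' from a key=value config file with [loadDistanceTemplates()].
#'
#' @param helix,strand named numeric vectors of the six window distances
#'   (`d13`, `d14`, `d15`, `d24`, `d25`, `d35`), Angstrom.
#' @param deltaHelix,deltaStrand tolerances around the targets, Angstrom.
#' @param turnD15 turn threshold on d15, Angstrom.
#' @return a [DistanceTemplates-class].
#' @examples
#' distanceTemplates()
#' @export
distanceTemplates <- function(
    helix = c(d13 = 5.45, d14 = 5.18, d15 = 6.37,
              d24 = 5.45, d25 = 5.18, d35 = 5.45),
    strand = c(d13 = 6.1, d14 = 10.4, d15 = 13.0,
               d24 = 6.1, d25 = 10.4, d35 = 6.1),
    deltaHelix = 2.1, deltaStrand = 1.42, turnD15 = 8.0) {
  new("DistanceTemplates",
      helix = helix[.distNames], strand = strand[.distNames],
      deltaHelix = deltaHelix, deltaStrand = deltaStrand, turnD15 = turnD15)
}

#' Load distance templates from a key=value config file
#'
#' The file holds one `key = value` pair per line (Angstrom units), with
#' keys `helix.d13` ... `helix.d35`, `strand.d13` ... `strand.d35`,
#' `delta.helix`, `delta.strand` and `turn.d15`. Missing keys keep their
#' defaults; `#` starts a comment.
#'
#' @param path path to the config file.
#' @return a [DistanceTemplates-class].
#' @export
loadDistanceTemplates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  keys <- trimws(kv[, 1L])
  vals <- as.numeric(trimws(kv[, 2L]))
  if (anyNA(vals))
    stop(sprintf("non-numeric value for key '%s'", keys[which(is.na(vals))[1]]))
  tpl <- distanceTemplates()
  h <- tpl@helix; s <- tpl@strand
  dh <- tpl@deltaHelix; ds <- tpl@deltaStrand; t15 <- tpl@turnD15
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (grepl("^helix\\.d[0-9]+$", k)) h[sub("helix.", "", k, fixed = TRUE)] <- v
    else if (grepl("^strand\\.d[0-9]+$", k)) s[sub("strand.", "", k, fixed = TRUE)] <- v
    else if (k == "delta.helix") dh <- v
    else if (k == "delta.strand") ds <- v
    else if (k == "turn.d15") t15 <- v
    else stop(sprintf("unknown template key '%s'", k))
  }
  distanceTemplates(helix = h, strand = s, deltaHelix = dh,
                    deltaStrand = ds, turnD15 = t15)
}

# the six window distances at centre i of coordinate matrix p (rows i-2..i+2
# must exist and be finite); returns named numeric vector
windowDistances <- function(p, i) {
  d <- function(a, b) sqrt(sum((p[a, ] - p[b, ])^2))
  c(d13 = d(i - 2L, i),      d14 = d(i - 2L, i + 1L), d15 = d(i - 2L, i + 2L),
    d24 = d(i - 1L, i + 1L), d25 = d(i - 1L, i + 2L), d35 = d(i, i + 2L))
}

#' Assign secondary structure from a CA trace
#'
#' Per-residue secondary structure states from alpha-carbon geometry alone,
#' by the distance-template rule: for each interior position i (both
#' neighbours on each side present), the six pairwise CA distances of the
#' 5-residue window are compared against the ideal helix and strand
#' templates. A position is `H` when all six are within the helix tolerance
#' of the helix targets, else `E` when all six are within the strand
#' tolerance of the strand targets, else `T` (turn) when d15 is below the
#' turn threshold, else `C` (coil). The first two and last two positions of
#' a trace have no complete window and are always `C`.
#'
#' @param trace a [CaTrace-class], or a numeric n x 3 coordinate matrix.
#' @param templates a [DistanceTemplates-class]; see [distanceTemplates()].
#' @return single character string over `{H, E, T, C}`, one state per trace
#'   point (the empty string for an empty trace).
#' @examples
#' helix <- makeTrace(geometryRecipe("ideal_helix", 12))
#' assignSecondaryStructure(helix)
#' @export
assignSecondaryStructure <- function(trace, templates = distanceTemplates()) {
  p <- if (is(trace, "CaTrace")) trace@coords else as.matrix(trace)
  n <- nrow(p)
  if (n == 0L) return("")
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  ss <- rep("C", n)
  if (n >= 5L) {
    for (i in 3L:(n - 2L)) {
      d <- windowDistances(p, i)
      if (all(abs(d - templates@helix) < templates@deltaHelix)) {
        ss[i] <- "H"
      } else if (all(abs(d - templates@strand) < templates@deltaStrand)) {
        ss[i] <- "E"
      } else if (d[["d15"]] < templates@turnD15) {
        ss[i] <- "T"
      }
    }
  }
  paste(ss, collapse = "")
}

#' Per-residue secondary structure of a chain
#'
#' Assigns secondary structure on the chain's CA trace and maps the states
#' back onto the full residue list. Residues without a CA atom are `C`, and
#' they break assignment windows: positions whose 5-residue window spans a
#' missing CA are `C` as well, so structure is never assigned across
#' unknown geometry.
#'
#' @param chain a [ChainModel-class].
#' @param templates a [DistanceTemplates-class].
#' @return single character string, one state per residue of the chain.
#' @export
chainSecondaryStructure <- function(chain, templates = distanceTemplates()) {
  n <- chainLength(chain)
  if (n == 0L) return("")
  ss <- rep("C", n)
  has <- !is.na(chain@ca[, 1L])
  if (n >= 5L) {
    for (i in 3L:(n - 2L)) {
      win <- (i - 2L):(i + 2L)
      if (!all(has[win])) next   # a missing CA breaks the window
      d <- windowDistances(chain@ca, i)
      if (all(abs(d - templates@helix) < templates@deltaHelix)) ss[i] <- "H"
      else if (all(abs(d - templates@strand) < templates@deltaStrand)) ss[i] <- "E"
      else if (d[["d15"]] < templates@turnD15) ss[i] <- "T"
    }
  }
  paste(ss, collapse = "")
}

#' Project secondary structure strings through an alignment
#'
#' Expands two per-residue secondary structure strings to the column space
#' of a pairwise alignment: each output string has one character per
#' alignment column, with `-` at columns where that side has a gap.
#'
#' @param aln an [AlignmentResult-class].
#' @param ssA,ssB secondary structure strings whose lengths equal the
#'   ungapped lengths of the aligned sequences.
#' @return named list with gapped state strings `a` and `b`.
#' @section Errors: a length mismatch raises an error naming which side
#'   disagrees.
#' @export
alignedSSTracks <- function(aln, ssA, ssB) {
  stopifnot(is(aln, "AlignmentResult"))
  ungappedA <- gsub("-", "", aln@alignedA, fixed = TRUE)
  ungappedB <- gsub("-", "", aln@alignedB, fixed = TRUE)
  if (nchar(ssA) != nchar(ungappedA))
    stop(sprintf(
      "side a: secondary structure has %d states but the sequence has %d residues",
      nchar(ssA), nchar(ungappedA)))
  if (nchar(ssB) != nchar(ungappedB))
    stop(sprintf(
      "side b: secondary structure has %d states but the sequence has %d residues",
      nchar(ssB), nchar(ungappedB)))
  project <- function(ss, idx) {
    states <- chars(ss)
    out <- rep("-", length(idx))
    out[!is.na(idx)] <- states[idx[!is.na(idx)] + 1L]
    paste(out, collapse = "")
  }
  list(a = project(ssA, aln@columnMap[, "a"]),
       b = project(ssB, aln@columnMap[, "b"]))
}
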