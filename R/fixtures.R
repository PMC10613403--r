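#' @include AllClasses.R secstruct.R pdbio.R
NULL

#' Recipe for a synthetic CA trace
#'
#' Describes a reproducible toy alpha-carbon geometry: an ideal parametric
#' helix, a planar strand zigzag solved to satisfy the strand distance
#' template, or a self-avoiding random coil rejected away from both
#' templates.
#'
#' @param kind one of `"ideal_helix"`, `"strand_zigzag"`, `"random_coil"`.
#' @param nResidues number of residues (>= 1).
#' @param seed integer seed for the random-coil generator.
#' @param radius,rise,twist ideal-helix parameters: radius (Angstrom), rise
#'   per residue (Angstrom) and twist per residue (degrees). The defaults
#'   (2.3, 1.5, 100) are the canonical alpha-helix CA geometry.
#' @return a named list describing the recipe, accepted by [makeTrace()].
#' @export
geometryRecipe <- function(kind = c("ideal_helix", "strand_zigzag",
                                    "random_coil"),
                           nResidues, seed = 1L,
                           radius = 2.3, rise = 1.5, twist = 100) {
  kind <- match.arg(kind)
  stopifnot(nResidues >= 1L)
  list(kind = kind, nResidues = as.integer(nResidues),
       seed = as.integer(seed), radius = radius, rise = rise, twist = twist)
}

# run code under a seeded RNG without disturbing the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CA trace
#'
#' `ideal_helix` places points on the parametric helix
#' `(r cos(i t), r sin(i t), i h)` with the recipe's radius, twist and
#' rise. `strand_zigzag` places points at `(i a, (-1)^i b, 0)` where
#' `(a, b)` are solved by least squares so the six window distances sit on
#' the strand template targets; generation fails loudly if the solved
#' geometry does not satisfy the template within its tolerance.
#' `random_coil` draws successive 3.8 Angstrom steps in seeded random
#' directions, rejecting any step that would make a complete window match
#' either the helix or the strand template.
#'
#' @param recipe a recipe from [geometryRecipe()].
#' @param templates the [DistanceTemplates-class] used for the zigzag check
#'   and the coil rejection rule.
#' @return a [CaTrace-class] with `nResidues` points.
#' @examples
#' tr <- makeTrace(geometryRecipe("ideal_helix", 12))
#' assignSecondaryStructure(tr)
#' @export
makeTrace <- function(recipe, templates = distanceTemplates()) {
  n <- recipe$nResidues
  coords <- switch(recipe$kind,
    ideal_helix = {
      i <- seq_len(n) - 1L
      t <- recipe$twist * pi / 180
      cbind(x = recipe$radius * cos(i * t),
            y = recipe$radius * sin(i * t),
            z = recipe$rise * i)
    },
    strand_zigzag = strandZigzagCoords(n, templates),
    random_coil = randomCoilCoords(n, recipe$seed, templates))
  new("CaTrace", coords = coords, dropped = integer(0),
      residueIndex = seq_len(n))
}

# least-squares placement of a planar zigzag (i*a, (-1)^i * b, 0) whose
# window distances match the strand template:
#   d13 = d24 = d35 = 2a,  d14 = d25 = sqrt(9a^2 + 4b^2),  d15 = 4a
strandZigzagCoords <- function(n, templates) {
  tgt <- templates@strand
  objective <- function(par) {
    a <- par[1L]; b <- par[2L]
    d14 <- sqrt(9 * a^2 + 4 * b^2)
    3 * (2 * a - tgt[["d13"]])^2 + 2 * (d14 - tgt[["d14"]])^2 +
      (4 * a - tgt[["d15"]])^2
  }
  fit <- stats::optim(c(3.2, 1.0), objective, method = "BFGS")
  a <- fit$par[1L]; b <- abs(fit$par[2L])
  i <- seq_len(n) - 1L
  coords <- cbind(x = i * a, y = b * (-1)^i, z = 0)
  if (n >= 5L) {
    d <- windowDistances(coords, 3L)
    if (!all(abs(d - tgt) < templates@deltaStrand))
      stop(sprintf(
        "strand zigzag solver failed: window distances (%s) do not satisfy the strand template",
        paste(sprintf("%s=%.2f", names(d), d), collapse = ", ")))
  }
  coords
}

randomCoilCoords <- function(n, seed, templates, step = 3.8,
                             maxTries = 500L) {
  withSeed(seed, {
    coords <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
    for (i in seq_len(n)[-1L]) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        u <- stats::rnorm(3)
        cand <- coords[i - 1L, ] + step * u / sqrt(sum(u^2))
        coords[i, ] <- cand
        # reject if any now-complete window matches either template
        ok <- TRUE
        for (c0 in seq.int(max(3L, i - 2L), i)) {
          if (c0 + 2L > i || c0 < 3L) next
          d <- windowDistances(coords, c0)
          if (all(abs(d - templates@helix) < templates@deltaHelix) ||
              all(abs(d - templates@strand) < templates@deltaStrand)) {
            ok <- FALSE
            break
          }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed)
        stop("random coil generation failed to escape the templates")
    }
    coords
  })
}

#' Write a toy PDB file
#'
#' Serialises chains of CA-only coordinates as fixed-column ATOM records
#' (3-decimal coordinates), with a TER record after each chain and END at
#' the end. The output parses back through [parsePDB()] with exact sequence
#' recovery and coordinates equal to 3 decimals.
#'
#' @param chains list of chains, each a list with elements `chainID`
#'   (single character), `sequence` (one-letter string) and `trace` (a
#'   [CaTrace-class] or an n x 3 coordinate matrix); sequence length must
#'   equal the number of trace points.
#' @param path optional path; when given the text is also written there.
#' @return the PDB text as a single string (invisibly when `path` is
#'   given).
#' @export
writeToyPDB <- function(chains, path = NULL) {
  lines <- character(0)
  serial <- 0L
  for (ch in chains) {
    coords <- if (is(ch$trace, "CaTrace")) ch$trace@coords else ch$trace
    seqChars <- chars(ch$sequence)
    if (length(seqChars) != nrow(coords))
      stop(sprintf("chain %s: sequence length %d != %d trace points",
                   ch$chainID, length(seqChars), nrow(coords)))
    three <- names(.aa3to1)[match(seqChars, .aa3to1)]
    three[is.na(three)] <- "UNK"
    for (i in seq_along(seqChars)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, three[i], ch$chainID, i,
        coords[i, 1L], coords[i, 2L], coords[i, 3L], 1, 0))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial, three[length(three)], ch$chainID,
                              length(seqChars)))
  }
  lines <- c(lines, "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

# deterministic toy sequence of a given length over the 20 standard residues
toySequence <- function(n, offset = 0L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(aa[(seq_len(n) + offset - 1L) %% 20L + 1L], collapse = "")
}

# seeded smooth random walk clipped to [0, 1]; emulates a per-residue
# predictor confidence track
confidenceTrack <- function(n, seed = 7L) {
  withSeed(seed, {
    steps <- stats::rnorm(n, sd = 0.08)
    pmin(pmax(0.7 + cumsum(steps), 0), 1)
  })
}

#' Generate the demo page specification
#'
#' Builds a complete demonstration input set with zero downloads: two toy
#' PDB files (a helix-rich chain and a mixed helix/coil chain) written into
#' `dir`, and a page specification exercising every component kind exactly
#' once — markdown, table, sequence (with a synthetic per-residue
#' confidence track), MSA, a PDB-backed pair alignment of the two toy
#' chains, a structure view, a network and a plot.
#'
#' @param dir directory the toy PDB files are written into.
#' @return the page specification as a JSON string; the component count is
#'   always 8 (one per kind).
#' @examples
#' json <- makeDemoSpec(tempdir())
#' length(pageComponents(parsePageSpec(json)))
#' @export
makeDemoSpec <- function(dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nHelix <- 24L
  helixSeq <- toySequence(nHelix)
  helixPdb <- file.path(dir, "toy_helix.pdb")
  writeToyPDB(list(list(chainID = "A", sequence = helixSeq,
                        trace = makeTrace(geometryRecipe("ideal_helix",
                                                         nHelix)))),
              path = helixPdb)

  # mixed chain: a helix segment continued by a random coil
  nMixHelix <- 14L; nMixCoil <- 10L
  helixPart <- makeTrace(geometryRecipe("ideal_helix", nMixHelix))@coords
  coilPart <- makeTrace(geometryRecipe("random_coil", nMixCoil,
                                       seed = 11L))@coords
  shift <- helixPart[nMixHelix, ] + c(0, 0, 3.8)
  coilPart <- sweep(coilPart, 2L, shift, `+`)
  mixedSeq <- toySequence(nMixHelix + nMixCoil, offset = 2L)
  mixedPdb <- file.path(dir, "toy_mixed.pdb")
  writeToyPDB(list(list(chainID = "A", sequence = mixedSeq,
                        trace = rbind(helixPart, coilPart))),
              path = mixedPdb)

  track <- round(confidenceTrack(nHelix), 4)
  doc <- list(
    title = "Demo: paired toy proteins",
    components = list(
      list(kind = "markdown",
           text = paste0("# Toy protein pair\n\nThis demo page pairs a ",
                         "**helix-rich** toy chain with a mixed ",
                         "helix/coil chain and shows every supported ",
                         "component kind.")),
      list(kind = "table",
           columns = list("id", "residues", "fold"),
           rows = list(list("toy_helix", nHelix, "all-alpha"),
                       list("toy_mixed", nMixHelix + nMixCoil, "mixed")),
           page_size = 10),
      list(kind = "sequence", id = "toy_helix", sequence = helixSeq,
           track = as.list(track), track_name = "confidence"),
      list(kind = "msa",
           ids = list("toy_helix", "toy_mixed", "consensus"),
           sequences = list(substr(paste0(helixSeq, "----"), 1, 24),
                            substr(paste0(mixedSeq, "----"), 1, 24),
                            substr(paste0(helixSeq, "----"), 1, 24))),
      list(kind = "pair_alignment",
           side_a = list(id = "toy_helix", pdb = helixPdb, chain = "A"),
           side_b = list(id = "toy_mixed", pdb = mixedPdb, chain = "A"),
           matrix_name = "blosum62", show_structures = TRUE),
      list(kind = "structure",
           sources = list(helixPdb, mixedPdb),
           labels = list("toy_helix", "toy_mixed")),
      list(kind = "network",
           nodes = list(list(id = "toy_helix"), list(id = "toy_mixed"),
                        list(id = "query")),
           edges = list(list(source = "query", target = "toy_helix",
                             label = "hit", weight = 0.9),
                        list(source = "query", target = "toy_mixed",
                             label = "hit", weight = 0.6))),
      list(kind = "plot",
           traces = list(list(x = as.list(seq_len(nHelix)),
                              y = as.list(track),
                              name = "confidence", mode = "lines")),
           layout = list(title = "Synthetic per-residue confidence",
                         xaxis = "residue", yaxis = "confidence"))))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA))
}
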