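toy22 <- function(match = 1L, mismatch = -3L,
                  alphabet = c("A", "B")) {
  k <- length(alphabet)
  s <- matrix(mismatch, k, k, dimnames = list(alphabet, alphabet))
  diag(s) <- match
  substitutionMatrix(s, name = "toy")
}

test_that("bundled BLOSUM62 matches the canonical table", {
  m <- loadMatrix("blosum62")
  expect_identical(matrixScore(m, "W", "W"), 11L)
  expect_identical(matrixScore(m, "A", "A"), 4L)
  expect_identical(matrixScore(m, "W", "C"), matrixScore(m, "C", "W"))
  # independent cross-check of the 20 standard residues against the copy
  # shipped with Biostrings (published variants differ only in the
  # B/Z/X ambiguity rows)
  skip_if_not_installed("Biostrings")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  std <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  expect_identical(m@scores[std, std],
                   matrix(as.integer(BLOSUM62[std, std]), 20,
                          dimnames = list(std, std)))
})

test_that("matrix files are validated: symmetry, totality, layout", {
  f <- tempfile(fileext = ".mat")
  writeLines(c("# toy", "   A  B", "A  1 -1", "B -1  1"), f)
  m <- loadMatrix(f)
  expect_identical(m@alphabet, c("A", "B"))
  expect_identical(matrixScore(m, "A", "B"), -1L)
  writeLines(c("   A  B", "A  1 -1", "B  2  1"), f)
  expect_error(loadMatrix(f), "asymmetric.*\\(A, B\\)")
  writeLines(c("   A  B", "A  1 -1"), f)
  expect_error(loadMatrix(f), "incomplete.*\\(B, A\\)")
  writeLines(c("   A  B", "A  1 -1", "B -1  x"), f)
  expect_error(loadMatrix(f), "non-integer")
  expect_error(loadMatrix("nosuchmatrix"), "blosum62")
})

test_that("self-alignment with a dominant diagonal has no gaps", {
  m <- toy22(match = 4L)
  r <- globalAlign("AAA", "AAA", m, gapPenalties(open = 2, extend = 1))
  expect_identical(unname(alignedSeqs(r)), c("AAA", "AAA"))
  expect_identical(alignmentScore(r), 12)
  expect_identical(percentIdentity(r), 1)
})

test_that("DP optimum equals the brute-force optimum on crafted gap cases", {
  m <- toy22(match = 1L, mismatch = -3L)
  g <- gapPenalties(open = 2, extend = 1)
  for (pair in list(c("AB", "B"), c("A", "A"), c("AABB", "AB"),
                    c("ABAB", "BABA"), c("B", "AAB"))) {
    r <- globalAlign(pair[1], pair[2], m, g)
    expect_identical(
      alignmentScore(r),
      oracleBestScore(pair[1], pair[2], m@scores, 2, 1),
      label = sprintf("optimal score for %s/%s", pair[1], pair[2]))
  }
})

test_that("alignment results satisfy their structural invariants", {
  set.seed(11)
  m <- loadMatrix("blosum62")
  g <- gapPenalties()
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (rep in 1:25) {
    a <- paste(sample(aa, sample(1:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:30, 1), replace = TRUE), collapse = "")
    r <- globalAlign(a, b, m, g)
    ga <- alignedSeqs(r)[["a"]]; gb <- alignedSeqs(r)[["b"]]
    # de-gapping recovers the inputs exactly
    expect_identical(gsub("-", "", ga, fixed = TRUE), a)
    expect_identical(gsub("-", "", gb, fixed = TRUE), b)
    # no double-gap columns
    expect_false(any(strsplit(ga, "")[[1]] == "-" &
                       strsplit(gb, "")[[1]] == "-"))
    # reported score equals rescoring of the emitted alignment
    expect_identical(alignmentScore(r), rescoreAlignment(r, m, g))
    # score symmetry under a symmetric matrix
    expect_identical(alignmentScore(globalAlign(b, a, m, g)),
                     alignmentScore(r))
    # column map points at the right residues
    ca <- strsplit(a, "")[[1]]
    idx <- r@columnMap[, "a"]
    expect_identical(paste(ca[idx[!is.na(idx)] + 1L], collapse = ""), a)
  }
})

test_that("characters outside the alphabet are reported with their position", {
  m <- toy22()
  expect_error(globalAlign("ABZA", "AB", m, gapPenalties(2, 1)),
               "'Z' at position 3")
  expect_error(globalAlign("", "A", m, gapPenalties(2, 1)), "non-empty")
})

test_that("percent identity follows the shared-column definition", {
  mk <- function(ga, gb) {
    mapCol <- function(g) {
      idx <- cumsum(strsplit(g, "")[[1]] != "-") - 1L
      idx[strsplit(g, "")[[1]] == "-"] <- NA_integer_
      idx
    }
    new("AlignmentResult", alignedA = ga, alignedB = gb, score = 0,
        columnMap = cbind(a = mapCol(ga), b = mapCol(gb)))
  }
  expect_identical(percentIdentity(mk("AB", "AC")), 0.5)
  expect_identical(percentIdentity(mk("AB", "CD")), 0)
  expect_identical(percentIdentity(mk("A-", "-A")), 0)
  expect_identical(percentIdentity(mk("ABC", "ABC")), 1)
})

test_that("semi-global mode aligns a domain inside a longer sequence", {
  m <- toy22(match = 2L, mismatch = -2L)
  g <- gapPenalties(open = 3, extend = 1)
  r <- globalAlign("ABBA", "BABBAB", m, g, endGapFree = TRUE)
  expect_identical(alignmentScore(r), 8)
  expect_identical(gsub("-", "", alignedSeqs(r)[["a"]], fixed = TRUE), "ABBA")
  expect_identical(rescoreAlignment(r, m, g, endGapFree = TRUE),
                   alignmentScore(r))
})

test_that("DP equals exhaustive enumeration on random pairs and penalties", {
  set.seed(1234)
  nPairs <- 200L
  for (rep in seq_len(nPairs)) {
    m <- randomToyMatrix()
    open <- sample(0:5, 1L)
    extend <- sample(1:3, 1L)
    a <- randomSeq(); b <- randomSeq()
    r <- globalAlign(a, b, m, gapPenalties(open, extend))
    expected <- oracleBestScore(a, b, m@scores, open, extend)
    expect_identical(alignmentScore(r), expected,
                     label = sprintf("pair %d: %s vs %s", rep, a, b))
    # the emitted alignment achieves the reported score under the oracle's
    # independent scorer
    expect_identical(
      oracleScoreGapped(strsplit(alignedSeqs(r)[["a"]], "")[[1]],
                        strsplit(alignedSeqs(r)[["b"]], "")[[1]],
                        m@scores, open, extend),
      alignmentScore(r))
  }
})
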