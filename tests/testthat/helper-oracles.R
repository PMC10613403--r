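# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# score a gapped alignment pair: substitution scores over residue columns,
# each maximal gap run charged open + extend * length
oracleScoreGapped <- function(ga, gb, scores, open, extend,
                              endGapFree = FALSE) {
  n <- length(ga)
  s <- 0
  for (i in seq_len(n)) if (ga[i] != "-" && gb[i] != "-")
    s <- s + scores[ga[i], gb[i]]
  for (g in list(ga == "-", gb == "-")) {
    i <- 1L
    while (i <= n) {
      if (g[i]) {
        j <- i
        while (j < n && g[j + 1L]) j <- j + 1L
        if (!(endGapFree && (i == 1L || j == n)))
          s <- s - open - extend * (j - i + 1L)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  s
}

# exhaustive enumeration of all global alignments of a and b, returning the
# maximum achievable affine-gap score; feasible for lengths <= 6
oracleBestScore <- function(a, b, scores, open, extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: M = residue column, X = gap in b, Y = gap in a
  recurse <- function(i, j, acc, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc)
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1L, j + 1L, acc + scores[ca[i], cb[j]], "M")
    if (i <= length(ca))
      recurse(i + 1L, j,
              acc - (if (state == "X") extend else open + extend), "X")
    if (j <= length(cb))
      recurse(i, j + 1L,
              acc - (if (state == "Y") extend else open + extend), "Y")
    invisible(NULL)
  }
  recurse(1L, 1L, 0, "start")
  best
}

# random small symmetric integer substitution matrix over an alphabet
randomToyMatrix <- function(alphabet = c("A", "C", "D", "E")) {
  k <- length(alphabet)
  s <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  for (i in seq_len(k)) for (j in i:k)
    s[i, j] <- s[j, i] <- sample(-4:5, 1L)
  substitutionMatrix(s, name = "toy")
}

randomSeq <- function(maxLen = 6L, alphabet = c("A", "C", "D", "E")) {
  n <- sample(seq_len(maxLen), 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# apply a random rigid-body transform (rotation + translation) to coords
randomRigidTransform <- function(coords) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  sweep(coords %*% q, 2L, stats::rnorm(3, sd = 20), `+`)
}

# a fully extended collinear CA trace with the canonical 3.8 A spacing
extendedTrace <- function(n) cbind(x = (seq_len(n) - 1L) * 3.8, y = 0, z = 0)

demoSpecJSON <- function(dir = file.path(tempdir(), "demo-fixtures")) {
  makeDemoSpec(dir)
}
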