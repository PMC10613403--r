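test_that("markdown renders CommonMark and neutralises raw HTML", {
  expect_match(renderMarkdown("**x**"), "<strong>x</strong>", fixed = TRUE)
  expect_match(renderMarkdown("# Title"), "<h1>Title</h1>", fixed = TRUE)
  out <- renderMarkdown("<script>alert(1)</script>")
  expect_false(grepl("<script>", out, fixed = TRUE))
  expect_match(out, "&lt;script&gt;", fixed = TRUE)
})

test_that("tables embed all rows regardless of page size", {
  payload <- componentPayload(pageComponents(parsePageSpec(paste0(
    '{"title":"T","components":[{"kind":"table",',
    '"columns":["id","n"],"rows":[["r1",1],["r2",2],["r3",3]],',
    '"page_size":10}]}')))[[1]])
  html <- renderTable(payload, id = "component-1")
  for (cell in c("r1", "r2", "r3"))
    expect_match(html, cell, fixed = TRUE)
  expect_match(html, "component-1-data", fixed = TRUE)
})

test_that("table search twin is a case-insensitive substring over all cells", {
  rows <- list(list("abc", 1), list("ABD", 2), list("xyz", 3))
  expect_length(tableSearch(rows, "ab"), 2L)
  expect_length(tableSearch(rows, ""), 3L)
  expect_length(tableSearch(rows, "2"), 1L)
  expect_length(tableSearch(rows, "zz"), 0L)
})

test_that("table sort twin sorts numeric-looking columns numerically", {
  rows <- list(list("b", "10"), list("a", "2"), list("c", "1"))
  sorted <- tableSort(rows, 2L)
  expect_identical(vapply(sorted, `[[`, character(1), 2L),
                   c("1", "2", "10"))
  sortedDesc <- tableSort(rows, 2L, decreasing = TRUE)
  expect_identical(vapply(sortedDesc, `[[`, character(1), 2L),
                   c("10", "2", "1"))
  # lexicographic on a mixed column
  rowsMixed <- list(list("10"), list("2"), list("x"))
  expect_identical(unlist(tableSort(rowsMixed, 1L)), c("10", "2", "x"))
  # stable on ties
  rowsTie <- list(list("a", 1), list("b", 1), list("c", 0))
  expect_identical(vapply(tableSort(rowsTie, 2L), `[[`, character(1), 1L),
                   c("c", "a", "b"))
})

test_that("table filter twin restricts matching to one column", {
  rows <- list(list("abc", "x"), list("abd", "ab"), list("zzz", "ab"))
  expect_length(tableFilter(rows, 1L, "ab"), 2L)
  expect_length(tableFilter(rows, 2L, "ab"), 2L)
  expect_length(tableFilter(rows, 2L, "ABC"), 0L)
})

test_that("pair alignment rendering colors residues by state and wraps at 60", {
  n <- 12L
  trace <- makeTrace(geometryRecipe("ideal_helix", n))
  sequence <- strrep("A", n)
  ss <- assignSecondaryStructure(trace)
  m <- loadMatrix("blosum62")
  aln <- globalAlign(sequence, sequence, m, gapPenalties())
  tracks <- alignedSSTracks(aln, ss, ss)
  html <- renderPairAlignment(aln, tracks, idA = "x", idB = "y")
  # interior residues carry the helix class, termini the coil class
  expect_identical(lengths(regmatches(html, gregexpr("ss-H", html))), 16L)
  expect_match(html, "ss-C", fixed = TRUE)
  # 130-column alignment wraps into 3 blocks
  seqLong <- strrep("A", 130L)
  alnLong <- globalAlign(seqLong, seqLong, m, gapPenalties())
  tracksLong <- alignedSSTracks(alnLong, strrep("C", 130L), strrep("C", 130L))
  htmlLong <- renderPairAlignment(alnLong, tracksLong)
  expect_identical(lengths(regmatches(htmlLong,
                                      gregexpr("aln-block", htmlLong))), 3L)
  # gap columns render '-' with the neutral style
  aln2 <- globalAlign("AAAAAAAAAAWW", "AAAAAAAAAA", m, gapPenalties())
  tr2 <- alignedSSTracks(aln2, strrep("C", 12L), strrep("C", 10L))
  html2 <- renderPairAlignment(aln2, tr2)
  expect_match(html2, "<span class=\"ss-gap\">-</span>", fixed = TRUE)
})

test_that("de-gapped residue spans reconstruct the input sequences", {
  set.seed(5)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  a <- paste(sample(aa, 70, replace = TRUE), collapse = "")
  b <- paste(sample(aa, 55, replace = TRUE), collapse = "")
  m <- loadMatrix("blosum62")
  aln <- globalAlign(a, b, m, gapPenalties())
  tracks <- alignedSSTracks(aln, strrep("C", 70), strrep("C", 55))
  html <- renderPairAlignment(aln, tracks, idA = "seqA", idB = "seqB")
  skip_if_not_installed("xml2")
  doc <- xml2::read_html(html)
  rows <- xml2::xml_find_all(doc, "//div[contains(@class,'aln-row')]")
  rowText <- vapply(rows, function(r) paste(
    xml2::xml_text(xml2::xml_find_all(
      r, ".//span[starts-with(@class,'ss-')]")), collapse = ""),
    character(1))
  rowText <- rowText[nzchar(rowText)]   # drop midlines
  sideA <- paste(rowText[seq_along(rowText) %% 2L == 1L], collapse = "")
  sideB <- paste(rowText[seq_along(rowText) %% 2L == 0L], collapse = "")
  expect_identical(gsub("-", "", sideA, fixed = TRUE), a)
  expect_identical(gsub("-", "", sideB, fixed = TRUE), b)
})

test_that("sequence view wraps at 60 and embeds its track as a plot", {
  payload <- list(id = "s1", sequence = strrep("M", 130L),
                  track = rep(0.5, 130L), track_name = "conf")
  html <- renderSequence(payload, id = "component-3")
  expect_identical(lengths(regmatches(html, gregexpr("seq-row", html))), 3L)
  expect_match(html, "Plotly.newPlot", fixed = TRUE)
  expect_match(html, "component-3-track", fixed = TRUE)
})

test_that("msa view renders one row per sequence per block", {
  payload <- list(ids = c("s1", "s2", "s3"),
                  sequences = rep(strrep("A-", 40L), 3L))
  html <- renderMsa(payload, id = "component-4")
  # 80 columns -> 2 blocks x 3 rows
  expect_identical(lengths(regmatches(html, gregexpr("msa-block", html))), 2L)
  expect_identical(lengths(regmatches(html, gregexpr("aln-row", html))), 6L)
})

test_that("structure and network embeds carry their data and assets", {
  html <- renderStructure(list(sources = c("data/a.pdb", "data/b.pdb"),
                               labels = c("a", "b")), id = "component-6")
  expect_identical(lengths(regmatches(html, gregexpr("stage.loadFile", html))),
                   2L)
  # both sources share one viewer stage
  expect_identical(lengths(regmatches(html, gregexpr("pp-structure", html))),
                   1L)
  expect_match(html, "data/a.pdb", fixed = TRUE)
  expect_match(html, "data/b.pdb", fixed = TRUE)

  net <- renderNetwork(list(
    nodes = list(list(id = "n1", label = "n1"), list(id = "n2", label = "n2")),
    edges = list(list(source = "n1", target = "n2", label = NULL,
                      weight = NULL))), id = "component-7")
  expect_match(net, "\"id\":\"n1\"", fixed = TRUE)
  expect_match(net, "\"source\":\"n1\",\"target\":\"n2\"", fixed = TRUE)

  plt <- renderPlot(list(
    traces = list(list(x = list(1, 2, 3), y = c(0.1, 0.5, 0.9),
                       name = "t", mode = "lines")),
    layout = list(title = "p", xaxis = "x", yaxis = "y")),
    id = "component-8")
  expect_match(plt, "0.1", fixed = TRUE)
  expect_match(plt, "0.9", fixed = TRUE)
})

test_that("rendered pages are deterministic with ordered anchored containers", {
  json <- demoSpecJSON()
  spec <- parsePageSpec(json)
  p1 <- renderPage(spec)
  p2 <- renderPage(spec)
  expect_identical(pageHTML(p1), pageHTML(p2))
  html <- pageHTML(p1)
  anchors <- regmatches(html,
    gregexpr("<section class=\"pp-component\" id=\"component-[0-9]+\"", html))[[1]]
  expect_identical(anchors, sprintf(
    "<section class=\"pp-component\" id=\"component-%d\"", 1:8))
  # a table of contents links every component
  for (i in 1:8)
    expect_match(html, sprintf("href=\"#component-%d\"", i), fixed = TRUE)
})

test_that("an unresolvable component yields an error panel, not a dead page", {
  json <- paste0('{"title":"T","components":[',
                 '{"kind":"markdown","text":"ok"},',
                 '{"kind":"pair_alignment",',
                 '"side_a":{"pdb":"/nonexistent/x.pdb","chain":"A"},',
                 '"side_b":{"sequence":"ACDEF"}}]}')
  page <- renderPage(parsePageSpec(json))
  html <- pageHTML(page)
  expect_match(html, "pp-error", fixed = TRUE)
  expect_match(html, "id=\"component-2\"", fixed = TRUE)
  expect_match(html, "<p>ok</p>", fixed = TRUE)
})

test_that("empty markdown still produces its anchored container", {
  page <- renderPage(parsePageSpec(
    '{"title":"T","components":[{"kind":"markdown","text":""}]}'))
  expect_match(pageHTML(page), "id=\"component-1\"", fixed = TRUE)
})

test_that("page-level colors override the default scheme", {
  scheme <- colorScheme(c(H = "#123456"))
  expect_identical(scheme$H, "#123456")
  expect_identical(scheme$E, colorScheme()$E)
  json <- paste0('{"title":"T","colors":{"H":"#123456"},',
                 '"components":[{"kind":"markdown","text":"x"}]}')
  expect_match(pageHTML(renderPage(parsePageSpec(json))),
               ".ss-H{background:#123456", fixed = TRUE)
})
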