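test_that("a minimal document parses into a one-component PageSpec", {
  spec <- parsePageSpec(
    '{"title":"T","components":[{"kind":"markdown","text":"hi"}]}')
  expect_s4_class(spec, "PageSpec")
  expect_identical(pageTitle(spec), "T")
  expect_length(pageComponents(spec), 1L)
  expect_identical(componentKind(pageComponents(spec)[[1]]), "markdown")
})

test_that("JSON syntax errors are reported as parse failures", {
  expect_error(parsePageSpec('{"title": "T", '), class = "protpage_parse_error")
})

test_that("unknown component kinds are rejected at validation, citing the path", {
  err <- tryCatch(
    parsePageSpec('{"title":"T","components":[{"kind":"hologram"}]}'),
    error = identity)
  expect_s3_class(err, "protpage_validation_error")
  expect_match(conditionMessage(err), "components\\[0\\]\\.kind")
})

test_that("table rows must match the column count, citing the row index", {
  json <- paste0('{"title":"T","components":[{"kind":"table",',
                 '"columns":["a","b","c"],',
                 '"rows":[["1","2","3"],["1","2"]]}]}')
  err <- tryCatch(parsePageSpec(json), error = identity)
  expect_s3_class(err, "protpage_validation_error")
  expect_match(conditionMessage(err), "components\\[0\\]\\.rows\\[1\\]")
})

test_that("component order is preserved exactly", {
  kinds <- c("markdown", "plot", "markdown", "table")
  comps <- list(
    list(kind = "markdown", text = "one"),
    list(kind = "plot", traces = list(list(x = list(1), y = list(2)))),
    list(kind = "markdown", text = "two"),
    list(kind = "table", columns = list("x"), rows = list(list("1"))))
  json <- jsonlite::toJSON(list(title = "T", components = comps),
                           auto_unbox = TRUE)
  spec <- parsePageSpec(json)
  expect_identical(vapply(pageComponents(spec), componentKind, character(1)),
                   kinds)
})

test_that("a corpus of corrupted specs each fails naming the offending path", {
  table1 <- '{"kind":"table","columns":["a"],"rows":[["1"]]}'
  cases <- list(
    # document-level problems
    list(json = '{"components":[]}', path = "\\$\\.title"),
    list(json = '{"title":"","components":[]}', path = "\\$\\.title"),
    list(json = sprintf('{"title":"T","components":{"0":%s}}', table1),
         path = "\\$\\.components"),
    # component-level problems
    list(json = '{"title":"T","components":[{"text":"x"}]}',
         path = "components\\[0\\]\\.kind"),
    list(json = '{"title":"T","components":[{"kind":"hologram"}]}',
         path = "components\\[0\\]\\.kind"),
    list(json = '{"title":"T","components":[{"kind":"markdown"}]}',
         path = "components\\[0\\]\\.text"),
    list(json = paste0('{"title":"T","components":[', table1,
                       ',{"kind":"table","columns":["a","b"],"rows":[["1"]]}]}'),
         path = "components\\[1\\]\\.rows\\[0\\]"),
    list(json = '{"title":"T","components":[{"kind":"table","columns":["a"],"rows":[["1"]],"page_size":0}]}',
         path = "components\\[0\\]\\.page_size"),
    list(json = '{"title":"T","components":[{"kind":"sequence","id":"s","sequence":"ACD","track":[1,2]}]}',
         path = "components\\[0\\]\\.track"),
    list(json = '{"title":"T","components":[{"kind":"msa","ids":["a","b"],"sequences":["ACD-","AC"]}]}',
         path = "components\\[0\\]\\.sequences\\[1\\]"),
    list(json = '{"title":"T","components":[{"kind":"network","nodes":[{"id":"n1"}],"edges":[{"source":"n1","target":"ghost"}]}]}',
         path = "components\\[0\\]\\.edges\\[0\\]\\.target"),
    list(json = '{"title":"T","components":[{"kind":"pair_alignment","side_a":{"sequence":"ACD","ss":"HH"},"side_b":{"sequence":"ACD"}}]}',
         path = "components\\[0\\]\\.side_a\\.ss"),
    list(json = '{"title":"T","components":[{"kind":"structure","sources":[]}]}',
         path = "components\\[0\\]\\.sources"),
    list(json = '{"title":"T","components":[{"kind":"plot","traces":[{"x":[1,2],"y":[1]}]}]}',
         path = "components\\[0\\]\\.traces\\[0\\]\\.y"))
  for (case in cases) {
    err <- tryCatch(parsePageSpec(case$json), error = identity)
    expect_s3_class(err, "protpage_validation_error")
    expect_match(conditionMessage(err), case$path,
                 label = sprintf("diagnostic for %s", case$json))
  }
})

test_that("validation never silently coerces wrong-typed payloads", {
  bad <- list(
    '{"title":"T","components":[{"kind":"markdown","text":42}]}',
    '{"title":"T","components":[{"kind":"table","columns":"a","rows":[]}]}',
    '{"title":"T","components":[{"kind":"sequence","id":"s","sequence":["A"]}]}',
    '{"title":5,"components":[]}')
  for (json in bad)
    expect_error(parsePageSpec(json), class = "protpage_validation_error")
})

test_that("unknown top-level keys are tolerated, unknown kinds are not", {
  spec <- parsePageSpec(
    '{"title":"T","future_key":1,"components":[{"kind":"markdown","text":"x"}]}')
  expect_length(pageComponents(spec), 1L)
})

test_that("serialize -> parse round-trips generated specs", {
  jsons <- c(
    demoSpecJSON(),
    '{"title":"T","components":[{"kind":"markdown","text":"**hi** & <b>"}]}',
    paste0('{"title":"Round","colors":{"H":"#f00"},"components":[',
           '{"kind":"sequence","id":"s1","sequence":"ACDEF",',
           '"track":[0.1,0.2,0.3,0.4,0.5],"track_name":"conf"},',
           '{"kind":"network","nodes":[{"id":"a"},{"id":"b","label":"B"}],',
           '"edges":[{"source":"a","target":"b","weight":1.5}]}]}'))
  for (json in jsons) {
    p1 <- parsePageSpec(json)
    p2 <- parsePageSpec(serializePageSpec(p1))
    expect_identical(pageTitle(p2), pageTitle(p1))
    expect_identical(
      lapply(pageComponents(p2), componentPayload),
      lapply(pageComponents(p1), componentPayload))
    expect_identical(
      vapply(pageComponents(p2), componentKind, character(1)),
      vapply(pageComponents(p1), componentKind, character(1)))
  }
})

test_that("the published schema is stable and total over the renderers", {
  s1 <- specSchema()
  s2 <- specSchema()
  expect_identical(s1, s2)
  expect_setequal(names(s1$kinds),
                  c("markdown", "table", "sequence", "msa", "pair_alignment",
                    "structure", "network", "plot"))
  # schema document round-trips through JSON unchanged
  expect_identical(
    jsonlite::fromJSON(jsonlite::toJSON(s1, auto_unbox = TRUE),
                       simplifyVector = FALSE),
    s1)
  # every fixture demo component validates against it
  expect_s4_class(parsePageSpec(demoSpecJSON()), "PageSpec")
})
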