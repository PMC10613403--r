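#' @include AllClasses.R utils.R
NULL

.schemaCache <- new.env(parent = emptyenv())

#' The canonical page-specification schema
#'
#' Returns the machine-readable schema document that [parsePageSpec()]
#' validates against: the required and optional keys of the page object and
#' of every component kind, with their JSON types. The document ships with
#' the package (`inst/extdata/page-schema.json`) and is stable across calls.
#'
#' @return a named list mirroring the JSON schema document, with entries
#'   `format`, `version`, `page` and `kinds`.
#' @examples
#' names(specSchema()$kinds)
#' @export
specSchema <- function() {
  if (is.null(.schemaCache$schema)) {
    path <- system.file("extdata", "page-schema.json", package = "protpage",
                        mustWork = TRUE)
    .schemaCache$schema <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  .schemaCache$schema
}

componentKinds <- function() names(specSchema()$kinds)

# ---- JSON type predicates over jsonlite's simplifyVector = FALSE forms ----

isJsonString  <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
isJsonBool    <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
isJsonNumber  <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
isJsonInteger <- function(x) isJsonNumber(x) && x == round(x)
isJsonArray   <- function(x) is.list(x) && (is.null(names(x)) || length(x) == 0L)
isJsonObject  <- function(x) is.list(x) && (length(x) == 0L || !is.null(names(x)))

checkJsonType <- function(x, type, path) {
  ok <- switch(type,
    string  = isJsonString(x),
    boolean = isJsonBool(x),
    number  = isJsonNumber(x),
    integer = isJsonInteger(x),
    array   = isJsonArray(x),
    object  = isJsonObject(x),
    FALSE)
  if (!ok) ppValidationError(path, sprintf("expected a JSON %s", type))
  invisible(x)
}

# check an object's keys against a schema record {required, optional};
# unknown keys are ignored with a logged warning (forward compatibility)
checkKeys <- function(x, rec, path) {
  req <- rec$required
  opt <- rec$optional
  for (k in names(req)) {
    if (is.null(x[[k]]))
      ppValidationError(paste0(path, ".", k), "required key is missing")
    checkJsonType(x[[k]], req[[k]], paste0(path, ".", k))
  }
  for (k in intersect(names(x), names(opt)))
    checkJsonType(x[[k]], opt[[k]], paste0(path, ".", k))
  unknown <- setdiff(names(x), c(names(req), names(opt), "kind"))
  if (length(unknown) > 0L)
    ppLog("info", sprintf("ignoring unknown key(s) at %s: %s", path,
                          paste(unknown, collapse = ", ")))
  invisible(x)
}

# ---- kind-specific payload validators -------------------------------------
# each returns the normalised payload (defaults filled) or raises a
# validation error naming the JSON path of the offending key

validateMarkdown <- function(x, path) {
  list(text = x$text)
}

validateTable <- function(x, path) {
  ncolumns <- length(x$columns)
  if (ncolumns == 0L)
    ppValidationError(paste0(path, ".columns"), "at least one column required")
  for (j in seq_along(x$columns))
    checkJsonType(x$columns[[j]], "string",
                  sprintf("%s.columns[%d]", path, j - 1L))
  for (i in seq_along(x$rows)) {
    row <- x$rows[[i]]
    rpath <- sprintf("%s.rows[%d]", path, i - 1L)
    if (!isJsonArray(row))
      ppValidationError(rpath, "each row must be an array of cells")
    if (length(row) != ncolumns)
      ppValidationError(rpath, sprintf("row has %d cells but there are %d columns",
                                       length(row), ncolumns))
  }
  pageSize <- if (is.null(x$page_size)) 10L else as.integer(x$page_size)
  if (pageSize < 1L)
    ppValidationError(paste0(path, ".page_size"), "must be >= 1")
  list(columns = vapply(x$columns, identity, character(1)),
       rows = x$rows,
       page_size = pageSize,
       searchable = if (is.null(x$searchable)) TRUE else x$searchable,
       sortable = if (is.null(x$sortable)) TRUE else x$sortable,
       filterable = if (is.null(x$filterable)) TRUE else x$filterable)
}

validateSequence <- function(x, path) {
  if (!nzchar(x$sequence))
    ppValidationError(paste0(path, ".sequence"), "sequence must be non-empty")
  track <- NULL
  if (!is.null(x$track)) {
    if (length(x$track) != nchar(x$sequence))
      ppValidationError(paste0(path, ".track"),
        sprintf("track has %d values but the sequence has %d residues",
                length(x$track), nchar(x$sequence)))
    for (i in seq_along(x$track))
      checkJsonType(x$track[[i]], "number",
                    sprintf("%s.track[%d]", path, i - 1L))
    track <- vapply(x$track, as.numeric, numeric(1))
  }
  list(id = x$id, sequence = x$sequence, track = track,
       track_name = if (is.null(x$track_name)) "track" else x$track_name)
}

validateMsa <- function(x, path) {
  n <- length(x$ids)
  if (n == 0L)
    ppValidationError(paste0(path, ".ids"), "at least one sequence required")
  if (length(x$sequences) != n)
    ppValidationError(paste0(path, ".sequences"),
      sprintf("%d sequences for %d ids", length(x$sequences), n))
  for (i in seq_len(n)) {
    checkJsonType(x$ids[[i]], "string", sprintf("%s.ids[%d]", path, i - 1L))
    checkJsonType(x$sequences[[i]], "string",
                  sprintf("%s.sequences[%d]", path, i - 1L))
  }
  lens <- vapply(x$sequences, nchar, integer(1))
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    ppValidationError(sprintf("%s.sequences[%d]", path, bad - 1L),
      sprintf("gapped length %d differs from first sequence's %d",
              lens[bad], lens[1L]))
  }
  list(ids = vapply(x$ids, identity, character(1)),
       sequences = vapply(x$sequences, identity, character(1)))
}

validateAlignmentSide <- function(x, path) {
  if (!isJsonObject(x))
    ppValidationError(path, "expected a JSON object")
  if (!is.null(x$sequence)) {
    checkJsonType(x$sequence, "string", paste0(path, ".sequence"))
    if (!nzchar(x$sequence))
      ppValidationError(paste0(path, ".sequence"), "sequence must be non-empty")
    if (!is.null(x$ss)) {
      checkJsonType(x$ss, "string", paste0(path, ".ss"))
      if (nchar(x$ss) != nchar(x$sequence))
        ppValidationError(paste0(path, ".ss"),
          sprintf("secondary-structure string has %d states for %d residues",
                  nchar(x$ss), nchar(x$sequence)))
      if (!grepl("^[HETC]*$", x$ss))
        ppValidationError(paste0(path, ".ss"),
                          "states must be drawn from {H, E, T, C}")
    }
    list(type = "inline",
         id = if (is.null(x$id)) "seq" else x$id,
         sequence = x$sequence, ss = x$ss)
  } else if (!is.null(x$pdb)) {
    checkJsonType(x$pdb, "string", paste0(path, ".pdb"))
    if (!is.null(x$chain))
      checkJsonType(x$chain, "string", paste0(path, ".chain"))
    list(type = "pdb", pdb = x$pdb, chain = x$chain,
         id = if (is.null(x$id)) basename(x$pdb) else x$id)
  } else {
    ppValidationError(path,
      "a side needs either an inline 'sequence' or a 'pdb' source")
  }
}

validatePairAlignment <- function(x, path) {
  list(side_a = validateAlignmentSide(x$side_a, paste0(path, ".side_a")),
       side_b = validateAlignmentSide(x$side_b, paste0(path, ".side_b")),
       matrix_name = if (is.null(x$matrix_name)) "blosum62" else x$matrix_name,
       show_structures = if (is.null(x$show_structures)) FALSE
                         else x$show_structures)
}

validateStructure <- function(x, path) {
  if (length(x$sources) == 0L)
    ppValidationError(paste0(path, ".sources"),
                      "at least one PDB source required")
  for (i in seq_along(x$sources))
    checkJsonType(x$sources[[i]], "string",
                  sprintf("%s.sources[%d]", path, i - 1L))
  labels <- if (is.null(x$labels))
    vapply(x$sources, basename, character(1))
  else {
    if (length(x$labels) != length(x$sources))
      ppValidationError(paste0(path, ".labels"),
                        "one label per source required")
    vapply(x$labels, identity, character(1))
  }
  list(sources = vapply(x$sources, identity, character(1)), labels = labels)
}

validateNetwork <- function(x, path) {
  ids <- character(0)
  nodes <- vector("list", length(x$nodes))
  for (i in seq_along(x$nodes)) {
    npath <- sprintf("%s.nodes[%d]", path, i - 1L)
    node <- x$nodes[[i]]
    if (!isJsonObject(node) || is.null(node$id))
      ppValidationError(paste0(npath, ".id"), "every node needs an 'id'")
    checkJsonType(node$id, "string", paste0(npath, ".id"))
    nodes[[i]] <- list(id = node$id,
                       label = if (is.null(node$label)) node$id else node$label)
    ids <- c(ids, node$id)
  }
  if (anyDuplicated(ids))
    ppValidationError(paste0(path, ".nodes"),
      sprintf("duplicate node id '%s'", ids[anyDuplicated(ids)]))
  edges <- vector("list", length(x$edges))
  for (i in seq_along(x$edges)) {
    epath <- sprintf("%s.edges[%d]", path, i - 1L)
    edge <- x$edges[[i]]
    if (!isJsonObject(edge))
      ppValidationError(epath, "expected a JSON object")
    for (endpoint in c("source", "target")) {
      if (is.null(edge[[endpoint]]))
        ppValidationError(paste0(epath, ".", endpoint), "required key is missing")
      checkJsonType(edge[[endpoint]], "string", paste0(epath, ".", endpoint))
      if (!edge[[endpoint]] %in% ids)
        ppValidationError(paste0(epath, ".", endpoint),
          sprintf("'%s' does not name an existing node id", edge[[endpoint]]))
    }
    edges[[i]] <- list(source = edge$source, target = edge$target,
                       label = edge$label, weight = edge$weight)
  }
  list(nodes = nodes, edges = edges)
}

validatePlot <- function(x, path) {
  if (length(x$traces) == 0L)
    ppValidationError(paste0(path, ".traces"), "at least one trace required")
  traces <- vector("list", length(x$traces))
  for (i in seq_along(x$traces)) {
    tpath <- sprintf("%s.traces[%d]", path, i - 1L)
    tr <- x$traces[[i]]
    if (!isJsonObject(tr))
      ppValidationError(tpath, "expected a JSON object")
    for (ax in c("x", "y")) {
      if (is.null(tr[[ax]]))
        ppValidationError(paste0(tpath, ".", ax), "required key is missing")
      if (!isJsonArray(tr[[ax]]))
        ppValidationError(paste0(tpath, ".", ax), "expected a JSON array")
    }
    if (length(tr$x) != length(tr$y))
      ppValidationError(paste0(tpath, ".y"),
        sprintf("%d y-values for %d x-values", length(tr$y), length(tr$x)))
    for (j in seq_along(tr$y))
      checkJsonType(tr$y[[j]], "number", sprintf("%s.y[%d]", tpath, j - 1L))
    traces[[i]] <- list(
      x = tr$x, y = vapply(tr$y, as.numeric, numeric(1)),
      name = if (is.null(tr$name)) sprintf("trace %d", i) else tr$name,
      mode = if (is.null(tr$mode)) "lines" else tr$mode)
  }
  layout <- x$layout
  list(traces = traces,
       layout = list(
         title = if (is.null(layout$title)) "" else layout$title,
         xaxis = if (is.null(layout$xaxis)) "" else layout$xaxis,
         yaxis = if (is.null(layout$yaxis)) "" else layout$yaxis))
}

.payloadValidators <- list(
  markdown = validateMarkdown, table = validateTable,
  sequence = validateSequence, msa = validateMsa,
  pair_alignment = validatePairAlignment, structure = validateStructure,
  network = validateNetwork, plot = validatePlot)

validateComponent <- function(x, path) {
  if (!isJsonObject(x))
    ppValidationError(path, "each component must be a JSON object")
  if (is.null(x$kind))
    ppValidationError(paste0(path, ".kind"), "required key is missing")
  checkJsonType(x$kind, "string", paste0(path, ".kind"))
  schema <- specSchema()
  if (!x$kind %in% names(schema$kinds))
    ppValidationError(paste0(path, ".kind"),
      sprintf("unknown component kind '%s' (known kinds: %s)", x$kind,
              paste(names(schema$kinds), collapse = ", ")))
  checkKeys(x, schema$kinds[[x$kind]], path)
  payload <- .payloadValidators[[x$kind]](x, path)
  new("ComponentSpec", kind = x$kind, payload = payload)
}

#' Parse and validate a JSON page specification
#'
#' Parses a JSON page-specification document and validates it eagerly
#' against the schema returned by [specSchema()]: component kinds must be
#' members of the supported vocabulary, and every kind-specific invariant
#' (table row widths, equal gapped MSA lengths, per-residue track lengths,
#' network edge endpoints naming existing nodes, ...) is checked at parse
#' time, never deferred to rendering. Unknown top-level or component-level
#' keys are ignored with a logged message; unknown component kinds are hard
#' errors.
#'
#' @param jsonText single character string holding the JSON document.
#' @param source informational origin label stored on the result.
#' @return a validated [PageSpec-class].
#' @section Errors: a JSON syntax error raises a parse error naming the
#'   position; a schema violation raises a validation error whose message
#'   starts with the JSON path of the offending key (e.g.
#'   `components[0].kind`).
#' @examples
#' spec <- parsePageSpec(
#'   '{"title":"T","components":[{"kind":"markdown","text":"hi"}]}')
#' length(pageComponents(spec))
#' @export
parsePageSpec <- function(jsonText, source = "inline") {
  doc <- tryCatch(
    jsonlite::fromJSON(jsonText, simplifyVector = FALSE),
    error = function(e)
      ppParseError(sprintf("JSON syntax error: %s", conditionMessage(e))))
  if (!isJsonObject(doc))
    ppValidationError("$", "the document root must be a JSON object")
  schema <- specSchema()
  checkKeys(doc, schema$page, "$")
  if (!nzchar(doc$title))
    ppValidationError("$.title", "title must be non-empty")
  components <- vector("list", length(doc$components))
  for (i in seq_along(doc$components))
    components[[i]] <- validateComponent(doc$components[[i]],
                                         sprintf("components[%d]", i - 1L))
  colors <- character(0)
  if (!is.null(doc$colors)) {
    for (k in names(doc$colors))
      checkJsonType(doc$colors[[k]], "string", paste0("$.colors.", k))
    colors <- vapply(doc$colors, identity, character(1))
  }
  new("PageSpec", title = doc$title, components = components,
      colors = colors, source = source)
}

#' Serialize a page specification back to JSON
#'
#' The inverse of [parsePageSpec()] up to default filling:
#' `parsePageSpec(serializePageSpec(p))` reproduces `p` for every valid
#' spec.
#'
#' @param spec a [PageSpec-class].
#' @return single character string of pretty-printed JSON.
#' @export
serializePageSpec <- function(spec) {
  stopifnot(is(spec, "PageSpec"))
  comps <- lapply(spec@components, function(cc) {
    payload <- cc@payload
    out <- switch(cc@kind,
      markdown = list(text = payload$text),
      table = list(columns = as.list(payload$columns), rows = payload$rows,
                   page_size = payload$page_size,
                   searchable = payload$searchable,
                   sortable = payload$sortable,
                   filterable = payload$filterable),
      sequence = {
        x <- list(id = payload$id, sequence = payload$sequence)
        if (!is.null(payload$track)) {
          x$track <- as.list(payload$track)
          x$track_name <- payload$track_name
        }
        x
      },
      msa = list(ids = as.list(payload$ids),
                 sequences = as.list(payload$sequences)),
      pair_alignment = list(
        side_a = serializeSide(payload$side_a),
        side_b = serializeSide(payload$side_b),
        matrix_name = payload$matrix_name,
        show_structures = payload$show_structures),
      structure = list(sources = as.list(payload$sources),
                       labels = as.list(payload$labels)),
      network = list(nodes = payload$nodes,
                     edges = lapply(payload$edges, dropNulls)),
      plot = list(traces = lapply(payload$traces, function(tr)
                    list(x = tr$x, y = as.list(tr$y), name = tr$name,
                         mode = tr$mode)),
                  layout = payload$layout))
    c(list(kind = cc@kind), out)
  })
  doc <- list(title = spec@title, components = comps)
  if (length(spec@colors) > 0L) doc$colors <- as.list(spec@colors)
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null",
                   digits = NA)
}

serializeSide <- function(side) {
  if (side$type == "inline")
    dropNulls(list(id = side$id, sequence = side$sequence, ss = side$ss))
  else
    dropNulls(list(id = side$id, pdb = side$pdb, chain = side$chain))
}

dropNulls <- function(x) x[!vapply(x, is.null, logical(1))]

#' Components of a page specification
#'
#' @param spec a [PageSpec-class].
#' @return the ordered list of [ComponentSpec-class] objects.
#' @export
pageComponents <- function(spec) spec@components

#' Title of a page specification
#'
#' @param spec a [PageSpec-class].
#' @return single character string.
#' @export
pageTitle <- function(spec) spec@title

#' Kind of a component
#'
#' @param x a [ComponentSpec-class].
#' @return single character string.
#' @export
componentKind <- function(x) x@kind

#' Payload of a component
#'
#' @param x a [ComponentSpec-class].
#' @return named list of validated, default-filled payload fields.
#' @export
componentPayload <- function(x) x@payload

setMethod("show", "PageSpec", function(object) {
  cat(sprintf("PageSpec \"%s\" (%d component%s)\n", object@title,
              length(object@components),
              if (length(object@components) == 1L) "" else "s"))
  for (i in seq_along(object@components))
    cat(sprintf("  [%d] %s\n", i, object@components[[i]]@kind))
})

setMethod("show", "ComponentSpec", function(object) {
  cat(sprintf("ComponentSpec kind=%s (%d payload field%s)\n", object@kind,
              length(object@payload),
              if (length(object@payload) == 1L) "" else "s"))
})
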