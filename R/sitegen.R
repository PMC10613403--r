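#' @include AllClasses.R AllGenerics.R utils.R pagespec.R pairalign.R secstruct.R
NULL

.assetCache <- new.env(parent = emptyenv())

#' Pinned third-party browser assets
#'
#' The versioned CDN URLs of the third-party renderers embedded in
#' generated pages (3D structure viewer, network renderer, plot renderer),
#' read from the package's asset config. Pinning keeps builds reproducible:
#' the same page specification always references the same asset versions.
#'
#' @return named character vector of URLs.
#' @export
pinnedAssets <- function() {
  if (is.null(.assetCache$assets)) {
    path <- system.file("extdata", "assets.json", package = "protpage",
                        mustWork = TRUE)
    cfg <- jsonlite::fromJSON(path)
    cfg$comment <- NULL
    .assetCache$assets <- unlist(cfg)
  }
  .assetCache$assets
}

#' Secondary structure color scheme
#'
#' Maps each secondary structure state to a CSS color, plus emphasis styles
#' for identical and substituted alignment columns. The defaults follow the
#' conventional palette: helices red, strands yellow (on dark text), turns
#' and coil neutral gray.
#'
#' @param overrides named character vector overriding individual state
#'   colors (names among `H`, `E`, `T`, `C`, `match`, `mismatch`).
#' @return named list with entries `H`, `E`, `T`, `C`, `match`,
#'   `mismatch`, total over the 4-state alphabet.
#' @export
colorScheme <- function(overrides = character(0)) {
  scheme <- list(H = "#e41a1c", E = "#ffd92f", T = "#bdbdbd", C = "#bdbdbd",
                 match = "bold", mismatch = "normal")
  for (k in intersect(names(overrides), names(scheme)))
    scheme[[k]] <- overrides[[k]]
  scheme
}

# serialize an R object to JSON for embedding in a script tag; </ must not
# terminate the surrounding script element
embedJSON <- function(x) {
  json <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                        null = "null"))
  gsub("</", "<\\/", json, fixed = TRUE)
}

#' Render markdown to an HTML fragment
#'
#' CommonMark rendering of author-supplied text. Raw HTML in the source is
#' neutralised before rendering (`&` and `<` are entity-escaped), so markup
#' like `<script>` appears as literal text and is never executable;
#' CommonMark syntax itself (emphasis, headings, lists, fenced code, links)
#' is rendered normally.
#'
#' @param text markdown source text.
#' @return single character string of HTML.
#' @export
renderMarkdown <- function(text) {
  safe <- gsub("<", "&lt;", gsub("&", "&amp;", text, fixed = TRUE),
               fixed = TRUE)
  commonmark::markdown_html(safe, smart = FALSE)
}

# ---- table rendering and its server-side twin -----------------------------

stringifyCell <- function(cell) {
  if (is.null(cell)) "" else as.character(cell)
}

# a column sorts numerically iff every non-empty stringified cell parses as
# a finite number (so "10" orders after "2")
numericColumn <- function(values) {
  nonEmpty <- values[nzchar(values)]
  if (length(nonEmpty) == 0L) return(FALSE)
  suppressWarnings(all(is.finite(as.numeric(nonEmpty))))
}

#' Table search semantics (server-side twin)
#'
#' The reference implementation of the embedded table widget's search:
#' case-insensitive substring match over the stringified cells of each row.
#' The browser-side script embedded by [renderTable()] implements exactly
#' these semantics; this twin makes them testable without a browser.
#'
#' @param rows list of rows (each a list of cells).
#' @param query search string; the empty string keeps every row.
#' @return the surviving rows, in input order.
#' @export
tableSearch <- function(rows, query) {
  if (!nzchar(query)) return(rows)
  q <- tolower(query)
  keep <- vapply(rows, function(row)
    any(grepl(q, tolower(vapply(row, stringifyCell, character(1))),
              fixed = TRUE)), logical(1))
  rows[keep]
}

#' Table per-column filter semantics (server-side twin)
#'
#' Case-insensitive substring match restricted to one column.
#'
#' @param rows list of rows.
#' @param column 1-based column index.
#' @param query filter string; empty keeps every row.
#' @return the surviving rows, in input order.
#' @export
tableFilter <- function(rows, column, query) {
  if (!nzchar(query)) return(rows)
  q <- tolower(query)
  keep <- vapply(rows, function(row)
    grepl(q, tolower(stringifyCell(row[[column]])), fixed = TRUE),
    logical(1))
  rows[keep]
}

#' Table sort semantics (server-side twin)
#'
#' Sorts rows by one column. A column whose non-empty stringified cells all
#' parse as finite numbers sorts numerically (so `"10"` orders after
#' `"2"`); any other column sorts lexicographically (C locale). Ties keep
#' input order (stable sort); empty cells sort last in ascending order.
#'
#' @param rows list of rows.
#' @param column 1-based column index.
#' @param decreasing logical sort direction.
#' @return the reordered rows.
#' @export
tableSort <- function(rows, column, decreasing = FALSE) {
  if (length(rows) == 0L) return(rows)
  values <- vapply(rows, function(row) stringifyCell(row[[column]]),
                   character(1))
  if (numericColumn(values)) {
    keys <- suppressWarnings(as.numeric(values))
    keys[!nzchar(values)] <- if (decreasing) -Inf else Inf
    ord <- order(keys, decreasing = decreasing)
  } else {
    empty <- !nzchar(values)
    ord <- order(empty != decreasing, method = "radix",
                 if (decreasing) -xtfrm(values) else xtfrm(values))
  }
  rows[ord]
}

# browser-side table widget; mirrors tableSearch/tableFilter/tableSort
.tableScript <- paste(
  "function ppCellStr(c){return c===null||c===undefined?'':String(c);}",
  "function ppNumericCol(rows,j){var seen=false;for(var i=0;i<rows.length;i++){",
  " var v=ppCellStr(rows[i][j]);if(v===''){continue;}seen=true;",
  " if(!isFinite(Number(v))){return false;}}return seen;}",
  "function ppInitTable(id){",
  " var data=JSON.parse(document.getElementById(id+'-data').textContent);",
  " var state={page:0,query:'',filters:{},sortCol:-1,sortDesc:false};",
  " var root=document.getElementById(id+'-widget');",
  " function visibleRows(){",
  "  var rows=data.rows.slice();",
  "  if(state.query!==''){var q=state.query.toLowerCase();",
  "   rows=rows.filter(function(r){return r.some(function(c){",
  "    return ppCellStr(c).toLowerCase().indexOf(q)>=0;});});}",
  "  Object.keys(state.filters).forEach(function(j){var q=state.filters[j].toLowerCase();",
  "   if(q==='')return;rows=rows.filter(function(r){",
  "    return ppCellStr(r[j]).toLowerCase().indexOf(q)>=0;});});",
  "  if(state.sortCol>=0){var j=state.sortCol;var num=ppNumericCol(rows,j);",
  "   rows=rows.map(function(r,i){return [r,i];});",
  "   rows.sort(function(a,b){var x=ppCellStr(a[0][j]),y=ppCellStr(b[0][j]);",
  "    var c;if(num){var nx=x===''?Infinity:Number(x),ny=y===''?Infinity:Number(y);",
  "     c=nx<ny?-1:nx>ny?1:0;}else{c=x<y?-1:x>y?1:0;}",
  "    if(state.sortDesc){c=-c;}return c!==0?c:a[1]-b[1];});",
  "   rows=rows.map(function(p){return p[0];});}",
  "  return rows;}",
  " function render(){",
  "  var rows=visibleRows();var ps=data.page_size;",
  "  var pages=Math.max(1,Math.ceil(rows.length/ps));",
  "  if(state.page>=pages){state.page=pages-1;}",
  "  var body=root.querySelector('tbody');body.innerHTML='';",
  "  rows.slice(state.page*ps,(state.page+1)*ps).forEach(function(r){",
  "   var tr=document.createElement('tr');r.forEach(function(c){",
  "    var td=document.createElement('td');td.textContent=ppCellStr(c);",
  "    tr.appendChild(td);});body.appendChild(tr);});",
  "  root.querySelector('.pp-page-info').textContent=",
  "   (state.page+1)+' / '+pages+' ('+rows.length+' rows)';}",
  " root.querySelectorAll('th').forEach(function(th,j){",
  "  if(data.sortable){th.addEventListener('click',function(){",
  "   if(state.sortCol===j){state.sortDesc=!state.sortDesc;}",
  "   else{state.sortCol=j;state.sortDesc=false;}render();});}});",
  " root.querySelectorAll('.pp-col-filter').forEach(function(inp,j){",
  "  inp.addEventListener('input',function(){state.filters[j]=inp.value;",
  "   state.page=0;render();});});",
  " var search=root.querySelector('.pp-search');",
  " if(search){search.addEventListener('input',function(){",
  "  state.query=search.value;state.page=0;render();});}",
  " root.querySelector('.pp-prev').addEventListener('click',function(){",
  "  if(state.page>0){state.page--;render();}});",
  " root.querySelector('.pp-next').addEventListener('click',function(){",
  "  state.page++;render();});",
  " render();}",
  sep = "\n")

#' Render a table component to an HTML fragment
#'
#' All row data is embedded in the document (as a JSON script element and
#' as static table rows, so the table is readable without JavaScript); a
#' small embedded script drives pagination through `page_size` rows,
#' case-insensitive substring search across all cells, per-column sort
#' (numeric-looking columns sort numerically) and per-column substring
#' filters. The search/sort/filter semantics are exactly those of
#' [tableSearch()], [tableSort()] and [tableFilter()].
#'
#' @param payload validated table payload (see [parsePageSpec()]).
#' @param id container element id.
#' @return single character string of HTML.
#' @export
renderTable <- function(payload, id = "table") {
  head <- paste0("<th>", escapeHtml(payload$columns), "</th>",
                 collapse = "")
  filters <- if (isTRUE(payload$filterable))
    paste0("<tr class=\"pp-filters\">",
           strrep("<td><input class=\"pp-col-filter\" placeholder=\"filter\"/></td>",
                  length(payload$columns)),
           "</tr>")
  else ""
  bodyRows <- vapply(payload$rows, function(row)
    paste0("<tr>", paste0("<td>",
                          escapeHtml(vapply(row, stringifyCell, character(1))),
                          "</td>", collapse = ""), "</tr>"),
    character(1))
  search <- if (isTRUE(payload$searchable))
    "<input class=\"pp-search\" type=\"search\" placeholder=\"search\"/>"
  else ""
  data <- list(columns = as.list(payload$columns), rows = payload$rows,
               page_size = payload$page_size,
               sortable = isTRUE(payload$sortable))
  paste0(
    "<script type=\"application/json\" id=\"", id, "-data\">",
    embedJSON(data), "</script>\n",
    "<div class=\"pp-table\" id=\"", id, "-widget\">\n", search,
    "<table>\n<thead><tr>", head, "</tr>", filters, "</thead>\n<tbody>\n",
    paste(bodyRows, collapse = "\n"),
    "\n</tbody>\n</table>\n",
    "<div class=\"pp-pager\"><button class=\"pp-prev\">&#8249;</button> ",
    "<span class=\"pp-page-info\"></span> ",
    "<button class=\"pp-next\">&#8250;</button></div>\n</div>\n",
    "<script>ppInitTable(\"", id, "\");</script>\n")
}

# residue span with secondary-structure class; gaps get the neutral style
residueSpan <- function(char, state) {
  cls <- if (char == "-" || !state %in% c("H", "E", "T", "C")) "ss-gap"
         else paste0("ss-", state)
  paste0("<span class=\"", cls, "\">", escapeHtml(char), "</span>")
}

#' Render a pairwise alignment colored by secondary structure
#'
#' Fixed-width, line-wrapped display (`width` columns per line) of a
#' pairwise alignment: each residue is wrapped in a span styled by its
#' secondary structure state (helices and strands highlighted; turns, coil
#' and gaps in the neutral style), with the author residue number of the
#' first residue in each line annotated at the line start and a midline
#' marking identical columns.
#'
#' @param aln an [AlignmentResult-class].
#' @param tracks gapped secondary structure pair from [alignedSSTracks()].
#' @param idA,idB display names of the two sides.
#' @param numbersA,numbersB author residue numbers, one per (ungapped)
#'   residue of each side; defaults to 1-based positions.
#' @param colors a [colorScheme()] list.
#' @param width columns per wrapped line block.
#' @return single character string of HTML.
#' @export
renderPairAlignment <- function(aln, tracks, idA = "a", idB = "b",
                                numbersA = NULL, numbersB = NULL,
                                colors = colorScheme(), width = 60L) {
  ca <- chars(aln@alignedA)
  cb <- chars(aln@alignedB)
  sa <- chars(tracks$a)
  sb <- chars(tracks$b)
  stopifnot(length(sa) == length(ca), length(sb) == length(cb))
  if (is.null(numbersA))
    numbersA <- seq_len(nchar(gsub("-", "", aln@alignedA, fixed = TRUE)))
  if (is.null(numbersB))
    numbersB <- seq_len(nchar(gsub("-", "", aln@alignedB, fixed = TRUE)))
  lineStart <- function(map, numbers, idx) {
    res <- map[idx]
    res <- res[!is.na(res)]
    if (length(res) == 0L) "" else as.character(numbers[res[1L] + 1L])
  }
  blocks <- vapply(wrapIndices(length(ca), width), function(idx) {
    startA <- lineStart(aln@columnMap[, "a"], numbersA, idx)
    startB <- lineStart(aln@columnMap[, "b"], numbersB, idx)
    mid <- paste(ifelse(ca[idx] != "-" & ca[idx] == cb[idx], "|", " "),
                 collapse = "")
    paste0(
      "<div class=\"aln-block\">",
      "<div class=\"aln-row\"><span class=\"aln-id\">", escapeHtml(idA),
      "</span><span class=\"aln-num\">", startA, "</span><span class=\"aln-seq\">",
      paste(mapply(residueSpan, ca[idx], sa[idx]), collapse = ""),
      "</span></div>",
      "<div class=\"aln-row aln-mid\"><span class=\"aln-id\"></span>",
      "<span class=\"aln-num\"></span><span class=\"aln-seq\">",
      escapeHtml(mid), "</span></div>",
      "<div class=\"aln-row\"><span class=\"aln-id\">", escapeHtml(idB),
      "</span><span class=\"aln-num\">", startB, "</span><span class=\"aln-seq\">",
      paste(mapply(residueSpan, cb[idx], sb[idx]), collapse = ""),
      "</span></div></div>")
  }, character(1))
  stats <- sprintf(
    "<p class=\"aln-stats\">score %g; identity %.1f%%; %d columns</p>",
    aln@score, 100 * percentIdentity(aln), length(ca))
  paste0("<div class=\"pp-alignment\">", stats,
         paste(blocks, collapse = "\n"), "</div>\n")
}

#' Render a sequence view
#'
#' 60 residues per line with position numbers; a per-residue numeric track,
#' when present, is rendered as a line plot beneath the sequence.
#'
#' @param payload validated sequence payload.
#' @param id container element id.
#' @param width residues per line.
#' @return single character string of HTML.
#' @export
renderSequence <- function(payload, id = "sequence", width = 60L) {
  cc <- chars(payload$sequence)
  blocks <- vapply(wrapIndices(length(cc), width), function(idx)
    paste0("<div class=\"seq-row\"><span class=\"aln-num\">", idx[1L],
           "</span><span class=\"aln-seq\">",
           escapeHtml(paste(cc[idx], collapse = "")), "</span></div>"),
    character(1))
  trackHtml <- ""
  if (!is.null(payload$track)) {
    trackHtml <- renderPlot(
      list(traces = list(list(x = as.list(seq_along(cc)),
                              y = payload$track,
                              name = payload$track_name, mode = "lines")),
           layout = list(title = paste0(payload$id, ": ",
                                        payload$track_name),
                         xaxis = "residue", yaxis = payload$track_name)),
      id = paste0(id, "-track"))
  }
  paste0("<div class=\"pp-sequence\"><h4>", escapeHtml(payload$id),
         " (", length(cc), " aa)</h4>\n",
         paste(blocks, collapse = "\n"), "</div>\n", trackHtml)
}

#' Render a multiple sequence alignment view
#'
#' Display-only rendering of precomputed, equal-length gapped sequences,
#' wrapped at `width` columns with one row per sequence in each block.
#'
#' @param payload validated MSA payload.
#' @param id container element id.
#' @param width columns per block.
#' @return single character string of HTML.
#' @export
renderMsa <- function(payload, id = "msa", width = 60L) {
  mat <- lapply(payload$sequences, chars)
  ncols <- length(mat[[1L]])
  blocks <- vapply(wrapIndices(ncols, width), function(idx)
    paste0("<div class=\"msa-block\">",
           paste(vapply(seq_along(payload$ids), function(i)
             paste0("<div class=\"aln-row\"><span class=\"aln-id\">",
                    escapeHtml(payload$ids[i]),
                    "</span><span class=\"aln-seq\">",
                    escapeHtml(paste(mat[[i]][idx], collapse = "")),
                    "</span></div>"), character(1)), collapse = ""),
           "</div>"),
    character(1))
  paste0("<div class=\"pp-msa\">", paste(blocks, collapse = "\n"),
         "</div>\n")
}

#' Render an embedded 3D structure viewer
#'
#' A single shared viewer stage plus an initialization script that loads
#' every PDB source from the pinned CDN 3D viewer; multiple sources render
#' in one stage with distinct colors.
#'
#' @param payload validated structure payload (sources possibly rewritten
#'   to output-relative paths by the build step).
#' @param id container element id.
#' @return single character string of HTML.
#' @export
renderStructure <- function(payload, id = "structure") {
  palette <- c("royalblue", "tomato", "mediumseagreen", "orange", "orchid")
  loads <- vapply(seq_along(payload$sources), function(i) sprintf(
    "stage.loadFile(%s, {ext: \"pdb\"}).then(function(c){c.addRepresentation(\"cartoon\", {color: %s});c.autoView();});",
    embedJSON(payload$sources[[i]]),
    embedJSON(palette[(i - 1L) %% length(palette) + 1L])),
    character(1))
  paste0("<div class=\"pp-structure\" id=\"", id,
         "-stage\" style=\"width:100%;height:420px;\"></div>\n",
         "<script>(function(){var stage=new NGL.Stage(\"", id,
         "-stage\", {backgroundColor: \"white\"});\n",
         paste(loads, collapse = "\n"), "})();</script>\n")
}

#' Render an embedded network view
#'
#' Node and edge data serialized into the document in element-list form and
#' handed to the pinned CDN network renderer.
#'
#' @param payload validated network payload.
#' @param id container element id.
#' @return single character string of HTML.
#' @export
renderNetwork <- function(payload, id = "network") {
  elements <- c(
    lapply(payload$nodes, function(n)
      list(data = list(id = n$id, label = n$label))),
    lapply(payload$edges, function(e)
      list(data = dropNulls(list(source = e$source, target = e$target,
                                 label = e$label, weight = e$weight)))))
  paste0(
    "<script type=\"application/json\" id=\"", id, "-data\">",
    embedJSON(elements), "</script>\n",
    "<div class=\"pp-network\" id=\"", id,
    "-stage\" style=\"width:100%;height:360px;\"></div>\n",
    "<script>cytoscape({container: document.getElementById(\"", id,
    "-stage\"), elements: JSON.parse(document.getElementById(\"", id,
    "-data\").textContent), layout: {name: \"cose\"}, style: [",
    "{selector: \"node\", style: {label: \"data(label)\"}},",
    "{selector: \"edge\", style: {\"curve-style\": \"bezier\"}}",
    "]});</script>\n")
}

#' Render an embedded plot
#'
#' Trace and layout data serialized into the document and handed to the
#' pinned CDN plot renderer.
#'
#' @param payload validated plot payload.
#' @param id container element id.
#' @return single character string of HTML.
#' @export
renderPlot <- function(payload, id = "plot") {
  traces <- lapply(payload$traces, function(tr)
    list(x = tr$x, y = as.list(tr$y), name = tr$name, mode = tr$mode,
         type = "scatter"))
  layout <- list(title = payload$layout$title,
                 xaxis = list(title = payload$layout$xaxis),
                 yaxis = list(title = payload$layout$yaxis))
  paste0(
    "<script type=\"application/json\" id=\"", id, "-data\">",
    embedJSON(list(data = traces, layout = layout)), "</script>\n",
    "<div class=\"pp-plot\" id=\"", id,
    "-stage\" style=\"width:100%;height:360px;\"></div>\n",
    "<script>(function(){var fig=JSON.parse(document.getElementById(\"", id,
    "-data\").textContent);Plotly.newPlot(\"", id,
    "-stage\", fig.data, fig.layout, {displaylogo: false});})();</script>\n")
}

# resolve one side of a PDB-backed pair alignment into sequence, secondary
# structure and author residue numbers
resolveAlignmentSide <- function(side, templates) {
  if (side$type == "inline") {
    n <- nchar(side$sequence)
    list(id = side$id, sequence = side$sequence,
         ss = if (is.null(side$ss)) strrep("C", n) else side$ss,
         numbers = seq_len(n))
  } else {
    text <- if (isURL(side$pdb)) {
      fetchText(side$pdb)
    } else {
      if (!grepl("\n", side$pdb, fixed = TRUE) && !file.exists(side$pdb))
        stop(sprintf("no such PDB file: %s", side$pdb))
      side$pdb
    }
    chains <- parsePDB(text)
    chain <- if (!is.null(side$chain)) {
      if (!side$chain %in% names(chains))
        stop(sprintf("chain '%s' not found in %s (chains: %s)", side$chain,
                     side$pdb, paste(names(chains), collapse = ", ")))
      chains[[side$chain]]
    } else {
      if (length(chains) > 1L)
        ppLog("info", sprintf("no chain given for %s; using first chain '%s'",
                              side$pdb, names(chains)[1L]))
      chains[[1L]]
    }
    list(id = side$id, sequence = chainSequence(chain),
         ss = chainSecondaryStructure(chain, templates),
         numbers = residueNumbers(chain))
  }
}

#' Resolve and render a PDB-backed pair alignment component
#'
#' Pulls both sides into sequence + secondary structure form (extracting
#' sequences from PDB files and assigning secondary structure from their
#' CA traces where a side is PDB-backed), computes the global alignment
#' under the component's substitution matrix, and renders it colored by
#' secondary structure. With `show_structures` and PDB sources present, a
#' shared structure stage follows the alignment.
#'
#' @param payload validated pair-alignment payload.
#' @param id container element id.
#' @param colors a [colorScheme()] list.
#' @param templates a [DistanceTemplates-class].
#' @param g a [GapPenalties-class].
#' @param sourceMap optional named character vector rewriting PDB sources
#'   to output-relative paths for the embedded viewer.
#' @return single character string of HTML.
#' @export
renderPairAlignmentComponent <- function(payload, id = "pair",
                                         colors = colorScheme(),
                                         templates = distanceTemplates(),
                                         g = gapPenalties(),
                                         sourceMap = character(0)) {
  m <- loadMatrix(payload$matrix_name)
  a <- resolveAlignmentSide(payload$side_a, templates)
  b <- resolveAlignmentSide(payload$side_b, templates)
  aln <- globalAlign(a$sequence, b$sequence, m, g)
  tracks <- alignedSSTracks(aln, a$ss, b$ss)
  html <- renderPairAlignment(aln, tracks, idA = a$id, idB = b$id,
                              numbersA = a$numbers, numbersB = b$numbers,
                              colors = colors)
  if (isTRUE(payload$show_structures)) {
    sources <- c(if (payload$side_a$type == "pdb") payload$side_a$pdb,
                 if (payload$side_b$type == "pdb") payload$side_b$pdb)
    if (length(sources) > 0L) {
      mapped <- ifelse(sources %in% names(sourceMap), sourceMap[sources],
                       sources)
      html <- paste0(html, renderStructure(
        list(sources = unname(mapped), labels = c(a$id, b$id)),
        id = paste0(id, "-structures")))
    }
  }
  html
}

.pageCSS <- paste(
  "body{font-family:system-ui,sans-serif;max-width:960px;margin:2em auto;",
  " padding:0 1em;color:#222;}",
  "h1.pp-title{border-bottom:2px solid #ddd;padding-bottom:0.3em;}",
  "nav.pp-toc ol{columns:2;}",
  "section.pp-component{margin:2em 0;padding-top:0.5em;",
  " border-top:1px solid #eee;}",
  ".aln-seq,.seq-row,.msa-block{font-family:ui-monospace,monospace;",
  " white-space:pre;}",
  ".aln-row{display:flex;}",
  ".aln-id{width:8em;overflow:hidden;text-overflow:ellipsis;}",
  ".aln-num{width:4em;text-align:right;padding-right:1em;color:#888;}",
  ".aln-block,.msa-block{margin-bottom:1em;}",
  ".pp-table table{border-collapse:collapse;width:100%;}",
  ".pp-table th{cursor:pointer;background:#f5f5f5;}",
  ".pp-table th,.pp-table td{border:1px solid #ddd;padding:0.3em 0.5em;}",
  ".pp-error{border:1px solid #c00;background:#fee;padding:1em;}",
  sep = "\n")

ssCSS <- function(colors) {
  paste0(
    ".ss-H{background:", colors$H, ";color:#fff;}\n",
    ".ss-E{background:", colors$E, ";color:#222;}\n",
    ".ss-T{background:", colors$T, ";}\n",
    ".ss-C{background:", colors$C, ";}\n",
    ".ss-gap{color:#888;}\n")
}

.componentTitles <- c(
  markdown = "Text", table = "Table", sequence = "Sequence",
  msa = "Multiple sequence alignment", pair_alignment = "Pair alignment",
  structure = "Structure", network = "Network", plot = "Plot")

renderComponentDispatch <- function(cc, id, colors, templates, g,
                                    sourceMap) {
  payload <- cc@payload
  switch(cc@kind,
    markdown = renderMarkdown(payload$text),
    table = renderTable(payload, id = id),
    sequence = renderSequence(payload, id = id),
    msa = renderMsa(payload, id = id),
    pair_alignment = renderPairAlignmentComponent(
      payload, id = id, colors = colors, templates = templates, g = g,
      sourceMap = sourceMap),
    structure = {
      mapped <- ifelse(payload$sources %in% names(sourceMap),
                       sourceMap[payload$sources], payload$sources)
      renderStructure(list(sources = unname(mapped),
                           labels = payload$labels), id = id)
    },
    network = renderNetwork(payload, id = id),
    plot = renderPlot(payload, id = id),
    stop(sprintf("no renderer for kind '%s'", cc@kind)))   # unreachable for
                                                           # schema-valid specs
}

#' @describeIn renderPage renders a validated [PageSpec-class] into one
#'   self-contained HTML document. Components appear in source order, each
#'   in a uniquely-anchored container (`component-1`, `component-2`, ...
#'   ids derive from the component index, never from randomness, so
#'   rendering is byte-deterministic), preceded by a generated table of
#'   contents. A component whose resolution fails (e.g. an unreachable or
#'   unparsable PDB source) renders as a visible error panel and the page
#'   still builds.
#'
#' @param templates [DistanceTemplates-class] for PDB-backed alignments.
#' @param g [GapPenalties-class] for PDB-backed alignments.
#' @param sourceMap named character vector rewriting local PDB sources to
#'   output-relative copies (used by [buildSite()]).
#' @export
setMethod("renderPage", "PageSpec", function(spec,
                                             templates = distanceTemplates(),
                                             g = gapPenalties(),
                                             sourceMap = character(0),
                                             ...) {
  colors <- colorScheme(spec@colors)
  assets <- pinnedAssets()
  kinds <- vapply(spec@components, componentKind, character(1))
  needed <- c(ngl = any(kinds %in% c("structure", "pair_alignment")),
              cytoscape = any(kinds == "network"),
              plotly = any(kinds %in% c("plot", "sequence")))
  usedAssets <- assets[names(needed)[needed]]
  scriptTags <- paste0("<script src=\"", usedAssets, "\"></script>",
                       collapse = "\n")
  sections <- character(length(spec@components))
  failures <- character(0)
  for (i in seq_along(spec@components)) {
    cc <- spec@components[[i]]
    id <- sprintf("component-%d", i)
    body <- tryCatch(
      renderComponentDispatch(cc, id, colors, templates, g, sourceMap),
      error = function(e) {
        failures <<- c(failures, sprintf("%s: %s", id, conditionMessage(e)))
        paste0("<div class=\"pp-error\"><strong>Component ", i, " (",
               escapeHtml(cc@kind), ") failed:</strong> ",
               escapeHtml(conditionMessage(e)), "</div>\n")
      })
    sections[i] <- paste0(
      "<section class=\"pp-component\" id=\"", id, "\">\n<h2>", i, ". ",
      escapeHtml(.componentTitles[[cc@kind]]), "</h2>\n", body,
      "</section>\n")
  }
  toc <- paste0(
    "<nav class=\"pp-toc\"><ol>\n",
    paste0("<li><a href=\"#component-", seq_along(kinds), "\">",
           escapeHtml(.componentTitles[kinds]), "</a></li>",
           collapse = "\n"),
    "\n</ol></nav>\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<meta name=\"viewport\" content=\"width=device-width, initial-scale=1\"/>\n",
    "<title>", escapeHtml(spec@title), "</title>\n",
    scriptTags, "\n",
    "<style>\n", .pageCSS, "\n", ssCSS(colors), "</style>\n",
    "<script>\n", .tableScript, "\n</script>\n",
    "</head>\n<body>\n<h1 class=\"pp-title\">", escapeHtml(spec@title),
    "</h1>\n", toc,
    paste(sections, collapse = "\n"),
    "</body>\n</html>\n")
  page <- new("RenderedPage", html = html, assets = unname(usedAssets))
  attr(page, "failures") <- failures
  page
})

#' HTML of a rendered page
#'
#' @param page a [RenderedPage-class].
#' @return single character string: the full HTML document.
#' @export
pageHTML <- function(page) page@html

#' Third-party assets of a rendered page
#'
#' @param page a [RenderedPage-class].
#' @return character vector of pinned asset URLs.
#' @export
pageAssets <- function(page) page@assets

setMethod("show", "RenderedPage", function(object) {
  cat(sprintf("RenderedPage: %d characters of HTML, %d third-party asset(s)\n",
              nchar(object@html), length(object@assets)))
})
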