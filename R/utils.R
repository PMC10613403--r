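# internal helpers shared across modules

# escape text for insertion into HTML element content or attribute values
escapeHtml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&#39;", x, fixed = TRUE)
}

# split a string into single characters
chars <- function(x) {
  if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1]]
}

# wrap 1..n into blocks of `width`, returning a list of index vectors
wrapIndices <- function(n, width) {
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = width)
  lapply(starts, function(s) seq.int(s, min(s + width - 1L, n)))
}

.logLevels <- c(quiet = 0L, info = 1L, debug = 2L)

# all log output goes to stderr; stdout is reserved for machine-readable
# report lines
ppLog <- function(level, ..., threshold = getOption("protpage.logLevel", "info")) {
  if (.logLevels[[level]] <= .logLevels[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

# condition constructors: validation errors carry the JSON path of the
# offending key so callers (and page authors) can locate the problem
ppValidationError <- function(path, msg) {
  stop(structure(
    class = c("protpage_validation_error", "error", "condition"),
    list(message = sprintf("%s: %s", path, msg), call = NULL,
         jsonPath = path)))
}

ppParseError <- function(msg) {
  stop(structure(
    class = c("protpage_parse_error", "error", "condition"),
    list(message = msg, call = NULL)))
}

ppFetchError <- function(msg, status = NA_integer_) {
  stop(structure(
    class = c("protpage_fetch_error", "error", "condition"),
    list(message = msg, call = NULL, status = status)))
}

isURL <- function(x) grepl("^https?://", x)
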