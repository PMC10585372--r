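#' Canonical JSON serialisation
#'
#' The canonical interchange format consumed and produced by every module.
#' Schema `nereid-dataset/1`: a `characters` array (number, label, kind,
#' states, unit, reliability, dependencies, section) and a `taxa` array
#' (name, authority, metadata, attributes with status RECORDED / UNKNOWN /
#' INAPPLICABLE).  UNKNOWN cells are omitted on write and restored on read.
#'
#' @param ds a [dataset()].
#' @param path file path; for [dataset_to_json()] `NULL` returns the JSON
#'   string instead of writing.
#' @return [dataset_to_json()]: the path (or JSON string, invisibly);
#'   [dataset_from_json()]: a [dataset()].
#' @export
dataset_to_json <- function(ds, path = NULL) {
  chars <- lapply(ds$characters, function(ch) {
    out <- list(number = ch$number, label = ch$label, kind = ch$kind)
    if (ch$kind == "multistate") out$states <- as.list(ch$states)
    if (nzchar(ch$unit)) out$unit <- ch$unit
    if (ch$reliability != 5) out$reliability <- ch$reliability
    if (length(ch$dependencies)) out$dependencies <- ch$dependencies
    if (nzchar(ch$section)) out$section <- ch$section
    out
  })
  taxa <- lapply(ds$taxa, function(tx) {
    attrs <- list()
    for (nm in names(tx$attributes)) {
      a <- tx$attributes[[nm]]
      rec <- list(char = as.integer(nm), status = a$status)
      if (!is.null(a$states)) rec$states <- a$states
      if (!is.null(a$range)) rec$range <- a$range
      if (nzchar(a$comment)) rec$comment <- a$comment
      attrs[[length(attrs) + 1L]] <- rec
    }
    out <- list(name = tx$name, authority = tx$authority, attributes = attrs)
    if (length(tx$metadata)) out$metadata <- tx$metadata
    out
  })
  obj <- list(schema = "nereid-dataset/1", title = ds$title,
              characters = chars, taxa = unname(taxa))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname dataset_to_json
#' @param text JSON string (alternative to `path`).
#' @export
dataset_from_json <- function(path = NULL, text = NULL) {
  obj <- jsonlite::fromJSON(if (is.null(text)) path else text,
                            simplifyVector = FALSE)
  if (!identical(obj$schema, "nereid-dataset/1")) {
    stop("unrecognised dataset schema: ", obj$schema, call. = FALSE)
  }
  chars <- lapply(obj$characters, function(ch) {
    character_def(ch$number, ch$label, ch$kind,
                  states = unlist(ch$states) %||% character(),
                  unit = ch$unit %||% "",
                  reliability = ch$reliability %||% 5,
                  dependencies = lapply(ch$dependencies %||% list(), function(d)
                    list(controller = as.integer(d$controller),
                         states = as.integer(unlist(d$states)))),
                  section = ch$section %||% "")
  })
  taxa <- lapply(obj$taxa, function(tx) {
    attrs <- list()
    for (rec in tx$attributes) {
      a <- switch(rec$status,
        RECORDED = if (!is.null(rec$states))
            attr_states(unlist(rec$states), comment = rec$comment %||% "")
          else
            attr_range(rec$range[[1]], rec$range[[2]],
                       comment = rec$comment %||% ""),
        UNKNOWN = attr_unknown(comment = rec$comment %||% ""),
        INAPPLICABLE = attr_inapplicable(comment = rec$comment %||% ""),
        stop("bad attribute status: ", rec$status, call. = FALSE))
      attrs[[as.character(rec$char)]] <- a
    }
    taxon_record(tx$name, tx$authority %||% "", attrs,
                 metadata = tx$metadata %||% list())
  })
  dataset(chars, taxa, title = obj$title %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
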