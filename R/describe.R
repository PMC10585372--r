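#' Description style
#'
#' Controls the rendering of natural-language descriptions: descriptions are
#' concatenations of the states recorded for a taxon, traversed in
#' character-number order, with alternative states of a polymorphic cell
#' joined by `polymorphism_joiner` ("present, or absent").
#'
#' @param include_comments append cell comments parenthetically.
#' @param section_headings emit a heading line when the character section
#'   changes.
#' @param polymorphism_joiner text between alternative states.
#' @param sentence_terminator text after each character sentence.
#' @return A list of class `nereid_style`.
#' @export
description_style <- function(include_comments = FALSE,
                              section_headings = FALSE,
                              polymorphism_joiner = ", or ",
                              sentence_terminator = ". ") {
  stopifnot(nzchar(polymorphism_joiner))
  structure(list(include_comments = include_comments,
                 section_headings = section_headings,
                 polymorphism_joiner = polymorphism_joiner,
                 sentence_terminator = sentence_terminator),
            class = "nereid_style")
}

fmt_value <- function(x) {
  sub("\\.0+$", "", format(x, scientific = FALSE, trim = TRUE))
}

#' Natural-language description of one taxon
#'
#' Renders every RECORDED attribute as "<character label> <state label>"
#' (alternatives joined by the style's joiner) or, for numeric characters,
#' "<character label> <lo>[-<hi>] <unit>".  UNKNOWN and INAPPLICABLE cells
#' are omitted, so every state phrase in the output is traceable to a
#' recorded state.  Identical inputs yield byte-identical text.
#'
#' @param ds a [dataset()].
#' @param taxon taxon name.
#' @param style a [description_style()].
#' @return A single string (possibly empty).
#' @export
describe_taxon <- function(ds, taxon, style = description_style()) {
  tx <- get_taxon(ds, taxon)
  parts <- character()
  last_section <- NULL
  for (ch in ds$characters) {
    a <- get_attribute(tx, ch$number)
    if (!is_recorded(a)) next
    if (style$section_headings && !identical(ch$section, last_section) &&
        nzchar(ch$section)) {
      parts <- c(parts, paste0("\n[", ch$section, "]\n"))
      last_section <- ch$section
    }
    body <- if (!is.null(a$states)) {
      paste0(ch$label, " ",
             paste(ch$states[a$states], collapse = style$polymorphism_joiner))
    } else {
      rng <- if (a$range[1] == a$range[2]) fmt_value(a$range[1]) else
        paste0(fmt_value(a$range[1]), "–", fmt_value(a$range[2]))
      paste0(ch$label, " ", rng,
             if (nzchar(ch$unit)) paste0(" ", ch$unit) else "")
    }
    if (style$include_comments && nzchar(a$comment)) {
      body <- paste0(body, " (", a$comment, ")")
    }
    parts <- c(parts, paste0(body, style$sentence_terminator))
  }
  trimws(paste(parts, collapse = ""))
}

#' Descriptions for every taxon
#'
#' @inheritParams describe_taxon
#' @return Named character vector, one description per taxon, ordered by
#'   taxon name.
#' @export
describe_dataset <- function(ds, style = description_style()) {
  nms <- sort(names(ds$taxa))
  vapply(nms, function(nm) describe_taxon(ds, nm, style), character(1))
}
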