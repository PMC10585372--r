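#' Define a morphological character
#'
#' A character is either qualitative (`multistate`, with two or more ordered
#' state labels whose codes are 1-based) or quantitative (`numeric`, e.g. a
#' count or a chaetiger position, with an optional unit).  Characters may
#' declare applicability dependencies: this character can only be scored when
#' a controlling character takes one of the given states (e.g. palpostyle
#' form is only applicable when palpostyles are present).
#'
#' @param number 1-based character number, unique within a dataset.
#' @param label character label (free text).
#' @param kind `"multistate"` or `"numeric"`.
#' @param states character vector of state labels (multistate only, >= 2).
#' @param unit unit of measurement (numeric only; `""` if dimensionless).
#' @param reliability weight in `[0, 10]` used by key generation; default 5
#'   (neutral).
#' @param dependencies list of `list(controller =, states =)` entries:
#'   applicable only when `controller` takes one of `states`.
#' @param section free-text grouping heading (e.g. a body region).
#' @return An object of class `nereid_character`.
#' @export
character_def <- function(number, label, kind = c("multistate", "numeric"),
                          states = character(), unit = "", reliability = 5,
                          dependencies = list(), section = "") {
  kind <- match.arg(kind)
  number <- as.integer(number)
  stopifnot(length(number) == 1L, !is.na(number), number >= 1L,
            is.character(label), length(label) == 1L,
            is.numeric(reliability), reliability >= 0, reliability <= 10)
  if (kind == "multistate" && length(states) < 2L) {
    stop("multistate character ", number, " needs >= 2 states", call. = FALSE)
  }
  if (kind == "numeric" && length(states) > 0L) {
    stop("numeric character ", number, " must not declare states", call. = FALSE)
  }
  structure(list(number = number, label = label, kind = kind,
                 states = as.character(states), unit = unit,
                 reliability = as.numeric(reliability),
                 dependencies = dependencies, section = section),
            class = "nereid_character")
}

#' Attribute constructors
#'
#' An attribute is one cell of the matrix: the scoring of one taxon for one
#' character.  It is either `RECORDED` (a non-empty set of state codes for a
#' multistate character, or a closed interval for a numeric character),
#' `UNKNOWN` (not scored), or `INAPPLICABLE` (cannot logically be scored
#' because a controlling character excludes it).  A multistate attribute
#' with two or more states records polymorphism ("present, or absent").
#'
#' @param states integer vector of 1-based state codes (multistate).
#' @param lo,hi closed interval bounds (numeric); a single value is the
#'   degenerate interval `[v, v]`.
#' @param comment free-text comment carried with the cell.
#' @return An object of class `nereid_attribute`.
#' @export
attr_states <- function(states, comment = "") {
  states <- sort(unique(as.integer(states)))
  stopifnot(length(states) >= 1L, !anyNA(states), all(states >= 1L))
  structure(list(status = "RECORDED", states = states, range = NULL,
                 comment = comment), class = "nereid_attribute")
}

#' @rdname attr_states
#' @export
attr_range <- function(lo, hi = lo, comment = "") {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(is.finite(lo), is.finite(hi), lo <= hi)
  structure(list(status = "RECORDED", states = NULL, range = c(lo, hi),
                 comment = comment), class = "nereid_attribute")
}

#' @rdname attr_states
#' @export
attr_unknown <- function(comment = "") {
  structure(list(status = "UNKNOWN", states = NULL, range = NULL,
                 comment = comment), class = "nereid_attribute")
}

#' @rdname attr_states
#' @export
attr_inapplicable <- function(comment = "") {
  structure(list(status = "INAPPLICABLE", states = NULL, range = NULL,
                 comment = comment), class = "nereid_attribute")
}

is_recorded <- function(a) !is.null(a) && a$status == "RECORDED"

#' Create a taxon record
#'
#' @param name taxon name (unique within a dataset).
#' @param authority author and year string (e.g. `"Kinberg, 1865"`).
#' @param attributes named list of [attr_states()]-family objects; names are
#'   character numbers.  Characters not listed are `UNKNOWN`.
#' @param metadata opaque named character list (type species, remarks, ...).
#' @return An object of class `nereid_taxon`.
#' @export
taxon_record <- function(name, authority = "", attributes = list(),
                         metadata = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(attributes)) {
    stopifnot(!is.null(names(attributes)),
              all(grepl("^[0-9]+$", names(attributes))))
    for (a in attributes) stopifnot(inherits(a, "nereid_attribute"))
  }
  structure(list(name = name, authority = authority,
                 attributes = attributes, metadata = metadata),
            class = "nereid_taxon")
}

#' Assemble a dataset
#'
#' The dataset is the unit every algorithm consumes: an ordered character
#' list (numbers contiguous from 1) plus taxon records.
#'
#' @param characters list of [character_def()] objects, numbers 1..n.
#' @param taxa list of [taxon_record()] objects with unique names.
#' @param title dataset title.
#' @return An object of class `nereid_dataset`.
#' @export
dataset <- function(characters, taxa, title = "") {
  nums <- vapply(characters, function(c) c$number, integer(1))
  if (!identical(nums, seq_along(characters))) {
    stop("character numbers must be contiguous starting at 1", call. = FALSE)
  }
  names <- vapply(taxa, function(t) t$name, character(1))
  if (anyDuplicated(names)) {
    stop("duplicate taxon names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  # dependency sanity: acyclic, controllers exist
  dep_edges <- list()
  for (ch in characters) {
    for (d in ch$dependencies) {
      if (d$controller < 1L || d$controller > length(characters)) {
        stop("character ", ch$number, " depends on unknown character ",
             d$controller, call. = FALSE)
      }
      dep_edges[[length(dep_edges) + 1L]] <- c(d$controller, ch$number)
    }
  }
  if (length(dep_edges) && has_cycle(dep_edges, length(characters))) {
    stop("dependency graph is cyclic", call. = FALSE)
  }
  names(taxa) <- names
  structure(list(title = title, characters = characters, taxa = taxa),
            class = "nereid_dataset")
}

has_cycle <- function(edges, n) {
  adj <- vector("list", n)
  indeg <- integer(n)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    indeg[e[2]] <- indeg[e[2]] + 1L
  }
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < n
}

#' @export
print.nereid_dataset <- function(x, ...) {
  ms <- sum(vapply(x$characters, function(c) c$kind == "multistate", logical(1)))
  cat(sprintf("<nereid_dataset> %s\n  %d taxa, %d characters (%d multistate, %d numeric)\n",
              x$title, length(x$taxa), length(x$characters), ms,
              length(x$characters) - ms))
  invisible(x)
}

#' @export
print.nereid_character <- function(x, ...) {
  cat(sprintf("#%d. %s [%s]%s\n", x$number, x$label, x$kind,
              if (length(x$states)) paste0(": ",
                paste(seq_along(x$states), x$states, sep = "=", collapse = "; "))
              else ""))
  invisible(x)
}

get_taxon <- function(ds, taxon) {
  t <- ds$taxa[[taxon]]
  if (is.null(t)) stop("unknown taxon: ", taxon, call. = FALSE)
  t
}

get_character <- function(ds, number) {
  number <- as.integer(number)
  if (is.na(number) || number < 1L || number > length(ds$characters)) {
    stop("unknown character number: ", number, call. = FALSE)
  }
  ds$characters[[number]]
}

get_attribute <- function(tx, number) {
  tx$attributes[[as.character(number)]]
}

taxon_names <- function(ds) names(ds$taxa)
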