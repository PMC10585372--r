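#' Start an interactive (multi-entry) identification session
#'
#' Characters can be asserted in any order; each assertion increments a
#' mismatch count for every taxon whose recorded attribute is disjoint from
#' the observation.  Candidates are the taxa with at most `tolerance`
#' mismatches, so a single observation error need not eliminate the true
#' taxon when `tolerance >= 1`.  Taxa with UNKNOWN data never mismatch.
#'
#' @param ds a [dataset()].
#' @param tolerance non-negative integer: maximum mismatches allowed before
#'   a taxon stops being a candidate.
#' @return A list of class `nereid_session`.
#' @export
identification_session <- function(ds, tolerance = 0L) {
  tolerance <- as.integer(tolerance)
  stopifnot(tolerance >= 0L)
  structure(list(dataset = ds, tolerance = tolerance,
                 asserted = list(),
                 mismatches = stats::setNames(integer(length(ds$taxa)),
                                              names(ds$taxa))),
            class = "nereid_session")
}

recount <- function(session) {
  ds <- session$dataset
  mm <- stats::setNames(integer(length(ds$taxa)), names(ds$taxa))
  for (nm in names(session$asserted)) {
    obs <- session$asserted[[nm]]
    for (tx in names(ds$taxa)) {
      a <- get_attribute(ds$taxa[[tx]], nm)
      if (attrs_differ(a, obs)) mm[tx] <- mm[tx] + 1L
    }
  }
  session$mismatches <- mm
  session
}

#' Assert an observed character state
#'
#' @param session a [identification_session()].
#' @param char character number.
#' @param observed integer state codes observed (multistate) or a numeric
#'   value/length-2 range (numeric characters).  Re-asserting a character
#'   replaces the earlier assertion.
#' @return The updated session.
#' @export
assert_attribute <- function(session, char, observed) {
  ds <- session$dataset
  ch <- get_character(ds, char)
  obs <- if (ch$kind == "multistate") {
    observed <- as.integer(observed)
    if (anyNA(observed) || any(observed < 1L) ||
        any(observed > length(ch$states))) {
      stop("invalid state code for character ", ch$number, call. = FALSE)
    }
    attr_states(observed)
  } else {
    observed <- as.numeric(observed)
    attr_range(observed[1], observed[length(observed)])
  }
  session$asserted[[as.character(ch$number)]] <- obs
  recount(session)
}

#' Current candidate taxa
#'
#' @param session a session.
#' @return Character vector of taxa with mismatch count `<=` tolerance.
#' @export
candidates <- function(session) {
  names(session$mismatches)[session$mismatches <= session$tolerance]
}

#' Rank unasserted characters by how much they narrow the candidates
#'
#' Characters are scored by the expected number of remaining candidates
#' after observing them, under a uniform prior: a state is drawn by picking
#' a candidate uniformly and one of its recorded states uniformly;
#' candidates compatible with the drawn state (or unscored) remain.  Lower
#' is better; ties go to the lowest character number.  Characters unscored
#' for every candidate are unusable and omitted.
#'
#' @param session a session with at least two candidates (otherwise an
#'   empty ranking is returned).
#' @return data.frame with columns `character` and `expected_remaining`,
#'   best first.
#' @export
rank_characters <- function(session) {
  ds <- session$dataset
  cand <- candidates(session)
  empty <- data.frame(character = integer(), expected_remaining = numeric())
  if (length(cand) < 2L) return(empty)
  rows <- list()
  for (ch in ds$characters) {
    if (ch$kind != "multistate") next
    if (as.character(ch$number) %in% names(session$asserted)) next
    sets <- lapply(cand, function(nm) {
      a <- get_attribute(ds$taxa[[nm]], ch$number)
      if (is_recorded(a) && !is.null(a$states)) a$states else NULL
    })
    rec <- !vapply(sets, is.null, logical(1))
    if (!any(rec)) next
    states <- sort(unique(unlist(sets)))
    if (length(states) < 2L) next
    # P(state) under the uniform candidate-then-state prior
    p <- vapply(states, function(s) {
      sum(vapply(sets[rec], function(st) (s %in% st) / length(st), numeric(1)))
    }, numeric(1)) / sum(rec)
    remaining <- vapply(states, function(s) {
      sum(vapply(sets, function(st) is.null(st) || s %in% st, logical(1)))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      character = ch$number, expected_remaining = sum(p * remaining))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$expected_remaining, out$character), , drop = FALSE]
}

#' Differences between a specimen and a taxon
#'
#' The verification step after a tentative identification: lists every
#' character for which both the specimen and the taxon are RECORDED and
#' their values are disjoint.  An empty report means the specimen is
#' consistent with the taxon.
#'
#' @param specimen named list of attributes (names = character numbers),
#'   e.g. built with [attr_states()].
#' @param taxon taxon name.
#' @param ds a [dataset()].
#' @return data.frame with columns `character`, `specimen`, `taxon` (both
#'   rendered as state-code / range strings).
#' @export
differences_report <- function(specimen, taxon, ds) {
  tx <- get_taxon(ds, taxon)
  fmt <- function(a) {
    if (!is.null(a$states)) paste(a$states, collapse = "/")
    else paste(fmt_value(a$range[1]), fmt_value(a$range[2]), sep = "-")
  }
  rows <- list()
  for (nm in names(specimen)) {
    a <- specimen[[nm]]
    b <- get_attribute(tx, nm)
    if (attrs_differ(a, b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        character = as.integer(nm), specimen = fmt(a), taxon = fmt(b),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(character = integer(), specimen = character(),
                      taxon = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$character), , drop = FALSE]
}
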