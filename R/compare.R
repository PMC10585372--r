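#' Do two taxa differ for a character?
#'
#' The comparison underlying diagnosis and identification: two taxa differ
#' for a character iff both are RECORDED and their values cannot agree —
#' disjoint state sets for a multistate character, non-overlapping closed
#' intervals for a numeric one.  UNKNOWN or INAPPLICABLE on either side never
#' creates a difference (an unscored cell matches everything), so missing
#' data can never eliminate a taxon.  The relation is symmetric and
#' irreflexive over recorded attributes.
#'
#' @param ds a [dataset()].
#' @param a,b taxon names.
#' @param char character number.
#' @return `TRUE` or `FALSE`.
#' @examples
#' ds <- load_nereididae_genera()
#' differ(ds, "Hediste", "Simplisetia", 55)  # oral ring paragnaths: TRUE
#' @export
differ <- function(ds, a, b, char) {
  ta <- get_taxon(ds, a); tb <- get_taxon(ds, b)
  get_character(ds, char)  # validates the number
  attrs_differ(get_attribute(ta, char), get_attribute(tb, char))
}

attrs_differ <- function(x, y) {
  if (!is_recorded(x) || !is_recorded(y)) return(FALSE)
  if (!is.null(x$states) && !is.null(y$states)) {
    return(length(intersect(x$states, y$states)) == 0L)
  }
  if (!is.null(x$range) && !is.null(y$range)) {
    return(x$range[2] < y$range[1] || y$range[2] < x$range[1])
  }
  FALSE  # mixed payloads cannot be compared
}

#' All characters distinguishing two taxa
#'
#' @inheritParams differ
#' @return Integer vector of character numbers, ascending, for which
#'   [differ()] is `TRUE`.
#' @export
distinguishing_characters <- function(ds, a, b) {
  ta <- get_taxon(ds, a); tb <- get_taxon(ds, b)
  out <- integer()
  shared <- intersect(names(ta$attributes), names(tb$attributes))
  for (nm in shared) {
    if (attrs_differ(ta$attributes[[nm]], tb$attributes[[nm]])) {
      out <- c(out, as.integer(nm))
    }
  }
  sort(out)
}

# -- fast bitmask representation (<= 31 states per character) ----------------

#' @keywords internal
dataset_masks <- function(ds) {
  nt <- length(ds$taxa); nc <- length(ds$characters)
  mask <- matrix(0L, nt, nc, dimnames = list(names(ds$taxa), NULL))
  lo <- matrix(NA_real_, nt, nc); hi <- matrix(NA_real_, nt, nc)
  for (i in seq_len(nt)) {
    at <- ds$taxa[[i]]$attributes
    for (nm in names(at)) {
      a <- at[[nm]]; j <- as.integer(nm)
      if (a$status != "RECORDED") next
      if (!is.null(a$states)) {
        mask[i, j] <- sum(bitwShiftL(1L, a$states - 1L))
      } else {
        lo[i, j] <- a$range[1]; hi[i, j] <- a$range[2]
      }
    }
  }
  list(mask = mask, lo = lo, hi = hi)
}

# logical matrix D[rival, char]: does `rival` differ from taxon row `i0`?
differ_matrix <- function(m, i0) {
  nt <- nrow(m$mask)
  base <- m$mask[rep(i0, nt), , drop = FALSE]
  d <- base > 0L & m$mask > 0L & bitwAnd(base, m$mask) == 0L
  blo <- m$lo[rep(i0, nt), , drop = FALSE]; bhi <- m$hi[rep(i0, nt), , drop = FALSE]
  dn <- !is.na(blo) & !is.na(m$lo) & (bhi < m$lo | m$hi < blo)
  out <- d | dn
  rownames(out) <- rownames(m$mask)
  out
}

#' Validate a dataset
#'
#' Report-based validation: lists state-code violations (a recorded state
#' outside the character's declared states), applicability violations (a
#' dependent character RECORDED although its controlling character is
#' recorded at a state that excludes it), duplicate names, and count
#' summaries.  A valid dataset yields an empty violation list.
#'
#' @param ds a [dataset()].
#' @return A list of class `nereid_validation` with elements `violations`
#'   (data.frame: taxon, character, type, detail) and `counts`.
#' @export
validate_dataset <- function(ds) {
  v <- list()
  add <- function(taxon, char, type, detail) {
    v[[length(v) + 1L]] <<- data.frame(taxon = taxon, character = char,
                                       type = type, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  for (tx in ds$taxa) {
    for (nm in names(tx$attributes)) {
      a <- tx$attributes[[nm]]
      j <- as.integer(nm)
      if (j < 1L || j > length(ds$characters)) {
        add(tx$name, j, "unknown-character", "attribute for undeclared character")
        next
      }
      ch <- ds$characters[[j]]
      if (a$status != "RECORDED") next
      if (!is.null(a$states)) {
        if (ch$kind != "multistate") {
          add(tx$name, j, "payload-kind", "state set recorded for numeric character")
        } else if (any(a$states > length(ch$states))) {
          add(tx$name, j, "state-code",
              paste0("state ", max(a$states), " > ", length(ch$states)))
        }
      } else if (!is.null(a$range) && ch$kind != "numeric") {
        add(tx$name, j, "payload-kind", "range recorded for multistate character")
      }
      for (d in ch$dependencies) {
        ctl <- get_attribute(tx, d$controller)
        if (is_recorded(ctl) && !is.null(ctl$states) &&
            length(intersect(ctl$states, d$states)) == 0L) {
          add(tx$name, j, "dependency",
              paste0("recorded although controller ", d$controller,
                     " excludes applicability"))
        }
      }
    }
  }
  ms <- sum(vapply(ds$characters, function(c) c$kind == "multistate", logical(1)))
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(taxon = character(), character = integer(),
               type = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(violations = violations,
                 counts = list(n_taxa = length(ds$taxa),
                               n_characters = length(ds$characters),
                               n_multistate = ms,
                               n_numeric = length(ds$characters) - ms)),
            class = "nereid_validation")
}

#' @export
print.nereid_validation <- function(x, ...) {
  cat(sprintf("dataset: %d taxa, %d characters (%d multistate, %d numeric)\n",
              x$counts$n_taxa, x$counts$n_characters, x$counts$n_multistate,
              x$counts$n_numeric))
  if (nrow(x$violations) == 0L) cat("no violations\n")
  else print(x$violations)
  invisible(x)
}
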