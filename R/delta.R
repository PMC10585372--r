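#' Read and write the DELTA-style text dialect
#'
#' A documented plain-text dialect of the classic descriptive-taxonomy
#' format, as a character-list file plus an item (taxon) file.
#'
#' Character list file:
#' \preformatted{
#'   #7. Eyes/            <- character header, "#<number>. <label>/"
#'   1. present/          <- state lines (multistate characters only)
#'   2. absent/
#'   u chaetiger/         <- optional unit line (numeric characters)
#'   d 5,1/               <- optional dependency "controller,states"
#' }
#' Item file:
#' \preformatted{
#'   #1. Alitta <Kinberg, 1865>/     <- taxon header; <...> = authority
#'   3,2 4,2/3 23,50-110 7,U 9,- 27,1<a comment>
#' }
#' Attribute tokens are `char,states` with `/` separating alternative
#' (polymorphic) states, `lo-hi` a numeric range, `U` explicit unknown, `-`
#' inapplicable, and an optional trailing `<comment>`.  Lines beginning
#' with `*` are comments.  Unsupported directives are skipped with a
#' warning, never silently misread.  The round trip
#' `read_delta(write_delta(ds))` is lossless.
#'
#' @param chars_path,items_path paths of the two files.
#' @param title dataset title.
#' @return [read_delta()] returns a [dataset()].
#' @export
read_delta <- function(chars_path, items_path, title = "") {
  chars <- read_delta_chars(chars_path)
  taxa <- read_delta_items(items_path, chars)
  dataset(chars, taxa, title = title)
}

strip_term <- function(x) sub("/\\s*$", "", x)

read_delta_chars <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  chars <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    kind <- if (length(cur$states)) "multistate" else "numeric"
    chars[[length(chars) + 1L]] <<- character_def(
      cur$number, cur$label, kind, states = cur$states, unit = cur$unit,
      dependencies = cur$deps, section = cur$section)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "*")) next
    if (startsWith(ln, "#")) {
      flush()
      m <- regmatches(ln, regexec("^#([0-9]+)\\. (.*)/\\s*$", ln))[[1]]
      if (length(m) != 3L) {
        stop("line ", i, ": malformed character header: ", ln, call. = FALSE)
      }
      cur <- list(number = as.integer(m[2]), label = m[3],
                  states = character(), unit = "", deps = list(), section = "")
    } else if (grepl("^u ", ln)) {
      cur$unit <- strip_term(sub("^u ", "", ln))
    } else if (grepl("^d ", ln)) {
      spec <- strip_term(sub("^d ", "", ln))
      parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
      cur$deps[[length(cur$deps) + 1L]] <- list(
        controller = as.integer(parts[1]),
        states = as.integer(strsplit(parts[2], "/", fixed = TRUE)[[1]]))
    } else if (grepl("^[0-9]+\\. ", ln)) {
      k <- as.integer(sub("\\..*", "", ln))
      if (k != length(cur$states) + 1L) {
        stop("line ", i, ": state ", k, " out of order for character ",
             cur$number, call. = FALSE)
      }
      cur$states <- c(cur$states, strip_term(sub("^[0-9]+\\. ", "", ln)))
    } else {
      warning("line ", i, ": unsupported directive skipped: ", ln, call. = FALSE)
    }
  }
  flush()
  chars
}

read_delta_items <- function(path, chars) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\* ", lines)   # comment lines are "* ..." at column 1
  text <- paste(lines[keep], collapse = "\n")
  chunks <- strsplit(text, "(?m)^#", perl = TRUE)[[1]]
  chunks <- chunks[nzchar(trimws(chunks))]
  nstates <- vapply(chars, function(c) length(c$states), integer(1))
  taxa <- list()
  for (chunk in chunks) {
    nl <- regexpr("\n", chunk, fixed = TRUE)
    header <- if (nl > 0) substr(chunk, 1, nl - 1) else chunk
    body <- if (nl > 0) substr(chunk, nl + 1L, nchar(chunk)) else ""
    m <- regmatches(header, regexec(
      "^([0-9]+)\\. ([^<]*?)\\s*(?:<(.*)>)?\\s*/\\s*$", header))[[1]]
    if (length(m) < 3L) stop("malformed item header: #", header, call. = FALSE)
    name <- m[3]; authority <- if (length(m) >= 4L) m[4] else ""
    body <- gsub("\n", " ", body)
    attrs <- list()
    # tokens: char,value optionally followed by <comment> (spaces allowed)
    pat <- "([0-9]+),([0-9./U-]+|U|-)(<[^>]*>)?"
    for (tok in regmatches(body, gregexpr(pat, body))[[1]]) {
      m2 <- regmatches(tok, regexec(pat, tok))[[1]]
      cn <- as.integer(m2[2]); val <- m2[3]
      comment <- if (nzchar(m2[4])) substr(m2[4], 2, nchar(m2[4]) - 1L) else ""
      if (cn < 1L || cn > length(chars)) {
        stop("item ", name, ": attribute for undeclared character ", cn,
             call. = FALSE)
      }
      a <- if (val == "U") {
        attr_unknown(comment)
      } else if (val == "-") {
        attr_inapplicable(comment)
      } else if (chars[[cn]]$kind == "numeric") {
        b <- as.numeric(strsplit(val, "-", fixed = TRUE)[[1]])
        attr_range(b[1], if (length(b) > 1L) b[2] else b[1], comment)
      } else {
        st <- as.integer(strsplit(val, "/", fixed = TRUE)[[1]])
        if (any(is.na(st)) || any(st > nstates[cn])) {
          stop("item ", name, ": state out of range for character ", cn,
               " (", val, ")", call. = FALSE)
        }
        attr_states(st, comment)
      }
      attrs[[as.character(cn)]] <- a
    }
    taxa[[length(taxa) + 1L]] <- taxon_record(name, authority, attrs)
  }
  taxa
}

#' @rdname read_delta
#' @param ds a [dataset()].
#' @export
write_delta <- function(ds, chars_path, items_path) {
  out <- character()
  for (ch in ds$characters) {
    out <- c(out, sprintf("#%d. %s/", ch$number, ch$label))
    for (k in seq_along(ch$states)) {
      out <- c(out, sprintf("%d. %s/", k, ch$states[k]))
    }
    if (ch$kind == "numeric" && nzchar(ch$unit)) {
      out <- c(out, sprintf("u %s/", ch$unit))
    }
    for (d in ch$dependencies) {
      out <- c(out, sprintf("d %d,%s/", d$controller,
                            paste(d$states, collapse = "/")))
    }
  }
  writeLines(out, chars_path, useBytes = TRUE)

  fmt_num <- function(x) sub("\\.0+$", "", format(x, scientific = FALSE, trim = TRUE))
  out <- character()
  for (i in seq_along(ds$taxa)) {
    tx <- ds$taxa[[i]]
    auth <- if (nzchar(tx$authority)) sprintf(" <%s>", tx$authority) else ""
    out <- c(out, sprintf("#%d. %s%s/", i, tx$name, auth))
    toks <- character()
    for (nm in as.character(sort(as.integer(names(tx$attributes))))) {
      a <- tx$attributes[[nm]]
      val <- switch(a$status,
        UNKNOWN = "U",
        INAPPLICABLE = "-",
        RECORDED = if (!is.null(a$states)) paste(a$states, collapse = "/")
                   else paste(fmt_num(a$range[1]), fmt_num(a$range[2]), sep = "-"))
      com <- if (nzchar(a$comment))
        sprintf("<%s>", gsub("[<>]", " ", a$comment)) else ""
      toks <- c(toks, paste0(nm, ",", val, com))
    }
    if (length(toks)) out <- c(out, paste(toks, collapse = " "))
  }
  writeLines(out, items_path, useBytes = TRUE)
  invisible(list(chars = chars_path, items = items_path))
}
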