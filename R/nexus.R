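#' NEXUS export options
#'
#' @param exclude_numeric drop numeric (meristic) characters; the standard
#'   morphology export keeps qualitative characters only.
#' @param full_labels emit full character/state labels.  `FALSE` reproduces
#'   the legacy 30-character truncation of older tools.
#' @param symbols state symbols, one per state code.
#' @param missing symbol for UNKNOWN cells.
#' @param gap symbol for INAPPLICABLE cells.
#' @return A list of class `nereid_nexus_options`.
#' @export
nexus_options <- function(exclude_numeric = TRUE, full_labels = TRUE,
                          symbols = "123456789", missing = "?", gap = "-") {
  stopifnot(nchar(missing) == 1L, nchar(gap) == 1L, nchar(symbols) >= 1L)
  structure(list(exclude_numeric = exclude_numeric, full_labels = full_labels,
                 symbols = symbols, missing = missing, gap = gap),
            class = "nereid_nexus_options")
}

nexus_quote <- function(x) {
  paste0("'", gsub("'", "''", x), "'")
}

trunc30 <- function(x, full) if (full) x else substr(x, 1, 30)

#' Write a dataset as a NEXUS morphology matrix
#'
#' Emits `#NEXUS` with TAXA and CHARACTERS blocks; CHARSTATELABELS carries
#' character and state labels; polymorphic cells are brace-enclosed
#' multi-symbol sets; UNKNOWN maps to the missing symbol and INAPPLICABLE to
#' the gap symbol; characters are declared unordered.  By default numeric
#' (meristic) characters are excluded, since their coding for phylogenetic
#' use needs assumptions beyond this format.
#'
#' @param ds a [dataset()].
#' @param path output file; `NULL` returns the text.
#' @param options a [nexus_options()].
#' @return The NEXUS text, invisibly (also written to `path` if given).
#' @export
write_nexus <- function(ds, path = NULL, options = nexus_options()) {
  keep <- vapply(ds$characters, function(ch)
    !(options$exclude_numeric && ch$kind == "numeric"), logical(1))
  chars <- ds$characters[keep]
  if (length(ds$taxa) == 0L) stop("cannot export an empty dataset", call. = FALSE)
  if (length(chars) == 0L) stop("no exportable characters", call. = FALSE)
  maxstates <- max(vapply(chars, function(ch)
    max(1L, length(ch$states)), integer(1)))
  syms <- strsplit(options$symbols, "")[[1]]
  if (maxstates > length(syms)) {
    stop("symbols cover ", length(syms), " states but the dataset needs ",
         maxstates, call. = FALSE)
  }
  ntax <- length(ds$taxa); nchar_ <- length(chars)
  lab <- function(x) nexus_quote(trunc30(x, options$full_labels))
  out <- c("#NEXUS", "",
           "BEGIN TAXA;",
           sprintf("  DIMENSIONS NTAX=%d;", ntax),
           paste0("  TAXLABELS ",
                  paste(nexus_quote(names(ds$taxa)), collapse = " "), ";"),
           "END;", "",
           "BEGIN CHARACTERS;",
           sprintf("  DIMENSIONS NCHAR=%d;", nchar_),
           sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=%s GAP=%s;",
                   paste(syms[seq_len(min(maxstates, length(syms)))], collapse = ""),
                   options$missing, options$gap),
           "  CHARSTATELABELS")
  csl <- vapply(seq_along(chars), function(k) {
    ch <- chars[[k]]
    states <- if (length(ch$states)) paste(vapply(ch$states, lab, character(1)),
                                           collapse = " ") else ""
    sprintf("    %d %s%s%s", k, lab(ch$label),
            if (nzchar(states)) " / " else "", states)
  }, character(1))
  csl <- paste0(csl, c(rep(",", length(csl) - 1L), ";"))
  out <- c(out, csl, "  MATRIX")
  for (tx in ds$taxa) {
    row <- vapply(chars, function(ch) {
      a <- get_attribute(tx, ch$number)
      if (is.null(a) || a$status == "UNKNOWN") return(options$missing)
      if (a$status == "INAPPLICABLE") return(options$gap)
      if (!is.null(a$states)) {
        s <- paste(syms[a$states], collapse = "")
        if (length(a$states) > 1L) paste0("{", s, "}") else s
      } else {
        options$missing  # numeric kept but unrepresentable: treated as missing
      }
    }, character(1))
    out <- c(out, paste0("    ", nexus_quote(tx$name), " ",
                         paste(row, collapse = "")))
  }
  out <- c(out, "  ;", "END;", "",
           "BEGIN ASSUMPTIONS;",
           sprintf("  TYPESET * UNTITLED = unord: 1-%d;", nchar_),
           "END;")
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

# tokenizer respecting quotes and braces
nexus_tokens <- function(text) {
  text <- gsub("\\[[^]]*\\]", " ", text)  # comments
  pat <- "'(?:[^']|'')*'|\\{[^}]*\\}|\\([^)]*\\)|[^\\s;=]+|;|="
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  regmatches(text, list(m))[[1]]
}

unquote <- function(x) {
  if (startsWith(x, "'")) gsub("''", "'", substr(x, 2, nchar(x) - 1L))
  else gsub("_", " ", x)
}

#' Read a NEXUS morphology matrix
#'
#' Parses the CHARACTERS (or DATA) block of a NEXUS file into a dataset of
#' multistate characters.  Both interleaved and non-interleaved matrices are
#' supported; missing and gap symbols map back to UNKNOWN and INAPPLICABLE.
#' Files without CHARSTATELABELS get characters auto-named `char_<n>` (with
#' a message).
#'
#' @param path file path, or `text` a NEXUS string.
#' @param title dataset title.
#' @return A [dataset()].
#' @export
read_nexus <- function(path = NULL, text = NULL, title = "") {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    stop("not a NEXUS file (missing #NEXUS header) at line 1", call. = FALSE)
  }
  toks <- nexus_tokens(text)
  up <- toupper(toks)
  ntax <- nchar_ <- NA_integer_
  symbols <- "0123456789"; missing <- "?"; gap <- "-"
  interleave <- FALSE
  labels <- NULL; states_lab <- NULL
  matrix_rows <- list()

  i <- 1L
  find_block <- function(name) {
    while (i <= length(up)) {
      if (up[i] == "BEGIN" && i < length(up) &&
          up[i + 1L] %in% name) return(i)
      i <<- i + 1L
    }
    NA_integer_
  }
  b <- find_block(c("CHARACTERS;", "DATA;", "CHARACTERS", "DATA"))
  if (is.na(b)) stop("no CHARACTERS/DATA block found", call. = FALSE)
  i <- b
  while (i <= length(up) && up[i] != "END;" &&
         !(up[i] == "END" && i < length(up) && up[i + 1L] == ";")) {
    t <- up[i]
    if (t == "DIMENSIONS") {
      while (up[i] != ";") {
        if (up[i] == "NTAX") ntax <- as.integer(toks[i + 2L])
        if (up[i] == "NCHAR") nchar_ <- as.integer(toks[i + 2L])
        i <- i + 1L
      }
    } else if (t == "FORMAT") {
      while (up[i] != ";") {
        if (up[i] == "SYMBOLS") symbols <- gsub('"', "", toks[i + 2L])
        if (up[i] == "MISSING") missing <- toks[i + 2L]
        if (up[i] == "GAP") gap <- toks[i + 2L]
        if (up[i] == "INTERLEAVE") interleave <- TRUE
        i <- i + 1L
      }
    } else if (t == "CHARSTATELABELS") {
      i <- i + 1L
      labels <- character(nchar_); states_lab <- vector("list", nchar_)
      while (up[i] != ";") {
        k <- as.integer(toks[i]); i <- i + 1L
        labels[k] <- unquote(toks[i]); i <- i + 1L
        st <- character()
        if (toks[i] == "/") {
          i <- i + 1L
          while (!toks[i] %in% c(",", ";")) {
            st <- c(st, unquote(toks[i])); i <- i + 1L
          }
        }
        states_lab[[k]] <- st
        if (toks[i] == ",") i <- i + 1L
      }
    } else if (t == "MATRIX") {
      i <- i + 1L
      allowed <- c(strsplit(symbols, "")[[1]], missing, gap,
                   "{", "}", "(", ")")
      is_cellrun <- function(tok) {
        !startsWith(tok, "'") &&
          all(strsplit(tok, "")[[1]] %in% allowed)
      }
      while (up[i] != ";") {
        nm <- unquote(toks[i]); i <- i + 1L
        row <- character()
        while (i <= length(up) && toks[i] != ";" && is_cellrun(toks[i])) {
          row <- c(row, toks[i]); i <- i + 1L
        }
        cells <- parse_nexus_row(paste(row, collapse = ""), symbols, missing, gap)
        matrix_rows[[nm]] <- c(matrix_rows[[nm]], cells)
      }
    }
    i <- i + 1L
  }
  if (length(matrix_rows) == 0L) stop("empty MATRIX block", call. = FALSE)
  if (is.na(nchar_)) nchar_ <- length(matrix_rows[[1]])
  bad <- vapply(matrix_rows, length, integer(1)) != nchar_
  if (any(bad)) {
    stop("row length != NCHAR for: ",
         paste(names(matrix_rows)[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) {
    message("no CHARSTATELABELS; characters auto-named char_<n>")
    labels <- paste0("char_", seq_len(nchar_))
    states_lab <- rep(list(character()), nchar_)
  }
  syms <- strsplit(symbols, "")[[1]]
  # maximum state code used per character decides the state count
  chars <- vector("list", nchar_)
  for (k in seq_len(nchar_)) {
    mx <- 2L
    for (r in matrix_rows) {
      if (is.integer(r[[k]])) mx <- max(mx, r[[k]])
    }
    st <- states_lab[[k]]
    if (length(st) < mx) st <- c(st, paste0("state_", seq.int(length(st) + 1L, mx)))
    chars[[k]] <- character_def(k, labels[k], "multistate", states = st)
  }
  taxa <- lapply(names(matrix_rows), function(nm) {
    attrs <- list()
    r <- matrix_rows[[nm]]
    for (k in seq_len(nchar_)) {
      cell <- r[[k]]
      attrs[[as.character(k)]] <- if (is.integer(cell)) attr_states(cell)
        else if (identical(cell, "gap")) attr_inapplicable()
        else attr_unknown()
    }
    taxon_record(nm, attributes = attrs)
  })
  dataset(chars, taxa, title = title)
}

parse_nexus_row <- function(row, symbols, missing, gap) {
  syms <- strsplit(symbols, "")[[1]]
  cells <- list()
  i <- 1L
  n <- nchar(row)
  while (i <= n) {
    ch <- substr(row, i, i)
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      grp <- character()
      while (substr(row, j, j) != close) {
        grp <- c(grp, substr(row, j, j)); j <- j + 1L
        if (j > n) stop("unterminated polymorphism group", call. = FALSE)
      }
      cells[[length(cells) + 1L]] <- match(grp, syms)
      i <- j + 1L
    } else if (ch == missing) {
      cells[[length(cells) + 1L]] <- "missing"; i <- i + 1L
    } else if (ch == gap) {
      cells[[length(cells) + 1L]] <- "gap"; i <- i + 1L
    } else {
      s <- match(ch, syms)
      if (is.na(s)) stop("unexpected matrix symbol '", ch, "'", call. = FALSE)
      cells[[length(cells) + 1L]] <- s
      i <- i + 1L
    }
  }
  lapply(cells, function(c) if (is.character(c)) c else as.integer(c))
}
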