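#' Key-generation parameters
#'
#' Defaults reproduce the settings used for the published Nereididae key:
#' `rbase` weights character reliability into the score (balancing key
#' length), `abase` would weight taxon abundance (disabled at 1.0 and kept
#' only as a hook), `reuse` penalises re-using a character along one path,
#' and `varywt` down-weights characters for which node taxa are variable
#' (polymorphic/unknown, hence following more than one lead).
#'
#' @param rbase reliability base, > 1.
#' @param abase abundance base (1 = disabled; reserved).
#' @param reuse re-use penalty base, >= 1.
#' @param varywt variable-taxon down-weight in (0, 1].
#' @param n_confirmatory confirmatory statements appended per lead.
#' @param max_depth recursion guard.
#' @return A list of class `nereid_keygen_params`.
#' @export
keygen_params <- function(rbase = 2.00, abase = 1.00, reuse = 1.01,
                          varywt = 0.80, n_confirmatory = 2L,
                          max_depth = 50L) {
  stopifnot(rbase > 1, reuse >= 1, varywt > 0, varywt <= 1,
            n_confirmatory >= 0L, max_depth >= 1L)
  structure(list(rbase = rbase, abase = abase, reuse = reuse,
                 varywt = varywt, n_confirmatory = as.integer(n_confirmatory),
                 max_depth = as.integer(max_depth)),
            class = "nereid_keygen_params")
}

# taxa compatible with state s of character cn (state in set, or unscored)
compatible_taxa <- function(ds, taxa, cn, s) {
  taxa[vapply(taxa, function(nm) {
    a <- get_attribute(ds$taxa[[nm]], cn)
    !is_recorded(a) || is.null(a$states) || s %in% a$states
  }, logical(1))]
}

#' Score a character at a key node
#'
#' The node score is
#' `E(c) * varywt^v * rbase^(r - 5) / reuse^u` where `E(c)` is the Shannon
#' entropy, normalised to `[0, 1]`, of the node taxa across the leads the
#' character induces (taxa that would follow several leads are counted in
#' each), `v` is the number of node taxa following more than one lead, `r`
#' the character's reliability and `u` the number of times the character was
#' already used on the path.  An even binary split of fully scored taxa with
#' neutral reliability and no re-use scores exactly 1.
#'
#' @param ds a [dataset()].
#' @param node_taxa character vector of taxon names at the node.
#' @param cn character number (multistate).
#' @param usage named integer vector of prior per-character use counts.
#' @param params a [keygen_params()].
#' @return The numeric score, or `NA` if the character is unusable at the
#'   node (fewer than two leads realised).
#' @export
score_character <- function(ds, node_taxa, cn, usage = integer(),
                            params = keygen_params()) {
  ch <- get_character(ds, cn)
  if (ch$kind != "multistate") return(NA_real_)
  recorded <- vapply(node_taxa, function(nm) {
    a <- get_attribute(ds$taxa[[nm]], cn)
    is_recorded(a) && !is.null(a$states)
  }, logical(1))
  if (!any(recorded)) return(NA_real_)
  realised <- sort(unique(unlist(lapply(node_taxa[recorded], function(nm)
    get_attribute(ds$taxa[[nm]], cn)$states))))
  if (length(realised) < 2L) return(NA_real_)
  counts <- vapply(realised, function(s)
    length(compatible_taxa(ds, node_taxa, cn, s)), integer(1))
  p <- counts / sum(counts)
  ent <- -sum(p * log(p)) / log(length(realised))
  nlead <- vapply(node_taxa, function(nm) {
    a <- get_attribute(ds$taxa[[nm]], cn)
    if (!is_recorded(a) || is.null(a$states)) length(realised)
    else length(intersect(a$states, realised))
  }, integer(1))
  v <- sum(nlead > 1L)
  u <- if (as.character(cn) %in% names(usage)) usage[[as.character(cn)]] else 0L
  ent * params$varywt^v * params$rbase^(ch$reliability - 5) / params$reuse^u
}

#' Build an identification key
#'
#' Recursive partition of the taxa: at each node the best-scoring character
#' (ties to the lowest character number) becomes the couplet's primary
#' statement, with one lead per realised state (so polytomies arise
#' naturally); taxa whose attribute overlaps several leads, or is unscored,
#' follow every compatible lead.  Up to `n_confirmatory` compatible
#' characters are appended per lead; they corroborate but never drive the
#' branching.  Recursion ends at singleton nodes, or at multi-taxon nodes no
#' character separates (flagged in `inseparable`).
#'
#' @param ds a [dataset()].
#' @param params a [keygen_params()].
#' @return A list of class `nereid_key`: `couplets`, `n_confirmatory`,
#'   `inseparable`, `anomalies`.
#' @export
build_key <- function(ds, params = keygen_params()) {
  stopifnot(length(ds$taxa) >= 2L)
  couplets <- list()
  inseparable <- list()
  authority <- vapply(ds$taxa, function(t) t$authority, character(1))

  new_couplet <- function(parent) {
    couplets[[length(couplets) + 1L]] <<- list(number = length(couplets) + 1L,
                                               parent = parent, leads = list())
    length(couplets)
  }

  confirmatory_chars <- function(node_taxa, primary, realised) {
    # a character is confirmatory if, over node taxa monomorphic for both it
    # and the primary, it induces the same grouping as the primary
    out <- list()
    for (ch in ds$characters) {
      if (ch$number == primary || ch$kind != "multistate") next
      mono <- list()
      ok <- TRUE
      statemap <- list()  # primary state -> set of ch states seen
      for (nm in node_taxa) {
        ap <- get_attribute(ds$taxa[[nm]], primary)
        ac <- get_attribute(ds$taxa[[nm]], ch$number)
        if (!is_recorded(ap) || is.null(ap$states) || length(ap$states) != 1L) next
        if (!is_recorded(ac) || is.null(ac$states) || length(ac$states) != 1L) next
        key <- as.character(ap$states)
        statemap[[key]] <- union(statemap[[key]], ac$states)
      }
      if (length(statemap) < 2L) next
      vals <- statemap[as.character(realised)[as.character(realised) %in% names(statemap)]]
      if (any(vapply(vals, length, integer(1)) != 1L)) next
      flat <- unlist(vals)
      if (anyDuplicated(flat)) next  # must discriminate the leads
      # every taxon that can follow a lead must be compatible with the
      # confirmatory statement there, else the statement would contradict a
      # legitimately routed taxon
      ok <- TRUE
      for (s in realised) {
        cs <- statemap[[as.character(s)]]
        if (is.null(cs)) next
        for (nm in compatible_taxa(ds, node_taxa, primary, s)) {
          ac <- get_attribute(ds$taxa[[nm]], ch$number)
          if (is_recorded(ac) && !is.null(ac$states) &&
              !any(cs %in% ac$states)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      out[[length(out) + 1L]] <- list(char = ch$number, map = statemap)
    }
    out
  }

  grow <- function(node_taxa, usage, parent, depth, banned = integer()) {
    scores <- vapply(seq_along(ds$characters), function(cn)
      score_character(ds, node_taxa, cn, usage, params), numeric(1))
    scores[banned] <- NA_real_
    if (all(is.na(scores)) || max(scores, na.rm = TRUE) <= 0 ||
        depth > params$max_depth) {
      inseparable[[length(inseparable) + 1L]] <<- node_taxa
      return(list(terminal = node_taxa))
    }
    best <- which(scores == max(scores, na.rm = TRUE))[1]  # lowest number wins
    cn <- best
    recorded <- Filter(function(nm) {
      a <- get_attribute(ds$taxa[[nm]], cn)
      is_recorded(a) && !is.null(a$states)
    }, node_taxa)
    realised <- sort(unique(unlist(lapply(recorded, function(nm)
      get_attribute(ds$taxa[[nm]], cn)$states))))
    me <- new_couplet(parent)
    conf <- if (params$n_confirmatory > 0L)
      confirmatory_chars(node_taxa, cn, realised) else list()
    usage2 <- usage
    k <- as.character(cn)
    usage2[k] <- (if (k %in% names(usage2)) usage2[[k]] else 0L) + 1L
    leads <- list()
    for (s in realised) {
      members <- compatible_taxa(ds, node_taxa, cn, s)
      stmts <- list(list(char = cn, states = s))
      for (cf in conf) {
        if (length(stmts) - 1L >= params$n_confirmatory) break
        cs <- cf$map[[as.character(s)]]
        if (!is.null(cs)) {
          stmts[[length(stmts) + 1L]] <- list(char = cf$char, states = cs)
        }
      }
      dest <- if (length(members) == 1L) {
        list(taxon = members, authority = unname(authority[members]))
      } else {
        # a lead that excludes nobody makes no progress: ban the character
        # below it so the recursion must try something else (and terminates)
        banned2 <- if (setequal(members, node_taxa)) c(banned, cn) else integer()
        sub <- grow(members, usage2, me, depth + 1L, banned2)
        if (!is.null(sub$terminal)) {
          if (length(sub$terminal) == 1L)
            list(taxon = sub$terminal, authority = unname(authority[sub$terminal]))
          else list(taxa = sub$terminal)
        } else list(couplet = sub$couplet)
      }
      leads[[length(leads) + 1L]] <- list(statements = stmts, destination = dest)
    }
    couplets[[me]]$leads <<- leads
    list(couplet = me)
  }

  root <- grow(names(ds$taxa), integer(), 0L, 1L)
  if (!is.null(root$terminal)) {
    stop("no character separates any taxa: cannot build a key", call. = FALSE)
  }
  structure(list(title = paste("Key:", ds$title),
                 n_confirmatory = params$n_confirmatory,
                 couplets = couplets,
                 inseparable = inseparable,
                 anomalies = NULL),
            class = "nereid_key")
}

#' @export
print.nereid_key <- function(x, ...) {
  terms <- key_terminal_taxa(x)
  cat(sprintf("<nereid_key> %d couplets, %d terminal taxa\n",
              length(x$couplets), length(unique(terms))))
  invisible(x)
}

key_terminal_taxa <- function(key) {
  out <- character()
  for (c in key$couplets) {
    for (l in c$leads) {
      d <- l$destination
      if (!is.null(d$taxon)) out <- c(out, d$taxon)
      if (!is.null(d$taxa)) out <- c(out, d$taxa)
    }
  }
  out
}

# is a specimen attribute compatible with a lead statement?
stmt_compatible <- function(attrs, stmt) {
  if (is.null(stmt$char)) return(NA)  # free-text statement: cannot test
  a <- attrs[[as.character(stmt$char)]]
  if (!is_recorded(a) || is.null(a$states)) return(NA)  # unknown passes
  length(intersect(a$states, stmt$states)) > 0L
}

#' Route a specimen through a key
#'
#' From couplet 1, every lead whose primary statement is compatible with the
#' specimen (overlapping states, or the specimen unscored for the character)
#' is followed; all reachable terminals are returned with their couplet
#' paths.  Confirmatory statements are checked and reported as
#' agree/disagree but never block a lead.
#'
#' @param key a `nereid_key` (generated or loaded).
#' @param attrs named list of [attr_states()] attributes (names = character
#'   numbers), e.g. a taxon's attribute map.
#' @return A list of class `nereid_routing`: `terminals` (character vector)
#'   and `paths` (list of `list(taxa, path, confirmatory_disagreements)`).
#' @export
route_specimen <- function(key, attrs) {
  bynum <- list()
  for (c in key$couplets) bynum[[c$number]] <- c
  results <- list()
  walk <- function(num, path, disagreements) {
    if (num > length(bynum) || is.null(bynum[[num]])) {
      stop("dangling couplet reference: ", num, call. = FALSE)
    }
    c <- bynum[[num]]
    for (li in seq_along(c$leads)) {
      l <- c$leads[[li]]
      comp <- stmt_compatible(attrs, l$statements[[1]])
      if (identical(comp, FALSE)) next
      dis <- disagreements
      for (s in l$statements[-1]) {
        sc <- stmt_compatible(attrs, s)
        if (identical(sc, FALSE)) {
          dis[[length(dis) + 1L]] <- list(couplet = num, lead = li,
                                          char = s$char)
        }
      }
      d <- l$destination
      if (!is.null(d$couplet)) {
        if (!d$couplet %in% path) walk(d$couplet, c(path, d$couplet), dis)
      } else {
        taxa <- d$taxon %||% d$taxa
        results[[length(results) + 1L]] <<-
          list(taxa = taxa, path = path, confirmatory_disagreements = dis)
      }
    }
  }
  walk(1L, 1L, list())
  structure(list(terminals = unique(unlist(lapply(results, `[[`, "taxa"))),
                 paths = results),
            class = "nereid_routing")
}

#' Consistency-check a key against a dataset
#'
#' Routes every taxon's own attributes through the key and lists
#' contradictions: `(taxon, couplet, character)` triples where a taxon
#' reaching a lead is recorded at states disjoint from the lead's statement,
#' and taxa that never reach a terminal bearing their own name.
#'
#' @param key a `nereid_key`.
#' @param ds the [dataset()] the key refers to.
#' @return A list of class `nereid_key_report`: `contradictions`
#'   (data.frame), `unreached` (character vector of taxa whose own routing
#'   misses them).
#' @export
check_key_consistency <- function(key, ds) {
  contradictions <- list()
  unreached <- character()
  for (nm in names(ds$taxa)) {
    attrs <- ds$taxa[[nm]]$attributes
    r <- route_specimen(key, attrs)
    if (!nm %in% r$terminals) unreached <- c(unreached, nm)
    for (p in r$paths) {
      if (!nm %in% p$taxa) next
      for (d in p$confirmatory_disagreements) {
        contradictions[[length(contradictions) + 1L]] <-
          data.frame(taxon = nm, couplet = d$couplet, character = d$char,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    contradictions = if (length(contradictions)) do.call(rbind, contradictions)
      else data.frame(taxon = character(), couplet = integer(),
                      character = integer(), stringsAsFactors = FALSE),
    unreached = unreached), class = "nereid_key_report")
}

#' Render a key as text
#'
#' Emits the classic two-column couplet layout: a numbered first lead with
#' its parent in parentheses ("4(3)"), em-dash alternate leads, and bold
#' terminal taxa with authorities.
#'
#' @param key a `nereid_key`.
#' @param ds optional [dataset()] used to spell out statement labels; if
#'   omitted, stored statement text (paper keys) or "char n state s" is used.
#' @return Character vector of lines.
#' @export
render_key <- function(key, ds = NULL) {
  stmt_text <- function(s) {
    if (!is.null(s$text)) return(s$text)
    if (!is.null(ds) && !is.null(s$char)) {
      ch <- get_character(ds, s$char)
      return(paste0(ch$label, " ",
                    paste(ch$states[s$states], collapse = ", or ")))
    }
    paste0("character ", s$char, " state ",
           paste(s$states, collapse = "/"))
  }
  dest_text <- function(d) {
    if (!is.null(d$couplet)) return(sprintf("**%d**", d$couplet))
    taxa <- d$taxon %||% d$taxa
    auth <- if (!is.null(d$authority) && nzchar(d$authority))
      paste0(" ", d$authority) else ""
    paste0("**", paste(taxa, collapse = " / "), auth, "**")
  }
  out <- character()
  for (c in key$couplets) {
    for (li in seq_along(c$leads)) {
      l <- c$leads[[li]]
      head <- if (li == 1L) sprintf("%d(%d)", c$number, c$parent) else "–"
      stmts <- paste(vapply(l$statements, stmt_text, character(1)),
                     collapse = "; ")
      out <- c(out, sprintf("%s\t%s\t%s", head, stmts, dest_text(l$destination)))
    }
  }
  out
}
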