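#' Diagnosis parameters
#'
#' The diagnostic level `level` (the classic DiagLevel setting) is the
#' minimum number of characters on which a diagnostic description must
#' differ from every other taxon: level 1 gives a minimal diagnosis, level 2
#' adds a verification margin (a "secondary diagnosis").
#'
#' @param level positive integer (DiagLevel).
#' @param mode `"exact"` (provably minimum cardinality, branch and bound) or
#'   `"greedy"` (fast heuristic approximating the legacy behaviour).
#' @param tie_break `"lowest-character-number"` or
#'   `"highest-reliability-then-number"` (greedy mode).
#' @return A list of class `nereid_diag_params`.
#' @export
diagnosis_params <- function(level = 1L, mode = c("exact", "greedy"),
                             tie_break = c("lowest-character-number",
                                           "highest-reliability-then-number")) {
  level <- as.integer(level)
  stopifnot(length(level) == 1L, !is.na(level), level >= 1L)
  structure(list(level = level, mode = match.arg(mode),
                 tie_break = match.arg(tie_break)),
            class = "nereid_diag_params")
}

#' Verify a candidate diagnosis
#'
#' A character set is a valid level-`d` diagnosis of `taxon` iff every other
#' taxon differs (per [differ()]) from `taxon` on at least `d` of the
#' characters.  Unscored rival cells never contribute: UNKNOWN cannot help a
#' diagnosis.
#'
#' @param ds a [dataset()].
#' @param taxon focal taxon name.
#' @param chars integer vector of character numbers, all RECORDED for
#'   `taxon`.
#' @param level required margin (DiagLevel).
#' @return A list: `valid` (logical) and `rival_margins` (named integer
#'   vector: count of diagnosis characters on which each rival differs).
#' @export
verify_diagnosis <- function(ds, taxon, chars, level = 1L) {
  tx <- get_taxon(ds, taxon)
  chars <- sort(unique(as.integer(chars)))
  for (cn in chars) {
    a <- get_attribute(tx, cn)
    if (!is_recorded(a)) {
      stop("character ", cn, " is not RECORDED for ", taxon,
           ": invalid diagnosis", call. = FALSE)
    }
  }
  rivals <- setdiff(names(ds$taxa), taxon)
  margins <- vapply(rivals, function(r) {
    sum(vapply(chars, function(cn) differ(ds, taxon, r, cn), logical(1)))
  }, integer(1))
  list(valid = length(margins) == 0L || all(margins >= level),
       rival_margins = margins)
}

#' Is a diagnosis at the given level attainable at all?
#'
#' Feasible iff every rival taxon differs from the focal taxon on at least
#' `level` characters in total (using every character in the dataset).
#' Genera whose closest rival differs on a single character only cannot
#' attain level 2 ("secondary diagnosis not attained").
#'
#' @inheritParams verify_diagnosis
#' @return list(feasible = logical, blocking = named integer vector of
#'   rivals whose total distinguishing count is below `level`).
#' @export
diagnosis_feasibility <- function(ds, taxon, level = 1L) {
  m <- dataset_masks(ds)
  i0 <- match(taxon, names(ds$taxa))
  if (is.na(i0)) stop("unknown taxon: ", taxon, call. = FALSE)
  D <- differ_matrix(m, i0)
  tot <- rowSums(D)
  tot <- tot[-i0]
  blocking <- tot[tot < level]
  list(feasible = length(blocking) == 0L,
       blocking = vapply(blocking, as.integer, integer(1)))
}

#' Compute a minimal diagnosis
#'
#' Finds a smallest set of characters whose recorded states separate the
#' focal taxon from every rival at the requested level.  Exact mode solves
#' the underlying set-multicover problem by branch and bound (greedy upper
#' bound, counting lower bound) and is deterministic; greedy mode
#' iteratively adds the character that raises the most below-level rivals,
#' breaking ties per `params$tie_break`.
#'
#' @param ds a [dataset()].
#' @param taxon focal taxon name.
#' @param params a [diagnosis_params()].
#' @return A list of class `nereid_diagnosis`: `taxon`, `level`, `characters`
#'   (integer vector), `attributes` (the taxon's attribute for each),
#'   `rival_margins`.
#' @export
minimal_diagnosis <- function(ds, taxon, params = diagnosis_params()) {
  feas <- diagnosis_feasibility(ds, taxon, params$level)
  if (!feas$feasible) {
    stop("DiagnosisInfeasible: no level-", params$level, " diagnosis for ",
         taxon, "; blocking rivals: ",
         paste(names(feas$blocking), collapse = ", "), call. = FALSE)
  }
  m <- dataset_masks(ds)
  i0 <- match(taxon, names(ds$taxa))
  D <- differ_matrix(m, i0)[-i0, , drop = FALSE]
  rivals <- names(ds$taxa)[-i0]
  usable <- which(colSums(D) > 0L)
  level <- params$level
  rel <- vapply(ds$characters, function(c) c$reliability, numeric(1))

  greedy_cover <- function() {
    deficit <- rep(level, nrow(D))
    chosen <- integer()
    avail <- usable
    while (any(deficit > 0L)) {
      gain <- vapply(avail, function(j) sum(D[deficit > 0L, j]), integer(1))
      if (all(gain == 0L)) return(NULL)  # cannot happen if feasible
      best <- max(gain)
      cand <- avail[gain == best]
      pick <- if (params$tie_break == "lowest-character-number") min(cand)
              else cand[order(-rel[cand], cand)][1]
      chosen <- c(chosen, pick)
      deficit <- pmax(0L, deficit - D[, pick])
      avail <- setdiff(avail, pick)
    }
    sort(chosen)
  }

  exact_cover <- function(ub_set) {
    best <- ub_set
    ncol_av <- length(usable)
    # order characters by coverage, descending, for effective branching
    ord <- usable[order(-colSums(D[, usable, drop = FALSE]), usable)]
    maxgain <- rowSums(D[, ord, drop = FALSE])  # per rival (unused)
    recurse <- function(idx, chosen, deficit) {
      if (all(deficit == 0L)) {
        if (length(chosen) < length(best) ||
            (length(chosen) == length(best) &&
             !identical(sort(chosen), sort(best)))) {
          if (length(chosen) < length(best)) best <<- sort(chosen)
        }
        return()
      }
      if (idx > length(ord)) return()
      # lower bound: every remaining character covers each rival at most
      # once, so at least max remaining deficit more characters are needed;
      # also total-deficit / max-column-coverage
      need <- max(deficit)
      cov <- colSums(D[deficit > 0L, ord[idx:length(ord)], drop = FALSE])
      if (max(cov, 0L) == 0L) return()
      need2 <- ceiling(sum(deficit) / max(cov))
      if (length(chosen) + max(need, need2) >= length(best)) return()
      j <- ord[idx]
      # branch: include j
      recurse(idx + 1L, c(chosen, j), pmax(0L, deficit - D[, j]))
      # branch: exclude j (only if remaining columns can still cover)
      recurse(idx + 1L, chosen, deficit)
    }
    recurse(1L, integer(), rep(level, nrow(D)))
    best
  }

  g <- greedy_cover()
  chars <- if (params$mode == "greedy") g else exact_cover(g)
  ver <- verify_diagnosis(ds, taxon, chars, level)
  stopifnot(ver$valid)
  tx <- ds$taxa[[taxon]]
  structure(list(taxon = taxon, level = level, characters = chars,
                 attributes = lapply(chars, function(cn)
                   get_attribute(tx, cn)),
                 rival_margins = ver$rival_margins),
            class = "nereid_diagnosis")
}

#' @export
print.nereid_diagnosis <- function(x, ...) {
  cat(sprintf("level-%d diagnosis of %s: characters %s (min rival margin %d)\n",
              x$level, x$taxon, paste(x$characters, collapse = ", "),
              if (length(x$rival_margins)) min(x$rival_margins) else NA_integer_))
  invisible(x)
}

#' Render a diagnosis as prose
#'
#' @param ds the dataset the diagnosis was computed from.
#' @param diag a `nereid_diagnosis`.
#' @return A string in the classic "(minimal diagnosis)" style.
#' @export
diagnosis_prose <- function(ds, diag) {
  style <- description_style()
  parts <- vapply(seq_along(diag$characters), function(i) {
    ch <- get_character(ds, diag$characters[i])
    a <- diag$attributes[[i]]
    if (!is.null(a$states)) {
      paste0(ch$label, " ",
             paste(ch$states[a$states], collapse = style$polymorphism_joiner))
    } else {
      paste0(ch$label, " ", fmt_value(a$range[1]),
             if (a$range[1] != a$range[2]) paste0("–", fmt_value(a$range[2])) else "")
    }
  }, character(1))
  paste0(paste(parts, collapse = "; "),
         if (diag$level == 1L) " (minimal diagnosis)." else
           sprintf(" (level-%d diagnosis).", diag$level))
}
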