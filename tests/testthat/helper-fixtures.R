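# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's comparison internals: they re-derive differences from the
# raw attribute payloads.

# small hand-built dataset: 4 taxa, 5 characters (1 numeric), 1 dependency
tiny_dataset <- function() {
  chars <- list(
    character_def(1, "antennae", "multistate", c("present", "absent")),
    character_def(2, "colour", "multistate", c("red", "green", "blue")),
    character_def(3, "palpostyles", "multistate", c("present", "absent")),
    character_def(4, "palpostyle form", "multistate",
                  c("spherical", "conical"),
                  dependencies = list(list(controller = 3L, states = 1L))),
    character_def(5, "eye count", "numeric", unit = "count")
  )
  taxa <- list(
    taxon_record("Alpha", "Smith, 1900", list(
      `1` = attr_states(1), `2` = attr_states(1), `3` = attr_states(1),
      `4` = attr_states(1), `5` = attr_range(2, 4))),
    taxon_record("Beta", "Jones, 1910", list(
      `1` = attr_states(2), `2` = attr_states(c(2, 3)), `3` = attr_states(1),
      `4` = attr_states(2), `5` = attr_range(6))),
    taxon_record("Gamma", "", list(
      `1` = attr_states(1), `2` = attr_states(2), `3` = attr_states(2),
      `5` = attr_range(3, 5))),
    taxon_record("Delta", "", list(
      `2` = attr_states(3)))
  )
  dataset(chars, taxa, title = "tiny")
}

# independent per-cell difference: raw payload comparison
oracle_cell_differs <- function(ds, a, b, cn) {
  x <- ds$taxa[[a]]$attributes[[as.character(cn)]]
  y <- ds$taxa[[b]]$attributes[[as.character(cn)]]
  if (is.null(x) || is.null(y)) return(FALSE)
  if (x$status != "RECORDED" || y$status != "RECORDED") return(FALSE)
  if (!is.null(x$states) && !is.null(y$states)) {
    return(!any(x$states %in% y$states))
  }
  if (!is.null(x$range) && !is.null(y$range)) {
    return(max(x$range[1], y$range[1]) > min(x$range[2], y$range[2]))
  }
  FALSE
}

oracle_distinguishing <- function(ds, a, b) {
  which(vapply(seq_along(ds$characters), function(cn)
    oracle_cell_differs(ds, a, b, cn), logical(1)))
}

# exhaustive minimal-multicover oracle (enumeration over all subsets of the
# characters recorded for the focal taxon; feasible for <= ~15 characters)
oracle_min_diagnosis_size <- function(ds, taxon, level = 1L) {
  rivals <- setdiff(names(ds$taxa), taxon)
  cand <- which(vapply(seq_along(ds$characters), function(cn) {
    a <- ds$taxa[[taxon]]$attributes[[as.character(cn)]]
    !is.null(a) && a$status == "RECORDED"
  }, logical(1)))
  D <- vapply(cand, function(cn) vapply(rivals, function(r)
    oracle_cell_differs(ds, taxon, r, cn), logical(1)),
    logical(length(rivals)))
  D <- matrix(D, nrow = length(rivals))
  nc <- length(cand)
  for (k in 0:nc) {
    for (sub in utils::combn(nc, k, simplify = FALSE)) {
      cover <- if (length(sub)) rowSums(D[, sub, drop = FALSE]) else
        rep(0L, length(rivals))
      if (all(cover >= level)) return(k)
    }
  }
  Inf
}

# expected-remaining-candidates oracle for rank_characters
oracle_expected_remaining <- function(ds, cand, cn) {
  sets <- lapply(cand, function(nm) {
    a <- ds$taxa[[nm]]$attributes[[as.character(cn)]]
    if (!is.null(a) && a$status == "RECORDED" && !is.null(a$states)) a$states
    else NULL
  })
  rec <- Filter(Negate(is.null), sets)
  if (!length(rec)) return(NA_real_)
  states <- sort(unique(unlist(rec)))
  if (length(states) < 2L) return(NA_real_)
  total <- 0
  for (st in rec) {
    for (s in st) {
      p <- (1 / length(rec)) * (1 / length(st))
      remaining <- sum(vapply(sets, function(x) is.null(x) || s %in% x,
                              logical(1)))
      total <- total + p * remaining
    }
  }
  total
}

small_params <- function(seed, n_taxa = 6L, n_characters = 10L,
                         unknown_rate = 0.2, polymorphism_rate = 0.1, ...) {
  synthetic_params(n_taxa = n_taxa, n_characters = n_characters,
                   unknown_rate = unknown_rate,
                   polymorphism_rate = polymorphism_rate,
                   dependency_rate = 0.1, numeric_fraction = 0.2,
                   seed = seed, ...)
}

# cached heavyweight fixtures, built once per test run
nereid_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(nereid_cache[[name]])) nereid_cache[[name]] <- force(expr)
  nereid_cache[[name]]
}

nereid_fixture <- function() cached("ds", load_nereididae_genera())
paper_key <- function() cached("key", load_paper_key())
printed_diagnoses <- function() cached("pd", load_printed_diagnoses())
fixture_built_key <- function() cached("built_key", build_key(nereid_fixture()))
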