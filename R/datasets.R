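#' Load the packaged Nereididae genus dataset
#'
#' The genus-level morphological matrix for the polychaete family
#' Nereididae: 45 genera scored for 186 characters (146 multistate, 40
#' numeric/meristic), transcribed from published natural-language
#' descriptions with curated database-default ("implicit") states
#' materialised as recorded attributes.  The curation metadata — the
#' implicit-state table, individually justified curated cells, and the
#' applicability dependencies — ships alongside and is returned by
#' [nereididae_curation()].
#'
#' @return A [dataset()] that passes [validate_dataset()] with zero
#'   violations.
#' @export
load_nereididae_genera <- function() {
  chars_path <- fixture_path("nereididae-chars.txt")
  items_path <- fixture_path("nereididae-items.txt")
  ds <- read_delta(chars_path, items_path,
                   title = "Nereididae genera (45 taxa x 186 characters)")
  if (length(ds$taxa) != 45L || length(ds$characters) != 186L) {
    stop("fixture integrity error: expected 45 taxa x 186 characters, got ",
         length(ds$taxa), " x ", length(ds$characters), call. = FALSE)
  }
  # attach section headings by the published numbering ranges
  sections <- list(
    c(1, 20, "Prostomium, pharynx, and ventrum"),
    c(21, 82, "Pharyngeal papillae and paragnaths"),
    c(83, 128, "Dorsal lamellae and parapodia"),
    c(129, 178, "Aciculae and chaetae"),
    c(179, 179, "Pygidium and appendages"),
    c(180, 186, "Epitokal modifications and reproduction"))
  for (s in sections) {
    for (n in s[[1]]:s[[2]]) ds$characters[[n]]$section <- s[[3]]
  }
  ds
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "nereidkey")
  if (!nzchar(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}

#' Curation metadata for the Nereididae fixture
#'
#' @return List with `implicit_states`, `curated_cells`, `dependencies` and
#'   `notes`, as shipped in `extdata/nereididae-meta.json`.
#' @export
nereididae_curation <- function() {
  jsonlite::fromJSON(fixture_path("nereididae-meta.json"),
                     simplifyVector = FALSE)
}

#' Load the printed key to Nereididae genera
#'
#' The published 49-couplet dichotomous key, encoded verbatim: couplet 29 is
#' polytomous with four leads, terminals carry genus plus authority, and the
#' printed couplet-18 cross-reference anomaly (second lead pointing to
#' couplet 9 although couplet 19 is labelled "19(18)") is preserved and
#' flagged in `$anomalies` rather than silently repaired.
#'
#' @return A `nereid_key`.
#' @export
load_paper_key <- function() {
  obj <- jsonlite::fromJSON(fixture_path("nereididae-key.json"),
                            simplifyVector = FALSE)
  couplets <- lapply(obj$couplets, function(c) {
    leads <- lapply(c$leads, function(l) {
      stmts <- lapply(l$statements, function(s) list(
        char = if (is.null(s$char)) NULL else as.integer(s$char),
        states = if (is.null(s$states)) NULL else as.integer(unlist(s$states)),
        text = s$text))
      d <- l$destination
      dest <- if (!is.null(d$couplet)) list(couplet = as.integer(d$couplet))
        else list(taxon = d$taxon, authority = d$authority)
      list(statements = stmts, destination = dest)
    })
    list(number = as.integer(c$number), parent = as.integer(c$parent),
         leads = leads)
  })
  structure(list(title = obj$title,
                 n_confirmatory = as.integer(obj$n_confirmatory),
                 couplets = couplets,
                 inseparable = list(),
                 anomalies = obj$anomalies),
            class = "nereid_key")
}

#' Load the printed diagnoses
#'
#' The published per-genus minimal diagnoses (DiagLevel = 1) and, where
#' attained, secondary diagnoses (DiagLevel = 2), as (character, states)
#' sets, plus the documented list of genus/rival pairs whose printed
#' minimal diagnosis cannot be reproduced from the transcribed matrix under
#' disjoint-state comparison (see the fixture curation notes).
#'
#' @return List with `diagnoses` (per genus: `minimal`, `secondary`,
#'   `secondary_attained`, `unmatched`) and `known_level1_failures`.
#' @export
load_printed_diagnoses <- function() {
  obj <- jsonlite::fromJSON(fixture_path("nereididae-diagnoses.json"),
                            simplifyVector = FALSE)
  diag <- lapply(obj$diagnoses, function(d) {
    list(genus = d$genus,
         minimal = lapply(d$minimal, function(x)
           list(char = as.integer(x$char), states = as.integer(unlist(x$states)))),
         secondary = lapply(d$secondary, function(x)
           list(char = as.integer(x$char), states = as.integer(unlist(x$states)))),
         secondary_attained = isTRUE(d$secondary_attained),
         unmatched = d$unmatched)
  })
  names(diag) <- vapply(diag, `[[`, character(1), "genus")
  list(diagnoses = diag,
       known_level1_failures = obj$known_level1_failures)
}

#' Synthetic dataset parameters
#'
#' Defaults emulate the structure of the packaged genus matrix: 45 taxa,
#' 186 characters of which about a fifth are numeric, mostly binary state
#' lists, about 6% of recorded multistate cells polymorphic, and roughly
#' half of all cells unscored.
#'
#' @param n_taxa,n_characters matrix dimensions.
#' @param numeric_fraction fraction of characters that are numeric.
#' @param states_distribution probabilities of 2/3/4/5-state characters.
#' @param polymorphism_rate chance a recorded multistate cell carries more
#'   than one state.
#' @param unknown_rate chance a cell is left unscored.
#' @param dependency_rate fraction of eligible characters given an
#'   applicability dependency on a preceding binary character.
#' @param guarantee_distinct resample (bounded retries) until every pair of
#'   taxa differs on at least one character.
#' @param seed integer seed; generation is a pure function of the params.
#' @return A list of class `nereid_synth_params`.
#' @export
synthetic_params <- function(n_taxa = 45L, n_characters = 186L,
                             numeric_fraction = 0.215,
                             states_distribution = c(`2` = 0.92, `3` = 0.06,
                                                     `4` = 0.015, `5` = 0.005),
                             polymorphism_rate = 0.06,
                             unknown_rate = 0.48,
                             dependency_rate = 0.1,
                             guarantee_distinct = TRUE,
                             seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  rates <- c(numeric_fraction, polymorphism_rate, unknown_rate, dependency_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), n_taxa >= 1L, n_characters >= 1L,
            length(states_distribution) == 4L)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_characters = as.integer(n_characters),
                 numeric_fraction = numeric_fraction,
                 states_distribution = states_distribution / sum(states_distribution),
                 polymorphism_rate = polymorphism_rate,
                 unknown_rate = unknown_rate,
                 dependency_rate = dependency_rate,
                 guarantee_distinct = isTRUE(guarantee_distinct),
                 seed = as.integer(seed)),
            class = "nereid_synth_params")
}

#' Generate a synthetic dataset
#'
#' A pure function of its parameters: the same `params` always yield the
#' identical dataset.  Dimensions are exact; the stochastic rates hold in
#' expectation.  With `guarantee_distinct`, generation is retried (up to 25
#' times) until all taxon pairs differ on at least one character, and fails
#' with an error if the parameter combination cannot satisfy it.
#'
#' @param params a [synthetic_params()].
#' @return A [dataset()].
#' @export
generate_synthetic <- function(params) {
  stopifnot(inherits(params, "nereid_synth_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  for (try in seq_len(if (params$guarantee_distinct) 25L else 1L)) {
    ds <- generate_once(params)
    if (!params$guarantee_distinct || all_pairs_distinct(ds)) return(ds)
  }
  stop("could not satisfy guarantee_distinct after 25 attempts ",
       "(too few informative characters?)", call. = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

generate_once <- function(p) {
  nch <- p$n_characters
  kinds <- ifelse(stats::runif(nch) < p$numeric_fraction, "numeric", "multistate")
  nstates <- integer(nch)
  chars <- vector("list", nch)
  controllers <- integer()   # binary multistate chars seen so far
  for (j in seq_len(nch)) {
    if (kinds[j] == "multistate") {
      ns <- sample(2:5, 1L, prob = p$states_distribution)
      nstates[j] <- ns
      deps <- list()
      if (length(controllers) && stats::runif(1) < p$dependency_rate) {
        ctl <- if (length(controllers) == 1L) controllers else
          sample(controllers, 1L)
        deps <- list(list(controller = ctl, states = 1L))
      }
      chars[[j]] <- character_def(j, sprintf("character %d", j), "multistate",
                                  states = sprintf("state %d.%d", j, seq_len(ns)),
                                  dependencies = deps)
      if (ns == 2L && !length(deps)) controllers <- c(controllers, j)
    } else {
      chars[[j]] <- character_def(j, sprintf("measure %d", j), "numeric",
                                  unit = "count")
    }
  }
  taxa <- vector("list", p$n_taxa)
  for (i in seq_len(p$n_taxa)) {
    attrs <- list()
    for (j in seq_len(nch)) {
      ch <- chars[[j]]
      # applicability first: controller recorded at excluding state
      dep <- if (length(ch$dependencies)) ch$dependencies[[1]] else NULL
      if (!is.null(dep)) {
        ctl <- attrs[[as.character(dep$controller)]]
        if (is_recorded(ctl) && !is.null(ctl$states) &&
            !any(dep$states %in% ctl$states)) {
          attrs[[as.character(j)]] <- attr_inapplicable()
          next
        }
      }
      if (stats::runif(1) < p$unknown_rate) next  # UNKNOWN: simply unscored
      a <- if (ch$kind == "multistate") {
        ns <- length(ch$states)
        k <- if (stats::runif(1) < p$polymorphism_rate && ns >= 2L) 2L else 1L
        attr_states(sample.int(ns, k))
      } else {
        lo <- sample.int(50L, 1L)
        attr_range(lo, lo + sample(0:10, 1L))
      }
      attrs[[as.character(j)]] <- a
    }
    taxa[[i]] <- taxon_record(sprintf("taxon_%02d", i), attributes = attrs)
  }
  dataset(chars, taxa,
          title = sprintf("synthetic (seed %d)", p$seed))
}

all_pairs_distinct <- function(ds) {
  m <- dataset_masks(ds)
  n <- nrow(m$mask)
  for (i in seq_len(n - 1L)) {
    D <- differ_matrix(m, i)
    if (any(rowSums(D[(i + 1L):n, , drop = FALSE]) == 0L)) return(FALSE)
  }
  TRUE
}
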