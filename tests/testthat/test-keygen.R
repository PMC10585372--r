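test_that("score_character follows the documented formula", {
  chars <- list(character_def(1, "c1", "multistate", c("a", "b")),
                character_def(2, "c2", "multistate", c("a", "b")))
  taxa <- list(
    taxon_record("A", attributes = list(`1` = attr_states(1), `2` = attr_states(1))),
    taxon_record("B", attributes = list(`1` = attr_states(2), `2` = attr_states(1))))
  ds <- dataset(chars, taxa)
  # even binary split, neutral reliability, no reuse: exactly 1
  expect_equal(score_character(ds, c("A", "B"), 1), 1.0)
  # one prior use divides by the reuse base
  expect_equal(score_character(ds, c("A", "B"), 1, usage = c(`1` = 1L)),
               1 / 1.01)
  # a character with a single realised state is unusable
  expect_true(is.na(score_character(ds, c("A", "B"), 2)))
  # reliability feeds in through rbase^(r - 5)
  ds$characters[[1]]$reliability <- 7
  expect_equal(score_character(ds, c("A", "B"), 1), 2^2)
})

test_that("score ranking equals brute-force recomputation on synthetic nodes", {
  for (seed in 4:8) {
    ds <- generate_synthetic(small_params(seed))
    node <- names(ds$taxa)
    usage <- stats::setNames(c(1L, 2L), c("1", "3"))
    p <- keygen_params()
    for (cn in seq_along(ds$characters)) {
      got <- score_character(ds, node, cn, usage, p)
      ch <- ds$characters[[cn]]
      if (ch$kind != "multistate") { expect_true(is.na(got)); next }
      sets <- lapply(node, function(nm) {
        a <- ds$taxa[[nm]]$attributes[[as.character(cn)]]
        if (!is.null(a) && a$status == "RECORDED" && !is.null(a$states))
          a$states else NULL
      })
      realised <- sort(unique(unlist(sets)))
      if (length(realised) < 2L) { expect_true(is.na(got)); next }
      counts <- vapply(realised, function(s) sum(vapply(sets, function(x)
        is.null(x) || s %in% x, logical(1))), numeric(1))
      pr <- counts / sum(counts)
      ent <- -sum(pr * log(pr)) / log(length(realised))
      v <- sum(vapply(sets, function(x)
        (if (is.null(x)) length(realised) else length(intersect(x, realised))) > 1L,
        logical(1)))
      u <- if (as.character(cn) %in% names(usage)) usage[[as.character(cn)]] else 0L
      want <- ent * p$varywt^v * p$rbase^(ch$reliability - 5) / p$reuse^u
      expect_equal(got, want, info = paste(seed, cn))
    }
  }
})

test_that("a two-taxon one-character dataset builds a single couplet", {
  ds <- dataset(list(character_def(1, "wings", "multistate", c("present", "absent"))),
                list(taxon_record("A", "X, 1900",
                                  attributes = list(`1` = attr_states(1))),
                     taxon_record("B", "Y, 1901",
                                  attributes = list(`1` = attr_states(2)))))
  k <- build_key(ds)
  expect_length(k$couplets, 1L)
  expect_length(k$couplets[[1]]$leads, 2L)
  expect_identical(k$couplets[[1]]$leads[[1]]$destination$taxon, "A")
  expect_identical(k$couplets[[1]]$leads[[2]]$destination$authority, "Y, 1901")
  # golden render of the one-couplet key
  expect_identical(render_key(k, ds),
                   c("1(0)\twings present\t**A X, 1900**",
                     "–\twings absent\t**B Y, 1901**"))
})

test_that("generated keys are complete, sound and deterministic", {
  for (seed in c(2, 9, 21)) {
    ds <- generate_synthetic(small_params(seed, n_taxa = 7L, n_characters = 14L))
    k <- build_key(ds)
    terms <- unlist(lapply(k$couplets, function(c) lapply(c$leads, function(l)
      c(l$destination$taxon, l$destination$taxa))))
    expect_true(all(names(ds$taxa) %in% terms), info = seed)
    for (nm in names(ds$taxa)) {
      r <- route_specimen(k, ds$taxa[[nm]]$attributes)
      expect_true(nm %in% r$terminals, info = paste(seed, nm))
    }
    expect_identical(build_key(ds), k)
    # parameters change character choice but never soundness
    k2 <- build_key(ds, keygen_params(reuse = 1.5, varywt = 0.5))
    for (nm in names(ds$taxa)) {
      expect_true(nm %in% route_specimen(k2, ds$taxa[[nm]]$attributes)$terminals)
    }
  }
})

test_that("routing follows every compatible lead", {
  ds <- tiny_dataset()
  k <- build_key(ds)
  # an all-unknown specimen reaches every terminal
  r <- route_specimen(k, list())
  expect_setequal(r$terminals, names(ds$taxa))
  # confirmatory disagreements never block a path
  expect_true(all(vapply(r$paths, function(p) length(p$taxa) >= 1L, logical(1))))
})

test_that("generated fixture key separates all 45 genera", {
  ds <- nereid_fixture()
  k <- fixture_built_key()
  expect_length(k$inseparable, 0L)
  terms <- unlist(lapply(k$couplets, function(c) lapply(c$leads, function(l)
    c(l$destination$taxon, l$destination$taxa))))
  expect_true(all(names(ds$taxa) %in% terms))
  rep <- check_key_consistency(k, ds)
  expect_identical(nrow(rep$contradictions), 0L)
  expect_length(rep$unreached, 0L)
})

test_that("the encoded printed key matches the published structure", {
  key <- paper_key()
  expect_length(key$couplets, 49L)
  # the polytomous couplet has four leads on the ligule-commencement states
  c29 <- key$couplets[[29]]
  expect_length(c29$leads, 4L)
  expect_identical(vapply(c29$leads, function(l) l$statements[[1]]$char,
                          integer(1)), rep(90L, 4))
  # first couplet splits on maxillary ring paragnaths
  s1 <- key$couplets[[1]]$leads[[1]]$statements[[1]]
  expect_identical(s1$char, 25L)
  expect_identical(s1$states, 1L)
  # every destination resolves, except via the flagged couplet-18 anomaly
  dests <- unlist(lapply(key$couplets, function(c)
    vapply(c$leads, function(l)
      if (is.null(l$destination$couplet)) NA_integer_ else l$destination$couplet,
      integer(1))))
  dests <- dests[!is.na(dests)]
  expect_true(all(dests %in% 1:49))
  reachable <- integer()
  walk <- function(n) {
    if (n %in% reachable) return()
    reachable <<- c(reachable, n)
    for (l in key$couplets[[n]]$leads) {
      if (!is.null(l$destination$couplet)) walk(l$destination$couplet)
    }
  }
  walk(1L)
  expect_identical(setdiff(1:49, reachable),
                   as.integer(unlist(key$anomalies$unreachable_couplets)))
  # terminals carry genus + authority as printed
  t4 <- key$couplets[[4]]$leads[[1]]$destination
  expect_identical(t4$taxon, "Pseudonereis")
  expect_identical(t4$authority, "Kinberg, 1865")
})

test_that("routing genera through the printed key flags only the known anomaly", {
  ds <- nereid_fixture()
  key <- paper_key()
  missed <- character()
  for (nm in names(ds$taxa)) {
    r <- route_specimen(key, ds$taxa[[nm]]$attributes)
    if (!nm %in% r$terminals) missed <- c(missed, nm)
  }
  expect_setequal(missed, unlist(key$anomalies$affected_taxa))
  # the published route of Pseudonereis: couplets 1 -> 2 -> 3 -> 4
  r <- route_specimen(key, ds$taxa[["Pseudonereis"]]$attributes)
  hit <- Filter(function(p) "Pseudonereis" %in% p$taxa, r$paths)
  expect_identical(hit[[1]]$path, c(1L, 2L, 3L, 4L))
})

test_that("dangling destinations are a key-structure error", {
  ds <- tiny_dataset()
  k <- build_key(ds)
  k$couplets[[1]]$leads[[1]]$destination <- list(couplet = 99L)
  expect_error(route_specimen(k, list()), "dangling")
})
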