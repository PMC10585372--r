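test_that("canonical JSON round trip is lossless", {
  ds <- tiny_dataset()
  j <- dataset_to_json(ds)
  ds2 <- dataset_from_json(text = j)
  expect_identical(dataset_to_json(ds2), j)
  expect_identical(names(ds2$taxa), names(ds$taxa))
  for (seed in 1:5) {
    sds <- generate_synthetic(small_params(seed))
    expect_identical(dataset_to_json(dataset_from_json(text = dataset_to_json(sds))),
                     dataset_to_json(sds))
  }
})

test_that("DELTA dialect round trip is lossless", {
  ds <- tiny_dataset()
  cp <- withr::local_tempfile(fileext = ".txt")
  ip <- withr::local_tempfile(fileext = ".txt")
  write_delta(ds, cp, ip)
  ds2 <- read_delta(cp, ip, title = ds$title)
  expect_identical(dataset_to_json(ds2), dataset_to_json(ds))

  for (seed in 1:5) {
    sds <- generate_synthetic(small_params(seed))
    write_delta(sds, cp, ip)
    expect_identical(dataset_to_json(read_delta(cp, ip, title = sds$title)),
                     dataset_to_json(sds))
  }
})

test_that("DELTA attribute tokens parse per the dialect definition", {
  cp <- withr::local_tempfile(fileext = ".txt")
  ip <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#1. shape/", "1. round/", "2. oval/", "3. flat/",
               "#2. width/", "u count/"), cp)
  writeLines(c("#1. Thing <Doe, 2000>/", "1,1/2 2,2-4",
               "#2. Other/", "1,3<rarely> 2,7-7"), ip)
  ds <- read_delta(cp, ip)
  a <- ds$taxa[["Thing"]]$attributes
  expect_identical(a[["1"]]$states, c(1L, 2L))     # "1,1/2" on a 3-state char
  expect_identical(a[["2"]]$range, c(2, 4))        # numeric range
  b <- ds$taxa[["Other"]]$attributes
  expect_identical(b[["1"]]$comment, "rarely")
  expect_identical(b[["2"]]$range, c(7, 7))
  expect_identical(ds$taxa[["Thing"]]$authority, "Doe, 2000")
  # undeclared state is a parse error naming the item
  writeLines(c("#1. Thing/", "1,4"), ip)
  expect_error(read_delta(cp, ip), "Thing.*character 1")
})

test_that("fixture DELTA round trip is byte-identical as canonical JSON", {
  ds <- nereid_fixture()
  cp <- withr::local_tempfile(fileext = ".txt")
  ip <- withr::local_tempfile(fileext = ".txt")
  write_delta(ds, cp, ip)
  ds2 <- read_delta(cp, ip, title = ds$title)
  # sections are loader metadata, not part of the file format
  for (n in seq_along(ds2$characters)) {
    ds2$characters[[n]]$section <- ds$characters[[n]]$section
  }
  expect_identical(dataset_to_json(ds2), dataset_to_json(ds))
})

test_that("NEXUS writer emits correct dimensions and cells", {
  ds <- nereid_fixture()
  txt <- write_nexus(ds)
  expect_match(txt, "NTAX=45", fixed = TRUE)
  expect_match(txt, "NCHAR=146", fixed = TRUE)

  one <- dataset(list(character_def(1, "c1", "multistate", c("a", "b"))),
                 list(taxon_record("T", attributes = list(`1` = attr_states(1:2)))))
  expect_match(write_nexus(one), "{12}", fixed = TRUE)
  expect_error(write_nexus(dataset(list(character_def(1, "n", "numeric")),
                                   list(taxon_record("T")))),
               "no exportable characters")
  # symbols must cover the state count
  six <- dataset(list(character_def(1, "c", "multistate", letters[1:6])),
                 list(taxon_record("T", attributes = list(`1` = attr_states(6)))))
  expect_error(write_nexus(six, options = nexus_options(symbols = "123")),
               "symbols cover")
})

test_that("NEXUS round trip preserves every exported cell", {
  for (seed in 1:8) {
    sds <- generate_synthetic(small_params(seed))
    txt <- write_nexus(sds)
    back <- read_nexus(text = txt)
    keep <- which(vapply(sds$characters, function(c) c$kind == "multistate",
                         logical(1)))
    expect_identical(names(back$taxa), names(sds$taxa))
    expect_identical(length(back$characters), length(keep))
    for (nm in names(sds$taxa)) {
      for (k in seq_along(keep)) {
        orig <- sds$taxa[[nm]]$attributes[[as.character(keep[k])]]
        got <- back$taxa[[nm]]$attributes[[as.character(k)]]
        if (is.null(orig)) orig <- attr_unknown()
        expect_identical(got$status, orig$status,
                         info = sprintf("seed %d %s char %d", seed, nm, keep[k]))
        if (orig$status == "RECORDED") {
          expect_identical(got$states, orig$states)
        }
      }
    }
  }
})

test_that("interleaved and non-interleaved NEXUS parse identically", {
  sds <- generate_synthetic(small_params(3, n_taxa = 4L, n_characters = 6L))
  txt <- write_nexus(sds)
  ds1 <- read_nexus(text = txt)
  # hand-build an interleaved variant of the same matrix
  lines <- strsplit(txt, "\n")[[1]]
  mstart <- grep("MATRIX", lines)
  mrows <- grep("^    '", lines)
  rows <- lines[mrows]
  split_at <- 3L
  inter <- vapply(rows, function(r) {
    m <- regmatches(r, regexec("^(    '[^']*' )(.*)$", r))[[1]]
    paste0(m[2], substr(m[3], 1, split_at))
  }, character(1))
  inter2 <- vapply(rows, function(r) {
    m <- regmatches(r, regexec("^(    '[^']*' )(.*)$", r))[[1]]
    paste0(m[2], substr(m[3], split_at + 1L, nchar(m[3])))
  }, character(1))
  lines2 <- c(lines[1:(mstart)], inter, inter2,
              lines[(max(mrows) + 1L):length(lines)])
  lines2 <- sub("FORMAT ", "FORMAT INTERLEAVE ", lines2)
  ds2 <- read_nexus(text = paste(lines2, collapse = "\n"))
  expect_identical(dataset_to_json(ds2), dataset_to_json(ds1))
})

test_that("NEXUS without CHARSTATELABELS auto-names characters", {
  txt <- paste(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=2 NCHAR=3;",
    "FORMAT DATATYPE=STANDARD SYMBOLS=\"12\" MISSING=? GAP=-;",
    "MATRIX",
    "t_one 12?",
    "t_two 2-1",
    ";",
    "END;", sep = "\n")
  expect_message(ds <- read_nexus(text = txt), "auto-named")
  expect_identical(ds$characters[[1]]$label, "char_1")
  expect_identical(ds$taxa[["t one"]]$attributes[["3"]]$status, "UNKNOWN")
  expect_identical(ds$taxa[["t two"]]$attributes[["2"]]$status, "INAPPLICABLE")
  expect_error(read_nexus(text = "not nexus"), "line 1")
})

test_that("legacy label truncation is reproducible on request", {
  ds <- nereid_fixture()
  txt <- write_nexus(ds, options = nexus_options(full_labels = FALSE))
  back <- read_nexus(text = txt)
  lens <- nchar(vapply(back$characters, function(c) c$label, character(1)))
  expect_true(all(lens <= 30L))
  full <- read_nexus(text = write_nexus(ds))
  expect_true(any(nchar(vapply(full$characters, function(c) c$label,
                               character(1))) > 30L))
})

test_that("independent parser (ape) agrees on a polymorphism-free export", {
  skip_if_not_installed("ape")
  sds <- generate_synthetic(small_params(11, n_taxa = 5L, n_characters = 8L,
                                         polymorphism_rate = 0))
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus(sds, path = nex)
  ape_read <- ape::read.nexus.data(nex)
  ours <- read_nexus(nex)
  expect_identical(sort(names(ape_read)), sort(names(ours$taxa)))
  for (nm in names(ours$taxa)) {
    ape_row <- toupper(unlist(ape_read[[nm]]))
    our_row <- vapply(seq_along(ours$characters), function(k) {
      a <- ours$taxa[[nm]]$attributes[[as.character(k)]]
      if (a$status == "RECORDED") as.character(a$states)
      else if (a$status == "UNKNOWN") "?" else "-"
    }, character(1))
    expect_identical(unname(ape_row), our_row, info = nm)
  }
})
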