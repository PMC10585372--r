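# nereidkey

A descriptive-taxonomy engine for R, built around coded taxon-by-character
matrices, with the genus-level morphological dataset of the polychaete
family **Nereididae** (ragworms: 45 genera scored for 186 characters) as its
packaged, fully worked dataset.

Identification of nereidid genera is hard: the most species-rich genera are
polymorphic for the characters that separate other genera, many characters
cannot be scored on damaged material, and a dichotomous key always ends at
*a* name, right or wrong.  The toolchain this package implements is the
classic answer of computer-assisted taxonomy:

* **Descriptions** — natural-language taxon descriptions generated as
  concatenations of the states recorded for each taxon
  (`describe_taxon()`).
* **Minimal diagnoses** — the smallest set of characters whose recorded
  states distinguish one taxon from *all* others at a chosen diagnostic
  level *d* (the classic *DiagLevel*: each rival must differ on at least
  *d* of the characters; *d* = 1 is a minimal diagnosis, *d* = 2 a
  "secondary diagnosis" usable for verification).  Formally a minimum
  set-multicover, solved exactly by branch and bound
  (`minimal_diagnosis()`, `verify_diagnosis()`, `diagnosis_feasibility()`).
* **Key generation** — dichotomous/polytomous keys built by recursive
  partitioning, scoring each candidate character at a node by
  `E(c) · varywt^v · rbase^(r−5) / reuse^u` (normalised Shannon entropy of
  the induced split, down-weighted for variable taxa, reliability and
  re-use), with the published settings `RBASE = 2.00`, `REUSE = 1.01`,
  `VARYWT = 0.80` and two confirmatory statements per lead as defaults
  (`build_key()`, `route_specimen()`, `render_key()`,
  `check_key_consistency()`).
* **Interactive (multi-entry) identification** — assert characters in any
  order; taxa accumulate mismatch counts instead of being eliminated
  outright, so an error tolerance is a count threshold
  (`identification_session()`, `assert_attribute()`, `rank_characters()`,
  `differences_report()`).
* **Formats** — a documented DELTA-style text dialect, NEXUS morphology
  matrices (`write_nexus()` / `read_nexus()`), and a canonical JSON
  serialisation; plus a seeded synthetic-matrix generator for
  property-based testing (`generate_synthetic()`).

Besides the matrix, the package ships the printed 49-couplet key to genera
(verbatim, including a flagged cross-reference slip in couplet 18) and the
printed minimal/secondary diagnoses, with all curation decisions recorded
as data (`nereididae_curation()`).

## Worked example

```r
library(nereidkey)

ds <- load_nereididae_genera()
validate_dataset(ds)
#> dataset: 45 taxa, 186 characters (146 multistate, 40 numeric)
#> no violations

# the smallest character set separating a genus from all 44 others
d <- minimal_diagnosis(ds, "Gymnonereis")
diagnosis_prose(ds, d)
#> Dorsal notopodial ligule, reduction on posterior chaetigers markedly
#> reduced; Accessory ventral cirrus present (i.e., double ventral cirri)
#> (minimal diagnosis).

# why some genera cannot attain a secondary (level-2) diagnosis:
f <- diagnosis_feasibility(ds, "Alitta", 2)
f$feasible      #> FALSE
f$blocking      #> Neanthes: 1   (a single character separates the two)

# interactive identification: one decisive observation
s <- identification_session(ds, tolerance = 0)
s <- assert_attribute(s, 15, 1)   # ventral peristomial flap present
candidates(s)
#> [1] "Cheilonereis"

# routing a genus through the printed key
key <- load_paper_key()
r <- route_specimen(key, ds$taxa[["Pseudonereis"]]$attributes)
r$terminals
#> [1] "Pseudonereis"     # via couplets 1 -> 2 -> 3 -> 4
```

Each printed value above is what the code actually returns on the shipped
fixture.

A command-line wrapper is installed under `inst/scripts/nereidkey`
(subcommands `describe`, `diagnose`, `key build|render|route|check`,
`identify`, `export-nexus`, `convert`, `fixtures`, `validate`), all backed
by `nereid_cli()`.

## What a green test does (and does not) establish

The fixture was transcribed from published natural-language descriptions,
which omit characters at their database default; a curated implicit-state
table reconstructs those defaults and is constrained by the printed
diagnoses themselves (see the methods vignette,
`vignettes/nereidkey-methods.Rmd`).  Seven genus/rival diagnosis pairs and
five key-routing exceptions are genuine contradictions in the source
material under disjoint-state comparison; they ship as data and the test
suite asserts them *exactly* — no more, no fewer.
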