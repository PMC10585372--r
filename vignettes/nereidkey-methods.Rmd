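---
title: "Descriptive taxonomy with nereidkey: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptive taxonomy with nereidkey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nereidkey)
```

## The data model

Everything in this package operates on a *taxon-by-character matrix*.  A
**character** is a scored morphological feature, either qualitative
("Oral ring paragnaths": present / absent; state codes are 1-based) or
meristic (a count, or a chaetiger position).  A matrix cell — an
**attribute** — is a non-empty *set* of state codes (a set with two or more
states records polymorphism, e.g. "present, or absent"), a closed numeric
interval (a single printed value is the degenerate interval `[v, v]`), or
one of two kinds of missingness: **UNKNOWN** (not scored) and
**INAPPLICABLE** (cannot logically be scored, e.g. palpostyle form when
palpostyles are absent; applicability is declared per character as a
dependency on a controlling character's states).

The comparison semantics everything else builds on is `differ()`: two taxa
*differ* for a character iff both are recorded and their values cannot
agree — disjoint state sets, or non-overlapping intervals.  UNKNOWN and
INAPPLICABLE never create a difference.  This is the conservative
convention of multi-access identification practice: missing data must not
eliminate a taxon.  The consequence worth remembering is that a polymorphic
cell is hard to distinguish: `{present, absent}` overlaps everything, so a
genus recorded "present, or absent" can never be separated on that
character.

## Diagnoses

A level-`d` diagnosis of a taxon is a set of characters on which every
other taxon differs at least `d` times (`d` is the classic *DiagLevel*
setting: `d = 1` is a minimal diagnosis; `d = 2` adds a safety margin — a
"secondary diagnosis" — so that one misinterpreted character cannot produce
a false confirmation).  Finding a smallest such set is a set-multicover
problem.  `minimal_diagnosis()` solves it exactly by branch and bound
(greedy solution as the upper bound; the bound at each node is the larger
of the maximum remaining deficit and total-deficit over best-column
coverage), with ties resolved toward the lowest character number so results
are deterministic.  The greedy mode approximates the behaviour of legacy
tools: repeatedly add the character that raises the most below-level
rivals.  Greedy is never smaller than exact, and both are validated in the
test suite against exhaustive subset enumeration on small synthetic
matrices.  `verify_diagnosis()` returns per-rival margins so users can see
how much redundancy a diagnosis really has.

## Key generation

`build_key()` recursively partitions the taxa.  At each node every usable
multistate character is scored

    score = E(c) * varywt^v * rbase^(r - 5) / reuse^u

where `E(c)` is the Shannon entropy of the node's taxa across the
character's realised states, normalised to `[0, 1]` (taxa that are
polymorphic or unscored are counted in every lead they could follow), `v`
is the number of such multi-lead taxa, `r` the character's reliability
weight (0–10, default 5 = neutral), and `u` the number of times the
character was already used on the path.  The defaults (`rbase = 2.0`,
`abase = 1.0` disabled, `reuse = 1.01`, `varywt = 0.8`, two confirmatory
statements per lead) are the settings used for the published Nereididae
key.  The published software never documented its internal scoring
function; this formula is this package's own, designed to reproduce the
*roles* of those settings, and reproducing the printed key verbatim is
explicitly not promised — reproducing its routing behaviour is, and is
tested.

Two design points are worth flagging.  First, a lead that excludes nobody
(every node taxon is compatible with it) makes no progress; the generator
bans the character below such a lead until the taxon set shrinks, which
both guarantees termination and mirrors how printed keys let polymorphic
taxa "key out in more than one couplet".  Second, confirmatory statements
are only attached when *every* taxon that can follow the lead is compatible
with them, so a generated key can never contradict a legitimately routed
taxon; in routing they are checked and reported but never block — exactly
how printed keys intend them (verification, not branching).

`route_specimen()` follows every compatible lead, so unknowns fan out and
reach every terminal they might belong to; `check_key_consistency()` sweeps
all taxa through a key and reports contradictions and taxa that fail to
reach themselves.

## Interactive identification

`identification_session()` implements multi-entry identification with
*mismatch counting* rather than hard elimination: each asserted character
increments a mismatch count for the taxa whose recorded states are disjoint
from the observation, and candidates are the taxa with at most `tolerance`
mismatches.  With `tolerance = 1` a single observation error never
eliminates the true taxon (a property the test suite checks by simulation).
`rank_characters()` orders the unasserted characters by the expected number
of remaining candidates, computed under a uniform prior over candidates and
their recorded states — a documented substitute for the undocumented
"best characters" statistic of legacy interactive keys.

## The Nereididae fixture and its curation

The package ships a transcription of a genus-level matrix for the
polychaete family Nereididae: 45 genera, 186 characters (146 multistate, 40
meristic), the printed 49-couplet key to genera, and the printed minimal
and secondary diagnoses.  Published natural-language descriptions are
*concatenations of recorded states*, which makes them mechanically
invertible; the transcription pipeline matched description clauses against
the character/state dictionary, with every unmatched clause resolved by
hand.

Two curation layers deserve honesty:

* **Implicit states.**  Descriptive-taxonomy databases omit characters at
  their default value from generated prose ("implicit values"), so the
  printed descriptions alone under-determine the matrix: several printed
  one-character minimal diagnoses (e.g. the P-bar paragnath character for
  *Pseudonereis*) are only valid if every rival genus is *recorded* at the
  default state.  A curated implicit-state table was therefore
  reconstructed, constrained by requiring the printed minimal diagnoses to
  verify and the printed pattern of secondary-diagnosis attainment (30
  attained / 15 not attained) to be reproduced — the latter is a sharp
  constraint, since over-filling the matrix creates spurious differences
  and makes level 2 feasible everywhere.  Both constraints now hold
  exactly, except for seven documented diagnosis failures.  The table, the
  individually justified curated cells, and the per-case reasons ship with
  the fixture (`nereididae_curation()`, and the known-failure list in
  `load_printed_diagnoses()`).

* **Known contradictions.**  Seven genus/rival pairs cannot satisfy their
  printed minimal diagnoses under disjoint-state comparison no matter how
  the matrix is coded: two hinge on an "antennae form" character used by
  the printed diagnoses and key but absent from the printed character list,
  and five involve rivals polymorphic for every character in the printed
  set.  The printed key also contains a cross-reference slip (couplet 18's
  second lead points to couplet 9, stranding the five genera keyed under
  couplet 19); it is stored verbatim and flagged, not repaired, and the
  routing sweep asserts that exactly those five genera fail to self-route.

## The synthetic generator

`generate_synthetic()` is the test harness's world: its defaults mirror the
fixture's measured structure (45 × 186, 21.5% numeric characters, mostly
binary state lists, 6% of recorded multistate cells polymorphic, 48% of
cells unscored, and applicability dependencies on binary controllers).
Generation is a pure function of its parameter object — the seed is
mandatory, the session RNG stream is left untouched — and
`guarantee_distinct` retries (boundedly) until every taxon pair differs
somewhere, which is what makes level-1 diagnoses feasible for every taxon.
What the generator does *not* emulate: correlated characters, the strongly
non-uniform distribution of unknowns across body regions, comment text,
and taxonomic structure among taxa.  A green property test on synthetic
data therefore establishes algorithmic correctness, not fidelity to any
particular real dataset — that is what the fixture-based tests are for.
Property tests scale the matrices down (typically 4–9 taxa, 7–14
characters) to keep exhaustive oracles affordable; the protocol sizes of
the acceptance checks are preserved where stated (100 seeded matrices for
the solver-vs-enumeration check, 50 for keys and round trips).

## File formats

The DELTA-style dialect is deliberately a *documented subset* of the
classic format: characters as `#n. label/` with `k. state/` lines plus
`u unit/` and `d controller,states/` extensions, items as attribute tokens
(`4,1/2`, `23,50-110`, `U`, `-`, trailing `<comment>`).  Unsupported
directives are skipped with a warning, never silently misread.  Round trips
through DELTA and the canonical JSON are byte-lossless and tested; NEXUS
round trips are lossless over the exported (multistate) characters.
UNKNOWN is exported to NEXUS as `?` and INAPPLICABLE as the gap symbol
`-` — common morphological-matrix convention, documented here because the
source material never states its own.  Labels are exported in full by
default; the legacy 30-character truncation is available as an option
(`full_labels = FALSE`) for compatibility.  The independent-parser
cross-check in the tests uses `ape::read.nexus.data()`, which does not
support polymorphic cells, so that check runs on polymorphism-free
exports; our own reader covers the full format.

## Known limitations

* The implicit-state reconstruction is constrained by printed outputs, not
  observed morphology; cells it fills are defaults, and
  `nereididae_curation()` should be consulted before treating any single
  implicit cell as evidence.
* Exact diagnosis search is exponential in the worst case; on the fixture
  the largest exact minimal diagnosis (9 characters) solves in well under a
  second, but adversarial matrices could be slow — the greedy mode is the
  escape hatch.
* Numeric characters participate in `differ()` and diagnoses but not in
  key generation or NEXUS export, matching how meristic characters are
  treated in the source workflow.
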