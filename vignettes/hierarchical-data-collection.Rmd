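---
title: "Hierarchical field data collection: model, engine and synchronisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical field data collection: model, engine and synchronisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcollect)
```

## The problem

Field epidemiology, ecology and citizen-science projects routinely collect
structured questionnaire data on mobile devices, offline, from many
gatherers at once, and submit it later to a central database. A single flat
questionnaire rarely fits: a school survey needs one record per school,
linked to many class records, each linked to many pupil records, with
side-records (a teacher's absences) whose count is unknown in advance.
`fieldcollect` models this domain end to end: declarative multi-form
project definitions, an interview engine with skip logic and validation, a
hierarchical entry store with referential integrity, top-down client-server
synchronisation, and delimited/XML export.

## The data model

A **project** is an ordered chain of **forms** in strict one-to-many
parent-child relation (level 1 at the top), plus **branch forms** attached
to a specific `branch_trigger` question of a host form. The design space
here was genuinely open -- trees of forms are conceivable -- but every
worked example in this domain (schools surveys, multi-level specimen
collection) is a linear chain with side-branches, so the hierarchy is
deliberately restricted to a linear chain; a branch form may not itself
declare branches, which keeps synchronisation ordering trivially
well-defined.

Each form is an ordered list of **fields**: free text (`text`,
`long_text`), choices (`dropdown`, `radio` -- one answer; `checkbox` --
several), and media (`location` as latitude/longitude/altitude/accuracy in
degrees and metres, `image`, `video`, `audio`, `barcode` as its decoded
string). Any number (0, 1 or many) of each kind may appear per form.

Entries link to their parent through a **key field**: a text or barcode
field whose value must be unique among siblings, or `AUTO`, which yields
`"<device id>_<creation ms>"` via `generate_auto_key()`. Key uniqueness is
enforced per (form, parent): two classes named "5B" in different schools
are legal. Reading uniqueness globally instead would make the canonical
schools example unusable, which is why the per-parent scope was chosen; its
one consequence is that a grandchild's parent key can in principle match
same-keyed parents under different grandparents, and the nested XML export
then attaches it to the first match in insertion order.

## The interview engine

A session presents fields in order. **Jumps** (skip logic) are clauses on
dropdown/radio questions: the first declared clause whose trigger values
contain the answer sends the cursor to its destination, a *later* field or
`END`; otherwise the interview continues to the next field. Forward-only
destinations are a model invariant, so every session terminates in at most
one submission per field, and a field skipped by a jump stores nothing (it
exports as an empty cell -- deliberately distinct from an explicit empty
answer, which optional fields may also produce). Jumps on checkbox fields
are rejected at validation time: a multi-answer has no single routing
value. Overlapping clauses resolve by declaration order.

Answer **validation** applies, in order: required, choice membership or
type parsing, integer/decimal typing, minimum/maximum (closed bounds),
date/time format (`dd/mm/yyyy` is checked as a real calendar date;
`mm:ss`/`hh:mm` check unit ranges), regular expression, and double-entry
equality. All failures are collected and reported together; a failed
submission never moves the cursor. Double entry compares the two inputs
byte-for-byte after stripping leading/trailing whitespace, case-sensitive.
Regex mismatches are hard errors by default with a `lenient_regex` switch
that downgrades them to warnings -- the barcode use case, where a wrongly
prefixed but readable barcode deserves a warning rather than a dead end.

A `branch_trigger` question takes a count n: n = 0 continues automatically
to the next question; n > 0 opens a branch prompt during which n entries of
the attached branch form are completed inline and bound to the host entry
(their parent key is filled in when the host is finalised, since an AUTO
host key does not exist earlier). Branch entries cannot be added after the
host form is complete; the inline prompt is the only path, matching how the
workflow presents them.

Sessions never read the host clock or hardware: time comes from an injected
`make_clock()` and the device identifier is a parameter, so every entry id,
timestamp and auto key in tests and simulations is reproducible.

## Store, synchronisation and export

`entry_store()` enforces two invariants on every insertion: a non-top-level
entry must have a parent entry above it whose key matches its parent key
(otherwise `orphan`), and a (form, parent, key) may appear once (otherwise
`duplicate` -- which also makes re-submission of an identical entry a
detectable no-op). `preload(store, k)` returns every entry of levels 1..k
and nothing below, the contract for resuming collection mid-project on a
fresh device. `query_entries()` filters by a closed time window and by
choice values (checkbox fields match on non-empty intersection), and
`chart_counts()` tallies answer distributions with declared-but-unanswered
values present at zero; unanswered entries are excluded from the
denominator rather than counted as a pseudo-choice.

Synchronisation sends data from the highest hierarchy level downwards so a
child can never arrive before its parent: `build_batches()` emits one batch
per level, with a host's branch entries placed immediately after it (the
ordering of branch entries relative to levels was open; host-adjacency
preserves integrity without a separate level). `apply_batch()` reports
`accepted`/`duplicate`/`orphan` per entry and never throws; rejected
entries stay queued client-side and reappear in the next batch build, so
repeated rounds (`sync_stores()`) converge to the union of client entries.
When two devices submit different entries under the same user-chosen key,
the first writer wins and the later one reports `duplicate` -- the model
cannot adjudicate content conflicts, only detect them. Media are planned
separately: image thumbnails always travel immediately, full
images/video/audio are deferred by default to a separate transfer.

Exports are CSV/TSV (RFC 4180 quoting; header `entry_id, created_at,
device_id, parent_key, key`, then field ids in form order) and nested XML
mirroring the hierarchy, which doubles as the store's persistence format
and reaches a byte-identical fixed point under export-import-export.
Checkbox values join with `";"` (escaped as `"\;"` inside values);
`created_at` is ISO-8601 UTC with milliseconds in tables and epoch
milliseconds in XML. Web-path entry (`import_web_entry()`) runs the
identical validation and jump pipeline with device id `"web"`, so a web
entry and a phone entry with the same answers export identically outside
the provenance columns.

## The fixture generators

`schools_demo_project()` is the canonical three-level chain
(school-class-pupil) with an absence branch on the class form, a
double-entered `^SC-[0-9]{5}$` barcode at pupil level and an AUTO pupil
key. `random_project(seed, ...)` draws projects covering every field kind,
validation rule (from a catalogue of regexes paired with samplers), jump
shapes and branch attachments; defaults (depth 3, 5 fields per form,
branch probability 0.3) mirror the demo project's scale.
`simulate_collection()` replays full collection runs through the ordinary
session pipeline -- every generated answer passes `validate_answer()` by
construction -- over per-device deterministic clocks (device d starts at
1408500000000 + (d-1)x10^9 ms, 1 s per step) so multi-device stores are
byte-reproducible per seed.

What the generators emulate is the *mechanics* of collection: hierarchy
shapes, answer typing, skip routing, interleaved multi-device submission.
What they do not emulate is real field data: answer distributions are
uniform, text is drawn from a word list, media are path strings with no
payloads, GPS fixes are uniform numbers rather than spatial clusters, and
devices never disagree about the same real-world school. Passing tests
therefore demonstrate the correctness of the machinery (round trips,
ordering, integrity, idempotence), not robustness to messy real-world
answer content beyond what the validation rules themselves express.

## Numerical and format choices

- Timestamps are UTC epoch milliseconds throughout; temporal filters are
  closed on both ends.
- Numeric attribute and cell serialisation uses plain notation with 15
  significant digits; the fixture generators round coordinates to 6
  decimals and decimals to 2, so all generated values round-trip exactly
  through text.
- Documents are UTF-8 only; unknown XML attributes/elements are preserved
  verbatim so the vocabulary stays extensible.
- The auto key joins device id and milliseconds with `"_"` so the parts
  stay recoverable from the concatenation.
- Problem sizes in the test-suite and acceptance runs (100 seeded projects
  for definition round trips, 50 stores for export fixed points, 500
  choice-only forms checked exhaustively against the naive interpreter, 20
  three-device sync scenarios, 10^4 generated keys) were chosen as the
  smallest sets that exercise every code path many times over while keeping
  a full run comfortably interactive.

## Known limitations

- The hierarchy is a strict linear chain; general form trees are out of
  scope, as is nesting branches within branches.
- There is no live HTTP transport: synchronisation is an in-process
  client-server simulation with the same ordering and integrity contract a
  network binding would use.
- Form versioning/migration of live projects is not modelled; a project
  definition is immutable once collection starts.
- The deeper-level key ambiguity described above is inherent to per-parent
  key scoping and is resolved by first-match nesting in exports.
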