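# fieldcollect

Hierarchical field data collection in R: declarative multi-form survey
projects, an interview engine with skip logic and validation, entry stores
with parent-key integrity, client-server synchronisation, and
delimited/XML export.

## Who this is for

Teams that collect structured questionnaire data offline on many devices
-- school vaccination surveys, multi-level specimen collection, ecological
transects, citizen-science sightings -- and need the *data management*
core of such a system to be scriptable and testable: define the project
once, execute interviews (interactively, scripted, or simulated),
guarantee that no child record ever exists without its parent, merge many
devices' entries into one consistent central store, and get tabular data
out.

## The model

A project is a chain of forms in strict one-to-many parent-child relation,
top level first (e.g. school → class → pupil): every entry below the top
level carries the **key** of its parent entry. Keys are a designated text
or barcode field, or `AUTO` = `<device id>_<creation time in ms>`, and are
unique per (form, parent). **Branch forms** hang off a `branch_trigger`
question of a host form and are filled 0..n times per host entry (e.g. one
absence record per reported teacher absence).

Interviews present fields in order; **jump clauses** on dropdown/radio
questions route to a strictly later field or `END` (first matching clause
wins), so every session terminates in at most one submission per field.
Answers pass a validation chain -- required, choice membership,
integer/decimal with min/max, date/time formats such as `dd/mm/yyyy` or
`mm:ss`, regular expressions, double entry -- with all failures collected
and a failed submission never advancing the cursor.

Synchronisation is top-down: batches go hierarchy level by hierarchy
level, a host's branch entries immediately after it, so no entry arrives
before its parent. The server store accepts, rejects orphans, and reports
duplicates -- re-applying a batch is a no-op, and repeated rounds converge
to the union of all clients' entries.

## Worked example

```r
library(fieldcollect)

p <- schools_demo_project()
p
#> <collect_project> schoolsdemo (v1, public)
#>   hierarchy: school -> class -> pupil
#>   branches:  absence

st    <- entry_store(p)
clock <- make_clock(1408500000000)   # injected ms clock: runs reproduce exactly

school <- run_script(p, "school", list(
  list(field = "school_name", value = "Hilltop Primary"),
  list(field = "school_type", value = "state"),
  list(field = "sex_mix",     value = "mixed"),
  list(field = "n_teachers",  value = "35"),
  list(field = "n_pupils",    value = "420"),
  list(field = "photo",       value = "media/hilltop.jpg"),
  list(field = "position",    value = "-1.283,36.817,1680.0,12.5")
), device_id = "ph1", clock = clock)
insert_entry(st, school)$status
#> [1] "accepted"

# a class reporting 2 teacher absences: the branch prompt opens twice
class2 <- run_script(p, "class", list(
  list(field = "class_name",      value = "5B"),
  list(field = "class_size",      value = "28"),
  list(field = "teacher_name",    value = "Mr Otieno"),
  list(field = "record_absences", value = "2"),
  list(field = "reason", value = "illness"),  list(field = "days", value = "3"),
  list(field = "reason", value = "training"), list(field = "days", value = "1")
), parent_key = "Hilltop Primary", device_id = "ph1", clock = clock)
insert_entry_tree(st, class2)
st
#> <entry_store> project 'schoolsdemo': 4 entries
#>   school: 1
#>   class: 1
#>   pupil: 0
#>   absence: 2
```

The two absence entries are linked to class "5B"; their reason
distribution (the summary behind pie/bar charts) keeps declared but unused
choices at zero:

```r
chart_counts(st, "absence", "reason")
#>  illness training personal    other
#>        1        1        0        0

cat(export_table(st, "class"))
#> "entry_id","created_at","device_id","parent_key","key","class_name","class_size","teacher_name","record_absences"
#> "ph1-class-1408500007000","2014-08-20T02:00:07.000Z","ph1","Hilltop Primary","5B","5B","28","Mr Otieno","2"
```

Synchronising to a fresh server store sends schools before classes before
pupils, branch entries riding with their host, and is idempotent:

```r
server <- entry_store(p)
sync_stores(st, server)$results[[1]]
#> <sync_result> accepted=1 duplicate=0 orphan=0
check_store(server)$ok
#> [1] TRUE
```

Project definitions serialise to a canonical XML dialect (and a JSON
mirror) with `write_project()`/`parse_project()`; stores persist via
`store_save()`/`store_load()`; `random_project()` and
`simulate_collection()` generate seeded projects and multi-device
collection runs for testing. A thin CLI over these functions ships in
`inst/cli/fieldcollect` (`schools-demo`, `validate`, `collect --script`,
`simulate`, `export`).

## Vignette

`vignettes/hierarchical-data-collection.Rmd` documents the data model and
its invariants, the interview engine's validation and routing semantics,
the synchronisation and export contracts, what the simulators do and do
not emulate, and the package's design decisions and limitations.
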