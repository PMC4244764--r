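test_that("table exports have the fixed columns plus field ids in form order", {
  p <- schools_demo_project()
  st <- entry_store(p)
  clock <- make_clock(1408500000000)
  for (nm in c("Hilltop Primary", "Lakeside Academy")) {
    s <- start_session(p, "school", device_id = "d1", clock = clock)
    submit_answer(s, nm); submit_answer(s, "state"); submit_answer(s, "mixed")
    submit_answer(s, "35"); submit_answer(s, "420")
    submit_answer(s, "media/pic.jpg"); submit_answer(s, "-1.28,36.82,1680,12.5")
    insert_entry(st, finalize_entry(s))
  }
  txt <- export_table(st, "school")
  df <- read.csv(text = txt, check.names = FALSE, colClasses = "character")
  # column-count oracle: 5 fixed + the form's 7 fields
  expect_identical(dim(df), c(2L, 12L))
  expect_identical(names(df)[1:5],
                   c("entry_id", "created_at", "device_id", "parent_key", "key"))
  expect_identical(names(df)[6:12],
                   vapply(p$forms[[1]]$fields, `[[`, "", "field_id"))
  expect_identical(df$key, c("Hilltop Primary", "Lakeside Academy"))
  expect_match(df$created_at[1], "^2014-08-20T.*Z$")
  expect_identical(df$photo[1], "media/pic.jpg")

  # empty form exports a header-only file
  empty <- export_table(st, "pupil")
  expect_identical(length(strsplit(empty, "\n")[[1]]), 1L)
})

test_that("values with commas, quotes and separators round-trip through csv and tsv", {
  p <- new_project("quoting", forms = list(new_form("f", list(
    new_field("txt", "T", "text"),
    new_field("tags", "Tags", "checkbox",
              choices = list(new_choice("a;b", "a;b"), new_choice("c", "c")))
  ))))
  st <- entry_store(p)
  e <- structure(
    list(entry_id = "e1", form_id = "f", key_value = "k1",
         parent_key = NA_character_, created_at = 1408500000000,
         device_id = "d",
         answers = list(txt = "says \"hi, there\"\tand more",
                        tags = c("a;b", "c")),
         branch_children = list()),
    class = "collect_entry")
  insert_entry(st, e)
  for (fmt in c("csv", "tsv")) {
    back <- import_table(p, "f", export_table(st, "f", fmt), fmt)
    expect_identical(back[[1]], store_entries(st, "f")[[1]])
  }
})

test_that("every field kind survives a table round trip on seeded stores", {
  for (seed in c(2, 6, 10)) {
    p <- random_project(seed, depth = 2, fields_per_form = 6)
    st <- simulate_collection(p, 1, 3, seed = seed)[[1]]
    for (form_id in names(st$entries)) {
      entries <- store_entries(st, form_id)
      if (length(entries) == 0L) next
      back <- import_table(p, form_id, export_table(st, form_id))
      expect_identical(back, entries)
    }
  }
})

test_that("answers never land under the wrong column on seeded random entries", {
  p <- random_project(17, depth = 2, fields_per_form = 6)
  st <- simulate_collection(p, 2, 4, seed = 17)[[1]]
  form_id <- hierarchy_chain(p)[2]
  form <- Filter(function(f) f$form_id == form_id, p$forms)[[1]]
  entries <- store_entries(st, form_id)
  df <- read.csv(text = export_table(st, form_id), check.names = FALSE,
                 colClasses = "character")
  # positional oracle: recompute each cell independently from the entry
  for (i in seq_along(entries)) {
    for (fl in form$fields) {
      a <- entries[[i]]$answers[[fl$field_id]]
      expected <- if (is.null(a)) "" else if (is.list(a) && !is.null(a$uri)) {
        a$uri
      } else if (fl$kind == "checkbox") {
        paste(gsub(";", "\\\\;", a), collapse = ";")
      } else if (fl$kind == "location") {
        paste(format(unlist(a), scientific = FALSE, trim = TRUE, digits = 15),
              collapse = ",")
      } else if (is.numeric(a)) {
        format(a, scientific = FALSE, trim = TRUE, digits = 15)
      } else {
        as.character(a)
      }
      expect_identical(df[[fl$field_id]][i], expected)
    }
  }
})

test_that("nested XML preserves the hierarchy and reaches a fixed point", {
  p <- schools_demo_project()
  st <- simulate_collection(p, 1, 2, seed = 51)[[1]]
  txt <- export_xml(st)
  doc <- xml2::read_xml(txt)
  # pupils nest at depth 3: entries/entry/entry/entry
  pupils <- xml2::xml_find_all(doc, "/entries/entry/entry/entry[@form='pupil']")
  expect_length(pupils, length(store_entries(st, "pupil")))
  # absences nest under their class's branch element
  absences <- xml2::xml_find_all(
    doc, "/entries/entry/entry[@form='class']/branch[@field='record_absences']/entry")
  expect_length(absences, length(store_entries(st, "absence")))

  st2 <- import_entries_xml(p, txt)
  expect_identical(st2$entries, st$entries)
  expect_identical(export_xml(st2), txt)

  # single top-level entry with no children
  st3 <- entry_store(p)
  s <- start_session(p, "school", device_id = "d", clock = make_clock())
  submit_answer(s, "Solo School"); submit_answer(s, "state")
  submit_answer(s, "mixed"); submit_answer(s, "5"); submit_answer(s, "50")
  submit_answer(s, ""); submit_answer(s, "")
  insert_entry(st3, finalize_entry(s))
  doc3 <- xml2::read_xml(export_xml(st3))
  expect_length(xml2::xml_find_all(doc3, "/entries/entry"), 1L)
  expect_length(xml2::xml_find_all(doc3, "/entries/entry/entry"), 0L)
})

test_that("export -> import -> export is byte-identical on seeded stores", {
  for (seed in c(4, 12, 20)) {
    p <- random_project(seed, depth = 2, fields_per_form = 4)
    st <- simulate_collection(p, 1, 2, seed = seed)[[1]]
    txt <- export_xml(st)
    expect_identical(export_xml(import_entries_xml(p, txt)), txt)
  }
})

test_that("web entries run the same pipeline and land linked to their parent", {
  p <- schools_demo_project()
  st <- entry_store(p)
  clock <- make_clock(1408500000000)
  s <- start_session(p, "school", device_id = "ph1", clock = clock)
  submit_answer(s, "Hilltop Primary"); submit_answer(s, "state")
  submit_answer(s, "mixed"); submit_answer(s, "35"); submit_answer(s, "420")
  submit_answer(s, ""); submit_answer(s, "")
  insert_entry(st, finalize_entry(s))

  # lab-result style: a pupil record entered via the web against a barcode
  res <- import_web_entry(
    st, "class",
    answers = list(class_name = "5B", class_size = "28",
                   teacher_name = "Mr K", record_absences = "0"),
    parent_key = "Hilltop Primary", clock = clock)
  expect_identical(res$status, "accepted")
  expect_identical(res$entry$device_id, "web")
  res2 <- import_web_entry(
    st, "pupil",
    answers = list(name_audio = "upload/p.m4a",
                   sample_barcode = c("SC-00173", "SC-00173")),
    parent_key = "5B", clock = clock)
  expect_identical(res2$status, "accepted")
  expect_true(res2$entry$key_value %in%
                vapply(store_entries(st, "pupil"), `[[`, "", "key_value"))

  # invalid integer: field-level error, nothing inserted
  n <- length(store_entries(st, "class"))
  bad <- import_web_entry(
    st, "class",
    answers = list(class_name = "6A", class_size = "many",
                   teacher_name = "", record_absences = "0"),
    parent_key = "Hilltop Primary", clock = clock)
  expect_identical(bad$status, "invalid")
  expect_named(bad$errors, "class_size")
  expect_length(store_entries(st, "class"), n)

  # orphan parent rejected as in the datastore
  orphan <- import_web_entry(
    st, "class",
    answers = list(class_name = "7C", class_size = "20",
                   teacher_name = "", record_absences = "0"),
    parent_key = "No Such School", clock = clock)
  expect_identical(orphan$status, "orphan")

  # web branch entries through nested answer maps
  wb <- import_web_entry(
    st, "class",
    answers = list(class_name = "8D", class_size = "22", teacher_name = "Ms P",
                   record_absences = list(
                     list(reason = "illness", days = "3"),
                     list(reason = "training", days = "1"))),
    parent_key = "Hilltop Primary", clock = clock)
  expect_identical(wb$status, "accepted")
  expect_length(store_entries(st, "absence"), 2L)
})

test_that("a web entry equals a phone entry up to the fixed columns", {
  p <- schools_demo_project()
  answers <- list(class_name = "5B", class_size = "28", teacher_name = "Mr K",
                  record_absences = "0")
  mk_store <- function() {
    st <- entry_store(p)
    s <- start_session(p, "school", device_id = "ph", clock = make_clock())
    submit_answer(s, "Hill"); submit_answer(s, "state"); submit_answer(s, "mixed")
    submit_answer(s, "5"); submit_answer(s, "50")
    submit_answer(s, ""); submit_answer(s, "")
    insert_entry(st, finalize_entry(s))
    st
  }
  st_web <- mk_store()
  import_web_entry(st_web, "class", answers, parent_key = "Hill",
                   clock = make_clock(99))
  st_ph <- mk_store()
  script <- lapply(names(answers), function(f) list(field = f,
                                                    value = answers[[f]]))
  insert_entry(st_ph, run_script(p, "class", script, parent_key = "Hill",
                                 device_id = "ph", clock = make_clock(77)))
  row_web <- read.csv(text = export_table(st_web, "class"),
                      check.names = FALSE, colClasses = "character")[1, ]
  row_ph <- read.csv(text = export_table(st_ph, "class"),
                     check.names = FALSE, colClasses = "character")[1, ]
  fixed <- c("entry_id", "created_at", "device_id")
  expect_identical(row_web[setdiff(names(row_web), fixed)],
                   row_ph[setdiff(names(row_ph), fixed)])
  expect_identical(row_web$device_id, "web")
})
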