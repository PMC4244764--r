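toy_project <- function(fields, form_id = "f") {
  new_project("toy", forms = list(new_form(form_id, fields)))
}

int_field <- function(id = "n", min = 0, max = 100, required = TRUE) {
  new_field(id, "N", "text",
            validation = new_validation(required = required,
                                        numeric = "integer",
                                        min = min, max = max))
}

test_that("validation chain: accept and reject cases for every rule", {
  # required
  req <- new_field("a", "A", "text", validation = new_validation(required = TRUE))
  expect_false(validate_answer(req, "")$ok)
  expect_true(validate_answer(req, "x")$ok)
  opt <- new_field("a", "A", "text")
  blank <- validate_answer(opt, "")
  expect_true(blank$ok)
  expect_null(blank$value)

  # integer typing and range
  f <- int_field()
  expect_identical(validate_answer(f, "42")$value, 42)
  expect_false(validate_answer(f, "4.2")$ok)
  expect_false(validate_answer(f, "abc")$ok)
  expect_false(validate_answer(f, "-1")$ok)
  expect_false(validate_answer(f, "101")$ok)
  expect_true(validate_answer(f, "0")$ok)   # closed bounds
  expect_true(validate_answer(f, "100")$ok)

  # decimal
  d <- new_field("d", "D", "text",
                 validation = new_validation(numeric = "decimal",
                                             min = 0.5, max = 1.5))
  expect_identical(validate_answer(d, "0.75")$value, 0.75)
  expect_false(validate_answer(d, "0.25")$ok)

  # date and time formats
  dt <- new_field("dt", "D", "text",
                  validation = new_validation(datetime_format = "dd/mm/yyyy"))
  expect_true(validate_answer(dt, "31/12/2013")$ok)
  expect_false(validate_answer(dt, "2013-12-31")$ok)
  expect_false(validate_answer(dt, "31/13/2013")$ok)  # no 13th month
  expect_false(validate_answer(dt, "29/02/2013")$ok)  # not a real date
  ms <- new_field("ms", "M", "text",
                  validation = new_validation(datetime_format = "mm:ss"))
  expect_true(validate_answer(ms, "07:30")$ok)
  expect_false(validate_answer(ms, "07:61")$ok)
  expect_false(validate_answer(ms, "7:30")$ok)

  # regex (the pre-printed barcode-prefix scenario)
  bc <- new_field("bc", "B", "barcode",
                  validation = new_validation(regex = "^SC-[0-9]{5}$"))
  expect_true(validate_answer(bc, "SC-00173")$ok)
  hard <- validate_answer(bc, "XX-00173")
  expect_false(hard$ok)
  expect_identical(hard$errors[[1]]$code, "regex")
  soft <- validate_answer(bc, "XX-00173", lenient_regex = TRUE)
  expect_true(soft$ok)
  expect_identical(soft$warnings[[1]]$code, "regex")

  # double entry: exact after whitespace strip, case-sensitive
  de <- new_field("de", "D", "barcode", double_entry = TRUE)
  expect_true(validate_answer(de, "SC-00173", "SC-00173")$ok)
  expect_true(validate_answer(de, "SC-00173", " SC-00173 ")$ok)
  expect_false(validate_answer(de, "SC-00173", "SC-00174")$ok)
  expect_false(validate_answer(de, "abc", "ABC")$ok)
  expect_false(validate_answer(de, "abc")$ok)  # second entry missing

  # choice membership
  dd <- new_field("c", "C", "dropdown",
                  choices = list(new_choice("A"), new_choice("B")))
  expect_true(validate_answer(dd, "A")$ok)
  expect_false(validate_answer(dd, "Z")$ok)
  cb <- new_field("c", "C", "checkbox",
                  choices = list(new_choice("A"), new_choice("B")))
  expect_identical(validate_answer(cb, "A;B")$value, c("A", "B"))
  expect_false(validate_answer(cb, "A;Z")$ok)

  # location: four numbers, lat/lon ranges
  loc <- new_field("l", "L", "location")
  good <- validate_answer(loc, "-1.28,36.82,1680,12.5")
  expect_true(good$ok)
  expect_identical(good$value$accuracy, 12.5)
  expect_false(validate_answer(loc, "1,2,3")$ok)
  expect_false(validate_answer(loc, "91,0,0,1")$ok)

  # all failures are collected, not just the first
  multi <- new_field("m", "M", "text", double_entry = TRUE,
                     validation = new_validation(numeric = "integer",
                                                 regex = "^[0-9]{2}$"))
  res <- validate_answer(multi, "abc", "abd")
  expect_setequal(vapply(res$errors, `[[`, character(1), "code"),
                  c("type", "regex", "double_entry"))
})

test_that("jump clauses route as declared: A or C to Q5, B to Q7, else continue", {
  fields <- lapply(1:7, function(i) {
    new_field(paste0("q", i), paste0("Q", i), "dropdown",
              choices = lapply(c("A", "B", "C", "D"), new_choice))
  })
  fields[[1]]$jumps <- list(new_jump(c("A", "C"), "q5"), new_jump("B", "q7"))
  form <- new_form("f", fields)
  expect_identical(next_field(form, "q1", "A"), "q5")
  expect_identical(next_field(form, "q1", "C"), "q5")
  expect_identical(next_field(form, "q1", "B"), "q7")
  expect_identical(next_field(form, "q1", "D"), "q2")
  expect_identical(next_field(form, "q7", "A"), "END")
  expect_error(next_field(form, "q1", c("A", "B")), "incompatible")
})

test_that("favourite-colour pattern: predefined colours skip the free-text box", {
  colour <- new_field("q1", "What is your favourite colour?", "dropdown",
                      choices = lapply(c("blue", "red", "green", "other"),
                                       new_choice),
                      jumps = list(new_jump(c("blue", "red", "green"), "q3")))
  other <- new_field("q2", "Please enter your favourite colour", "text")
  next_q <- new_field("q3", "Q3", "text")
  p <- toy_project(list(colour, other, next_q))
  for (ans in c("blue", "red", "green")) {
    expect_identical(engine_walk(p, "f", list(q1 = ans, q2 = "x", q3 = "y")),
                     c("q1", "q3"))
  }
  expect_identical(engine_walk(p, "f", list(q1 = "other", q2 = "teal", q3 = "y")),
                   c("q1", "q2", "q3"))
})

test_that("engine matches the naive clause-scanning interpreter exhaustively", {
  combos <- 0L
  for (seed in 1:60) {
    combos <- combos + expect_walks_agree(random_choice_form_project(seed))
  }
  expect_gt(combos, 500L)
})

test_that("failed validation leaves the cursor unmoved; skipped fields store nothing", {
  p <- toy_project(list(
    new_field("q1", "Q1", "dropdown",
              choices = lapply(c("yes", "no"), new_choice),
              jumps = list(new_jump("no", "END"))),
    int_field("q2")
  ))
  s <- start_session(p, "f", device_id = "d", clock = make_clock())
  bad <- submit_answer(s, "maybe")
  expect_identical(bad$status, "invalid")
  expect_identical(current_field(s), "q1")
  expect_length(s$answers, 0L)

  submit_answer(s, "no")   # jumps over q2 to END
  expect_true(s$complete)
  e <- finalize_entry(s)
  expect_named(e$answers, "q1")
  expect_false("q2" %in% names(e$answers))
})

test_that("sessions terminate within |fields| submissions on random forms", {
  for (seed in 61:80) {
    p <- random_choice_form_project(seed)
    n <- length(p$forms[[1]]$fields)
    combos <- all_answer_combos(p$forms[[1]])
    r <- combos[nrow(combos) %/% 2L + 1L, , drop = FALSE]
    expect_lte(length(engine_walk(p, "f", as.list(r))), n)
  }
})

test_that("auto keys concatenate device and milliseconds and never collide", {
  expect_identical(generate_auto_key("a1b2c3", 1408500000000),
                   "a1b2c3_1408500000000")
  expect_identical(generate_auto_key("a1b2c3", 1408500000000),
                   generate_auto_key("a1b2c3", 1408500000000))
  expect_error(generate_auto_key("", 1), "non-empty")
  set.seed(42)
  uuids <- sprintf("dev%04d", sample.int(200L, 10000L, replace = TRUE))
  ts <- sample.int(1e6L, 10000L)
  pairs <- unique(data.frame(uuids, ts))
  keys <- mapply(generate_auto_key, pairs$uuids, pairs$ts)
  expect_identical(length(unique(keys)), nrow(pairs))
})

test_that("session preconditions: parent keys and finalisation guards", {
  p <- schools_demo_project()
  expect_error(start_session(p, "pupil", device_id = "d"), "orphan session")
  expect_error(start_session(p, "school", parent_key = "x", device_id = "d"),
               "takes no parent_key")
  s <- start_session(p, "class", parent_key = "Hilltop Primary",
                     device_id = "d", clock = make_clock())
  expect_identical(s$parent_key, "Hilltop Primary")
  expect_error(finalize_entry(s), "class_name")

  # finalised class entry carries the parent key through
  submit_answer(s, "5B"); submit_answer(s, "28"); submit_answer(s, "Mrs A")
  submit_answer(s, "0")
  e <- finalize_entry(s)
  expect_identical(e$parent_key, "Hilltop Primary")
  expect_identical(e$key_value, "5B")
})

test_that("AUTO-keyed entries match the device_ms shape and stamp creation time", {
  p <- schools_demo_project()
  clock <- make_clock(1408500000000, 500)
  s <- start_session(p, "pupil", parent_key = "5B", device_id = "dev9",
                     clock = clock)
  submit_answer(s, "media/a.m4a")
  submit_answer(s, "SC-00001", "SC-00001")
  e <- finalize_entry(s)
  expect_match(e$key_value, "^dev9_[0-9]+$")
  expect_identical(e$created_at, 1408500000500)
  expect_identical(e$device_id, "dev9")
})

test_that("scripted sessions replay branch prompts and double entries", {
  p <- schools_demo_project()
  script <- list(
    list(field = "class_name", value = "6A"),
    list(field = "class_size", value = "30"),
    list(field = "teacher_name", value = "Mr K"),
    list(field = "record_absences", value = "1"),
    list(field = "reason", value = "illness"),
    list(field = "days", value = "2")
  )
  e <- run_script(p, "class", script, parent_key = "Hilltop Primary",
                  device_id = "d", clock = make_clock())
  expect_length(e$branch_children$record_absences, 1L)
  expect_identical(e$branch_children$record_absences[[1]]$answers$days, 2)

  # script out of step with the interview order is refused
  bad <- list(list(field = "class_size", value = "30"))
  expect_error(run_script(p, "class", bad, parent_key = "H", device_id = "d"),
               "at 'class_name'")
})
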