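# Run code under a private RNG stream: seed explicitly, restore any global
# state afterwards. Generators never touch the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The schools demonstration project
#'
#' A three-level hierarchy (school -> class -> pupil) with an absence
#' branch form on the class level: schools record name (the key), type,
#' single-sex/mixed, staff and pupil counts, a photo and a location; each
#' class records its name (key), size and teacher plus a branch question
#' recording 0..n teacher absences (reason and days each); each pupil entry
#' is auto-keyed and records an audio clip of the pupil's name and a
#' pre-printed blood-sample barcode (double-entered, prefix-checked).
#'
#' @return A valid `collect_project`.
#' @export
schools_demo_project <- function() {
  school <- new_form(
    "school", title = "School", key_field = "school_name",
    fields = list(
      new_field("school_name", "Name of school", "text",
                validation = new_validation(required = TRUE)),
      new_field("school_type", "Type of school", "dropdown",
                choices = list(new_choice("State", "state"),
                               new_choice("Independent", "independent"),
                               new_choice("Faith", "faith"),
                               new_choice("Other", "other")),
                chartable = TRUE,
                validation = new_validation(required = TRUE)),
      new_field("sex_mix", "Single-sex or mixed?", "radio",
                choices = list(new_choice("Single-sex", "single_sex"),
                               new_choice("Mixed", "mixed")),
                chartable = TRUE,
                validation = new_validation(required = TRUE)),
      new_field("n_teachers", "Number of teachers", "text",
                validation = new_validation(required = TRUE,
                                            numeric = "integer",
                                            min = 1, max = 500)),
      new_field("n_pupils", "Number of pupils", "text",
                validation = new_validation(required = TRUE,
                                            numeric = "integer",
                                            min = 1, max = 5000)),
      new_field("photo", "Photo of the school", "image"),
      new_field("position", "School location", "location")
    )
  )
  class_form <- new_form(
    "class", title = "Class", key_field = "class_name",
    fields = list(
      new_field("class_name", "Name of class", "text",
                validation = new_validation(required = TRUE)),
      new_field("class_size", "Number of pupils in class", "text",
                validation = new_validation(required = TRUE,
                                            numeric = "integer",
                                            min = 1, max = 100)),
      new_field("teacher_name", "Class teacher", "text"),
      new_field("record_absences", "Please record absences", "branch_trigger",
                branch = "absence",
                validation = new_validation(required = TRUE))
    )
  )
  pupil <- new_form(
    "pupil", title = "Pupil", key_field = "AUTO",
    fields = list(
      new_field("name_audio", "Pupil pronouncing their name", "audio"),
      new_field("sample_barcode", "Scan blood-sample barcode", "barcode",
                double_entry = TRUE,
                validation = new_validation(required = TRUE,
                                            regex = "^SC-[0-9]{5}$"))
    )
  )
  absence <- new_form(
    "absence", title = "Absence", key_field = "AUTO",
    fields = list(
      new_field("reason", "Reason for absence", "dropdown",
                choices = list(new_choice("Illness", "illness"),
                               new_choice("Training", "training"),
                               new_choice("Personal", "personal"),
                               new_choice("Other", "other")),
                chartable = TRUE,
                validation = new_validation(required = TRUE)),
      new_field("days", "Number of days absent", "text",
                validation = new_validation(required = TRUE,
                                            numeric = "integer",
                                            min = 1, max = 365))
    )
  )
  new_project("schoolsdemo", title = "Schools survey",
              forms = list(school, class_form, pupil),
              branches = list(absence))
}

# Regex patterns the generators may attach to text/barcode fields, paired
# with a sampler that produces matching strings.
REGEX_CATALOG <- list(
  list(pattern = "^SC-[0-9]{5}$",
       gen = function() sprintf("SC-%05d", sample.int(99999L, 1L))),
  list(pattern = "^[A-Z]{2}[0-9]{3}$",
       gen = function() paste0(paste(sample(LETTERS, 2L, TRUE), collapse = ""),
                               sprintf("%03d", sample.int(999L, 1L)))),
  list(pattern = "^site_[a-z]{4}$",
       gen = function() paste0("site_", paste(sample(letters, 4L, TRUE),
                                              collapse = "")))
)

WORDS <- c("acacia", "baobab", "cassava", "dhow", "emerald", "fig", "guava",
           "harbour", "ivory", "jacaranda", "kudu", "lagoon", "mango",
           "nyala", "okra", "papaya")

random_choices <- function(n) {
  vals <- paste0("opt", seq_len(n))
  lapply(vals, function(v) new_choice(toupper(v), v))
}

random_validation <- function() {
  pick <- sample.int(6L, 1L)
  if (pick == 1L) {
    new_validation(required = TRUE)
  } else if (pick == 2L) {
    lo <- sample.int(50L, 1L)
    new_validation(required = TRUE, numeric = "integer",
                   min = lo, max = lo + sample.int(100L, 1L))
  } else if (pick == 3L) {
    new_validation(numeric = "decimal", min = 0, max = 1000)
  } else if (pick == 4L) {
    new_validation(required = TRUE, datetime_format = "dd/mm/yyyy")
  } else if (pick == 5L) {
    new_validation(datetime_format = "mm:ss")
  } else {
    rc <- REGEX_CATALOG[[sample.int(length(REGEX_CATALOG), 1L)]]
    new_validation(required = TRUE, regex = rc$pattern)
  }
}

random_field <- function(field_id, kind, branch = NULL) {
  if (kind %in% CHOICE_KINDS) {
    ch <- random_choices(sample(2:4, 1L))
    new_field(field_id, paste("Question", field_id), kind, choices = ch,
              chartable = stats::runif(1) < 0.5,
              validation = new_validation(required = stats::runif(1) < 0.5))
  } else if (kind %in% c("text", "long_text")) {
    new_field(field_id, paste("Question", field_id), kind,
              validation = random_validation(),
              double_entry = kind == "text" && stats::runif(1) < 0.2)
  } else if (kind == "barcode") {
    rc <- REGEX_CATALOG[[sample.int(length(REGEX_CATALOG), 1L)]]
    new_field(field_id, paste("Scan", field_id), kind,
              validation = new_validation(required = TRUE, regex = rc$pattern),
              double_entry = stats::runif(1) < 0.3)
  } else if (kind == "branch_trigger") {
    new_field(field_id, paste("Record", field_id), kind, branch = branch,
              validation = new_validation(required = TRUE))
  } else {
    new_field(field_id, paste("Capture", field_id), kind)
  }
}

add_random_jumps <- function(fields) {
  n <- length(fields)
  for (i in seq_len(max(0L, n - 1L))) {
    fl <- fields[[i]]
    if (!fl$kind %in% c("dropdown", "radio") || stats::runif(1) > 0.4) next
    vals <- choice_values(fl)
    ntrig <- sample.int(length(vals), 1L)
    trig <- sample(vals, ntrig)
    dest_pool <- c(vapply(fields[(i + 1L):n], `[[`, "", "field_id"), "END")
    fields[[i]]$jumps <- list(new_jump(trig, sample(dest_pool, 1L)))
  }
  fields
}

#' Generate a seeded random project
#'
#' Deterministic per seed; the generated project always passes
#' [validate_project()]. Field kinds, validation rules (integer/decimal
#' ranges, date and time formats, catalogued regexes, double entry), jumps
#' and branch forms are drawn with fixed probabilities so that every engine
#' feature is exercised.
#'
#' @param seed Integer seed for the generator's private RNG stream.
#' @param depth Number of hierarchy levels (>= 1).
#' @param fields_per_form Questions per form (>= 1).
#' @param branch_prob Probability that a form carries a branch form.
#' @return A valid `collect_project`.
#' @export
random_project <- function(seed, depth = 3L, fields_per_form = 5L,
                           branch_prob = 0.3) {
  if (depth < 1L) stop("depth must be >= 1")
  if (fields_per_form < 1L) stop("fields_per_form must be >= 1")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0, 1]")
  with_seed(seed, {
    kinds <- c("text", "long_text", "dropdown", "checkbox", "radio",
               "location", "image", "video", "audio", "barcode")
    forms <- list()
    branches <- list()
    for (k in seq_len(depth)) {
      fid <- sprintf("form%d", k)
      # first field: plain required text, usable as a key
      fields <- list(new_field(
        paste0(fid, "_name"), paste("Name for", fid), "text",
        validation = new_validation(required = TRUE)
      ))
      for (j in seq_len(fields_per_form - 1L)) {
        kind <- sample(kinds, 1L)
        fields[[j + 1L]] <- random_field(sprintf("%s_q%d", fid, j), kind)
      }
      if (stats::runif(1) < branch_prob) {
        bid <- sprintf("branch%d", k)
        branches[[length(branches) + 1L]] <- new_form(
          bid, title = paste("Branch of", fid), key_field = "AUTO",
          fields = list(
            random_field(paste0(bid, "_what"), "dropdown"),
            new_field(paste0(bid, "_n"), "How many?", "text",
                      validation = new_validation(required = TRUE,
                                                  numeric = "integer",
                                                  min = 0, max = 99))
          )
        )
        fields[[length(fields) + 1L]] <-
          random_field(paste0(fid, "_branch"), "branch_trigger", branch = bid)
      }
      fields <- add_random_jumps(fields)
      key <- if (stats::runif(1) < 0.5) "AUTO" else paste0(fid, "_name")
      forms[[k]] <- new_form(fid, title = paste("Form", k), fields = fields,
                             key_field = key)
    }
    new_project(sprintf("random%d", seed), forms = forms, branches = branches)
  })
}

# Raw answer (and second entry where needed) satisfying a field's rules.
# Key fields get an explicit unique value from the caller instead.
gen_raw_answer <- function(field) {
  v <- field$validation
  raw <- if (field$kind %in% c("dropdown", "radio")) {
    sample(choice_values(field), 1L)
  } else if (field$kind == "checkbox") {
    vals <- choice_values(field)
    n <- sample.int(length(vals), 1L)
    escape_multi(sample(vals, n))
  } else if (field$kind == "location") {
    sprintf("%.6f,%.6f,%.1f,%.1f", stats::runif(1, -35, 35),
            stats::runif(1, -20, 50), stats::runif(1, 0, 2000),
            stats::runif(1, 1, 50))
  } else if (field$kind %in% MEDIA_KINDS) {
    sprintf("media/%s_%04d.%s", field$field_id, sample.int(9999L, 1L),
            switch(field$kind, image = "jpg", video = "mp4", audio = "m4a"))
  } else if (field$kind == "branch_trigger") {
    as.character(sample(0:2, 1L))
  } else if (!is.null(v$regex)) {
    hit <- Filter(function(rc) identical(rc$pattern, v$regex), REGEX_CATALOG)
    if (length(hit) == 0L) stop("no sampler for regex ", v$regex)
    hit[[1]]$gen()
  } else if (v$numeric == "integer") {
    lo <- v$min %||% 0
    hi <- v$max %||% (lo + 100)
    as.character(sample(seq(lo, hi), 1L))
  } else if (v$numeric == "decimal") {
    lo <- v$min %||% 0
    hi <- v$max %||% (lo + 100)
    format_num(round(stats::runif(1, lo, hi), 2))
  } else if (identical(v$datetime_format, "dd/mm/yyyy")) {
    sprintf("%02d/%02d/%04d", sample.int(28L, 1L), sample.int(12L, 1L),
            sample(1990:2014, 1L))
  } else if (identical(v$datetime_format, "mm:ss")) {
    sprintf("%02d:%02d", sample(0:59, 1L), sample(0:59, 1L))
  } else {
    paste(sample(WORDS, 2L), collapse = " ")
  }
  if (field$double_entry) c(raw, raw) else raw
}

# Complete one session with generated answers, attaching generated branch
# entries at prompts; `key_override` forces the key field's value.
simulate_session <- function(project, form_id, parent_key, device_id, clock,
                             key_override = NULL) {
  s <- start_session(project, form_id, parent_key = parent_key,
                     device_id = device_id, clock = clock)
  while (!s$complete) {
    fl <- s$form$fields[[s$cursor]]
    raw <- if (!is.null(key_override) &&
               identical(fl$field_id, s$form$key_field)) {
      key_override
    } else {
      gen_raw_answer(fl)
    }
    res <- submit_answer(s, raw[1], if (length(raw) > 1L) raw[2])
    if (identical(res$status, "invalid")) {
      stop("generated answer rejected for '", fl$field_id, "': ",
           paste(vapply(res$errors, `[[`, "", "message"), collapse = "; "))
    }
    while (identical(res$status, "branch_prompt")) {
      child <- simulate_session(project, s$pending_branch$branch_form,
                                NULL, device_id, clock)
      res <- attach_branch_entry(s, child)
    }
  }
  finalize_entry(s)
}

#' Simulate multi-device data collection
#'
#' Emulates several phones gathering a full hierarchy: each device fills in
#' `entries_per_level` entries at the top level and, per parent entry, the
#' same number of children at every level below. Every answer is generated
#' to satisfy its field's validation rules and entered through the ordinary
#' session pipeline (jumps, branch prompts and all), so the resulting
#' stores hold only validated, invariant-respecting entries. Deterministic
#' per seed: devices get disjoint deterministic clocks and a private RNG
#' stream.
#'
#' @param project A valid project.
#' @param n_devices Number of simulated phones.
#' @param entries_per_level Entries per parent at each hierarchy level.
#' @param seed Integer seed.
#' @return List of per-device client `entry_store`s.
#' @export
simulate_collection <- function(project, n_devices = 2L,
                                entries_per_level = 2L, seed = 1L) {
  stop_if_invalid(project)
  with_seed(seed, {
    lapply(seq_len(n_devices), function(d) {
      device_id <- sprintf("dev%02d", d)
      clock <- make_clock(1408500000000 + (d - 1L) * 1e9, step_ms = 1000)
      store <- entry_store(project)
      counter <- 0L
      descend <- function(level, parent_key) {
        form <- project$forms[[level]]
        for (i in seq_len(entries_per_level)) {
          counter <<- counter + 1L
          key_override <- if (!identical(form$key_field, "AUTO")) {
            sprintf("%s %s %04d", device_id, form$form_id, counter)
          }
          entry <- simulate_session(project, form$form_id, parent_key,
                                    device_id, clock,
                                    key_override = key_override)
          res <- insert_entry_tree(store, entry)
          if (res[[entry$entry_id]]$status != "accepted") {
            stop("simulated entry rejected: ", res[[entry$entry_id]]$reason)
          }
          if (level < length(project$forms)) {
            descend(level + 1L, entry$key_value)
          }
        }
      }
      descend(1L, NULL)
      store
    })
  })
}
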