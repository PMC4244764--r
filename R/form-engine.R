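#' Deterministic millisecond clock
#'
#' Sessions never read the host clock; time is injected so entry ids, keys
#' and timestamps are reproducible. Each call to the returned function
#' advances by `step_ms`.
#'
#' @param start_ms First timestamp to return (UTC epoch milliseconds).
#' @param step_ms Increment per call.
#' @return A zero-argument function returning successive timestamps.
#' @export
make_clock <- function(start_ms = 1408500000000, step_ms = 1000) {
  t <- start_ms - step_ms
  function() {
    t <<- t + step_ms
    t
  }
}

#' Generate an automatic entry key
#'
#' The device's unique identifier concatenated with the entry-creation time
#' in milliseconds; distinct (device, time) pairs yield distinct keys, which
#' makes re-submission of the same entry detectable server-side. An
#' underscore separates the two parts so they stay recoverable.
#'
#' @param device_uuid Non-empty device identifier.
#' @param timestamp_ms Entry time, UTC epoch milliseconds (>= 0).
#' @return Key string `"<uuid>_<ms>"`.
#' @export
generate_auto_key <- function(device_uuid, timestamp_ms) {
  if (!is.character(device_uuid) || length(device_uuid) != 1L ||
      !nzchar(device_uuid)) {
    stop("device_uuid must be a non-empty string")
  }
  stopifnot(is.numeric(timestamp_ms), length(timestamp_ms) == 1L,
            timestamp_ms >= 0)
  sprintf("%s_%s", device_uuid, format_num(timestamp_ms))
}

verr <- function(code, message) list(code = code, message = message)

is_blank <- function(raw) {
  is.null(raw) || length(raw) == 0L || is.na(raw) || !nzchar(trimws(raw))
}

# Translate a date/time format pattern (dd/mm/yyyy, mm:ss, hh:mm, ...) into
# an anchored regex; full calendar dates additionally get a real-date check.
datetime_regex <- function(pattern) {
  esc <- gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", pattern)
  rx <- esc
  rx <- gsub("yyyy", "[0-9]{4}", rx, fixed = TRUE)
  rx <- gsub("dd", "[0-9]{2}", rx, fixed = TRUE)
  rx <- gsub("mm", "[0-9]{2}", rx, fixed = TRUE)
  rx <- gsub("hh", "[0-9]{2}", rx, fixed = TRUE)
  rx <- gsub("ss", "[0-9]{2}", rx, fixed = TRUE)
  paste0("^", rx, "$")
}

check_datetime <- function(value, pattern) {
  if (!grepl(datetime_regex(pattern), value)) return(FALSE)
  if (identical(pattern, "dd/mm/yyyy")) {
    d <- as.Date(value, format = "%d/%m/%Y")
    if (is.na(d) || format(d, "%d/%m/%Y") != value) return(FALSE)
  }
  if (identical(pattern, "mm:ss") || identical(pattern, "hh:mm")) {
    parts <- as.integer(strsplit(value, ":", fixed = TRUE)[[1]])
    if (parts[2] > 59L) return(FALSE)
    if (identical(pattern, "hh:mm") && parts[1] > 23L) return(FALSE)
    if (identical(pattern, "mm:ss") && parts[1] > 59L) return(FALSE)
  }
  TRUE
}

parse_location_raw <- function(raw) {
  parts <- suppressWarnings(as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]]))
  if (length(parts) != 4L || anyNA(parts)) return(NULL)
  list(lat = parts[1], lon = parts[2], alt = parts[3], accuracy = parts[4])
}

media_thumbnail <- function(uri) {
  paste0(tools::file_path_sans_ext(uri), "_thumb.jpg")
}

new_media_ref <- function(kind, uri) {
  list(kind = kind, uri = uri,
       thumbnail_uri = if (kind == "image") media_thumbnail(uri))
}

#' Validate a raw answer against a field's rules
#'
#' Checks are applied in order -- required, type/choice membership, numeric
#' parse, min/max, date/time format, regular expression, double-entry
#' equality -- and every failure is collected (not only the first).
#' Failures are returned as structured errors, never thrown.
#'
#' Raw answer conventions by kind: choice fields take the stored choice
#' value (checkbox: values joined by `";"`); location takes
#' `"lat,lon,alt,accuracy"` (degrees/metres); media fields take a file path
#' or URL; barcode takes the decoded string; `branch_trigger` takes the
#' number of branch entries to add.
#'
#' @param field A `collect_field`.
#' @param raw Raw input string; a blank counts as unanswered.
#' @param raw2 Second input for double-entry fields.
#' @param lenient_regex Report regex mismatches as warnings instead of
#'   errors (e.g. an unexpected but plausibly valid barcode prefix).
#' @return List with `ok`; on success `value` (the typed answer, `NULL` for
#'   a permitted blank) and `warnings`; on failure `errors` (list of
#'   code/message records).
#' @export
validate_answer <- function(field, raw, raw2 = NULL, lenient_regex = FALSE) {
  v <- field$validation
  errors <- list()
  warnings <- list()
  add <- function(code, msg) errors[[length(errors) + 1L]] <<- verr(code, msg)

  if (is_blank(raw)) {
    if (v$required) {
      add("required", paste0("'", field$field_id, "' requires an answer"))
      return(list(ok = FALSE, errors = errors, warnings = warnings))
    }
    return(list(ok = TRUE, value = NULL, warnings = warnings))
  }
  raw <- as.character(raw)
  value <- raw

  if (field$kind %in% c("dropdown", "radio")) {
    if (!raw %in% choice_values(field)) {
      add("choice", paste0("'", raw, "' is not a declared choice value"))
    }
  } else if (field$kind == "checkbox") {
    picked <- unescape_multi(raw)
    bad <- setdiff(picked, choice_values(field))
    if (length(bad)) {
      add("choice", paste0("not declared choice value(s): ",
                           paste(bad, collapse = ", ")))
    } else {
      value <- picked
    }
  } else if (field$kind == "location") {
    loc <- parse_location_raw(raw)
    if (is.null(loc)) {
      add("location", "expected four numbers: lat,lon,alt,accuracy")
    } else if (abs(loc$lat) > 90 || abs(loc$lon) > 180) {
      add("location", "latitude/longitude out of range")
    } else {
      value <- loc
    }
  } else if (field$kind %in% MEDIA_KINDS) {
    value <- new_media_ref(field$kind, raw)
  } else if (field$kind == "branch_trigger") {
    if (!grepl("^[0-9]+$", trimws(raw))) {
      add("type", "branch count must be a non-negative integer")
    } else {
      value <- as.integer(trimws(raw))
    }
  } else {
    # text / long_text / barcode
    if (v$numeric != "none") {
      txt <- trimws(raw)
      num_ok <- if (v$numeric == "integer") {
        grepl("^[+-]?[0-9]+$", txt)
      } else {
        grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", txt)
      }
      if (!num_ok) {
        add("type", paste0("expected ", v$numeric, " value"))
      } else {
        num <- as.numeric(txt)
        if (!is.null(v$min) && num < v$min) {
          add("min", paste0("value ", txt, " below minimum ", format_num(v$min)))
        }
        if (!is.null(v$max) && num > v$max) {
          add("max", paste0("value ", txt, " above maximum ", format_num(v$max)))
        }
        value <- num
      }
    }
    if (!is.null(v$datetime_format) && !check_datetime(raw, v$datetime_format)) {
      add("datetime", paste0("'", raw, "' does not match format ",
                             v$datetime_format))
    }
  }

  if (!is.null(v$regex) && !grepl(v$regex, raw, perl = TRUE)) {
    msg <- paste0("'", raw, "' does not match pattern ", v$regex)
    if (lenient_regex) {
      warnings[[length(warnings) + 1L]] <- verr("regex", msg)
    } else {
      add("regex", msg)
    }
  }

  if (field$double_entry) {
    if (is.null(raw2) || is.na(raw2)) {
      add("double_entry", "field requires the value to be entered twice")
    } else if (!identical(trimws(raw), trimws(as.character(raw2)))) {
      add("double_entry", "the two entries are not identical")
    }
  }

  if (length(errors)) {
    list(ok = FALSE, errors = errors, warnings = warnings)
  } else {
    list(ok = TRUE, value = value, warnings = warnings)
  }
}

#' Next field after an answered question
#'
#' The first declared jump clause whose trigger values contain the answer
#' wins; otherwise the next field in form order; past the last field,
#' `"END"`.
#'
#' @param form A `collect_form`.
#' @param at Field id of the answered question.
#' @param answer The typed answer (for jump evaluation a single choice
#'   value).
#' @return A field id or `"END"`.
#' @export
next_field <- function(form, at, answer) {
  fids <- field_ids(form)
  i <- match(at, fids)
  if (is.na(i)) stop("unknown field '", at, "'")
  fl <- form$fields[[i]]
  if (length(fl$jumps) && !is.null(answer)) {
    if (!is.character(answer) || length(answer) != 1L) {
      stop("answer variant incompatible with jump triggers on '", at, "'")
    }
    for (j in fl$jumps) {
      if (answer %in% j$trigger_values) return(j$destination)
    }
  }
  if (i == length(fids)) "END" else fids[[i + 1L]]
}

#' Start an interview session over one form
#'
#' @param project A valid project.
#' @param form_id Form to fill in.
#' @param parent_key Key of the parent entry; required for hierarchy forms
#'   below the top level. For branch forms it may be omitted when the host
#'   entry's key is not yet known (it is bound when the branch entry is
#'   attached to its host session).
#' @param device_id Identifier of the collecting device.
#' @param clock A [make_clock()] function (injected, never the host clock).
#' @param lenient_regex Passed through to [validate_answer()].
#' @return A mutable `collect_session` (environment).
#' @export
start_session <- function(project, form_id, parent_key = NULL,
                          device_id = "device", clock = make_clock(),
                          lenient_regex = FALSE) {
  form <- project_form(project, form_id)
  if (is.null(form)) stop("unknown form '", form_id, "'")
  level <- form_level(project, form_id)
  if (!is.na(level) && level >= 2L && is.null(parent_key)) {
    stop("orphan session: form '", form_id,
         "' sits below the top level and needs a parent_key")
  }
  if (!is.na(level) && level == 1L && !is.null(parent_key)) {
    stop("top-level form '", form_id, "' takes no parent_key")
  }
  s <- new.env(parent = emptyenv())
  s$project <- project
  s$form <- form
  s$form_id <- form_id
  s$parent_key <- if (is.null(parent_key)) NA_character_ else parent_key
  s$cursor <- 1L
  s$complete <- length(form$fields) == 0L
  s$answers <- list()
  s$branch_entries <- list()
  s$pending_branch <- NULL
  s$device_id <- device_id
  s$clock <- clock
  s$started_at <- clock()
  s$lenient_regex <- lenient_regex
  class(s) <- "collect_session"
  s
}

#' Field currently presented by a session
#'
#' @param session A `collect_session`.
#' @return The field id at the cursor, or `"COMPLETE"`.
#' @export
current_field <- function(session) {
  if (session$complete) "COMPLETE" else field_ids(session$form)[[session$cursor]]
}

advance_session <- function(session, from_field, jump_answer) {
  nxt <- next_field(session$form, from_field, jump_answer)
  if (identical(nxt, "END")) {
    session$complete <- TRUE
    list(status = "complete", next_field = "COMPLETE")
  } else {
    session$cursor <- match(nxt, field_ids(session$form))
    list(status = "advanced", next_field = nxt)
  }
}

#' Submit the answer for the current question
#'
#' Validates the raw input, records the answer, and advances the cursor via
#' the form's jump rules (forward-only, so a session terminates in at most
#' one submission per field). Validation failures leave the cursor unmoved.
#' Answering a `branch_trigger` question with a count n > 0 returns a
#' branch prompt: complete n sub-sessions over the branch form and attach
#' them with [attach_branch_entry()] before the interview continues; a count
#' of 0 continues automatically.
#'
#' @param session A `collect_session`.
#' @param raw Raw input string (see [validate_answer()]).
#' @param raw2 Second input for double-entry fields.
#' @return List with `status` (`"advanced"`, `"complete"`,
#'   `"branch_prompt"`, or `"invalid"`) plus `next_field`, `errors`,
#'   `warnings`, `host_field`/`expected` as applicable.
#' @export
submit_answer <- function(session, raw, raw2 = NULL) {
  if (!is.null(session$pending_branch)) {
    stop("branch entries pending for '", session$pending_branch$field_id,
         "'; attach them before continuing")
  }
  if (session$complete) stop("session already complete")
  fl <- session$form$fields[[session$cursor]]
  chk <- validate_answer(fl, raw, raw2, lenient_regex = session$lenient_regex)
  if (!chk$ok) {
    return(list(status = "invalid", errors = chk$errors,
                warnings = chk$warnings))
  }
  if (!is.null(chk$value)) session$answers[[fl$field_id]] <- chk$value

  if (fl$kind == "branch_trigger" && !is.null(chk$value) && chk$value > 0L) {
    session$pending_branch <- list(field_id = fl$field_id,
                                   branch_form = fl$branch,
                                   expected = chk$value, got = 0L)
    return(list(status = "branch_prompt", host_field = fl$field_id,
                branch_form = fl$branch, expected = chk$value,
                warnings = chk$warnings))
  }

  jump_answer <- if (fl$kind %in% c("dropdown", "radio")) chk$value else NULL
  out <- advance_session(session, fl$field_id, jump_answer)
  out$warnings <- chk$warnings
  out
}

#' Attach a completed branch entry to the session's pending branch prompt
#'
#' @param session Host `collect_session` currently at a branch prompt.
#' @param entry A finalised entry of the prompted branch form.
#' @return List with `status`: another `"branch_prompt"` while entries
#'   remain, then `"advanced"`/`"complete"`.
#' @export
attach_branch_entry <- function(session, entry) {
  pb <- session$pending_branch
  if (is.null(pb)) stop("no branch prompt pending")
  if (!identical(entry$form_id, pb$branch_form)) {
    stop("expected an entry of branch form '", pb$branch_form, "'")
  }
  fid <- pb$field_id
  session$branch_entries[[fid]] <- c(session$branch_entries[[fid]], list(entry))
  pb$got <- pb$got + 1L
  session$pending_branch <- pb
  if (pb$got < pb$expected) {
    return(list(status = "branch_prompt", host_field = fid,
                branch_form = pb$branch_form,
                expected = pb$expected - pb$got))
  }
  session$pending_branch <- NULL
  advance_session(session, fid, NULL)
}

#' Finalise a completed session into an entry
#'
#' The entry is stamped with the injected clock's time, given a unique id,
#' and keyed: from the key field's answer, or [generate_auto_key()] when the
#' form's key is `AUTO`. Attached branch entries have their parent key bound
#' to this entry's key.
#'
#' @param session A `collect_session` with every question answered or
#'   legitimately skipped.
#' @return A `collect_entry`.
#' @export
finalize_entry <- function(session) {
  if (!is.null(session$pending_branch)) {
    stop("branch entries pending; session cannot be finalised")
  }
  if (!session$complete) {
    missing <- character(0)
    fids <- field_ids(session$form)
    for (i in seq(session$cursor, length(fids))) {
      fl <- session$form$fields[[i]]
      if (fl$validation$required && is.null(session$answers[[fl$field_id]])) {
        missing <- c(missing, fl$field_id)
      }
    }
    stop("session incomplete; unanswered required field(s): ",
         paste(missing, collapse = ", "))
  }
  created_at <- session$clock()
  key <- if (identical(session$form$key_field, "AUTO")) {
    generate_auto_key(session$device_id, created_at)
  } else {
    as.character(session$answers[[session$form$key_field]])
  }
  if (length(key) == 0L || !nzchar(key)) {
    stop("key field '", session$form$key_field, "' yielded an empty key")
  }
  children <- session$branch_entries
  for (fid in names(children)) {
    children[[fid]] <- lapply(children[[fid]], function(e) {
      e$parent_key <- key
      e
    })
  }
  structure(
    list(
      entry_id = paste(session$device_id, session$form_id,
                       format_num(created_at), sep = "-"),
      form_id = session$form_id, key_value = key,
      parent_key = session$parent_key, created_at = created_at,
      device_id = session$device_id, answers = session$answers,
      branch_children = children
    ),
    class = "collect_entry"
  )
}

#' @export
print.collect_entry <- function(x, ...) {
  cat(sprintf("<collect_entry> %s form=%s key=%s parent=%s (%d answer(s))\n",
              x$entry_id, x$form_id, x$key_value,
              ifelse(is.na(x$parent_key), "-", x$parent_key),
              length(x$answers)))
  invisible(x)
}

#' Run a scripted (non-interactive) session
#'
#' A script is a list of records `list(field, value[, value2])` consumed in
#' interview order; the field id of each record must match the question
#' being presented (a guard against scripts drifting out of step with jump
#' logic). When a branch prompt opens, the following records must complete
#' the prompted number of branch-form sessions before the host form
#' resumes.
#'
#' @param project A valid project.
#' @param form_id Form to fill in.
#' @param script List of answer records.
#' @param parent_key,device_id,clock,lenient_regex As [start_session()].
#' @return The finalised `collect_entry`.
#' @export
run_script <- function(project, form_id, script, parent_key = NULL,
                       device_id = "device", clock = make_clock(),
                       lenient_regex = FALSE) {
  i <- 0L
  take <- function(expect_field) {
    i <<- i + 1L
    if (i > length(script)) {
      stop("script exhausted while form '", form_id, "' expects '",
           expect_field, "'")
    }
    rec <- script[[i]]
    if (!identical(rec$field, expect_field)) {
      stop("script record ", i, " answers '", rec$field,
           "' but the session is at '", expect_field, "'")
    }
    rec
  }
  run_one <- function(fid, pkey) {
    s <- start_session(project, fid, parent_key = pkey,
                       device_id = device_id, clock = clock,
                       lenient_regex = lenient_regex)
    while (!s$complete) {
      rec <- take(current_field(s))
      res <- submit_answer(s, rec$value, rec$value2)
      if (identical(res$status, "invalid")) {
        stop("invalid answer for '", rec$field, "': ",
             paste(vapply(res$errors, `[[`, "", "message"), collapse = "; "))
      }
      while (identical(res$status, "branch_prompt")) {
        child <- run_one(s$pending_branch$branch_form, NULL)
        res <- attach_branch_entry(s, child)
      }
    }
    finalize_entry(s)
  }
  run_one(form_id, parent_key)
}

#' Read a scripted-answer file
#'
#' One record per line, tab-separated: `field_id<TAB>value[<TAB>value2]`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A script list for [run_script()].
#' @export
read_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    rec <- list(field = parts[[1]], value = if (length(parts) > 1L) parts[[2]] else "")
    if (length(parts) > 2L) rec$value2 <- parts[[3]]
    rec
  })
}
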