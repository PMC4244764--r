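#' @importFrom stats setNames
NULL

# Field kinds recognised by the model. `branch_trigger` is the question that
# opens 0..n entries of an attached branch form.
FIELD_KINDS <- c(
  "text", "long_text", "dropdown", "checkbox", "radio",
  "location", "image", "video", "audio", "barcode", "branch_trigger"
)
CHOICE_KINDS <- c("dropdown", "checkbox", "radio")
MEDIA_KINDS <- c("image", "video", "audio")
TEXT_LIKE_KINDS <- c("text", "long_text", "barcode")

#' Define a choice for a single- or multi-select field
#'
#' `name` is what the data gatherer sees; `value` is what is stored.
#'
#' @param name Displayed label.
#' @param value Stored value (defaults to the name).
#' @return A `collect_choice` object.
#' @export
new_choice <- function(name, value = name) {
  stopifnot(is.character(name), length(name) == 1L)
  value <- as.character(value)
  structure(list(name = name, value = value), class = "collect_choice")
}

#' Define validation rules for a field
#'
#' Rules mirror what field workers need to keep free text honest: mandatory
#' answers, integer/decimal typing with ranges, date/time formats such as
#' `"dd/mm/yyyy"` or `"mm:ss"`, and regular-expression pattern matching.
#'
#' @param required Must the question be answered?
#' @param numeric One of `"none"`, `"integer"`, `"decimal"`.
#' @param min,max Numeric bounds; only legal when `numeric != "none"`.
#' @param datetime_format Pattern such as `"dd/mm/yyyy"`, `"mm:ss"`,
#'   `"hh:mm"`; only legal on text-like fields.
#' @param regex Regular expression the raw input must match.
#' @return A `collect_validation` object.
#' @export
new_validation <- function(required = FALSE,
                           numeric = c("none", "integer", "decimal"),
                           min = NULL, max = NULL,
                           datetime_format = NULL, regex = NULL) {
  numeric <- match.arg(numeric)
  structure(
    list(
      required = isTRUE(required), numeric = numeric,
      min = if (!is.null(min)) as.numeric(min),
      max = if (!is.null(max)) as.numeric(max),
      datetime_format = datetime_format, regex = regex
    ),
    class = "collect_validation"
  )
}

#' Define a jump (skip-logic) clause
#'
#' When the owning question is answered with any of `trigger_values`, the
#' interview jumps to `destination` (a later field id, or `"END"`). Clauses
#' are evaluated in declared order; the first match wins.
#'
#' @param trigger_values Character vector of stored choice values
#'   (OR semantics).
#' @param destination Field id later in the form, or `"END"`.
#' @return A `collect_jump` object.
#' @export
new_jump <- function(trigger_values, destination) {
  stopifnot(is.character(trigger_values), length(trigger_values) >= 1L,
            is.character(destination), length(destination) == 1L)
  structure(list(trigger_values = trigger_values, destination = destination),
            class = "collect_jump")
}

#' Define a form field (one question)
#'
#' @param field_id Unique id within the form (the column heading on export).
#' @param label Text shown to the data gatherer.
#' @param kind One of `r paste0('\x60', FIELD_KINDS, '\x60', collapse = ", ")`.
#' @param choices List of [new_choice()] values (choice kinds only).
#' @param validation A [new_validation()] object.
#' @param jumps List of [new_jump()] clauses.
#' @param chartable Summarise answer distribution as counts (choice kinds
#'   only).
#' @param double_entry Ask for the value twice and cross-check (text and
#'   barcode fields).
#' @param branch For `branch_trigger` fields, the id of the attached branch
#'   form.
#' @param extensions Unknown dialect attributes/elements preserved verbatim
#'   (see [parse_project()]).
#' @return A `collect_field` object.
#' @export
new_field <- function(field_id, label, kind,
                      choices = list(), validation = new_validation(),
                      jumps = list(), chartable = FALSE, double_entry = FALSE,
                      branch = NULL, extensions = list()) {
  stopifnot(is.character(field_id), length(field_id) == 1L, nzchar(field_id))
  if (!kind %in% FIELD_KINDS) {
    stop("unknown field kind '", kind, "' for field '", field_id, "'")
  }
  structure(
    list(
      field_id = field_id, label = as.character(label), kind = kind,
      choices = choices, validation = validation, jumps = jumps,
      chartable = isTRUE(chartable), double_entry = isTRUE(double_entry),
      branch = branch, extensions = extensions
    ),
    class = "collect_field"
  )
}

#' Define a form (an ordered questionnaire)
#'
#' @param form_id Unique id within the project.
#' @param fields Ordered list of [new_field()] objects.
#' @param title Displayed title.
#' @param key_field Field id whose answer identifies an entry among its
#'   siblings and links child entries to it, or `"AUTO"` for device-generated
#'   keys (see [generate_auto_key()]).
#' @param extensions Unknown dialect content preserved verbatim.
#' @return A `collect_form` object.
#' @export
new_form <- function(form_id, fields, title = form_id, key_field = "AUTO",
                     extensions = list()) {
  stopifnot(is.character(form_id), length(form_id) == 1L, nzchar(form_id))
  structure(
    list(form_id = form_id, title = as.character(title), fields = fields,
         key_field = key_field, extensions = extensions),
    class = "collect_form"
  )
}

#' Define a project: forms in hierarchy order plus branch forms
#'
#' Hierarchy forms make a strict linear chain in one-to-many parent-child
#' relation (e.g. school -> class -> pupil): form k+1's parent is form k.
#' Branch forms attach to a specific `branch_trigger` question of a host
#' form and are filled 0..n times per host entry.
#'
#' @param name Unique project identifier (also used in retrieval URLs).
#' @param forms Ordered list of hierarchy [new_form()] objects, top level
#'   first.
#' @param branches List of branch [new_form()] objects; each must be
#'   referenced by exactly one `branch_trigger` field.
#' @param title,version,visibility Descriptive metadata; visibility is
#'   `"public"` or `"private"`.
#' @param extensions Unknown dialect content preserved verbatim.
#' @return A `collect_project` object.
#' @export
new_project <- function(name, forms, branches = list(), title = name,
                        version = "1", visibility = c("public", "private"),
                        extensions = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  visibility <- match.arg(visibility)
  structure(
    list(name = name, title = as.character(title),
         version = as.character(version), visibility = visibility,
         forms = forms, branches = branches, extensions = extensions),
    class = "collect_project"
  )
}

#' @export
print.collect_project <- function(x, ...) {
  cat(sprintf("<collect_project> %s (v%s, %s)\n", x$name, x$version,
              x$visibility))
  cat("  hierarchy:", paste(vapply(x$forms, `[[`, "", "form_id"),
                            collapse = " -> "), "\n")
  if (length(x$branches)) {
    cat("  branches: ", paste(vapply(x$branches, `[[`, "", "form_id"),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

form_ids <- function(forms) vapply(forms, `[[`, character(1), "form_id")
field_ids <- function(form) vapply(form$fields, `[[`, character(1), "field_id")

# Look up a form by id anywhere in the project; NULL when absent.
project_form <- function(project, form_id) {
  for (f in c(project$forms, project$branches)) {
    if (f$form_id == form_id) return(f)
  }
  NULL
}

# Hierarchy level of a form (1 = top), or NA for branch forms.
form_level <- function(project, form_id) {
  m <- match(form_id, form_ids(project$forms))
  if (is.na(m)) NA_integer_ else m
}

is_branch_form <- function(project, form_id) {
  form_id %in% form_ids(project$branches)
}

# Host (form id, field id) of a branch form, or NULL.
branch_host <- function(project, branch_form_id) {
  for (f in project$forms) {
    for (fl in f$fields) {
      if (fl$kind == "branch_trigger" && identical(fl$branch, branch_form_id)) {
        return(list(host_form = f$form_id, host_field = fl$field_id))
      }
    }
  }
  NULL
}

form_field <- function(form, field_id) {
  for (fl in form$fields) if (fl$field_id == field_id) return(fl)
  NULL
}

choice_values <- function(field) {
  vapply(field$choices, `[[`, character(1), "value")
}

issue <- function(severity, location, message) {
  list(severity = severity, location = location, message = message)
}

#' Structurally validate a whole project
#'
#' Checks every model invariant -- unique ids, the linear hierarchy chain,
#' key-field existence, branch attachments, forward-only jump destinations,
#' choice/validation legality -- and reports all problems rather than
#' stopping at the first. The function is total: any structurally
#' well-formed input yields a report, never an error.
#'
#' @param project A [new_project()] object.
#' @return A `validation_report`: list with `ok` (no error-severity issues)
#'   and `issues` (data frame with columns severity, location, message).
#' @export
validate_project <- function(project) {
  issues <- list()
  add <- function(sev, loc, msg) issues[[length(issues) + 1L]] <<- issue(sev, loc, msg)

  if (!inherits(project, "collect_project")) {
    add("error", "project", "not a collect_project object")
    return(validation_report(issues))
  }
  if (length(project$forms) == 0L) {
    add("error", "project", "forms empty: a project needs at least one hierarchy form")
    return(validation_report(issues))
  }

  all_forms <- c(project$forms, project$branches)
  ids <- form_ids(all_forms)
  for (d in unique(ids[duplicated(ids)])) {
    add("error", paste0("project/form[", d, "]"), "duplicate form id")
  }

  branch_ids <- form_ids(project$branches)
  hier_ids <- form_ids(project$forms)

  # Every branch_trigger must point at a registered branch form; every branch
  # form must be referenced exactly once and sit in no hierarchy position.
  refs <- character(0)
  for (f in all_forms) {
    loc_f <- paste0("project/form[", f$form_id, "]")
    fids <- field_ids(f)
    for (d in unique(fids[duplicated(fids)])) {
      add("error", paste0(loc_f, "/field[", d, "]"), "duplicate field id")
    }

    if (!identical(f$key_field, "AUTO")) {
      kf <- form_field(f, f$key_field)
      if (is.null(kf)) {
        add("error", loc_f, paste0("key_field missing: no field '", f$key_field, "'"))
      } else if (!kf$kind %in% c("text", "barcode")) {
        add("error", loc_f,
            paste0("key_field '", f$key_field, "' must be a text or barcode field"))
      }
    }

    n <- length(f$fields)
    for (i in seq_len(n)) {
      fl <- f$fields[[i]]
      loc <- paste0(loc_f, "/field[", fl$field_id, "]")

      if (fl$kind %in% CHOICE_KINDS) {
        if (length(fl$choices) == 0L) {
          add("error", loc, "choice field declares no choices")
        }
        vals <- choice_values(fl)
        if (any(!nzchar(vals))) add("error", loc, "empty choice value")
        for (d in unique(vals[duplicated(vals)])) {
          add("error", loc, paste0("duplicate choice value '", d, "'"))
        }
      } else if (length(fl$choices) > 0L) {
        add("error", loc, "choices are only legal on dropdown/checkbox/radio fields")
      }

      if (fl$chartable && !fl$kind %in% CHOICE_KINDS) {
        add("error", loc, "chartable is only legal on dropdown/checkbox/radio fields")
      }
      if (fl$double_entry && !fl$kind %in% TEXT_LIKE_KINDS) {
        add("error", loc, "double_entry is only legal on text and barcode fields")
      }

      v <- fl$validation
      if (!is.null(v$min) && !is.null(v$max) && v$min > v$max) {
        add("error", loc, "validation min > max")
      }
      if ((!is.null(v$min) || !is.null(v$max)) && v$numeric == "none") {
        add("error", loc, "min/max require a numeric validation type")
      }
      if (!is.null(v$datetime_format) && !fl$kind %in% c("text", "long_text")) {
        add("error", loc, "datetime_format is only legal on text fields")
      }

      if (fl$kind == "branch_trigger") {
        if (is.null(fl$branch)) {
          add("error", loc, "branch_trigger does not name a branch form")
        } else {
          refs <- c(refs, fl$branch)
          if (!fl$branch %in% branch_ids) {
            if (fl$branch %in% hier_ids) {
              add("error", loc, paste0("branch '", fl$branch,
                                       "' is a hierarchy form, not a branch form"))
            } else {
              add("error", loc, paste0("branch form '", fl$branch, "' not registered"))
            }
          }
          if (f$form_id %in% branch_ids) {
            add("error", loc, "branch forms may not declare branch_trigger fields")
          }
        }
      }

      if (length(fl$jumps) > 0L && !fl$kind %in% c("dropdown", "radio")) {
        add("error", loc, "jumps are only legal on dropdown/radio fields")
      }
      for (j in fl$jumps) {
        if (identical(j$destination, "END")) next
        dest <- match(j$destination, fids)
        if (is.na(dest)) {
          add("error", loc, paste0("jump destination '", j$destination, "' does not exist"))
        } else if (dest <= i) {
          add("error", loc, paste0("backward jump: '", j$destination,
                                   "' is not later than '", fl$field_id, "'"))
        } else if (f$fields[[dest]]$kind == "branch_trigger") {
          add("warning", loc, paste0("jump targets branch_trigger field '",
                                     j$destination, "'"))
        }
        if (fl$kind %in% CHOICE_KINDS) {
          unknown <- setdiff(j$trigger_values, choice_values(fl))
          if (length(unknown)) {
            add("warning", loc, paste0("jump trigger value(s) not among choices: ",
                                      paste(unknown, collapse = ", ")))
          }
        }
      }
    }
  }

  for (b in branch_ids) {
    k <- sum(refs == b)
    if (k == 0L) {
      add("error", paste0("project/form[", b, "]"),
          "branch form is not referenced by any branch_trigger field")
    } else if (k > 1L) {
      add("error", paste0("project/form[", b, "]"),
          "branch form is referenced by more than one branch_trigger field")
    }
  }

  validation_report(issues)
}

validation_report <- function(issues) {
  df <- if (length(issues)) {
    data.frame(
      severity = vapply(issues, `[[`, character(1), "severity"),
      location = vapply(issues, `[[`, character(1), "location"),
      message = vapply(issues, `[[`, character(1), "message"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(severity = character(0), location = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
  structure(list(ok = !any(df$severity == "error"), issues = df),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok = %s, %d issue(s)\n", x$ok, nrow(x$issues)))
  if (nrow(x$issues)) print(x$issues, row.names = FALSE)
  invisible(x)
}

stop_if_invalid <- function(project) {
  rep <- validate_project(project)
  if (!rep$ok) {
    msg <- paste(rep$issues$message[rep$issues$severity == "error"], collapse = "; ")
    cond <- simpleError(paste0("invalid project: ", msg))
    cond$report <- rep
    stop(cond)
  }
  invisible(rep)
}

#' Hierarchy chain of a project
#'
#' @param project A valid project.
#' @return Character vector of hierarchy form ids, top level first; branch
#'   forms are excluded.
#' @export
hierarchy_chain <- function(project) {
  stop_if_invalid(project)
  form_ids(project$forms)
}

#' Branch attachments of a form
#'
#' @param project A project.
#' @param form_id A form id within the project.
#' @return List of `list(host_field, branch_form)` in host-field order;
#'   empty list when the form declares no branches.
#' @export
branches_of <- function(project, form_id) {
  f <- project_form(project, form_id)
  if (is.null(f)) stop("unknown form id '", form_id, "'")
  out <- list()
  for (fl in f$fields) {
    if (fl$kind == "branch_trigger") {
      out[[length(out) + 1L]] <- list(host_field = fl$field_id,
                                      branch_form = fl$branch)
    }
  }
  out
}
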