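# Multi-value cells (checkbox) join selected values with ";"; a literal ";"
# inside a value is escaped as "\;".
escape_multi <- function(values) {
  paste(gsub(";", "\\\\;", values, fixed = FALSE), collapse = ";")
}

unescape_multi <- function(txt) {
  # split on ";" not preceded by a backslash, then unescape
  parts <- strsplit(txt, "(?<!\\\\);", perl = TRUE)[[1]]
  gsub("\\;", ";", parts, fixed = TRUE)
}

# ISO-8601 UTC with milliseconds <-> epoch milliseconds.
iso_from_ms <- function(ms) {
  secs <- ms %/% 1000
  sprintf("%s.%03dZ",
          format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%S"),
          as.integer(ms %% 1000))
}

ms_from_iso <- function(txt) {
  base <- as.POSIXct(strptime(substr(txt, 1, 19), "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC"))
  as.numeric(base) * 1000 + as.integer(substr(txt, 21, 23))
}

# One table cell per answer; "" when unanswered (skipped fields export as
# empty cells).
cell_from_answer <- function(field, answer) {
  if (is.null(answer)) return("")
  switch(field$kind,
    checkbox = escape_multi(answer),
    location = paste(vapply(unlist(answer), format_num, character(1)),
                     collapse = ","),
    image = , video = , audio = answer$uri,
    branch_trigger = format_num(answer),
    if (is.numeric(answer)) format_num(answer) else as.character(answer)
  )
}

answer_from_cell <- function(field, cell) {
  if (!nzchar(cell)) return(NULL)
  switch(field$kind,
    checkbox = unescape_multi(cell),
    location = parse_location_raw(cell),
    image = , video = , audio = new_media_ref(field$kind, cell),
    branch_trigger = as.integer(cell),
    {
      if (field$validation$numeric != "none") as.numeric(cell) else cell
    }
  )
}

FIXED_COLUMNS <- c("entry_id", "created_at", "device_id", "parent_key", "key")

#' Export a form's entries as a delimited table
#'
#' Header: `entry_id, created_at, device_id, parent_key, key`, then field
#' ids in form order. Checkbox values are joined by `";"`; media cells
#' contain the stored URL/path; fields skipped by jump logic are empty
#' cells; `created_at` is ISO-8601 UTC with milliseconds. CSV quoting
#' follows RFC 4180 (quoted fields, embedded quotes doubled).
#'
#' @param store An `entry_store`.
#' @param form_id Form to export.
#' @param format `"csv"` or `"tsv"`.
#' @param path Optional file to write to.
#' @return The table as a single string (invisibly when `path` is given).
#' @export
export_table <- function(store, form_id, format = c("csv", "tsv"),
                         path = NULL) {
  format <- match.arg(format)
  form <- project_form(store$project, form_id)
  if (is.null(form)) stop("unknown form '", form_id, "'")
  entries <- store_entries(store, form_id)
  fids <- field_ids(form)
  mat <- matrix("", nrow = length(entries), ncol = 5L + length(fids),
                dimnames = list(NULL, c(FIXED_COLUMNS, fids)))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    mat[i, 1:5] <- c(e$entry_id, iso_from_ms(e$created_at), e$device_id,
                     ifelse(is.na(e$parent_key), "", e$parent_key),
                     e$key_value)
    for (j in seq_along(fids)) {
      mat[i, 5L + j] <- cell_from_answer(form$fields[[j]],
                                         e$answers[[fids[[j]]]])
    }
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  tc <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, tc, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, col.names = TRUE, quote = TRUE,
                     qmethod = "double", na = "")
  close(tc)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Import entries from a delimited table
#'
#' Inverse of [export_table()]: rebuilds typed entries (values, keys,
#' parents, timestamps) from the cells.
#'
#' @param project The project the table belongs to.
#' @param form_id Form the rows represent.
#' @param txt Table text or a file path.
#' @param format `"csv"` or `"tsv"`.
#' @return List of `collect_entry`.
#' @export
import_table <- function(project, form_id, txt, format = c("csv", "tsv")) {
  format <- match.arg(format)
  form <- project_form(project, form_id)
  if (is.null(form)) stop("unknown form '", form_id, "'")
  if (file.exists(txt) && !grepl("\n", txt, fixed = TRUE)) {
    txt <- readChar(txt, file.info(txt)$size, useBytes = TRUE)
  }
  df <- utils::read.table(text = txt, sep = if (format == "csv") "," else "\t",
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "\"")
  lapply(seq_len(nrow(df)), function(i) {
    answers <- list()
    for (fl in form$fields) {
      a <- answer_from_cell(fl, df[[fl$field_id]][i])
      if (!is.null(a)) answers[[fl$field_id]] <- a
    }
    pk <- df$parent_key[i]
    structure(
      list(entry_id = df$entry_id[i], form_id = form_id,
           key_value = df$key[i],
           parent_key = if (nzchar(pk)) pk else NA_character_,
           created_at = ms_from_iso(df$created_at[i]),
           device_id = df$device_id[i], answers = answers,
           branch_children = list()),
      class = "collect_entry"
    )
  })
}

value_to_xml <- function(parent, field, answer) {
  node <- xml2::xml_add_child(parent, "value")
  xml2::xml_set_attr(node, "field", field$field_id)
  if (field$kind == "checkbox") {
    for (v in answer) {
      vn <- xml2::xml_add_child(node, "v")
      xml2::xml_set_text(vn, v)
    }
  } else if (field$kind == "location") {
    xml2::xml_set_attrs(node, c(
      field = field$field_id,
      lat = format_num(answer$lat), lon = format_num(answer$lon),
      alt = format_num(answer$alt), accuracy = format_num(answer$accuracy)
    ))
  } else if (field$kind %in% MEDIA_KINDS) {
    attrs <- c(field = field$field_id, uri = answer$uri)
    if (!is.null(answer$thumbnail_uri)) {
      attrs <- c(attrs, thumbnail = answer$thumbnail_uri)
    }
    xml2::xml_set_attrs(node, attrs)
  } else {
    xml2::xml_set_text(node, cell_from_answer(field, answer))
  }
  node
}

entry_to_xml <- function(parent, store, entry) {
  project <- store$project
  form <- project_form(project, entry$form_id)
  node <- xml2::xml_add_child(parent, "entry")
  xml2::xml_set_attrs(node, c(
    form = entry$form_id, id = entry$entry_id, key = entry$key_value,
    parent = if (!is.na(entry$parent_key)) entry$parent_key,
    created = format_num(entry$created_at), device = entry$device_id
  ))
  for (fl in form$fields) {
    a <- entry$answers[[fl$field_id]]
    if (!is.null(a)) value_to_xml(node, fl, a)
  }
  # branch entries nested under their host, grouped per trigger field
  for (att in branches_of(project, entry$form_id)) {
    kids <- Filter(function(b) {
      identical(b$parent_key, entry$key_value) &&
        !already_nested(store, b, entry)
    }, store$entries[[att$branch_form]])
    if (length(kids)) {
      bn <- xml2::xml_add_child(node, "branch")
      xml2::xml_set_attr(bn, "field", att$host_field)
      for (b in kids) entry_to_xml(bn, store, b)
    }
  }
  # next hierarchy level nested inside the parent element
  level <- form_level(project, entry$form_id)
  if (!is.na(level) && level < hierarchy_depth(store)) {
    child_form <- form_ids(project$forms)[[level + 1L]]
    for (ch in store$entries[[child_form]]) {
      if (identical(ch$parent_key, entry$key_value) &&
          !already_nested(store, ch, entry)) {
        entry_to_xml(node, store, ch)
      }
    }
  }
  node
}

# With per-(form, parent) key scoping, a child key can in principle match
# several same-keyed parents across grandparents; nest under the first
# matching parent only.
already_nested <- function(store, child, parent_entry) {
  parents <- store$entries[[parent_entry$form_id]]
  for (p in parents) {
    if (identical(p$key_value, child$parent_key)) {
      return(!identical(p$entry_id, parent_entry$entry_id))
    }
  }
  FALSE
}

#' Export a store as nested XML
#'
#' The document preserves the hierarchy: parent entry elements contain
#' their child entries, and branch entries are nested under their host
#' entry grouped by trigger field. The same document format serves as the
#' store's on-disk persistence (see [store_save()]).
#'
#' @param store An `entry_store`.
#' @param form_id Optional root form; defaults to the top of the hierarchy.
#' @param path Optional file to write to.
#' @return XML text (invisibly when `path` is given).
#' @export
export_xml <- function(store, form_id = NULL, path = NULL) {
  project <- store$project
  root_form <- form_id %||% form_ids(project$forms)[[1L]]
  if (is.null(project_form(project, root_form))) {
    stop("unknown form '", root_form, "'")
  }
  doc <- xml2::xml_new_root("entries")
  xml2::xml_set_attrs(doc, c(project = project$name, dialect = DIALECT_VERSION,
                             form = root_form))
  for (e in store$entries[[root_form]]) entry_to_xml(doc, store, e)
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

answer_from_value_node <- function(field, node) {
  if (field$kind == "checkbox") {
    vapply(xml2::xml_find_all(node, "./v"), xml2::xml_text, character(1))
  } else if (field$kind == "location") {
    list(lat = as.numeric(xml2::xml_attr(node, "lat")),
         lon = as.numeric(xml2::xml_attr(node, "lon")),
         alt = as.numeric(xml2::xml_attr(node, "alt")),
         accuracy = as.numeric(xml2::xml_attr(node, "accuracy")))
  } else if (field$kind %in% MEDIA_KINDS) {
    new_media_ref(field$kind, xml2::xml_attr(node, "uri"))
  } else {
    answer_from_cell(field, xml2::xml_text(node))
  }
}

entry_from_xml <- function(project, node) {
  form_id <- xml2::xml_attr(node, "form")
  form <- project_form(project, form_id)
  if (is.null(form)) stop("entry references unknown form '", form_id, "'")
  answers <- list()
  for (vn in xml2::xml_find_all(node, "./value")) {
    fid <- xml2::xml_attr(vn, "field")
    fl <- form_field(form, fid)
    if (is.null(fl)) stop("value references unknown field '", fid, "'")
    answers[[fid]] <- answer_from_value_node(fl, vn)
  }
  pk <- xml2::xml_attr(node, "parent")
  structure(
    list(entry_id = xml2::xml_attr(node, "id"), form_id = form_id,
         key_value = xml2::xml_attr(node, "key"),
         parent_key = if (is.na(pk)) NA_character_ else pk,
         created_at = as.numeric(xml2::xml_attr(node, "created")),
         device_id = xml2::xml_attr(node, "device"),
         answers = answers, branch_children = list()),
    class = "collect_entry"
  )
}

#' Import a nested XML export into a fresh store
#'
#' Entries are inserted in document order (parents precede their children
#' by construction), through the same integrity checks as any other
#' insertion.
#'
#' @param project The project the document belongs to.
#' @param x XML text, a file path, or an `xml_document`.
#' @return A populated `entry_store`.
#' @export
import_entries_xml <- function(project, x) {
  doc <- if (inherits(x, "xml_document")) {
    x
  } else if (file.exists(x) && !grepl("<", x, fixed = TRUE)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(x)
  }
  store <- entry_store(project)
  walk <- function(node) {
    for (child in xml2::xml_children(node)) {
      nm <- xml2::xml_name(child)
      if (nm == "entry") {
        e <- entry_from_xml(project, child)
        res <- insert_entry(store, e)
        if (res$status != "accepted") {
          stop("import rejected entry '", e$entry_id, "': ", res$reason)
        }
        walk(child)
      } else if (nm == "branch") {
        walk(child)
      }
    }
  }
  walk(xml2::xml_root(doc))
  store
}

#' Persist a store to disk
#'
#' @param store An `entry_store`.
#' @param path File to write.
#' @return Invisibly, the path.
#' @export
store_save <- function(store, path) {
  export_xml(store, path = path)
  invisible(path)
}

#' Load a persisted store
#'
#' @param project The store's project.
#' @param path File written by [store_save()].
#' @return An `entry_store`.
#' @export
store_load <- function(project, path) {
  import_entries_xml(project, path)
}

#' Enter a form entry through the web path
#'
#' Runs the same interview pipeline as phone collection -- jump logic in
#' field order, the full validation chain per answered field -- then
#' finalises with device id `"web"` and inserts through the store's
#' integrity checks. For barcode fields only the decoded text can be
#' entered; media arrive as uploaded file references.
#'
#' @param store An `entry_store`.
#' @param form_id Form to add an entry to.
#' @param answers Named list mapping field ids to raw strings (a length-2
#'   character vector for double-entry fields; for a `branch_trigger`
#'   field, a list of per-branch-entry answer maps). Fields skipped by jump
#'   logic are simply never consulted.
#' @param parent_key Parent entry's key, for forms below the top level.
#' @param clock Injected [make_clock()].
#' @param lenient_regex Passed to [validate_answer()].
#' @return List with `status` (`"accepted"`, `"orphan"`, `"duplicate"`, or
#'   `"invalid"`), `entry` on success, `errors` (named by field) on
#'   validation failure.
#' @export
import_web_entry <- function(store, form_id, answers, parent_key = NULL,
                             clock = make_clock(), lenient_regex = FALSE) {
  run_form <- function(fid, pkey, ans) {
    s <- start_session(store$project, fid, parent_key = pkey,
                       device_id = "web", clock = clock,
                       lenient_regex = lenient_regex)
    errors <- list()
    while (!s$complete) {
      cur <- current_field(s)
      raw <- ans[[cur]]
      fl <- form_field(s$form, cur)
      if (fl$kind == "branch_trigger" && is.list(raw)) {
        res <- submit_answer(s, as.character(length(raw)))
        k <- 0L
        while (identical(res$status, "branch_prompt")) {
          k <- k + 1L
          sub <- run_form(s$pending_branch$branch_form, NULL, raw[[k]])
          if (!is.null(sub$errors)) return(sub)
          res <- attach_branch_entry(s, sub$entry)
        }
      } else {
        raw1 <- if (is.null(raw)) "" else as.character(raw)[1]
        raw2 <- if (length(raw) > 1L) as.character(raw)[2]
        res <- submit_answer(s, raw1, raw2)
      }
      if (identical(res$status, "invalid")) {
        errors[[cur]] <- res$errors
        return(list(errors = errors))
      }
    }
    list(entry = finalize_entry(s))
  }
  out <- run_form(form_id, parent_key, answers)
  if (!is.null(out$errors)) {
    return(list(status = "invalid", errors = out$errors))
  }
  res <- insert_entry_tree(store, out$entry)
  list(status = res[[out$entry$entry_id]]$status, entry = out$entry)
}
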