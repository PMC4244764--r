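key_slot <- function(form_id, parent_key, key_value) {
  paste(form_id, ifelse(is.na(parent_key), "", parent_key), key_value,
        sep = "\r")
}

#' Create an empty hierarchical entry store
#'
#' The store enforces the two referential invariants of the collection
#' model: an entry below the top level must have a parent entry above it
#' whose key matches its parent key, and keys are unique per (form, parent)
#' -- so two classes named "5B" in different schools are legal, but
#' re-submitting the same entry is rejected as a duplicate.
#'
#' @param project A valid project.
#' @return A mutable `entry_store` (environment).
#' @export
entry_store <- function(project) {
  stop_if_invalid(project)
  s <- new.env(parent = emptyenv())
  s$project <- project
  s$entries <- stats::setNames(
    rep(list(list()), length(c(project$forms, project$branches))),
    form_ids(c(project$forms, project$branches))
  )
  s$key_index <- new.env(parent = emptyenv())   # (form, parent, key) -> entry_id
  s$key_count <- new.env(parent = emptyenv())   # (form, key) -> n parents using it
  s$ids <- new.env(parent = emptyenv())         # entry_id -> TRUE
  s$synced <- new.env(parent = emptyenv())      # entry_id -> TRUE
  class(s) <- "entry_store"
  s
}

#' @export
print.entry_store <- function(x, ...) {
  counts <- vapply(x$entries, length, integer(1))
  cat(sprintf("<entry_store> project '%s': %d entr%s\n", x$project$name,
              sum(counts), ifelse(sum(counts) == 1, "y", "ies")))
  for (fid in names(counts)) cat(sprintf("  %s: %d\n", fid, counts[[fid]]))
  invisible(x)
}

hierarchy_depth <- function(store) length(store$project$forms)

# Does any entry of `form_id` carry this key (under any parent)?
form_has_key <- function(store, form_id, key_value) {
  k <- paste(form_id, key_value, sep = "\r")
  !is.null(store$key_count[[k]]) && store$key_count[[k]] > 0L
}

insert_result <- function(status, reason = NULL) {
  structure(list(status = status, reason = reason), class = "insert_result")
}

#' Insert one entry, enforcing parent-key integrity
#'
#' An entry is accepted iff its parent exists in the store (top-level
#' entries need none) and its (form, parent, key) is not already present.
#' Re-submission of an already-stored entry is therefore rejected as a
#' duplicate, making synchronisation retries idempotent. Branch children
#' carried inline on the entry are ignored here; use
#' [insert_entry_tree()] to insert an entry together with its branch
#' entries.
#'
#' @param store An `entry_store`.
#' @param entry A `collect_entry` belonging to a form of the store's
#'   project.
#' @return An `insert_result` with `status` `"accepted"`, `"duplicate"` or
#'   `"orphan"`.
#' @export
insert_entry <- function(store, entry) {
  form_id <- entry$form_id
  if (!form_id %in% names(store$entries)) {
    stop("entry belongs to unknown form '", form_id, "'")
  }
  if (isTRUE(store$ids[[entry$entry_id]])) {
    return(insert_result("duplicate", "entry already stored"))
  }
  level <- form_level(store$project, form_id)
  if (!is.na(level) && level == 1L) {
    if (!is.na(entry$parent_key)) {
      return(insert_result("orphan", "top-level entries take no parent key"))
    }
  } else {
    parent_form <- if (is.na(level)) {
      branch_host(store$project, form_id)$host_form
    } else {
      form_ids(store$project$forms)[[level - 1L]]
    }
    if (is.na(entry$parent_key) ||
        !form_has_key(store, parent_form, entry$parent_key)) {
      return(insert_result("orphan", paste0(
        "no entry of form '", parent_form, "' with key '", entry$parent_key, "'")))
    }
  }
  slot <- key_slot(form_id, entry$parent_key, entry$key_value)
  if (!is.null(store$key_index[[slot]])) {
    return(insert_result("duplicate",
                         paste0("key '", entry$key_value, "' already present")))
  }

  flat <- entry
  flat$branch_children <- list()
  store$entries[[form_id]] <- c(store$entries[[form_id]], list(flat))
  store$key_index[[slot]] <- entry$entry_id
  kc <- paste(form_id, entry$key_value, sep = "\r")
  store$key_count[[kc]] <- (store$key_count[[kc]] %||% 0L) + 1L
  store$ids[[entry$entry_id]] <- TRUE
  insert_result("accepted")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Insert an entry together with its attached branch entries
#'
#' The host is inserted first; if accepted, each branch child follows
#' (parent key bound to the host's key).
#'
#' @param store An `entry_store`.
#' @param entry A `collect_entry` (possibly carrying branch children).
#' @return Named list of `insert_result`s by entry id, host first.
#' @export
insert_entry_tree <- function(store, entry) {
  out <- list()
  out[[entry$entry_id]] <- insert_entry(store, entry)
  if (out[[entry$entry_id]]$status == "accepted") {
    for (kids in entry$branch_children) {
      for (child in kids) {
        child$parent_key <- entry$key_value
        out[[child$entry_id]] <- insert_entry(store, child)
      }
    }
  }
  out
}

#' Entries of one form, in insertion order
#'
#' @param store An `entry_store`.
#' @param form_id Form id.
#' @return List of `collect_entry`.
#' @export
store_entries <- function(store, form_id) {
  if (!form_id %in% names(store$entries)) stop("unknown form '", form_id, "'")
  store$entries[[form_id]]
}

#' Pre-load all entries at and above a hierarchy level
#'
#' Emulates loading server data onto a fresh device so collection can
#' resume mid-project: choosing level k returns every entry of hierarchy
#' levels 1..k (branch entries and lower levels excluded), ordered by level
#' then insertion.
#'
#' @param store An `entry_store`.
#' @param level Hierarchy level, 1 (top) to the hierarchy depth.
#' @return List of `collect_entry`.
#' @export
preload <- function(store, level) {
  depth <- hierarchy_depth(store)
  if (!is.numeric(level) || length(level) != 1L || level < 1L || level > depth) {
    stop("level must be between 1 and the hierarchy depth (", depth, ")")
  }
  out <- list()
  for (k in seq_len(level)) {
    out <- c(out, store$entries[[form_ids(store$project$forms)[[k]]]])
  }
  out
}

#' Construct an entry filter
#'
#' @param from_ms,to_ms Optional closed time window on entry creation time
#'   (UTC epoch milliseconds).
#' @param choices Named list mapping choice-field ids to accepted value
#'   vectors; an entry matches when every filter matches (checkbox fields
#'   match on non-empty intersection).
#' @return An `entry_filter`.
#' @export
entry_filter <- function(from_ms = NULL, to_ms = NULL, choices = list()) {
  if (!is.null(from_ms) && !is.null(to_ms) && from_ms > to_ms) {
    stop("filter window: from_ms must be <= to_ms")
  }
  structure(list(from_ms = from_ms, to_ms = to_ms, choices = choices),
            class = "entry_filter")
}

matches_filter <- function(entry, form, filter) {
  if (!is.null(filter$from_ms) && entry$created_at < filter$from_ms) return(FALSE)
  if (!is.null(filter$to_ms) && entry$created_at > filter$to_ms) return(FALSE)
  for (fid in names(filter$choices)) {
    ans <- entry$answers[[fid]]
    if (is.null(ans)) return(FALSE)
    if (length(intersect(ans, filter$choices[[fid]])) == 0L) return(FALSE)
  }
  TRUE
}

#' Query a form's entries through a filter
#'
#' @param store An `entry_store`.
#' @param form_id Form id.
#' @param filter An [entry_filter()]; `NULL` means no filtering (identity).
#' @return List of matching entries, in stable insertion order.
#' @export
query_entries <- function(store, form_id, filter = NULL) {
  entries <- store_entries(store, form_id)
  if (is.null(filter)) return(entries)
  form <- project_form(store$project, form_id)
  for (fid in names(filter$choices)) {
    fl <- form_field(form, fid)
    if (is.null(fl)) stop("filter references unknown field '", fid, "'")
    if (!fl$kind %in% CHOICE_KINDS) {
      stop("filter field '", fid, "' is not a dropdown/checkbox/radio field")
    }
  }
  Filter(function(e) matches_filter(e, form, filter), entries)
}

#' Answer-distribution counts for a choice field
#'
#' Counts answers over (optionally filtered) entries of a form, the summary
#' behind pie/bar charts. Checkbox answers contribute to every selected
#' value; declared values with no answers are present with count 0;
#' unanswered entries contribute nothing.
#'
#' @param store An `entry_store`.
#' @param form_id Form id.
#' @param field_id A dropdown/checkbox/radio field of that form.
#' @param filter Optional [entry_filter()].
#' @return Named integer vector over the field's declared choice values.
#' @export
chart_counts <- function(store, form_id, field_id, filter = NULL) {
  form <- project_form(store$project, form_id)
  if (is.null(form)) stop("unknown form '", form_id, "'")
  fl <- form_field(form, field_id)
  if (is.null(fl)) stop("unknown field '", field_id, "'")
  if (!fl$kind %in% CHOICE_KINDS) {
    stop("chart_counts needs a dropdown/checkbox/radio field")
  }
  counts <- stats::setNames(integer(length(fl$choices)), choice_values(fl))
  for (e in query_entries(store, form_id, filter)) {
    for (v in e$answers[[field_id]]) counts[[v]] <- counts[[v]] + 1L
  }
  counts
}

#' Check a store's referential invariants in full
#'
#' Recomputes, from the stored entries alone, that no entry is an orphan
#' and no (form, parent, key) is duplicated.
#'
#' @param store An `entry_store`.
#' @return List with `ok`, `orphans` (entry ids), `duplicate_keys`.
#' @export
check_store <- function(store) {
  orphans <- character(0)
  dupes <- character(0)
  seen <- new.env(parent = emptyenv())
  for (form_id in names(store$entries)) {
    level <- form_level(store$project, form_id)
    parent_form <- if (!is.na(level) && level == 1L) {
      NA_character_
    } else if (is.na(level)) {
      branch_host(store$project, form_id)$host_form
    } else {
      form_ids(store$project$forms)[[level - 1L]]
    }
    for (e in store$entries[[form_id]]) {
      slot <- key_slot(form_id, e$parent_key, e$key_value)
      if (isTRUE(seen[[slot]])) dupes <- c(dupes, e$entry_id)
      seen[[slot]] <- TRUE
      if (is.na(parent_form)) next
      parents <- store$entries[[parent_form]]
      hit <- any(vapply(parents, function(p) identical(p$key_value, e$parent_key),
                        logical(1)))
      if (!hit) orphans <- c(orphans, e$entry_id)
    }
  }
  list(ok = length(orphans) == 0L && length(dupes) == 0L,
       orphans = orphans, duplicate_keys = dupes)
}
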