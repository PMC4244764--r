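#' Plan media transfers for a set of entries
#'
#' All textual data sync immediately; media are potentially large, so by
#' default only image thumbnails travel with the entries and full images,
#' video and audio clips are deferred to a separate transfer the user
#' triggers when bandwidth allows. Thumbnails are never deferred.
#'
#' @param entries List of `collect_entry`.
#' @param policy `"default"` (thumbnails immediate, full media deferred),
#'   `"send_all"` (nothing deferred), or `"defer_all"` (only thumbnails
#'   immediate; same plan as the default policy, kept as an explicit
#'   option).
#' @return Data frame with columns entry_id, field_id, payload_class
#'   (`thumbnail`, `full_image`, `video`, `audio`), deferred.
#' @export
plan_media <- function(entries, policy = c("default", "send_all", "defer_all")) {
  policy <- match.arg(policy)
  defer_full <- policy != "send_all"
  rows <- list()
  add <- function(entry_id, field_id, payload_class, deferred) {
    rows[[length(rows) + 1L]] <<- data.frame(
      entry_id = entry_id, field_id = field_id,
      payload_class = payload_class, deferred = deferred,
      stringsAsFactors = FALSE
    )
  }
  for (e in entries) {
    for (fid in names(e$answers)) {
      a <- e$answers[[fid]]
      if (!is.list(a) || is.null(a$kind) || !a$kind %in% MEDIA_KINDS) next
      if (a$kind == "image") {
        add(e$entry_id, fid, "thumbnail", FALSE)
        add(e$entry_id, fid, "full_image", defer_full)
      } else {
        add(e$entry_id, fid, a$kind, defer_full)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(entry_id = character(0), field_id = character(0),
                      payload_class = character(0), deferred = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Entries of a client store not yet acknowledged by the server
#'
#' @param store An `entry_store`.
#' @return List of entries, hierarchy level ascending, branch entries after
#'   their host.
#' @export
unsynced_entries <- function(store) {
  unlist(lapply(build_batches(store, policy = "default"), `[[`, "entries"),
         recursive = FALSE) %||% list()
}

#' Build the ordered upload batches for a client store
#'
#' Data travel from the highest hierarchy level downwards so that no child
#' entry arrives before its parent: one batch per hierarchy level, each
#' holding that level's unsynced entries in insertion order, with a host's
#' unsynced branch entries placed immediately after it. Deterministic
#' given the store state; empty batches are dropped.
#'
#' @param store A client `entry_store`.
#' @param policy Media policy passed to [plan_media()].
#' @return List of `sync_batch` objects (`entries`, `media_plan`).
#' @export
build_batches <- function(store, policy = "default") {
  project <- store$project
  batches <- list()
  for (k in seq_len(hierarchy_depth(store))) {
    form_id <- form_ids(project$forms)[[k]]
    entries <- list()
    branch_forms <- vapply(branches_of(project, form_id), `[[`, "",
                           "branch_form")
    for (e in store$entries[[form_id]]) {
      if (!isTRUE(store$synced[[e$entry_id]])) {
        entries <- c(entries, list(e))
      }
      for (bf in branch_forms) {
        for (b in store$entries[[bf]]) {
          if (identical(b$parent_key, e$key_value) &&
              !isTRUE(store$synced[[b$entry_id]])) {
            entries <- c(entries, list(b))
          }
        }
      }
    }
    if (length(entries)) {
      batches[[length(batches) + 1L]] <- structure(
        list(entries = entries, media_plan = plan_media(entries, policy)),
        class = "sync_batch"
      )
    }
  }
  batches
}

#' Apply an upload batch to the server store
#'
#' Entries are applied in batch order through [insert_entry()]; every
#' outcome is reported in the result, never thrown. Re-applying a batch is
#' a no-op (every entry reports `duplicate`), and entries whose parent has
#' not arrived yet report `orphan` and can be retried after a later batch
#' supplies the parent.
#'
#' @param server_store The server-side `entry_store`.
#' @param batch A `sync_batch` (or plain list of entries).
#' @return A `sync_result`: data frame `statuses` (entry_id, status,
#'   reason) covering every batch entry exactly once, plus `counts`.
#' @export
apply_batch <- function(server_store, batch) {
  entries <- if (inherits(batch, "sync_batch")) batch$entries else batch
  statuses <- data.frame(
    entry_id = vapply(entries, `[[`, "", "entry_id"),
    status = character(length(entries)),
    reason = character(length(entries)),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(entries)) {
    res <- insert_entry(server_store, entries[[i]])
    statuses$status[i] <- res$status
    statuses$reason[i] <- res$reason %||% ""
  }
  structure(
    list(statuses = statuses,
         counts = c(accepted = sum(statuses$status == "accepted"),
                    duplicate = sum(statuses$status == "duplicate"),
                    orphan = sum(statuses$status == "orphan"))),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> accepted=%d duplicate=%d orphan=%d\n",
              x$counts[["accepted"]], x$counts[["duplicate"]],
              x$counts[["orphan"]]))
  invisible(x)
}

#' Mark client entries acknowledged by a sync result
#'
#' Accepted and duplicate entries are settled (the server holds them);
#' rejected entries stay queued and reappear in the next
#' [build_batches()] call.
#'
#' @param client_store The client `entry_store`.
#' @param result A `sync_result`.
#' @return Invisibly, the number of entries settled by this result.
#' @export
mark_synced <- function(client_store, result) {
  settled <- result$statuses[result$statuses$status %in% c("accepted", "duplicate"), ]
  for (id in settled$entry_id) client_store$synced[[id]] <- TRUE
  invisible(nrow(settled))
}

#' Synchronise a client store to a server store until convergence
#'
#' Repeats build/apply/acknowledge rounds until the client has no unsynced
#' entries or a round makes no progress (e.g. genuine orphans whose parent
#' exists on no store).
#'
#' @param client_store,server_store `entry_store`s over the same project.
#' @param max_rounds Safety bound on retry rounds.
#' @return List with `rounds` and the per-round `results`.
#' @export
sync_stores <- function(client_store, server_store, max_rounds = 10L) {
  results <- list()
  for (round in seq_len(max_rounds)) {
    batches <- build_batches(client_store)
    if (length(batches) == 0L) break
    settled <- 0L
    for (b in batches) {
      res <- apply_batch(server_store, b)
      settled <- settled + mark_synced(client_store, res)
      results[[length(results) + 1L]] <- res
    }
    if (settled == 0L) break
  }
  list(rounds = round - (length(batches) == 0L), results = results)
}
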