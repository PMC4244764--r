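# Independent oracles used across the suite. The naive interpreter re-reads
# jump clauses literally on every step and shares no code with the session
# engine.

# Sequence of fields a literal clause-scan presents, given one answer per
# field (answers for skipped fields are simply unused).
naive_walk <- function(form, answers) {
  fids <- vapply(form$fields, `[[`, character(1), "field_id")
  visited <- character(0)
  i <- 1L
  while (i <= length(fids)) {
    fid <- fids[[i]]
    visited <- c(visited, fid)
    ans <- answers[[fid]]
    dest <- NA_character_
    for (j in form$fields[[i]]$jumps) {
      if (ans %in% j$trigger_values) {
        dest <- j$destination
        break
      }
    }
    i <- if (is.na(dest)) i + 1L else if (identical(dest, "END")) {
      length(fids) + 1L
    } else {
      match(dest, fids)
    }
  }
  visited
}

# Sequence of fields the session engine presents for the same answers.
engine_walk <- function(project, form_id, answers) {
  s <- start_session(project, form_id, device_id = "oracle",
                     clock = make_clock())
  visited <- character(0)
  while (!s$complete) {
    fid <- current_field(s)
    visited <- c(visited, fid)
    res <- submit_answer(s, answers[[fid]])
    stopifnot(!identical(res$status, "invalid"))
  }
  visited
}

# Random single-form project of dropdown questions only (<= 6 fields, <= 3
# choices each), with random forward jump clauses. Wrapped as a one-form
# project so the engine can run it.
random_choice_form_project <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1L)
  fields <- lapply(seq_len(n), function(i) {
    vals <- paste0("c", seq_len(sample(2:3, 1L)))
    new_field(paste0("q", i), paste0("Q", i), "dropdown",
              choices = lapply(vals, new_choice),
              validation = new_validation(required = TRUE))
  })
  for (i in seq_len(n - 1L)) {
    if (runif(1) < 0.6) {
      vals <- vapply(fields[[i]]$choices, `[[`, character(1), "value")
      trig <- sample(vals, sample.int(length(vals), 1L))
      dests <- c(paste0("q", (i + 1L):n), "END")
      nclause <- sample(1:2, 1L)
      jumps <- list()
      for (k in seq_len(nclause)) {
        use <- if (k == 1L) trig else setdiff(vals, trig)
        if (length(use) == 0L) break
        jumps[[k]] <- new_jump(sample(use, min(length(use), 2L)),
                               sample(dests, 1L))
      }
      fields[[i]]$jumps <- jumps
    }
  }
  new_project(paste0("flow", seed), forms = list(new_form("f", fields)))
}

# All answer assignments of a choice-only form, one row per combination.
all_answer_combos <- function(form) {
  vals <- lapply(form$fields, function(f) {
    vapply(f$choices, `[[`, character(1), "value")
  })
  names(vals) <- vapply(form$fields, `[[`, character(1), "field_id")
  expand.grid(vals, stringsAsFactors = FALSE)
}

# One expectation per form: count combinations where the two interpreters
# disagree on the presented-field sequence.
expect_walks_agree <- function(project) {
  form <- project$forms[[1]]
  combos <- all_answer_combos(form)
  mismatches <- 0L
  for (r in seq_len(nrow(combos))) {
    answers <- as.list(combos[r, , drop = FALSE])
    if (!identical(engine_walk(project, form$form_id, answers),
                   naive_walk(form, answers))) {
      mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
  invisible(nrow(combos))
}
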