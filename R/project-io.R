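DIALECT_VERSION <- "1.0"

# Canonical numeric formatting for attributes: plain notation, enough digits
# to round-trip doubles used in validation bounds.
format_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

as_flag <- function(x) if (isTRUE(x)) "true" else NULL

# Known attribute names per element; anything else is an extension and is
# preserved verbatim (the vocabulary stays extensible).
KNOWN_ATTRS <- list(
  project = c("dialect", "name", "title", "version", "visibility"),
  form = c("id", "title", "key", "level", "branch-of", "branch-at"),
  field = c("id", "type", "label", "required", "numeric", "min", "max",
            "date", "regex", "double-entry", "chartable"),
  choice = c("name", "value"),
  jump = c("when", "to")
)

extension_attrs <- function(node, element) {
  at <- xml2::xml_attrs(node)
  at[setdiff(names(at), KNOWN_ATTRS[[element]])]
}

extension_children <- function(node, known) {
  kids <- xml2::xml_children(node)
  keep <- !(xml2::xml_name(kids) %in% known)
  vapply(kids[keep], function(k) as.character(k), character(1))
}

# Collapse to the empty extension record when nothing unknown was found, so
# parsed objects compare identical() to constructed ones.
make_ext <- function(attrs, children) {
  if (length(attrs) == 0L && length(children) == 0L) list()
  else list(attrs = attrs, children = children)
}

add_extensions <- function(node, extensions) {
  if (length(extensions$attrs)) {
    for (nm in names(extensions$attrs)) {
      xml2::xml_set_attr(node, nm, extensions$attrs[[nm]])
    }
  }
  for (frag in extensions$children) {
    xml2::xml_add_child(node, xml2::read_xml(frag))
  }
  invisible(node)
}

field_to_xml <- function(parent, field) {
  v <- field$validation
  attrs <- c(
    id = field$field_id, type = field$kind, label = field$label,
    required = as_flag(v$required),
    numeric = if (v$numeric != "none") v$numeric,
    min = if (!is.null(v$min)) format_num(v$min),
    max = if (!is.null(v$max)) format_num(v$max),
    date = v$datetime_format,
    regex = v$regex,
    `double-entry` = as_flag(field$double_entry),
    chartable = as_flag(field$chartable)
  )
  node <- xml2::xml_add_child(parent, "field")
  xml2::xml_set_attrs(node, attrs)
  for (ch in field$choices) {
    xml2::xml_add_child(node, "choice", name = ch$name, value = ch$value)
  }
  for (j in field$jumps) {
    xml2::xml_add_child(node, "jump",
                        when = paste(j$trigger_values, collapse = ","),
                        to = j$destination)
  }
  add_extensions(node, field$extensions)
  node
}

form_to_xml <- function(parent, form, role_attrs) {
  node <- xml2::xml_add_child(parent, "form")
  xml2::xml_set_attrs(node, c(id = form$form_id, title = form$title,
                              key = form$key_field, role_attrs))
  for (fl in form$fields) field_to_xml(node, fl)
  add_extensions(node, form$extensions)
  node
}

#' Serialise a project to its XML project-definition document
#'
#' Serialisation is canonical and deterministic: the same project always
#' yields byte-identical documents (stable element and attribute order),
#' and `parse_project(write_project(p))` is structurally identical to `p`.
#' Unknown attributes and elements carried in `extensions` slots are
#' re-emitted verbatim. The dialect is described by the machine-readable
#' schema shipped in `inst/extdata/project-dialect-schema.json`.
#'
#' @param project A valid project; invalid projects are refused with the
#'   validation report attached to the error condition.
#' @param path Optional file to write to.
#' @return The document as a single character string (invisibly when `path`
#'   is given).
#' @export
write_project <- function(project, path = NULL) {
  stop_if_invalid(project)
  doc <- xml2::xml_new_root("project")
  xml2::xml_set_attrs(doc, c(
    dialect = DIALECT_VERSION, name = project$name, title = project$title,
    version = project$version, visibility = project$visibility
  ))
  for (i in seq_along(project$forms)) {
    form_to_xml(doc, project$forms[[i]], c(level = as.character(i)))
  }
  for (b in project$branches) {
    host <- branch_host(project, b$form_id)
    form_to_xml(doc, b, c(`branch-of` = host$host_form,
                          `branch-at` = host$host_field))
  }
  add_extensions(doc, project$extensions)
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

schema_error <- function(path, message) {
  stop("schema error at ", path, ": ", message, call. = FALSE)
}

req_attr <- function(node, name, path) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) schema_error(path, paste0("missing mandatory attribute '", name, "'"))
  v
}

opt_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

field_from_xml <- function(node, path) {
  id <- req_attr(node, "id", path)
  path <- paste0(path, "/field[", id, "]")
  kind <- req_attr(node, "type", path)
  label <- req_attr(node, "label", path)
  if (!kind %in% FIELD_KINDS) schema_error(path, paste0("unknown field type '", kind, "'"))

  num <- opt_attr(node, "numeric")
  validation <- new_validation(
    required = identical(opt_attr(node, "required"), "true"),
    numeric = if (is.null(num)) "none" else num,
    min = opt_attr(node, "min"), max = opt_attr(node, "max"),
    datetime_format = opt_attr(node, "date"),
    regex = opt_attr(node, "regex")
  )
  choices <- lapply(xml2::xml_find_all(node, "./choice"), function(c) {
    new_choice(req_attr(c, "name", path), req_attr(c, "value", path))
  })
  jumps <- lapply(xml2::xml_find_all(node, "./jump"), function(j) {
    new_jump(strsplit(req_attr(j, "when", path), ",", fixed = TRUE)[[1]],
             req_attr(j, "to", path))
  })
  new_field(
    field_id = id, label = label, kind = kind, choices = choices,
    validation = validation, jumps = jumps,
    chartable = identical(opt_attr(node, "chartable"), "true"),
    double_entry = identical(opt_attr(node, "double-entry"), "true"),
    extensions = make_ext(extension_attrs(node, "field"),
                          extension_children(node, c("choice", "jump")))
  )
}

form_from_xml <- function(node, path) {
  id <- req_attr(node, "id", path)
  path <- paste0(path, "/form[", id, "]")
  fields <- lapply(xml2::xml_find_all(node, "./field"), field_from_xml, path = path)
  key <- opt_attr(node, "key")
  new_form(
    form_id = id, fields = fields,
    title = req_attr(node, "title", path),
    key_field = if (is.null(key)) "AUTO" else key,
    extensions = make_ext(extension_attrs(node, "form"),
                          extension_children(node, "field"))
  )
}

#' Parse a project-definition document
#'
#' Accepts a file path, a document string, or an `xml_document`. Documents
#' must be UTF-8. Unknown elements and attributes are preserved as opaque
#' extensions and re-emitted by [write_project()]. Pattern strings (regexes)
#' are never executed at parse time; compilation is deferred to answer
#' validation.
#'
#' @param x Path, XML string, or `xml_document`.
#' @return A `collect_project`.
#' @export
parse_project <- function(x) {
  if (inherits(x, "xml_document")) {
    doc <- x
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    raw_txt <- if (file.exists(x) && !grepl("<", x, fixed = TRUE)) {
      readChar(x, file.info(x)$size, useBytes = TRUE)
    } else {
      x
    }
    enc <- regmatches(raw_txt, regexpr('encoding="[^"]+"', raw_txt))
    if (length(enc) && !grepl('"(utf-8|UTF-8)"', enc)) {
      stop("project documents must be UTF-8 encoded (found ", enc, ")")
    }
    doc <- xml2::read_xml(raw_txt)
  }

  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "project") {
    schema_error("/", "root element must be <project>")
  }
  name <- req_attr(root, "name", "project")
  form_nodes <- xml2::xml_find_all(root, "./form")
  if (length(form_nodes) == 0L) schema_error("project", "forms empty")

  hier <- list(); branches <- list(); branch_info <- list()
  for (node in form_nodes) {
    f <- form_from_xml(node, "project")
    bof <- opt_attr(node, "branch-of")
    if (is.null(bof)) {
      hier[[length(hier) + 1L]] <- list(form = f,
                                        level = as.integer(req_attr(node, "level", "project")))
    } else {
      branches[[length(branches) + 1L]] <- f
      branch_info[[f$form_id]] <- list(host_form = bof,
                                       host_field = req_attr(node, "branch-at", "project"))
    }
  }
  hier <- hier[order(vapply(hier, `[[`, integer(1), "level"))]
  forms <- lapply(hier, `[[`, "form")

  # Bind each branch form to its host branch_trigger field.
  for (bid in names(branch_info)) {
    info <- branch_info[[bid]]
    hi <- match(info$host_form, form_ids(forms))
    if (is.na(hi)) schema_error(paste0("project/form[", bid, "]"),
                                paste0("branch-of names unknown form '", info$host_form, "'"))
    f <- forms[[hi]]
    fi <- match(info$host_field, field_ids(f))
    if (is.na(fi)) schema_error(paste0("project/form[", bid, "]"),
                                paste0("branch-at names unknown field '", info$host_field, "'"))
    forms[[hi]]$fields[[fi]]$branch <- bid
  }

  vis <- opt_attr(root, "visibility")
  title <- opt_attr(root, "title")
  version <- opt_attr(root, "version")
  new_project(
    name = name, forms = forms, branches = branches,
    title = if (is.null(title)) name else title,
    version = if (is.null(version)) "1" else version,
    visibility = if (is.null(vis)) "public" else vis,
    extensions = make_ext(extension_attrs(root, "project"),
                          extension_children(root, "form"))
  )
}

# ---- JSON mirror -----------------------------------------------------------

field_to_list <- function(field) {
  v <- field$validation
  out <- list(id = field$field_id, type = field$kind, label = field$label)
  if (v$required) out$required <- TRUE
  if (v$numeric != "none") out$numeric <- v$numeric
  if (!is.null(v$min)) out$min <- v$min
  if (!is.null(v$max)) out$max <- v$max
  if (!is.null(v$datetime_format)) out$date <- v$datetime_format
  if (!is.null(v$regex)) out$regex <- v$regex
  if (field$double_entry) out$double_entry <- TRUE
  if (field$chartable) out$chartable <- TRUE
  if (length(field$choices)) {
    out$choices <- lapply(field$choices, function(c) list(name = c$name, value = c$value))
  }
  if (length(field$jumps)) {
    out$jumps <- lapply(field$jumps, function(j) {
      list(when = as.list(j$trigger_values), to = j$destination)
    })
  }
  out
}

form_to_list <- function(form, role) {
  c(list(id = form$form_id, title = form$title, key = form$key_field), role,
    list(fields = lapply(form$fields, field_to_list)))
}

#' Serialise a project to the JSON mirror of the XML dialect
#'
#' @param project A valid project.
#' @return A JSON string (field-for-field equivalent of [write_project()]
#'   minus opaque XML extensions, which have no JSON rendering).
#' @export
project_to_json <- function(project) {
  stop_if_invalid(project)
  forms <- lapply(seq_along(project$forms), function(i) {
    form_to_list(project$forms[[i]], list(level = i))
  })
  branches <- lapply(project$branches, function(b) {
    host <- branch_host(project, b$form_id)
    form_to_list(b, list(branch_of = host$host_form, branch_at = host$host_field))
  })
  obj <- list(dialect = DIALECT_VERSION, name = project$name,
              title = project$title, version = project$version,
              visibility = project$visibility, forms = c(forms, branches))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

field_from_list <- function(x) {
  new_field(
    field_id = x$id, label = x$label, kind = x$type,
    choices = lapply(x$choices, function(c) new_choice(c$name, c$value)),
    validation = new_validation(
      required = isTRUE(x$required),
      numeric = if (is.null(x$numeric)) "none" else x$numeric,
      min = x$min, max = x$max, datetime_format = x$date, regex = x$regex
    ),
    jumps = lapply(x$jumps, function(j) new_jump(unlist(j$when), j$to)),
    chartable = isTRUE(x$chartable), double_entry = isTRUE(x$double_entry)
  )
}

#' Parse the JSON mirror of a project definition
#'
#' @param txt JSON string or path to a `.json` file.
#' @return A `collect_project`.
#' @export
project_from_json <- function(txt) {
  if (length(txt) == 1L && !grepl("{", txt, fixed = TRUE) && file.exists(txt)) {
    txt <- readChar(txt, file.info(txt)$size, useBytes = TRUE)
  }
  x <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  hier <- Filter(function(f) !is.null(f$level), x$forms)
  hier <- hier[order(vapply(hier, `[[`, integer(1), "level"))]
  branches <- Filter(function(f) is.null(f$level), x$forms)

  forms <- lapply(hier, function(f) {
    new_form(form_id = f$id, title = f$title, key_field = f$key,
             fields = lapply(f$fields, field_from_list))
  })
  branch_forms <- list()
  for (b in branches) {
    branch_forms[[length(branch_forms) + 1L]] <-
      new_form(form_id = b$id, title = b$title, key_field = b$key,
               fields = lapply(b$fields, field_from_list))
    hi <- match(b$branch_of, form_ids(forms))
    fi <- match(b$branch_at, field_ids(forms[[hi]]))
    forms[[hi]]$fields[[fi]]$branch <- b$id
  }
  new_project(name = x$name, forms = forms, branches = branch_forms,
              title = x$title, version = x$version, visibility = x$visibility)
}
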