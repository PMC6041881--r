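# Catalogue: the metadata inventory that drives loading, quality profiling,
# cohort building and extraction. Persisted as a single JSON document with a
# schema-version field so exported copies are diff-able and merge-friendly.

CATALOGUE_SCHEMA_VERSION <- 1L

SEMANTIC_TYPES <- c("text", "integer", "decimal", "date", "code")
EXTRACTION_CATEGORIES <- c("Core", "Supplemental", "SpecialApprovalRequired", "Internal")
RULE_KINDS <- c("not_null", "regex", "bounds", "lookup_membership", "date_range")
RULE_SEVERITIES <- c("missing", "wrong", "invalidates_row")

catalogue_path <- function(store) file.path(store$path, "catalogue.json")

# Parsed-catalogue cache keyed by path; invalidated on file mtime/size change.
# Safe under the store's documented single-writer contract.
.catalogue_cache <- new.env(parent = emptyenv())

read_catalogue <- function(store) {
  p <- catalogue_path(store)
  if (!file.exists(p)) {
    return(list(schema_version = CATALOGUE_SCHEMA_VERSION,
                entries = list(), lookups = list()))
  }
  info <- file.info(p)
  hit <- .catalogue_cache[[p]]
  if (!is.null(hit) && identical(hit$mtime, info$mtime) &&
      identical(hit$size, info$size)) {
    return(hit$doc)
  }
  doc <- read_json_file(p)
  doc$lookups <- doc$lookups %||% list()
  .catalogue_cache[[p]] <- list(doc = doc, mtime = info$mtime, size = info$size)
  doc
}

write_catalogue <- function(store, cat) {
  p <- catalogue_path(store)
  write_json_file(cat, p)
  info <- file.info(p)
  .catalogue_cache[[p]] <- list(doc = cat, mtime = info$mtime, size = info$size)
  invisible(cat)
}

# Resolve a dataset by id or (unique) name; error when unknown.
find_entry_index <- function(cat, dataset) {
  ids <- vapply(cat$entries, function(e) e$dataset_id, character(1))
  nms <- vapply(cat$entries, function(e) e$name, character(1))
  i <- match(dataset, ids)
  if (is.na(i)) i <- match(dataset, nms)
  if (is.na(i)) abort(sprintf("unknown dataset: %s", dataset))
  i
}

get_entry <- function(store, dataset) {
  cat <- read_catalogue(store)
  cat$entries[[find_entry_index(cat, dataset)]]
}

entry_columns <- function(entry) {
  vapply(entry$items, function(it) it$column_name, character(1))
}

entry_item <- function(entry, column) {
  cols <- entry_columns(entry)
  i <- match(column, cols)
  if (is.na(i)) abort(sprintf("dataset '%s' has no column '%s'", entry$name, column))
  entry$items[[i]]
}

# The single Internal item with role "identifier"; required for any dataset
# that participates in cohort evaluation or extraction.
entry_identifier_column <- function(entry) {
  idc <- purrr::keep(entry$items, function(it) {
    identical(it$extraction_category, "Internal") &&
      identical(it$role %||% "", "identifier")
  })
  if (length(idc) == 0) {
    abort(sprintf("dataset '%s' has no Internal item with role 'identifier'", entry$name))
  }
  if (length(idc) > 1) {
    abort(sprintf("dataset '%s' has more than one identifier item", entry$name))
  }
  idc[[1]]$column_name
}

# ---- registration and metadata --------------------------------------------

#' Register a dataset in the catalogue
#'
#' Creates a catalogue entry with one item per column. All items default to
#' extraction category `"Core"` with no validation rules; governance tiers and
#' rules are configured afterwards with [set_column_metadata()] and
#' [attach_validation_rule()].
#'
#' @param store A `dm_store`.
#' @param name Unique dataset name.
#' @param columns Named character vector `c(column = semantic_type)`, or a
#'   two-column data frame with `name` and `semantic_type`. Semantic types:
#'   `text`, `integer`, `decimal`, `date`, `code`.
#' @param primary_key Character vector of column names forming the primary key.
#' @param event_date_column Optional date column used for monthly bucketing in
#'   quality reports and summary aggregates.
#' @param description Free-text dataset description.
#' @return The new catalogue entry (invisibly), a named list.
#' @export
register_dataset <- function(store, name, columns, primary_key,
                             event_date_column = NULL, description = "") {
  stopifnot(is.character(name), nzchar(name))
  if (is.data.frame(columns)) {
    columns <- stats::setNames(columns$semantic_type, columns$name)
  }
  if (length(columns) == 0) abort("columns must be non-empty")
  bad_type <- setdiff(unique(unname(columns)), SEMANTIC_TYPES)
  if (length(bad_type)) abort(sprintf("unknown semantic type(s): %s",
                                      paste(bad_type, collapse = ", ")))
  if (anyDuplicated(names(columns))) abort("duplicate column names")
  unknown_pk <- setdiff(primary_key, names(columns))
  if (length(unknown_pk)) {
    abort(sprintf("primary_key references unknown column(s): %s",
                  paste(unknown_pk, collapse = ", ")))
  }
  if (length(primary_key) == 0) abort("primary_key must be non-empty")
  if (!is.null(event_date_column) && !event_date_column %in% names(columns)) {
    abort(sprintf("event_date_column '%s' is not among the columns", event_date_column))
  }
  cat <- read_catalogue(store)
  nms <- vapply(cat$entries, function(e) e$name, character(1))
  if (name %in% nms) abort(sprintf("dataset name already registered: %s", name))
  ids <- vapply(cat$entries, function(e) e$dataset_id, character(1))
  entry <- list(
    dataset_id = fresh_id("D", ids),
    name = name,
    description = description,
    primary_key = as.list(primary_key),
    event_date_column = event_date_column,
    items = purrr::imap(as.list(columns), function(type, col) {
      list(column_name = col, description = "", semantic_type = type,
           extraction_category = "Core", role = "",
           validation_rules = list(), lookup_id = NULL)
    }),
    load_logic = list(header_mapping = list(), headerless_column_order = NULL,
                      cleaning_steps = list("trim", "null_token_set")),
    issues = list(),
    documents = list()
  )
  names(entry$items) <- NULL
  cat$entries <- c(cat$entries, list(entry))
  write_catalogue(store, cat)
  invisible(entry)
}

#' List catalogue entries
#'
#' @param store A `dm_store`.
#' @return Tibble with one row per registered dataset.
#' @export
list_datasets <- function(store) {
  cat <- read_catalogue(store)
  if (length(cat$entries) == 0) {
    return(tibble(dataset_id = character(), name = character(),
                  n_columns = integer(), primary_key = character(),
                  event_date_column = character()))
  }
  purrr::map_dfr(cat$entries, function(e) {
    tibble(dataset_id = e$dataset_id, name = e$name,
           n_columns = length(e$items),
           primary_key = paste(unlist(e$primary_key), collapse = "+"),
           event_date_column = e$event_date_column %||% NA_character_)
  })
}

modify_entry <- function(store, dataset, fn) {
  cat <- read_catalogue(store)
  i <- find_entry_index(cat, dataset)
  cat$entries[[i]] <- fn(cat$entries[[i]])
  write_catalogue(store, cat)
  invisible(cat$entries[[i]])
}

modify_item <- function(store, dataset, column, fn) {
  out <- NULL
  modify_entry(store, dataset, function(entry) {
    cols <- entry_columns(entry)
    j <- match(column, cols)
    if (is.na(j)) abort(sprintf("dataset '%s' has no column '%s'", entry$name, column))
    entry$items[[j]] <- fn(entry$items[[j]])
    out <<- entry$items[[j]]
    entry
  })
  invisible(out)
}

#' Set column-level metadata
#'
#' Updates an item's description, extraction-governance category and role.
#' `Internal` items are never extractable; `SpecialApprovalRequired` items are
#' extracted only when an extraction configuration carries an approval for
#' them. The item with role `"identifier"` (necessarily `Internal`) is the
#' private patient identifier used for cohort linkage.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name.
#' @param column Column name.
#' @param description Optional new description.
#' @param category Optional extraction category: one of `"Core"`,
#'   `"Supplemental"`, `"SpecialApprovalRequired"`, `"Internal"`.
#' @param role Optional role; `"identifier"` marks the linkage identifier.
#' @return The updated item (invisibly).
#' @export
set_column_metadata <- function(store, dataset, column, description = NULL,
                                category = NULL, role = NULL) {
  if (!is.null(category)) category <- match.arg(category, EXTRACTION_CATEGORIES)
  if (identical(role, "identifier") && !identical(category, "Internal")) {
    abort("the identifier column must have extraction_category 'Internal'")
  }
  modify_item(store, dataset, column, function(it) {
    if (!is.null(description)) it$description <- description
    if (!is.null(category)) it$extraction_category <- category
    if (!is.null(role)) it$role <- role
    it$updated_at <- ts_now()
    it
  })
}

#' Declare the private identifier column of a dataset
#'
#' Convenience wrapper: marks the column `Internal` with role `"identifier"`.
#'
#' @inheritParams set_column_metadata
#' @export
set_identifier_column <- function(store, dataset, column) {
  set_column_metadata(store, dataset, column,
                      description = "private patient identifier",
                      category = "Internal", role = "identifier")
}

# ---- validation rules ------------------------------------------------------

#' Build a validation rule specification
#'
#' @param rule_kind One of `not_null`, `regex`, `bounds`, `lookup_membership`,
#'   `date_range`.
#' @param severity How a violation is classified: `missing` or `wrong` (counted
#'   in quality reports) or `invalidates_row` (the row is rejected at staging).
#' @param ... Rule parameters: `pattern` for `regex`; `lower`/`upper` for
#'   `bounds` and `date_range`; `lookup_id` for `lookup_membership`.
#' @return A `validation_rule` list.
#' @export
validation_rule <- function(rule_kind, severity = "wrong", ...) {
  rule_kind <- match.arg(rule_kind, RULE_KINDS)
  severity <- match.arg(severity, RULE_SEVERITIES)
  params <- list(...)
  if (rule_kind == "regex") {
    if (is.null(params$pattern)) abort("regex rule needs a 'pattern' parameter")
    ok <- tryCatch({ grepl(params$pattern, ""); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("regex does not compile: %s", params$pattern))
  }
  if (rule_kind == "bounds") {
    if (is.null(params$lower) || is.null(params$upper)) {
      abort("bounds rule needs 'lower' and 'upper'")
    }
    if (as.numeric(params$lower) > as.numeric(params$upper)) {
      abort("bounds rule has lower > upper")
    }
  }
  if (rule_kind == "date_range") {
    if (is.null(params$lower) || is.null(params$upper)) {
      abort("date_range rule needs 'lower' and 'upper'")
    }
    if (as.Date(params$lower) > as.Date(params$upper)) {
      abort("date_range rule has lower > upper")
    }
  }
  if (rule_kind == "lookup_membership" && is.null(params$lookup_id)) {
    abort("lookup_membership rule needs a 'lookup_id'")
  }
  structure(list(rule_kind = rule_kind, params = params, severity = severity),
            class = "validation_rule")
}

#' Attach a validation rule to a column
#'
#' Rules are appended in order; staging and quality evaluation apply them in
#' attachment order.
#'
#' @inheritParams set_column_metadata
#' @param rule A [validation_rule()].
#' @return The updated item (invisibly).
#' @export
attach_validation_rule <- function(store, dataset, column, rule) {
  if (!inherits(rule, "validation_rule")) {
    rule <- do.call(validation_rule, rule)   # re-validate plain lists
  }
  if (rule$rule_kind == "lookup_membership") {
    cat <- read_catalogue(store)
    if (is.null(cat$lookups[[rule$params$lookup_id]])) {
      abort(sprintf("unknown lookup: %s", rule$params$lookup_id))
    }
  }
  modify_item(store, dataset, column, function(it) {
    it$validation_rules <- c(it$validation_rules, list(unclass(rule)))
    it
  })
}

# ---- lookups, issues, documents, load logic --------------------------------

#' Register a code/description lookup table
#'
#' @param store A `dm_store`.
#' @param lookup_id Unique lookup identifier.
#' @param rows Data frame with columns `code` and `description` (codes unique),
#'   or a path to a CSV file with header `code,description`.
#' @return The lookup (invisibly).
#' @export
add_lookup <- function(store, lookup_id, rows) {
  if (is.character(rows) && length(rows) == 1) rows <- read_tbl(rows)
  rows <- as_tibble(rows)
  if (!all(c("code", "description") %in% names(rows))) {
    abort("lookup rows need 'code' and 'description' columns")
  }
  if (anyDuplicated(rows$code)) abort("lookup codes must be unique")
  cat <- read_catalogue(store)
  lk <- list(lookup_id = lookup_id, code_column = "code",
             description_column = "description",
             rows = as.list(stats::setNames(rows$description, rows$code)))
  cat$lookups[[lookup_id]] <- lk
  write_catalogue(store, cat)
  invisible(lk)
}

#' Bind a lookup to a coded column
#'
#' @inheritParams set_column_metadata
#' @param lookup_id A lookup registered with [add_lookup()].
#' @export
set_item_lookup <- function(store, dataset, column, lookup_id) {
  cat <- read_catalogue(store)
  if (is.null(cat$lookups[[lookup_id]])) abort(sprintf("unknown lookup: %s", lookup_id))
  modify_item(store, dataset, column, function(it) { it$lookup_id <- lookup_id; it })
}

lookup_codes <- function(store, lookup_id) {
  cat <- read_catalogue(store)
  lk <- cat$lookups[[lookup_id]]
  if (is.null(lk)) abort(sprintf("unknown lookup: %s", lookup_id))
  names(lk$rows)
}

#' Record or resolve a dataset issue
#'
#' Resolved issues retain their text immutably; resolution only flips status.
#'
#' @inheritParams set_column_metadata
#' @param text Issue description.
#' @return The issue (invisibly).
#' @export
add_dataset_issue <- function(store, dataset, text) {
  out <- NULL
  modify_entry(store, dataset, function(entry) {
    ids <- vapply(entry$issues, function(i) i$issue_id, character(1))
    issue <- list(issue_id = fresh_id("I", ids), text = text,
                  status = "open", created_at = ts_now())
    entry$issues <- c(entry$issues, list(issue))
    out <<- issue
    entry
  })
  invisible(out)
}

#' @rdname add_dataset_issue
#' @param issue_id Issue to mark resolved.
#' @export
resolve_dataset_issue <- function(store, dataset, issue_id) {
  modify_entry(store, dataset, function(entry) {
    ids <- vapply(entry$issues, function(i) i$issue_id, character(1))
    j <- match(issue_id, ids)
    if (is.na(j)) abort(sprintf("unknown issue: %s", issue_id))
    entry$issues[[j]]$status <- "resolved"
    entry
  })
}

#' Attach a supporting document to a dataset
#'
#' Documents with `global_flag = TRUE` are copied verbatim into every release
#' bundle that includes the dataset.
#'
#' @inheritParams set_column_metadata
#' @param title,body Document title and text body.
#' @param global_flag Extract with every release when `TRUE`.
#' @export
add_supporting_document <- function(store, dataset, title, body, global_flag = FALSE) {
  out <- NULL
  modify_entry(store, dataset, function(entry) {
    ids <- vapply(entry$documents, function(d) d$doc_id, character(1))
    doc <- list(doc_id = fresh_id("DOC", ids), title = title, body = body,
                global_flag = isTRUE(global_flag))
    entry$documents <- c(entry$documents, list(doc))
    out <<- doc
    entry
  })
  invisible(out)
}

#' Configure a dataset's load logic
#'
#' The load logic translates catalogue metadata into cleaning actions at load
#' time: header aliases are renamed to canonical columns, a headerless column
#' order supports feeds that drop their header row, and cleaning steps run in
#' the given order during staging.
#'
#' @inheritParams set_column_metadata
#' @param header_mapping Named character vector `c(alias = canonical)`.
#' @param headerless_column_order Column order assumed when a feed has no
#'   recognisable header row, or `NULL`.
#' @param cleaning_steps Ordered subset of `"trim"`, `"null_token_set"`,
#'   `"date_parse_formats"`, `"uppercase_codes"`.
#' @param date_formats Formats tried in order by the `date_parse_formats` step,
#'   written with `DD`, `MM`, `YYYY` tokens (e.g. `"DD/MM/YYYY"`).
#' @export
set_load_logic <- function(store, dataset, header_mapping = NULL,
                           headerless_column_order = NULL,
                           cleaning_steps = c("trim", "null_token_set"),
                           date_formats = character()) {
  steps <- match.arg(cleaning_steps,
                     c("trim", "null_token_set", "date_parse_formats", "uppercase_codes"),
                     several.ok = TRUE)
  modify_entry(store, dataset, function(entry) {
    cols <- entry_columns(entry)
    if (!is.null(header_mapping)) {
      bad <- setdiff(unname(header_mapping), cols)
      if (length(bad)) abort(sprintf("header_mapping targets unknown column(s): %s",
                                     paste(bad, collapse = ", ")))
    }
    if (!is.null(headerless_column_order)) {
      bad <- setdiff(headerless_column_order, cols)
      if (length(bad)) abort(sprintf("headerless order names unknown column(s): %s",
                                     paste(bad, collapse = ", ")))
    }
    entry$load_logic <- list(
      header_mapping = as.list(header_mapping %||% stats::setNames(list(), character())),
      headerless_column_order = if (is.null(headerless_column_order)) NULL
                                else as.list(headerless_column_order),
      cleaning_steps = as.list(steps),
      date_formats = as.list(date_formats)
    )
    entry
  })
}

# ---- export / import / merge ----------------------------------------------

#' Export a portable catalogue document
#'
#' The exported document is self-contained (entries, items, rules, lookups,
#' documents, issues — no row-level data) and re-imports losslessly, including
#' governance categories.
#'
#' @param store A `dm_store`.
#' @param datasets Dataset ids or names to export, or `NULL` for all.
#' @param path Optional file path; when given the JSON document is written there.
#' @return The portable catalogue document as a named list (invisibly when
#'   `path` is given).
#' @export
export_catalogue <- function(store, datasets = NULL, path = NULL) {
  cat <- read_catalogue(store)
  if (!is.null(datasets)) {
    idx <- vapply(datasets, function(d) find_entry_index(cat, d), integer(1))
    cat$entries <- cat$entries[idx]
  }
  used_lookups <- unique(unlist(purrr::map(cat$entries, function(e) {
    c(purrr::compact(purrr::map(e$items, "lookup_id")),
      purrr::compact(purrr::map(e$items, function(it) {
        purrr::compact(purrr::map(it$validation_rules, function(r) r$params$lookup_id))
      })))
  })))
  cat$lookups <- cat$lookups[intersect(names(cat$lookups), used_lookups %||% character())]
  doc <- list(schema_version = CATALOGUE_SCHEMA_VERSION,
              entries = cat$entries, lookups = cat$lookups)
  if (!is.null(path)) {
    write_json_file(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import a portable catalogue document into a store
#'
#' Intended for bootstrapping branch (project) nodes. Fails when any imported
#' dataset name already exists in the target store.
#'
#' @param store A `dm_store`.
#' @param doc A portable catalogue document (list) or path to its JSON file.
#' @return Invisibly, the imported entry names.
#' @export
import_catalogue <- function(store, doc) {
  doc <- as_catalogue_doc(doc)
  cat <- read_catalogue(store)
  have <- vapply(cat$entries, function(e) e$name, character(1))
  incoming <- vapply(doc$entries, function(e) e$name, character(1))
  clash <- intersect(have, incoming)
  if (length(clash)) abort(sprintf("dataset name(s) already present: %s",
                                   paste(clash, collapse = ", ")))
  cat$entries <- c(cat$entries, doc$entries)
  for (nm in names(doc$lookups)) cat$lookups[[nm]] <- doc$lookups[[nm]]
  write_catalogue(store, cat)
  invisible(incoming)
}

as_catalogue_doc <- function(doc) {
  if (is.character(doc) && length(doc) == 1) doc <- read_json_file(doc)
  if (!is.list(doc) || is.null(doc$schema_version) || is.null(doc$entries)) {
    abort("not a portable catalogue document (missing schema_version/entries)")
  }
  doc$lookups <- doc$lookups %||% list()
  doc
}

#' Merge researcher contributions from a branch catalogue into the root
#'
#' Additive with conflict report, root wins: new validation rules, issue texts
#' and descriptions (where the root's is empty) are merged; a description that
#' differs between root and branch is flagged as a conflict and the root value
#' retained. Datasets unknown to the root are reported, not merged.
#'
#' @param store The root `dm_store`.
#' @param branch_doc A portable catalogue document (list or JSON path).
#' @return Tibble merge report with columns `dataset`, `column`, `kind`,
#'   `action` (`added` / `conflict_root_kept` / `unknown_dataset`), `detail`.
#' @export
merge_catalogue_contributions <- function(store, branch_doc) {
  branch <- as_catalogue_doc(branch_doc)
  cat <- read_catalogue(store)
  root_names <- vapply(cat$entries, function(e) e$name, character(1))
  report <- list()
  note <- function(dataset, column, kind, action, detail) {
    report[[length(report) + 1L]] <<- tibble(
      dataset = dataset, column = column %||% NA_character_,
      kind = kind, action = action, detail = detail)
  }
  for (be in branch$entries) {
    i <- match(be$name, root_names)
    if (is.na(i)) {
      note(be$name, NULL, "dataset", "unknown_dataset", "not present in root; skipped")
      next
    }
    re <- cat$entries[[i]]
    # dataset description
    bd <- be$description %||% ""
    rd <- re$description %||% ""
    if (nzchar(bd) && !identical(bd, rd)) {
      if (!nzchar(rd)) {
        re$description <- bd
        note(be$name, NULL, "description", "added", bd)
      } else {
        note(be$name, NULL, "description", "conflict_root_kept", bd)
      }
    }
    # items: descriptions + rules
    rcols <- entry_columns(re)
    for (bit in be$items) {
      j <- match(bit$column_name, rcols)
      if (is.na(j)) next  # structural additions of columns are out of merge scope
      rit <- re$items[[j]]
      bdesc <- bit$description %||% ""
      rdesc <- rit$description %||% ""
      if (nzchar(bdesc) && !identical(bdesc, rdesc)) {
        if (!nzchar(rdesc)) {
          rit$description <- bdesc
          note(be$name, bit$column_name, "item_description", "added", bdesc)
        } else {
          note(be$name, bit$column_name, "item_description", "conflict_root_kept", bdesc)
        }
      }
      have_rules <- vapply(rit$validation_rules, rule_signature, character(1))
      for (br in bit$validation_rules) {
        sig <- rule_signature(br)
        if (!sig %in% have_rules) {
          rit$validation_rules <- c(rit$validation_rules, list(br))
          have_rules <- c(have_rules, sig)
          note(be$name, bit$column_name, "validation_rule", "added", sig)
        }
      }
      re$items[[j]] <- rit
    }
    # issues: new texts appended as open issues
    have_issues <- vapply(re$issues, function(x) x$text, character(1))
    for (bi in be$issues %||% list()) {
      if (!bi$text %in% have_issues) {
        ids <- vapply(re$issues, function(x) x$issue_id, character(1))
        re$issues <- c(re$issues, list(list(issue_id = fresh_id("I", ids),
                                            text = bi$text, status = "open",
                                            created_at = ts_now())))
        have_issues <- c(have_issues, bi$text)
        note(be$name, NULL, "issue", "added", bi$text)
      }
    }
    cat$entries[[i]] <- re
  }
  write_catalogue(store, cat)
  if (length(report) == 0) {
    return(tibble(dataset = character(), column = character(), kind = character(),
                  action = character(), detail = character()))
  }
  bind_rows(report)
}

rule_signature <- function(rule) {
  paste(rule$rule_kind, rule$severity,
        jsonlite::toJSON(rule$params[order(names(rule$params))], auto_unbox = TRUE),
        sep = "|")
}

#' Check catalogue referential integrity
#'
#' Verifies that every column referenced by a primary key, event-date setting,
#' load logic or lookup binding resolves to an existing item, and that every
#' `lookup_membership` rule references a registered lookup.
#'
#' @param store A `dm_store`.
#' @return Tibble of violations (zero rows when the catalogue is consistent).
#' @export
check_catalogue_integrity <- function(store) {
  cat <- read_catalogue(store)
  probs <- list()
  bad <- function(dataset, what) {
    probs[[length(probs) + 1L]] <<- tibble(dataset = dataset, problem = what)
  }
  for (e in cat$entries) {
    cols <- entry_columns(e)
    for (pk in unlist(e$primary_key)) {
      if (!pk %in% cols) bad(e$name, sprintf("primary key column '%s' missing", pk))
    }
    edc <- e$event_date_column
    if (!is.null(edc) && !edc %in% cols) {
      bad(e$name, sprintf("event_date_column '%s' missing", edc))
    }
    for (tgt in unlist(e$load_logic$header_mapping)) {
      if (!tgt %in% cols) bad(e$name, sprintf("header_mapping target '%s' missing", tgt))
    }
    for (hc in unlist(e$load_logic$headerless_column_order)) {
      if (!hc %in% cols) bad(e$name, sprintf("headerless column '%s' missing", hc))
    }
    for (it in e$items) {
      if (!is.null(it$lookup_id) && is.null(cat$lookups[[it$lookup_id]])) {
        bad(e$name, sprintf("column '%s' references unknown lookup '%s'",
                            it$column_name, it$lookup_id))
      }
      for (r in it$validation_rules) {
        if (r$rule_kind == "lookup_membership" &&
            is.null(cat$lookups[[r$params$lookup_id]])) {
          bad(e$name, sprintf("rule on '%s' references unknown lookup '%s'",
                              it$column_name, r$params$lookup_id))
        }
      }
    }
  }
  if (length(probs) == 0) return(tibble(dataset = character(), problem = character()))
  bind_rows(probs)
}
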