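# Extraction & disclosure control: join datasets to a committed cohort,
# substitute release identifiers, enforce column governance, run the
# blacklister and CHI scanner, and emit an audited release bundle (data,
# lookups, documents, extract-time quality report, branch catalogue,
# manifest). The scanner and blacklister veto the release (fail closed); an
# optional redact mode masks scanner matches instead but is never the default.

#' Validate a CHI-style modulus-11 check digit
#'
#' The Community Health Index number is a 10-digit identifier whose final
#' digit is a checksum of the first nine under weights 10, 9, ..., 2:
#' `check = 11 - (sum mod 11)`, with 11 mapping to 0 and a remainder yielding
#' check 10 meaning no valid check digit exists (always invalid).
#'
#' @param digits Character vector; each element exactly 10 decimal digits.
#' @return Logical vector: `TRUE` where the 10th digit equals the checksum.
#' @export
#' @examples
#' chi_checksum_valid(c("0000000000", "0000000019", "0000000011"))
chi_checksum_valid <- function(digits) {
  if (length(digits) == 0) return(logical(0))
  if (any(is.na(digits)) || any(!grepl("^[0-9]{10}$", digits))) {
    abort("chi_checksum_valid expects 10-character decimal digit strings")
  }
  mat <- matrix(as.integer(unlist(strsplit(digits, ""))), ncol = 10, byrow = TRUE)
  weights <- 10:2
  sums <- as.vector(mat[, 1:9, drop = FALSE] %*% weights)
  check <- 11L - (sums %% 11L)
  check[check == 11L] <- 0L
  check != 10L & mat[, 10] == check
}

#' Compute the CHI check digit for a 9-digit stem
#'
#' Returns `NA` where the modulus-11 remainder admits no valid check digit.
#'
#' @param stem9 Character vector of 9-digit strings.
#' @return Integer vector of check digits (0-9) or `NA`.
#' @export
chi_check_digit <- function(stem9) {
  if (any(!grepl("^[0-9]{9}$", stem9))) abort("stems must be 9 decimal digits")
  mat <- matrix(as.integer(unlist(strsplit(stem9, ""))), ncol = 9, byrow = TRUE)
  sums <- as.vector(mat %*% (10:2))
  check <- 11L - (sums %% 11L)
  check[check == 11L] <- 0L
  check[check == 10L] <- NA_integer_
  check
}

#' Scan a table for checksum-valid 10-digit identifier sequences
#'
#' Every maximal digit run of length >= 10 in any cell is scanned with a
#' sliding 10-digit window; windows passing [chi_checksum_valid()] are
#' reported. Catches patient identifiers leaking through free-text or
#' unexpected fields. In strict mode a finding additionally requires the first
#' six digits to parse as a DDMMYY date.
#'
#' @param table A data frame of text-renderable cells.
#' @param dataset Optional dataset label carried into the findings.
#' @param strict Require a plausible DDMMYY date prefix (default `FALSE`).
#' @return Tibble of findings: `dataset`, `column`, `row`, `match`.
#' @export
scan_for_chi <- function(table, dataset = NA_character_, strict = FALSE) {
  findings <- list()
  for (col in names(table)) {
    v <- as.character(table[[col]])
    has_run <- which(!is.na(v) & grepl("[0-9]{10}", v))
    for (i in has_run) {
      runs <- regmatches(v[i], gregexpr("[0-9]{10,}", v[i]))[[1]]
      for (run in runs) {
        for (s in seq_len(nchar(run) - 9L)) {
          win <- substr(run, s, s + 9L)
          if (!chi_checksum_valid(win)) next
          if (strict && !chi_date_prefix_ok(win)) next
          findings[[length(findings) + 1L]] <-
            tibble(dataset = dataset, column = col, row = i, match = win)
        }
      }
    }
  }
  if (length(findings) == 0) {
    return(tibble(dataset = character(), column = character(),
                  row = integer(), match = character()))
  }
  bind_rows(findings)
}

chi_date_prefix_ok <- function(win) {
  !is.na(as.Date(substr(win, 1, 6), format = "%d%m%y"))
}

#' Column blacklister
#'
#' Blocks an extraction when any column name matches the supplied regular
#' expression (case-insensitive), e.g. a pattern catching "Id", "Address" or
#' "Identifier". The pseudonymised `release_id` column is exempt. Returns the
#' table unchanged when nothing matches.
#'
#' @param table A data frame.
#' @param pattern Non-empty regular expression.
#' @return List: `ok` (logical) and either `table` or the offending `columns`.
#' @export
column_blacklister <- function(table, pattern) {
  if (is.null(pattern) || !nzchar(pattern)) abort("blacklist pattern must be non-empty")
  ok <- tryCatch({ grepl(pattern, ""); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("blacklist pattern does not compile: %s", pattern))
  candidates <- setdiff(names(table), "release_id")
  hits <- candidates[grepl(pattern, candidates, ignore.case = TRUE)]
  if (length(hits)) list(ok = FALSE, columns = hits)
  else list(ok = TRUE, table = table)
}

#' Governance filter
#'
#' Removes `Internal` columns unconditionally and `SpecialApprovalRequired`
#' columns unless approved; removals are reported for the audit.
#'
#' @param store A `dm_store`.
#' @param table A data frame whose columns are catalogue items (plus
#'   `release_id`).
#' @param dataset Dataset id or name.
#' @param approved Approved `SpecialApprovalRequired` column names.
#' @return List: `table` (filtered) and `removed` (tibble `column`, `reason`).
#' @export
governance_filter <- function(store, table, dataset, approved = character()) {
  entry <- get_entry(store, dataset)
  removed <- list()
  for (it in entry$items) {
    col <- it$column_name
    if (!col %in% names(table)) next
    drop_reason <- NULL
    if (identical(it$extraction_category, "Internal")) {
      drop_reason <- "Internal"
    } else if (identical(it$extraction_category, "SpecialApprovalRequired") &&
               !col %in% approved) {
      drop_reason <- "SpecialApprovalRequired without approval"
    }
    if (!is.null(drop_reason)) {
      table[[col]] <- NULL
      removed[[length(removed) + 1L]] <- tibble(column = col, reason = drop_reason)
    }
  }
  list(table = table,
       removed = if (length(removed)) bind_rows(removed)
                 else tibble(column = character(), reason = character()))
}

# ---- extraction configuration ---------------------------------------------

#' Build an extraction configuration
#'
#' @param project_id Registered project.
#' @param cohort_id Committed cohort to link against.
#' @param datasets List of selections, each `list(dataset =, columns =,
#'   approved = character())`; `columns` must not include `Internal` items and
#'   may include `SpecialApprovalRequired` items only when also in `approved`.
#' @param as_at `"live"` (default) or a UTC timestamp for a reproducible
#'   refresh against the data as at that time.
#' @param blacklist_pattern Regex for [column_blacklister()]; `NULL` disables
#'   the component (falls back to the store default when set).
#' @param components Ordered pipeline components; default
#'   `governance_filter`, `column_blacklister`, `chi_scanner`.
#' @param redact Mask CHI findings instead of vetoing (never the default).
#' @param strict_chi Require a DDMMYY date prefix for scanner findings.
#' @param config_id Stable identifier; defaults to a digest.
#' @return An `extraction_config`.
#' @export
extraction_config <- function(project_id, cohort_id, datasets, as_at = "live",
                              blacklist_pattern = NULL,
                              components = c("governance_filter",
                                             "column_blacklister", "chi_scanner"),
                              redact = FALSE, strict_chi = FALSE, config_id = NULL) {
  components <- match.arg(components,
                          c("governance_filter", "column_blacklister", "chi_scanner"),
                          several.ok = TRUE)
  if (!is.null(blacklist_pattern) && !nzchar(blacklist_pattern)) {
    abort("empty blacklist pattern; use NULL to disable the blacklister")
  }
  cfg <- list(project_id = project_id, cohort_id = cohort_id,
              datasets = datasets, as_at = as_at,
              blacklist_pattern = blacklist_pattern,
              components = components, redact = isTRUE(redact),
              strict_chi = isTRUE(strict_chi))
  if (is.null(config_id)) config_id <- paste0("X", substr(digest::digest(cfg), 1, 8))
  cfg$config_id <- config_id
  structure(cfg, class = "extraction_config")
}

validate_config_selection <- function(store, sel) {
  entry <- get_entry(store, sel$dataset)
  cols <- entry_columns(entry)
  unknown <- setdiff(sel$columns, cols)
  if (length(unknown)) {
    abort(sprintf("selection for '%s' names unknown column(s): %s",
                  entry$name, paste(unknown, collapse = ", ")))
  }
  for (col in sel$columns) {
    it <- entry_item(entry, col)
    if (identical(it$extraction_category, "Internal")) {
      abort(sprintf("column '%s' of '%s' is Internal and cannot be selected",
                    col, entry$name))
    }
    if (identical(it$extraction_category, "SpecialApprovalRequired") &&
        !col %in% (sel$approved %||% character())) {
      abort(sprintf("column '%s' of '%s' requires special approval", col, entry$name))
    }
  }
  invisible(entry)
}

# ---- audits ----------------------------------------------------------------

audits_path <- function(store) file.path(store$path, "audits.json")

read_audits <- function(store) read_json_file(audits_path(store), default = list())

append_audit <- function(store, audit) {
  audits <- read_audits(store)
  write_json_file(c(audits, list(audit)), audits_path(store))
  invisible(audit)
}

#' Fetch the audit record of a release
#'
#' @param store A `dm_store`.
#' @param release_id Release identifier.
#' @return The audit record (named list).
#' @export
release_audit <- function(store, release_id) {
  for (a in read_audits(store)) if (identical(a$release_id, release_id)) return(a)
  abort(sprintf("unknown release: %s", release_id))
}

#' List all release audits
#'
#' @param store A `dm_store`.
#' @return Tibble with one row per release attempt.
#' @export
list_release_audits <- function(store) {
  purrr::map_dfr(read_audits(store), function(a) {
    tibble(release_id = a$release_id, config_id = a$config_id,
           cohort_id = a$cohort_id, cohort_version = as.integer(a$cohort_version),
           release_type = a$release_type, started_at = a$started_at,
           succeeded = isTRUE(a$succeeded),
           crash_messages = paste(unlist(a$crash_messages), collapse = "; "))
  })
}

# ---- the release pipeline --------------------------------------------------

#' Run an audited extraction and assemble a release bundle
#'
#' For each selected dataset: reconstructs the table as at the configured
#' time, restricts rows to the committed cohort via the private identifier,
#' substitutes the project's stable release identifiers, and runs the
#' disclosure pipeline in order (governance filter, column blacklister, CHI
#' scanner). Any component veto aborts the release: the audit records the
#' crash messages and no bundle is emitted. On success a bundle directory is
#' written with per-dataset data files, lookup tables, global documents, an
#' extract-time quality report, a release metadata document, a tailored branch
#' catalogue and a digest manifest.
#'
#' @param store A `dm_store`.
#' @param config An [extraction_config()].
#' @param release_type One of `First`, `Refresh`, `HICError`,
#'   `ResearcherError`, `ChangeRequest` (caller-declared intent).
#' @return List: `audit` (always) and `bundle_dir` (`NULL` on veto).
#' @export
run_extraction <- function(store, config,
                           release_type = c("First", "Refresh", "HICError",
                                            "ResearcherError", "ChangeRequest")) {
  release_type <- match.arg(release_type)
  cohort <- get_cohort(store, config$cohort_id)
  members <- cohort$members
  rel_map <- cohort$release_map
  audits <- read_audits(store)
  release_id <- fresh_id("R", vapply(audits, function(a) a$release_id, character(1)))
  audit <- list(release_id = release_id, config_id = config$config_id,
                cohort_id = config$cohort_id, cohort_version = cohort$version,
                project_id = config$project_id, release_type = release_type,
                as_at = config$as_at, started_at = ts_now(),
                rows_created = stats::setNames(list(), character()),
                removed_columns = list(), crash_messages = list(),
                succeeded = FALSE)

  blk <- config$blacklist_pattern %||% store_config(store)$blacklist_pattern
  extracted <- list()   # dataset name -> final table
  entries <- list()
  veto <- NULL

  for (sel in config$datasets) {
    entry <- validate_config_selection(store, sel)
    idcol <- entry_identifier_column(entry)
    table <- if (identical(config$as_at, "live")) live_table(store, sel$dataset)
             else reconstruct_as_at(store, sel$dataset, config$as_at)
    table <- table[!is.na(table[[idcol]]) & table[[idcol]] %in% members, , drop = FALSE]
    if (!is.null(sel$row_filter)) {
      mask <- container_mask(sel$row_filter, table)
      table <- table[mask, , drop = FALSE]
    }
    table <- table[, unique(c(idcol, sel$columns)), drop = FALSE]
    table$release_id <- unname(rel_map[table[[idcol]]])

    for (comp in config$components) {
      if (comp == "governance_filter") {
        gf <- governance_filter(store, table, sel$dataset,
                                approved = sel$approved %||% character())
        table <- gf$table
        if (nrow(gf$removed)) {
          audit$removed_columns[[entry$name]] <-
            sprintf("%s (%s)", gf$removed$column, gf$removed$reason)
        }
      } else if (comp == "column_blacklister") {
        if (is.null(blk)) next
        res <- column_blacklister(table, blk)
        if (!res$ok) {
          veto <- sprintf("blacklisted column(s) in '%s': %s",
                          entry$name, paste(res$columns, collapse = ", "))
          break
        }
      } else if (comp == "chi_scanner") {
        found <- scan_for_chi(table, dataset = entry$name, strict = config$strict_chi)
        if (nrow(found) > 0) {
          if (config$redact) {
            for (k in seq_len(nrow(found))) {
              col <- found$column[k]; i <- found$row[k]
              table[[col]][i] <- gsub(found$match[k], strrep("#", 10),
                                      table[[col]][i], fixed = TRUE)
            }
            audit$removed_columns[[paste0(entry$name, ":redacted")]] <-
              sprintf("%s row %d", found$column, found$row)
          } else {
            veto <- sprintf("identifier checksum finding(s) in '%s': %s",
                            entry$name,
                            paste(sprintf("%s[%d]", found$column, found$row),
                                  collapse = ", "))
            audit$chi_findings <- purrr::transpose(as.list(found))
            break
          }
        }
      }
    }
    if (!is.null(veto)) break

    # deterministic layout: release_id first, then selected order; sorted rows
    keep <- c("release_id", intersect(sel$columns, names(table)))
    table <- table[, keep, drop = FALSE]
    ord <- do.call(order, unname(as.list(table)))
    table <- table[ord, , drop = FALSE]
    extracted[[entry$name]] <- table
    entries[[entry$name]] <- entry
    audit$rows_created[[entry$name]] <- nrow(table)
  }

  if (!is.null(veto)) {
    audit$crash_messages <- list(veto)
    audit$finished_at <- ts_now()
    append_audit(store, audit)
    return(list(audit = audit, bundle_dir = NULL))
  }

  bundle_dir <- file.path(store$path, "releases", release_id)
  dir.create(file.path(bundle_dir, "data"), recursive = TRUE)
  dir.create(file.path(bundle_dir, "lookups"))
  dir.create(file.path(bundle_dir, "docs"))

  for (nm in names(extracted)) {
    write_tbl(extracted[[nm]], file.path(bundle_dir, "data", paste0(nm, ".csv")))
  }
  # lookup tables for selected coded columns
  cat <- read_catalogue(store)
  emitted_lookups <- character()
  for (nm in names(entries)) {
    sel <- purrr::detect(config$datasets, function(s) {
      identical(get_entry(store, s$dataset)$name, nm)
    })
    for (col in sel$columns) {
      it <- entry_item(entries[[nm]], col)
      lid <- it$lookup_id
      if (!is.null(lid) && !lid %in% emitted_lookups) {
        lk <- cat$lookups[[lid]]
        write_tbl(tibble(code = names(lk$rows),
                         description = as.character(unlist(lk$rows))),
                  file.path(bundle_dir, "lookups", paste0(lid, ".csv")))
        emitted_lookups <- c(emitted_lookups, lid)
      }
    }
  }
  # global supporting documents
  for (nm in names(entries)) {
    for (doc in entries[[nm]]$documents) {
      if (isTRUE(doc$global_flag)) {
        writeLines(doc$body, file.path(bundle_dir, "docs",
                                       paste0(doc$doc_id, "_", gsub("\\W+", "_", doc$title), ".txt")))
      }
    }
  }
  # extract-time quality report over the extracted rows
  eq <- extract_quality(store, extracted, entries)
  write_json_file(eq, file.path(bundle_dir, "docs", "extract_quality.json"))
  # release metadata document and branch catalogue
  writeLines(generate_release_document(store, config, extracted, entries, cohort),
             file.path(bundle_dir, "docs", "release_document.md"))
  generate_branch_catalogue(store, config, path = file.path(bundle_dir, "catalogue.json"))
  write_manifest(bundle_dir)

  audit$succeeded <- TRUE
  audit$finished_at <- ts_now()
  append_audit(store, audit)
  list(audit = audit, bundle_dir = bundle_dir)
}

extract_quality <- function(store, extracted, entries) {
  lapply(stats::setNames(names(extracted), names(extracted)), function(nm) {
    table <- extracted[[nm]]
    entry <- entries[[nm]]
    cols <- intersect(entry_columns(entry), names(table))
    per_col <- lapply(stats::setNames(cols, cols), function(col) {
      cls <- classify_column(table[[col]], entry_item(entry, col), store)
      list(correct = sum(cls == "correct"), missing = sum(cls == "missing"),
           wrong = sum(cls == "wrong"))
    })
    list(rows = nrow(table), per_column = per_col)
  })
}

write_manifest <- function(bundle_dir) {
  files <- list.files(bundle_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- lapply(stats::setNames(files, files), function(f) {
    fp <- file.path(bundle_dir, f)
    list(sha256 = digest::digest(fp, algo = "sha256", file = TRUE),
         md5 = digest::digest(fp, algo = "md5", file = TRUE),
         bytes = file.info(fp)$size)
  })
  write_json_file(manifest, file.path(bundle_dir, "manifest.json"))
}

#' Verify a release bundle against its manifest
#'
#' @param bundle_dir Path to a release bundle.
#' @return Tibble per file with `ok` logical; all `TRUE` for an intact bundle.
#' @export
verify_release <- function(bundle_dir) {
  manifest <- read_json_file(file.path(bundle_dir, "manifest.json"))
  if (is.null(manifest)) abort("bundle has no manifest.json")
  purrr::map_dfr(names(manifest), function(f) {
    fp <- file.path(bundle_dir, f)
    ok <- file.exists(fp) &&
      identical(digest::digest(fp, algo = "sha256", file = TRUE), manifest[[f]]$sha256)
    tibble(file = f, ok = ok)
  })
}

#' Generate the release metadata document
#'
#' A Markdown document describing, for exactly the extracted fields, their
#' catalogue descriptions; the cohort logic rendering; and per-dataset monthly
#' record-count series for the extracted rows. Deterministic given the same
#' extracted content.
#'
#' @param store A `dm_store`.
#' @param config An [extraction_config()].
#' @param extracted Named list of extracted tables (as built by [run_extraction()]).
#' @param entries Named list of the matching catalogue entries.
#' @param cohort The committed cohort record.
#' @return Character vector of Markdown lines.
#' @export
generate_release_document <- function(store, config, extracted, entries, cohort) {
  lines <- c("# Release metadata", "",
             sprintf("Project: %s", config$project_id),
             sprintf("Cohort: %s (version %s, %d members)",
                     cohort$cohort_id, cohort$version, length(cohort$members)),
             sprintf("As at: %s", config$as_at), "",
             "## Cohort logic", "", "```")
  def <- read_cohort_definition_from_list(cohort$definition)
  lines <- c(lines, strsplit(describe_definition(def), "\n")[[1]], "```", "")
  for (nm in names(extracted)) {
    entry <- entries[[nm]]
    lines <- c(lines, sprintf("## Dataset: %s", nm), "",
               entry$description %||% "", "", "### Extracted fields", "")
    for (col in setdiff(names(extracted[[nm]]), "release_id")) {
      it <- entry_item(entry, col)
      desc <- if (nzchar(it$description %||% "")) it$description else "(no description)"
      lines <- c(lines, sprintf("- `%s` (%s): %s", col, it$semantic_type, desc))
    }
    lines <- c(lines, "- `release_id` (text): pseudonymised release identifier", "")
    edc <- entry$event_date_column
    if (!is.null(edc) && edc %in% names(extracted[[nm]])) {
      months <- event_month(extracted[[nm]][[edc]])
      tb <- sort(table(months))
      tb <- tb[order(names(tb))]
      lines <- c(lines, "### Monthly record counts", "")
      lines <- c(lines, sprintf("- %s: %d", names(tb), as.integer(tb)), "")
    }
  }
  lines
}

read_cohort_definition_from_list <- function(lst) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_json_file(lst, tf)
  read_cohort_definition(tf)
}

#' Generate a branch catalogue tailored to an extraction configuration
#'
#' Restricts the catalogue to the extracted datasets and columns, omits all
#' private-identifier (`Internal`) items, and adds a `release_id` item in
#' their place so the document can seed a branch (project) node and
#' round-trips through [import_catalogue()].
#'
#' @param store A `dm_store`.
#' @param config An [extraction_config()].
#' @param path Optional output path for the JSON document.
#' @return The portable catalogue document (list).
#' @export
generate_branch_catalogue <- function(store, config, path = NULL) {
  doc <- export_catalogue(store, datasets = vapply(config$datasets,
                                                   function(s) s$dataset, character(1)))
  doc$entries <- purrr::map2(doc$entries, config$datasets, function(entry, sel) {
    keep_cols <- intersect(entry_columns(entry), sel$columns)
    keep_cols <- purrr::keep(keep_cols, function(col) {
      it <- entry_item(entry, col)
      if (identical(it$extraction_category, "Internal")) return(FALSE)
      if (identical(it$extraction_category, "SpecialApprovalRequired") &&
          !col %in% (sel$approved %||% character())) return(FALSE)
      TRUE
    })
    idcol <- entry_identifier_column(entry)
    entry$items <- purrr::keep(entry$items, function(it) it$column_name %in% keep_cols)
    entry$items <- c(list(list(column_name = "release_id",
                               description = "pseudonymised release identifier",
                               semantic_type = "text", extraction_category = "Core",
                               role = "", validation_rules = list(), lookup_id = NULL)),
                     entry$items)
    pk <- unlist(entry$primary_key)
    pk[pk == idcol] <- "release_id"
    entry$primary_key <- as.list(intersect(pk, c("release_id", keep_cols)))
    entry$load_logic <- list(header_mapping = stats::setNames(list(), character()),
                             headerless_column_order = NULL,
                             cleaning_steps = list("trim", "null_token_set"),
                             date_formats = list())
    entry
  })
  used <- unique(unlist(purrr::map(doc$entries, function(e) {
    purrr::compact(purrr::map(e$items, "lookup_id"))
  })))
  doc$lookups <- doc$lookups[intersect(names(doc$lookups), used %||% character())]
  if (!is.null(path)) write_json_file(doc, path)
  doc
}
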