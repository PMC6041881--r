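# Load engine: RAW -> STAGING -> LIVE with full audit logging, catalogue-driven
# cleaning, schema-drift tolerance, primary-key upsert and archival of
# superseded rows. All values are stored as text; cleaning canonicalises
# (trimmed, null tokens to NA, ISO dates, upper-cased codes) so that live and
# archive tables round-trip byte-identically through CSV.

KEY_SEP <- "\x1f"

align_columns <- function(df, cols) {
  for (missing in setdiff(cols, names(df))) df[[missing]] <- NA_character_
  df[, cols, drop = FALSE]
}

row_keys <- function(df, pk) {
  if (nrow(df) == 0) return(character())
  do.call(paste, c(unname(as.list(df[, pk, drop = FALSE])), sep = KEY_SEP))
}

live_path <- function(store, dataset_id) file.path(store$path, "live", paste0(dataset_id, ".csv"))
archive_path <- function(store, dataset_id) file.path(store$path, "archive", paste0(dataset_id, ".csv"))

empty_live <- function(cols) {
  out <- as_tibble(stats::setNames(rep(list(character()), length(cols) + 1),
                                   c(cols, ".valid_from")))
  out
}

read_live <- function(store, entry) {
  tbl <- read_tbl(live_path(store, entry$dataset_id))
  if (is.null(tbl)) tbl <- empty_live(entry_columns(entry))
  tbl
}

read_archive <- function(store, entry) {
  tbl <- read_tbl(archive_path(store, entry$dataset_id))
  if (is.null(tbl)) {
    tbl <- empty_live(entry_columns(entry))
    tbl$.valid_to <- character()
  }
  tbl
}

# ---- ingest ----------------------------------------------------------------

#' Ingest a dataset feed file (RAW stage)
#'
#' Reads a delimited feed, resolves its header against the catalogue's load
#' logic (renamed columns via `header_mapping`; headerless feeds via
#' `headerless_column_order`), records the MD5 digest of the raw bytes and
#' creates a load job at stage `RAW`.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name (must be registered).
#' @param source_path Path to a CSV feed (RFC 4180, UTF-8).
#' @return A load job record (named list); `stage` is `"RAW"`, or `"FAILED"`
#'   with a fatal log entry when the columns cannot be resolved.
#' @export
ingest_file <- function(store, dataset, source_path) {
  entry <- get_entry(store, dataset)
  if (!file.exists(source_path)) abort(sprintf("file not readable: %s", source_path))
  jobs <- read_jobs(store)
  job <- list(
    job_id = fresh_id("J", jobs$job_id), dataset_id = entry$dataset_id,
    source_path = as.character(source_path),
    file_digest = digest::digest(source_path, algo = "md5", file = TRUE),
    started_at = ts_now(), finished_at = NA_character_,
    stage = "RAW", load_time = NA_character_,
    raw_row_count = 0L, staged_row_count = NA_integer_,
    rejected_row_count = NA_integer_, inserted_count = NA_integer_,
    updated_count = NA_integer_, unchanged_count = NA_integer_
  )
  canonical <- entry_columns(entry)
  mapping <- entry$load_logic$header_mapping
  order_hint <- unlist(entry$load_logic$headerless_column_order)

  first <- readr::read_csv(source_path, col_names = FALSE, n_max = 1,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE, show_col_types = FALSE)
  if (nrow(first) == 0) {
    upsert_job(store, job)
    append_log(store, job$job_id, "warning", "empty feed file: no rows parsed")
    return(job)
  }
  fields <- trimws(as.character(unlist(first[1, ])))
  resolved <- vapply(fields, function(f) {
    if (f %in% canonical) return(f)
    m <- mapping[[f]]
    if (!is.null(m)) return(m)
    NA_character_
  }, character(1), USE.NAMES = FALSE)

  if (!anyNA(resolved) && !anyDuplicated(resolved)) {
    raw <- readr::read_csv(source_path, col_names = resolved, skip = 1,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE, show_col_types = FALSE)
    if (!identical(fields, resolved)) {
      append_log(store, job$job_id, "info",
                 sprintf("header aliases resolved: %s",
                         paste(fields[fields != resolved], collapse = ", ")))
    }
  } else if (!is.null(order_hint) && length(order_hint) == length(fields)) {
    raw <- readr::read_csv(source_path, col_names = order_hint,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE, show_col_types = FALSE)
    append_log(store, job$job_id, "info",
               "no recognisable header; applied headerless column order")
  } else {
    job$stage <- "FAILED"
    job$finished_at <- ts_now()
    upsert_job(store, job)
    append_log(store, job$job_id, "fatal",
               sprintf("unresolvable columns: %s",
                       paste(fields[is.na(resolved)], collapse = ", ")))
    return(job)
  }
  job$raw_row_count <- nrow(raw)
  write_tbl(raw, file.path(store$path, "raw", paste0(job$job_id, ".csv")))
  upsert_job(store, job)
  if (nrow(raw) == 0) append_log(store, job$job_id, "warning", "feed contains no data rows")
  append_log(store, job$job_id, "info",
             sprintf("ingested %d raw rows (md5 %s)", nrow(raw), job$file_digest))
  job
}

# ---- cleaning --------------------------------------------------------------

date_format_to_strptime <- function(fmt) {
  fmt <- gsub("YYYY", "%Y", fmt, fixed = TRUE)
  fmt <- gsub("DD", "%d", fmt, fixed = TRUE)
  gsub("MM", "%m", fmt, fixed = TRUE)
}

clean_rows <- function(raw, entry, cfg) {
  steps <- unlist(entry$load_logic$cleaning_steps)
  types <- stats::setNames(vapply(entry$items, function(it) it$semantic_type, character(1)),
                           entry_columns(entry))
  for (step in steps) {
    if (step == "trim") {
      raw[] <- lapply(raw, function(v) ifelse(is.na(v), v, trimws(v)))
    } else if (step == "null_token_set") {
      toks <- cfg$null_tokens
      raw[] <- lapply(raw, function(v) { v[!is.na(v) & v %in% toks] <- NA_character_; v })
    } else if (step == "date_parse_formats") {
      fmts <- vapply(unlist(entry$load_logic$date_formats), date_format_to_strptime,
                     character(1))
      date_cols <- intersect(names(raw), names(types)[types == "date"])
      for (col in date_cols) {
        v <- raw[[col]]
        parsed <- rep(NA_character_, length(v))
        left <- !is.na(v)
        for (f in c(fmts, "%Y-%m-%d")) {
          if (!any(left)) break
          d <- as.Date(v[left], format = f)
          hit <- !is.na(d)
          parsed[which(left)[hit]] <- format(d[hit], "%Y-%m-%d")
          left[which(left)[hit]] <- FALSE
        }
        # unparseable values are kept verbatim; rules may then flag them
        raw[[col]] <- ifelse(is.na(parsed) & !is.na(v), v, parsed)
      }
    } else if (step == "uppercase_codes") {
      code_cols <- intersect(names(raw), names(types)[types == "code"])
      for (col in code_cols) raw[[col]] <- toupper(raw[[col]])
    }
  }
  raw
}

# ---- rule evaluation -------------------------------------------------------

# Returns a logical vector: TRUE where the (non-missing) value violates the
# rule. not_null is handled by the caller, which knows how missingness is
# being classified.
rule_violations <- function(values, rule, store) {
  out <- rep(FALSE, length(values))
  present <- !is.na(values)
  if (!any(present)) return(out)
  v <- values[present]
  viol <- switch(rule$rule_kind,
    not_null = rep(FALSE, length(v)),
    regex = !grepl(rule$params$pattern, v),
    bounds = {
      num <- suppressWarnings(as.numeric(v))
      is.na(num) | num < as.numeric(rule$params$lower) | num > as.numeric(rule$params$upper)
    },
    lookup_membership = !v %in% lookup_codes(store, rule$params$lookup_id),
    date_range = {
      d <- as.Date(v, format = "%Y-%m-%d")
      is.na(d) | d < as.Date(rule$params$lower) | d > as.Date(rule$params$upper)
    },
    abort(sprintf("unknown rule kind: %s", rule$rule_kind))
  )
  out[present] <- viol
  out
}

# ---- staging ---------------------------------------------------------------

#' Validate and stage an ingested load (STAGING stage)
#'
#' Applies the catalogue cleaning steps in order, rejects rows that violate an
#' `invalidates_row` rule, have a null primary-key component, or duplicate an
#' earlier in-batch primary key, and enforces the configurable reject-fraction
#' abort threshold. Always `staged + rejected = raw`.
#'
#' @param store A `dm_store`.
#' @param job A load job (or job id) at stage `RAW`.
#' @return The updated job; stage `"STAGING"`, or `"FAILED"` when the rejected
#'   fraction exceeds `store_config(store)$reject_threshold`.
#' @export
validate_and_stage <- function(store, job) {
  if (is.character(job)) job <- get_job(store, job)
  if (!identical(job$stage, "RAW")) abort(sprintf("job %s is not at RAW", job$job_id))
  cat <- read_catalogue(store)
  entry <- cat$entries[[find_entry_index(cat, job$dataset_id)]]
  cfg <- store_config(store)
  canonical <- entry_columns(entry)
  pk <- unlist(entry$primary_key)

  raw <- read_tbl(file.path(store$path, "raw", paste0(job$job_id, ".csv")))
  if (is.null(raw)) raw <- as_tibble(stats::setNames(rep(list(character()), length(canonical)), canonical))
  raw <- align_columns(raw, canonical)
  cleaned <- clean_rows(raw, entry, cfg)

  n <- nrow(cleaned)
  reject <- rep(FALSE, n)
  if (n > 0) {
    for (it in entry$items) {
      for (rule in it$validation_rules) {
        if (!identical(rule$severity, "invalidates_row")) next
        v <- cleaned[[it$column_name]]
        bad <- rule_violations(v, rule, store)
        if (identical(rule$rule_kind, "not_null")) bad <- bad | is.na(v)
        for (i in which(bad & !reject)) {
          append_log(store, job$job_id, "warning",
                     sprintf("row rejected: column '%s' violates %s rule",
                             it$column_name, rule$rule_kind), row_ref = i)
        }
        reject <- reject | bad
      }
    }
    # null primary-key components invalidate the row
    pk_null <- Reduce(`|`, lapply(pk, function(col) is.na(cleaned[[col]])))
    for (i in which(pk_null & !reject)) {
      append_log(store, job$job_id, "warning", "row rejected: null primary key",
                 row_ref = i)
    }
    reject <- reject | pk_null
    # in-batch duplicate primary keys: first occurrence wins
    keys <- row_keys(cleaned, pk)
    dup <- duplicated(keys) & !pk_null
    for (i in which(dup & !reject)) {
      append_log(store, job$job_id, "warning", "row rejected: duplicate primary key in batch",
                 row_ref = i)
    }
    reject <- reject | dup
  }

  staged <- cleaned[!reject, , drop = FALSE]
  job$staged_row_count <- nrow(staged)
  job$rejected_row_count <- sum(reject)
  if (n > 0 && sum(reject) / n > cfg$reject_threshold) {
    job$stage <- "FAILED"
    job$finished_at <- ts_now()
    upsert_job(store, job)
    append_log(store, job$job_id, "fatal",
               sprintf("rejected fraction %.3f exceeds threshold %.3f; load aborted",
                       sum(reject) / n, cfg$reject_threshold))
    return(job)
  }
  write_tbl(staged, file.path(store$path, "staging", paste0(job$job_id, ".csv")))
  job$stage <- "STAGING"
  upsert_job(store, job)
  append_log(store, job$job_id, "info",
             sprintf("staged %d rows, rejected %d", nrow(staged), sum(reject)))
  job
}

# ---- merge to live ---------------------------------------------------------

#' Merge a staged load into the live table (LIVE stage)
#'
#' Primary-key upsert: unseen keys are inserted with `valid_from = load_time`;
#' keys whose payload changed have the old row moved to the archive with
#' `valid_to = load_time` (half-open validity `[valid_from, valid_to)`) and the
#' new row inserted; identical payloads are counted as unchanged. Load times
#' are a strictly increasing per-dataset clock; back-dated loads are rejected.
#' In `tombstone` mode staged keys are archived without replacement.
#'
#' @param store A `dm_store`.
#' @param job A load job (or job id) at stage `STAGING`.
#' @param load_time UTC timestamp string `YYYY-MM-DDTHH:MM:SSZ`; defaults to now.
#' @param mode `"upsert"` (default) or `"tombstone"`.
#' @return The completed job at stage `"LIVE"` with insert/update/unchanged counts.
#' @export
merge_to_live <- function(store, job, load_time = ts_now(), mode = c("upsert", "tombstone")) {
  mode <- match.arg(mode)
  if (is.character(job)) job <- get_job(store, job)
  if (!identical(job$stage, "STAGING")) abort(sprintf("job %s is not at STAGING", job$job_id))
  entry <- get_entry(store, job$dataset_id)
  canonical <- entry_columns(entry)
  pk <- unlist(entry$primary_key)
  t_new <- parse_ts(load_time)

  jobs <- read_jobs(store)
  prior <- jobs$load_time[jobs$dataset_id == entry$dataset_id & jobs$stage == "LIVE"]
  prior <- prior[!is.na(prior)]
  if (length(prior) && any(parse_ts(prior) >= t_new)) {
    abort(sprintf("load_time %s is not after the latest load for dataset '%s'",
                  load_time, entry$name))
  }

  staged <- read_tbl(file.path(store$path, "staging", paste0(job$job_id, ".csv")))
  if (is.null(staged)) staged <- as_tibble(stats::setNames(rep(list(character()), length(canonical)), canonical))
  staged <- align_columns(staged, canonical)
  live <- read_live(store, entry)
  archive <- read_archive(store, entry)

  live_keys <- row_keys(live, pk)
  staged_keys <- row_keys(staged, pk)
  payload_equal <- function(i_staged, i_live) {
    a <- as.character(unlist(staged[i_staged, canonical]))
    b <- as.character(unlist(live[i_live, canonical]))
    all((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
  }

  inserted <- 0L; updated <- 0L; unchanged <- 0L
  to_archive <- integer()
  drop_live <- integer()
  new_rows <- list()
  for (i in seq_len(nrow(staged))) {
    j <- match(staged_keys[i], live_keys)
    if (mode == "tombstone") {
      if (!is.na(j)) { to_archive <- c(to_archive, j); drop_live <- c(drop_live, j); updated <- updated + 1L }
      else unchanged <- unchanged + 1L
      next
    }
    if (is.na(j)) {
      r <- staged[i, , drop = FALSE]
      r$.valid_from <- format_ts(t_new)
      new_rows[[length(new_rows) + 1L]] <- r
      inserted <- inserted + 1L
    } else if (payload_equal(i, j)) {
      unchanged <- unchanged + 1L
    } else {
      to_archive <- c(to_archive, j)
      drop_live <- c(drop_live, j)
      r <- staged[i, , drop = FALSE]
      r$.valid_from <- format_ts(t_new)
      new_rows[[length(new_rows) + 1L]] <- r
      updated <- updated + 1L
    }
  }
  if (length(to_archive)) {
    arch_new <- live[to_archive, , drop = FALSE]
    arch_new$.valid_to <- format_ts(t_new)
    archive <- bind_rows(archive, arch_new)
  }
  if (length(drop_live)) live <- live[-drop_live, , drop = FALSE]
  if (length(new_rows)) live <- bind_rows(live, bind_rows(new_rows))
  live <- live[order(row_keys(live, pk)), , drop = FALSE]
  write_tbl(live, live_path(store, entry$dataset_id))
  write_tbl(archive, archive_path(store, entry$dataset_id))

  job$inserted_count <- inserted
  job$updated_count <- updated
  job$unchanged_count <- unchanged
  job$load_time <- format_ts(t_new)
  job$stage <- "LIVE"
  job$finished_at <- ts_now()
  upsert_job(store, job)
  append_log(store, job$job_id, "info",
             sprintf("merged to live at %s: %d inserted, %d updated, %d unchanged",
                     job$load_time, inserted, updated, unchanged))
  job
}

#' Run a full load (RAW, STAGING, LIVE) in one call
#'
#' @inheritParams ingest_file
#' @inheritParams merge_to_live
#' @return The final job record; check `$stage` for `"LIVE"` or `"FAILED"`.
#' @export
run_load <- function(store, dataset, source_path, load_time = ts_now()) {
  job <- ingest_file(store, dataset, source_path)
  if (identical(job$stage, "FAILED")) return(job)
  job <- validate_and_stage(store, job)
  if (identical(job$stage, "FAILED")) return(job)
  merge_to_live(store, job, load_time)
}

# ---- history and as-at reconstruction --------------------------------------

#' Load history for a dataset
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name.
#' @return Tibble of job summaries in load order (failed jobs in start order at
#'   the end), including stage and row counts.
#' @export
load_history <- function(store, dataset) {
  entry <- get_entry(store, dataset)
  jobs <- read_jobs(store)
  jobs <- jobs[jobs$dataset_id == entry$dataset_id, , drop = FALSE]
  jobs[order(!is.na(jobs$load_time), jobs$load_time, jobs$started_at,
             decreasing = c(TRUE, FALSE, FALSE), method = "radix"), , drop = FALSE]
}

#' Current live table of a dataset
#'
#' @inheritParams load_history
#' @return Tibble of live rows (payload columns only), ordered by primary key.
#' @export
live_table <- function(store, dataset) {
  entry <- get_entry(store, dataset)
  live <- read_live(store, entry)
  live <- live[order(row_keys(live, unlist(entry$primary_key))), , drop = FALSE]
  live[, entry_columns(entry), drop = FALSE]
}

#' Reconstruct a dataset as it stood at a past time
#'
#' Bitemporal point query: returns live rows with `valid_from <= t` plus
#' archived rows with `valid_from <= t < valid_to` — exactly one row per
#' primary key that existed at `t`. Supports reproducible refreshes that
#' deliver the data exactly as it was at the time of a first release.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name.
#' @param t UTC timestamp string; times before the first load give an empty table.
#' @return Tibble of payload columns, ordered by primary key.
#' @export
reconstruct_as_at <- function(store, dataset, t) {
  entry <- get_entry(store, dataset)
  tt <- parse_ts(t)
  live <- read_live(store, entry)
  archive <- read_archive(store, entry)
  keep_live <- live[parse_ts(live$.valid_from) <= tt, , drop = FALSE]
  keep_arch <- archive[parse_ts(archive$.valid_from) <= tt &
                         parse_ts(archive$.valid_to) > tt, , drop = FALSE]
  out <- bind_rows(keep_live[, entry_columns(entry), drop = FALSE],
                   keep_arch[, entry_columns(entry), drop = FALSE])
  out[order(row_keys(out, unlist(entry$primary_key))), , drop = FALSE]
}
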