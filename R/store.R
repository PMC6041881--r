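#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows left_join anti_join
#'   group_by summarise n ungroup distinct across all_of
NULL

# ---- store handle ----------------------------------------------------------

#' Open (or create) a data-management store
#'
#' A store is a plain-file directory holding the catalogue, load audit trail,
#' live and archive tables, committed cohorts, project pseudonym maps and
#' release bundles. One store corresponds to one data-management node; all
#' other functions in the package take a store as their first argument.
#' Single-writer semantics: the store is not safe for concurrent writers.
#'
#' @param path Directory for the store. Created if absent.
#' @param create Create the directory layout when missing (default `TRUE`).
#' @return A `dm_store` handle.
#' @export
#' @examples
#' st <- dm_store(file.path(tempdir(), "store-example"))
#' st
dm_store <- function(path, create = TRUE) {
  if (!dir.exists(path)) {
    if (!create) abort(sprintf("store directory does not exist: %s", path))
    dir.create(path, recursive = TRUE)
  }
  for (d in c("load", "raw", "staging", "live", "archive", "projects", "releases")) {
    dd <- file.path(path, d)
    if (!dir.exists(dd)) dir.create(dd)
  }
  cfg_path <- file.path(path, "config.json")
  if (!file.exists(cfg_path)) {
    write_json_file(default_store_config(), cfg_path)
  }
  structure(list(path = normalizePath(path)), class = "dm_store")
}

default_store_config <- function() {
  list(
    reject_threshold = 0.10,
    null_tokens = c("", "NULL", "NA"),
    blacklist_pattern = NULL,
    summary_cardinality_limit = 1000
  )
}

#' @export
print.dm_store <- function(x, ...) {
  cat <- read_catalogue(x)
  cat("<dm_store> ", x$path, "\n", sep = "")
  cat("  datasets registered: ", length(cat$entries), "\n", sep = "")
  jobs <- read_jobs(x)
  cat("  load jobs: ", nrow(jobs), "\n", sep = "")
  invisible(x)
}

#' Store-level configuration
#'
#' @param store A `dm_store`.
#' @return Named list of configuration values (reject threshold, null tokens,
#'   default blacklist pattern, summary cardinality limit).
#' @export
store_config <- function(store) {
  cfg <- read_json_file(file.path(store$path, "config.json"))
  cfg$null_tokens <- as.character(unlist(cfg$null_tokens))
  cfg
}

#' @rdname store_config
#' @param ... Named configuration values to update.
#' @export
set_store_config <- function(store, ...) {
  cfg <- store_config(store)
  upd <- list(...)
  for (nm in names(upd)) cfg[[nm]] <- upd[[nm]]
  write_json_file(cfg, file.path(store$path, "config.json"))
  invisible(cfg)
}

# ---- file IO helpers -------------------------------------------------------

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_json_file <- function(path, default = NULL) {
  if (!file.exists(path)) return(default)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# All store tables are character-typed CSV; NA round-trips as empty field.
read_tbl <- function(path) {
  if (!file.exists(path)) return(NULL)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = "", progress = FALSE, show_col_types = FALSE)
}

write_tbl <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

# ---- timestamps ------------------------------------------------------------

TS_FMT <- "%Y-%m-%dT%H:%M:%SZ"

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = TS_FMT, tz = "UTC")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    # fall back to date-only form
    d <- as.POSIXct(x[bad], format = "%Y-%m-%d", tz = "UTC")
    out[bad] <- d
    if (anyNA(out[!is.na(x)])) {
      abort(sprintf("unparseable UTC timestamp: %s",
                    paste(x[is.na(out) & !is.na(x)], collapse = ", ")))
    }
  }
  out
}

format_ts <- function(t) format(t, TS_FMT, tz = "UTC")

ts_now <- function() format_ts(Sys.time())

# ---- id minting ------------------------------------------------------------

fresh_id <- function(prefix, existing) {
  i <- length(existing) + 1L
  repeat {
    cand <- sprintf("%s%04d", prefix, i)
    if (!cand %in% existing) return(cand)
    i <- i + 1L
  }
}

# ---- audit/job persistence -------------------------------------------------

JOB_INT_COLS <- c("raw_row_count", "staged_row_count", "rejected_row_count",
                  "inserted_count", "updated_count", "unchanged_count")

empty_jobs <- function() {
  tibble(
    job_id = character(), dataset_id = character(), source_path = character(),
    file_digest = character(), started_at = character(), finished_at = character(),
    stage = character(), load_time = character(),
    raw_row_count = integer(), staged_row_count = integer(),
    rejected_row_count = integer(), inserted_count = integer(),
    updated_count = integer(), unchanged_count = integer()
  )
}

read_jobs <- function(store) {
  tbl <- read_tbl(file.path(store$path, "load", "jobs.csv"))
  if (is.null(tbl)) return(empty_jobs())
  for (col in JOB_INT_COLS) tbl[[col]] <- as.integer(tbl[[col]])
  tbl
}

write_jobs <- function(store, jobs_tbl) {
  write_tbl(jobs_tbl, file.path(store$path, "load", "jobs.csv"))
}

upsert_job <- function(store, job) {
  jobs <- read_jobs(store)
  jobs <- jobs[jobs$job_id != job$job_id, , drop = FALSE]
  jobs <- bind_rows(jobs, as_tibble(job[names(jobs)]))
  write_jobs(store, jobs)
  invisible(job)
}

get_job <- function(store, job_id) {
  jobs <- read_jobs(store)
  row <- jobs[jobs$job_id == job_id, , drop = FALSE]
  if (nrow(row) == 0) abort(sprintf("unknown load job: %s", job_id))
  as.list(row[1, ])
}

log_path <- function(store) file.path(store$path, "load", "log.csv")

append_log <- function(store, job_id, level, message, row_ref = NA_integer_) {
  entry <- tibble(job_id = job_id, level = level, message = message,
                  row_ref = as.character(row_ref))
  p <- log_path(store)
  readr::write_csv(entry, p, na = "", append = file.exists(p),
                   col_names = !file.exists(p))
  invisible(entry)
}

#' Read the persistent load log
#'
#' @param store A `dm_store`.
#' @param job_id Optional job id to filter on.
#' @return Tibble with columns `job_id`, `level`, `message`, `row_ref`.
#' @export
load_log <- function(store, job_id = NULL) {
  log <- read_tbl(log_path(store))
  if (is.null(log)) {
    log <- tibble(job_id = character(), level = character(),
                  message = character(), row_ref = character())
  }
  if (!is.null(job_id)) log <- log[log$job_id == job_id, , drop = FALSE]
  log
}
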