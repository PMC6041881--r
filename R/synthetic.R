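# Synthetic longitudinal clinical worlds with known ground truth: a demography
# register plus accruing event datasets (prescriptions, biochemistry, optional
# extras), with planted missingness/wrong values, schema drift, temporal gaps,
# retrospective rewrites and embedded checksum-valid identifiers. Value
# distributions are deliberately simple — the generator exists to exercise
# data-management plumbing, not to model biology.

#' Configure a synthetic clinical world
#'
#' @param seed Integer seed; identical seeds give byte-identical worlds.
#' @param n_patients Number of patients in the demography register.
#' @param n_datasets Total datasets: demography, prescriptions, biochemistry,
#'   plus `n_datasets - 3` small extra event datasets sharing the identifier.
#' @param months Accrual period in months for event datasets.
#' @param start_month First accrual month, `"YYYY-MM"`.
#' @param error_rates Nested list `dataset -> column -> list(missing_rate,
#'   wrong_rate)`, rates in `[0, 1]`. Wrong values are only plantable on
#'   columns carrying a wrong-severity rule in the bootstrap catalogue
#'   (`sex`, `bnf_code`, `test_code`, `result`); never on primary keys or the
#'   identifier.
#' @param drift_plan List of `list(month =, dataset =, kind =)` with kind
#'   `"rename_column"` (feed header uses an alias the catalogue maps back) or
#'   `"drop_header"` (feed emitted headerless).
#' @param rewrite_rate Fraction of patients whose demography values change
#'   retrospectively in a rewrite feed.
#' @param rewrite_month Month index at which the rewrite feed is issued
#'   (default: last month).
#' @param gap_months Integer month indices with zero events in every event
#'   dataset (temporal gaps).
#' @param planted_chi_count Checksum-valid 10-digit identifiers embedded in
#'   free-text cells.
#' @param event_prob Per-patient, per-month probability of an event row.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 20160101, n_patients = 100, n_datasets = 3,
                         months = 6, start_month = "2016-01",
                         error_rates = list(
                           biochemistry = list(result = list(missing_rate = 0.05,
                                                             wrong_rate = 0.02)),
                           prescriptions = list(bnf_code = list(missing_rate = 0.03,
                                                                wrong_rate = 0.02))),
                         drift_plan = list(), rewrite_rate = 0,
                         rewrite_month = months, gap_months = integer(),
                         planted_chi_count = 0, event_prob = 0.8) {
  stopifnot(n_patients >= 1, n_datasets >= 1, months >= 1)
  for (ds in names(error_rates)) for (col in names(error_rates[[ds]])) {
    er <- error_rates[[ds]][[col]]
    m <- er$missing_rate %||% 0; w <- er$wrong_rate %||% 0
    if (m < 0 || m > 1 || w < 0 || w > 1 || m + w > 1) {
      abort(sprintf("error rates for %s.%s must lie in [0,1] with sum <= 1", ds, col))
    }
  }
  if (length(gap_months) && any(gap_months < 1 | gap_months > months)) {
    abort("gap_months must lie within the accrual period")
  }
  if (rewrite_rate < 0 || rewrite_rate > 1) abort("rewrite_rate must be in [0,1]")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_datasets = as.integer(n_datasets), months = as.integer(months),
                 start_month = start_month, error_rates = error_rates,
                 drift_plan = drift_plan, rewrite_rate = rewrite_rate,
                 rewrite_month = as.integer(rewrite_month),
                 gap_months = as.integer(gap_months),
                 planted_chi_count = as.integer(planted_chi_count),
                 event_prob = event_prob),
            class = "world_config")
}

month_labels <- function(start_month, months) {
  format(seq(as.Date(paste0(start_month, "-01")), by = "month", length.out = months),
         "%Y-%m")
}

# Feed date format is DD/MM/YYYY; catalogue cleaning parses it back to ISO.
feed_date <- function(iso) format(as.Date(iso), "%d/%m/%Y")

# CHI-like identifiers: DDMMYY of the birth date, 3 serial digits, mod-11
# check digit; serials are redrawn when the checksum admits no valid digit.
gen_chi_for_dob <- function(dob, used) {
  stem6 <- format(as.Date(dob), "%d%m%y")
  repeat {
    serial <- sprintf("%03d", sample.int(1000, 1) - 1L)
    stem <- paste0(stem6, serial)
    cd <- chi_check_digit(stem)
    if (is.na(cd)) next
    chi <- paste0(stem, cd)
    if (!chi %in% used) return(chi)
  }
}

world_dataset_names <- function(config) {
  base <- c("demography", "prescriptions", "biochemistry")[seq_len(min(3, config$n_datasets))]
  if (config$n_datasets > 3) {
    base <- c(base, sprintf("extra_%02d", seq_len(config$n_datasets - 3)))
  }
  base
}

NOTE_PHRASES <- c("routine sample", "seen in clinic", "repeat requested",
                  "no further action", "phoned ward", "fasting sample")

#' Generate a synthetic world
#'
#' Writes one CSV feed per dataset per accrual month (demography is a single
#' register feed plus an optional rewrite feed), applies the drift plan,
#' plants the configured errors and free-text identifiers, and returns the
#' exact ground truth alongside a bootstrap catalogue document ready for
#' [import_catalogue()].
#'
#' @param config A [world_config()].
#' @param out_dir Directory for the feed files (created if needed).
#' @return A `synthetic_world`: list with `config`, `dir`, `feeds` (tibble of
#'   feed files with load order), `catalogue_doc`, `ground_truth`, `patients`.
#' @export
generate_world <- function(config, out_dir) {
  stopifnot(inherits(config, "world_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  withr::local_seed(config$seed)
  months <- month_labels(config$start_month, config$months)
  ds_names <- world_dataset_names(config)

  # patients
  dob <- as.Date("1940-01-01") + sample.int(20000, config$n_patients, replace = TRUE)
  chis <- character(config$n_patients)
  for (i in seq_len(config$n_patients)) chis[i] <- gen_chi_for_dob(dob[i], chis)
  patients <- tibble(
    chi = chis, dob = format(dob, "%Y-%m-%d"),
    sex = sample(c("F", "M"), config$n_patients, replace = TRUE),
    postcode = sprintf("DD%d %d%s%s", sample.int(9, config$n_patients, TRUE),
                       sample.int(9, config$n_patients, TRUE),
                       sample(LETTERS, config$n_patients, TRUE),
                       sample(LETTERS, config$n_patients, TRUE)))

  truth <- list(monthly_rows = list(), planted = list(), rewrites = list(),
                chi_plants = list())
  feeds <- list()
  drift_for <- function(ds, m) {
    purrr::detect(config$drift_plan, function(d) {
      identical(d$dataset, ds) && identical(as.integer(d$month), as.integer(m))
    })
  }

  plant_errors <- function(df, ds) {
    spec <- config$error_rates[[ds]]
    if (is.null(spec)) return(df)
    for (col in names(spec)) {
      if (!col %in% names(df)) next
      if (col %in% c("chi", "presc_id", "sample_id", "rec_id")) {
        abort(sprintf("cannot plant errors on key/identifier column '%s'", col))
      }
      m <- spec[[col]]$missing_rate %||% 0
      w <- spec[[col]]$wrong_rate %||% 0
      u <- stats::runif(nrow(df))
      miss <- u < m
      wrong <- !miss & u < m + w
      df[[col]][miss] <- ""
      if (any(wrong)) {
        bad_value <- switch(col, sex = "X", bnf_code = "ZZZZ", test_code = "ZZZZ",
                            result = "99999",
                            abort(sprintf("no wrong-severity rule for column '%s'", col)))
        df[[col]][wrong] <- bad_value
      }
      prior <- truth$planted[[ds]][[col]] %||% list(missing = 0L, wrong = 0L)
      truth$planted[[ds]][[col]] <<- list(missing = prior$missing + sum(miss),
                                          wrong = prior$wrong + sum(wrong))
    }
    df
  }

  write_feed <- function(df, ds, m_idx, suffix = sprintf("m%02d", m_idx)) {
    d <- drift_for(ds, m_idx)
    path <- file.path(out_dir, sprintf("%s_%s.csv", ds, suffix))
    headerless <- FALSE
    if (!is.null(d) && identical(d$kind, "drop_header")) {
      readr::write_csv(df, path, na = "", col_names = FALSE)
      headerless <- TRUE
    } else {
      if (!is.null(d) && identical(d$kind, "rename_column")) {
        names(df)[names(df) == d$column] <- d$alias %||% toupper(d$column)
      }
      readr::write_csv(df, path, na = "")
    }
    feeds[[length(feeds) + 1L]] <<- tibble(
      dataset = ds, month_index = m_idx, month = months[min(m_idx, config$months)],
      path = path, headerless = headerless, rows = nrow(df), rewrite = grepl("rewrite", suffix))
    path
  }

  # demography: one register feed at month 1
  demo <- tibble(chi = patients$chi, dob = feed_date(patients$dob),
                 sex = patients$sex, postcode = patients$postcode)
  demo <- plant_errors(demo, "demography")
  write_feed(demo, "demography", 1L)

  # event datasets: monthly accrual
  event_ds <- setdiff(ds_names, "demography")
  for (ds in event_ds) {
    for (m_idx in seq_len(config$months)) {
      if (m_idx %in% config$gap_months) {
        df <- event_rows(ds, patients, months[m_idx], m_idx, integer())
      } else {
        who <- which(stats::runif(config$n_patients) < config$event_prob)
        df <- event_rows(ds, patients, months[m_idx], m_idx, who)
      }
      df <- plant_errors(df, ds)
      truth$monthly_rows[[ds]][[months[m_idx]]] <- nrow(df)
      write_feed(df, ds, m_idx)
    }
  }

  # retrospective rewrite feed for demography
  if (config$rewrite_rate > 0 && "demography" %in% ds_names) {
    n_rw <- max(1L, round(config$rewrite_rate * config$n_patients))
    who <- sort(sample.int(config$n_patients, n_rw))
    rw <- demo[who, , drop = FALSE]
    for (k in seq_len(nrow(rw))) {
      old <- rw$postcode[k]
      new <- sprintf("EH%d %d%s%s", sample.int(9, 1), sample.int(9, 1),
                     sample(LETTERS, 1), sample(LETTERS, 1))
      truth$rewrites[[length(truth$rewrites) + 1L]] <-
        list(dataset = "demography", key = rw$chi[k], column = "postcode",
             old = old, new = new, month = config$rewrite_month)
      rw$postcode[k] <- new
    }
    write_feed(rw, "demography", config$rewrite_month,
               suffix = sprintf("rewrite_m%02d", config$rewrite_month))
  }

  feeds <- bind_rows(feeds)
  world <- structure(list(config = config, dir = out_dir, feeds = feeds,
                          months = months, patients = patients,
                          catalogue_doc = bootstrap_catalogue(config),
                          ground_truth = truth),
                     class = "synthetic_world")

  if (config$planted_chi_count > 0) {
    world <- plant_freetext_identifiers(world, config$planted_chi_count)
  }
  world
}

event_rows <- function(ds, patients, month, m_idx, who) {
  n <- length(who)
  days <- if (n) sprintf("%02d", sample.int(28, n, replace = TRUE)) else character()
  event_date <- if (n) feed_date(paste0(month, "-", days)) else character()
  if (ds == "prescriptions") {
    tibble(presc_id = sprintf("P%02d_%04d", m_idx, seq_len(n)),
           chi = patients$chi[who],
           bnf_code = if (n) sample(c("0101", "0205", "0601", "1002"), n, TRUE) else character(),
           event_date = event_date,
           notes = if (n) sample(NOTE_PHRASES, n, TRUE) else character())
  } else if (ds == "biochemistry") {
    tibble(sample_id = sprintf("S%02d_%04d", m_idx, seq_len(n)),
           chi = patients$chi[who],
           test_code = if (n) sample(c("SOD", "K", "CREA", "HBA1C"), n, TRUE) else character(),
           result = if (n) sprintf("%.1f", stats::rlnorm(n, 3, 0.6)) else character(),
           event_date = event_date,
           notes = if (n) sample(NOTE_PHRASES, n, TRUE) else character())
  } else {
    tibble(rec_id = sprintf("%s_%02d_%04d", toupper(ds), m_idx, seq_len(n)),
           chi = patients$chi[who],
           value = if (n) sprintf("%.1f", stats::rlnorm(n, 2, 0.5)) else character(),
           event_date = event_date)
  }
}

#' Embed checksum-valid identifiers in free-text cells
#'
#' Plants `count` checksum-valid 10-digit strings inside `notes` cells of the
#' world's event feeds at recorded locations, emulating patient identifiers
#' leaking into free text. The planted strings are fresh (not patient
#' identifiers) and each passes [chi_checksum_valid()].
#'
#' @param world A `synthetic_world`.
#' @param count Number of identifiers to plant.
#' @return The world, with modified feed files and
#'   `ground_truth$chi_plants` filled in.
#' @export
plant_freetext_identifiers <- function(world, count) {
  if (count == 0) return(world)
  withr::local_seed(world$config$seed + 104729L)
  candidates <- world$feeds[!world$feeds$rewrite, , drop = FALSE]
  cells <- list()
  for (i in seq_len(nrow(candidates))) {
    df <- read_tbl(candidates$path[i])
    if (is.null(df) || !"notes" %in% names(df) || nrow(df) == 0) next
    for (r in seq_len(nrow(df))) {
      cells[[length(cells) + 1L]] <- list(feed = i, row = r)
    }
  }
  if (count > length(cells)) {
    abort(sprintf("cannot plant %d identifiers: only %d free-text cells available",
                  count, length(cells)))
  }
  picks <- cells[sort(sample.int(length(cells), count))]
  used <- world$patients$chi
  by_feed <- split(picks, vapply(picks, function(p) p$feed, numeric(1)))
  for (fi in names(by_feed)) {
    i <- as.integer(fi)
    df <- read_tbl(candidates$path[i])
    for (p in by_feed[[fi]]) {
      repeat {
        stem <- sprintf("%09d", sample.int(999999999L, 1))
        cd <- chi_check_digit(stem)
        if (is.na(cd)) next
        chi <- paste0(stem, cd)
        if (!chi %in% used) break
      }
      used <- c(used, chi)
      df$notes[p$row] <- sprintf("%s ref %s noted", df$notes[p$row], chi)
      world$ground_truth$chi_plants[[length(world$ground_truth$chi_plants) + 1L]] <-
        list(dataset = candidates$dataset[i], month = candidates$month[i],
             path = candidates$path[i], row = p$row, column = "notes", chi = chi)
    }
    readr::write_csv(df, candidates$path[i], na = "")
  }
  world
}

#' Retrieve (or inspect) the demography rewrite feed
#'
#' The rewrite feed re-supplies previously seen primary keys with changed
#' values, emulating retrospective corrections in an upstream system. When
#' `rewrite_rate` is zero an empty feed (header only) is written.
#'
#' @param world A `synthetic_world`.
#' @return List: `path` to the rewrite feed CSV, `keys` rewritten, `month`.
#' @export
emit_rewrite_feed <- function(world) {
  rw <- world$feeds[world$feeds$rewrite, , drop = FALSE]
  if (nrow(rw) == 0) {
    path <- file.path(world$dir, sprintf("demography_rewrite_m%02d.csv",
                                         world$config$rewrite_month))
    write_tbl(world$patients[0, c("chi", "dob", "sex", "postcode")], path)
    return(list(path = path, keys = character(), month = world$config$rewrite_month))
  }
  keys <- vapply(world$ground_truth$rewrites, function(r) r$key, character(1))
  list(path = rw$path[1], keys = keys, month = rw$month_index[1])
}

# ---- bootstrap catalogue ---------------------------------------------------

#' Bootstrap catalogue document for a synthetic world
#'
#' @param config A [world_config()].
#' @return A portable catalogue document (list) importable with
#'   [import_catalogue()]: entries, governance tiers (identifier columns
#'   `Internal` with role `identifier`), validation rules, lookups, load logic
#'   with drift aliases and feed date formats.
#' @export
bootstrap_catalogue <- function(config) {
  mk_item <- function(column_name, semantic_type, description = "",
                      category = "Core", role = "", rules = list(), lookup_id = NULL) {
    list(column_name = column_name, description = description,
         semantic_type = semantic_type, extraction_category = category,
         role = role, validation_rules = rules, lookup_id = lookup_id)
  }
  rule <- function(kind, severity, ...) list(rule_kind = kind, params = list(...),
                                             severity = severity)
  aliases_for <- function(ds) {
    renames <- purrr::keep(config$drift_plan, function(d) {
      identical(d$dataset, ds) && identical(d$kind, "rename_column")
    })
    out <- list()
    for (d in renames) out[[d$alias %||% toupper(d$column)]] <- d$column
    out
  }
  logic <- function(ds, cols) {
    list(header_mapping = aliases_for(ds),
         headerless_column_order = as.list(cols),
         cleaning_steps = list("trim", "null_token_set", "date_parse_formats",
                               "uppercase_codes"),
         date_formats = list("DD/MM/YYYY"))
  }
  chi_item <- mk_item("chi", "code", "patient identifier", "Internal", "identifier",
                      rules = list(rule("regex", "invalidates_row",
                                        pattern = "^[0-9]{10}$")))
  entries <- list()
  ds_names <- world_dataset_names(config)
  nid <- 0L
  add_entry <- function(name, items, pk, edc = NULL, description = "") {
    nid <<- nid + 1L
    entries[[length(entries) + 1L]] <<- list(
      dataset_id = sprintf("D%04d", nid), name = name, description = description,
      primary_key = as.list(pk), event_date_column = edc, items = items,
      load_logic = logic(name, vapply(items, function(i) i$column_name, character(1))),
      issues = list(), documents = list())
  }
  if ("demography" %in% ds_names) {
    add_entry("demography", list(
      chi_item,
      mk_item("dob", "date", "date of birth", "SpecialApprovalRequired"),
      mk_item("sex", "code", "administrative sex",
              rules = list(rule("lookup_membership", "wrong", lookup_id = "sex_codes")),
              lookup_id = "sex_codes"),
      mk_item("postcode", "text", "residential postcode", "Supplemental")),
      pk = "chi", description = "patient demography register")
  }
  if ("prescriptions" %in% ds_names) {
    add_entry("prescriptions", list(
      mk_item("presc_id", "text", "prescription id"),
      chi_item,
      mk_item("bnf_code", "code", "drug classification code",
              rules = list(rule("lookup_membership", "wrong", lookup_id = "drug_codes")),
              lookup_id = "drug_codes"),
      mk_item("event_date", "date", "prescribing date"),
      mk_item("notes", "text", "free-text dispensing notes")),
      pk = "presc_id", edc = "event_date", description = "community prescribing events")
  }
  if ("biochemistry" %in% ds_names) {
    add_entry("biochemistry", list(
      mk_item("sample_id", "text", "laboratory sample id"),
      chi_item,
      mk_item("test_code", "code", "laboratory test code",
              rules = list(rule("lookup_membership", "wrong", lookup_id = "test_codes")),
              lookup_id = "test_codes"),
      mk_item("result", "decimal", "numeric result",
              rules = list(rule("bounds", "wrong", lower = 0, upper = 1000))),
      mk_item("event_date", "date", "sample date"),
      mk_item("notes", "text", "free-text laboratory comment")),
      pk = "sample_id", edc = "event_date", description = "laboratory biochemistry results")
  }
  for (ds in grep("^extra_", ds_names, value = TRUE)) {
    add_entry(ds, list(
      mk_item("rec_id", "text", "record id"),
      chi_item,
      mk_item("value", "decimal", "measurement value"),
      mk_item("event_date", "date", "event date")),
      pk = "rec_id", edc = "event_date", description = "auxiliary event dataset")
  }
  lookups <- list(
    sex_codes = list(lookup_id = "sex_codes", code_column = "code",
                     description_column = "description",
                     rows = list(F = "female", M = "male")),
    drug_codes = list(lookup_id = "drug_codes", code_column = "code",
                      description_column = "description",
                      rows = list(`0101` = "antacids", `0205` = "antihypertensives",
                                  `0601` = "insulins", `1002` = "muscle relaxants")),
    test_codes = list(lookup_id = "test_codes", code_column = "code",
                      description_column = "description",
                      rows = list(SOD = "sodium", K = "potassium",
                                  CREA = "creatinine", HBA1C = "glycated haemoglobin")))
  used <- c("sex_codes", "drug_codes", "test_codes")
  list(schema_version = CATALOGUE_SCHEMA_VERSION, entries = entries,
       lookups = lookups[intersect(used, names(lookups))])
}

# ---- loading helpers -------------------------------------------------------

#' Deterministic load times for a world's feeds
#'
#' Month `k` feeds load on the first day of month `k + 1`; a rewrite feed
#' loads one hour after that month's regular feeds.
#'
#' @param world A `synthetic_world`.
#' @return The world's feeds tibble with a `load_time` column, in load order.
#' @export
world_load_schedule <- function(world) {
  feeds <- world$feeds
  base <- as.Date(paste0(world$config$start_month, "-01"))
  lt <- vapply(seq_len(nrow(feeds)), function(i) {
    m <- feeds$month_index[i]
    day1 <- seq(base, by = "month", length.out = m + 1)[m + 1]
    off <- if (feeds$rewrite[i]) 3600 else 0
    format_ts(as.POSIXct(paste0(format(day1), " 00:00:00"), tz = "UTC") + off)
  }, character(1))
  feeds$load_time <- lt
  feeds[order(feeds$load_time, feeds$dataset), , drop = FALSE]
}

#' Import a world's catalogue and load all its feeds
#'
#' @param store A `dm_store`.
#' @param world A `synthetic_world`.
#' @param up_to_month Only load feeds with `month_index <=` this (default all).
#' @return Tibble of completed load jobs (one row per feed).
#' @export
load_world <- function(store, world, up_to_month = Inf) {
  existing <- list_datasets(store)$name
  todo <- setdiff(vapply(world$catalogue_doc$entries, function(e) e$name, character(1)),
                  existing)
  if (length(todo)) {
    doc <- world$catalogue_doc
    doc$entries <- purrr::keep(doc$entries, function(e) e$name %in% todo)
    import_catalogue(store, doc)
  }
  sched <- world_load_schedule(world)
  sched <- sched[sched$month_index <= up_to_month, , drop = FALSE]
  # incremental: skip feeds at or before each dataset's latest load time
  jobs_done <- read_jobs(store)
  if (nrow(jobs_done) > 0 && nrow(sched) > 0) {
    name_by_id <- stats::setNames(list_datasets(store)$name, list_datasets(store)$dataset_id)
    done <- jobs_done[jobs_done$stage == "LIVE" & !is.na(jobs_done$load_time), , drop = FALSE]
    if (nrow(done) > 0) {
      latest <- tapply(done$load_time, name_by_id[done$dataset_id], max)
      keep <- vapply(seq_len(nrow(sched)), function(i) {
        lt <- latest[[sched$dataset[i]]]
        is.null(lt) || is.na(lt) || sched$load_time[i] > lt
      }, logical(1))
      sched <- sched[keep, , drop = FALSE]
    }
  }
  jobs <- purrr::map(seq_len(nrow(sched)), function(i) {
    run_load(store, sched$dataset[i], sched$path[i], load_time = sched$load_time[i])
  })
  purrr::map_dfr(jobs, function(j) as_tibble(j[c("job_id", "dataset_id", "stage",
                                                 "raw_row_count", "staged_row_count",
                                                 "rejected_row_count", "inserted_count",
                                                 "updated_count", "unchanged_count",
                                                 "load_time")]))
}
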