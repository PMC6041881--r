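# Data quality: evaluate catalogue validation rules over live data and build
# summary aggregates. The eight-dimension quality vocabulary maps onto
# computable metrics as: accuracy = rule conformance, completeness = null
# rate, consistency = lookup membership (a rule kind), timeliness = load
# recency, uniqueness = duplicate primary keys. Accessibility and access
# security are organisational and carried only as report metadata flags.

event_month <- function(dates) {
  out <- rep("undated", length(dates))
  ok <- !is.na(dates) & grepl("^\\d{4}-\\d{2}", dates)
  out[ok] <- substr(dates[ok], 1, 7)
  out
}

classify_column <- function(values, item, store) {
  cls <- rep("correct", length(values))
  cls[is.na(values)] <- "missing"
  for (rule in item$validation_rules) {
    if (identical(rule$severity, "invalidates_row")) next  # cannot reach live
    bad <- rule_violations(values, rule, store)
    hit <- bad & cls == "correct"
    cls[hit] <- rule$severity
  }
  cls
}

#' Evaluate data quality for a dataset
#'
#' Classifies every cell of the live table as correct, missing (null after
#' cleaning, or violating a rule of severity `missing`) or wrong (violating a
#' rule of severity `wrong`), per column and — when the dataset declares an
#' event-date column — per calendar month. The partition
#' `correct + missing + wrong = n` holds for every column and every period.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name.
#' @return A `quality_report`: list with `per_column` and `per_month` tibbles,
#'   `uniqueness` (duplicate primary-key count), `timeliness_days` (days since
#'   the last successful load), `row_count` and metadata flags.
#' @export
evaluate_quality <- function(store, dataset) {
  entry <- get_entry(store, dataset)
  live <- live_table(store, dataset)
  n <- nrow(live)
  cols <- entry_columns(entry)

  cls_by_col <- lapply(entry$items, function(it) classify_column(live[[it$column_name]], it, store))
  names(cls_by_col) <- cols

  per_column <- purrr::map_dfr(cols, function(col) {
    cls <- cls_by_col[[col]]
    tibble(column = col,
           correct = sum(cls == "correct"),
           missing = sum(cls == "missing"),
           wrong = sum(cls == "wrong"))
  })

  per_month <- NULL
  edc <- entry$event_date_column
  if (!is.null(edc) && n > 0) {
    months <- event_month(live[[edc]])
    per_month <- purrr::map_dfr(cols, function(col) {
      cls <- cls_by_col[[col]]
      tb <- tibble(month = months, cls = cls) |>
        group_by(.data$month) |>
        summarise(correct = sum(.data$cls == "correct"),
                  missing = sum(.data$cls == "missing"),
                  wrong = sum(.data$cls == "wrong"), .groups = "drop")
      tb$column <- col
      tb[, c("column", "month", "correct", "missing", "wrong")]
    })
  }

  jobs <- load_history(store, dataset)
  ok_times <- jobs$load_time[jobs$stage == "LIVE" & !is.na(jobs$load_time)]
  timeliness <- if (length(ok_times)) {
    as.numeric(difftime(Sys.time(), max(parse_ts(ok_times)), units = "days"))
  } else NA_real_

  pk <- unlist(entry$primary_key)
  dup_pk <- if (n > 0) sum(duplicated(row_keys(live, pk))) else 0L

  structure(list(
    dataset_id = entry$dataset_id, dataset = entry$name,
    generated_at = ts_now(), row_count = n,
    per_column = per_column, per_month = per_month,
    uniqueness_duplicate_pk = dup_pk,
    timeliness_days_since_load = timeliness,
    accessibility = "managed-store", access_security = "file-permissions"
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> ", x$dataset, " (", x$row_count, " rows)\n", sep = "")
  print(x$per_column)
  cat("duplicate primary keys:", x$uniqueness_duplicate_pk, "\n")
  invisible(x)
}

#' Export a quality report to JSON and CSV
#'
#' @param report A `quality_report`.
#' @param dir Output directory; writes `quality_report.json` and
#'   `quality_per_column.csv`.
#' @return Invisibly, the paths written.
#' @export
export_quality_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jpath <- file.path(dir, "quality_report.json")
  payload <- unclass(report)
  payload$per_column <- purrr::transpose(as.list(report$per_column))
  payload$per_month <- if (is.null(report$per_month)) NULL else
    purrr::transpose(as.list(report$per_month))
  write_json_file(payload, jpath)
  cpath <- file.path(dir, "quality_per_column.csv")
  write_tbl(report$per_column, cpath)
  invisible(c(jpath, cpath))
}

#' Build a summary aggregate
#'
#' Groups live records by the values of a column, or by calendar month of the
#' event-date column when `dimension = "month"`. Cells always sum to the live
#' row count; null values fall into a `"(missing)"` cell and rows without an
#' event date into `"undated"`.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name.
#' @param dimension Column name, or `"month"`.
#' @return Tibble with columns `value` and `records`.
#' @export
build_summary_aggregate <- function(store, dataset, dimension) {
  entry <- get_entry(store, dataset)
  live <- live_table(store, dataset)
  cfg <- store_config(store)
  if (identical(dimension, "month")) {
    edc <- entry$event_date_column
    if (is.null(edc)) abort(sprintf("dataset '%s' has no event_date_column", entry$name))
    key <- event_month(live[[edc]])
  } else {
    if (!dimension %in% entry_columns(entry)) {
      abort(sprintf("dataset '%s' has no column '%s'", entry$name, dimension))
    }
    key <- live[[dimension]]
    key[is.na(key)] <- "(missing)"
  }
  if (length(unique(key)) > cfg$summary_cardinality_limit) {
    abort(sprintf(paste0("column '%s' has %d distinct values, above the summary limit ",
                         "of %d; aggregate a coded or date dimension instead"),
                  dimension, length(unique(key)), cfg$summary_cardinality_limit))
  }
  if (length(key) == 0) return(tibble(value = character(), records = integer()))
  tibble(value = key) |>
    group_by(.data$value) |>
    summarise(records = n(), .groups = "drop") |>
    arrange(.data$value)
}

#' Monthly quality timeline
#'
#' Totals the correct/missing/wrong classification per calendar month of the
#' event-date column, zero-filling months with no events so that gaps in
#' accrual are visible. Optionally writes a chart.
#'
#' @param store A `dm_store`.
#' @param dataset Dataset id or name (must declare an event-date column).
#' @param chart_path Optional path for a PNG/SVG chart of the series.
#' @return List with `series` (tibble `month`, `correct`, `missing`, `wrong`,
#'   `records`) and `plot` (a ggplot object).
#' @export
render_quality_timeline <- function(store, dataset, chart_path = NULL) {
  entry <- get_entry(store, dataset)
  if (is.null(entry$event_date_column)) {
    abort(sprintf("dataset '%s' has no event_date_column; timeline unavailable", entry$name))
  }
  rep <- evaluate_quality(store, dataset)
  if (is.null(rep$per_month) || nrow(rep$per_month) == 0) {
    series <- tibble(month = character(), correct = integer(),
                     missing = integer(), wrong = integer(), records = integer())
  } else {
    totals <- rep$per_month |>
      group_by(.data$month) |>
      summarise(correct = sum(.data$correct), missing = sum(.data$missing),
                wrong = sum(.data$wrong), .groups = "drop")
    dated <- totals[totals$month != "undated", , drop = FALSE]
    if (nrow(dated) > 0) {
      rng <- range(as.Date(paste0(dated$month, "-01")))
      all_months <- format(seq(rng[1], rng[2], by = "month"), "%Y-%m")
      grid <- tibble(month = all_months)
      dated <- left_join(grid, dated, by = "month")
      dated[is.na(dated)] <- 0L
    }
    series <- bind_rows(dated, totals[totals$month == "undated", , drop = FALSE])
    ncols <- max(1L, length(entry_columns(entry)))
    series$records <- as.integer((series$correct + series$missing + series$wrong) / ncols)
  }
  plt <- NULL
  if (nrow(series) > 0) {
    long <- tidyr::pivot_longer(series[, c("month", "correct", "missing", "wrong")],
                                -"month", names_to = "class", values_to = "cells")
    plt <- ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$cells,
                                              fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "event month", y = "cells",
                    title = sprintf("Quality timeline: %s", entry$name)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  }
  if (!is.null(chart_path) && !is.null(plt)) {
    ggplot2::ggsave(chart_path, plt, width = 8, height = 4, dpi = 120)
  }
  list(series = series, plot = plt)
}
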