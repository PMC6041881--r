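# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain, brute-force R, separate from the package's implementation paths.

tmp_store <- function() dm_store(withr::local_tempdir(.local_envir = parent.frame()))

write_feed_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame()),
                           name = "feed.csv") {
  path <- file.path(dir, name)
  readr::write_csv(df, path, na = "")
  path
}

# A minimal single-dataset catalogue used across load/quality tests:
# patients(id, sbp, visit_date, code_col) keyed on id.
register_patients <- function(store, event_date = "visit_date") {
  register_dataset(store, "patients",
                   c(id = "text", sbp = "integer", visit_date = "date", clinic = "code"),
                   primary_key = "id", event_date_column = event_date)
  set_load_logic(store, "patients",
                 header_mapping = c(ID = "id", BP = "sbp"),
                 headerless_column_order = c("id", "sbp", "visit_date", "clinic"),
                 cleaning_steps = c("trim", "null_token_set", "date_parse_formats",
                                    "uppercase_codes"),
                 date_formats = "DD/MM/YYYY")
  set_identifier_column(store, "patients", "id")
  invisible(store)
}

# --- independent modulus-11 oracle -----------------------------------------

chi_oracle <- function(s) {
  d <- as.integer(strsplit(s, "")[[1]])
  total <- 0L
  for (i in 1:9) total <- total + d[i] * (11L - i)
  chk <- 11L - (total %% 11L)
  if (chk == 11L) chk <- 0L
  if (chk == 10L) return(FALSE)
  d[10] == chk
}

# --- brute-force bitemporal replay oracle -----------------------------------

# Replays cleaned feed data frames (in load order) up to time t with a simple
# keyed-environment upsert, returning the expected table.
replay_oracle <- function(feeds, load_times, t, pk) {
  state <- list()
  tt <- as.POSIXct(t, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (i in seq_along(feeds)) {
    lt <- as.POSIXct(load_times[i], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    if (lt > tt) break
    df <- feeds[[i]]
    for (r in seq_len(nrow(df))) {
      key <- paste(unlist(df[r, pk]), collapse = "|")
      state[[key]] <- df[r, , drop = FALSE]
    }
  }
  if (length(state) == 0) return(NULL)
  out <- do.call(rbind, state[sort(names(state))])
  rownames(out) <- NULL
  out
}

# --- brute-force cohort set-algebra oracle ----------------------------------

oracle_block_ids <- function(tbl, idcol, block) {
  v <- tbl[[block$column]]
  p <- block$params
  keep <- switch(block$predicate,
    equals = !is.na(v) & v == p$value,
    in_set = !is.na(v) & v %in% unlist(p$values),
    between = {
      n <- suppressWarnings(as.numeric(v))
      !is.na(n) & n >= p$lower & n <= p$upper
    },
    matches_regex = !is.na(v) & grepl(p$pattern, v),
    before = !is.na(v) & as.Date(v) < as.Date(p$date),
    after = !is.na(v) & as.Date(v) > as.Date(p$date))
  keep
}

oracle_container_mask <- function(tbl, idcol, cont) {
  masks <- lapply(cont$children, function(ch) {
    if (identical(ch$node, "filter")) oracle_block_ids(tbl, idcol, ch)
    else oracle_container_mask(tbl, idcol, ch)
  })
  Reduce(if (cont$mode == "AND") `&` else `|`, masks)
}

oracle_eval_tree <- function(node, tables, idcols) {
  if (identical(node$node, "leaf")) {
    tbl <- tables[[node$dataset]]
    mask <- oracle_container_mask(tbl, idcols[[node$dataset]], node$container)
    return(sort(unique(tbl[[idcols[[node$dataset]]]][mask])))
  }
  sets <- lapply(node$children, oracle_eval_tree, tables = tables, idcols = idcols)
  out <- switch(node$op,
    UNION = Reduce(union, sets),
    INTERSECT = Reduce(intersect, sets),
    EXCEPT = setdiff(sets[[1]], sets[[2]]))
  sort(unique(out))
}

# random definition trees over named toy datasets
random_tree <- function(datasets, columns_by_ds, depth = 0) {
  if (depth >= 2 || stats::runif(1) < 0.4) {
    ds <- sample(datasets, 1)
    cols <- columns_by_ds[[ds]]
    mk_block <- function() {
      col <- sample(names(cols), 1)
      if (cols[[col]] == "num") {
        lo <- sample(0:50, 1)
        filter_block(col, "between", lower = lo, upper = lo + sample(10:60, 1))
      } else {
        filter_block(col, sample(c("equals", "in_set"), 1),
                     value = sample(cols[[col]]$values, 1),
                     values = sample(cols[[col]]$values, 2))
      }
    }
    nblk <- sample(1:3, 1)
    blocks <- replicate(nblk, mk_block(), simplify = FALSE)
    cont <- do.call(filter_container, c(list(sample(c("AND", "OR"), 1)), blocks))
    return(cohort_leaf(ds, cont))
  }
  op <- sample(c("UNION", "INTERSECT", "EXCEPT"), 1)
  nch <- if (op == "EXCEPT") 2 else sample(2:3, 1)
  kids <- replicate(nch, random_tree(datasets, columns_by_ds, depth + 1), simplify = FALSE)
  do.call(cohort_op, c(list(op), kids))
}

# toy datasets for cohort oracle tests: three event tables sharing ids
build_toy_cohort_store <- function(store, seed = 1, n_ids = 30) {
  withr::local_seed(seed)
  ids <- sprintf("PT%03d", seq_len(n_ids))
  specs <- list(
    alpha = tibble::tibble(id = sample(ids, 40, TRUE),
                           age = as.character(sample(20:90, 40, TRUE)),
                           sex = sample(c("F", "M"), 40, TRUE)),
    beta = tibble::tibble(id = sample(ids, 35, TRUE),
                          score = as.character(sample(0:100, 35, TRUE)),
                          grp = sample(c("A", "B", "C"), 35, TRUE)),
    gamma = tibble::tibble(id = sample(ids, 25, TRUE),
                           level = as.character(sample(0:60, 25, TRUE)),
                           site = sample(c("N", "S"), 25, TRUE)))
  tables <- list()
  for (nm in names(specs)) {
    df <- specs[[nm]]
    df$rowid <- sprintf("%s_%03d", nm, seq_len(nrow(df)))
    cols <- c(rowid = "text", id = "code",
              stats::setNames(rep("text", ncol(df) - 2), setdiff(names(df), c("rowid", "id"))))
    register_dataset(store, nm, cols, primary_key = "rowid")
    set_identifier_column(store, nm, "id")
    path <- write_feed_csv(df[, names(cols)], name = paste0(nm, ".csv"))
    run_load(store, nm, path, load_time = paste0("2020-01-0", match(nm, names(specs)),
                                                 "T00:00:00Z"))
    tables[[nm]] <- df
  }
  tables
}

toy_columns_spec <- list(
  alpha = list(age = "num", sex = list(values = c("F", "M"))),
  beta = list(score = "num", grp = list(values = c("A", "B", "C"))),
  gamma = list(level = "num", site = list(values = c("N", "S"))))
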