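test_that("ingest resolves renamed and headerless feeds and digests raw bytes", {
  st <- tmp_store()
  register_patients(st)
  # renamed columns resolved through the header mapping
  p1 <- write_feed_csv(tibble::tibble(ID = "a1", BP = "120",
                                      visit_date = "01/02/2003", clinic = "ww"))
  job <- ingest_file(st, "patients", p1)
  expect_equal(job$stage, "RAW")
  expect_equal(job$raw_row_count, 1)
  expect_equal(job$file_digest, unname(tools::md5sum(p1)))

  # headerless feed falls back to the declared column order
  d <- withr::local_tempdir()
  writeLines("a2,130,2003-05-06,nw", file.path(d, "nohead.csv"))
  job2 <- ingest_file(st, "patients", file.path(d, "nohead.csv"))
  expect_equal(job2$raw_row_count, 1)
  raw2 <- cohortvault:::read_tbl(file.path(st$path, "raw", paste0(job2$job_id, ".csv")))
  expect_named(raw2, c("id", "sbp", "visit_date", "clinic"))

  # empty file: degenerate but not fatal
  writeLines(character(), file.path(d, "empty.csv"))
  job3 <- ingest_file(st, "patients", file.path(d, "empty.csv"))
  expect_equal(job3$stage, "RAW")
  expect_equal(job3$raw_row_count, 0)
  expect_true(any(load_log(st, job3$job_id)$level == "warning"))

  expect_error(ingest_file(st, "nope", p1), "unknown dataset")
})

test_that("a feed with unresolvable columns fails with a fatal log entry", {
  st <- tmp_store()
  register_dataset(st, "norescue", c(a = "text", b = "text"), "a")
  p <- write_feed_csv(tibble::tibble(mystery1 = "x", mystery2 = "y"))
  job <- ingest_file(st, "norescue", p)
  expect_equal(job$stage, "FAILED")
  expect_true(any(load_log(st, job$job_id)$level == "fatal"))
})

test_that("staging cleans in order, rejects invalid rows and conserves counts", {
  st <- tmp_store()
  register_patients(st)
  set_store_config(st, reject_threshold = 0.6)
  attach_validation_rule(st, "patients", "sbp",
                         validation_rule("bounds", "invalidates_row",
                                         lower = 0, upper = 300))
  feed <- tibble::tibble(
    id = c(" a1 ", "a2", "a3", "a2", "a5", NA),
    sbp = c("120", "999", "NULL", "101", "102", "103"),
    visit_date = c("01/02/2003", "02/02/2003", "2003-02-03", "04/02/2003",
                   "05/02/2003", "06/02/2003"),
    clinic = c("ww", "nw", "se", "se", "se", "se"))
  p <- write_feed_csv(feed)
  job <- validate_and_stage(st, ingest_file(st, "patients", p))
  # a2 duplicate, sbp=999 out of bounds (same row), null id rejected
  expect_equal(job$raw_row_count, 6)
  expect_equal(job$staged_row_count + job$rejected_row_count, job$raw_row_count)
  expect_equal(job$rejected_row_count, 3)
  staged <- cohortvault:::read_tbl(file.path(st$path, "staging",
                                             paste0(job$job_id, ".csv")))
  expect_equal(staged$id[1], "a1")                       # trimmed
  expect_equal(staged$visit_date[1], "2003-02-01")       # DD/MM/YYYY parsed
  expect_equal(staged$clinic, c("WW", "SE", "SE"))       # codes upper-cased
  expect_true(is.na(staged$sbp[staged$id == "a3"]))      # NULL token
})

test_that("staging aborts when the rejected fraction exceeds the threshold", {
  st <- tmp_store()
  register_patients(st)
  attach_validation_rule(st, "patients", "sbp",
                         validation_rule("bounds", "invalidates_row",
                                         lower = 0, upper = 300))
  feed <- tibble::tibble(id = sprintf("a%d", 1:10),
                         sbp = c(rep("999", 2), rep("120", 8)),
                         visit_date = rep("2003-01-01", 10), clinic = rep("x", 10))
  job <- validate_and_stage(st, ingest_file(st, "patients", write_feed_csv(feed)))
  expect_equal(job$stage, "FAILED")
  expect_true(any(grepl("threshold", load_log(st, job$job_id)$message)))
  hist <- load_history(st, "patients")
  expect_equal(hist$stage[nrow(hist)], "FAILED")
})

test_that("merge to live upserts, archives superseded rows and is idempotent", {
  st <- tmp_store()
  register_patients(st)
  f1 <- tibble::tibble(id = sprintf("a%d", 1:5), sbp = as.character(100 + 1:5),
                       visit_date = rep("2003-01-01", 5), clinic = rep("WW", 5))
  p1 <- write_feed_csv(f1, name = "f1.csv")
  j1 <- run_load(st, "patients", p1, load_time = "2020-01-01T00:00:00Z")
  expect_equal(j1$inserted_count, 5)
  expect_equal(j1$updated_count, 0)
  expect_equal(nrow(cohortvault:::read_archive(st, cohortvault:::get_entry(st, "patients"))), 0)

  # reloading the identical file changes nothing
  j2 <- run_load(st, "patients", p1, load_time = "2020-02-01T00:00:00Z")
  expect_equal(j2$inserted_count, 0)
  expect_equal(j2$updated_count, 0)
  expect_equal(j2$unchanged_count, 5)

  # one changed value: archived old row with valid_to = load time
  f2 <- f1; f2$sbp[3] <- "140"
  j3 <- run_load(st, "patients", write_feed_csv(f2, name = "f2.csv"),
                 load_time = "2020-03-01T00:00:00Z")
  expect_equal(j3$updated_count, 1)
  arch <- cohortvault:::read_archive(st, cohortvault:::get_entry(st, "patients"))
  expect_equal(nrow(arch), 1)
  expect_equal(arch$.valid_to, "2020-03-01T00:00:00Z")
  expect_equal(arch$sbp, "103")

  # monotonic load clock
  expect_error(run_load(st, "patients", p1, load_time = "2020-02-15T00:00:00Z"),
               "not after")
  hist <- load_history(st, "patients")
  expect_equal(sum(hist$stage == "LIVE"), 3)
})

test_that("as-at reconstruction matches live now and old values in between", {
  st <- tmp_store()
  register_patients(st)
  f1 <- tibble::tibble(id = c("a1", "a2"), sbp = c("100", "110"),
                       visit_date = rep("2003-01-01", 2), clinic = rep("WW", 2))
  f2 <- f1; f2$sbp[1] <- "150"
  run_load(st, "patients", write_feed_csv(f1, name = "v1.csv"),
           load_time = "2020-01-01T00:00:00Z")
  run_load(st, "patients", write_feed_csv(f2, name = "v2.csv"),
           load_time = "2020-03-01T00:00:00Z")

  expect_equal(nrow(reconstruct_as_at(st, "patients", "2019-12-31T23:59:59Z")), 0)
  expect_identical(reconstruct_as_at(st, "patients", "2021-01-01T00:00:00Z"),
                   live_table(st, "patients"))
  mid <- reconstruct_as_at(st, "patients", "2020-02-01T00:00:00Z")
  expect_equal(mid$sbp[mid$id == "a1"], "100")
})

test_that("randomized load sequences agree with the brute-force replay oracle", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      st <- tmp_store()
      register_dataset(st, "ds", c(k = "text", v = "text", w = "text"), "k")
      n_loads <- sample(2:4, 1)
      keys_pool <- sprintf("k%02d", 1:8)
      feeds <- list(); times <- character()
      d <- withr::local_tempdir()
      for (i in seq_len(n_loads)) {
        keys <- sort(sample(keys_pool, sample(3:8, 1)))
        df <- tibble::tibble(k = keys,
                             v = as.character(sample(100, length(keys))),
                             w = sample(letters, length(keys), TRUE))
        t_i <- sprintf("2020-%02d-01T00:00:00Z", i)
        path <- file.path(d, sprintf("f%d.csv", i))
        readr::write_csv(df, path, na = "")
        job <- run_load(st, "ds", path, load_time = t_i)
        expect_equal(job$staged_row_count + job$rejected_row_count, job$raw_row_count)
        expect_equal(job$inserted_count + job$updated_count + job$unchanged_count,
                     job$staged_row_count)
        feeds[[i]] <- as.data.frame(df); times[i] <- t_i
      }
      for (probe in c("2019-06-01T00:00:00Z",
                      sprintf("2020-%02d-15T00:00:00Z", seq_len(n_loads)))) {
        got <- as.data.frame(reconstruct_as_at(st, "ds", probe))
        want <- replay_oracle(feeds, times, probe, "k")
        if (is.null(want)) expect_equal(nrow(got), 0)
        else expect_equal(got, want, ignore_attr = TRUE)
      }
    })
  }
})

test_that("archive validity intervals are ordered and non-overlapping per key", {
  st <- tmp_store()
  register_dataset(st, "ds", c(k = "text", v = "text"), "k")
  d <- withr::local_tempdir()
  for (i in 1:4) {
    df <- tibble::tibble(k = "only", v = as.character(i))
    path <- file.path(d, sprintf("f%d.csv", i))
    readr::write_csv(df, path, na = "")
    run_load(st, "ds", path, load_time = sprintf("2020-0%d-01T00:00:00Z", i))
  }
  arch <- cohortvault:::read_archive(st, cohortvault:::get_entry(st, "ds"))
  expect_equal(nrow(arch), 3)
  from <- cohortvault:::parse_ts(arch$.valid_from)
  to <- cohortvault:::parse_ts(arch$.valid_to)
  expect_true(all(from < to))
  o <- order(from)
  expect_true(all(to[o][-3] <= from[o][-1]))
})

test_that("tombstone loads archive rows without replacement", {
  st <- tmp_store()
  register_dataset(st, "ds", c(k = "text", v = "text"), "k")
  d <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(k = c("x", "y"), v = c("1", "2")),
                   file.path(d, "f1.csv"), na = "")
  run_load(st, "ds", file.path(d, "f1.csv"), load_time = "2020-01-01T00:00:00Z")
  readr::write_csv(tibble::tibble(k = "x", v = "1"), file.path(d, "del.csv"), na = "")
  job <- ingest_file(st, "ds", file.path(d, "del.csv"))
  job <- validate_and_stage(st, job)
  job <- merge_to_live(st, job, load_time = "2020-02-01T00:00:00Z", mode = "tombstone")
  expect_equal(nrow(live_table(st, "ds")), 1)
  expect_equal(live_table(st, "ds")$k, "y")
  expect_equal(reconstruct_as_at(st, "ds", "2020-01-15T00:00:00Z")$k, c("x", "y"))
})
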