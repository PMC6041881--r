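test_that("identical seeds generate byte-identical worlds", {
  td <- withr::local_tempdir()
  cfg <- world_config(seed = 55, n_patients = 15, months = 3,
                      planted_chi_count = 2, rewrite_rate = 0.2)
  w1 <- generate_world(cfg, file.path(td, "a"))
  w2 <- generate_world(cfg, file.path(td, "b"))
  expect_equal(basename(w1$feeds$path), basename(w2$feeds$path))
  for (i in seq_len(nrow(w1$feeds))) {
    f1 <- w1$feeds$path[i]; f2 <- w2$feeds$path[i]
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  w3 <- generate_world(world_config(seed = 56, n_patients = 15, months = 3),
                       file.path(td, "c"))
  expect_false(identical(readLines(w1$feeds$path[1]), readLines(w3$feeds$path[1])))
})

test_that("ground-truth planted counts equal an independent recount of the files", {
  td <- withr::local_tempdir()
  cfg <- world_config(seed = 60, n_patients = 100, months = 2,
                      error_rates = list(
                        biochemistry = list(result = list(missing_rate = 0.07,
                                                          wrong_rate = 0.05))))
  w <- generate_world(cfg, td)
  bio_files <- w$feeds$path[w$feeds$dataset == "biochemistry"]
  n_missing <- 0L; n_wrong <- 0L; n_rows <- 0L
  for (f in bio_files) {
    df <- utils::read.csv(f, colClasses = "character")
    n_rows <- n_rows + nrow(df)
    n_missing <- n_missing + sum(df$result == "")
    n_wrong <- n_wrong + sum(df$result == "99999")
  }
  gt <- w$ground_truth$planted$biochemistry$result
  expect_equal(gt$missing, n_missing)
  expect_equal(gt$wrong, n_wrong)
  expect_equal(sum(unlist(w$ground_truth$monthly_rows$biochemistry)), n_rows)
})

test_that("drift plan renames headers and drops them on schedule", {
  td <- withr::local_tempdir()
  cfg <- world_config(seed = 61, n_patients = 10, months = 3,
                      drift_plan = list(
                        list(month = 2L, dataset = "prescriptions",
                             kind = "rename_column", column = "bnf_code",
                             alias = "BNFCode"),
                        list(month = 3L, dataset = "prescriptions",
                             kind = "drop_header")))
  w <- generate_world(cfg, td)
  h1 <- readLines(w$feeds$path[w$feeds$dataset == "prescriptions" &
                                 w$feeds$month_index == 1][1], n = 1)
  h2 <- readLines(w$feeds$path[w$feeds$dataset == "prescriptions" &
                                 w$feeds$month_index == 2][1], n = 1)
  expect_match(h1, "bnf_code")
  expect_match(h2, "BNFCode")
  expect_true(w$feeds$headerless[w$feeds$dataset == "prescriptions" &
                                   w$feeds$month_index == 3])
  # and the bootstrap catalogue still loads all three shapes cleanly
  st <- tmp_store()
  jobs <- load_world(st, w)
  expect_true(all(jobs$stage == "LIVE"))
  expect_equal(sum(jobs$rejected_row_count), 0)
})

test_that("planted identifiers all pass the checksum and are found end to end", {
  td <- withr::local_tempdir()
  cfg <- world_config(seed = 62, n_patients = 20, months = 2,
                      planted_chi_count = 5)
  w <- generate_world(cfg, td)
  plants <- w$ground_truth$chi_plants
  expect_length(plants, 5)
  expect_true(all(chi_checksum_valid(vapply(plants, function(p) p$chi, character(1)))))
  # scanning the free-text column locates exactly the planted cells
  found <- list()
  for (f in unique(vapply(plants, function(p) p$path, character(1)))) {
    tb <- cohortvault:::read_tbl(f)
    hits <- scan_for_chi(tb[, "notes", drop = FALSE])
    for (k in seq_len(nrow(hits))) {
      found[[length(found) + 1L]] <- paste(basename(f), hits$row[k], hits$match[k])
    }
  }
  want <- vapply(plants, function(p) paste(basename(p$path), p$row, p$chi), character(1))
  expect_setequal(unlist(found), want)

  # planting zero identifiers leaves the free text clean
  cfg0 <- world_config(seed = 62, n_patients = 20, months = 2, planted_chi_count = 0)
  w0 <- generate_world(cfg0, file.path(td, "zero"))
  clean_feeds <- w0$feeds$path[w0$feeds$dataset != "demography"]
  clean_hits <- sum(vapply(clean_feeds, function(f) {
    tb <- cohortvault:::read_tbl(f)
    if (is.null(tb) || !"notes" %in% names(tb) || nrow(tb) == 0) return(0)
    nrow(scan_for_chi(tb[, "notes", drop = FALSE]))
  }, numeric(1)))
  expect_equal(clean_hits, 0)

  # infeasible plant counts are rejected
  tiny <- world_config(seed = 63, n_patients = 2, months = 1,
                       planted_chi_count = 500, event_prob = 0.5)
  expect_error(generate_world(tiny, file.path(td, "tiny")), "cannot plant")
})

test_that("generated patient identifiers are unique, checksum-valid and dated", {
  td <- withr::local_tempdir()
  w <- generate_world(world_config(seed = 64, n_patients = 50, months = 1), td)
  chis <- w$patients$chi
  expect_false(any(duplicated(chis)))
  expect_true(all(chi_checksum_valid(chis)))
  expect_identical(substr(chis, 1, 6), format(as.Date(w$patients$dob), "%d%m%y"))
})

test_that("the rewrite feed re-supplies known keys and as-at hides the rewrite", {
  td <- withr::local_tempdir()
  cfg <- world_config(seed = 65, n_patients = 20, months = 3,
                      rewrite_rate = 0.2, rewrite_month = 3L)
  w <- generate_world(cfg, td)
  rw <- emit_rewrite_feed(w)
  expect_length(rw$keys, 4)
  st <- tmp_store()
  jobs <- load_world(st, w)
  demo_jobs <- jobs[jobs$dataset_id == "D0001", ]
  expect_equal(demo_jobs$updated_count[nrow(demo_jobs)], length(rw$keys))

  # before the rewrite load, old values; after, new values
  pre <- reconstruct_as_at(st, "demography", "2016-03-01T00:00:00Z")
  post <- live_table(st, "demography")
  for (r in w$ground_truth$rewrites) {
    expect_equal(pre$postcode[pre$chi == r$key], r$old)
    expect_equal(post$postcode[post$chi == r$key], r$new)
  }

  # rewrite_rate zero yields an empty feed
  w0 <- generate_world(world_config(seed = 65, n_patients = 5, months = 1),
                       file.path(td, "zero"))
  rw0 <- emit_rewrite_feed(w0)
  expect_length(rw0$keys, 0)
  expect_equal(nrow(cohortvault:::read_tbl(rw0$path)), 0)
})

test_that("loading a full world recovers planted error counts through quality", {
  for (seed in c(71, 72)) {
    td <- withr::local_tempdir()
    cfg <- world_config(seed = seed, n_patients = 60, months = 3,
                        gap_months = 2L,
                        error_rates = list(
                          biochemistry = list(result = list(missing_rate = 0.08,
                                                            wrong_rate = 0.04)),
                          prescriptions = list(bnf_code = list(missing_rate = 0.05,
                                                               wrong_rate = 0.03))))
    w <- generate_world(cfg, td)
    st <- dm_store(file.path(td, "store"))
    load_world(st, w)
    for (ds in c("biochemistry", "prescriptions")) {
      col <- if (ds == "biochemistry") "result" else "bnf_code"
      rep <- evaluate_quality(st, ds)
      row <- rep$per_column[rep$per_column$column == col, ]
      gt <- w$ground_truth$planted[[ds]][[col]]
      expect_equal(row$missing, gt$missing)
      expect_equal(row$wrong, gt$wrong)
      # the gap month shows as a zero-count point in the timeline
      tl <- render_quality_timeline(st, ds)
      expect_equal(tl$series$records[tl$series$month == w$months[2]], 0L)
    }
  }
})
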