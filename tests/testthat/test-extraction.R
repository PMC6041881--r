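# A small loaded world with a committed cohort, shared by the release tests.
extraction_fixture <- function(seed = 21, n_patients = 25, months = 3,
                               planted_chi_count = 0, env = parent.frame()) {
  td <- withr::local_tempdir(.local_envir = env)
  cfg <- world_config(seed = seed, n_patients = n_patients, months = months,
                      planted_chi_count = planted_chi_count)
  world <- generate_world(cfg, file.path(td, "world"))
  st <- dm_store(file.path(td, "store"))
  load_world(st, world)
  create_project(st, "proj", seed = 301)
  def <- cohort_definition(cohort_leaf("demography",
                                       filter_block("sex", "in_set", values = c("F", "M"))))
  cohort <- commit_cohort(st, def, "proj")
  list(store = st, world = world, cohort = cohort)
}

test_that("the CHI modulus-11 checksum matches hand-worked and oracle values", {
  expect_true(chi_checksum_valid("0000000000"))   # sum 0 -> check 11 -> 0
  expect_true(chi_checksum_valid("0000000019"))   # sum 2 -> check 9
  expect_false(chi_checksum_valid("0000000011"))
  expect_error(chi_checksum_valid("123"), "10-character")
  expect_error(chi_checksum_valid("12345abcde"), "10-character")

  # exhaustive agreement with an independent oracle over 10,000 candidates
  candidates <- sprintf("010203%04d", 0:9999)
  got <- chi_checksum_valid(candidates)
  want <- vapply(candidates, chi_oracle, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
  # exactly one valid check digit per stem unless the remainder forbids all
  expect_lte(sum(got), 1000)
})

test_that("the scanner reports every checksum-valid 10-digit window and no others", {
  tb <- tibble::tibble(
    notes = c("seen 0000000019 in clinic", "tel 0000000011", "nothing here"),
    vals = c("12.5", "999999999", "0000000019"))
  found <- scan_for_chi(tb)
  expect_equal(nrow(found), 2)
  expect_setequal(found$match, "0000000019")
  expect_setequal(found$column, c("notes", "vals"))

  # windows inside longer digit runs are all scanned
  run <- paste0("9", "0000000019")   # 11 digits: windows 9000000001*, 0000000019
  hits <- scan_for_chi(tibble::tibble(x = run))
  expect_true("0000000019" %in% hits$match)

  # strict mode additionally requires a DDMMYY date prefix
  expect_equal(nrow(scan_for_chi(tibble::tibble(x = "0000000019"), strict = TRUE)), 0)
})

test_that("the column blacklister vetoes on matching names and passes otherwise", {
  tb <- tibble::tibble(PatientId = "x", sbp = "120", release_id = "abc123abc123")
  res <- column_blacklister(tb, "(?i)id|address|identifier")
  expect_false(res$ok)
  expect_equal(res$columns, "PatientId")

  ok <- column_blacklister(tb[, c("sbp", "release_id")], "(?i)id|address|identifier")
  expect_true(ok$ok)                          # release_id is exempt
  expect_identical(ok$table, tb[, c("sbp", "release_id")])
  expect_error(column_blacklister(tb, ""), "non-empty")
  expect_error(column_blacklister(tb, "(unbalanced"), "compile")
})

test_that("governance removes Internal always and SpecialApproval unless approved", {
  st <- tmp_store()
  register_dataset(st, "demo", c(chi = "text", dob = "date", sex = "code"), "chi")
  set_identifier_column(st, "demo", "chi")
  set_column_metadata(st, "demo", "dob", category = "SpecialApprovalRequired")
  tb <- tibble::tibble(chi = "1", dob = "1950-01-01", sex = "F")
  out <- governance_filter(st, tb, "demo")
  expect_named(out$table, "sex")
  expect_setequal(out$removed$column, c("chi", "dob"))
  out2 <- governance_filter(st, tb, "demo", approved = "dob")
  expect_named(out2$table, c("dob", "sex"))
})

test_that("an extraction links the cohort, pseudonymises and passes governance", {
  fx <- extraction_fixture()
  xc <- extraction_config("proj", fx$cohort$cohort_id,
                          datasets = list(
                            list(dataset = "demography", columns = c("sex", "postcode")),
                            list(dataset = "biochemistry",
                                 columns = c("test_code", "result", "event_date"))),
                          blacklist_pattern = "(?i)address|identifier")
  res <- run_extraction(st <- fx$store, xc)
  expect_false(is.null(res$bundle_dir))
  expect_true(res$audit$succeeded)

  demo <- cohortvault:::read_tbl(file.path(res$bundle_dir, "data", "demography.csv"))
  expect_named(demo, c("release_id", "sex", "postcode"))
  expect_equal(nrow(demo), length(fx$cohort$members))
  expect_setequal(demo$release_id, unname(fx$cohort$release_map))

  # linkage correctness: extracted rows equal a brute-force cohort filter
  bio <- cohortvault:::read_tbl(file.path(res$bundle_dir, "data", "biochemistry.csv"))
  live <- live_table(st, "biochemistry")
  keep <- live$chi %in% fx$cohort$members
  expect_equal(nrow(bio), sum(keep))
  want <- sort(paste(unname(fx$cohort$release_map[live$chi[keep]]),
                     live$test_code[keep], live$result[keep]))
  got <- sort(paste(bio$release_id, bio$test_code, bio$result))
  expect_equal(gsub("NA", "", got), gsub("NA", "", want))

  # manifest digests verify and the lookup tables ride along
  expect_true(all(verify_release(res$bundle_dir)$ok))
  expect_true(file.exists(file.path(res$bundle_dir, "lookups", "test_codes.csv")))

  # disclosure safety on the emitted bundle: no Internal column, no blacklist
  # hit, no checksum-valid identifier anywhere
  for (f in list.files(file.path(res$bundle_dir, "data"), full.names = TRUE)) {
    tb <- cohortvault:::read_tbl(f)
    expect_false("chi" %in% names(tb))
    expect_equal(nrow(scan_for_chi(tb)), 0)
    expect_true(column_blacklister(tb, "(?i)address|identifier")$ok)
  }
  expect_equal(release_audit(st, res$audit$release_id)$release_id,
               res$audit$release_id)
})

test_that("selecting an Internal or unapproved column is rejected at config time", {
  fx <- extraction_fixture(seed = 22)
  xc_bad <- extraction_config("proj", fx$cohort$cohort_id,
                              datasets = list(list(dataset = "demography",
                                                   columns = c("chi", "sex"))))
  expect_error(run_extraction(fx$store, xc_bad), "Internal")
  xc_sar <- extraction_config("proj", fx$cohort$cohort_id,
                              datasets = list(list(dataset = "demography",
                                                   columns = "dob")))
  expect_error(run_extraction(fx$store, xc_sar), "special approval")
  xc_ok <- extraction_config("proj", fx$cohort$cohort_id,
                             datasets = list(list(dataset = "demography",
                                                  columns = "dob", approved = "dob")))
  res <- run_extraction(fx$store, xc_ok)
  expect_true("dob" %in% names(cohortvault:::read_tbl(
    file.path(res$bundle_dir, "data", "demography.csv"))))
})

test_that("planted free-text identifiers veto the release; redact mode masks them", {
  fx <- extraction_fixture(seed = 23, planted_chi_count = 3)
  xc <- extraction_config("proj", fx$cohort$cohort_id,
                          datasets = list(
                            list(dataset = "prescriptions",
                                 columns = c("bnf_code", "notes")),
                            list(dataset = "biochemistry",
                                 columns = c("result", "notes"))))
  res <- run_extraction(fx$store, xc)
  expect_null(res$bundle_dir)
  expect_gte(length(res$audit$crash_messages), 1)
  # the veto fires on the first selected dataset carrying a plant, and its
  # findings are exactly that dataset's planted identifiers
  hit_ds <- unique(vapply(res$audit$chi_findings, function(f) f$dataset, character(1)))
  expect_length(hit_ds, 1)
  planted <- vapply(Filter(function(p) p$dataset == hit_ds,
                           fx$world$ground_truth$chi_plants),
                    function(p) p$chi, character(1))
  found <- vapply(res$audit$chi_findings, function(f) f$match, character(1))
  expect_setequal(found, planted)

  xr <- extraction_config("proj", fx$cohort$cohort_id, datasets = xc$datasets,
                          redact = TRUE)
  res2 <- run_extraction(fx$store, xr)
  expect_false(is.null(res2$bundle_dir))
  masked <- 0L
  for (f in list.files(file.path(res2$bundle_dir, "data"), full.names = TRUE)) {
    tb <- cohortvault:::read_tbl(f)
    expect_equal(nrow(scan_for_chi(tb)), 0)
    if ("notes" %in% names(tb)) masked <- masked + sum(grepl("##########", tb$notes))
  }
  expect_equal(masked, 3L)
})

test_that("a blacklisted column name vetoes with the offending names audited", {
  fx <- extraction_fixture(seed = 24)
  xc <- extraction_config("proj", fx$cohort$cohort_id,
                          datasets = list(list(dataset = "demography",
                                               columns = c("sex", "postcode"))),
                          blacklist_pattern = "(?i)postcode")
  res <- run_extraction(fx$store, xc)
  expect_null(res$bundle_dir)
  expect_match(unlist(res$audit$crash_messages), "postcode")
  expect_false(isTRUE(res$audit$succeeded))
})

test_that("the release document covers exactly the extracted fields and logic", {
  fx <- extraction_fixture(seed = 25)
  xc <- extraction_config("proj", fx$cohort$cohort_id,
                          datasets = list(list(dataset = "biochemistry",
                                               columns = c("test_code", "event_date"))))
  res <- run_extraction(fx$store, xc)
  doc <- readLines(file.path(res$bundle_dir, "docs", "release_document.md"))
  expect_true(any(grepl("`test_code`", doc)))
  expect_false(any(grepl("`result`", doc)))       # not extracted, not described
  expect_false(any(grepl("`chi`", doc)))
  def <- read_cohort_definition(
    cohortvault:::write_json_file(fx$cohort$definition, tempfile(fileext = ".json")))
  logic <- strsplit(describe_definition(def), "\n")[[1]]
  expect_true(all(logic %in% doc))
  expect_true(any(grepl("Monthly record counts", doc)))
  # regeneration is deterministic
  doc2 <- readLines(file.path(res$bundle_dir, "docs", "release_document.md"))
  expect_identical(doc, doc2)
})

test_that("the branch catalogue is restricted, identifier-free and importable", {
  fx <- extraction_fixture(seed = 26)
  xc <- extraction_config("proj", fx$cohort$cohort_id,
                          datasets = list(list(dataset = "demography",
                                               columns = c("sex", "postcode"))))
  res <- run_extraction(fx$store, xc)
  branch <- cohortvault:::read_json_file(file.path(res$bundle_dir, "catalogue.json"))
  expect_length(branch$entries, 1)
  cats <- vapply(branch$entries[[1]]$items, function(it) it$extraction_category,
                 character(1))
  expect_false(any(cats == "Internal"))
  cols <- vapply(branch$entries[[1]]$items, function(it) it$column_name, character(1))
  expect_setequal(cols, c("release_id", "sex", "postcode"))
  st2 <- tmp_store()
  import_catalogue(st2, branch)
  expect_equal(list_datasets(st2)$name, "demography")
  expect_equal(nrow(check_catalogue_integrity(st2)), 0)
})

test_that("refreshes at the first release time are byte-identical", {
  td <- withr::local_tempdir()
  cfg <- world_config(seed = 31, n_patients = 20, months = 3,
                      rewrite_rate = 0.15, rewrite_month = 3L)
  world <- generate_world(cfg, file.path(td, "world"))
  st <- dm_store(file.path(td, "store"))
  load_world(st, world, up_to_month = 2)
  create_project(st, "proj", seed = 77)
  def <- cohort_definition(cohort_leaf("demography",
                                       filter_block("sex", "in_set", values = c("F", "M"))))
  cohort <- commit_cohort(st, def, "proj")
  t0 <- "2016-03-15T00:00:00Z"
  sel <- list(list(dataset = "demography", columns = c("sex", "postcode")))
  xc <- extraction_config("proj", cohort$cohort_id, datasets = sel, as_at = t0)
  r1 <- run_extraction(st, xc, release_type = "First")

  load_world(st, world, up_to_month = 3)   # rewrite feed arrives
  r2 <- run_extraction(st, xc, release_type = "Refresh")
  f1 <- file.path(r1$bundle_dir, "data", "demography.csv")
  f2 <- file.path(r2$bundle_dir, "data", "demography.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # a live refresh differs at exactly the ground-truth rewritten keys
  xl <- extraction_config("proj", cohort$cohort_id, datasets = sel, as_at = "live")
  r3 <- run_extraction(st, xl, release_type = "Refresh")
  d1 <- cohortvault:::read_tbl(f1)
  d3 <- cohortvault:::read_tbl(file.path(r3$bundle_dir, "data", "demography.csv"))
  changed_rel <- sort(d3$release_id[!do.call(paste, d3) %in% do.call(paste, d1)])
  rewritten <- vapply(world$ground_truth$rewrites, function(r) r$key, character(1))
  expect_identical(changed_rel, sort(unname(cohort$release_map[rewritten])))
})
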