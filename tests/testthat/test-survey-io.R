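test_that("canonical CSV round-trips records exactly, byte-for-byte", {
  records <- fixture_small()
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_table(records, path)
  back <- read_response_table(path)
  expect_equal(as.data.frame(back), as.data.frame(records))

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_response_table(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("reader reports schema and validation errors with locations", {
  records <- control_volunteer("V1", c(3, 1), c(-3, -1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_table(records, path)

  txt <- readLines(path)

  # out-of-range rating on a known line (row 2 of data = file line 3)
  mutated <- txt
  mutated[3] <- sub(",1,", ",5,", mutated[3], fixed = TRUE)
  writeLines(mutated, path)
  expect_error(read_response_table(path), "line\\(s\\) 3")

  # non-integer rating
  mutated <- txt
  mutated[3] <- sub(",1,", ",1.5,", mutated[3], fixed = TRUE)
  writeLines(mutated, path)
  expect_error(read_response_table(path), "non-integer rating")

  # unknown enum value
  mutated <- txt
  mutated[3] <- sub("same", "sam", mutated[3], fixed = TRUE)
  writeLines(mutated, path)
  expect_error(read_response_table(path), "unknown")

  # missing column
  write_response_table(records, path)
  tab <- utils::read.csv(path)
  utils::write.csv(tab[, setdiff(names(tab), "rating")], path,
                   row.names = FALSE)
  expect_error(read_response_table(path), "rating")
})

test_that("duplicate volunteer x item rows are a hard error", {
  records <- control_volunteer("V1", c(3, 1), c(-3, -1))
  expect_error(validate_records(dplyr::bind_rows(records, records[1, ])),
               "duplicate")
})

test_that("control responses must be unlabelled and sourced ones labelled", {
  records <- control_volunteer("V1", c(3, 1), c(-3, -1))
  bad <- records
  bad$prior_label[1] <- "same"
  expect_error(validate_records(bad), "control")

  sourced <- records
  sourced$variant <- "human_source"
  sourced$version <- "1"
  expect_error(validate_records(sourced), "prior label")
})

test_that("simulated survey has one record per volunteer x item", {
  cfg <- sim_config(n_volunteers_per_variant = 5, seed = 7)
  records <- simulate_survey(simulate_raters(cfg))
  n_items <- cfg$n_same_items + cfg$n_diff_items + cfg$n_catch
  expect_identical(nrow(records), 3L * 5L * n_items)
  expect_identical(
    nrow(dplyr::distinct(records, volunteer_id, item_id)), nrow(records))
})

test_that("catch screening excludes exactly the violating volunteers", {
  good <- dplyr::bind_rows(lapply(1:4, function(i) {
    control_volunteer(paste0("G", i), c(3, 1), c(-3, -1))
  }))
  # planted failures: wrong sign on mated pair, and an unsure 0 response
  bad1 <- control_volunteer("B1", c(3, 1), c(-3, -1),
                            catch_ratings = c(-2L, -3L))
  bad2 <- control_volunteer("B2", c(3, 1), c(-3, -1),
                            catch_ratings = c(0L, -3L))
  screened <- screen_catch_trials(dplyr::bind_rows(good, bad1, bad2))

  expect_setequal(screened$excluded$volunteer_id, c("B1", "B2"))
  expect_false(any(screened$kept$is_catch))
  expect_length(intersect(screened$kept$volunteer_id,
                          screened$excluded$volunteer_id), 0)

  # the lenient rule accepts "not sure" on a catch pair
  lenient <- screen_catch_trials(dplyr::bind_rows(good, bad1, bad2),
                                 rule = catch_rule(unsure_fails = FALSE))
  expect_setequal(lenient$excluded$volunteer_id, "B1")

  # all-correct input: nobody excluded
  expect_identical(nrow(screen_catch_trials(good)$excluded), 0L)
})

test_that("screening is idempotent and warns about unscreenable volunteers", {
  records <- dplyr::bind_rows(
    control_volunteer("A", c(3, 1), c(-3, -1)),
    control_volunteer("B", c(2, 0), c(-2, -1), catch_ratings = c(0L, -3L))
  )
  first <- screen_catch_trials(records)
  # the kept set has no catch trials left, so everyone is unscreenable now
  expect_warning(second <- screen_catch_trials(first$kept), "no catch trials")
  expect_identical(nrow(second$excluded), 0L)
  expect_identical(as.data.frame(second$kept), as.data.frame(first$kept))
  expect_setequal(second$unscreenable, "A")

  expect_error(screen_catch_trials(records[0, ]), "empty")
})

test_that("planted catch failures are recovered from a simulated cohort", {
  cfg <- sim_config(n_volunteers_per_variant = 40, catch_fail_rate = 0.25,
                    seed = 11)
  truth <- simulate_raters(cfg)
  records <- simulate_survey(truth)
  screened <- screen_catch_trials(records)
  planted <- truth$volunteers$volunteer_id[truth$volunteers$catch_fail]
  expect_true(all(planted %in% screened$excluded$volunteer_id))
  # incidental failures beyond the planted ones are rare by design
  expect_lte(nrow(screened$excluded), length(planted) + 3)
})

test_that("design summary reports the nested structure and its violations", {
  records <- simulate_survey(simulate_raters(sim_config(
    n_volunteers_per_variant = 6, seed = 3)))
  design <- summarize_design(records)
  expect_true(all(design$balance))
  expect_identical(sort(design$volunteers_by_variant$n_volunteers),
                   c(6L, 6L, 6L))
  expect_identical(nrow(design$items), 12L)

  # force an item to appear under only one label in both versions
  broken <- records
  broken$prior_label[broken$item_id == "s01" &
                       broken$prior_label == "different"] <- "same"
  design2 <- summarize_design(broken)
  expect_false(design2$balance[["labels_counterbalanced"]])
  cov <- design2$item_label_coverage
  expect_true(all(cov$n_labels[cov$item_id == "s01"] == 1L))
})

test_that("volunteer profile reader validates bins and fills missing trust", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    volunteer_id = c("V1", "V2"), gender = c("female", "male"),
    age_bin = c("26-35", "65+"), race = c("black", "white"),
    trust_response = c("yes", "")
  ), path, row.names = FALSE)
  prof <- read_volunteer_table(path)
  expect_identical(prof$trust_response, c("yes", "missing"))

  utils::write.csv(data.frame(
    volunteer_id = "V1", gender = "female", age_bin = "30ish",
    race = "black", trust_response = "yes"
  ), path, row.names = FALSE)
  expect_error(read_volunteer_table(path), "age_bin")
})
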