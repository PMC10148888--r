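test_that("read/write round-trip preserves the packaged fixture field for field", {
  path <- system.file("extdata", "six_subject_trial.csv", package = "pwmmrm")
  ds <- read_trial_long(path)
  expect_s3_class(ds, "trial_dataset")
  expect_equal(nrow(ds$subjects), 6)
  expect_equal(length(ds$arms), 2)
  expect_equal(nrow(ds$visits), 3)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trial_long(ds, tmp)
  ds2 <- read_trial_long(tmp)
  expect_identical(ds$subjects, ds2$subjects)
  expect_identical(ds$screening_items, ds2$screening_items)
  expect_identical(ds$baseline_items, ds2$baseline_items)
  expect_identical(ds$totals[order(ds$totals$subject_id, ds$totals$visit), ],
                   ds2$totals[order(ds2$totals$subject_id, ds2$totals$visit), ],
                   ignore_attr = TRUE)
  expect_identical(ds$visits, ds2$visits)
})

test_that("round-trip also holds for generated trials with dropout, and TSV dialect", {
  gen <- generate_trial(sim_config(arm_sizes = c(placebo = 10L, x = 10L),
                                   visit_weeks = c(1L, 4L, 8L),
                                   drug_effect = c(x = -2),
                                   dropout_hazard = 0.15), seed = 11)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_trial_long(gen$dataset, tmp)
  ds2 <- read_trial_long(tmp, arms = gen$dataset$arms,
                         placebo_arm = "placebo")
  expect_identical(gen$dataset$baseline_items, ds2$baseline_items)
  expect_equal(nrow(gen$dataset$totals), nrow(ds2$totals))
  # a subject missing a visit has no row at all
  raw <- utils::read.table(tmp, sep = "\t", header = TRUE)
  n_expected <- 2 * nrow(gen$dataset$subjects) + nrow(gen$dataset$totals)
  expect_equal(nrow(raw), n_expected)
})

test_that("a file with zero post-baseline rows yields an empty-totals dataset", {
  ds <- make_dataset(c(24L, 20L), c("placebo", "active"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trial_long(ds, tmp)
  ds2 <- read_trial_long(tmp)
  expect_equal(nrow(ds2$totals), 0)
  expect_equal(nrow(ds2$subjects), 2)
})

test_that("schema and validation errors name the offending column/subject", {
  path <- system.file("extdata", "six_subject_trial.csv", package = "pwmmrm")
  df <- utils::read.csv(path, check.names = FALSE)
  tmp <- withr::local_tempfile(fileext = ".csv")

  utils::write.csv(df[setdiff(names(df), "arm")], tmp, row.names = FALSE)
  expect_error(read_trial_long(tmp), "arm", class = "pwmmrm_schema_error")

  bad <- df
  bad$item1[bad$visit == "baseline"][1] <- 99L
  bad$total[bad$visit == "baseline"][1] <- NA  # avoid the cross-check firing first
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_trial_long(tmp), "S0001.*item 1|item 1",
               class = "pwmmrm_validation_error")

  dup <- rbind(df, df[df$visit == "week8", ][1, ])
  utils::write.csv(dup, tmp, row.names = FALSE)
  expect_error(read_trial_long(tmp), "duplicate",
               class = "pwmmrm_integrity_error")
})

test_that("item_changes matches element-wise subtraction and is pure", {
  ds <- make_dataset(c(24L, 20L, 26L), c("placebo", "a", "a"),
                     screening_totals = c(26L, 20L, 23L))
  d1 <- item_changes(ds)
  expect_identical(d1, ds$baseline_items - ds$screening_items)
  expect_identical(d1, item_changes(ds))
  # identical screening and baseline give the zero vector
  expect_true(all(item_changes(ds)["P02", ] == 0))
  # randomized property check
  set.seed(5)
  for (k in 1:10) {
    gen <- generate_trial(sim_config(arm_sizes = c(placebo = 5L)),
                          seed = 100 + k)
    expect_identical(item_changes(gen$dataset),
                     gen$dataset$baseline_items - gen$dataset$screening_items)
  }
})

test_that("change_from_baseline subtracts the baseline and marks missing visits NA", {
  ds <- make_dataset(c(24L, 24L), c("placebo", "a"),
                     totals = data.frame(subject = c(1L, 1L, 2L),
                                         visit = c("week4", "week8", "week4"),
                                         total = c(20L, 14L, 24L)))
  cb8 <- change_from_baseline(ds, "week8")
  expect_equal(unname(cb8["P01"]), -10)
  expect_true(is.na(cb8["P02"]))      # missing, never zero
  expect_equal(unname(change_from_baseline(ds, "week4")["P02"]), 0)
  expect_error(change_from_baseline(ds, "week99"), "visit")
})

test_that("dataset invariants reject bad inputs", {
  expect_error(
    trial_dataset(
      subjects = data.frame(subject_id = "P01", arm = "undeclared",
                            screening_to_baseline_days = 7L),
      screening_items = matrix(fill_items(24L), 1),
      baseline_items = matrix(fill_items(24L), 1),
      totals = data.frame(subject_id = character(0), visit = character(0),
                          total = integer(0)),
      visits = data.frame(visit = "week8", week = 8L),
      arms = "placebo", placebo_arm = "placebo"),
    "arm", class = "pwmmrm_validation_error")
  ds <- make_dataset(c(24L, 20L), c("placebo", "a"))
  ds$baseline_items[1, 1] <- 99L
  expect_error(pwmmrm:::validate_trial_dataset(ds), "P01",
               class = "pwmmrm_validation_error")
})
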