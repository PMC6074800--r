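test_that("a toy coding sheet round-trips field for field", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 100, 130),
    agg_row("A2", "2020-06-01", 5000, 5040, a = "Su", v = "Ta",
            context = "food", intensity = "high", behaviour = "chase+bite"),
    agg_row("A3", "2020-06-03", 200, 230, a = "Dm", v = "Ei"))
  af <- dplyr::bind_rows(
    aff_row("F1", "2020-06-01", 200, "Dm", "To"),
    aff_row("F2", "2020-06-02", 300, "Ta", "Ei",
            beh = "contact_sitting+touch_body", vis = FALSE))
  iv <- tibble::tibble(event_id = "A2", intervener = "To",
                       mode = "peaceful", supported = "Ta",
                       successful = TRUE)
  log <- ethogram_log(setup, ag, af, iv)
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(log, path)
  back <- read_coding_sheet(path, setup)
  rep <- attr(back, "parse_report")
  expect_equal(rep$n_rows, 5)
  expect_equal(nrow(rep$skipped), 0)
  expect_equal(back$aggressions, log$aggressions)
  expect_equal(back$affiliations, log$affiliations)
  expect_equal(back$interventions, log$interventions)
  # two behaviour types travel in one cell, "+"-joined
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_true("contact_sitting+touch_body" %in% raw$behaviour)
})

test_that("an empty log writes a header-only sheet that reads back empty", {
  setup <- toy_setup()
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(ethogram_log(setup), path)
  expect_length(readLines(path), 1L)
  back <- read_coding_sheet(path, setup)
  expect_equal(nrow(back$aggressions), 0L)
  expect_equal(nrow(back$affiliations), 0L)
})

test_that("strict mode rejects out-of-vocabulary rows naming row and value", {
  setup <- toy_setup()
  log <- ethogram_log(setup, agg_row("A1", "2020-06-01", 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(log, path)
  txt <- sub("medium", "severe", readLines(path))
  writeLines(txt, path)
  expect_error(read_coding_sheet(path, setup), "row 1.*severe")
  lenient <- read_coding_sheet(path, setup, mode = "lenient")
  expect_equal(nrow(lenient$aggressions), 0L)
  expect_equal(attr(lenient, "parse_report")$skipped$row, 1L)
})

test_that("a column map renames source headers onto the canonical schema", {
  setup <- toy_setup()
  log <- ethogram_log(setup, agg_row("A1", "2020-06-01", 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(log, path)
  txt <- readLines(path)
  txt[1] <- sub("^event_id", "EventNr", txt[1])
  writeLines(txt, path)
  expect_error(read_coding_sheet(path, setup), "event_id")
  back <- read_coding_sheet(path, setup, mapping = c(event_id = "EventNr"))
  expect_equal(back$aggressions$event_id, "A1")
})

test_that("validate_log reports each broken type invariant", {
  setup <- toy_setup()
  good <- ethogram_log(setup, agg_row("A1", "2020-06-01", 100))
  expect_equal(nrow(validate_log(good)), 0L)

  self <- ethogram_log(setup, agg_row("A1", "2020-06-01", 100, v = "To"))
  expect_match(validate_log(self)$problem, "aggressor equals victim")

  # indoor condition requires subgroup membership
  roster <- default_roster()
  roster$subgroup[roster$id == "Dm"] <- "none"
  setup2 <- study_setup(roster, setup$calendar)
  indoor <- ethogram_log(setup2, agg_row("A1", "2020-06-01", 100))
  expect_match(validate_log(indoor)$problem, "subgroup missing")

  neg <- ethogram_log(setup, agg_row("A1", "2020-06-01", 100, off = 50))
  expect_match(validate_log(neg)$problem, "offset before onset")

  # intervener must not be an opponent
  bad_iv <- ethogram_log(setup, agg_row("A1", "2020-06-01", 100),
                         interventions = tibble::tibble(
                           event_id = "A1", intervener = "To",
                           mode = "peaceful", supported = "Dm",
                           successful = TRUE))
  expect_match(validate_log(bad_iv)$problem, "opponent")
})

test_that("study setup round-trips through YAML and checks its invariants", {
  setup <- toy_setup(days = 4, condition = c("outdoor", "outdoor",
                                             "indoor", "indoor"))
  path <- withr::local_tempfile(fileext = ".yml")
  write_study_setup(setup, path)
  back <- read_study_setup(path)
  expect_equal(back$hours, setup$hours)
  expect_equal(back$roster$id, setup$roster$id)
  expect_error(study_setup(default_roster(),
                           setup$calendar[c(1, 1, 2), ]), "duplicated")
  bad_roster <- default_roster()[c(1, 1, 2), ]
  expect_error(study_setup(bad_roster, setup$calendar), "unique")
})

test_that("events stay chronologically ordered through the container", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(agg_row("A2", "2020-06-03", 50),
                         agg_row("A1", "2020-06-01", 500))
  log <- ethogram_log(setup, ag)
  expect_equal(log$aggressions$event_id, c("A1", "A2"))
})
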