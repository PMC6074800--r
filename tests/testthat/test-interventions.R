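test_that("intervention tabulation is permutation-invariant and typed", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 100),
    agg_row("A2", "2020-06-01", 2000, a = "Su", v = "Ta"),
    agg_row("A3", "2020-06-03", 100, a = "Dm", v = "Ei"))
  iv <- tibble::tibble(
    event_id = c("A1", "A2", "A2"),
    intervener = c("Su", "To", "Wa"),
    mode = c("peaceful", "aggressive", "peaceful"),
    supported = c("Dm", "Ta", "Ta"), successful = c(TRUE, TRUE, FALSE))
  log <- ethogram_log(setup, ag, interventions = iv)
  s <- tabulate_interventions(log)
  expect_equal(s$n_conflicts_considered, 3L)
  expect_equal(s$n_intervened, 2L)
  expect_equal(s$n_interventions, 3L)
  expect_equal(unname(s$mode_counts), c(2L, 1L))
  expect_equal(sum(s$matrix), 3L)
  # event order does not matter
  log2 <- ethogram_log(setup, ag[c(3, 1, 2), ], interventions = iv[3:1, ])
  s2 <- tabulate_interventions(log2)
  expect_equal(s2$n_intervened, s$n_intervened)
  expect_equal(s2$mode_counts, s$mode_counts)
  # empty log -> zero summary
  zero <- tabulate_interventions(ethogram_log(setup))
  expect_equal(zero$n_interventions, 0L)
})

test_that("undetermined intervention status is governed by the flag", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 100),
    agg_row("A2", "2020-06-01", 2000, undet = TRUE))
  log <- ethogram_log(setup, ag)
  expect_equal(tabulate_interventions(log)$n_conflicts_considered, 2L)
  expect_equal(tabulate_interventions(log, drop_undetermined = TRUE)$
                 n_conflicts_considered, 1L)
})

test_that("the condition contrast requires both conditions and controls influence", {
  setup <- toy_setup(days = 4, hours = 2,
                     condition = c("outdoor", "outdoor", "indoor", "indoor"))
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 100, cond = "outdoor"),
    agg_row("A2", "2020-06-01", 2000, cond = "outdoor"),
    agg_row("A3", "2020-06-03", 100),
    agg_row("A4", "2020-06-03", 2000))
  iv <- tibble::tibble(event_id = c("A1", "A3"),
                       intervener = c("Su", "Wa"),
                       mode = "peaceful", supported = "Dm",
                       successful = TRUE)
  r <- intervention_condition_test(ethogram_log(setup, ag,
                                                interventions = iv))
  expect_equal(r$pooled$or_cmle, 1, tolerance = 1e-6)  # equal rates
  expect_s3_class(r$influence, "fisher_rxc_result")
  only_in <- ethogram_log(setup, ag[3:4, ])
  expect_error(intervention_condition_test(only_in), "both")
})

test_that("the coercion summary keeps the male context apart", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(
    agg_row("C1", "2020-06-01", 100, a = "Wa", v = "To",
            context = "sexual_coercion", intensity = "high",
            behaviour = "chase+bite"),
    agg_row("C2", "2020-06-01", 3000, a = "To", v = "Wa",
            context = "sexual_coercion"),          # counter-aggression
    agg_row("A1", "2020-06-03", 100))              # unrelated conflict
  iv <- tibble::tibble(event_id = "C1", intervener = "Ei",
                       mode = "aggressive", supported = "To",
                       successful = FALSE)
  af <- aff_row("F1", "2020-06-01", 150, "To", "Ei", beh = "embrace")
  log <- ethogram_log(setup, ag, af, iv)
  cs <- coercion_summary(log)
  expect_equal(cs$n_events, 1L)
  expect_equal(cs$n_counter_aggressions, 1L)
  expect_equal(cs$n_intervened, 1L)
  expect_equal(cs$post_event_affiliations$interval, 1L)
  # coercion conflicts never enter the general tabulation
  expect_equal(tabulate_interventions(log)$n_conflicts_considered, 1L)
  # no coercion events -> empty summary
  none <- coercion_summary(ethogram_log(setup, ag[3, ]))
  expect_equal(none$n_events, 0L)
})
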