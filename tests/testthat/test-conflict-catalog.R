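test_that("the 4-minute rule chains conflicts into sequences", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 0, 0),
    agg_row("A2", "2020-06-01", 120, 120),
    agg_row("A3", "2020-06-01", 900, 900))
  seg <- segment_conflicts(ethogram_log(setup, ag))
  s <- attr(seg, "summary")
  expect_equal(s$n_distinct, 1L)
  expect_equal(s$n_in_sequences, 2L)
  expect_equal(seg$sequence_id[seg$event_id %in% c("A1", "A2")],
               c(1L, 1L))
  # a single event is one distinct sequence
  one <- segment_conflicts(ethogram_log(setup, agg_row("A1", "2020-06-01", 5)))
  expect_true(one$is_distinct)
})

test_that("sequence segmentation partitions the event set", {
  log <- simulate_log(simulation_config(seed = 31))
  seg <- segment_conflicts(log)
  s <- attr(seg, "summary")
  expect_equal(nrow(seg), nrow(log$aggressions))
  expect_equal(s$n_distinct + s$n_in_sequences, nrow(log$aggressions))
  expect_equal(sum(s$sequence_sizes) + s$n_distinct, nrow(log$aggressions))
})

test_that("composite aggressions take the intensity of their worst element", {
  expect_equal(aggression_intensity("gentle_push"), "low")
  expect_equal(aggression_intensity(c("chase", "bite")), "high")
  expect_equal(aggression_intensity(character()), "undetermined")
  expect_equal(aggression_intensity(c("chase", "mystery_code")),
               "undetermined")
})

test_that("context summary counts all cells including empty ones", {
  setup <- toy_setup()
  empty <- summarize_contexts(ethogram_log(setup))
  expect_true(all(empty$n == 0))
  log <- ethogram_log(setup, dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 0),
    agg_row("A2", "2020-06-01", 2000, context = "food", intensity = "high")))
  sc <- summarize_contexts(log)
  expect_equal(sum(sc$n), 2L)
  expect_equal(sc$proportion[sc$context == "food" & sc$intensity == "high"],
               0.5)
})

test_that("aggression rates scale with counts and feed the paired test", {
  setup <- toy_setup(days = 4, hours = 2,
                     condition = c("outdoor", "outdoor", "indoor", "indoor"))
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 10, cond = "outdoor"),
    agg_row("A2", "2020-06-03", 10),
    agg_row("A3", "2020-06-03", 2000),
    agg_row("A4", "2020-06-04", 10, a = "Su", v = "Dm"))
  r <- aggression_rates(ethogram_log(setup, ag))
  to_in <- r$rates[r$rates$individual == "To" & r$rates$condition == "indoor", ]
  expect_equal(to_in$rate, 2 / 4)  # 2 events over 4 indoor hours
  expect_equal(r$test$n_used, 2L)  # To and Su change; others all-zero
  # an inactive group propagates the undefined-test error
  expect_error(aggression_rates(ethogram_log(setup)), "zero")
})

test_that("network weights sum to the aggression count per condition", {
  log <- simulate_log(simulation_config(seed = 32))
  net <- aggression_network(log)
  by_cond <- tapply(net$edges$weight, net$edges$condition, sum)
  counts <- table(log$aggressions$condition)
  expect_equal(as.integer(by_cond[names(counts)]), as.integer(counts))
  expect_equal(sum(net$totals$n), nrow(log$aggressions))
  empty <- aggression_network(ethogram_log(toy_setup()))
  expect_equal(nrow(empty$edges), 0L)
})

test_that("condition/intensity and mesh contrasts delegate to the 2x2 kernel", {
  setup <- toy_setup(days = 4, hours = 2,
                     condition = c("outdoor", "outdoor", "indoor", "indoor"))
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 10, cond = "outdoor", intensity = "high",
            behaviour = "bite"),
    agg_row("A2", "2020-06-01", 2000, cond = "outdoor"),
    agg_row("A3", "2020-06-03", 10, intensity = "high", behaviour = "bite"),
    agg_row("A4", "2020-06-03", 2000))
  ct <- condition_intensity_test(ethogram_log(setup, ag))
  expect_equal(ct$pooled$or_cmle, 1, tolerance = 1e-6)   # symmetric table
  expect_equal(ct$pooled$p, 1)
  # one condition empty -> degenerate flag
  ct2 <- condition_intensity_test(
    ethogram_log(setup, agg_row("A1", "2020-06-03", 10)))
  expect_true(ct2$pooled$degenerate)
  # mesh test consumes the subgroup map; To-Dm is a separated dyad
  m <- mesh_effect_test(ethogram_log(setup, ag))
  expect_identical(dim(m$table), c(2L, 2L))
  expect_equal(m$table["indoor", "separated"], 2)
})
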