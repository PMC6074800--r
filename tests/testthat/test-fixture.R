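## Deep checks of the deterministic benchmark log: every quantity below is
## fixed by the fixture's construction, so a mismatch indicates a defect
## in either the construction or the pipeline stage that measures it.

fx <- study_fixture_log()
fx_pairs <- build_pcmc_pairs(fx)

test_that("the benchmark log is valid and deterministic", {
  expect_equal(nrow(validate_log(fx)), 0L)
  expect_identical(write_coding_sheet(fx, withr::local_tempfile()) |>
                     readLines(),
                   write_coding_sheet(study_fixture_log(),
                                      withr::local_tempfile()) |>
                     readLines())
})

test_that("conflict counts, sequences, contexts and intensities are as designed", {
  expect_equal(nrow(fx$aggressions), 114L)
  s <- attr(segment_conflicts(fx), "summary")
  expect_equal(s$n_distinct, 85L)
  expect_equal(s$n_in_sequences, 29L)
  expect_setequal(unique(s$sequence_sizes), c(2L, 3L, 4L))
  ctx <- summarize_contexts(fx)
  expect_equal(as.vector(tapply(ctx$n, ctx$context, sum)[
    c("spontaneous", "sexual_coercion", "weaning", "food", "object",
      "punishment", "unknown")]),
    c(49L, 26L, 17L, 9L, 6L, 1L, 6L))
  expect_equal(as.vector(tapply(ctx$n, ctx$intensity, sum)[
    c("medium", "high", "low", "undetermined")]),
    c(57L, 37L, 14L, 6L))
  # stored intensities agree with the most-intense-constituent rule
  derived <- vapply(strsplit(fx$aggressions$behaviour, "+", fixed = TRUE),
                    aggression_intensity, "", USE.NAMES = FALSE)
  expect_equal(unname(derived), fx$aggressions$intensity)
})

test_that("the aggression network matches the designed dyad counts", {
  net <- aggression_network(fx)
  expect_equal(net$totals$n[net$totals$aggressor == "To"], 66L)
  expect_equal(net$totals$share[net$totals$aggressor == "To"], 66 / 114)
  w <- function(a, v) sum(net$edges$weight[net$edges$aggressor == a &
                                             net$edges$victim == v])
  expect_equal(w("To", "Dm"), 27L)
  expect_equal(w("To", "Ta"), 24L)
  expect_equal(w("Wa", "To"), 14L)
})

test_that("exclusion bookkeeping matches the designed 12/8/6/3 split", {
  nc <- fx_pairs[!fx_pairs$male_coercion, ]
  expect_equal(sum(nc$excluded_reason == "conflict_resumed", na.rm = TRUE), 12L)
  expect_equal(sum(nc$excluded_reason == "pc_unavailable", na.rm = TRUE), 3L)
  base <- nc[is.na(nc$excluded_reason), ]
  expect_equal(nrow(base), 78L)
  expect_equal(sum(base$opp_unspec), 8L)
  expect_equal(sum(base$tp_unspec), 6L)
})

test_that("male-coercion machinery finds 13 analysable PCs of 16 coercions", {
  cz <- fx_pairs[fx_pairs$male_coercion, ]
  expect_equal(nrow(cz), 21L)
  expect_equal(sum(!cz$resumed), 13L)
  cs <- coercion_summary(fx)
  expect_equal(cs$n_events, 16L)
  expect_equal(cs$n_intervened, 16L)
  expect_equal(cs$n_counter_aggressions, 5L)
  # the mother's interventions succeed, the immatures' never do
  succ <- cs$success_by_intervener
  expect_equal(succ$n_successful[succ$intervener == "To"], 2L)
  expect_equal(sum(succ$n_successful[succ$intervener %in% c("Ta", "Ei")]), 0L)
  # post-coercion affiliation with the offspring in every female-victim PC
  expect_equal(nrow(cs$post_event_affiliations), 11L)
})

test_that("matched controls land on the next conflict-free day", {
  ok <- fx_pairs[is.na(fx_pairs$excluded_reason), ]
  expect_true(all(ok$mc_day_offset == 1L))
  expect_true(all(ok$mc_clock_offset_s == 0))
})

test_that("third-party latency histograms start at 25 vs 16 first-minute contacts", {
  h <- latency_histograms(fx_pairs, "third_party")
  expect_equal(h$pc_n[1], 25L)
  expect_equal(h$mc_n[1], 16L)
})

test_that("the full pipeline runs and serialises its artefacts", {
  out <- withr::local_tempdir()
  rep <- run_pipeline(fx, out_dir = out)
  expect_s3_class(rep, "pcmc_report")
  expect_true(all(file.exists(file.path(out, c(
    "pairs.csv", "rates.csv", "contexts.csv", "network.csv",
    "curves_opponent.csv", "curves_third_party.csv", "typology.csv",
    "summary.txt")))))
  # report numbers trace to the stage outputs
  expect_equal(rep$opponent$labels$n_reconciled, 29L)
  expect_equal(rep$third_party$test$T, 5)
  # round trip through the coding sheet preserves the analysis
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(fx, path)
  back <- read_coding_sheet(path, fx$setup)
  expect_equal(build_pcmc_pairs(back), fx_pairs)
})
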