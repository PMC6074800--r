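test_that("the 3-minute restart rule re-anchors the PC window", {
  setup <- toy_setup()
  ag <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 1000, 1030),
    agg_row("A2", "2020-06-01", 1130, 1160))  # same dyad, 100 s after end
  log <- ethogram_log(setup, ag)
  pc <- extract_pc(log, "A1")
  expect_true(pc$resumed)
  expect_equal(pc$anchor_s, 1160)
  expect_equal(pc$restarted_from, "A2")
  # a different dyad does not abort the PC
  ag2 <- dplyr::bind_rows(
    agg_row("A1", "2020-06-01", 1000, 1030),
    agg_row("A2", "2020-06-01", 1130, 1160, a = "Su", v = "Ta"))
  pc2 <- extract_pc(ethogram_log(setup, ag2), "A1")
  expect_false(pc2$resumed)
  expect_equal(pc2$anchor_s, 1030)
  # a window cut off by the session end is unavailable
  late <- agg_row("A1", "2020-06-01", 3 * 3600 - 200, 3 * 3600 - 170)
  expect_false(extract_pc(ethogram_log(setup, late), "A1")$available)
})

test_that("MC selection walks the deterministic priority ladder", {
  setup <- toy_setup(days = 9)
  conflict <- agg_row("A1", "2020-06-02", 1000, 1030)
  log <- ethogram_log(setup, conflict)
  pc <- extract_pc(log, "A1")
  mc <- select_mc(log, pc)
  expect_equal(mc$day_offset, 1L)       # very next day, same clock time
  expect_equal(mc$clock_offset_s, 0)
  expect_equal(mc$start_s, 1030)

  # a conflict 5 min before the matched window pushes it to the nearest
  # minute offset whose preceding 10 minutes are conflict-free
  block <- agg_row("A2", "2020-06-03", 730, 760)
  log2 <- ethogram_log(setup, dplyr::bind_rows(conflict, block))
  mc2 <- select_mc(log2, extract_pc(log2, "A1"))
  expect_equal(mc2$day_offset, 1L)
  expect_equal(mc2$clock_offset_s, -300)
  expect_equal(mc2$start_s, 730)

  # no other recorded day within +-7 days -> unavailable
  lone <- study_setup(default_roster(),
                      tibble::tibble(date = as.Date("2020-06-01"),
                                     start_s = 8 * 3600, duration_h = 3,
                                     condition = "indoor"))
  log3 <- ethogram_log(lone, agg_row("A1", "2020-06-01", 1000, 1030))
  expect_false(select_mc(log3, extract_pc(log3, "A1"))$available)
})

test_that("first-affiliation latencies honour the (60(k-1), 60k] convention", {
  setup <- toy_setup()
  ag <- agg_row("A1", "2020-06-01", 1000, 1030)
  lat <- function(af) {
    log <- ethogram_log(setup, ag, af)
    first_affiliation_latency(log, as.Date("2020-06-01"), 1030, "Dm", "To",
                              "opponent")
  }
  expect_equal(lat(aff_row("F1", "2020-06-01", 1060, "Dm", "To")), 1L)
  expect_equal(lat(aff_row("F1", "2020-06-01", 1030, "Dm", "To")), 1L)  # t = 0
  expect_equal(lat(aff_row("F1", "2020-06-01", 1030 + 120, "Dm", "To")), 2L)
  expect_equal(lat(aff_row("F1", "2020-06-01", 1030 + 601, "Dm", "To")),
               NA_integer_)
  expect_equal(lat(aff_row("F1", "2020-06-01", 1060, "Dm", "To",
                           vis = FALSE)), "unspecifiable")
  # third-party filter ignores the opponent and vice versa
  log <- ethogram_log(setup, ag, aff_row("F1", "2020-06-01", 1060, "Dm", "Su"))
  expect_equal(first_affiliation_latency(log, as.Date("2020-06-01"), 1030,
                                         "Dm", "To", "any_third_party"), 1L)
  expect_equal(first_affiliation_latency(log, as.Date("2020-06-01"), 1030,
                                         "Dm", "To", "opponent"),
               NA_integer_)
})

test_that("pair classification follows the attracted/dispersed/neutral rules", {
  expect_equal(classify_pair(1L, NA), "attracted")
  expect_equal(classify_pair(NA, 2L), "dispersed")
  expect_equal(classify_pair(4L, 4L), "neutral")
  expect_equal(classify_pair(NA, NA), "neutral")
  expect_equal(classify_pair(2L, 7L), "attracted")
  expect_error(classify_pair("unspecifiable", 3L), "excluded")
})

test_that("classification partitions specifiable pairs and is antisymmetric", {
  set.seed(21)
  draw <- function(n) {
    x <- sample(c(NA, 1:10), n, replace = TRUE,
                prob = c(0.4, rep(0.06, 10)))
    as.integer(x)
  }
  pc <- draw(400); mc <- draw(400)
  cls <- classify_pair(pc, mc)
  expect_true(all(cls %in% c("attracted", "dispersed", "neutral")))
  expect_equal(length(cls), 400L)
  swapped <- classify_pair(mc, pc)
  expect_equal(swapped[cls == "attracted"],
               rep("dispersed", sum(cls == "attracted")))
  expect_equal(swapped[cls == "dispersed"],
               rep("attracted", sum(cls == "dispersed")))
  expect_equal(swapped[cls == "neutral"],
               rep("neutral", sum(cls == "neutral")))
})

test_that("MC selection and the pair table are deterministic", {
  log <- simulate_log(simulation_config(seed = 22))
  p1 <- build_pcmc_pairs(log)
  p2 <- build_pcmc_pairs(log)
  expect_identical(p1, p2)
  # attracted + dispersed + neutral = analysable pairs
  nc <- p1[!p1$male_coercion & p1$opp_analysable, ]
  expect_equal(sum(table(nc$opp_class)), nrow(nc))
})

test_that("victim proportions respect the minimum-received threshold", {
  pc <- c(1, 1, 3, NA)
  mc <- c(NA, 2, 3, 2)
  pairs <- make_pairs(pc, mc)             # one victim, four pairs
  pairs2 <- make_pairs(c(1, NA), c(NA, 1), focal = "Su")
  all_pairs <- dplyr::bind_rows(pairs, pairs2)
  props <- victim_proportions(all_pairs, "opponent", min_received = 3)
  expect_equal(props$focal, "Dm")          # Su's two pairs fall below
  expect_equal(props$attracted, 0.5)
  expect_equal(props$dispersed, 0.25)
  expect_equal(props$neutral, 0.25)
  expect_error(victim_proportions(pairs2, "opponent", min_received = 3),
               "minimum")
  # a single eligible victim gives the two-sign p of 0.5
  expect_equal(reconciliation_test(props)$p, 0.5)
})

test_that("build_pcmc_pairs agrees with the single-conflict operations", {
  log <- simulate_log(simulation_config(seed = 23))
  pairs <- build_pcmc_pairs(log)
  idx <- which(is.na(pairs$excluded_reason))[1:10]
  for (i in idx) {
    pc <- extract_pc(log, pairs$conflict_id[i])
    expect_equal(pc$anchor_s, pairs$pc_anchor_s[i])
    mc <- select_mc(log, pc)
    expect_equal(mc$date, pairs$mc_date[i])
    expect_equal(mc$start_s, pairs$mc_start_s[i])
    lat <- first_affiliation_latency(log, pc$date, pc$anchor_s, pc$focal,
                                     pc$opponent, "opponent")
    expect_equal(lat,
                 if (pairs$opp_unspec[i]) "unspecifiable" else
                   pairs$opp_pc[i])
  }
})
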