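test_that("histograms and cumulative curves count first contacts only once", {
  pairs <- make_pairs(pc = c(3, 1, NA, 2, NA), mc = c(NA, 1, NA, 5, 2))
  h <- latency_histograms(pairs, "opponent")
  expect_equal(h$pc_n[c(1, 2, 3)], c(1L, 1L, 1L))
  expect_equal(sum(h$pc_n), 3L)
  expect_equal(sum(h$mc_n), 3L)
  cv <- cumulative_curves(pairs, "opponent")
  expect_equal(attr(cv, "n_pairs"), 5L)
  # contact-free pairs stay in the denominator
  expect_equal(cv$pc_prop[10], 3 / 5)
  expect_equal(cv$delta, cv$pc_prop - cv$mc_prop)
  expect_true(all(diff(cv$pc_cum_n) >= 0))
})

test_that("identical PC and MC latencies give flat zero delta and OR 1", {
  pairs <- make_pairs(pc = c(1, 2, 5, NA), mc = c(1, 2, 5, NA))
  cv <- cumulative_curves(pairs, "opponent")
  expect_true(all(cv$delta == 0))
  ia <- interval_association(pairs, "opponent", t = 2)
  expect_equal(ia$or_cmle, 1, tolerance = 1e-6)
  cr <- critical_interval(cv, pairs = pairs, target = "opponent")
  expect_equal(cr$t_star, 1L)          # earliest interval on a flat tie
  expect_true(cr$degenerate)
})

test_that("exchanging PC and MC latencies negates delta", {
  pairs <- make_pairs(pc = c(1, 1, 2, NA, 4), mc = c(2, NA, 6, 3, NA))
  flipped <- make_pairs(pc = c(2, NA, 6, 3, NA), mc = c(1, 1, 2, NA, 4))
  expect_equal(cumulative_curves(flipped, "opponent")$delta,
               -cumulative_curves(pairs, "opponent")$delta)
})

test_that("interval association at t = 10 contrasts contact-bearing pairs", {
  pairs <- make_pairs(pc = c(1, 2, NA, NA, 7), mc = c(NA, NA, NA, 3, 9))
  ia <- interval_association(pairs, "opponent", t = 10)
  expect_equal(unname(ia$table[, "contact"]), c(3, 2))
  expect_equal(unname(ia$table[, "none"]), c(2, 3))
})

test_that("the critical interval maximises delta, earliest on ties", {
  pairs <- make_pairs(pc = c(1, 1, 1, 2, NA, NA),
                      mc = c(NA, NA, 5, NA, 4, NA))
  cv <- cumulative_curves(pairs, "opponent")
  cr <- critical_interval(cv, pairs = pairs, target = "opponent")
  expect_equal(cr$t_star, which.max(cv$delta))
  expect_equal(cr$delta_max, max(cv$delta))
  expect_true(is.finite(cr$or_max) || is.na(cr$or_max))
})

test_that("reconciliation labels equal the PC cumulative count at t*", {
  pairs <- make_pairs(pc = c(1, 2, 2, 5, NA, NA),
                      mc = c(NA, NA, 1, NA, NA, 3))
  cv <- cumulative_curves(pairs, "opponent")
  for (t_star in c(1L, 2L, 10L)) {
    lab <- label_reconciled(pairs, t_star, "opponent")
    expect_equal(lab$n_reconciled, cv$pc_cum_n[t_star])
    expect_equal(lab$n_pairs, 6L)
  }
  # a pair without PC contact is never labelled reconciled
  expect_false(any(label_reconciled(pairs, 10L, "opponent")$labels$reconciled[5:6]))
})

test_that("the KS stage compares contact-bearing latency distributions", {
  pairs <- make_pairs(pc = c(1, 1, 2, NA), mc = c(8, 9, 10, NA))
  r <- ks_contacts(pairs, "opponent")
  expect_equal(r$D, 1)
  same <- make_pairs(pc = c(1, 3, 5), mc = c(1, 3, 5))
  expect_equal(ks_contacts(same, "opponent")$D, 0)
  pairs2 <- make_pairs(pc = c(1, 2, NA), mc = c(1, 2, 3))
  expect_equal(ks_contacts(pairs2, "opponent")$D, 1 / 3, tolerance = 1e-12)
  none <- make_pairs(pc = c(NA, NA), mc = c(1, 2))
  expect_error(ks_contacts(none, "opponent"), "contact-bearing")
})
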