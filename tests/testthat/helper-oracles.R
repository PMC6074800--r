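## Independent oracles (brute force / enumeration / direct evaluation)
## used to cross-check the exact-statistics kernel, plus small builders
## for toy logs and pair tables.

# Full 2^n enumeration of sign assignments, conditioning on observed ranks.
signed_rank_oracle <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(grid %*% r)
  switch(alternative,
         greater = mean(ws >= wobs - 1e-9),
         less = mean(ws <= wobs + 1e-9),
         two_sided = mean(abs(ws - sum(r) / 2) >= abs(wobs - sum(r) / 2) - 1e-9))
}

# Conditional-likelihood grid + refine oracle for the 2x2 cMLE odds ratio.
or_cmle_oracle <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  support <- lo:hi
  ld <- lchoose(m, support) + lchoose(n2, k - support)
  loglik <- function(lpsi) {
    lw <- ld + support * lpsi
    x * lpsi + ld[support == x] - (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  grid <- seq(-15, 15, length.out = 2001)
  best <- grid[which.max(vapply(grid, loglik, 0))]
  exp(stats::optimize(loglik, c(best - 0.1, best + 0.1), maximum = TRUE)$maximum)
}

# Direct ECDF evaluation at all pooled points.
ks_D_oracle <- function(xs, ys) {
  pts <- sort(unique(c(xs, ys)))
  max(abs(vapply(pts, function(t) mean(xs <= t) - mean(ys <= t), 0)))
}

# Exhaustive enumeration of r x 2 tables with fixed margins.
fisher_rxc_oracle <- function(tab) {
  rows <- rowSums(tab); k <- sum(tab[, 1]); n <- sum(rows)
  grid <- expand.grid(lapply(rows, function(m) 0:m))
  grid <- grid[rowSums(grid) == k, , drop = FALSE]
  lp <- apply(grid, 1, function(x) sum(lchoose(rows, x))) - lchoose(n, k)
  lpobs <- sum(lchoose(rows, tab[, 1])) - lchoose(n, k)
  sum(exp(lp)[exp(lp) <= exp(lpobs) * (1 + 1e-7)])
}

## ---- toy data builders -------------------------------------------------

toy_setup <- function(days = 10, hours = 3, condition = "indoor",
                      start = as.Date("2020-06-01")) {
  study_setup(default_roster(),
              tibble::tibble(date = start + seq_len(days) - 1,
                             start_s = 8 * 3600, duration_h = hours,
                             condition = condition))
}

agg_row <- function(id, date, on, off = on + 30, a = "To", v = "Dm",
                    cond = "indoor", context = "spontaneous",
                    intensity = "medium", behaviour = "chase",
                    reaction = "avoidance", mesh = FALSE, undet = FALSE) {
  tibble::tibble(event_id = id, date = as.Date(date), onset_s = on,
                 offset_s = off, condition = cond, aggressor = a,
                 victim = v, behaviour = behaviour, intensity = intensity,
                 context = context, through_mesh = mesh,
                 reaction = reaction, intervention_undetermined = undet)
}

aff_row <- function(id, date, on, pa, pb, cond = "indoor",
                    beh = "touch_body", vis = TRUE, init = pa) {
  tibble::tibble(event_id = id, date = as.Date(date), onset_s = on,
                 condition = cond, participant_a = pa, participant_b = pb,
                 behaviour = beh, initiator = init, visibility_ok = vis)
}

# Minimal pair table for exercising the time-rule stage directly.
make_pairs <- function(pc, mc, focal = "Dm", opponent = "To") {
  n <- length(pc)
  tibble::tibble(
    conflict_id = sprintf("AG%03d", seq_len(n)), focal = focal,
    opponent = opponent, condition = "indoor",
    date = as.Date("2020-06-01"), male_coercion = FALSE,
    pc_anchor_s = 0, resumed = FALSE, excluded_reason = NA_character_,
    mc_date = as.Date("2020-06-02"), mc_start_s = 0,
    mc_day_offset = 1L, mc_clock_offset_s = 0,
    opp_pc = as.integer(pc), opp_mc = as.integer(mc),
    tp_pc = NA_integer_, tp_mc = NA_integer_,
    opp_unspec = FALSE, tp_unspec = FALSE,
    opp_class = classify_pair(pc, mc), tp_class = NA_character_,
    opp_analysable = TRUE, tp_analysable = FALSE)
}
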