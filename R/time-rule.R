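## The time-rule method: per-interval first-contact histograms, cumulative
## curves, interval-wise association tests, the critical interval, and the
## operational reconciliation/PCTA labelling it induces.

N_INTERVALS <- 10L

#' First-contact latency histograms
#'
#' Counts, per 1-minute interval, the analysable pairs whose first
#' affiliative contact fell in that interval, separately for the PC and MC
#' windows.
#'
#' @param pairs Pair table from [build_pcmc_pairs()].
#' @param target `"opponent"` or `"third_party"`.
#' @param include_male_coercion Pool male sexual-coercion conflicts.
#' @return Tibble: `interval`, `pc_n`, `mc_n`.
#' @export
latency_histograms <- function(pairs, target = c("opponent", "third_party"),
                               include_male_coercion = FALSE) {
  p <- pairs_for_target(pairs, target, include_male_coercion)
  tibble::tibble(
    interval = seq_len(N_INTERVALS),
    pc_n = vapply(seq_len(N_INTERVALS),
                  function(t) sum(p$pc_int == t, na.rm = TRUE), 0L),
    mc_n = vapply(seq_len(N_INTERVALS),
                  function(t) sum(p$mc_int == t, na.rm = TRUE), 0L))
}

#' Cumulative first-contact curves and their gap
#'
#' Cumulated relative frequencies of first contacts over the ten 1-minute
#' intervals, for PC and MC. Denominators are *all* analysable pairs:
#' contact-free pairs contribute to the denominator but never to a
#' numerator. `delta` is the PC-minus-MC gap of cumulative proportions per
#' interval.
#'
#' @inheritParams latency_histograms
#' @return Tibble of class `cumulative_curves`: `interval`, `pc_cum_n`,
#'   `mc_cum_n`, `pc_prop`, `mc_prop`, `delta`; attribute `n_pairs`.
#' @export
cumulative_curves <- function(pairs, target = c("opponent", "third_party"),
                              include_male_coercion = FALSE) {
  p <- pairs_for_target(pairs, target, include_male_coercion)
  n <- nrow(p)
  if (n == 0) abort("no analysable pairs for cumulative curves")
  h <- latency_histograms(pairs, target, include_male_coercion)
  out <- tibble::tibble(
    interval = h$interval,
    pc_cum_n = cumsum(h$pc_n), mc_cum_n = cumsum(h$mc_n),
    pc_prop = cumsum(h$pc_n) / n, mc_prop = cumsum(h$mc_n) / n)
  out$delta <- out$pc_prop - out$mc_prop
  attr(out, "n_pairs") <- n
  class(out) <- c("cumulative_curves", class(out))
  out
}

#' Interval-wise association between window type and contact occurrence
#'
#' For interval `t`, tests the 2x2 table of pairs with versus without a
#' first contact by minute `t`, in PC versus MC, with the exact 2x2 kernel;
#' the conditional-MLE odds ratio quantifies how much more probable an
#' affiliative contact is after a conflict.
#'
#' @inheritParams latency_histograms
#' @param t Interval index 1..10.
#' @return A `fisher_result` (table rows PC/MC, columns contact/none).
#' @export
interval_association <- function(pairs, target = c("opponent", "third_party"),
                                 t, include_male_coercion = FALSE) {
  stopifnot(t >= 1, t <= N_INTERVALS)
  p <- pairs_for_target(pairs, target, include_male_coercion)
  n <- nrow(p)
  pc_le <- sum(p$pc_int <= t, na.rm = TRUE)
  mc_le <- sum(p$mc_int <= t, na.rm = TRUE)
  tab <- matrix(c(pc_le, n - pc_le, mc_le, n - mc_le), 2, 2, byrow = TRUE,
                dimnames = list(c("pc", "mc"), c("contact", "none")))
  fisher_exact_2x2(tab)
}

#' KS comparison of first-contact latency distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the first-contact latency
#' intervals of contact-bearing pairs, PC versus MC. With 1-minute binning
#' ties are always present, so the p-value is the asymptotic one and is
#' flagged as such.
#'
#' @inheritParams latency_histograms
#' @return A `ks_result`.
#' @export
ks_contacts <- function(pairs, target = c("opponent", "third_party"),
                        include_male_coercion = FALSE) {
  p <- pairs_for_target(pairs, target, include_male_coercion)
  xs <- p$pc_int[!is.na(p$pc_int)]
  ys <- p$mc_int[!is.na(p$mc_int)]
  if (length(xs) == 0 || length(ys) == 0) {
    abort("need at least one contact-bearing pair per window type")
  }
  ks_two_sample(xs, ys)
}

#' Determine the critical post-conflict interval
#'
#' The critical interval is the minute at which the gap between the
#' cumulative PC and MC curves is largest (earliest interval on ties). The
#' interval with the largest interval-wise odds ratio is recorded
#' alongside, so that a disagreement between the two criteria is visible.
#'
#' @param curves A [cumulative_curves()] table.
#' @param assoc Optional list of [interval_association()] results, one per
#'   interval (computed when omitted and `pairs`/`target` are given).
#' @param pairs,target,include_male_coercion Used to compute `assoc` when
#'   not supplied.
#' @return List of class `critical_window`: `t_star`, `delta_max`,
#'   `t_max_or`, `or_max`, `per_interval` (tibble interval/or/p),
#'   `degenerate` (flat zero curves).
#' @export
critical_interval <- function(curves, assoc = NULL, pairs = NULL,
                              target = "opponent",
                              include_male_coercion = FALSE) {
  if (is.null(assoc)) {
    if (is.null(pairs)) abort("supply either `assoc` or `pairs`")
    assoc <- lapply(seq_len(N_INTERVALS), function(t)
      interval_association(pairs, target, t, include_male_coercion))
  }
  t_star <- which.max(curves$delta)  # earliest argmax
  per <- tibble::tibble(
    interval = curves$interval,
    or = vapply(assoc, function(a) a$or_cmle %||% NA_real_, 0),
    p = vapply(assoc, function(a) a$p, 0))
  finite_or <- ifelse(is.finite(per$or), per$or, -Inf)
  t_max_or <- if (all(!is.finite(finite_or))) NA_integer_ else
    which.max(finite_or)
  structure(list(t_star = as.integer(t_star),
                 delta_max = curves$delta[t_star],
                 t_max_or = t_max_or,
                 or_max = if (is.na(t_max_or)) NA_real_ else per$or[t_max_or],
                 per_interval = per,
                 degenerate = all(curves$delta == 0)),
            class = "critical_window")
}

#' @export
print.critical_window <- function(x, ...) {
  cat(sprintf(paste0("Critical interval: minute %d (max delta = %.3f; ",
                     "max OR %.3g at minute %s)\n"),
              x$t_star, x$delta_max, x$or_max, format(x$t_max_or)))
  invisible(x)
}

#' Label conflicts as reconciled (or PCTA-positive)
#'
#' A conflict is operationally reconciled when its PC first contact with
#' the target falls within the critical interval.
#'
#' @inheritParams latency_histograms
#' @param t_star Critical interval from [critical_interval()].
#' @return List: `labels` (tibble `conflict_id`, `reconciled`),
#'   `n_reconciled`, `n_pairs`, `proportion`.
#' @export
label_reconciled <- function(pairs, t_star,
                             target = c("opponent", "third_party"),
                             include_male_coercion = FALSE) {
  p <- pairs_for_target(pairs, target, include_male_coercion)
  lab <- !is.na(p$pc_int) & p$pc_int <= t_star
  list(labels = tibble::tibble(conflict_id = p$conflict_id,
                               reconciled = lab),
       n_reconciled = sum(lab), n_pairs = nrow(p),
       proportion = mean(lab))
}
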