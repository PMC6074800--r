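## Exact small-sample statistics. Sample sizes in this problem domain are
## tiny (five or six focal animals, two-digit conflict counts), so every
## p-value here is computed by enumeration of the exact permutation or
## hypergeometric distribution; nothing uses a normal approximation.

#' Exact Wilcoxon signed-rank test
#'
#' One- or two-sided exact signed-rank test on paired differences. Zero
#' differences are dropped; absolute values are mid-ranked (ties receive
#' averaged ranks) and the null distribution is obtained by enumerating
#' all `2^n` sign assignments *conditioned on the observed rank vector* —
#' the correct exact reference set in the presence of ties. The reported
#' statistic `T` is the sum of ranks opposing the alternative (so `T = 0`
#' means every difference favours it), matching the convention used when
#' reporting, e.g., `n = 5, T = 0, p = 0.031`.
#'
#' @param differences Numeric vector of paired differences.
#' @param alternative `"greater"` (positive differences expected),
#'   `"less"`, or `"two_sided"`.
#' @return A list of class `signed_rank_result`: `T`, `n_used`, `p`,
#'   `alternative`.
#' @examples
#' exact_signed_rank_test(c(.1, .2, .3, .4, .5), "greater")  # T = 0, p = 1/32
#' @export
exact_signed_rank_test <- function(differences,
                                   alternative = c("greater", "less",
                                                   "two_sided")) {
  alternative <- match.arg(alternative)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    abort("signed-rank test undefined: no nonzero differences")
  }
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled mid-ranks: integers
  tot <- sum(r2)
  ## exact distribution of the doubled positive rank sum, by the
  ## generating polynomial prod_i (1 + x^r2_i); counts stay exact in
  ## doubles for n <= ~50
  counts <- numeric(tot + 1L); counts[1L] <- 1
  for (w in r2) {
    counts[(w + 1L):(tot + 1L)] <- counts[(w + 1L):(tot + 1L)] +
      counts[1L:(tot + 1L - w)]
  }
  wpos <- sum(r2[d > 0])  # doubled W+
  total <- 2^n
  p_ge <- sum(counts[(wpos + 1L):(tot + 1L)]) / total   # P(W+ >= obs)
  p_le <- sum(counts[1L:(wpos + 1L)]) / total           # P(W+ <= obs)
  if (alternative == "greater") {
    Tstat <- (tot - wpos) / 2  # rank sum of negative differences
    p <- p_ge
  } else if (alternative == "less") {
    Tstat <- wpos / 2
    p <- p_le
  } else {
    dev <- abs(2 * wpos - tot)  # doubled |W+ - E(W+)| * 2
    devs <- abs(2 * seq(0L, tot) - tot)
    p <- sum(counts[devs >= dev]) / total
    Tstat <- min(wpos, tot - wpos) / 2
  }
  structure(list(T = Tstat, n_used = n, p = p, alternative = alternative),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon signed-rank: n = %d, T = %g, p = %.4g (%s)\n",
              x$n_used, x$T, x$p, x$alternative))
  invisible(x)
}

## Conditional-MLE odds ratio of a 2x2 table: the psi maximising the
## noncentral hypergeometric likelihood, i.e. solving E_psi[X] = x.
.or_cmle <- function(x, m, n2, k) {
  lo <- max(0L, k - n2); hi <- min(k, m)
  if (lo == hi) return(NA_real_)          # degenerate margin
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  support <- lo:hi
  ldc <- lchoose(m, support) + lchoose(n2, k - support)
  mean_nc <- function(lpsi) {
    lw <- ldc + support * lpsi
    w <- exp(lw - max(lw))
    sum(support * w) / sum(w)
  }
  f <- function(lpsi) mean_nc(lpsi) - x
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root |> exp()
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test of independence with the probability-ordering ("minimum
#' likelihood") two-sided rule: the two-sided p is the sum of hypergeometric
#' probabilities not exceeding that of the observed table, with a
#' `1 + 1e-7` relative tolerance on the comparison. The reported odds ratio
#' is the conditional maximum-likelihood estimate (0 or `Inf` when the
#' observed count sits at the boundary of its support).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (tail of the
#'   (1,1) cell).
#' @return List of class `fisher_result`: `p`, `or_cmle`, `table`,
#'   `alternative`, `degenerate` (TRUE when a margin is zero).
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    abort("2x2 table must hold non-negative integer counts")
  }
  x <- table[1, 1]; m <- sum(table[1, ]); n2 <- sum(table[2, ])
  k <- sum(table[, 1])
  degenerate <- m == 0 || n2 == 0 || k == 0 || k == m + n2
  if (degenerate) {
    return(structure(list(p = 1, or_cmle = NA_real_, table = table,
                          alternative = alternative, degenerate = TRUE),
                     class = "fisher_result"))
  }
  lo <- max(0, k - n2); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n2, k)
  pobs <- stats::dhyper(x, m, n2, k)
  p <- switch(alternative,
    two_sided = sum(dens[dens <= pobs * (1 + 1e-7)]),
    greater   = sum(dens[support >= x]),
    less      = sum(dens[support <= x]))
  structure(list(p = min(p, 1), or_cmle = .or_cmle(x, m, n2, k),
                 table = table, alternative = alternative,
                 degenerate = FALSE),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact: p = %.4g, cMLE odds ratio = %s\n",
              x$p, format(x$or_cmle)))
  invisible(x)
}

#' Fisher's exact test for an r x 2 table
#'
#' Exact test of independence for `r` rows by two columns, used as an
#' influence control (rows = individuals or dyads). All tables with the
#' observed margins are enumerated when their number does not exceed
#' `exact_limit`; the p-value is the total probability of tables no more
#' probable than the observed one (same `1 + 1e-7` tolerance as the 2x2
#' kernel). Larger problems fall back to Monte-Carlo sampling of
#' margin-fixed tables (via [stats::r2dtable()]), reporting the estimate
#' and its standard error.
#'
#' @param table r x 2 matrix of non-negative integer counts.
#' @param exact_limit Maximum number of candidate tables for full
#'   enumeration.
#' @param mc_reps Monte-Carlo replicates for the fallback.
#' @param seed Seed for the fallback sampler.
#' @return List of class `fisher_rxc_result`: `p`, `method`
#'   (`"exact"`/`"monte_carlo"`), `se` (NA for exact), `table`.
#' @export
fisher_exact_rxc <- function(table, exact_limit = 1e6, mc_reps = 1e5,
                             seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("table must hold non-negative integer counts")
  }
  if (ncol(table) != 2L) abort("influence-control table must have 2 columns")
  table <- table[rowSums(table) > 0, , drop = FALSE]  # empty rows carry nothing
  r <- nrow(table)
  if (r < 2L) {
    return(structure(list(p = 1, method = "exact", se = NA_real_,
                          table = table), class = "fisher_rxc_result"))
  }
  rows <- rowSums(table); k <- sum(table[, 1]); n <- sum(rows)
  lpobs <- sum(lchoose(rows, table[, 1])) - lchoose(n, k)
  n_candidates <- prod(pmin(rows, k) + 1)
  if (n_candidates <= exact_limit) {
    ## depth-first enumeration of first-column counts with fixed margins
    logp <- numeric(0)
    recurse <- function(i, remaining, acc_l) {
      if (i == r) {
        if (remaining <= rows[r]) {
          logp[length(logp) + 1L] <<- acc_l + lchoose(rows[r], remaining)
        }
        return(invisible())
      }
      hi <- min(rows[i], remaining)
      lo <- max(0, remaining - sum(rows[(i + 1):r]))
      for (x in lo:hi) {
        recurse(i + 1L, remaining - x, acc_l + lchoose(rows[i], x))
      }
    }
    recurse(1L, k, 0)
    logp <- logp - lchoose(n, k)
    p <- sum(exp(logp)[exp(logp) <= exp(lpobs) * (1 + 1e-7)])
    structure(list(p = min(p, 1), method = "exact", se = NA_real_,
                   table = table), class = "fisher_rxc_result")
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sims <- stats::r2dtable(mc_reps, rows, c(k, n - k))
    lps <- vapply(sims, function(tt)
      sum(lchoose(rows, tt[, 1])) - lchoose(n, k), 0)
    hits <- sum(lps <= lpobs + log(1 + 1e-7))
    p <- (hits + 1) / (mc_reps + 1)
    structure(list(p = p, method = "monte_carlo",
                   se = sqrt(p * (1 - p) / mc_reps), table = table),
              class = "fisher_rxc_result")
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.fisher_rxc_result <- function(x, ...) {
  cat(sprintf("Fisher exact (r x 2, %s): p = %.4g\n", x$method, x$p))
  invisible(x)
}

## Exact two-sample KS tail probability P(D >= d) by counting monotone
## lattice paths that stay strictly below the band |i/n - j/m| >= d.
## Path counts are exact in doubles while choose(n+m, n) < 2^53.
.ks_exact_p <- function(n, m, d) {
  eps <- 1e-9
  A <- matrix(0, n + 1, m + 1)
  A[1, 1] <- 1
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    if (abs(i / n - j / m) >= d - eps) { A[i + 1, j + 1] <- 0; next }
    acc <- 0
    if (i > 0) acc <- acc + A[i, j + 1]
    if (j > 0) acc <- acc + A[i + 1, j]
    A[i + 1, j + 1] <- acc
  }
  1 - A[n + 1, m + 1] / choose(n + m, n)
}

## Kolmogorov asymptotic tail: P(D >= d) ~ 2 sum (-1)^{k-1} exp(-2 k^2 t^2)
.ks_asymp_p <- function(n, m, d) {
  t <- sqrt(n * m / (n + m)) * d
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum gap between the two empirical CDFs, evaluated at all
#' pooled sample points. The p-value is exact (lattice-path enumeration)
#' when neither sample has ties with the other and the path count is
#' representable; otherwise the asymptotic Kolmogorov series is used and
#' `ties_present` flags the p-value as approximate (the latency data this
#' package handles are binned to 1-minute intervals, so ties are the rule).
#'
#' @param xs,ys Non-empty numeric samples.
#' @return List of class `ks_result`: `D`, `p`, `n`, `m`, `ties_present`,
#'   `p_exact` (logical).
#' @export
ks_two_sample <- function(xs, ys) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  n <- length(xs); m <- length(ys)
  if (n == 0 || m == 0) abort("both samples must be non-empty")
  pooled <- sort(unique(c(xs, ys)))
  Fx <- vapply(pooled, function(t) mean(xs <= t), 0)
  Fy <- vapply(pooled, function(t) mean(ys <= t), 0)
  D <- max(abs(Fx - Fy))
  ties <- anyDuplicated(c(xs, ys)) > 0
  exact_ok <- !ties && is.finite(choose(n + m, n)) &&
    choose(n + m, n) < 2^53
  p <- if (exact_ok) .ks_exact_p(n, m, D) else .ks_asymp_p(n, m, D)
  structure(list(D = D, p = p, n = n, m = m, ties_present = ties,
                 p_exact = exact_ok),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4g, p = %.4g (%s%s)\n", x$D, x$p,
              if (x$p_exact) "exact" else "asymptotic",
              if (x$ties_present) ", ties present" else ""))
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two equal-length categorical codings
#' over a shared category universe.
#'
#' @param labels_a,labels_b Vectors of category labels, same length.
#' @return List of class `kappa_result`: `kappa`, `p_observed`,
#'   `p_expected`, `n_items`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("label vectors must have equal length")
  }
  n <- length(labels_a)
  if (n < 1) abort("need at least one rated item")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(kappa = kappa, p_observed = po, p_expected = pe,
                 n_items = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
              x$kappa, x$p_observed, x$p_expected, x$n_items))
  invisible(x)
}
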