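## Descriptive and condition-contrast analyses of the aggression log.

#' Segment aggressions into causally connected sequences
#'
#' Greedy chaining: an aggression joins the open sequence when its onset
#' falls within `gap_s` seconds of the previous member's end (the 4-minute
#' rule); otherwise it opens a new sequence. Singleton sequences are the
#' "distinct" conflicts.
#'
#' @param log An [ethogram_log()] (aggressions are used).
#' @param gap_s Chaining gap in seconds (default 240 = 4 min).
#' @return A tibble, one row per aggression: `event_id`, `sequence_id`,
#'   `sequence_size`, `is_distinct`, with attribute `summary` (list:
#'   `n_distinct`, `n_in_sequences`, `sequence_sizes`).
#' @export
segment_conflicts <- function(log, gap_s = 240) {
  ag <- log$aggressions
  if (nrow(ag) == 0) {
    out <- tibble::tibble(event_id = character(), sequence_id = integer(),
                          sequence_size = integer(), is_distinct = logical())
    attr(out, "summary") <- list(n_distinct = 0L, n_in_sequences = 0L,
                                 sequence_sizes = integer())
    return(out)
  }
  t_on <- .abs_time(log$setup, ag$date, ag$onset_s)
  t_off <- .abs_time(log$setup, ag$date, ag$offset_s)
  ord <- order(t_on)
  seq_id <- integer(nrow(ag))
  cur <- 1L
  seq_id[ord[1]] <- 1L
  if (nrow(ag) > 1) {
    for (i in 2:nrow(ag)) {
      prev <- ord[i - 1]; this <- ord[i]
      if (t_on[this] - t_off[prev] <= gap_s) {
        seq_id[this] <- cur
      } else {
        cur <- cur + 1L
        seq_id[this] <- cur
      }
    }
  }
  sizes <- table(seq_id)
  out <- tibble::tibble(
    event_id = ag$event_id, sequence_id = seq_id,
    sequence_size = as.integer(sizes[as.character(seq_id)]),
    is_distinct = as.integer(sizes[as.character(seq_id)]) == 1L)
  attr(out, "summary") <- list(
    n_distinct = sum(sizes == 1L),
    n_in_sequences = sum(out$sequence_size > 1L),
    sequence_sizes = as.integer(sizes[sizes > 1L]))
  out
}

#' Default ethogram intensity map
#'
#' Assigns each aggressive behavioural element a rank among
#' low/medium/high; an aggression's intensity is that of its most intense
#' constituent.
#'
#' @return Named character vector, element -> level.
#' @export
default_intensity_map <- function() {
  c(gentle_push = "low", pull_fur = "low", poke = "low", grab = "low",
    hit = "medium", chase = "medium", grab_and_pull = "medium",
    wrestle = "medium", shove = "medium",
    bite = "high", bite_attempt = "high", lunge_attack = "high")
}

#' Intensity of a composite aggression
#'
#' @param behaviour_elements Character vector of ethogram codes (one
#'   aggression's constituents).
#' @param intensity_map Named vector mapping elements to
#'   `low`/`medium`/`high`.
#' @return `"low"`, `"medium"`, `"high"`, or `"undetermined"` when the
#'   element list is empty or any element is unmapped.
#' @export
aggression_intensity <- function(behaviour_elements,
                                 intensity_map = default_intensity_map()) {
  if (length(behaviour_elements) == 0) return("undetermined")
  lv <- unname(intensity_map[behaviour_elements])
  if (anyNA(lv)) return("undetermined")
  c("low", "medium", "high")[max(match(lv, c("low", "medium", "high")))]
}

#' Context-by-intensity summary of the aggression log
#'
#' @param log An [ethogram_log()].
#' @return A tibble with one row per (context, intensity) cell: `n` and
#'   `proportion` of all aggressions; zero cells included.
#' @export
summarize_contexts <- function(log) {
  ag <- log$aggressions
  grid <- tidyr::expand_grid(context = .pcmc_vocab$context,
                             intensity = .pcmc_vocab$intensity)
  if (nrow(ag) == 0) return(dplyr::mutate(grid, n = 0L, proportion = NA_real_))
  counts <- dplyr::count(ag, .data$context, .data$intensity)
  out <- dplyr::left_join(grid, counts, by = c("context", "intensity"))
  out$n[is.na(out$n)] <- 0L
  out$proportion <- out$n / nrow(ag)
  out
}

#' Per-individual aggression rates and the housing-condition test
#'
#' Computes each individual's aggression rate (as aggressor) per
#' observation hour in each housing condition, and tests whether rates
#' increase under the less spacious (indoor) condition with an exact
#' one-tailed signed-rank test on the paired indoor-minus-outdoor
#' differences (individuals with a zero difference drop out under the
#' test's zero rule).
#'
#' @param log An [ethogram_log()].
#' @return List of class `rate_result`: `rates` (tibble individual x
#'   condition with `n`, `hours`, `rate`), `medians` (named by condition,
#'   across all roster individuals), `test` (a `signed_rank_result`).
#' @export
aggression_rates <- function(log) {
  setup <- log$setup
  if (!all(c("indoor", "outdoor") %in% names(setup$hours))) {
    abort("both condition hour totals are required to compare rates")
  }
  ids <- setup$roster$id
  grid <- tidyr::expand_grid(individual = ids,
                             condition = c("outdoor", "indoor"))
  counts <- dplyr::count(log$aggressions, individual = .data$aggressor,
                         .data$condition)
  rates <- dplyr::left_join(grid, counts, by = c("individual", "condition"))
  rates$n[is.na(rates$n)] <- 0L
  rates$hours <- unname(setup$hours[rates$condition])
  rates$rate <- rates$n / rates$hours
  wide <- tidyr::pivot_wider(rates[c("individual", "condition", "rate")],
                             names_from = "condition", values_from = "rate")
  medians <- c(outdoor = stats::median(wide$outdoor),
               indoor = stats::median(wide$indoor))
  test <- exact_signed_rank_test(wide$indoor - wide$outdoor, "greater")
  structure(list(rates = rates, medians = medians, test = test),
            class = "rate_result")
}

#' Housing-condition effect on aggression intensity
#'
#' Pooled 2x2 Fisher test (high vs not-high intensity by indoor vs
#' outdoor); events of undetermined intensity carry no level and are
#' excluded. The influence control is an exact r x 2 test of the
#' individual-by-condition distribution of high-intensity aggressions.
#'
#' @param log An [ethogram_log()].
#' @return List: `pooled` (a `fisher_result`; `degenerate` flagged when a
#'   condition is absent), `influence` (a `fisher_rxc_result` or NULL).
#' @export
condition_intensity_test <- function(log) {
  ag <- log$aggressions[log$aggressions$intensity != "undetermined", ]
  tab <- matrix(c(
    sum(ag$intensity == "high" & ag$condition == "indoor"),
    sum(ag$intensity != "high" & ag$condition == "indoor"),
    sum(ag$intensity == "high" & ag$condition == "outdoor"),
    sum(ag$intensity != "high" & ag$condition == "outdoor")),
    2, 2, byrow = TRUE,
    dimnames = list(c("indoor", "outdoor"), c("high", "not_high")))
  pooled <- fisher_exact_2x2(tab)
  hi <- ag[ag$intensity == "high", ]
  influence <- NULL
  if (nrow(hi) > 0) {
    itab <- as.matrix(table(factor(hi$aggressor),
                            factor(hi$condition,
                                   levels = c("indoor", "outdoor"))))
    if (nrow(itab) >= 2) influence <- fisher_exact_rxc(itab)
  }
  list(pooled = pooled, influence = influence)
}

#' Mesh (subgroup separation) effect on aggression frequency
#'
#' Classifies every aggression dyad as "separated" (members belong to
#' different indoor subgroups) or not, and runs the pooled 2x2 Fisher test
#' of condition by separation.
#'
#' @param log An [ethogram_log()].
#' @return A `fisher_result`.
#' @export
mesh_effect_test <- function(log) {
  ag <- log$aggressions
  roster <- log$setup$roster
  sg <- function(id) roster$subgroup[match(id, roster$id)]
  sep <- sg(ag$aggressor) != sg(ag$victim)
  if (any(is.na(sep) & ag$condition == "indoor")) {
    abort("indoor events with unknown subgroup; run validate_log()")
  }
  tab <- matrix(c(sum(sep & ag$condition == "indoor", na.rm = TRUE),
                  sum(!sep & ag$condition == "indoor", na.rm = TRUE),
                  sum(sep & ag$condition == "outdoor", na.rm = TRUE),
                  sum(!sep & ag$condition == "outdoor", na.rm = TRUE)),
                2, 2, byrow = TRUE,
                dimnames = list(c("indoor", "outdoor"),
                                c("separated", "not_separated")))
  fisher_exact_2x2(tab)
}

#' Directed, weighted aggression network
#'
#' @param log An [ethogram_log()].
#' @return List: `edges` (tibble `aggressor`, `victim`, `condition`,
#'   `weight`), `totals` (tibble `aggressor`, `n`, `share` over all
#'   aggressions).
#' @export
aggression_network <- function(log) {
  ag <- log$aggressions
  if (nrow(ag) == 0) {
    return(list(edges = tibble::tibble(aggressor = character(),
                                       victim = character(),
                                       condition = character(),
                                       weight = integer()),
                totals = tibble::tibble(aggressor = character(),
                                        n = integer(), share = numeric())))
  }
  edges <- dplyr::count(ag, .data$aggressor, .data$victim, .data$condition,
                        name = "weight")
  totals <- dplyr::count(ag, .data$aggressor)
  totals$share <- totals$n / nrow(ag)
  list(edges = edges, totals = totals)
}
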