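## Third-party interventions: tabulation, the housing-condition contrast,
## and the separate summary of the male sexual-coercion context.

#' Tabulate third-party interventions
#'
#' Summarises interventions over all conflicts outside the male
#' sexual-coercion context (which is reported separately by
#' [coercion_summary()]). A conflict whose intervention status could not be
#' determined is flagged; by default it stays in the denominator as
#' not-intervened, `drop_undetermined = TRUE` removes it.
#'
#' @param log An [ethogram_log()].
#' @param drop_undetermined Drop conflicts with undeterminable intervention
#'   status from the denominator.
#' @return List of class `intervention_summary`: `n_conflicts_considered`,
#'   `n_undetermined`, `n_intervened`, `n_interventions`, `mode_counts`,
#'   `success_counts`, `by_intervener` (tibble), `matrix` (intervener x
#'   victim counts).
#' @export
tabulate_interventions <- function(log, drop_undetermined = FALSE) {
  ag <- log$aggressions[!is_male_coercion(log), ]
  undet <- !is.na(ag$intervention_undetermined) & ag$intervention_undetermined
  if (drop_undetermined) ag <- ag[!undet, ]
  iv <- log$interventions[log$interventions$event_id %in% ag$event_id, ]
  intervened_ids <- unique(iv$event_id)
  victims <- ag$victim[match(iv$event_id, ag$event_id)]
  mat <- if (nrow(iv)) as.matrix(table(iv$intervener, victims)) else
    matrix(0L, 0, 0)
  structure(list(
    n_conflicts_considered = nrow(ag),
    n_undetermined = if (drop_undetermined) sum(undet) else sum(undet),
    n_intervened = length(intervened_ids),
    n_interventions = nrow(iv),
    mode_counts = c(peaceful = sum(iv$mode == "peaceful"),
                    aggressive = sum(iv$mode == "aggressive")),
    success_counts = c(successful = sum(iv$successful),
                       unsuccessful = sum(!iv$successful)),
    by_intervener = dplyr::count(iv, .data$intervener, .data$mode),
    matrix = mat),
    class = "intervention_summary")
}

#' @export
print.intervention_summary <- function(x, ...) {
  cat(sprintf(paste0("Interventions: %d of %d conflicts intervened ",
                     "(%.0f%%), %d interventions (%d peaceful)\n"),
              x$n_intervened, x$n_conflicts_considered,
              100 * x$n_intervened / max(x$n_conflicts_considered, 1),
              x$n_interventions, x$mode_counts[["peaceful"]]))
  invisible(x)
}

#' Housing-condition effect on intervention probability
#'
#' Pooled 2x2 Fisher test (conflict intervened vs not, indoor vs outdoor)
#' over conflicts outside the male sexual-coercion context, with an exact
#' r x 2 influence control on the intervener-by-condition counts.
#'
#' @param log An [ethogram_log()].
#' @param drop_undetermined See [tabulate_interventions()].
#' @return List: `pooled` (`fisher_result`, rows indoor/outdoor, columns
#'   intervened/not), `influence` (`fisher_rxc_result` or NULL).
#' @export
intervention_condition_test <- function(log, drop_undetermined = FALSE) {
  ag <- log$aggressions[!is_male_coercion(log), ]
  undet <- !is.na(ag$intervention_undetermined) & ag$intervention_undetermined
  if (drop_undetermined) ag <- ag[!undet, ]
  if (length(unique(ag$condition)) < 2) {
    abort("both housing conditions must be represented")
  }
  intervened <- ag$event_id %in% log$interventions$event_id
  tab <- matrix(c(sum(intervened & ag$condition == "indoor"),
                  sum(!intervened & ag$condition == "indoor"),
                  sum(intervened & ag$condition == "outdoor"),
                  sum(!intervened & ag$condition == "outdoor")),
                2, 2, byrow = TRUE,
                dimnames = list(c("indoor", "outdoor"),
                                c("intervened", "not_intervened")))
  pooled <- fisher_exact_2x2(tab)
  iv <- log$interventions[log$interventions$event_id %in% ag$event_id, ]
  influence <- NULL
  if (nrow(iv)) {
    cond <- ag$condition[match(iv$event_id, ag$event_id)]
    itab <- as.matrix(table(iv$intervener,
                            factor(cond, levels = c("indoor", "outdoor"))))
    if (nrow(itab) >= 2) influence <- fisher_exact_rxc(itab)
  }
  list(pooled = pooled, influence = influence)
}

#' Summary of the male sexual-coercion context
#'
#' Forced copulations are summarised apart from other conflicts: how many
#' provoked an intervention, who intervened in which mode and with what
#' success, and which mother-offspring affiliations followed each event
#' (within the PC window).
#'
#' @param log An [ethogram_log()].
#' @return List of class `coercion_summary`: `n_events` (coercions by the
#'   male), `n_counter_aggressions`, `n_intervened`, `interventions`
#'   (tibble with victim attached), `success_by_intervener`,
#'   `post_event_affiliations` (tibble conflict_id x partner pair of the
#'   victim's first post-event affiliation, if any).
#' @export
coercion_summary <- function(log) {
  mc <- is_male_coercion(log)
  ag <- log$aggressions[mc, ]
  males <- log$setup$roster$id[log$setup$roster$sex == "male" &
                                 log$setup$roster$age_class == "adult"]
  by_male <- ag[ag$aggressor %in% males, ]
  counters <- ag[!ag$aggressor %in% males, ]
  iv <- log$interventions[log$interventions$event_id %in% by_male$event_id, ]
  iv$victim <- by_male$victim[match(iv$event_id, by_male$event_id)]
  succ <- if (nrow(iv)) {
    iv |>
      dplyr::group_by(.data$intervener) |>
      dplyr::summarise(n = dplyr::n(), n_successful = sum(.data$successful),
                       .groups = "drop")
  } else tibble::tibble(intervener = character(), n = integer(),
                        n_successful = integer())
  post <- list()
  for (i in seq_len(nrow(by_male))) {
    e <- by_male[i, ]
    pc <- extract_pc(log, e$event_id)
    if (pc$resumed) next  # the window belongs to the resuming conflict
    lat <- first_affiliation_latency(log, e$date, pc$anchor_s, e$victim,
                                     e$aggressor, "any_third_party")
    if (!identical(lat, NA_integer_) && !identical(lat, "unspecifiable")) {
      post[[length(post) + 1L]] <- tibble::tibble(
        conflict_id = e$event_id, victim = e$victim, interval = lat)
    }
  }
  structure(list(
    n_events = nrow(by_male),
    n_counter_aggressions = nrow(counters),
    n_intervened = length(unique(iv$event_id)),
    interventions = iv,
    success_by_intervener = succ,
    post_event_affiliations = if (length(post)) dplyr::bind_rows(post) else
      tibble::tibble(conflict_id = character(), victim = character(),
                     interval = integer())),
    class = "coercion_summary")
}

#' @export
print.coercion_summary <- function(x, ...) {
  cat(sprintf(paste0("Male sexual coercion: %d events (%d intervened), ",
                     "%d counter-aggressions\n"),
              x$n_events, x$n_intervened, x$n_counter_aggressions))
  invisible(x)
}
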