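## End-to-end orchestration: descriptives -> PC/MC -> time rule ->
## interventions -> contact typology, with optional CSV artefacts.

#' Run the full post-conflict analysis pipeline
#'
#' Executes every stage of the analysis on one event log: conflict
#' descriptives (sequences, contexts, rates, condition contrasts,
#' aggression network), PC/MC pair construction and the reconciliation /
#' third-party-affiliation tests, the time-rule analysis for both targets,
#' intervention summaries and the affiliative contact typology. All
#' numbers in the returned report are the direct output of the exported
#' stage functions.
#'
#' @param log An [ethogram_log()], e.g. from [read_coding_sheet()],
#'   [simulate_log()] or [study_fixture_log()].
#' @param out_dir Optional directory for CSV artefacts (`pairs.csv`,
#'   `curves_*.csv`, `network.csv`, `rates.csv`, `contexts.csv`,
#'   `typology.csv`, `summary.txt`).
#' @param strict Abort when [validate_log()] reports violations.
#' @return A list of class `pcmc_report`.
#' @export
run_pipeline <- function(log, out_dir = NULL, strict = TRUE) {
  issues <- validate_log(log)
  if (strict && nrow(issues) > 0) {
    abort(paste0("log fails validation (", nrow(issues),
                 " problem(s)); see validate_log()"))
  }

  segments <- segment_conflicts(log)
  contexts <- summarize_contexts(log)
  rates <- aggression_rates(log)
  intensity_test <- condition_intensity_test(log)
  mesh <- mesh_effect_test(log)
  network <- aggression_network(log)

  pairs <- build_pcmc_pairs(log)
  analyse_target <- function(target) {
    out <- list(target = target)
    out$props <- tryCatch(victim_proportions(pairs, target),
                          error = function(e) NULL)
    out$test <- if (!is.null(out$props))
      tryCatch(reconciliation_test(out$props), error = function(e) NULL)
    have_pairs <- sum(pairs_for_target(pairs, target) |> nrow()) > 0
    if (have_pairs) {
      out$histograms <- latency_histograms(pairs, target)
      out$curves <- cumulative_curves(pairs, target)
      out$critical <- critical_interval(out$curves, pairs = pairs,
                                        target = target)
      out$labels <- label_reconciled(pairs, out$critical$t_star, target)
      out$ks <- tryCatch(ks_contacts(pairs, target),
                         error = function(e) NULL)
    }
    out
  }
  opponent <- analyse_target("opponent")
  third_party <- analyse_target("third_party")

  interventions <- tabulate_interventions(log)
  intervention_test <- tryCatch(intervention_condition_test(log),
                                error = function(e) NULL)
  coercion <- coercion_summary(log)

  contacts <- collect_window_contacts(log, pairs, "third_party")
  typology <- behaviour_type_table(contacts$pc, contacts$mc)
  contact_sitting <- if (any(grepl("contact_sitting", c(contacts$pc$behaviour,
                                                        contacts$mc$behaviour))))
    type_association_test(contacts$pc, contacts$mc, "contact_sitting") else NULL

  report <- structure(list(
    n_aggressions = nrow(log$aggressions),
    validation = issues, segments = segments, contexts = contexts,
    rates = rates, intensity_test = intensity_test, mesh = mesh,
    network = network, pairs = pairs, opponent = opponent,
    third_party = third_party, interventions = interventions,
    intervention_test = intervention_test, coercion = coercion,
    typology = typology, contact_sitting = contact_sitting),
    class = "pcmc_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(pairs, file.path(out_dir, "pairs.csv"))
    readr::write_csv(rates$rates, file.path(out_dir, "rates.csv"))
    readr::write_csv(contexts, file.path(out_dir, "contexts.csv"))
    readr::write_csv(network$edges, file.path(out_dir, "network.csv"))
    for (tg in list(opponent, third_party)) {
      if (!is.null(tg$curves)) {
        readr::write_csv(tg$curves,
                         file.path(out_dir, paste0("curves_", tg$target,
                                                   ".csv")))
      }
    }
    readr::write_csv(tibble::as_tibble(typology),
                     file.path(out_dir, "typology.csv"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "summary.txt"))
  }
  report
}

#' @export
print.pcmc_report <- function(x, ...) {
  seg <- attr(x$segments, "summary")
  cat("== Post-conflict analysis report ==\n")
  cat(sprintf("Aggressions: %d (%d distinct, %d in sequences)\n",
              x$n_aggressions, seg$n_distinct, seg$n_in_sequences))
  cat(sprintf("Aggression rate medians: indoor %.3f/h, outdoor %.3f/h\n",
              x$rates$medians[["indoor"]], x$rates$medians[["outdoor"]]))
  print(x$rates$test)
  for (tg in list(x$opponent, x$third_party)) {
    cat(sprintf("-- target: %s --\n", tg$target))
    if (!is.null(tg$props)) {
      counts <- table(factor(pairs_for_target(x$pairs, tg$target)$class,
                             levels = c("attracted", "dispersed", "neutral")))
      cat(sprintf("pairs: %d analysable (%d attracted / %d dispersed / %d neutral)\n",
                  sum(counts), counts[1], counts[2], counts[3]))
      if (!is.null(tg$test)) print(tg$test)
    } else {
      cat("no analysable pairs\n")
    }
    if (!is.null(tg$critical)) {
      print(tg$critical)
      cat(sprintf("operationally positive: %d of %d pairs (%.0f%%)\n",
                  tg$labels$n_reconciled, tg$labels$n_pairs,
                  100 * tg$labels$proportion))
    }
  }
  print(x$interventions)
  if (!is.null(x$intervention_test)) {
    cat("condition effect on intervention: ")
    print(x$intervention_test$pooled)
  }
  print(x$coercion)
  invisible(x)
}
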