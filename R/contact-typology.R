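## Behaviour-type composition of post-conflict versus matched-control
## affiliative contacts (victim with third parties), and per-type
## association tests.

#' Collect all window contacts for the typology
#'
#' Gathers every affiliative contact (not only the first) between the
#' focal victim and a partner passing the target filter, inside the PC and
#' MC windows of the analysable pairs.
#'
#' @param log An [ethogram_log()].
#' @param pairs Pair table from [build_pcmc_pairs()].
#' @param target `"third_party"` (default, the typology of interest) or
#'   `"opponent"`.
#' @param include_male_coercion Pool male sexual-coercion conflicts.
#' @return List with tibbles `pc` and `mc`; each row is one contact with
#'   `conflict_id`, `dyad`, `behaviour` (1-2 "+"-joined types).
#' @export
collect_window_contacts <- function(log, pairs,
                                    target = c("third_party", "opponent"),
                                    include_male_coercion = FALSE) {
  target <- match.arg(target)
  tchoice <- if (target == "third_party") "third_party" else "opponent"
  p <- pairs_for_target(pairs, c(opponent = "opponent",
                                 third_party = "third_party")[[tchoice]],
                        include_male_coercion)
  af <- log$affiliations
  af_abs <- .abs_time(log$setup, af$date, af$onset_s)
  grab <- function(date, start_s, focal, opponent) {
    abs_start <- .abs_time(log$setup, date, start_s)
    inv <- (af$participant_a == focal | af$participant_b == focal) &
      af_abs >= abs_start & af_abs <= abs_start + PC_WINDOW_S &
      af$visibility_ok
    partner <- ifelse(af$participant_a == focal, af$participant_b,
                      af$participant_a)
    keep <- if (target == "third_party") partner != opponent else
      partner == opponent
    w <- which(inv & keep)
    if (!length(w)) return(NULL)
    tibble::tibble(dyad = paste(pmin(focal, partner[w]),
                                pmax(focal, partner[w]), sep = "-"),
                   behaviour = af$behaviour[w])
  }
  pc_rows <- list(); mc_rows <- list()
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    g <- grab(r$date, r$pc_anchor_s, r$focal, r$opponent)
    if (!is.null(g)) pc_rows[[length(pc_rows) + 1L]] <-
        dplyr::mutate(g, conflict_id = r$conflict_id)
    g <- grab(r$mc_date, r$mc_start_s, r$focal, r$opponent)
    if (!is.null(g)) mc_rows[[length(mc_rows) + 1L]] <-
        dplyr::mutate(g, conflict_id = r$conflict_id)
  }
  empty <- tibble::tibble(dyad = character(), behaviour = character(),
                          conflict_id = character())
  list(pc = if (length(pc_rows)) dplyr::bind_rows(pc_rows) else empty,
       mc = if (length(mc_rows)) dplyr::bind_rows(mc_rows) else empty)
}

#' Behaviour-type frequency table (PC vs MC)
#'
#' Counts, per affiliative behaviour type, the contacts in which it occurs
#' in the PC and MC windows. A contact combining two behaviours increments
#' both types, so proportions (relative to total contacts per condition)
#' may sum to more than 100%.
#'
#' @param pc_contacts,mc_contacts Contact tibbles (column `behaviour`,
#'   types "+"-joined), e.g. from [collect_window_contacts()].
#' @return Tibble of class `type_frequency_table`: `behaviour`, `pc_n`,
#'   `pc_prop`, `mc_n`, `mc_prop`; attributes `pc_total`, `mc_total`.
#' @export
behaviour_type_table <- function(pc_contacts, mc_contacts) {
  count_types <- function(x) {
    if (nrow(x) == 0) return(table(character()))
    table(unlist(strsplit(x$behaviour, "+", fixed = TRUE)))
  }
  pc_t <- count_types(pc_contacts); mc_t <- count_types(mc_contacts)
  types <- sort(unique(c(names(pc_t), names(mc_t))))
  n_pc <- nrow(pc_contacts); n_mc <- nrow(mc_contacts)
  out <- tibble::tibble(
    behaviour = types,
    pc_n = as.integer(ifelse(types %in% names(pc_t), pc_t[types], 0L)),
    mc_n = as.integer(ifelse(types %in% names(mc_t), mc_t[types], 0L)))
  out$pc_prop <- if (n_pc) out$pc_n / n_pc else NA_real_
  out$mc_prop <- if (n_mc) out$mc_n / n_mc else NA_real_
  out <- out[order(-out$pc_n, -out$mc_n, out$behaviour), ]
  attr(out, "pc_total") <- n_pc
  attr(out, "mc_total") <- n_mc
  class(out) <- c("type_frequency_table", class(out))
  out
}

#' Association of one behaviour type with the post-conflict condition
#'
#' Exact 2x2 test of contacts with versus without the behaviour, PC versus
#' MC, with a dyad-influence control: an exact r x 2 test of the dyad
#' distribution of the behaviour's occurrences across PC/MC.
#'
#' @param pc_contacts,mc_contacts As for [behaviour_type_table()], with a
#'   `dyad` column for the influence control.
#' @param behaviour The behaviour type to test.
#' @return List: `pooled` (`fisher_result`, unbounded OR flagged via
#'   `Inf`), `influence` (`fisher_rxc_result` or NULL).
#' @export
type_association_test <- function(pc_contacts, mc_contacts, behaviour) {
  has_type <- function(x) vapply(strsplit(x$behaviour, "+", fixed = TRUE),
                                 function(b) behaviour %in% b, TRUE)
  pc_has <- has_type(pc_contacts); mc_has <- has_type(mc_contacts)
  if (!any(pc_has) && !any(mc_has)) {
    abort(paste0("behaviour '", behaviour, "' absent from both conditions"))
  }
  tab <- matrix(c(sum(pc_has), sum(!pc_has), sum(mc_has), sum(!mc_has)),
                2, 2, byrow = TRUE,
                dimnames = list(c("pc", "mc"), c("with", "without")))
  pooled <- fisher_exact_2x2(tab)
  dy <- c(pc_contacts$dyad[pc_has], mc_contacts$dyad[mc_has])
  cond <- c(rep("pc", sum(pc_has)), rep("mc", sum(mc_has)))
  influence <- NULL
  if (length(unique(dy)) >= 2) {
    itab <- as.matrix(table(dy, factor(cond, levels = c("pc", "mc"))))
    influence <- fisher_exact_rxc(itab)
  }
  list(pooled = pooled, influence = influence)
}
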