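#' @importFrom rlang .data abort warn %||%
#' @importFrom stats setNames
NULL

## Closed coding vocabularies. Values outside these sets are rejected by the
## strict reader and reported by validate_log().
.pcmc_vocab <- list(
  condition = c("outdoor", "indoor"),
  sex       = c("male", "female"),
  age_class = c("adult", "semi-dependent immature", "dependent immature"),
  subgroup  = c("A", "B", "none"),
  intensity = c("low", "medium", "high", "undetermined"),
  context   = c("spontaneous", "sexual_coercion", "weaning", "food",
                "object", "punishment", "unknown"),
  reaction  = c("avoidance", "nonaggressive_cease", "counter_aggression",
                "redirection", "none"),
  intervention_mode = c("peaceful", "aggressive"),
  affiliation = c("contact_sitting", "touch_body", "embrace", "play",
                  "food_object_transfer", "grooming", "nursing",
                  "sucking_fur", "sexual_interaction", "cuddling",
                  "contact_walking", "close_proximity", "begging",
                  "cofeeding")
)

#' Coding vocabularies used by the ethogram model
#'
#' Returns the closed vocabularies (conditions, intensities, contexts,
#' reaction categories, intervention modes, affiliative behaviour types)
#' against which coding sheets are validated.
#'
#' @return A named list of character vectors.
#' @export
pcmc_vocabularies <- function() .pcmc_vocab

#' Default study roster
#'
#' A six-individual roster modelled on a socially housed Sumatran orangutan
#' group: one adult male, three adult females, and two immature offspring of
#' the dominant female. The `subgroup` column records the two winter
#' (indoor) subgroups; `mother` and `father` encode kin links.
#'
#' @return A tibble with columns `id`, `name`, `sex`, `age_class`,
#'   `subgroup`, `mother`, `father`.
#' @export
default_roster <- function() {
  tibble::tibble(
    id        = c("Wa", "To", "Ta", "Ei", "Su", "Dm"),
    name      = c("Walter", "Toba", "Tao", "Eirina", "Suma", "Djamuna"),
    sex       = c("male", "female", "female", "female", "female", "female"),
    age_class = c("adult", "adult", "semi-dependent immature",
                  "dependent immature", "adult", "adult"),
    subgroup  = c("A", "A", "A", "A", "B", "B"),
    mother    = c(NA, NA, "To", "To", NA, NA),
    father    = c(NA, NA, "Wa", "Wa", NA, NA)
  )
}

#' Default session calendar
#'
#' Lays out daily video sessions over two observation blocks: 14 outdoor
#' days totalling 74.35 h and 16 indoor days totalling 83.15 h (157.5 h in
#' all), each session starting at the same clock time (10:00). Durations
#' are equal within a condition so that the block totals are exact.
#'
#' @param outdoor_hours,indoor_hours Total observation hours per condition.
#' @param outdoor_days,indoor_days Number of session days per condition.
#' @param start_clock_s Session start, seconds after midnight.
#' @return A tibble with columns `date`, `start_s`, `duration_h`,
#'   `condition`.
#' @export
default_calendar <- function(outdoor_hours = 74.35, indoor_hours = 83.15,
                             outdoor_days = 14, indoor_days = 16,
                             start_clock_s = 10 * 3600) {
  tibble::tibble(
    date = c(as.Date("2011-09-01") + seq_len(outdoor_days) - 1,
             as.Date("2012-02-01") + seq_len(indoor_days) - 1),
    start_s = start_clock_s,
    duration_h = c(rep(outdoor_hours / outdoor_days, outdoor_days),
                   rep(indoor_hours / indoor_days, indoor_days)),
    condition = c(rep("outdoor", outdoor_days), rep("indoor", indoor_days))
  )
}

#' Construct a study setup
#'
#' Bundles a roster and a session calendar and derives the observation
#' hours per housing condition. One session per calendar date is assumed;
#' all event times are seconds from the start of their date's session.
#'
#' @param roster Tibble as returned by [default_roster()].
#' @param calendar Tibble as returned by [default_calendar()].
#' @return An object of class `study_setup`: a list with elements `roster`,
#'   `calendar`, `hours` (named by condition).
#' @export
study_setup <- function(roster = default_roster(),
                        calendar = default_calendar()) {
  stopifnot(is.data.frame(roster), is.data.frame(calendar))
  if (anyDuplicated(roster$id)) {
    abort("roster ids must be unique")
  }
  if (anyDuplicated(calendar$date)) {
    abort("one session per date is assumed; duplicated dates in calendar")
  }
  if (any(calendar$duration_h < 0)) abort("session durations must be >= 0")
  bad <- setdiff(unique(calendar$condition), .pcmc_vocab$condition)
  if (length(bad)) abort(paste0("unknown condition in calendar: ", bad[1]))
  hours <- vapply(split(calendar$duration_h, calendar$condition), sum, 0)
  structure(list(roster = roster, calendar = calendar, hours = hours),
            class = "study_setup")
}

#' @export
print.study_setup <- function(x, ...) {
  cat("<study_setup> ", nrow(x$roster), " individuals, ",
      nrow(x$calendar), " sessions (",
      paste(sprintf("%s %.2f h", names(x$hours), x$hours), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

## Absolute time (seconds since epoch) of an event given its session date
## and its onset in seconds from session start.
.abs_time <- function(setup, date, onset_s) {
  idx <- match(as.character(date), as.character(setup$calendar$date))
  if (anyNA(idx)) abort("event date not present in session calendar")
  as.numeric(setup$calendar$date[idx]) * 86400 +
    setup$calendar$start_s[idx] + onset_s
}

## Clock time (seconds after midnight) of an event.
.clock_time <- function(setup, date, onset_s) {
  idx <- match(as.character(date), as.character(setup$calendar$date))
  setup$calendar$start_s[idx] + onset_s
}

.session_row <- function(setup, date) {
  idx <- match(as.character(date), as.character(setup$calendar$date))
  setup$calendar[idx, , drop = FALSE]
}

#' Construct an ethogram event log
#'
#' The central data container: a study setup plus three event tables.
#' Aggression and affiliation events are kept chronologically sorted
#' (date, then onset).
#'
#' @param setup A [study_setup()].
#' @param aggressions Tibble of aggressive interactions (see
#'   [read_coding_sheet()] for columns).
#' @param affiliations Tibble of affiliative contacts.
#' @param interventions Tibble of third-party intervention records, keyed by
#'   `event_id` of the parent aggression.
#' @return An object of class `ethogram_log`.
#' @export
ethogram_log <- function(setup,
                         aggressions = empty_aggressions(),
                         affiliations = empty_affiliations(),
                         interventions = empty_interventions()) {
  stopifnot(inherits(setup, "study_setup"))
  aggressions <- dplyr::arrange(tibble::as_tibble(aggressions),
                                .data$date, .data$onset_s)
  affiliations <- dplyr::arrange(tibble::as_tibble(affiliations),
                                 .data$date, .data$onset_s)
  structure(list(setup = setup,
                 aggressions = aggressions,
                 affiliations = affiliations,
                 interventions = tibble::as_tibble(interventions)),
            class = "ethogram_log")
}

#' @export
print.ethogram_log <- function(x, ...) {
  cat("<ethogram_log> ", nrow(x$aggressions), " aggressions, ",
      nrow(x$affiliations), " affiliations, ",
      nrow(x$interventions), " interventions\n", sep = "")
  invisible(x)
}

#' @rdname ethogram_log
#' @export
empty_aggressions <- function() {
  tibble::tibble(event_id = character(), date = as.Date(character()),
                 onset_s = numeric(), offset_s = numeric(),
                 condition = character(), aggressor = character(),
                 victim = character(), behaviour = character(),
                 intensity = character(), context = character(),
                 through_mesh = logical(), reaction = character(),
                 intervention_undetermined = logical())
}

#' @rdname ethogram_log
#' @export
empty_affiliations <- function() {
  tibble::tibble(event_id = character(), date = as.Date(character()),
                 onset_s = numeric(), condition = character(),
                 participant_a = character(), participant_b = character(),
                 behaviour = character(), initiator = character(),
                 visibility_ok = logical())
}

#' @rdname ethogram_log
#' @export
empty_interventions <- function() {
  tibble::tibble(event_id = character(), intervener = character(),
                 mode = character(), supported = character(),
                 successful = logical())
}

## Is the adult male part of this (unordered) dyad? Used to separate male
## sexual coercion from all other contexts.
.male_in_dyad <- function(log, a, b) {
  males <- log$setup$roster$id[log$setup$roster$sex == "male" &
                                 log$setup$roster$age_class == "adult"]
  a %in% males | b %in% males
}

#' Identify male sexual-coercion conflicts
#'
#' Forced copulations are a class of their own in orangutan aggression, and
#' the analyses treat them separately: a conflict belongs to the male
#' sexual-coercion set when its context is `sexual_coercion` and the adult
#' male is one of the opponents (this also captures female
#' counter-aggressions against the male within that context, while leaving
#' female-female sexual coercion with the general contexts).
#'
#' @param log An [ethogram_log()].
#' @return Logical vector along `log$aggressions`.
#' @export
is_male_coercion <- function(log) {
  ag <- log$aggressions
  ag$context == "sexual_coercion" &
    .male_in_dyad(log, ag$aggressor, ag$victim)
}

#' Validate an event log
#'
#' Checks every type invariant of the log: known individuals, events inside
#' their sessions, non-negative durations, no self-directed aggression,
#' vocabularies respected, subgroup membership present for indoor events,
#' interveners distinct from the opponents, and at most two behaviour types
#' per affiliative contact.
#'
#' @param log An [ethogram_log()].
#' @return A tibble with columns `table`, `event_id`, `problem`; zero rows
#'   when the log is consistent.
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "ethogram_log"))
  setup <- log$setup
  ids <- setup$roster$id
  out <- list()
  note <- function(table, event_id, problem) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      table = table, event_id = as.character(event_id), problem = problem)
  }

  ag <- log$aggressions
  if (nrow(ag)) {
    sess <- .session_row(setup, ag$date)
    for (i in seq_len(nrow(ag))) {
      e <- ag[i, ]
      if (!e$aggressor %in% ids) note("aggressions", e$event_id, "unknown aggressor id")
      if (!e$victim %in% ids) note("aggressions", e$event_id, "unknown victim id")
      if (identical(e$aggressor, e$victim)) note("aggressions", e$event_id, "aggressor equals victim")
      if (is.na(sess$date[i])) note("aggressions", e$event_id, "date not in calendar")
      if (!is.na(e$offset_s) && !is.na(e$onset_s) && e$offset_s < e$onset_s)
        note("aggressions", e$event_id, "offset before onset")
      if (!e$intensity %in% .pcmc_vocab$intensity)
        note("aggressions", e$event_id, paste0("unknown intensity '", e$intensity, "'"))
      if (!e$context %in% .pcmc_vocab$context)
        note("aggressions", e$event_id, paste0("unknown context '", e$context, "'"))
      if (!is.na(e$reaction) && nzchar(e$reaction)) {
        parts <- strsplit(e$reaction, "+", fixed = TRUE)[[1]]
        if (!all(parts %in% .pcmc_vocab$reaction))
          note("aggressions", e$event_id, "unknown reaction category")
      }
      if (e$condition == "indoor") {
        sg <- setup$roster$subgroup[match(c(e$aggressor, e$victim), ids)]
        if (any(is.na(sg) | sg == "none"))
          note("aggressions", e$event_id, "indoor event but subgroup missing")
      }
    }
  }

  af <- log$affiliations
  if (nrow(af)) {
    for (i in seq_len(nrow(af))) {
      e <- af[i, ]
      if (!e$participant_a %in% ids) note("affiliations", e$event_id, "unknown participant id")
      if (!e$participant_b %in% ids) note("affiliations", e$event_id, "unknown participant id")
      if (identical(e$participant_a, e$participant_b))
        note("affiliations", e$event_id, "participants not distinct")
      types <- strsplit(e$behaviour, "+", fixed = TRUE)[[1]]
      if (length(types) < 1 || length(types) > 2)
        note("affiliations", e$event_id, "affiliation must carry 1-2 behaviour types")
      if (!all(types %in% .pcmc_vocab$affiliation))
        note("affiliations", e$event_id, "unknown affiliation behaviour type")
    }
  }

  iv <- log$interventions
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      e <- iv[i, ]
      parent <- ag[match(e$event_id, ag$event_id), ]
      if (is.na(parent$event_id)) {
        note("interventions", e$event_id, "no parent aggression event")
      } else if (e$intervener %in% c(parent$aggressor, parent$victim)) {
        note("interventions", e$event_id, "intervener is an opponent")
      }
      if (!e$mode %in% .pcmc_vocab$intervention_mode)
        note("interventions", e$event_id, "unknown intervention mode")
    }
  }

  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(table = character(), event_id = character(),
                   problem = character())
}
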