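## Coding-sheet I/O. The canonical sheet is a comma-separated UTF-8 file
## with one row per coded event (aggressive interaction or affiliative
## contact). Two behaviour types of one contact are joined by "+";
## intervention records are packed into one cell as
## "intervener:mode:supported:successful" joined by ";".

.sheet_columns <- c("event_id", "event_type", "date", "onset_s", "offset_s",
                    "condition", "actor", "target", "behaviour", "intensity",
                    "context", "through_mesh", "reaction", "initiator",
                    "visibility_ok", "interventions",
                    "intervention_undetermined")

.pack_interventions <- function(iv) {
  if (nrow(iv) == 0) return("")
  paste(sprintf("%s:%s:%s:%s", iv$intervener, iv$mode,
                ifelse(is.na(iv$supported), "", iv$supported),
                ifelse(iv$successful, "TRUE", "FALSE")),
        collapse = ";")
}

.unpack_interventions <- function(cell, event_id) {
  if (is.na(cell) || !nzchar(cell)) return(empty_interventions())
  parts <- strsplit(strsplit(cell, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 4L, TRUE)
  if (any(bad)) abort(paste0("malformed intervention cell in event ", event_id))
  tibble::tibble(
    event_id = event_id,
    intervener = vapply(parts, `[`, "", 1),
    mode = vapply(parts, `[`, "", 2),
    supported = ifelse(nzchar(vapply(parts, `[`, "", 3)),
                       vapply(parts, `[`, "", 3), NA_character_),
    successful = vapply(parts, `[`, "", 4) == "TRUE")
}

#' Write an event log as a coding sheet
#'
#' Serialises the aggression and affiliation tables of a log into a single
#' canonical CSV (one row per event, chronological). The study setup is not
#' part of the sheet; see [write_study_setup()].
#'
#' @param log An [ethogram_log()].
#' @param path File path; a header-only file is written for an empty log.
#' @return `path`, invisibly.
#' @seealso [read_coding_sheet()] for the inverse; the pair is an exact
#'   round trip on valid logs.
#' @export
write_coding_sheet <- function(log, path) {
  stopifnot(inherits(log, "ethogram_log"))
  ag <- log$aggressions
  iv_by_event <- split(log$interventions, log$interventions$event_id)
  ag_rows <- tibble::tibble(
    event_id = ag$event_id, event_type = rep("aggression", nrow(ag)),
    date = as.character(ag$date), onset_s = ag$onset_s,
    offset_s = ag$offset_s, condition = ag$condition,
    actor = ag$aggressor, target = ag$victim, behaviour = ag$behaviour,
    intensity = ag$intensity, context = ag$context,
    through_mesh = ag$through_mesh, reaction = ag$reaction,
    initiator = NA_character_, visibility_ok = NA,
    interventions = vapply(ag$event_id, function(id) {
      iv <- iv_by_event[[id]]
      if (is.null(iv)) "" else .pack_interventions(iv)
    }, ""),
    intervention_undetermined = ag$intervention_undetermined)
  af <- log$affiliations
  af_rows <- tibble::tibble(
    event_id = af$event_id, event_type = rep("affiliation", nrow(af)),
    date = as.character(af$date), onset_s = af$onset_s,
    offset_s = NA_real_, condition = af$condition,
    actor = af$participant_a, target = af$participant_b,
    behaviour = af$behaviour, intensity = NA_character_,
    context = NA_character_, through_mesh = NA, reaction = NA_character_,
    initiator = af$initiator, visibility_ok = af$visibility_ok,
    interventions = rep("", nrow(af)),
    intervention_undetermined = NA)
  rows <- dplyr::bind_rows(ag_rows, af_rows)
  rows <- rows[order(rows$date, rows$onset_s, rows$event_id), ]
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

.sheet_col_types <- function() {
  readr::cols(
    event_id = readr::col_character(), event_type = readr::col_character(),
    date = readr::col_date(), onset_s = readr::col_double(),
    offset_s = readr::col_double(), condition = readr::col_character(),
    actor = readr::col_character(), target = readr::col_character(),
    behaviour = readr::col_character(), intensity = readr::col_character(),
    context = readr::col_character(), through_mesh = readr::col_logical(),
    reaction = readr::col_character(), initiator = readr::col_character(),
    visibility_ok = readr::col_logical(),
    interventions = readr::col_character(),
    intervention_undetermined = readr::col_logical())
}

#' Read a coding sheet
#'
#' Parses a delimited coding sheet into an [ethogram_log()]. Because field
#' names of third-party sheets vary, a column map can translate source
#' headers to the canonical schema. In `strict` mode any row carrying a
#' value outside the coding vocabularies aborts the parse (naming row and
#' value); in `lenient` mode such rows are skipped and reported.
#'
#' @param path CSV file path.
#' @param setup The [study_setup()] the events belong to.
#' @param mapping Optional named character vector, `canonical = source`,
#'   renaming source columns onto the canonical schema.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return An `ethogram_log` with attribute `parse_report`: a list with
#'   `n_rows`, `n_aggressions`, `n_affiliations`, `skipped` (tibble of row
#'   index + reason).
#' @export
read_coding_sheet <- function(path, setup, mapping = NULL,
                              mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(setup, "study_setup"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (!is.null(mapping)) {
    miss <- setdiff(mapping, names(raw))
    if (length(miss)) abort(paste0("mapped source column missing: ", miss[1]))
    names(raw)[match(mapping, names(raw))] <- names(mapping)
  }
  missing_cols <- setdiff(.sheet_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("coding sheet lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[.sheet_columns]

  skipped <- list()
  bad_row <- function(i, reason) {
    if (mode == "strict") abort(sprintf("row %d: %s", i, reason))
    skipped[[length(skipped) + 1L]] <<- tibble::tibble(row = i, reason = reason)
  }
  keep <- rep(TRUE, nrow(raw))
  onset <- suppressWarnings(as.numeric(raw$onset_s))
  offset <- suppressWarnings(as.numeric(raw$offset_s))
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    if (!r$event_type %in% c("aggression", "affiliation")) {
      bad_row(i, paste0("unknown event_type '", r$event_type, "'")); keep[i] <- FALSE; next
    }
    if (is.na(date[i])) { bad_row(i, "unparseable date"); keep[i] <- FALSE; next }
    if (is.na(onset[i])) { bad_row(i, "unparseable onset time"); keep[i] <- FALSE; next }
    if (!r$condition %in% .pcmc_vocab$condition) {
      bad_row(i, paste0("unknown condition '", r$condition, "'")); keep[i] <- FALSE; next
    }
    if (r$event_type == "aggression") {
      if (is.na(offset[i])) { bad_row(i, "unparseable offset time"); keep[i] <- FALSE; next }
      if (!r$intensity %in% .pcmc_vocab$intensity) {
        bad_row(i, paste0("intensity '", r$intensity, "' not in vocabulary"))
        keep[i] <- FALSE; next
      }
      if (!r$context %in% .pcmc_vocab$context) {
        bad_row(i, paste0("context '", r$context, "' not in vocabulary"))
        keep[i] <- FALSE; next
      }
    } else {
      types <- strsplit(r$behaviour, "+", fixed = TRUE)[[1]]
      if (length(types) < 1 || length(types) > 2 ||
          !all(types %in% .pcmc_vocab$affiliation)) {
        bad_row(i, paste0("affiliation behaviour '", r$behaviour,
                          "' not in vocabulary"))
        keep[i] <- FALSE; next
      }
    }
  }
  raw <- raw[keep, ]; onset <- onset[keep]; offset <- offset[keep]
  date <- date[keep]

  is_ag <- raw$event_type == "aggression"
  ag <- tibble::tibble(
    event_id = raw$event_id[is_ag], date = date[is_ag],
    onset_s = onset[is_ag], offset_s = offset[is_ag],
    condition = raw$condition[is_ag], aggressor = raw$actor[is_ag],
    victim = raw$target[is_ag], behaviour = raw$behaviour[is_ag],
    intensity = raw$intensity[is_ag], context = raw$context[is_ag],
    through_mesh = raw$through_mesh[is_ag] == "TRUE",
    reaction = raw$reaction[is_ag],
    intervention_undetermined =
      raw$intervention_undetermined[is_ag] == "TRUE")
  iv <- dplyr::bind_rows(purrr::map2(
    raw$interventions[is_ag], raw$event_id[is_ag],
    function(cell, id) .unpack_interventions(ifelse(nzchar(cell), cell, NA), id)))
  if (nrow(iv) == 0) iv <- empty_interventions()
  af <- tibble::tibble(
    event_id = raw$event_id[!is_ag], date = date[!is_ag],
    onset_s = onset[!is_ag], condition = raw$condition[!is_ag],
    participant_a = raw$actor[!is_ag], participant_b = raw$target[!is_ag],
    behaviour = raw$behaviour[!is_ag],
    initiator = ifelse(nzchar(raw$initiator[!is_ag]),
                       raw$initiator[!is_ag], NA_character_),
    visibility_ok = raw$visibility_ok[!is_ag] != "FALSE")

  log <- ethogram_log(setup, ag, af, iv)
  attr(log, "parse_report") <- list(
    n_rows = length(keep), n_aggressions = nrow(ag), n_affiliations = nrow(af),
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble::tibble(row = integer(), reason = character()))
  log
}

#' Write / read the study setup as structured text
#'
#' The roster and session calendar travel alongside the coding sheet in a
#' small YAML file.
#'
#' @param setup A [study_setup()].
#' @param path YAML file path.
#' @return `write_study_setup()` returns `path` invisibly;
#'   `read_study_setup()` returns a `study_setup`.
#' @export
write_study_setup <- function(setup, path) {
  stopifnot(inherits(setup, "study_setup"))
  yaml::write_yaml(list(
    roster = lapply(seq_len(nrow(setup$roster)), function(i)
      as.list(setup$roster[i, ])),
    calendar = lapply(seq_len(nrow(setup$calendar)), function(i) {
      r <- as.list(setup$calendar[i, ]); r$date <- as.character(r$date); r
    })), path)
  invisible(path)
}

#' @rdname write_study_setup
#' @export
read_study_setup <- function(path) {
  y <- yaml::read_yaml(path)
  roster <- dplyr::bind_rows(lapply(y$roster, function(r)
    tibble::as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))))
  calendar <- dplyr::bind_rows(lapply(y$calendar, tibble::as_tibble))
  calendar$date <- as.Date(calendar$date)
  study_setup(roster, calendar)
}
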