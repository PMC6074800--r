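## The PC/MC method: post-conflict observation windows, matched-control
## selection, first-affiliation latencies, attracted/dispersed/neutral
## classification, per-victim proportions and the reconciliation test.

PC_WINDOW_S <- 600   # 10-min post-conflict observation window
PC_RESTART_S <- 180  # conflict resumed within the first 3 min -> restart
MC_MAX_CLOCK_OFFSET_S <- 3600   # +-60 min around the matched clock time
MC_MAX_DAY_OFFSET <- 7          # +-7 days
MC_GUARD_S <- 600               # conflict-free 10 min before an MC window

## Latency intervals are 1-minute bins of the window: interval k covers
## (60(k-1), 60k] seconds after the window start, with a contact at
## exactly the window start assigned to interval 1.
.latency_interval <- function(dt) {
  k <- ceiling(dt / 60)
  as.integer(ifelse(dt == 0, 1L, k))
}

#' Extract the post-conflict (PC) observation window of a conflict
#'
#' The PC window is anchored at the conflict's end. If an aggression
#' between the same (unordered) opponent dyad begins within the first
#' 3 minutes of the window, the conflict counts as resumed: the PC is
#' aborted and re-anchored immediately after that aggression ends,
#' recursively. A window cut short by the end of the session is marked
#' unavailable.
#'
#' @param log An [ethogram_log()].
#' @param conflict_id `event_id` of the aggression.
#' @return List of class `pc_record`: `conflict_id`, `focal` (victim),
#'   `opponent` (aggressor), `date`, `anchor_s` (window onset, seconds from
#'   session start), `window_s`, `restarted_from` (event ids of the
#'   resuming aggressions, character(0) if none), `resumed` (TRUE when the
#'   original PC was aborted at least once), `available`.
#' @export
extract_pc <- function(log, conflict_id) {
  ag <- log$aggressions
  i <- match(conflict_id, ag$event_id)
  if (is.na(i)) abort(paste0("unknown conflict id: ", conflict_id))
  e <- ag[i, ]
  sess <- .session_row(log$setup, e$date)
  sess_len <- sess$duration_h * 3600
  dyad <- sort(c(e$aggressor, e$victim))
  same_dyad <- ag$date == e$date &
    pmin(ag$aggressor, ag$victim) == dyad[1] &
    pmax(ag$aggressor, ag$victim) == dyad[2]
  anchor <- e$offset_s
  chain <- character(0)
  repeat {
    nxt <- which(same_dyad & ag$onset_s > anchor &
                   ag$onset_s <= anchor + PC_RESTART_S)
    if (length(nxt) == 0) break
    j <- nxt[which.min(ag$onset_s[nxt])]
    chain <- c(chain, ag$event_id[j])
    anchor <- ag$offset_s[j]
  }
  structure(list(conflict_id = e$event_id, focal = e$victim,
                 opponent = e$aggressor, date = e$date, anchor_s = anchor,
                 window_s = PC_WINDOW_S, restarted_from = chain,
                 resumed = length(chain) > 0,
                 available = anchor + PC_WINDOW_S <= sess_len),
            class = "pc_record")
}

#' Select the matched-control (MC) window for a PC record
#'
#' Deterministic priority ladder over the session calendar: candidate
#' windows on other recorded days within +-7 days of the conflict, at the
#' matched clock time or shifted by up to +-60 min (whole minutes).
#' Candidates are ranked by absolute day offset (following days before
#' preceding days on ties), then absolute clock offset (earlier clock time
#' first on ties). A candidate is admissible when the full 10-min window
#' lies inside its session and no aggression started in the 10 minutes
#' preceding the window. The first admissible candidate wins.
#'
#' @param log An [ethogram_log()].
#' @param pc A `pc_record` from [extract_pc()].
#' @return List of class `mc_record` (`date`, `start_s`, `day_offset`,
#'   `clock_offset_s`, `available = TRUE`) or, if no candidate is
#'   admissible, a list with `available = FALSE`.
#' @export
select_mc <- function(log, pc) {
  cal <- log$setup$calendar
  ag <- log$aggressions
  ag_abs_on <- .abs_time(log$setup, ag$date, ag$onset_s)
  pc_clock <- .clock_time(log$setup, pc$date, pc$anchor_s)
  day0 <- as.numeric(pc$date)

  offs <- as.numeric(cal$date) - day0
  cand_days <- which(offs != 0 & abs(offs) <= MC_MAX_DAY_OFFSET)
  if (length(cand_days)) {
    ord <- order(abs(offs[cand_days]), offs[cand_days] < 0)
    cand_days <- cand_days[ord]
  }
  clock_offsets <- unique(as.vector(rbind(-seq(0, MC_MAX_CLOCK_OFFSET_S, 60),
                                          seq(0, MC_MAX_CLOCK_OFFSET_S, 60))))
  clock_offsets <- clock_offsets[order(abs(clock_offsets), clock_offsets)]

  for (ci in cand_days) {
    sess <- cal[ci, ]
    sess_len <- sess$duration_h * 3600
    for (off in clock_offsets) {
      start_clock <- pc_clock + off
      start_s <- start_clock - sess$start_s  # seconds from session start
      if (start_s < 0 || start_s + PC_WINDOW_S > sess_len) next
      abs_start <- as.numeric(sess$date) * 86400 + start_clock
      if (any(ag_abs_on >= abs_start - MC_GUARD_S & ag_abs_on < abs_start)) next
      return(structure(list(date = sess$date, start_s = start_s,
                            day_offset = as.integer(offs[ci]),
                            clock_offset_s = off, available = TRUE),
                       class = "mc_record"))
    }
  }
  structure(list(available = FALSE), class = "mc_record")
}

#' First-affiliation latency within an observation window
#'
#' Finds the focal individual's earliest qualifying affiliative contact in
#' a 10-min window and assigns its 1-minute latency interval. If the
#' earliest candidate could not be coded reliably (`visibility_ok` FALSE),
#' the latency is unspecifiable and the pair must be excluded.
#'
#' @param log An [ethogram_log()].
#' @param date,start_s Window onset (session date, seconds from session
#'   start).
#' @param focal Focal individual (the conflict's victim).
#' @param opponent The former opponent (the conflict's aggressor).
#' @param partner_filter `"opponent"` (contacts with the former opponent)
#'   or `"any_third_party"` (contacts with any other individual).
#' @return Integer interval 1..10, `NA_integer_` when no qualifying contact
#'   occurs (`none`), or the string `"unspecifiable"`.
#' @export
first_affiliation_latency <- function(log, date, start_s, focal, opponent,
                                      partner_filter = c("opponent",
                                                         "any_third_party")) {
  partner_filter <- match.arg(partner_filter)
  af <- log$affiliations
  abs_start <- .abs_time(log$setup, date, start_s)
  af_abs <- .abs_time(log$setup, af$date, af$onset_s)
  inv <- af$participant_a == focal | af$participant_b == focal
  partner <- ifelse(af$participant_a == focal, af$participant_b,
                    af$participant_a)
  ok_partner <- if (partner_filter == "opponent") partner == opponent
                else partner != opponent
  hit <- which(inv & ok_partner & af_abs >= abs_start &
                 af_abs <= abs_start + PC_WINDOW_S)
  if (length(hit) == 0) return(NA_integer_)
  first <- hit[which.min(af_abs[hit])]
  if (!af$visibility_ok[first]) return("unspecifiable")
  .latency_interval(af_abs[first] - abs_start)
}

#' Classify a PC-MC pair from its two first-contact intervals
#'
#' A pair is *attracted* when the affiliative contact came earlier in the
#' PC than in the MC (or only in the PC), *dispersed* when earlier in the
#' MC (or only in the MC), and *neutral* when it fell in the same interval
#' in both or occurred in neither.
#'
#' @param pc_interval,mc_interval Integer latency intervals (`NA` = no
#'   contact). Vectorised.
#' @return Character vector: `"attracted"`, `"dispersed"`, `"neutral"`.
#' @export
classify_pair <- function(pc_interval, mc_interval) {
  if (any(pc_interval == "unspecifiable" | mc_interval == "unspecifiable",
          na.rm = TRUE)) {
    abort("unspecifiable latency: pair must be excluded, not classified")
  }
  pc <- as.integer(pc_interval); mc <- as.integer(mc_interval)
  dplyr::case_when(
    is.na(pc) & is.na(mc) ~ "neutral",
    is.na(mc)             ~ "attracted",
    is.na(pc)             ~ "dispersed",
    pc < mc               ~ "attracted",
    pc > mc               ~ "dispersed",
    TRUE                  ~ "neutral")
}

## Internal fast latency lookup used by build_pcmc_pairs: affiliation
## times/participants are precomputed once.
.first_lat_fast <- function(af_abs, af_a, af_b, af_vis, abs_start, focal,
                            opponent, third_party) {
  inv <- (af_a == focal | af_b == focal) &
    af_abs >= abs_start & af_abs <= abs_start + PC_WINDOW_S
  if (!any(inv)) return(list(int = NA_integer_, unspec = FALSE))
  partner <- ifelse(af_a[inv] == focal, af_b[inv], af_a[inv])
  keep <- if (third_party) partner != opponent else partner == opponent
  if (!any(keep)) return(list(int = NA_integer_, unspec = FALSE))
  tt <- af_abs[inv][keep]; vis <- af_vis[inv][keep]
  first <- which.min(tt)
  if (!vis[first]) return(list(int = NA_integer_, unspec = TRUE))
  list(int = .latency_interval(tt[first] - abs_start), unspec = FALSE)
}

#' Build the full PC-MC pair table of a log
#'
#' Runs PC extraction, MC selection and latency coding for every
#' aggression, then classifies each pair for both targets (former opponent
#' and third parties). Conflicts whose PC was aborted by a resumption,
#' whose PC window was cut off by the session end, or for which no
#' admissible MC exists are excluded with a reason. Male sexual-coercion
#' conflicts are processed identically but flagged so that downstream
#' analyses keep them separate. Semantics are those of [extract_pc()],
#' [select_mc()] and [first_affiliation_latency()] (re-implemented here on
#' precomputed time vectors so that simulation experiments over hundreds
#' of studies stay fast).
#'
#' @param log An [ethogram_log()].
#' @return A tibble, one row per aggression: ids and roles, `condition`,
#'   `male_coercion`, `excluded_reason` (NA when the pair is usable),
#'   latency intervals `opp_pc`, `opp_mc`, `tp_pc`, `tp_mc` (NA = no
#'   contact), unspecifiability flags `opp_unspec`, `tp_unspec`,
#'   classifications `opp_class`, `tp_class` (NA when not analysable), and
#'   the logical columns `opp_analysable`, `tp_analysable`.
#' @export
build_pcmc_pairs <- function(log) {
  setup <- log$setup
  ag <- log$aggressions
  af <- log$affiliations
  n <- nrow(ag)
  male_coercion <- is_male_coercion(log)
  cal <- setup$calendar
  cal_day <- as.numeric(cal$date)
  cal_len <- cal$duration_h * 3600

  day_idx <- match(as.numeric(ag$date), cal_day)
  ag_abs_on <- cal_day[day_idx] * 86400 + cal$start_s[day_idx] + ag$onset_s
  ag_abs_off <- ag_abs_on + (ag$offset_s - ag$onset_s)
  stopifnot(!is.unsorted(ag_abs_on))
  dyad_key <- paste(pmin(ag$aggressor, ag$victim),
                    pmax(ag$aggressor, ag$victim))
  by_dyad <- split(seq_len(n), dyad_key)

  af_n <- nrow(af)
  if (af_n) {
    af_idx <- match(as.numeric(af$date), cal_day)
    af_abs <- cal_day[af_idx] * 86400 + cal$start_s[af_idx] + af$onset_s
    o <- order(af_abs)
    af_abs <- af_abs[o]
    af_a <- af$participant_a[o]; af_b <- af$participant_b[o]
    af_vis <- af$visibility_ok[o]
  }
  eps <- 1e-6
  latency <- function(abs_start, focal, opponent, third) {
    if (af_n == 0) return(list(int = NA_integer_, unspec = FALSE))
    lo <- findInterval(abs_start - eps, af_abs) + 1L
    hi <- findInterval(abs_start + PC_WINDOW_S + eps, af_abs)
    if (lo > hi) return(list(int = NA_integer_, unspec = FALSE))
    for (j in lo:hi) {
      if (af_a[j] == focal) partner <- af_b[j]
      else if (af_b[j] == focal) partner <- af_a[j]
      else next
      if (third && partner == opponent) next
      if (!third && partner != opponent) next
      if (!af_vis[j]) return(list(int = NA_integer_, unspec = TRUE))
      return(list(int = .latency_interval(af_abs[j] - abs_start),
                  unspec = FALSE))
    }
    list(int = NA_integer_, unspec = FALSE)
  }
  conflict_before <- function(abs_start) {
    findInterval(abs_start - eps, ag_abs_on) -
      findInterval(abs_start - MC_GUARD_S - eps, ag_abs_on) > 0
  }

  cand_order <- order(abs(seq(-MC_MAX_DAY_OFFSET, MC_MAX_DAY_OFFSET)),
                      seq(-MC_MAX_DAY_OFFSET, MC_MAX_DAY_OFFSET) < 0)
  day_offsets <- seq(-MC_MAX_DAY_OFFSET, MC_MAX_DAY_OFFSET)[cand_order]
  day_offsets <- day_offsets[day_offsets != 0]
  clock_offsets <- unique(as.vector(rbind(
    -seq(0, MC_MAX_CLOCK_OFFSET_S, 60), seq(0, MC_MAX_CLOCK_OFFSET_S, 60))))
  clock_offsets <- clock_offsets[order(abs(clock_offsets), clock_offsets)]

  pc_anchor <- numeric(n); resumed <- logical(n); pc_avail <- logical(n)
  mc_date <- rep(as.Date(NA), n); mc_start <- rep(NA_real_, n)
  mc_doff <- rep(NA_integer_, n); mc_coff <- rep(NA_real_, n)
  excluded <- rep(NA_character_, n)
  opp_pc <- opp_mc <- tp_pc <- tp_mc <- rep(NA_integer_, n)
  opp_un <- tp_un <- logical(n)

  for (i in seq_len(n)) {
    ## --- PC extraction with the 3-min restart rule ---
    sibs <- by_dyad[[dyad_key[i]]]
    anchor_abs <- ag_abs_off[i]
    res_i <- FALSE
    repeat {
      nxt <- sibs[ag_abs_on[sibs] > anchor_abs &
                    ag_abs_on[sibs] <= anchor_abs + PC_RESTART_S]
      if (length(nxt) == 0) break
      j <- nxt[which.min(ag_abs_on[nxt])]
      anchor_abs <- ag_abs_off[j]
      res_i <- TRUE
    }
    di <- day_idx[i]
    anchor_s <- anchor_abs - (cal_day[di] * 86400 + cal$start_s[di])
    pc_anchor[i] <- anchor_s
    resumed[i] <- res_i
    pc_avail[i] <- anchor_s + PC_WINDOW_S <= cal_len[di]
    if (res_i) { excluded[i] <- "conflict_resumed"; next }
    if (!pc_avail[i]) { excluded[i] <- "pc_unavailable"; next }

    ## --- MC selection ladder ---
    pc_clock <- cal$start_s[di] + anchor_s
    found <- FALSE
    for (doff in day_offsets) {
      ci <- match(cal_day[di] + doff, cal_day)
      if (is.na(ci)) next
      for (coff in clock_offsets) {
        start_clock <- pc_clock + coff
        start_s <- start_clock - cal$start_s[ci]
        if (start_s < 0 || start_s + PC_WINDOW_S > cal_len[ci]) next
        abs_start <- cal_day[ci] * 86400 + start_clock
        if (conflict_before(abs_start)) next
        mc_date[i] <- cal$date[ci]; mc_start[i] <- start_s
        mc_doff[i] <- doff; mc_coff[i] <- coff
        found <- TRUE
        break
      }
      if (found) break
    }
    if (!found) { excluded[i] <- "mc_unavailable"; next }

    ## --- first-affiliation latencies, both targets ---
    pc_abs <- anchor_abs
    mc_abs <- cal_day[match(as.numeric(mc_date[i]), cal_day)] * 86400 +
      pc_clock + mc_coff[i]
    o_pc <- latency(pc_abs, ag$victim[i], ag$aggressor[i], FALSE)
    o_mc <- latency(mc_abs, ag$victim[i], ag$aggressor[i], FALSE)
    t_pc <- latency(pc_abs, ag$victim[i], ag$aggressor[i], TRUE)
    t_mc <- latency(mc_abs, ag$victim[i], ag$aggressor[i], TRUE)
    opp_pc[i] <- o_pc$int; opp_mc[i] <- o_mc$int
    tp_pc[i] <- t_pc$int; tp_mc[i] <- t_mc$int
    opp_un[i] <- o_pc$unspec || o_mc$unspec
    tp_un[i] <- t_pc$unspec || t_mc$unspec
  }

  usable <- is.na(excluded)
  opp_class <- rep(NA_character_, n); tp_class <- rep(NA_character_, n)
  sel <- usable & !opp_un
  opp_class[sel] <- classify_pair(opp_pc[sel], opp_mc[sel])
  sel <- usable & !tp_un
  tp_class[sel] <- classify_pair(tp_pc[sel], tp_mc[sel])

  tibble::tibble(
    conflict_id = ag$event_id, focal = ag$victim, opponent = ag$aggressor,
    condition = ag$condition, date = ag$date, male_coercion = male_coercion,
    pc_anchor_s = pc_anchor, resumed = resumed, excluded_reason = excluded,
    mc_date = mc_date, mc_start_s = mc_start, mc_day_offset = mc_doff,
    mc_clock_offset_s = mc_coff,
    opp_pc = opp_pc, opp_mc = opp_mc, tp_pc = tp_pc, tp_mc = tp_mc,
    opp_unspec = opp_un, tp_unspec = tp_un,
    opp_class = opp_class, tp_class = tp_class,
    opp_analysable = usable & !opp_un, tp_analysable = usable & !tp_un)
}

#' Analysable pair rows for one target
#'
#' Filters the pair table to the rows analysable for the chosen target
#' (not excluded, latency specifiable) and renames that target's latency
#' and classification columns to `pc_int`, `mc_int`, `class`. Male
#' sexual-coercion conflicts are kept out unless asked for.
#'
#' @param pairs Pair table from [build_pcmc_pairs()].
#' @param target `"opponent"` or `"third_party"`.
#' @param include_male_coercion Pool male sexual-coercion conflicts.
#' @return A tibble of analysable pairs.
#' @export
pairs_for_target <- function(pairs, target = c("opponent", "third_party"),
                             include_male_coercion = FALSE) {
  target <- match.arg(target)
  ok <- if (target == "opponent") pairs$opp_analysable else pairs$tp_analysable
  if (!include_male_coercion) ok <- ok & !pairs$male_coercion
  p <- pairs[ok, ]
  if (target == "opponent") {
    dplyr::rename(p, pc_int = "opp_pc", mc_int = "opp_mc",
                  class = "opp_class")
  } else {
    dplyr::rename(p, pc_int = "tp_pc", mc_int = "tp_mc", class = "tp_class")
  }
}

#' Per-victim attracted/dispersed/neutral proportions
#'
#' @param pairs Pair table from [build_pcmc_pairs()].
#' @param target `"opponent"` or `"third_party"`.
#' @param min_received Minimum analysable pairs a victim must have to be
#'   included (victims who received aggression fewer times are dropped).
#' @param include_male_coercion Pool male sexual-coercion conflicts too
#'   (default FALSE; they are reported separately).
#' @return A tibble per included victim: `focal`, `n_pairs`, `attracted`,
#'   `dispersed`, `neutral` (proportions), plus the raw counts.
#' @export
victim_proportions <- function(pairs, target = c("opponent", "third_party"),
                               min_received = 3,
                               include_male_coercion = FALSE) {
  p <- pairs_for_target(pairs, target, include_male_coercion)
  if (nrow(p) == 0) abort("no analysable pairs")
  out <- p |>
    dplyr::group_by(focal = .data$focal) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_attracted = sum(.data$class == "attracted"),
      n_dispersed = sum(.data$class == "dispersed"),
      n_neutral = sum(.data$class == "neutral"), .groups = "drop") |>
    dplyr::filter(.data$n_pairs >= min_received) |>
    dplyr::mutate(attracted = .data$n_attracted / .data$n_pairs,
                  dispersed = .data$n_dispersed / .data$n_pairs,
                  neutral = .data$n_neutral / .data$n_pairs)
  if (nrow(out) == 0) {
    abort("no victim reaches the minimum number of received aggressions")
  }
  out
}

#' Reconciliation (or PCTA) test on per-victim proportions
#'
#' Exact one-tailed signed-rank test of the paired per-victim differences
#' attracted-minus-dispersed proportion; a significantly higher attracted
#' proportion demonstrates reconciliation (opponent target) or
#' post-conflict third-party affiliation (third-party target).
#'
#' @param proportions Output of [victim_proportions()].
#' @param alternative Passed to [exact_signed_rank_test()]; default
#'   `"greater"`.
#' @return A `signed_rank_result`.
#' @export
reconciliation_test <- function(proportions, alternative = "greater") {
  exact_signed_rank_test(proportions$attracted - proportions$dispersed,
                         alternative)
}
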