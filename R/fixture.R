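## A deterministic synthetic benchmark log. Every count below is fixed by
## construction so that the full pipeline has known expected output at
## study scale: 114 aggressions (85 distinct, 29 in sequences of 2-4);
## context/intensity margins 49/26/17/9/6/1/6 and 57/37/14/6; per-hour
## aggression medians 0.144 indoor / 0.020 outdoor with an all-positive
## paired contrast (T = 0); 70 analysable opponent pairs split 31/16/23
## (attracted/dispersed/neutral) with exclusions 12 resumed / 8
## unspecifiable / 3 unavailable; 72 third-party pairs split 29/26/17 with
## an opposing-rank configuration giving T = 5; cumulative-curve gap
## 17/70 at minute two (the critical interval); 29/70 conflicts
## operationally reconciled; 22 of 93 conflicts intervened (25
## interventions, 17 peaceful) with condition table [19/61 indoor, 3/32
## outdoor]; and 16 male coercions, all intervened, yielding 13 analysable
## coercion PCs. The layout puts conflicts on alternate session days so
## that every matched control lands on a conflict-free day.

.fx_slot_pitch <- 1320  # seconds between conflict slots within a session

.fx_tp_partner <- c(To = "Ei", Ta = "Ei", Ei = "Ta", Su = "Dm",
                    Dm = "Ei", Wa = "To")

## outcome pools: list(type, pc, mc); NA = no contact in that window
.fx_pool <- function(both, pc_only = NULL, mc_only = NULL, none = 0) {
  out <- lapply(both, function(b) list(pc = b[1], mc = b[2]))
  out <- c(out, lapply(pc_only, function(k) list(pc = k, mc = NA)))
  out <- c(out, lapply(mc_only, function(k) list(pc = NA, mc = k)))
  c(out, rep(list(list(pc = NA, mc = NA)), none))
}

.fx_opp_pools <- function() {
  list(
    A = .fx_pool(list(c(2, 5), c(1, 8)),
                 pc_only = c(rep(1, 24), rep(2, 3), 3, 6)),
    D = .fx_pool(list(c(9, 6)),
                 mc_only = c(rep(1, 9), rep(2, 3), rep(3, 2), 10)),
    N = c(.fx_pool(list(c(4, 4))), .fx_pool(list(), none = 22)))
}

.fx_tp_pools <- function() {
  list(
    A = .fx_pool(list(c(1, 4), c(2, 5), c(3, 7)),
                 pc_only = c(rep(1, 24), 2, 3)),
    D = .fx_pool(list(c(4, 1), c(5, 2), c(6, 3)),
                 mc_only = c(rep(1, 15), rep(2, 4), rep(3, 2), 5, 8)),
    N = c(.fx_pool(list(c(2, 2), c(9, 9))), .fx_pool(list(), none = 15)))
}

## per-victim outcome needs: attracted, dispersed, neutral, unspecifiable
.fx_opp_needs <- list(To = c(4, 2, 2, 1), Ta = c(9, 6, 7, 2),
                      Ei = c(4, 2, 2, 0), Su = c(4, 2, 2, 1),
                      Dm = c(10, 4, 9, 4), Wa = c(0, 0, 1, 0))
.fx_tp_needs <- list(To = c(2, 4, 2, 1), Ta = c(7, 14, 3, 0),
                     Ei = c(3, 1, 1, 3), Su = c(3, 2, 3, 1),
                     Dm = c(14, 5, 7, 1), Wa = c(0, 0, 1, 0))

## draw per-victim outcome sequences from the pools (consumed in victim
## order To, Ta, Ei, Su, Dm, Wa); returns list(victim -> list(outcomes))
.fx_allocate <- function(pools, needs, reverse = FALSE) {
  idx <- c(A = 0L, D = 0L, N = 0L)
  out <- list()
  for (v in names(needs)) {
    nd <- needs[[v]]
    seqs <- list()
    for (ci in 1:3) {
      cls <- c("A", "D", "N")[ci]
      if (nd[ci] > 0) for (j in seq_len(nd[ci])) {
        idx[cls] <- idx[cls] + 1L
        o <- pools[[cls]][[idx[cls]]]
        o$type <- cls
        seqs[[length(seqs) + 1L]] <- o
      }
    }
    if (nd[4] > 0) for (j in seq_len(nd[4])) {
      seqs[[length(seqs) + 1L]] <- list(pc = 1, mc = NA, type = "U")
    }
    if (reverse) seqs <- rev(seqs)
    out[[v]] <- seqs
  }
  stopifnot(idx["A"] == length(pools$A), idx["D"] == length(pools$D),
            idx["N"] == length(pools$N))
  out
}

## conflict specification rows (context/intensity assigned later)
.fx_unit <- function(kind, events) list(kind = kind, events = events)

.fx_conflict_units <- function() {
  ev <- function(a, v, ctx, rel_on, dur = 30, resumed = FALSE) {
    list(aggressor = a, victim = v, context = ctx, rel_on = rel_on,
         dur = dur, resumed = resumed)
  }
  chain4 <- function(a, v, ctx) {
    lapply(0:3, function(k) ev(a, v, ctx, k * 90, resumed = k < 3))
  }
  units_in <- list(
    ## four same-dyad chains of four: members 1-3 resumed (12 exclusions)
    .fx_unit("seq", chain4("To", "Dm", "spontaneous")),
    .fx_unit("seq", chain4("To", "Dm", "spontaneous")),
    .fx_unit("seq", chain4("To", "Ta", "spontaneous")),
    .fx_unit("seq", chain4("To", "Ta", "spontaneous")),
    ## a two-event sequence, different dyads, 200-s gap: chained by the
    ## 4-min rule but no resumption, both members analysable
    .fx_unit("seq", list(ev("To", "Ta", "spontaneous", 0),
                         ev("To", "Dm", "spontaneous", 230))),
    ## male-coercion chains (8 resumed coercion PCs)
    .fx_unit("seq", list(ev("Wa", "To", "sexual_coercion", 0, resumed = TRUE),
                         ev("To", "Wa", "sexual_coercion", 90, resumed = TRUE),
                         ev("Wa", "To", "sexual_coercion", 180, resumed = TRUE),
                         ev("To", "Wa", "sexual_coercion", 270))),
    .fx_unit("seq", list(ev("Wa", "To", "sexual_coercion", 0, resumed = TRUE),
                         ev("To", "Wa", "sexual_coercion", 90, resumed = TRUE),
                         ev("Wa", "To", "sexual_coercion", 180))),
    .fx_unit("seq", list(ev("Wa", "Ta", "sexual_coercion", 0, resumed = TRUE),
                         ev("Ta", "Wa", "sexual_coercion", 90, resumed = TRUE),
                         ev("Wa", "Ta", "sexual_coercion", 180, resumed = TRUE),
                         ev("Ta", "Wa", "sexual_coercion", 270))))
  single <- function(a, v, ctx, n = 1) {
    rep(list(.fx_unit("single", list(ev(a, v, ctx, 0)))), n)
  }
  units_in <- c(units_in,
    single("Wa", "To", "sexual_coercion", 8),
    single("To", "Dm", "spontaneous", 1),
    single("To", "Dm", "sexual_coercion", 1),
    single("To", "Dm", "unknown", 3),
    single("To", "Ta", "weaning", 6),
    single("To", "Su", "spontaneous", 2),
    single("To", "Su", "sexual_coercion", 1),
    single("Su", "Dm", "spontaneous", 5),
    single("Su", "To", "spontaneous", 3),
    single("Su", "To", "unknown", 2),
    single("Su", "Ta", "spontaneous", 2),
    single("Su", "Ei", "spontaneous", 1),
    single("Su", "Ei", "object", 1),
    single("Dm", "Ta", "food", 3),
    single("Dm", "Ta", "object", 2),
    single("Dm", "Ei", "food", 2),
    single("Dm", "Ei", "object", 1),
    single("Dm", "To", "food", 1),
    single("Dm", "To", "object", 1),
    single("Ta", "Dm", "food", 1),
    single("Ta", "Dm", "object", 1))
  stopifnot(length(units_in) == 56)
  units_out <- c(
    single("Wa", "To", "sexual_coercion", 2),
    single("To", "Dm", "spontaneous", 9),
    single("To", "Dm", "sexual_coercion", 2),
    single("To", "Dm", "unknown", 1),
    single("To", "Ta", "weaning", 8),
    single("To", "Su", "spontaneous", 4),
    single("To", "Su", "sexual_coercion", 1),
    single("To", "Ei", "weaning", 3),
    single("Su", "To", "spontaneous", 1),
    single("Su", "Wa", "punishment", 1),
    single("Dm", "To", "food", 1),
    single("Ta", "Su", "food", 1))
  stopifnot(length(units_out) == 34)
  ## windows cut off by the session end (PC unavailable)
  units_end <- c(single("To", "Dm", "spontaneous", 1),
                 single("To", "Ta", "spontaneous", 1),
                 single("To", "Su", "spontaneous", 1))
  list(indoor = units_in, outdoor = units_out, indoor_end = units_end)
}

## intensity plan per context: counts of low/medium/high/undetermined in
## construction order, split by male-coercion where the mix differs
.fx_intensities <- function(ctx, male_coercion) {
  plan <- list(
    spontaneous = c(medium = 36, high = 13),
    weaning = c(low = 12, medium = 5),
    food = c(medium = 4, high = 5),
    object = c(low = 2, medium = 2, high = 2),
    punishment = c(high = 1),
    unknown = c(undetermined = 6),
    coercion_female = c(medium = 3, high = 2),
    coercion_male = c(medium = 7, high = 14))
  key <- ifelse(ctx == "sexual_coercion",
                ifelse(male_coercion, "coercion_male", "coercion_female"),
                ctx)
  out <- character(length(ctx))
  used <- lapply(plan, function(p) setNames(rep(0L, length(p)), names(p)))
  for (i in seq_along(key)) {
    p <- plan[[key[i]]]
    u <- used[[key[i]]]
    nx <- names(p)[which(u < p)[1]]
    used[[key[i]]][nx] <- u[nx] + 1L
    out[i] <- nx
  }
  out
}

.fx_elements <- function(intensity) {
  n_high <- 0L
  vapply(intensity, function(x) {
    switch(x,
           low = "gentle_push",
           medium = "chase",
           high = {
             n_high <<- n_high + 1L
             if (n_high <= 16) "chase+bite" else "lunge_attack"
           },
           undetermined = "not_visible")
  }, "")
}

#' Synthetic benchmark log with known pipeline output
#'
#' Builds a fully deterministic synthetic ethogram log (no randomness)
#' whose analysis results are fixed by construction; see the package
#' vignette for the complete list of designed counts. It serves as an
#' end-to-end regression benchmark for the whole pipeline at realistic
#' study scale.
#'
#' @return An [ethogram_log()] passing [validate_log()].
#' @export
study_fixture_log <- function() {
  setup <- study_setup()
  cal <- setup$calendar
  units <- .fx_conflict_units()

  ## ---- place units on alternate days so MC days are conflict-free ----
  rows <- list()
  place <- function(unit, cal_row, base_s) {
    for (e in unit$events) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        date = cal$date[cal_row], onset_s = base_s + e$rel_on,
        offset_s = base_s + e$rel_on + e$dur,
        condition = cal$condition[cal_row],
        aggressor = e$aggressor, victim = e$victim, context = e$context,
        resumed_by_design = e$resumed,
        unavailable_by_design = unit$kind == "end")
    }
  }
  out_days <- seq(1, 13, 2)
  for (i in seq_along(units$outdoor)) {
    place(units$outdoor[[i]], out_days[(i - 1) %/% 5 + 1],
          ((i - 1) %% 5) * .fx_slot_pitch)
  }
  in_days <- seq(15, 29, 2)
  for (i in seq_along(units$indoor)) {
    place(units$indoor[[i]], in_days[(i - 1) %/% 7 + 1],
          ((i - 1) %% 7) * .fx_slot_pitch)
  }
  for (i in seq_along(units$indoor_end)) {
    u <- units$indoor_end[[i]]
    u$kind <- "end"
    cr <- in_days[i]
    place(u, cr, cal$duration_h[cr] * 3600 - 400)
  }
  ag <- dplyr::bind_rows(rows)
  ag <- ag[order(ag$date, ag$onset_s), ]
  ag$event_id <- sprintf("AG%03d", seq_len(nrow(ag)))
  stopifnot(nrow(ag) == 114)

  males <- "Wa"
  ag$male_coercion <- ag$context == "sexual_coercion" &
    (ag$aggressor %in% males | ag$victim %in% males)
  ag$intensity <- .fx_intensities(ag$context, ag$male_coercion)
  ag$behaviour <- .fx_elements(ag$intensity)
  reaction_plan <- rep(c("avoidance", "nonaggressive_cease",
                         "counter_aggression", "none"),
                       times = c(47, 38, 20, 9))
  ag$reaction <- reaction_plan[seq_len(nrow(ag))]
  sg <- setNames(setup$roster$subgroup, setup$roster$id)
  ag$through_mesh <- ag$condition == "indoor" &
    sg[ag$aggressor] != sg[ag$victim]

  ## ---- third-party interventions --------------------------------------
  iv <- list()
  add_iv <- function(event_id, who, mode, supported, success = TRUE) {
    iv[[length(iv) + 1L]] <<- tibble::tibble(
      event_id = event_id, intervener = who, mode = mode,
      supported = supported, successful = success)
  }
  pick <- function(a, v, cond = NULL, n = Inf) {
    ok <- ag$aggressor == a & ag$victim == v & !ag$male_coercion
    if (!is.null(cond)) ok <- ok & ag$condition == cond
    utils::head(ag$event_id[ok], n)
  }
  for (id in pick("Dm", "Ta")) add_iv(id, "To", "aggressive", "Ta")
  for (id in pick("Su", "Ta")) add_iv(id, "To", "peaceful", "Ta")
  td_in <- pick("To", "Dm", "indoor")
  add_iv(td_in[1], "Su", "aggressive", "Dm"); add_iv(td_in[1], "Wa", "peaceful", "Dm")
  add_iv(td_in[2], "Su", "aggressive", "Dm"); add_iv(td_in[2], "Ei", "peaceful", "Dm")
  add_iv(td_in[3], "Wa", "aggressive", "Dm"); add_iv(td_in[3], "Su", "peaceful", "Dm")
  add_iv(td_in[4], "Su", "peaceful", "Dm")
  add_iv(td_in[5], "Su", "peaceful", "Dm")
  add_iv(td_in[6], "Wa", "peaceful", "Dm")
  add_iv(td_in[7], "Ei", "peaceful", "Dm")
  add_iv(td_in[8], "Ei", "peaceful", "Dm")
  add_iv(pick("To", "Dm", "outdoor", 1), "Su", "peaceful", "Dm")
  ts_out <- pick("To", "Su", "outdoor", 2)
  add_iv(ts_out[1], "Ta", "peaceful", "Su", success = FALSE)
  add_iv(ts_out[2], "Ta", "peaceful", "Su")
  ts_in <- pick("To", "Su", "indoor")
  add_iv(ts_in[1], "Ta", "peaceful", "Su")
  add_iv(ts_in[2], "Ta", "peaceful", "Su")
  add_iv(ts_in[3], "Ta", "peaceful", "Su")
  add_iv(ts_in[4], "Ei", "peaceful", "Su")
  ## male coercions all provoke an aggressive kin intervention
  coerce <- ag[ag$male_coercion & ag$aggressor == "Wa", ]
  for (i in seq_len(nrow(coerce))) {
    e <- coerce[i, ]
    if (e$victim == "Ta") {
      add_iv(e$event_id, "To", "aggressive", "Ta", success = TRUE)
    } else {
      add_iv(e$event_id, if (i %% 2 == 0) "Ta" else "Ei", "aggressive",
             e$victim, success = FALSE)
    }
  }
  iv <- dplyr::bind_rows(iv)

  ## one conflict with undeterminable intervention status (not intervened)
  undet_pool <- setdiff(pick("To", "Dm", "indoor"), iv$event_id)
  ag$intervention_undetermined <- ag$event_id == undet_pool[1]

  ## ---- affiliations realising the designed PC/MC outcomes -------------
  opp_out <- .fx_allocate(.fx_opp_pools(), .fx_opp_needs)
  tp_out <- .fx_allocate(.fx_tp_pools(), .fx_tp_needs, reverse = TRUE)

  af <- list()
  beh_opp <- c("touch_body", "contact_sitting", "grooming",
               "touch_body+contact_sitting")
  beh_tp_pc <- c("contact_sitting", "touch_body", "contact_sitting",
                 "embrace", "contact_sitting+touch_body",
                 "food_object_transfer")
  beh_tp_mc <- c("play", "touch_body", "play", "sucking_fur",
                 "contact_sitting", "play+touch_body", "cuddling")
  n_af <- 0L
  cond_of <- setNames(cal$condition, as.character(cal$date))
  add_af <- function(date, t, a, b, beh, vis = TRUE, initiator = a) {
    n_af <<- n_af + 1L
    af[[length(af) + 1L]] <<- tibble::tibble(
      event_id = sprintf("AF%03d", n_af), date = date, onset_s = t,
      condition = unname(cond_of[as.character(date)]),
      participant_a = a, participant_b = b, behaviour = beh,
      initiator = initiator, visibility_ok = vis)
  }
  base <- ag[!ag$resumed_by_design & !ag$unavailable_by_design &
               !ag$male_coercion, ]
  base <- base[order(base$date, base$onset_s), ]
  stopifnot(nrow(base) == 78)
  ctr <- setNames(rep(0L, 6), names(.fx_opp_needs))
  k_opp <- k_tp_pc <- k_tp_mc <- 0L
  for (i in seq_len(nrow(base))) {
    e <- base[i, ]
    v <- e$victim
    ctr[v] <- ctr[v] + 1L
    oo <- opp_out[[v]][[ctr[v]]]
    to <- tp_out[[v]][[ctr[v]]]
    anchor <- e$offset_s
    partner_tp <- .fx_tp_partner[[v]]
    stopifnot(partner_tp != e$aggressor)
    if (!is.na(oo$pc)) {
      k_opp <- k_opp + 1L
      add_af(e$date, anchor + (oo$pc - 1) * 60 + 20, v, e$aggressor,
             beh_opp[(k_opp - 1) %% length(beh_opp) + 1],
             vis = !identical(oo$type, "U"))
    }
    if (!is.na(oo$mc)) {
      k_opp <- k_opp + 1L
      add_af(e$date + 1, anchor + (oo$mc - 1) * 60 + 20, v, e$aggressor,
             beh_opp[(k_opp - 1) %% length(beh_opp) + 1])
    }
    if (!is.na(to$pc)) {
      k_tp_pc <- k_tp_pc + 1L
      add_af(e$date, anchor + (to$pc - 1) * 60 + 40, v, partner_tp,
             beh_tp_pc[(k_tp_pc - 1) %% length(beh_tp_pc) + 1],
             vis = !identical(to$type, "U"))
    }
    if (!is.na(to$mc)) {
      k_tp_mc <- k_tp_mc + 1L
      add_af(e$date + 1, anchor + (to$mc - 1) * 60 + 40, v, partner_tp,
             beh_tp_mc[(k_tp_mc - 1) %% length(beh_tp_mc) + 1])
    }
  }
  stopifnot(all(ctr == lengths(opp_out)))

  ## post-coercion mother-offspring affiliation in every analysable
  ## coercion PC with the female as victim; one late opponent contact
  coerce_pc <- ag[ag$male_coercion & !ag$resumed_by_design &
                    ag$victim != "Wa", ]
  for (i in seq_len(nrow(coerce_pc))) {
    e <- coerce_pc[i, ]
    buddy <- if (e$victim == "Ei") "To" else "Ei"
    add_af(e$date, e$offset_s + 20, e$victim, buddy,
           if (i %% 2 == 0) "embrace" else "contact_sitting",
           initiator = buddy)
  }
  ## exactly one coercion followed by an opponent reunion (9th minute)
  last_s2 <- coerce_pc[coerce_pc$onset_s %% .fx_slot_pitch == 180, ][1, ]
  add_af(last_s2$date, last_s2$offset_s + 8 * 60 + 20, last_s2$victim, "Wa",
         "touch_body")

  af <- dplyr::bind_rows(af)
  ag_final <- ag[, c("event_id", "date", "onset_s", "offset_s", "condition",
                     "aggressor", "victim", "behaviour", "intensity",
                     "context", "through_mesh", "reaction",
                     "intervention_undetermined")]
  ethogram_log(setup, ag_final, af, iv)
}
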