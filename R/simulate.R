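## Seeded generator of synthetic ethogram logs with the statistical
## structure the PC/MC analysis assumes: per-dyad Poisson aggression
## skewed down the dominance hierarchy, context/intensity patterning,
## third-party interventions, and affiliative contact point processes
## whose hazard is multiplied in a post-conflict window.

## Baseline dyad weighting of aggression: heavily skewed to the dominant
## female, forced copulations by the male, occasional counter-aggression.
.default_dyad_weights <- function() {
  ids <- default_roster()$id
  w <- matrix(0, 6, 6, dimnames = list(ids, ids))
  w["Wa", "To"] <- 14; w["Wa", "Ta"] <- 2
  w["To", "Dm"] <- 27; w["To", "Ta"] <- 24; w["To", "Su"] <- 9
  w["To", "Ei"] <- 3;  w["To", "Wa"] <- 3
  w["Su", "Dm"] <- 5;  w["Su", "To"] <- 6; w["Su", "Ta"] <- 2
  w["Su", "Ei"] <- 2;  w["Su", "Wa"] <- 1
  w["Dm", "Ta"] <- 5;  w["Dm", "Ei"] <- 3; w["Dm", "To"] <- 3
  w["Ta", "Dm"] <- 2;  w["Ta", "Su"] <- 1; w["Ta", "Wa"] <- 2
  w
}

#' Simulation configuration
#'
#' Parameters of the synthetic ethogram generator. Defaults emulate the
#' study conditions the analysis pipeline is built for: a six-individual
#' group observed 74.35 h outdoors and 83.15 h indoors, roughly 114
#' aggressive interactions with rates skewed down the dominance hierarchy
#' and a ~6.4-fold indoor increase, context frequencies of about 43%
#' spontaneous / 23% sexual coercion / 15% weaning, and dyadic affiliation
#' point processes whose hazard is multiplied by `attraction_alpha`
#' (opponent dyad) or `attraction_beta` (victim-bystander dyads) for
#' `window_s` seconds after each conflict.
#'
#' @param roster,calendar Study structure; see [default_roster()],
#'   [default_calendar()].
#' @param dyad_weights Aggressor-by-victim weight matrix; scaled so the
#'   expected aggression totals match `total_outdoor`/`total_indoor`.
#' @param total_outdoor,total_indoor Expected aggression counts per
#'   condition.
#' @param context_probs Named context probabilities (must sum to 1);
#'   renormalised per dyad over the contexts it can express (sexual
#'   coercion needs the male or two adult females, weaning the
#'   mother-offspring dyad).
#' @param affiliation_rate Baseline affiliative contacts per dyad per hour.
#' @param attraction_alpha,attraction_beta Post-conflict hazard multipliers
#'   (>= 0) for the opponent dyad and for victim-bystander dyads.
#' @param window_s Length of the elevated-hazard window (seconds).
#' @param intervention_prob Named per-condition probability that a conflict
#'   outside male coercion draws an intervention.
#' @param p_counter Probability that a male coercion is followed by a
#'   counter-aggression by the victim within 3 minutes.
#' @param p_visibility Probability an affiliative contact is codeable.
#' @param seed Integer seed fixing every draw.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(roster = default_roster(),
                              calendar = default_calendar(),
                              dyad_weights = .default_dyad_weights(),
                              total_outdoor = 14, total_indoor = 100,
                              context_probs = c(spontaneous = 0.43,
                                                sexual_coercion = 0.23,
                                                weaning = 0.15, food = 0.08,
                                                object = 0.05,
                                                punishment = 0.01,
                                                unknown = 0.05),
                              affiliation_rate = 1.9,
                              attraction_alpha = 8.5,
                              attraction_beta = 2,
                              window_s = 120,
                              intervention_prob = c(outdoor = 0.09,
                                                    indoor = 0.31),
                              p_counter = 0.25,
                              p_visibility = 0.95,
                              seed = 1L) {
  if (abs(sum(context_probs) - 1) > 1e-8) {
    abort("context probabilities must sum to 1")
  }
  if (attraction_alpha < 0 || attraction_beta < 0) {
    abort("attraction multipliers must be >= 0")
  }
  structure(list(roster = roster, calendar = calendar,
                 dyad_weights = dyad_weights,
                 total_outdoor = total_outdoor, total_indoor = total_indoor,
                 context_probs = context_probs,
                 affiliation_rate = affiliation_rate,
                 attraction_alpha = attraction_alpha,
                 attraction_beta = attraction_beta, window_s = window_s,
                 intervention_prob = intervention_prob,
                 p_counter = p_counter, p_visibility = p_visibility,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.intensity_by_context <- list(
  spontaneous = c(medium = 0.73, high = 0.27),
  sexual_coercion = c(medium = 0.38, high = 0.62),
  weaning = c(low = 0.7, medium = 0.3),
  food = c(medium = 0.45, high = 0.55),
  object = c(low = 0.33, medium = 0.33, high = 0.34),
  punishment = c(high = 1),
  unknown = c(undetermined = 1))

.elements_for_intensity <- function(intensity) {
  map <- default_intensity_map()
  if (intensity == "undetermined") return("not_visible")
  pool <- names(map)[map == intensity]
  pool[sample.int(length(pool), 1L)]
}

.sample_affiliation_types <- function(n) {
  vocab <- c("contact_sitting", "touch_body", "play", "embrace",
             "food_object_transfer", "grooming", "cuddling", "sucking_fur")
  probs <- c(0.28, 0.22, 0.2, 0.06, 0.08, 0.06, 0.06, 0.04)
  one <- sample(vocab, n, replace = TRUE, prob = probs)
  two <- stats::runif(n) < 0.15
  second <- sample(vocab, n, replace = TRUE, prob = probs)
  ifelse(two & second != one, paste(one, second, sep = "+"), one)
}

#' Simulate a full ethogram log
#'
#' Draws aggressions as per-dyad Poisson processes over the session
#' calendar, assigns contexts, intensities, reactions and third-party
#' interventions, and draws affiliative contacts as per-dyad Poisson
#' processes whose hazard is multiplied by `attraction_alpha` (former
#' opponents) or `attraction_beta` (victim with bystanders) for `window_s`
#' seconds after each conflict ends. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An [ethogram_log()] that passes [validate_log()], with the
#'   config attached as attribute `config`.
#' @export
simulate_log <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  setup <- study_setup(config$roster, config$calendar)
  cal <- setup$calendar
  roster <- setup$roster
  ids <- roster$id
  male <- ids[roster$sex == "male" & roster$age_class == "adult"]
  adult_female <- ids[roster$sex == "female" & roster$age_class == "adult"]

  w <- config$dyad_weights[ids, ids]
  wsum <- sum(w)
  rate_h <- list(outdoor = w / wsum * config$total_outdoor /
                   setup$hours[["outdoor"]],
                 indoor = w / wsum * config$total_indoor /
                   setup$hours[["indoor"]])

  allowed_contexts <- function(a, v) {
    ## aggression against the adult male only occurs as counter-aggression
    ## within the sexual-coercion context
    if (v %in% male) return("sexual_coercion")
    ok <- names(config$context_probs)
    coercion_ok <- a %in% male ||
      (a %in% adult_female && v %in% adult_female)
    if (!coercion_ok) ok <- setdiff(ok, "sexual_coercion")
    mother_v <- roster$mother[match(v, ids)]
    if (is.na(mother_v) || mother_v != a) ok <- setdiff(ok, "weaning")
    ok
  }

  ag_rows <- list(); iv_rows <- list(); next_ag <- 1L
  add_aggression <- function(date, onset, dur, cond, a, v, context,
                             intensity) {
    id <- sprintf("AG%04d", next_ag); next_ag <<- next_ag + 1L
    sg <- roster$subgroup[match(c(a, v), ids)]
    reaction <- sample(c("avoidance", "nonaggressive_cease",
                         "counter_aggression", "none"), 1L,
                       prob = c(0.41, 0.30, 0.18, 0.11))
    ag_rows[[length(ag_rows) + 1L]] <<- list(
      event_id = id, date = date, onset_s = onset, offset_s = onset + dur,
      condition = cond, aggressor = a, victim = v,
      behaviour = .elements_for_intensity(intensity),
      intensity = intensity, context = context,
      through_mesh = cond == "indoor" && sg[1] != sg[2],
      reaction = reaction, intervention_undetermined = FALSE)
    id
  }

  dyad_idx <- which(w >= 0 & row(w) != col(w), arr.ind = TRUE)
  for (si in seq_len(nrow(cal))) {
    sess <- cal[si, ]
    r <- rate_h[[sess$condition]]
    for (k in seq_len(nrow(dyad_idx))) {
      a <- ids[dyad_idx[k, 1]]; v <- ids[dyad_idx[k, 2]]
      lam <- r[a, v] * sess$duration_h
      if (lam <= 0) next
      n_ev <- stats::rpois(1L, lam)
      if (n_ev == 0) next
      sess_len <- sess$duration_h * 3600
      onsets <- sort(stats::runif(n_ev, 0, max(sess_len - 700, 1)))
      for (t0 in onsets) {
        ok <- allowed_contexts(a, v)
        pr <- config$context_probs[ok] / sum(config$context_probs[ok])
        ctx <- sample(names(pr), 1L, prob = pr)
        ip <- .intensity_by_context[[ctx]]
        intensity <- sample(names(ip), 1L, prob = ip)
        id <- add_aggression(sess$date, t0, stats::runif(1, 20, 60),
                             sess$condition, a, v, ctx, intensity)
        is_male_coerce <- ctx == "sexual_coercion" && a %in% male
        if (is_male_coerce) {
          ## forced copulations always provoke an intervention by kin
          interveners <- if (v == "To") {
            kids <- ids[!is.na(roster$mother) & roster$mother == v]
            if (stats::runif(1) < 0.2 && length(kids) > 1) kids else
              kids[sample.int(length(kids), 1L)]
          } else "To"
          for (iv in interveners) {
            if (iv %in% c(a, v)) next
            iv_rows[[length(iv_rows) + 1L]] <- list(
              event_id = id, intervener = iv, mode = "aggressive",
              supported = v, successful = iv == "To")
          }
          if (stats::runif(1) < config$p_counter) {
            add_aggression(sess$date, t0 + 60 + stats::runif(1, 10, 110),
                           15, sess$condition, v, a, "sexual_coercion",
                           sample(c("medium", "high"), 1L))
          }
        } else if (!(ctx == "sexual_coercion" && v %in% male)) {
          p_iv <- config$intervention_prob[[sess$condition]]
          if (stats::runif(1) < p_iv) {
            cand <- setdiff(ids, c(a, v))
            iv1 <- cand[sample.int(length(cand), 1L)]
            iv_rows[[length(iv_rows) + 1L]] <- list(
              event_id = id, intervener = iv1,
              mode = sample(c("peaceful", "aggressive"), 1L,
                            prob = c(0.68, 0.32)),
              supported = v, successful = stats::runif(1) < 0.95)
          }
        }
      }
    }
  }
  chr <- function(rows, f) vapply(rows, `[[`, NA_character_, f)
  num <- function(rows, f) vapply(rows, `[[`, NA_real_, f)
  lgl <- function(rows, f) vapply(rows, `[[`, NA, f)
  ag <- if (length(ag_rows)) {
    tibble::tibble(
      event_id = chr(ag_rows, "event_id"),
      date = as.Date(num(ag_rows, "date"), origin = "1970-01-01"),
      onset_s = num(ag_rows, "onset_s"), offset_s = num(ag_rows, "offset_s"),
      condition = chr(ag_rows, "condition"),
      aggressor = chr(ag_rows, "aggressor"), victim = chr(ag_rows, "victim"),
      behaviour = chr(ag_rows, "behaviour"),
      intensity = chr(ag_rows, "intensity"), context = chr(ag_rows, "context"),
      through_mesh = lgl(ag_rows, "through_mesh"),
      reaction = chr(ag_rows, "reaction"),
      intervention_undetermined = lgl(ag_rows, "intervention_undetermined"))
  } else empty_aggressions()
  iv <- if (length(iv_rows)) {
    tibble::tibble(
      event_id = chr(iv_rows, "event_id"),
      intervener = chr(iv_rows, "intervener"), mode = chr(iv_rows, "mode"),
      supported = chr(iv_rows, "supported"),
      successful = lgl(iv_rows, "successful"))
  } else empty_interventions()

  ## --- affiliations: baseline homogeneous process per unordered dyad ---
  pair_grid <- utils::combn(ids, 2)
  n_dyads <- ncol(pair_grid)
  sess_idx <- rep(seq_len(nrow(cal)), each = n_dyads)
  dyad_idx2 <- rep(seq_len(n_dyads), times = nrow(cal))
  counts <- stats::rpois(length(sess_idx),
                         config$affiliation_rate * cal$duration_h[sess_idx])
  sidx <- rep(sess_idx, counts); didx <- rep(dyad_idx2, counts)
  af <- tibble::tibble(
    date = cal$date[sidx],
    onset_s = stats::runif(length(sidx), 0,
                           cal$duration_h[sidx] * 3600),
    condition = cal$condition[sidx],
    participant_a = pair_grid[1, didx], participant_b = pair_grid[2, didx])

  ## post-conflict hazard modulation: thin baseline events when the
  ## multiplier is < 1, superpose extra events when it is > 1
  if (nrow(ag)) {
    alpha <- config$attraction_alpha; beta <- config$attraction_beta
    r_s <- config$affiliation_rate / 3600
    keep <- rep(TRUE, nrow(af))
    af_day <- as.numeric(af$date)
    sess_len_of <- cal$duration_h[match(as.numeric(ag$date),
                                        as.numeric(cal$date))] * 3600
    x_date <- numeric(); x_on <- numeric(); x_cond <- character()
    x_pa <- character(); x_pb <- character()
    for (i in seq_len(nrow(ag))) {
      w0 <- ag$offset_s[i]
      w1 <- min(w0 + config$window_s, sess_len_of[i])
      if (w1 <= w0) next
      vict <- ag$victim[i]; aggr <- ag$aggressor[i]
      others <- setdiff(ids, c(aggr, vict))
      boost <- function(p1, p2, mult) {
        if (mult > 1) {
          n_x <- stats::rpois(1L, r_s * (mult - 1) * (w1 - w0))
          if (n_x > 0) {
            x_date <<- c(x_date, rep(as.numeric(ag$date[i]), n_x))
            x_on <<- c(x_on, stats::runif(n_x, w0, w1))
            x_cond <<- c(x_cond, rep(ag$condition[i], n_x))
            x_pa <<- c(x_pa, rep(min(p1, p2), n_x))
            x_pb <<- c(x_pb, rep(max(p1, p2), n_x))
          }
        } else if (mult < 1) {
          in_w <- af_day == as.numeric(ag$date[i]) &
            af$onset_s >= w0 & af$onset_s <= w1 &
            ((af$participant_a == p1 & af$participant_b == p2) |
               (af$participant_a == p2 & af$participant_b == p1))
          drop <- in_w & stats::runif(nrow(af)) > mult
          keep <<- keep & !drop
        }
      }
      boost(vict, aggr, alpha)
      for (x in others) boost(vict, x, beta)
    }
    af <- af[keep, ]
    if (length(x_on)) {
      af <- dplyr::bind_rows(af, tibble::tibble(
        date = as.Date(x_date, origin = "1970-01-01"), onset_s = x_on,
        condition = x_cond, participant_a = x_pa, participant_b = x_pb))
    }
  }
  if (nrow(af)) {
    af <- af[order(af$date, af$onset_s), ]
    af$event_id <- sprintf("AF%04d", seq_len(nrow(af)))
    af$behaviour <- .sample_affiliation_types(nrow(af))
    af$initiator <- ifelse(stats::runif(nrow(af)) < 0.5,
                           af$participant_a, af$participant_b)
    af$visibility_ok <- stats::runif(nrow(af)) < config$p_visibility
    af <- af[, c("event_id", "date", "onset_s", "condition",
                 "participant_a", "participant_b", "behaviour",
                 "initiator", "visibility_ok")]
  } else {
    af <- empty_affiliations()
  }

  out <- ethogram_log(setup, ag, af, iv)
  attr(out, "config") <- config
  out
}

#' Pipeline recovery experiment
#'
#' Runs the full pipeline (simulate, match, classify, test) on repeated
#' synthetic studies across a grid of post-conflict attraction multipliers
#' and reports, per multiplier, the rejection rate of the exact
#' reconciliation test at the 0.05 level together with the mean
#' attracted/dispersed proportions. With `alpha = 1` the generator is an
#' exact null and the rejection rate estimates the test's realised size;
#' large multipliers estimate its power. Replicates share seeds across
#' multipliers (common random numbers).
#'
#' @param config Base [simulation_config()].
#' @param alphas Numeric vector of `attraction_alpha` values.
#' @param reps Replicates per value.
#' @param seed Master seed for the experiment.
#' @param level Test level (default 0.05).
#' @return Tibble: `alpha`, `reps`, `rejection_rate`, `mean_attracted`,
#'   `mean_dispersed`, `mean_diff`.
#' @export
recovery_experiment <- function(config = simulation_config(),
                                alphas = c(1, 8.5), reps = 50, seed = 1L,
                                level = 0.05) {
  stopifnot(reps >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, reps)
  out <- list()
  for (a in alphas) {
    rej <- logical(reps); att <- disp <- numeric(reps)
    for (r in seq_len(reps)) {
      cfg <- config
      cfg$attraction_alpha <- a
      cfg$seed <- rep_seeds[r]
      log <- simulate_log(cfg)
      pairs <- build_pcmc_pairs(log)
      res <- tryCatch({
        props <- victim_proportions(pairs, "opponent")
        tst <- reconciliation_test(props)
        list(p = tst$p, att = mean(props$attracted),
             disp = mean(props$dispersed))
      }, error = function(e) list(p = 1, att = NA_real_, disp = NA_real_))
      rej[r] <- res$p <= level
      att[r] <- res$att; disp[r] <- res$disp
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      alpha = a, reps = reps, rejection_rate = mean(rej),
      mean_attracted = mean(att, na.rm = TRUE),
      mean_dispersed = mean(disp, na.rm = TRUE),
      mean_diff = mean(att - disp, na.rm = TRUE))
  }
  dplyr::bind_rows(out)
}
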