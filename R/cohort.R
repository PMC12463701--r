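# Eligibility cascade, index-episode selection, and mother-infant dyad
# linkage. The cascade report is the machine analog of a study flow chart:
# every woman leaving the cohort is attributed to the first criterion that
# removed her, so stage counts always reconcile.

.default_culmination_window <- as.Date(c("2016-01-01", "2020-06-30"))

#' Check continuous enrollment around a pregnancy culmination
#'
#' True iff the union of a person's coverage spans covers every day of
#' `[culmination - pre_days, culmination + post_days]` (closed interval,
#' zero uncovered days; spans meeting on consecutive days count as
#' continuous).
#'
#' @param spans data.frame with `span_start`, `span_end` (Date) for one person.
#' @param culmination_date the pregnancy culmination date.
#' @param pre_days,post_days window half-lengths in days (default 365 each).
#' @return Logical scalar.
#' @export
check_continuous_enrollment <- function(spans, culmination_date,
                                        pre_days = 365L, post_days = 365L) {
  culmination_date <- as.Date(culmination_date)
  w0 <- as.integer(culmination_date) - as.integer(pre_days)
  w1 <- as.integer(culmination_date) + as.integer(post_days)
  s <- pmax(as.integer(as.Date(spans$span_start)), w0)
  e <- pmin(as.integer(as.Date(spans$span_end)), w1)
  keep <- e >= s
  if (!any(keep)) return(FALSE)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  covered <- 0L
  reach <- s[1] - 1L
  for (i in seq_along(s)) {
    if (s[i] > reach + 1L && i > 1L) return(FALSE)  # hole before this span
    covered <- covered + max(0L, e[i] - max(s[i], reach + 1L) + 1L)
    reach <- max(reach, e[i])
  }
  covered == (w1 - w0 + 1L)
}

# vectorized continuous-enrollment check, one result per culmination row
# (a woman with several episodes has one window per episode)
enrollment_ok_all <- function(spans, culm, pre_days = 365L, post_days = 365L) {
  culm <- data.table::as.data.table(culm)
  culm[, .row := .I]
  dt <- data.table::as.data.table(spans)[culm, on = "person_id",
                                         nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(dt) == 0L) return(rep(FALSE, nrow(culm)))
  dt[, `:=`(w0 = as.integer(as.Date(culmination_date)) - as.integer(pre_days),
            w1 = as.integer(as.Date(culmination_date)) + as.integer(post_days),
            s = as.integer(as.Date(span_start)),
            e = as.integer(as.Date(span_end)))]
  dt[, `:=`(s = pmax(s, w0), e = pmin(e, w1))]
  dt <- dt[e >= s]
  data.table::setorder(dt, .row, s, e)
  dt[, prev_reach := shift(cummax(e), fill = NA_integer_), by = .row]
  dt[, cov := e - pmax(s, data.table::fifelse(
    is.na(prev_reach), w0, prev_reach + 1L)) + 1L]
  dt[cov < 0L, cov := 0L]
  tot <- dt[, .(covered = sum(cov), need = w1[1] - w0[1] + 1L), by = .row]
  ok <- tot[covered == need, .row]
  culm[, .row := NULL]
  seq_len(nrow(culm)) %in% ok
}

#' Flag each pregnancy episode against the eligibility criteria
#'
#' Evaluates, per episode: culmination inside the study culmination window;
#' maternal age 18-45 at delivery (delivery year minus birth year); not an
#' induced abortion; not a multiple gestation (episodes carrying O30/O31
#' claims are excluded whether their outcome is known or unknown);
#' continuous enrollment for `pre_days`/`post_days` around the culmination.
#'
#' @param episodes episode table from [build_episodes()].
#' @param enrollment enrollment table with `person_id`, `span_start`,
#'   `span_end`, `birth_year`.
#' @param culmination_window length-2 Date vector (default
#'   2016-01-01..2020-06-30).
#' @param age_range closed age interval (default 18-45).
#' @param pre_days,post_days continuous-enrollment half-windows.
#' @return The episode table with logical flag columns `ok_window`,
#'   `ok_age`, `ok_not_induced`, `ok_singleton`, `ok_enrolled`, `eligible`.
#' @export
apply_eligibility <- function(episodes, enrollment,
                              culmination_window = .default_culmination_window,
                              age_range = c(18L, 45L),
                              pre_days = 365L, post_days = 365L) {
  ep <- data.table::copy(data.table::as.data.table(episodes))
  en <- data.table::as.data.table(enrollment)
  by_birth <- unique(en[, .(person_id, birth_year)])
  ep[, birth_year := by_birth[match(ep$woman_id, person_id), birth_year]]
  ep[, age_at_delivery := data.table::year(delivery_date) - as.integer(birth_year)]
  ep[, ok_window := delivery_date >= culmination_window[1] &
       delivery_date <= culmination_window[2]]
  ep[, ok_age := !is.na(age_at_delivery) &
       age_at_delivery >= age_range[1] & age_at_delivery <= age_range[2]]
  ep[, ok_not_induced := outcome_class != "induced_abortion"]
  ep[, ok_singleton := !multiple_gestation]
  ok_en <- enrollment_ok_all(
    en[, .(person_id, span_start, span_end)],
    ep[, .(person_id = woman_id, culmination_date = delivery_date)],
    pre_days, post_days)
  ep[, ok_enrolled := ok_en]
  ep[, eligible := ok_window & ok_age & ok_not_induced & ok_singleton & ok_enrolled]
  ep[]
}

#' Select one index episode per woman by outcome hierarchy
#'
#' Applies the prioritization live birth > stillbirth > spontaneous
#' abortion > unknown outcome; ties within a priority class are broken by
#' the earliest delivery date.
#'
#' @param episodes eligible episodes (any number of women).
#' @return One row per woman: her index episode.
#' @export
select_index_episode <- function(episodes) {
  ep <- data.table::as.data.table(episodes)
  if (nrow(ep) == 0L) return(ep)
  prio <- c(live_birth = 1L, stillbirth = 2L, spontaneous_abortion = 3L,
            unknown = 4L, induced_abortion = 5L)
  ep <- data.table::copy(ep)[, .prio := prio[outcome_class]]
  data.table::setorder(ep, woman_id, .prio, delivery_date)
  out <- unique(ep, by = "woman_id")  # first row per woman = highest priority
  out[, .prio := NULL]
  out[]
}

#' Link live-birth index episodes to infants via the family identifier
#'
#' A dyad links a live-birth episode to an infant that shares the mother's
#' `family_id` and whose first claim date falls within `link_window` days
#' of the episode delivery date. When several infants qualify, the one with
#' the nearest first-claim date is chosen.
#'
#' @param index_episodes index episodes carrying `woman_id`, `family_id`,
#'   `delivery_date`, `outcome_class`.
#' @param infant_claims infant claims with `person_id`, `family_id`,
#'   `service_date`.
#' @param link_window maximum |first claim - delivery| in days (default 60).
#' @return data.table `woman_id`, `infant_id`, `first_claim_date`,
#'   `n_candidates`; unlinked mothers are absent.
#' @export
link_dyads <- function(index_episodes, infant_claims, link_window = 60L) {
  ie <- data.table::as.data.table(index_episodes)[outcome_class == "live_birth"]
  empty <- data.table::data.table(woman_id = character(),
                                  infant_id = character(),
                                  first_claim_date = as.Date(character()),
                                  n_candidates = integer())
  inf <- data.table::as.data.table(infant_claims)
  if (nrow(ie) == 0L || nrow(inf) == 0L) return(empty)
  first <- inf[, .(first_claim_date = min(as.Date(service_date))),
               by = .(infant_id = person_id, family_id)]
  cand <- first[ie[, .(woman_id, family_id, delivery_date)], on = "family_id",
                nomatch = NULL, allow.cartesian = TRUE]
  cand[, dist := abs(as.integer(first_claim_date) - as.integer(delivery_date))]
  cand <- cand[dist <= link_window]
  if (nrow(cand) == 0L) return(empty)
  data.table::setorder(cand, woman_id, dist, infant_id)
  out <- cand[, .(infant_id = infant_id[1L],
                  first_claim_date = first_claim_date[1L],
                  n_candidates = .N), by = woman_id]
  out[]
}

#' Run the full cohort stage: cascade, index selection, dyad linkage
#'
#' Applies [apply_eligibility()], attributes each excluded woman to the
#' first criterion that removed her (fixed order: culmination window, age,
#' multiple gestation, induced abortion, continuous enrollment), selects
#' the index episode for the survivors, links dyads, and derives the two
#' analysis sets: the maternal-outcome cohort (index outcome known) and
#' the birth-outcome cohort (live births with a linked infant).
#'
#' @param episodes episode table from [build_episodes()].
#' @param enrollment combined enrollment table (mothers need `birth_year`,
#'   `family_id`).
#' @param infant_claims infant claims table (may be empty).
#' @param culmination_window,age_range,pre_days,post_days,link_window see
#'   the stage functions.
#' @return List: `members` (one row per cohort woman with index episode,
#'   `infant_id`, `in_maternal_cohort`, `in_birth_cohort`), `cascade`
#'   (stage, n_in, n_excluded, reason), `flagged_episodes`.
#' @export
build_cohort <- function(episodes, enrollment, infant_claims,
                         culmination_window = .default_culmination_window,
                         age_range = c(18L, 45L),
                         pre_days = 365L, post_days = 365L,
                         link_window = 60L) {
  ep <- apply_eligibility(episodes, enrollment, culmination_window,
                          age_range, pre_days, post_days)
  women <- unique(ep$woman_id)
  # attribute each fully-excluded woman to her first failing criterion,
  # judged on her "best" episode under that ordering
  crit <- c(window = "ok_window", age = "ok_age",
            multiple_gestation = "ok_singleton",
            induced_abortion = "ok_not_induced",
            enrollment = "ok_enrolled")
  remaining <- ep
  cascade <- data.table::data.table(stage = character(), n_in = integer(),
                                    n_excluded = integer(), reason = character())
  n_in <- length(women)
  for (k in seq_along(crit)) {
    keep <- remaining[remaining[[crit[k]]] == TRUE]
    lost <- setdiff(unique(remaining$woman_id), unique(keep$woman_id))
    cascade <- rbind(cascade, data.table::data.table(
      stage = names(crit)[k], n_in = n_in, n_excluded = length(lost),
      reason = names(crit)[k]))
    n_in <- n_in - length(lost)
    remaining <- keep
  }
  idx <- select_index_episode(remaining)
  cascade <- rbind(cascade, data.table::data.table(
    stage = "dedup_to_index", n_in = n_in, n_excluded = 0L,
    reason = "one episode per woman"))

  en <- data.table::as.data.table(enrollment)
  fam <- unique(en[, .(person_id, family_id)])
  idx[, family_id := fam[match(idx$woman_id, person_id), family_id]]
  dy <- link_dyads(idx, infant_claims, link_window)
  idx[, infant_id := dy[match(idx$woman_id, woman_id), infant_id]]
  idx[, in_maternal_cohort := outcome_class != "unknown"]
  idx[, in_birth_cohort := in_maternal_cohort &
        outcome_class == "live_birth" & !is.na(infant_id)]

  cascade <- rbind(cascade, data.table::data.table(
    stage = c("maternal_outcome_cohort", "birth_outcome_cohort"),
    n_in = c(n_in, sum(idx$in_maternal_cohort)),
    n_excluded = c(sum(!idx$in_maternal_cohort),
                   sum(idx$in_maternal_cohort & !idx$in_birth_cohort)),
    reason = c("unknown outcome", "stillbirth or unlinked dyad")))
  list(members = idx[], cascade = cascade, flagged_episodes = ep)
}

#' Structured flow-chart summary of a cascade report
#'
#' Orders the cascade stages, carries the running cohort size, and hard-fails
#' if the counts do not reconcile (an internal-consistency bug, never a data
#' property).
#'
#' @param cascade the cascade table from [build_cohort()].
#' @return data.table with `stage`, `n_in`, `n_excluded`, `n_out`, `reason`.
#' @export
emit_flowchart <- function(cascade) {
  fc <- data.table::copy(data.table::as.data.table(cascade))
  fc[, n_out := n_in - n_excluded]
  main <- fc[!stage %in% c("maternal_outcome_cohort", "birth_outcome_cohort")]
  if (nrow(main) > 1L && !all(main$n_out[-nrow(main)] == main$n_in[-1L])) {
    stop("cascade counts do not reconcile")
  }
  fc[]
}
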