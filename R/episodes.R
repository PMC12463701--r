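# Pregnancy-episode reconstruction: filter pregnancy-related claims, group
# them per woman under the temporal gap rules, classify each episode's
# outcome, and estimate LMP / delivery date / gestational age.

.outcome_levels <- c("live_birth", "stillbirth", "spontaneous_abortion",
                     "induced_abortion", "unknown")
.outcome_gap_type <- c(live_birth = 1L, stillbirth = 2L,
                       spontaneous_abortion = 3L, induced_abortion = 4L)
# gestational-age defaults (completed weeks) when an episode carries no
# weeks-of-gestation code; flagged as imputed
.ga_defaults <- c(live_birth = 39L, stillbirth = 30L,
                  spontaneous_abortion = 10L, induced_abortion = 10L,
                  unknown = NA_integer_)

#' Retain the pregnancy-related subset of a claims table
#'
#' Keeps claims whose codes belong to the pregnancy-related families used
#' for episode construction: the obstetric O chapter, Z3A weeks of
#' gestation, Z33/Z34 pregnancy state and supervision, Z37 delivery
#' outcome, Z38 liveborn, and the corresponding ICD-9 ranges (630-679,
#' V22/V23/V27, 765.2x). Input ordering is preserved.
#'
#' @param claims data.frame/data.table with at least `code`, `icd_version`.
#' @return The qualifying rows, as a data.table.
#' @export
extract_pregnancy_claims <- function(claims) {
  claims <- data.table::as.data.table(claims)
  if (nrow(claims) == 0L) return(claims)
  claims[is_pregnancy_code(claims$code, claims$icd_version)]
}

#' Group one woman's pregnancy-related claims into episodes
#'
#' Greedy left-to-right grouping: claims are absorbed into the open episode
#' until a gap rule fires. A new episode opens when the current claim is at
#' least `gap_live` (default 120) days after the open episode's most recent
#' live-birth record, at least `gap_loss` (default 42) days after its most
#' recent stillbirth or abortion record, or -- when the open episode has no
#' outcome record yet -- more than `max_span` (default 308) days after the
#' episode's first claim. "X days after" means a date difference of at
#' least X.
#'
#' @param claims claims for a single woman, sorted by service date, with
#'   columns `service_date`, `code`, `icd_version`.
#' @param gap_live,gap_loss,max_span gap-rule day counts.
#' @return Integer vector of 1-based episode indices, one per claim.
#' @export
group_into_episodes <- function(claims, gap_live = 120L, gap_loss = 42L,
                                max_span = 308L) {
  claims <- data.table::as.data.table(claims)
  if (nrow(claims) == 0L) return(integer(0))
  dates <- as.Date(claims$service_date)
  if (is.unsorted(dates)) stop("claims must be sorted by service date")
  ev <- classify_outcome_evidence(claims$code, claims$icd_version)
  ot <- .outcome_gap_type[ev]
  ot[is.na(ot)] <- 0L
  group_episodes_cpp(rep(1L, nrow(claims)), as.integer(dates),
                     as.integer(ot), as.integer(gap_live),
                     as.integer(gap_loss), as.integer(max_span))
}

#' Classify a pregnancy episode's outcome from its claim codes
#'
#' Outcome families are evidenced by: live birth (O80/O82, Z37.0),
#' stillbirth (Z37.1, P95), spontaneous abortion (O03), induced abortion
#' (O04). When several families co-occur within one episode the precedence
#' is live birth > stillbirth > spontaneous abortion > induced abortion;
#' with no outcome evidence the episode is "unknown".
#'
#' @param codes character vector of the episode's ICD codes.
#' @param icd_version 9 or 10, recycled.
#' @return One of `"live_birth"`, `"stillbirth"`, `"spontaneous_abortion"`,
#'   `"induced_abortion"`, `"unknown"`.
#' @export
classify_outcome <- function(codes, icd_version = 10L) {
  ev <- classify_outcome_evidence(codes, icd_version)
  for (cls in .outcome_levels[1:4]) if (any(ev == cls, na.rm = TRUE)) return(cls)
  "unknown"
}

#' Estimate LMP, delivery date and gestational age for one episode
#'
#' The delivery (culmination) date is the earliest claim of the
#' outcome-defining family, or the episode's last claim date when there is
#' no outcome record. Gestational age is the maximum week observed across
#' Z3A.xx / 765.2x codes; without any week code it defaults by outcome
#' class (live birth 39, stillbirth 30, spontaneous/induced abortion 10,
#' unknown missing) and is flagged imputed. LMP is the delivery date minus
#' seven days per gestational week.
#'
#' @param dates claim service dates (Date).
#' @param codes claim ICD codes.
#' @param icd_version claim ICD versions.
#' @param outcome_class the episode outcome from [classify_outcome()].
#' @return List with `lmp_date`, `delivery_date`, `ga_weeks`, `ga_imputed`.
#' @export
estimate_dates <- function(dates, codes, icd_version = 10L,
                           outcome_class = classify_outcome(codes, icd_version)) {
  dates <- as.Date(dates)
  ev <- classify_outcome_evidence(codes, icd_version)
  delivery <- if (outcome_class != "unknown" && any(ev == outcome_class, na.rm = TRUE)) {
    min(dates[!is.na(ev) & ev == outcome_class])
  } else {
    max(dates)
  }
  wk <- suppressWarnings(gestational_week_from_code(codes, icd_version))
  ga <- if (all(is.na(wk))) NA_integer_ else max(wk, na.rm = TRUE)
  imputed <- is.na(ga)
  if (imputed) ga <- .ga_defaults[[outcome_class]]
  lmp <- if (is.na(ga)) as.Date(NA) else delivery - 7L * as.integer(ga)
  list(lmp_date = lmp, delivery_date = delivery,
       ga_weeks = as.integer(ga), ga_imputed = imputed)
}

#' Build the pregnancy-episode table for a full claims stream
#'
#' Runs the complete episode stage on a multi-woman mother claims table:
#' pregnancy-claim extraction, same-day duplicate removal on
#' (woman, date, code), greedy gap-rule grouping, outcome classification,
#' and date/gestational-age estimation.
#'
#' @param claims mother claims with columns `person_id`, `service_date`,
#'   `icd_version`, `code`.
#' @param gap_live,gap_loss,max_span gap-rule day counts; see
#'   [group_into_episodes()].
#' @return data.table with one row per episode: `woman_id`, `episode_id`,
#'   `min_date`, `max_date`, `lmp_date`, `delivery_date`, `ga_weeks`,
#'   `ga_imputed`, `outcome_class`, `multiple_gestation`, `n_claims`.
#' @export
build_episodes <- function(claims, gap_live = 120L, gap_loss = 42L,
                           max_span = 308L) {
  cl <- extract_pregnancy_claims(claims)
  empty <- data.table::data.table(
    woman_id = character(), episode_id = integer(),
    min_date = as.Date(character()), max_date = as.Date(character()),
    lmp_date = as.Date(character()), delivery_date = as.Date(character()),
    ga_weeks = integer(), ga_imputed = logical(),
    outcome_class = character(), multiple_gestation = logical(),
    n_claims = integer())
  if (nrow(cl) == 0L) return(empty)
  cl <- data.table::copy(cl)
  cl[, service_date := as.Date(service_date)]
  cl <- unique(cl, by = c("person_id", "service_date", "code"))
  data.table::setorder(cl, person_id, service_date, code)

  code_norm <- normalize_icd(cl$code, cl$icd_version)
  ev <- classify_outcome_evidence(code_norm, cl$icd_version)
  ot <- .outcome_gap_type[ev]; ot[is.na(ot)] <- 0L
  wid <- match(cl$person_id, unique(cl$person_id))
  cl[, episode_id := group_episodes_cpp(
    wid, as.integer(service_date), as.integer(ot),
    as.integer(gap_live), as.integer(gap_loss), as.integer(max_span))]

  # vectorized per-episode aggregation (GForce): sentinel-coded mins/maxes
  BIG <- .Machine$integer.max
  day <- as.integer(cl$service_date)
  week <- suppressWarnings(gestational_week_from_code(code_norm, cl$icd_version))
  cl[, `:=`(
    day = day,
    wk2 = data.table::fifelse(is.na(week), -1L, as.integer(week)),
    multi = as.integer(startsWith(code_norm, "O30") | startsWith(code_norm, "O31")),
    d_live  = data.table::fifelse(!is.na(ev) & ev == "live_birth", day, BIG),
    d_still = data.table::fifelse(!is.na(ev) & ev == "stillbirth", day, BIG),
    d_spont = data.table::fifelse(!is.na(ev) & ev == "spontaneous_abortion", day, BIG),
    d_ind   = data.table::fifelse(!is.na(ev) & ev == "induced_abortion", day, BIG)
  )]
  ep <- cl[, .(min_day = min(day), max_day = max(day), n_claims = .N,
               n_multi = sum(multi), wmax = max(wk2),
               d_live = min(d_live), d_still = min(d_still),
               d_spont = min(d_spont), d_ind = min(d_ind)),
           by = .(woman_id = person_id, episode_id)]
  ep[, outcome_class := data.table::fcase(
    d_live < BIG, "live_birth",
    d_still < BIG, "stillbirth",
    d_spont < BIG, "spontaneous_abortion",
    d_ind < BIG, "induced_abortion",
    default = "unknown")]
  ep[, delivery_day := data.table::fcase(
    d_live < BIG, d_live, d_still < BIG, d_still,
    d_spont < BIG, d_spont, d_ind < BIG, d_ind, default = max_day)]
  ep[, ga_imputed := wmax < 0L]
  ep[, ga_weeks := data.table::fifelse(
    ga_imputed, .ga_defaults[outcome_class], wmax)]
  out <- ep[, .(
    woman_id, episode_id,
    min_date = as.Date(min_day, origin = "1970-01-01"),
    max_date = as.Date(max_day, origin = "1970-01-01"),
    lmp_date = as.Date(
      data.table::fifelse(is.na(ga_weeks), NA_integer_,
                          delivery_day - 7L * ga_weeks),
      origin = "1970-01-01"),
    delivery_date = as.Date(delivery_day, origin = "1970-01-01"),
    ga_weeks, ga_imputed, outcome_class,
    multiple_gestation = n_multi > 0L, n_claims)]
  data.table::setorder(out, woman_id, episode_id)
  out[]
}
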