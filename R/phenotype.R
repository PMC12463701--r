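# Phenotyping: sleep-disorder exposure (one diagnosis per person),
# maternal outcomes under their ascertainment windows, birth outcomes with
# conflict-to-missing rules, and model covariates.

.maternal_outcomes <- c("cesarean", "gestational_diabetes",
                        "gestational_hypertension", "preeclampsia",
                        "postpartum_depression", "stillbirth")
.birth_axes <- list(
  size_for_ga = c(ref = "AGA", "SGA", "LGA"),
  birthweight = c(ref = "normal", "LBW", "HBW"),
  gestation_period = c(ref = "term", "preterm", "post_term")
)

#' Assign sleep-disorder exposure profiles
#'
#' A woman is exposed if she has at least one claim with a qualifying
#' sleep-disorder or breathing-abnormality code inside her ascertainment
#' window (by default one year either side of her index pregnancy's
#' culmination, matching the enrollment design). ICD-9 claims are converted
#' to ICD-10 first. Each distinct ICD-10 code counts once regardless of how
#' many claims carry it; the diagnosis burden is categorized 0 / 1 / 2+.
#'
#' @param claims mother claims (`person_id`, `service_date`, `icd_version`,
#'   `code`).
#' @param index_episodes one row per woman with `woman_id`,
#'   `delivery_date`.
#' @param pre_days,post_days ascertainment half-windows around the
#'   culmination (`NULL` disables the window and uses the full stream).
#' @return data.table: `woman_id`, `exposed`, `n_diagnoses`, `burden`
#'   ("0"/"1"/"2+"), `n_f51`, `n_g25`, `n_g47`, `n_r06`.
#' @export
assign_exposure <- function(claims, index_episodes,
                            pre_days = 365L, post_days = 365L) {
  ie <- data.table::as.data.table(index_episodes)
  cl <- data.table::as.data.table(claims)
  base <- data.table::data.table(woman_id = ie$woman_id)
  code10 <- normalize_icd(cl$code, cl$icd_version)
  is9 <- cl$icd_version == 9L
  if (any(is9)) code10[is9] <- convert_icd9_sleep(code10[is9])
  fam <- match_code_rules(code10, load_code_maps()$exposure, "family")
  qual <- cl[!is.na(fam), .(person_id, service_date = as.Date(service_date))]
  qual[, `:=`(code10 = code10[!is.na(fam)], family = fam[!is.na(fam)])]
  qual <- qual[ie[, .(person_id = woman_id, delivery_date)],
               on = "person_id", nomatch = NULL]
  if (!is.null(pre_days)) {
    qual <- qual[service_date >= delivery_date - as.integer(pre_days) &
                 service_date <= delivery_date + as.integer(post_days)]
  }
  qual <- unique(qual[, .(person_id, code10, family)])
  prof <- qual[, .(n_diagnoses = .N,
                   n_f51 = sum(family == "F51"), n_g25 = sum(family == "G25"),
                   n_g47 = sum(family == "G47"), n_r06 = sum(family == "R06")),
               by = .(woman_id = person_id)]
  out <- prof[base, on = "woman_id"]
  for (col in c("n_diagnoses", "n_f51", "n_g25", "n_g47", "n_r06")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, exposed := n_diagnoses >= 1L]
  out[, burden := data.table::fcase(n_diagnoses == 0L, "0",
                                    n_diagnoses == 1L, "1",
                                    default = "2+")]
  out[]
}

#' Ascertain the six maternal outcomes for index episodes
#'
#' Ascertainment windows, anchored on the estimated pregnancy dates:
#' cesarean, gestational diabetes and gestational hypertension within
#' `[lmp_date, delivery_date]`; preeclampsia within `[lmp_date,
#' delivery_date + 42d]` (the postpartum preeclampsia window); postpartum
#' depression within `(delivery_date, delivery_date + 365d]` (a
#' delivery-day code counts as in-pregnancy depression, not PPD).
#' Stillbirth comes from the episode outcome class or a Z37.1/P95 claim
#' inside the episode. Cesarean evidence on a linked infant's record
#' (Z38.01) propagates to the mother through the dyad.
#'
#' @param claims mother claims.
#' @param index_episodes one row per woman with `woman_id`, `lmp_date`,
#'   `delivery_date`, `min_date`, `max_date`, `outcome_class`, and
#'   optionally `infant_id`.
#' @param infant_claims infant claims (for Z38.01 propagation); may be NULL.
#' @param ppd_days,pe_extra_days window lengths (365 and 42 by default).
#' @return data.table keyed by `woman_id` with one logical column per
#'   outcome. Women with a missing delivery date get `NA` for all windowed
#'   outcomes.
#' @export
ascertain_maternal_outcomes <- function(claims, index_episodes,
                                        infant_claims = NULL,
                                        ppd_days = 365L, pe_extra_days = 42L) {
  ie <- data.table::as.data.table(index_episodes)
  cl <- data.table::as.data.table(claims)
  out <- data.table::data.table(woman_id = ie$woman_id)
  # outcome codes are ICD-10 only; ICD-9 rows (2015 sleep claims) never match
  lab <- rep(NA_character_, nrow(cl))
  i10 <- cl$icd_version == 10L
  lab[i10] <- classify_maternal_outcome_code(normalize_icd(cl$code[i10], 10L))
  hits <- cl[!is.na(lab), .(person_id, service_date = as.Date(service_date))]
  hits[, outcome := lab[!is.na(lab)]]
  hits <- hits[ie[, .(person_id = woman_id, lmp_date, delivery_date,
                      min_date, max_date)],
               on = "person_id", nomatch = NULL]
  hits[, keep := data.table::fcase(
    outcome %in% c("cesarean", "gestational_diabetes", "gestational_hypertension"),
    !is.na(lmp_date) & service_date >= lmp_date & service_date <= delivery_date,
    outcome == "preeclampsia",
    !is.na(lmp_date) & service_date >= lmp_date &
      service_date <= delivery_date + as.integer(pe_extra_days),
    outcome == "postpartum_depression",
    service_date > delivery_date &
      service_date <= delivery_date + as.integer(ppd_days),
    outcome == "stillbirth",
    service_date >= min_date & service_date <= max_date)]
  pos <- unique(hits[keep == TRUE, .(person_id, outcome)])
  for (oc in .maternal_outcomes) {
    out[, (oc) := woman_id %in% pos[outcome == oc, person_id]]
  }
  # stillbirth agrees with the index episode outcome class
  out[, stillbirth := stillbirth | ie$outcome_class == "stillbirth"]
  # dyad-propagated cesarean evidence from the infant record
  if (!is.null(infant_claims) && "infant_id" %in% names(ie)) {
    inf <- data.table::as.data.table(infant_claims)
    z38 <- unique(inf[normalize_icd(code, icd_version) == "Z38.01", person_id])
    out[, cesarean := cesarean | (!is.na(ie$infant_id) & ie$infant_id %in% z38)]
  }
  # no estimable pregnancy interval -> windowed outcomes unknowable
  miss <- is.na(ie$lmp_date)
  if (any(miss)) {
    for (oc in setdiff(.maternal_outcomes, "stillbirth")) {
      data.table::set(out, which(miss), oc, NA)
    }
  }
  out[]
}

#' Ascertain the three 3-level birth outcomes from infant claims
#'
#' Each axis (newborn size for gestational age, birthweight, gestation
#' period) is set by code evidence: one level present sets that level,
#' absence of any axis code sets the reference level (AGA / normal /
#' term), and a conflicting pair (e.g. both SGA and LGA) forces the axis
#' to missing -- never a silent choice.
#'
#' @param infant_claims claims of the linked infants.
#' @param dyads data.table `woman_id`, `infant_id`.
#' @return data.table: `woman_id`, `infant_id`, `size_for_ga`,
#'   `birthweight`, `gestation_period` (factor-like character columns;
#'   `NA` = missing/conflict).
#' @export
ascertain_birth_outcomes <- function(infant_claims, dyads) {
  dy <- data.table::as.data.table(dyads)[!is.na(infant_id)]
  inf <- data.table::as.data.table(infant_claims)
  out <- data.table::data.table(woman_id = dy$woman_id, infant_id = dy$infant_id)
  bc <- classify_birth_outcome_code(normalize_icd(inf$code, inf$icd_version))
  hits <- unique(data.table::data.table(
    infant_id = inf$person_id, axis = bc$axis, level = bc$level)[!is.na(axis)])
  for (ax in names(.birth_axes)) {
    lv <- .birth_axes[[ax]]
    h <- hits[axis == ax, .(n = data.table::uniqueN(level),
                            level = level[1L]), by = infant_id]
    val <- rep(lv[["ref"]], nrow(out))
    m <- match(out$infant_id, h$infant_id)
    val[!is.na(m) & h$n[m] == 1L] <- h$level[m[!is.na(m) & h$n[m] == 1L]]
    val[!is.na(m) & h$n[m] > 1L] <- NA_character_   # conflicting pair
    out[, (ax) := val]
  }
  out[]
}

#' Derive model covariates for cohort members
#'
#' Maternal age is delivery year minus birth year (year arithmetic only),
#' grouped 18-25 / 26-34 / 35-45; gestational age is grouped <=36 / 37-40 /
#' 41-42 weeks (missing otherwise); the state of residence maps to its US
#' census division; the four insurance attributes pass through.
#'
#' @param enrollment enrollment rows for the mothers.
#' @param index_episodes one row per woman (`woman_id`, `delivery_date`,
#'   `ga_weeks`).
#' @return data.table keyed by `woman_id` with `age`, `age_group`,
#'   `ga_group`, `race_ethnicity`, `division`, `aso`, `cdhp`,
#'   `health_exchange`, `product`.
#' @export
derive_covariates <- function(enrollment, index_episodes) {
  ie <- data.table::as.data.table(index_episodes)
  en <- unique(data.table::as.data.table(enrollment), by = "person_id")
  m <- match(ie$woman_id, en$person_id)
  age <- data.table::year(ie$delivery_date) - as.integer(en$birth_year[m])
  out <- data.table::data.table(
    woman_id = ie$woman_id,
    age = age,
    age_group = data.table::fcase(age >= 18L & age <= 25L, "18-25",
                                  age >= 26L & age <= 34L, "26-34",
                                  age >= 35L & age <= 45L, "35-45",
                                  default = NA_character_),
    ga_group = data.table::fcase(ie$ga_weeks <= 36L, "<=36",
                                 ie$ga_weeks <= 40L, "37-40",
                                 ie$ga_weeks <= 42L, "41-42",
                                 default = NA_character_),
    race_ethnicity = en$race_ethnicity[m],
    division = census_division(en$state[m]),
    aso = en$aso[m],
    cdhp = en$cdhp[m],
    health_exchange = en$health_exchange[m],
    product = en$product[m]
  )
  out[race_ethnicity %in% c("", "missing"), race_ethnicity := NA_character_]
  out[]
}

#' Assemble the person-level analysis table
#'
#' Joins cohort membership, exposure profile, maternal outcome panel,
#' birth outcome panel (for linked dyads) and covariates into the single
#' one-row-per-woman table consumed by the modeling stage.
#'
#' @param cohort output of [build_cohort()].
#' @param claims mother claims.
#' @param infant_claims infant claims.
#' @param enrollment combined enrollment table.
#' @param exposure_pre_days,exposure_post_days exposure window around the
#'   culmination.
#' @return data.table, one row per cohort woman.
#' @export
build_analysis_table <- function(cohort, claims, infant_claims, enrollment,
                                 exposure_pre_days = 365L,
                                 exposure_post_days = 365L) {
  idx <- cohort$members
  expo <- assign_exposure(claims, idx, exposure_pre_days, exposure_post_days)
  mat <- ascertain_maternal_outcomes(claims, idx, infant_claims)
  cov <- derive_covariates(enrollment, idx)
  birth <- ascertain_birth_outcomes(infant_claims,
                                    idx[, .(woman_id, infant_id)])
  en <- data.table::as.data.table(enrollment)
  sx <- if ("sex" %in% names(en)) {
    en[, .(infant_id = person_id, infant_sex = sex)]
  }
  tab <- idx[, .(woman_id, episode_id, outcome_class, delivery_date,
                 lmp_date, ga_weeks, ga_imputed, infant_id,
                 in_maternal_cohort, in_birth_cohort)]
  tab <- expo[tab, on = "woman_id"]
  tab <- mat[tab, on = "woman_id"]
  tab <- cov[tab, on = "woman_id"]
  tab <- birth[, .(woman_id, size_for_ga, birthweight, gestation_period)][
    tab, on = "woman_id"]
  if (!is.null(sx)) {
    tab[, infant_sex := sx$infant_sex[match(tab$infant_id, sx$infant_id)]]
  }
  data.table::setcolorder(tab, "woman_id")
  tab[]
}
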