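# Synthetic mother + infant claims generator. The generator plants known
# exposure prevalence, known conditional odds ratios and known episode
# structure, and returns full ground truth, so that every downstream stage
# (episode grouping, cascade, phenotyping, modeling) can be validated
# end-to-end without access to any real claims data.
#
# Default parameters are a recognizable miniature of a large US
# commercial-claims pregnancy cohort: ~3.4% exposure prevalence with an
# 84/16 one-vs-multiple diagnosis split, unexposed outcome rates around
# 10% (cesarean, gestational diabetes, gestational hypertension), 7%
# (preeclampsia), 2.3% (postpartum depression) and 0.5% (stillbirth), and
# planted adjusted odds ratios between 1.25 and 3.4.

# pool of emittable sleep-disorder codes: ICD-10 form, its unique ICD-9
# preimage in the shipped conversion table, family, and sampling weight
# (weights reproduce the F51/G25/G47/R06 family mix of the diagnosis
# distribution)
.sleep_pool <- data.frame(
  icd10 = c("G47.00", "G47.33", "G47.30", "G47.10", "G47.20", "G47.9",
            "R06.02", "R06.00", "R06.3", "R06.2", "R06.89",
            "F51.01", "F51.02", "F51.9", "G25.81"),
  icd9  = c("780.52", "327.23", "780.57", "780.54", "780.55", "780.50",
            "786.05", "786.00", "786.04", "786.07", "786.09",
            "307.41", "307.42", "307.40", "333.94"),
  family = c(rep("G47", 6), rep("R06", 5), rep("F51", 3), "G25"),
  weight = c(0.20, 0.12, 0.06, 0.05, 0.03, 0.0222,
             0.20, 0.09, 0.04, 0.04, 0.0253,
             0.05, 0.02, 0.0127, 0.0398),
  stringsAsFactors = FALSE
)

.division_state <- c(
  "New England" = "MA", "Middle Atlantic" = "NY",
  "East North Central" = "OH", "West North Central" = "MN",
  "South Atlantic" = "FL", "East South Central" = "TN",
  "West South Central" = "TX", "Mountain" = "AZ", "Pacific" = "CA")

#' Build a simulation configuration
#'
#' All probabilities, rates and planted effects of the synthetic-claims
#' generator, with defaults that mirror the study conditions the package
#' is designed around: exposure prevalence 3.41% with one diagnosis for
#' 84.45% of the exposed, unexposed maternal/birth outcome rates from the
#' observed unexposed columns, and planted exposure log-odds equal to the
#' log of the adjusted odds ratios (cesarean 1.44, gestational diabetes
#' 1.61, gestational hypertension 1.60, preeclampsia 1.70, postpartum
#' depression 3.37, stillbirth 2.14; SGA 1.40, LGA 1.33, LBW 1.42, HBW
#' 1.25, preterm 1.51, post-term 0.87). Covariate effects are modest
#' (|log OR| <= 0.3) so exposure effects dominate.
#'
#' @param n_women number of women to simulate.
#' @param seed integer seed; the generator is fully deterministic given
#'   (config, seed), and each woman consumes a fixed block of the random
#'   stream so per-woman data are stable under `n_women` changes.
#' @param exposure_prevalence probability a woman carries any qualifying
#'   diagnosis.
#' @param burden_split probability of exactly one diagnosis, given exposed
#'   (the remainder is 2+).
#' @param baseline_outcome_rates named unexposed (reference-covariate)
#'   rates for the six maternal outcomes.
#' @param planted_log_odds named exposure log-odds for the six maternal
#'   outcomes.
#' @param birth_baseline_rates,birth_planted_log_odds per-axis baseline
#'   rates / exposure log-odds for the non-reference birth-outcome levels.
#' @param covariate_log_odds named list of per-level covariate effects
#'   shared across outcomes.
#' @param date_window calendar claim window.
#' @param culmination_window eligible culmination window (needs >= 365d of
#'   margin inside `date_window` on both sides).
#' @param episode_count_probs probabilities of 1, 2, 3 pregnancy episodes.
#' @param episode_separation_days minimum distance between consecutive
#'   deliveries of one woman.
#' @param multi_diag_split conditional distribution of 2..8 diagnoses
#'   given 2+.
#' @param unlinked_rate probability a live-birth mother has no infant
#'   records (fails family-ID linkage).
#' @param enrollment_gap_rate probability a woman's coverage has a 30-day
#'   hole near her index delivery (default 0: clean data; use
#'   [inject_pathologies()] for controlled anomalies).
#' @param class_probs episode-outcome distribution conditional on no
#'   stillbirth (live birth, spontaneous abortion, induced abortion,
#'   unknown).
#' @param exposure_claim_window days before/after the index culmination
#'   within which exposure claims are dated (matches the exposure
#'   ascertainment window so planted prevalence is the measured
#'   prevalence).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    n_women = 5000L,
    seed = 1L,
    exposure_prevalence = 0.0341,
    burden_split = c(one = 0.8445, two_plus = 0.1555),
    baseline_outcome_rates = c(
      cesarean = 0.0993, gestational_diabetes = 0.0964,
      gestational_hypertension = 0.1064, preeclampsia = 0.0716,
      postpartum_depression = 0.0234, stillbirth = 0.0051),
    planted_log_odds = log(c(
      cesarean = 1.44, gestational_diabetes = 1.61,
      gestational_hypertension = 1.60, preeclampsia = 1.70,
      postpartum_depression = 3.37, stillbirth = 2.14)),
    birth_baseline_rates = list(
      size_for_ga = c(SGA = 0.0306, LGA = 0.0069),
      birthweight = c(LBW = 0.0364, HBW = 0.0626),
      gestation_period = c(preterm = 0.0737, post_term = 0.0530)),
    birth_planted_log_odds = list(
      size_for_ga = c(SGA = log(1.40), LGA = log(1.33)),
      birthweight = c(LBW = log(1.42), HBW = log(1.25)),
      gestation_period = c(preterm = log(1.51), post_term = log(0.87))),
    covariate_log_odds = list(
      age_group = c("18-25" = 0.10, "35-45" = 0.15),
      race_ethnicity = c(Asian = -0.10, Black = 0.20, Hispanic = 0.10),
      division = c("East South Central" = 0.10, "Pacific" = -0.05),
      aso = c(yes = -0.05),
      cdhp = c(HRA = 0.05, HSA = -0.05),
      health_exchange = c(yes = 0.10),
      product = c(EPO = 0.05, HMO = 0.05, Other = 0.10, PPO = 0.00),
      infant_sex = c(M = 0.10),
      complications = c(gestational_diabetes = 0.25,
                        gestational_hypertension = 0.20,
                        preeclampsia = 0.30, cesarean = 0.15)),
    covariate_distributions = list(
      age_group = c("18-25" = 0.1889, "26-34" = 0.6068, "35-45" = 0.2043),
      race_ethnicity = c(Asian = 0.0662, Black = 0.1040, Hispanic = 0.1413,
                         White = 0.5236, missing = 0.1649),
      division = c("New England" = 0.0197, "Middle Atlantic" = 0.0572,
                   "East North Central" = 0.1334, "West North Central" = 0.0951,
                   "South Atlantic" = 0.2272, "East South Central" = 0.0513,
                   "West South Central" = 0.2121, "Mountain" = 0.1081,
                   "Pacific" = 0.0923, missing = 0.0036),
      aso_yes = 0.3089,
      cdhp = c(HRA = 0.0317, HSA = 0.2210, none = 0.7473),
      exchange_yes = 0.0772,
      product = c(EPO = 0.1282, HMO = 0.1537, Other = 0.0061,
                  POS = 0.7032, PPO = 0.0088)),
    date_window = as.Date(c("2015-01-01", "2021-06-30")),
    culmination_window = as.Date(c("2016-01-01", "2020-06-30")),
    episode_count_probs = c(0.80, 0.17, 0.03),
    episode_separation_days = 700L,
    multi_diag_split = c(`2` = 356, `3` = 84, `4` = 30, `5` = 18,
                         `6` = 5, `7` = 3, `8` = 2) / 498,
    unlinked_rate = 0.177,
    enrollment_gap_rate = 0,
    class_probs = c(live_birth = 0.930, spontaneous_abortion = 0.048,
                    induced_abortion = 0.020, unknown = 0.002),
    exposure_claim_window = c(pre = 365L, post = 365L),
    icd10_transition = as.Date("2015-10-01")) {
  cfg <- list(
    n_women = as.integer(n_women), seed = as.integer(seed),
    exposure_prevalence = exposure_prevalence, burden_split = burden_split,
    baseline_outcome_rates = baseline_outcome_rates,
    planted_log_odds = planted_log_odds,
    birth_baseline_rates = birth_baseline_rates,
    birth_planted_log_odds = birth_planted_log_odds,
    covariate_log_odds = covariate_log_odds,
    covariate_distributions = covariate_distributions,
    date_window = as.Date(date_window),
    culmination_window = as.Date(culmination_window),
    episode_count_probs = episode_count_probs,
    episode_separation_days = as.integer(episode_separation_days),
    multi_diag_split = multi_diag_split,
    unlinked_rate = unlinked_rate,
    enrollment_gap_rate = enrollment_gap_rate,
    class_probs = class_probs,
    exposure_claim_window = exposure_claim_window,
    icd10_transition = as.Date(icd10_transition))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pr <- c(cfg$exposure_prevalence, cfg$burden_split, cfg$episode_count_probs,
          cfg$multi_diag_split, cfg$unlinked_rate, cfg$enrollment_gap_rate,
          cfg$class_probs, unlist(cfg$baseline_outcome_rates),
          unlist(cfg$birth_baseline_rates),
          unlist(cfg$covariate_distributions))
  if (any(pr < 0 | pr > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$burden_split) - 1) > 1e-8) stop("burden_split must sum to 1")
  if (abs(sum(cfg$class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (cfg$n_women < 1L) stop("n_women must be positive")
  if (as.numeric(diff(cfg$date_window)) < 730) {
    stop("date_window must span at least 2 years")
  }
  if (cfg$culmination_window[1] - cfg$date_window[1] < 365 ||
      cfg$date_window[2] - cfg$culmination_window[2] < 365) {
    stop("culmination_window needs >= 365 days of margin inside date_window")
  }
  len <- as.integer(diff(cfg$culmination_window))
  kmax <- max(which(cfg$episode_count_probs > 0))
  if (len - (kmax - 1L) * cfg$episode_separation_days <= 0L) {
    stop("infeasible config: ", kmax,
         " episodes cannot fit in the culmination window")
  }
  invisible(cfg)
}

# categorical inverse-CDF draw: u in [0,1) -> 1-based level index
.cat_draw <- function(u, probs) {
  cuts <- cumsum(probs)
  pmin(findInterval(u, cuts) + 1L, length(probs))
}

# truncated-normal inverse-CDF draw
.tnorm_draw <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

# per-woman covariate contribution to every outcome's linear predictor
.cov_eta <- function(eff, level_vec, var) {
  e <- eff[[var]]
  out <- numeric(length(level_vec))
  hit <- !is.na(level_vec) & level_vec %in% names(e)
  out[hit] <- e[level_vec[hit]]
  out
}

#' Generate a synthetic claims population with ground truth
#'
#' Emits the enrollment table (mothers and infants), mother claims, infant
#' claims, and a ground-truth object. Per woman: 1-3 pregnancy episodes
#' with deliveries separated by at least the configured distance, prenatal
#' supervision and weeks-of-gestation claims, an outcome record per
#' known-outcome episode, exposure claims at the configured prevalence
#' (ICD-9-coded before the October 2015 transition), maternal-outcome
#' claims drawn from a logistic model with the planted exposure effects,
#' and, for linked live births, a family-linked infant claim stream with
#' birth-outcome codes drawn from baseline-category multinomial models.
#'
#' @param config a [sim_config()].
#' @return List `enrollment`, `mother_claims`, `infant_claims`, `truth`
#'   (list of `women`, `episodes`, `params`, `pathologies`), `config`.
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  n <- config$n_women
  set.seed(config$seed)
  U <- matrix(runif(n * 64L), nrow = n, ncol = 64L, byrow = TRUE)
  cd <- config$covariate_distributions
  eff <- config$covariate_log_odds

  woman_id <- sprintf("W%07d", seq_len(n))
  family_id <- sprintf("F%07d", seq_len(n))

  ## covariates -------------------------------------------------------------
  ag_lv <- names(cd$age_group)
  ag_i <- .cat_draw(U[, 1], cd$age_group)
  lo <- c(18L, 26L, 35L)[ag_i]; hi <- c(25L, 34L, 45L)[ag_i]
  age0 <- lo + pmin(as.integer(floor(U[, 2] * (hi - lo + 1L))), hi - lo)
  race <- names(cd$race_ethnicity)[.cat_draw(U[, 3], cd$race_ethnicity)]
  div <- names(cd$division)[.cat_draw(U[, 4], cd$division)]
  state <- ifelse(div == "missing", "", .division_state[div])
  aso <- ifelse(U[, 5] < cd$aso_yes, "yes", "no")
  cdhp <- names(cd$cdhp)[.cat_draw(U[, 6], cd$cdhp)]
  exch <- ifelse(U[, 7] < cd$exchange_yes, "yes", "no")
  product <- names(cd$product)[.cat_draw(U[, 8], cd$product)]

  age_group0 <- ag_lv[ag_i]
  eta_cov <- .cov_eta(eff, age_group0, "age_group") +
    .cov_eta(eff, ifelse(race == "missing", NA, race), "race_ethnicity") +
    .cov_eta(eff, ifelse(div == "missing", NA, div), "division") +
    .cov_eta(eff, aso, "aso") + .cov_eta(eff, cdhp, "cdhp") +
    .cov_eta(eff, exch, "health_exchange") + .cov_eta(eff, product, "product")

  ## exposure and maternal outcomes -----------------------------------------
  exposed <- U[, 19] < config$exposure_prevalence
  rates <- config$baseline_outcome_rates
  plant <- config$planted_log_odds
  ocols <- c(stillbirth = 10L, cesarean = 11L, gestational_diabetes = 12L,
             gestational_hypertension = 13L, preeclampsia = 14L,
             postpartum_depression = 15L)
  oind <- sapply(names(ocols), function(o) {
    eta <- qlogis(rates[[o]]) + plant[[o]] * exposed + eta_cov
    U[, ocols[[o]]] < plogis(eta)
  })
  S <- oind[, "stillbirth"]

  ## episodes ---------------------------------------------------------------
  k <- .cat_draw(U[, 9], config$episode_count_probs)
  sep <- config$episode_separation_days
  cw0 <- as.integer(config$culmination_window[1])
  cw1 <- as.integer(config$culmination_window[2])
  ep <- data.table::data.table(w = rep(seq_len(n), k))
  ep[, slot := seq_len(.N), by = w]
  ep[, u_del := U[cbind(w, 40L + slot)]]
  data.table::setorder(ep, w, u_del)
  ep[, j := seq_len(.N), by = w]
  ep[, kk := k[w]]
  ep[, d := cw0 + as.integer(floor(u_del * (cw1 - cw0 - (kk - 1L) * sep + 1L))) +
       (j - 1L) * sep]
  # episode outcome classes; stillbirth mothers: the last (index) episode is
  # the stillbirth, earlier ones are losses or unknowns, never live births
  ep[, u_cls := U[cbind(w, 46L + j)]]
  ep[, Sw := S[w]]
  cls_no_s <- names(config$class_probs)[.cat_draw(ep$u_cls, config$class_probs)]
  cls_s <- ifelse(ep$j == ep$kk, "stillbirth",
                  ifelse(ep$u_cls < 0.9, "spontaneous_abortion", "unknown"))
  ep[, class := ifelse(Sw, cls_s, cls_no_s)]
  ep[, u_ga := U[cbind(w, 43L + j)]]
  ep[, ga := data.table::fcase(
    class == "live_birth",
    as.integer(round(.tnorm_draw(u_ga, 38.4, 2.14, 27.5, 42.49))),
    class == "stillbirth",
    as.integer(round(.tnorm_draw(u_ga, 30, 4, 21.5, 40.49))),
    class %in% c("spontaneous_abortion", "induced_abortion"),
    8L + as.integer(floor(u_ga * 7)),
    default = NA_integer_)]
  ep[, lmp := data.table::fifelse(is.na(ga), NA_integer_, d - 7L * ga)]

  ## index selection (same hierarchy + eligibility rules as the pipeline) ---
  birth_year <- integer(n)
  d_first <- ep[j == 1L, d]
  birth_year <- data.table::year(as.Date(d_first, origin = "1970-01-01")) - age0
  ep[, by_w := birth_year[w]]
  ep[, culm := data.table::fifelse(class == "unknown", d - 70L, d)]
  ep[, age_ep := data.table::year(as.Date(d, origin = "1970-01-01")) - by_w]
  ep[, elig := culm >= cw0 & culm <= cw1 & age_ep >= 18L & age_ep <= 45L &
       class != "induced_abortion"]
  prio <- c(live_birth = 1L, stillbirth = 2L, spontaneous_abortion = 3L,
            unknown = 4L)
  ep[, pr := prio[class]]
  cand <- ep[elig == TRUE]
  data.table::setorder(cand, w, pr, d)
  idx <- unique(cand, by = "w")
  ep[, is_index := FALSE]
  ep[idx[, .(w, j)], on = c("w", "j"), is_index := TRUE]

  has_index <- seq_len(n) %in% idx$w
  d_index <- rep(NA_integer_, n); d_index[idx$w] <- idx$d
  ga_index <- rep(NA_integer_, n); ga_index[idx$w] <- idx$ga
  lmp_index <- rep(NA_integer_, n); lmp_index[idx$w] <- idx$lmp
  cls_index <- rep(NA_character_, n); cls_index[idx$w] <- idx$class
  # anchor for exposure/noise claims: index delivery, else latest delivery
  d_anchor <- ep[, .(d = max(d)), by = w][order(w), d]
  d_anchor[has_index] <- d_index[has_index]

  ## birth outcomes for index live births -----------------------------------
  sexM <- U[, 37] < 0.512
  linked <- has_index & cls_index == "live_birth" & U[, 38] >= config$unlinked_rate
  linked[is.na(linked)] <- FALSE
  eta_birth <- eta_cov + .cov_eta(eff, ifelse(sexM, "M", "F"), "infant_sex")
  comp_eff <- eff$complications
  for (cp in names(comp_eff)) eta_birth <- eta_birth + comp_eff[[cp]] * oind[, cp]
  axis_u <- c(size_for_ga = 16L, birthweight = 17L, gestation_period = 18L)
  birth_lv <- list()
  for (ax in names(axis_u)) {
    base <- config$birth_baseline_rates[[ax]]
    bpl <- config$birth_planted_log_odds[[ax]]
    ref_p <- 1 - sum(base)
    e1 <- log(base[[1]] / ref_p) + bpl[[1]] * exposed + eta_birth
    e2 <- log(base[[2]] / ref_p) + bpl[[2]] * exposed + eta_birth
    den <- 1 + exp(e1) + exp(e2)
    p1 <- exp(e1) / den; p2 <- exp(e2) / den
    uu <- U[, axis_u[[ax]]]
    lvl <- ifelse(uu < p1, names(base)[1],
                  ifelse(uu < p1 + p2, names(base)[2], "ref"))
    refname <- c(size_for_ga = "AGA", birthweight = "normal",
                 gestation_period = "term")[[ax]]
    lvl[lvl == "ref"] <- refname
    birth_lv[[ax]] <- lvl
  }

  ## exposure diagnosis sets -------------------------------------------------
  n_diag <- integer(n)
  if (any(exposed)) {
    p1 <- config$burden_split[["one"]]
    u20 <- U[, 20]
    nd <- ifelse(u20 < p1, 1L,
                 1L + .cat_draw(pmin((u20 - p1) / (1 - p1), 1 - 1e-12),
                                config$multi_diag_split))
    n_diag[exposed] <- nd[exposed]
  }
  pool <- .sleep_pool
  exp_rows <- which(exposed)
  code_pick <- matrix(NA_integer_, n, 8L)
  if (length(exp_rows)) {
    keys <- -log(U[exp_rows, 21:35, drop = FALSE]) /
      matrix(pool$weight, length(exp_rows), 15L, byrow = TRUE)
    ord <- apply(keys, 1L, order)   # 15 x n_exposed
    for (i in seq_along(exp_rows)) {
      code_pick[exp_rows[i], seq_len(n_diag[exp_rows[i]])] <-
        ord[seq_len(n_diag[exp_rows[i]]), i]
    }
  }

  ## claims emission ---------------------------------------------------------
  D <- function(x) as.Date(x, origin = "1970-01-01")
  pieces <- list()
  add <- function(w_idx, day, code, version = 10L, ep_j = NA_integer_) {
    data.table::data.table(w = w_idx, day = as.integer(day),
                           code = code, icd_version = as.integer(version),
                           ep = ep_j)
  }
  known <- ep$class != "unknown"
  # prenatal supervision + weeks-of-gestation claims
  pieces$z34 <- add(ep$w, ifelse(known, ep$lmp + 56L, ep$d - 154L),
                    "Z34.91", 10L, ep$j)
  pieces$z3a <- add(ep$w, ifelse(known, ep$d, ep$d - 70L),
                    ifelse(known, sprintf("Z3A.%02d", ep$ga), "Z3A.20"),
                    10L, ep$j)
  # outcome records
  lv <- ep[class == "live_birth"]
  ces_w <- oind[, "cesarean"]
  pieces$lv1 <- add(lv$w, lv$d,
                    ifelse(lv$is_index & ces_w[lv$w], "O82", "O80"), 10L, lv$j)
  pieces$lv2 <- add(lv$w, lv$d, "Z37.0", 10L, lv$j)
  sb <- ep[class == "stillbirth"]
  pieces$sb <- add(sb$w, sb$d, "Z37.1", 10L, sb$j)
  sp <- ep[class == "spontaneous_abortion"]
  pieces$sp <- add(sp$w, sp$d, "O03.9", 10L, sp$j)
  ia <- ep[class == "induced_abortion"]
  pieces$ia <- add(ia$w, ia$d, "O04.89", 10L, ia$j)
  # maternal-outcome claims, anchored on the index episode
  ix <- ep[is_index == TRUE & class != "unknown"]
  span <- ix$d - ix$lmp
  emit_out <- function(name, frac, code) {
    rows <- ix[oind[ix$w, name]]
    if (nrow(rows) == 0L) return(NULL)
    add(rows$w, rows$lmp + as.integer(round(frac * (rows$d - rows$lmp))),
        code, 10L, rows$j)
  }
  pieces$gdm <- emit_out("gestational_diabetes", 0.75, "O24.410")
  pieces$ghtn <- emit_out("gestational_hypertension", 0.85, "O13.3")
  pieces$pe <- emit_out("preeclampsia", 0.92, "O14.93")
  ppd_rows <- ix[oind[ix$w, "postpartum_depression"]]
  if (nrow(ppd_rows)) {
    pieces$ppd <- add(ppd_rows$w, ppd_rows$d + 90L, "F53.0", 10L, NA_integer_)
  }
  ces_nl <- ix[class != "live_birth" & ces_w[w]]
  if (nrow(ces_nl)) {
    pieces$cesx <- add(ces_nl$w, ces_nl$d, "O75.82", 10L, ces_nl$j)
  }
  # exposure claims (duplicate claim of the first code exercises the
  # one-diagnosis-per-person rule)
  if (length(exp_rows)) {
    pre <- config$exposure_claim_window[["pre"]]
    post <- config$exposure_claim_window[["post"]]
    ec <- list()
    for (s in 1:8) {
      rows <- exp_rows[n_diag[exp_rows] >= s]
      if (!length(rows)) break
      day <- d_anchor[rows] +
        as.integer(floor(U[rows, 56L + s] * (pre + post + 1L))) - pre
      ec[[s]] <- data.table::data.table(w = rows, day = day,
                                        pick = code_pick[rows, s])
    }
    dup_rows <- exp_rows
    ec[[9]] <- data.table::data.table(
      w = dup_rows,
      day = d_anchor[dup_rows] +
        as.integer(floor(U[dup_rows, 36L] * (pre + post + 1L))) - pre,
      pick = code_pick[dup_rows, 1L])
    ecl <- data.table::rbindlist(ec)
    is9 <- ecl$day < as.integer(config$icd10_transition)
    pieces$expo <- data.table::data.table(
      w = ecl$w, day = ecl$day,
      code = ifelse(is9, pool$icd9[ecl$pick], pool$icd10[ecl$pick]),
      icd_version = ifelse(is9, 9L, 10L), ep = NA_integer_)
  }
  # non-obstetric noise claims
  noise_pool <- c("J06.9", "M54.5", "K21.9")
  n_noise <- pmin(as.integer(floor(U[, 50] * 3)), 2L)
  for (s in 1:2) {
    rows <- which(n_noise >= s)
    if (!length(rows)) next
    pieces[[paste0("noise", s)]] <- add(
      rows, d_anchor[rows] + as.integer(floor(U[rows, 53L + s] * 731L)) - 365L,
      noise_pool[.cat_draw(U[rows, 50L + s], rep(1 / 3, 3))], 10L, NA_integer_)
  }

  mcl <- data.table::rbindlist(pieces, use.names = TRUE)
  mother_claims <- data.table::data.table(
    person_id = woman_id[mcl$w], family_id = family_id[mcl$w],
    service_date = D(mcl$day), icd_version = mcl$icd_version,
    code = mcl$code, record_type = "mother")
  # ground-truth episode intervals from the emitted pregnancy-related claims
  preg <- is_pregnancy_code(mcl$code, mcl$icd_version)
  tep <- mcl[preg & !is.na(ep), .(first_claim = min(day),
                                  last_claim = max(day)),
             by = .(w, ep)]
  tep[, `:=`(first_claim = D(first_claim), last_claim = D(last_claim))]
  ep_info <- ep[, .(w, ep = j, class, delivery = D(d),
                    lmp = D(lmp), ga, is_index)]
  truth_episodes <- tep[ep_info, on = c("w", "ep")]
  truth_episodes[, `:=`(woman_id = woman_id[w], w = NULL)]
  data.table::setcolorder(truth_episodes, "woman_id")
  data.table::setorder(truth_episodes, woman_id, ep)

  ## infants ------------------------------------------------------------------
  inf_rows <- which(linked)
  infant_claims <- data.table::data.table(
    person_id = character(), family_id = character(),
    service_date = as.Date(character()), icd_version = integer(),
    code = character(), record_type = character())
  infant_enroll <- NULL
  if (length(inf_rows)) {
    infant_id_all <- rep(NA_character_, n)
    infant_id_all[inf_rows] <- sprintf("I%07d", inf_rows)
    icl <- list()
    icl$z38 <- data.table::data.table(
      w = inf_rows, day = d_index[inf_rows],
      code = ifelse(ces_w[inf_rows], "Z38.01", "Z38.00"))
    lvmap <- list(
      size_for_ga = c(SGA = "P05.19", LGA = "P08.0"),
      birthweight = c(LBW = "P07.14", HBW = "P08.1"),
      gestation_period = c(preterm = "P07.36", post_term = "P08.21"))
    for (ax in names(lvmap)) {
      lvv <- birth_lv[[ax]][inf_rows]
      hit <- lvv %in% names(lvmap[[ax]])
      if (any(hit)) {
        icl[[ax]] <- data.table::data.table(
          w = inf_rows[hit], day = d_index[inf_rows[hit]] + 1L,
          code = unname(lvmap[[ax]][lvv[hit]]))
      }
    }
    icld <- data.table::rbindlist(icl)
    infant_claims <- data.table::data.table(
      person_id = infant_id_all[icld$w], family_id = family_id[icld$w],
      service_date = D(icld$day), icd_version = 10L,
      code = icld$code, record_type = "infant")
    infant_enroll <- data.table::data.table(
      person_id = infant_id_all[inf_rows], family_id = family_id[inf_rows],
      span_start = D(d_index[inf_rows]), span_end = D(d_index[inf_rows] + 420L),
      birth_year = data.table::year(D(d_index[inf_rows])),
      sex = ifelse(sexM[inf_rows], "M", "F"),
      race_ethnicity = "missing", state = state[inf_rows],
      aso = aso[inf_rows], cdhp = cdhp[inf_rows],
      health_exchange = exch[inf_rows], product = product[inf_rows])
  } else {
    infant_id_all <- rep(NA_character_, n)
  }

  ## enrollment ---------------------------------------------------------------
  claim_rng <- mcl[, .(dmin = min(day), dmax = max(day)), by = w][order(w)]
  dmin <- rep(NA_integer_, n); dmax <- rep(NA_integer_, n)
  dmin[claim_rng$w] <- claim_rng$dmin; dmax[claim_rng$w] <- claim_rng$dmax
  ep_rng <- ep[, .(dlo = min(d), dhi = max(d)), by = w][order(w)]
  span_start <- pmin(dmin, ep_rng$dlo - 380L, na.rm = TRUE) - 30L
  span_end <- pmax(dmax, ep_rng$dhi + 380L, na.rm = TRUE) + 30L
  gap <- U[, 39] < config$enrollment_gap_rate
  gs <- d_anchor - 200L + as.integer(floor(U[, 40] * 400L))
  m_en <- list(
    data.table::data.table(
      person_id = woman_id[!gap], family_id = family_id[!gap],
      span_start = D(span_start[!gap]), span_end = D(span_end[!gap])),
    data.table::data.table(
      person_id = rep(woman_id[gap], 2L),
      family_id = rep(family_id[gap], 2L),
      span_start = D(c(span_start[gap], gs[gap] + 30L)),
      span_end = D(c(gs[gap] - 1L, span_end[gap]))))
  mother_enroll <- data.table::rbindlist(m_en)
  mother_enroll[, `:=`(
    birth_year = birth_year[match(person_id, woman_id)],
    sex = "F",
    race_ethnicity = race[match(person_id, woman_id)],
    state = state[match(person_id, woman_id)],
    aso = aso[match(person_id, woman_id)],
    cdhp = cdhp[match(person_id, woman_id)],
    health_exchange = exch[match(person_id, woman_id)],
    product = product[match(person_id, woman_id)])]
  enrollment <- data.table::rbindlist(
    c(list(mother_enroll), if (!is.null(infant_enroll)) list(infant_enroll)),
    use.names = TRUE)
  data.table::setorder(enrollment, person_id, span_start)
  data.table::setorder(mother_claims, person_id, service_date, code)
  if (nrow(infant_claims)) {
    data.table::setorder(infant_claims, person_id, service_date, code)
  }

  truth_women <- data.table::data.table(
    woman_id = woman_id, family_id = family_id,
    exposed = exposed, n_diagnoses = n_diag,
    burden = data.table::fcase(n_diag == 0L, "0", n_diag == 1L, "1",
                               default = "2+"),
    age_first = age0, birth_year = birth_year,
    race_ethnicity = race, division = div, state = state,
    aso = aso, cdhp = cdhp, health_exchange = exch, product = product,
    cesarean = oind[, "cesarean"],
    gestational_diabetes = oind[, "gestational_diabetes"],
    gestational_hypertension = oind[, "gestational_hypertension"],
    preeclampsia = oind[, "preeclampsia"],
    postpartum_depression = oind[, "postpartum_depression"],
    stillbirth = S,
    has_index = has_index, index_class = cls_index,
    index_delivery = D(d_index), index_lmp = D(lmp_index),
    index_ga = ga_index,
    size_for_ga = birth_lv$size_for_ga,
    birthweight = birth_lv$birthweight,
    gestation_period = birth_lv$gestation_period,
    infant_sex = ifelse(sexM, "M", "F"),
    linked = linked, infant_id = infant_id_all,
    enrollment_gap = gap)

  list(
    enrollment = enrollment,
    mother_claims = mother_claims,
    infant_claims = infant_claims,
    truth = list(
      women = truth_women,
      episodes = truth_episodes,
      params = list(planted_log_odds = config$planted_log_odds,
                    birth_planted_log_odds = config$birth_planted_log_odds,
                    exposure_prevalence = config$exposure_prevalence),
      pathologies = data.table::data.table(woman_id = character(),
                                           type = character())),
    config = config)
}

#' Inject controlled data pathologies into a synthetic population
#'
#' Perturbs the emitted tables with anomalies that exercise the pipeline's
#' edge rules, each tagged in the ground truth: `enrollment_gap` (a 30-day
#' coverage hole straddling the index delivery), `twin_codes` (an O30
#' multiple-gestation claim inside the index episode), `sga_lga_conflict`
#' (both SGA and LGA codes on a linked infant), `duplicate_claims` (exact
#' duplicate claim rows), and `extra_episode` (an additional spontaneous-
#' abortion episode 800 days before the index delivery). Target women are
#' chosen deterministically: the first `n` women (in id order) satisfying
#' the pathology's precondition and not already tagged.
#'
#' @param population output of [generate_population()].
#' @param spec named integer vector/list, e.g.
#'   `c(twin_codes = 5, sga_lga_conflict = 2)`.
#' @return The population with perturbed tables and updated
#'   `truth$pathologies`.
#' @export
inject_pathologies <- function(population, spec) {
  pop <- population
  tw <- pop$truth$women
  known <- c("enrollment_gap", "twin_codes", "sga_lga_conflict",
             "duplicate_claims", "extra_episode")
  if (is.null(names(spec)) || !all(names(spec) %in% known)) {
    stop("unknown pathology name; known: ", paste(known, collapse = ", "))
  }
  tagged <- function() pop$truth$pathologies$woman_id
  pick <- function(ok, n) {
    ids <- tw$woman_id[ok & !(tw$woman_id %in% tagged())]
    if (length(ids) < n) stop("not enough eligible women for pathology")
    sort(ids)[seq_len(n)]
  }
  tag <- function(ids, type) {
    pop$truth$pathologies <<- rbind(
      pop$truth$pathologies,
      data.table::data.table(woman_id = ids, type = type))
  }
  claim_row <- function(ids, day_off, code, version = 10L) {
    m <- match(ids, tw$woman_id)
    data.table::data.table(
      person_id = ids, family_id = tw$family_id[m],
      service_date = tw$index_delivery[m] + day_off,
      icd_version = as.integer(version), code = code,
      record_type = "mother")
  }
  for (nm in names(spec)) {
    n_inj <- as.integer(spec[[nm]])
    if (n_inj <= 0L) next
    if (nm == "enrollment_gap") {
      n_ep <- pop$truth$episodes[, .N, by = woman_id]
      single <- tw$woman_id %in% n_ep[N == 1L, woman_id]
      ids <- pick(tw$has_index & single & !tw$enrollment_gap, n_inj)
      en <- pop$enrollment
      for (id in ids) {
        i <- which(en$person_id == id)[1L]
        d <- tw$index_delivery[match(id, tw$woman_id)]
        row <- en[i]
        hole0 <- d - 100L
        en <- rbind(en[-i],
                    data.table::data.table(row[, .(person_id, family_id)],
                      span_start = row$span_start, span_end = hole0 - 1L,
                      row[, .(birth_year, sex, race_ethnicity, state, aso,
                              cdhp, health_exchange, product)]),
                    data.table::data.table(row[, .(person_id, family_id)],
                      span_start = hole0 + 30L, span_end = row$span_end,
                      row[, .(birth_year, sex, race_ethnicity, state, aso,
                              cdhp, health_exchange, product)]),
                    use.names = TRUE)
      }
      data.table::setorder(en, person_id, span_start)
      pop$enrollment <- en
      tag(ids, nm)
    } else if (nm == "twin_codes") {
      n_ep <- pop$truth$episodes[, .N, by = woman_id]
      single <- tw$woman_id %in% n_ep[N == 1L, woman_id]
      ids <- pick(tw$has_index & tw$index_class == "live_birth" & single &
                    !is.na(tw$index_ga) & tw$index_ga >= 28L, n_inj)
      pop$mother_claims <- rbind(pop$mother_claims,
                                 claim_row(ids, -100L, "O30.002"))
      tag(ids, nm)
    } else if (nm == "sga_lga_conflict") {
      ids <- pick(tw$linked, n_inj)
      m <- match(ids, tw$woman_id)
      extra <- data.table::data.table(
        person_id = tw$infant_id[m], family_id = tw$family_id[m],
        service_date = rep(tw$index_delivery[m] + 1L, 2L),
        icd_version = 10L,
        code = rep(c("P05.19", "P08.0"), each = length(ids)),
        record_type = "infant")
      pop$infant_claims <- rbind(pop$infant_claims, extra)
      tag(ids, nm)
    } else if (nm == "duplicate_claims") {
      ids <- pick(rep(TRUE, nrow(tw)), n_inj)
      pop$mother_claims <- rbind(pop$mother_claims,
                                 pop$mother_claims[person_id %in% ids])
      tag(ids, nm)
    } else if (nm == "extra_episode") {
      cw0 <- as.integer(pop$config$culmination_window[1])
      ids <- pick(tw$has_index &
                    as.integer(tw$index_delivery) - 800L >= cw0, n_inj)
      pop$mother_claims <- rbind(pop$mother_claims,
                                 claim_row(ids, -856L, "Z34.91"),
                                 claim_row(ids, -800L, "O03.9"))
      tag(ids, nm)
    }
  }
  data.table::setorder(pop$mother_claims, person_id, service_date, code)
  if (nrow(pop$infant_claims)) {
    data.table::setorder(pop$infant_claims, person_id, service_date, code)
  }
  pop
}
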