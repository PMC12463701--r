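mk_index <- function(delivery = "2018-06-01", ga = 39L,
                     outcome = "live_birth", infant = NA_character_) {
  delivery <- as.Date(delivery)
  data.table::data.table(
    woman_id = "W1", episode_id = 1L,
    min_date = delivery - 7L * ga + 56L, max_date = delivery,
    lmp_date = delivery - 7L * ga, delivery_date = delivery,
    ga_weeks = ga, ga_imputed = FALSE, outcome_class = outcome,
    multiple_gestation = FALSE, infant_id = infant)
}

test_that("one diagnosis per person regardless of claim multiplicity", {
  idx <- mk_index()
  cl <- make_claims(as.Date("2018-03-01") + (0:4) * 10, rep("G47.00", 5))
  prof <- assign_exposure(cl, idx)
  expect_true(prof$exposed)
  expect_equal(prof$n_diagnoses, 1L)
  expect_equal(prof$burden, "1")
  # two distinct codes -> burden 2+
  cl2 <- make_claims(c("2018-03-01", "2018-03-02"), c("G47.00", "R06.02"))
  prof2 <- assign_exposure(cl2, idx)
  expect_equal(prof2$burden, "2+")
  expect_equal(prof2$n_g47, 1L)
  expect_equal(prof2$n_r06, 1L)
  # no qualifying claims -> unexposed
  prof3 <- assign_exposure(make_claims("2018-03-01", "J06.9"), idx)
  expect_false(prof3$exposed)
  expect_equal(prof3$burden, "0")
})

test_that("exposure is invariant to claim order and duplication", {
  idx <- mk_index()
  set.seed(5)
  cl <- make_claims(as.Date("2018-01-01") + sample(0:300, 6),
                    c("G47.00", "R06.02", "327.23", "G47.00", "F51.01", "I10"),
                    version = c(10, 10, 9, 10, 10, 10))
  base <- assign_exposure(cl, idx)
  for (i in 1:5) {
    perm <- cl[sample(nrow(cl))]
    dup <- rbind(perm, perm[sample(nrow(perm), 3)])
    expect_equal(assign_exposure(dup, idx), base)
  }
  # the ICD-9 claim 327.23 counts as its ICD-10 image G47.33
  expect_equal(base$n_diagnoses, 4L)
})

test_that("ICD-9 claims dated 2015 convert before exposure assignment", {
  idx <- mk_index(delivery = "2016-03-01")
  cl <- make_claims(c("2015-06-01", "2016-02-01"), c("780.52", "G47.00"),
                    version = c(9, 10))
  prof <- assign_exposure(cl, idx)
  # 780.52 -> G47.00: same distinct ICD-10 code, counted once
  expect_equal(prof$n_diagnoses, 1L)
})

test_that("exposure claims outside the per-woman window are ignored", {
  idx <- mk_index(delivery = "2018-06-01")
  cl <- make_claims(c("2017-06-01", "2019-06-01", "2019-06-02"),
                    c("G47.00", "R06.02", "F51.01"))
  prof <- assign_exposure(cl, idx)
  expect_equal(prof$n_diagnoses, 2L)  # 2019-06-02 is delivery + 366
})

test_that("maternal outcome ascertainment windows are boundary-exact", {
  idx <- mk_index(delivery = "2018-06-01")
  d <- as.Date("2018-06-01")
  run <- function(dates, codes) {
    ascertain_maternal_outcomes(make_claims(dates, codes), idx)
  }
  # gestational diabetes only inside [lmp, delivery]
  expect_false(run(d + 10, "O24.410")$gestational_diabetes)
  expect_true(run(d - 10, "O24.410")$gestational_diabetes)
  # postpartum preeclampsia: six extra weeks
  expect_true(run(d + 30, "O14.15")$preeclampsia)
  expect_false(run(d + 43, "O14.15")$preeclampsia)
  # PPD: half-open (delivery, delivery + 365]
  expect_true(run(d + 200, "F53.0")$postpartum_depression)
  expect_true(run(d + 365, "F53.0")$postpartum_depression)
  expect_false(run(d + 366, "F53.0")$postpartum_depression)
  expect_false(run(d, "F53.0")$postpartum_depression)
  # stillbirth agrees with the episode outcome class
  sb <- ascertain_maternal_outcomes(
    make_claims(d, "Z37.1"), mk_index(outcome = "stillbirth"))
  expect_true(sb$stillbirth)
})

test_that("cesarean evidence on the linked infant propagates to the mother", {
  idx <- mk_index(infant = "I1")
  inf <- make_claims("2018-06-01", "Z38.01", person = "I1",
                     record_type = "infant")
  pan <- ascertain_maternal_outcomes(make_claims("2018-03-01", "Z34.91"),
                                     idx, infant_claims = inf)
  expect_true(pan$cesarean)
})

test_that("birth outcomes use code evidence with conflict-to-missing", {
  dy <- data.table::data.table(woman_id = "W1", infant_id = "I1")
  run <- function(codes) {
    ascertain_birth_outcomes(
      make_claims(rep("2018-06-02", length(codes)), codes, person = "I1",
                  record_type = "infant"), dy)
  }
  # conflicting SGA + LGA forces the axis to missing
  expect_true(is.na(run(c("P05.1", "P08.0"))$size_for_ga))
  expect_equal(run("P07.18")$birthweight, "LBW")
  expect_equal(run("P08.1")$birthweight, "HBW")
  # no birth-outcome codes at all -> the reference levels
  ref <- run("Z38.00")
  expect_equal(ref$size_for_ga, "AGA")
  expect_equal(ref$birthweight, "normal")
  expect_equal(ref$gestation_period, "term")
})

test_that("covariates derive from enrollment and the index episode", {
  idx <- mk_index(ga = 36L)
  cov <- derive_covariates(make_enrollment(birth_year = 1990L, state = "TX"), idx)
  expect_equal(cov$age, 28L)
  expect_equal(cov$age_group, "26-34")
  expect_equal(cov$ga_group, "<=36")
  expect_equal(cov$division, "West South Central")
  cov2 <- derive_covariates(make_enrollment(birth_year = 1990L, state = "TX"),
                            mk_index(ga = 41L))
  expect_equal(cov2$ga_group, "41-42")
  # missing race recodes to NA; unknown state gives missing division
  cov3 <- derive_covariates(make_enrollment(race = "missing", state = "ZZ"),
                            mk_index())
  expect_true(is.na(cov3$race_ethnicity))
  expect_true(is.na(cov3$division))
})

test_that("phenotype panels match ground truth on clean synthetic data", {
  pop <- generate_population(sim_config(n_women = 1500, seed = 71))
  eps <- build_episodes(pop$mother_claims)
  coh <- build_cohort(eps, pop$enrollment, pop$infant_claims)
  an <- build_analysis_table(coh, pop$mother_claims, pop$infant_claims,
                             pop$enrollment)
  m <- merge(an, pop$truth$women, by = "woman_id", suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(an))
  expect_true(all(m$exposed == m$exposed.t))
  expect_true(all(m$n_diagnoses == m$n_diagnoses.t))
  for (oc in c("cesarean", "gestational_diabetes", "gestational_hypertension",
               "preeclampsia", "postpartum_depression", "stillbirth")) {
    expect_true(all(m[[oc]] == m[[paste0(oc, ".t")]]), label = oc)
  }
  b <- m[in_birth_cohort == TRUE]
  for (ax in c("size_for_ga", "birthweight", "gestation_period")) {
    expect_true(all(b[[ax]] == b[[paste0(ax, ".t")]]), label = ax)
  }
  expect_true(all(b$infant_sex == b$infant_sex.t))
})
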