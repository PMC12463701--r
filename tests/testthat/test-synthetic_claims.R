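test_that("identical seeds give byte-identical populations", {
  a <- generate_population(sim_config(n_women = 300, seed = 7))
  b <- generate_population(sim_config(n_women = 300, seed = 7))
  expect_identical(a$mother_claims, b$mother_claims)
  expect_identical(a$infant_claims, b$infant_claims)
  expect_identical(a$enrollment, b$enrollment)
  expect_identical(a$truth$women, b$truth$women)
  # a different seed gives different data
  c <- generate_population(sim_config(n_women = 300, seed = 8))
  expect_false(identical(a$mother_claims, c$mother_claims))
})

test_that("per-woman data are stable when n_women grows", {
  small <- generate_population(sim_config(n_women = 60, seed = 13))
  big <- generate_population(sim_config(n_women = 150, seed = 13))
  ids <- small$truth$women$woman_id
  expect_identical(small$mother_claims,
                   big$mother_claims[person_id %in% ids])
  expect_identical(small$truth$women, big$truth$women[woman_id %in% ids])
})

test_that("zero exposure prevalence yields zero exposed women", {
  pop <- generate_population(sim_config(n_women = 400, seed = 3,
                                        exposure_prevalence = 0))
  expect_equal(sum(pop$truth$women$exposed), 0L)
  expect_false(any(pop$mother_claims$icd_version == 9L))
})

test_that("empirical exposure prevalence converges to the configured value", {
  pop <- generate_population(sim_config(n_women = 8000, seed = 17))
  p <- mean(pop$truth$women$exposed)
  tol <- 3 * sqrt(0.0341 * (1 - 0.0341) / 8000)
  expect_lt(abs(p - 0.0341), tol)
  # diagnosed-burden split among the exposed
  tw <- pop$truth$women[exposed == TRUE]
  expect_lt(abs(mean(tw$n_diagnoses == 1L) - 0.8445),
            3 * sqrt(0.8445 * 0.1555 / nrow(tw)))
})

test_that("every claim is attributable to exactly one truth record", {
  pop <- generate_population(sim_config(n_women = 300, seed = 23))
  tw <- pop$truth$women
  expect_true(all(pop$mother_claims$person_id %in% tw$woman_id))
  expect_true(all(pop$infant_claims$person_id %in% tw$infant_id))
  # family ids agree between claims and truth
  m <- match(pop$mother_claims$person_id, tw$woman_id)
  expect_true(all(pop$mother_claims$family_id == tw$family_id[m]))
  # claims stay inside the configured calendar window
  expect_true(all(pop$mother_claims$service_date >= as.Date("2015-01-01")))
  expect_true(all(pop$mother_claims$service_date <= as.Date("2021-06-30")))
})

test_that("infeasible episode packing is rejected", {
  expect_error(sim_config(culmination_window = c("2016-01-01", "2017-06-30"),
                          date_window = c("2015-01-01", "2018-06-30")),
               "infeasible")
  expect_error(sim_config(exposure_prevalence = 1.2), "probabilities")
  expect_error(sim_config(burden_split = c(one = 0.5, two_plus = 0.4)),
               "sum to 1")
})

test_that("injected pathologies are tagged and surface downstream", {
  pop <- generate_population(sim_config(n_women = 500, seed = 29))
  pop <- inject_pathologies(pop, c(twin_codes = 4, sga_lga_conflict = 2,
                                   enrollment_gap = 3, duplicate_claims = 5))
  pt <- pop$truth$pathologies
  expect_equal(nrow(pt), 14L)
  eps <- build_episodes(pop$mother_claims)
  coh <- build_cohort(eps, pop$enrollment, pop$infant_claims)
  # twin-code women are excluded as multiple gestations
  twins <- pt[type == "twin_codes", woman_id]
  expect_false(any(twins %in% coh$members$woman_id))
  # enrollment-gap women fail the continuous-enrollment filter
  gaps <- pt[type == "enrollment_gap", woman_id]
  expect_false(any(gaps %in% coh$members$woman_id))
  # conflicting SGA+LGA forces the axis to missing
  an <- build_analysis_table(coh, pop$mother_claims, pop$infant_claims,
                             pop$enrollment)
  confl <- pt[type == "sga_lga_conflict", woman_id]
  expect_true(all(is.na(an[woman_id %in% confl, size_for_ga])))
  # exact duplicate claims change nothing (dedup before grouping)
  clean <- generate_population(sim_config(n_women = 500, seed = 29))
  dup_ids <- pt[type == "duplicate_claims", woman_id]
  eps_clean <- build_episodes(clean$mother_claims)
  expect_equal(eps[woman_id %in% dup_ids], eps_clean[woman_id %in% dup_ids])
  expect_error(inject_pathologies(pop, c(nonsense = 1)), "unknown pathology")
  # an injected prior loss adds one episode and leaves the index unchanged
  pop3 <- generate_population(sim_config(n_women = 400, seed = 77))
  pop3 <- inject_pathologies(pop3, c(extra_episode = 3))
  ids3 <- pop3$truth$pathologies[type == "extra_episode", woman_id]
  eps3 <- build_episodes(pop3$mother_claims)
  counts <- eps3[woman_id %in% ids3, .N, by = woman_id]
  expect_true(all(counts$N == 2L))
  expect_true(all(eps3[woman_id %in% ids3 & episode_id == 1L,
                       outcome_class] == "spontaneous_abortion"))
})

test_that("null planted effects estimate odds ratios near one", {
  cfg <- sim_config(n_women = 12000, seed = 37,
                    exposure_prevalence = 0.2,
                    planted_log_odds = c(
                      cesarean = 0, gestational_diabetes = 0,
                      gestational_hypertension = 0, preeclampsia = 0,
                      postpartum_depression = 0, stillbirth = 0))
  pop <- generate_population(cfg)
  eps <- build_episodes(pop$mother_claims)
  coh <- build_cohort(eps, pop$enrollment, pop$infant_claims)
  an <- build_analysis_table(coh, pop$mother_claims, pop$infant_claims,
                             pop$enrollment)
  fm <- fit_maternal_models(an[in_maternal_cohort == TRUE],
                            outcomes = c("cesarean", "gestational_diabetes",
                                         "gestational_hypertension"))
  ors <- fm[term == "exposed_yes"]
  expect_true(all(ors$ci_low < 1 & 1 < ors$ci_high))
  expect_true(all(abs(ors$estimate) < 0.25))
})
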