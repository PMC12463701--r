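test_that("continuous enrollment demands zero uncovered days", {
  culm <- as.Date("2017-06-15")
  spans <- data.frame(span_start = as.Date("2016-01-01"),
                      span_end = as.Date("2019-01-01"))
  expect_true(check_continuous_enrollment(spans, culm))
  # a single-day hole inside the window fails
  spans2 <- data.frame(
    span_start = as.Date(c("2016-01-01", "2017-01-01")),
    span_end = as.Date(c("2016-12-31", "2019-01-01")))
  expect_true(check_continuous_enrollment(spans2, culm))  # consecutive days
  spans3 <- data.frame(
    span_start = as.Date(c("2016-01-01", "2017-01-02")),
    span_end = as.Date(c("2016-12-31", "2019-01-01")))
  expect_false(check_continuous_enrollment(spans3, culm))  # 1-day hole
  # spans ending exactly on culmination + 365d still qualify
  spans4 <- data.frame(span_start = culm - 365, span_end = culm + 365)
  expect_true(check_continuous_enrollment(spans4, culm))
  expect_false(check_continuous_enrollment(
    data.frame(span_start = culm - 365, span_end = culm + 364), culm))
})

test_that("eligibility flags each exclusion rule", {
  mk_ep <- function(...) {
    d <- data.table::data.table(
      woman_id = "W1", episode_id = 1L,
      min_date = as.Date("2017-01-01"), max_date = as.Date("2017-10-01"),
      lmp_date = as.Date("2017-01-01"), delivery_date = as.Date("2017-10-01"),
      ga_weeks = 39L, ga_imputed = FALSE, outcome_class = "live_birth",
      multiple_gestation = FALSE, n_claims = 3L)
    mods <- list(...)
    for (nm in names(mods)) data.table::set(d, j = nm, value = mods[[nm]])
    d
  }
  en <- make_enrollment(birth_year = 1990L)
  expect_true(apply_eligibility(mk_ep(), en)$eligible)
  # aged 17 at delivery (year arithmetic)
  expect_false(apply_eligibility(mk_ep(), make_enrollment(birth_year = 2000L))$eligible)
  f <- apply_eligibility(mk_ep(), make_enrollment(birth_year = 2000L))
  expect_false(f$ok_age)
  # culminated in 2015
  f <- apply_eligibility(mk_ep(delivery_date = as.Date("2015-12-20"),
                               min_date = as.Date("2015-04-01"),
                               lmp_date = as.Date("2015-03-20")), en)
  expect_false(f$ok_window)
  # multiple gestation (O30/O31 evidence), including unknown outcomes
  f <- apply_eligibility(mk_ep(multiple_gestation = TRUE,
                               outcome_class = "unknown"), en)
  expect_false(f$ok_singleton)
  # induced abortion
  f <- apply_eligibility(mk_ep(outcome_class = "induced_abortion"), en)
  expect_false(f$ok_not_induced)
})

test_that("index selection follows the outcome hierarchy with earliest-date ties", {
  ep <- data.table::data.table(
    woman_id = "W1", episode_id = 1:2,
    delivery_date = as.Date(c("2018-01-01", "2017-01-01")),
    outcome_class = c("live_birth", "stillbirth"))
  expect_equal(select_index_episode(ep)$outcome_class, "live_birth")
  ep$outcome_class <- c("unknown", "spontaneous_abortion")
  expect_equal(select_index_episode(ep)$outcome_class, "spontaneous_abortion")
  ep <- data.table::data.table(
    woman_id = "W1", episode_id = 1:2,
    delivery_date = as.Date(c("2019-05-01", "2017-05-01")),
    outcome_class = "live_birth")
  expect_equal(select_index_episode(ep)$delivery_date, as.Date("2017-05-01"))
})

test_that("dyads link by family id within the delivery window", {
  idx <- data.table::data.table(
    woman_id = c("W1", "W2", "W3"), family_id = c("F1", "F2", "F3"),
    delivery_date = as.Date("2018-06-01"),
    outcome_class = c("live_birth", "live_birth", "stillbirth"))
  inf <- make_claims(rep("2018-06-01", 2), rep("Z38.00", 2),
                     person = c("I1", "I9"), family = c("F1", "F9"),
                     record_type = "infant")
  dy <- link_dyads(idx, inf)
  expect_equal(dy$woman_id, "W1")
  expect_equal(dy$infant_id, "I1")
  # W2 has no infant with her family id; W3 is a stillbirth: never linked
  expect_false(any(c("W2", "W3") %in% dy$woman_id))
  # two candidates: nearest first-claim date wins
  inf2 <- make_claims(c("2018-06-20", "2018-06-03"), rep("Z38.00", 2),
                      person = c("Ifar", "Inear"), family = "F1",
                      record_type = "infant")
  dy2 <- link_dyads(idx, inf2)
  expect_equal(dy2[woman_id == "W1", infant_id], "Inear")
  expect_equal(dy2[woman_id == "W1", n_candidates], 2L)
  # outside the 60-day window: unlinked
  inf3 <- make_claims("2018-08-15", "Z38.00", person = "I1", family = "F1",
                      record_type = "infant")
  expect_equal(nrow(link_dyads(idx, inf3)), 0L)
})

test_that("cascade accounting reconciles and cohort identities hold", {
  pop <- generate_population(sim_config(n_women = 800, seed = 99,
                                        enrollment_gap_rate = 0.05))
  eps <- build_episodes(pop$mother_claims)
  coh <- build_cohort(eps, pop$enrollment, pop$infant_claims)
  fc <- emit_flowchart(coh$cascade)
  main <- fc[!stage %in% c("maternal_outcome_cohort", "birth_outcome_cohort")]
  expect_equal(main$n_in[1] - sum(main$n_excluded), nrow(coh$members))
  # exactly one index episode per woman
  expect_equal(anyDuplicated(coh$members$woman_id), 0L)
  # analysis-set identities
  m <- coh$members
  expect_true(all(m[in_maternal_cohort == TRUE, outcome_class] != "unknown"))
  expect_true(all(m[in_birth_cohort == TRUE, outcome_class] == "live_birth"))
  expect_true(all(!is.na(m[in_birth_cohort == TRUE, infant_id])))
  expect_true(all(m[in_birth_cohort == TRUE, in_maternal_cohort]))
  # flow-chart consistency is enforced
  bad <- data.table::copy(coh$cascade)
  bad$n_in[2] <- bad$n_in[2] + 1L
  expect_error(emit_flowchart(bad), "reconcile")
})
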