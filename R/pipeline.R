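# End-to-end runner and study-shaped reports: the selection-cascade flow
# chart, the demographic, diagnosis-burden, maternal-outcome and
# birth-outcome tables, and the adjusted-odds-ratio forest tables.

.claims_schema <- c("person_id", "family_id", "service_date", "icd_version",
                    "code", "record_type")
.enroll_schema <- c("person_id", "family_id", "span_start", "span_end",
                    "birth_year", "sex", "race_ethnicity", "state", "aso",
                    "cdhp", "health_exchange", "product")

#' Build a pipeline configuration
#'
#' Holds either a simulation request or input paths, plus the study
#' constants: claim and culmination calendar windows, gap-rule day counts
#' (120 after live births, 42 after stillbirths/abortions), enrollment and
#' ascertainment window lengths, and dyad-linkage window.
#'
#' @param simulate a [sim_config()] to generate inputs, or `NULL`.
#' @param claims_path,enrollment_path delimited input files (used when
#'   `simulate` is `NULL`).
#' @param culmination_window eligible culmination dates.
#' @param gap_live,gap_loss,max_span episode gap rules (days).
#' @param pre_days,post_days continuous-enrollment / exposure windows.
#' @param ppd_days,pe_extra_days outcome ascertainment windows.
#' @param link_window dyad first-claim window (days).
#' @param age_range eligible maternal age interval.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL,
                            claims_path = NULL, enrollment_path = NULL,
                            culmination_window = .default_culmination_window,
                            gap_live = 120L, gap_loss = 42L, max_span = 308L,
                            pre_days = 365L, post_days = 365L,
                            ppd_days = 365L, pe_extra_days = 42L,
                            link_window = 60L, age_range = c(18L, 45L)) {
  if (is.null(simulate) && (is.null(claims_path) || is.null(enrollment_path))) {
    stop("provide either a simulation config or input paths")
  }
  stopifnot(gap_live > 0L, gap_loss > 0L, max_span > 0L,
            pre_days > 0L, post_days > 0L, ppd_days > 0L,
            pe_extra_days > 0L, link_window > 0L)
  structure(list(
    simulate = simulate, claims_path = claims_path,
    enrollment_path = enrollment_path,
    culmination_window = as.Date(culmination_window),
    gap_live = gap_live, gap_loss = gap_loss, max_span = max_span,
    pre_days = pre_days, post_days = post_days, ppd_days = ppd_days,
    pe_extra_days = pe_extra_days, link_window = link_window,
    age_range = age_range), class = "pipeline_config")
}

validate_schema <- function(tab, schema, what) {
  missing_cols <- setdiff(schema, names(tab))
  if (length(missing_cols)) {
    stop(what, " table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop(what, " table is empty")
  invisible(tab)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the claims and enrollment tables, builds pregnancy
#' episodes, applies the eligibility cascade with index-episode selection
#' and dyad linkage, phenotypes exposure / outcomes / covariates, and
#' produces the study-shaped outputs: flow chart, demographic table with
#' t / chi-squared p-values, diagnosis-burden table, maternal and birth
#' outcome tables with column percentages, and adjusted-odds-ratio forest
#' tables from the binary and multinomial models.
#'
#' @param config a [pipeline_config()].
#' @section Input schemas:
#' Delimited text with a header row, UTF-8. Claims: `person_id`,
#' `family_id`, `service_date` (ISO-8601), `icd_version` (9 or 10),
#' `code`, `record_type` (`mother`/`infant`). Enrollment: `person_id`,
#' `family_id`, `span_start`, `span_end`, `birth_year`, `sex`,
#' `race_ethnicity`, `state`, `aso`, `cdhp`, `health_exchange`,
#' `product`.
#' @return A named list (the artifact bundle): `flowchart`, `demographics`,
#'   `burden`, `maternal_outcomes`, `birth_outcomes`, `forest_maternal`,
#'   `forest_birth`, `analysis`, `prevalence_pct`, `run_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    pop <- generate_population(config$simulate)
    mother_claims <- pop$mother_claims
    infant_claims <- pop$infant_claims
    enrollment <- pop$enrollment
  } else {
    claims <- data.table::fread(config$claims_path)
    validate_schema(claims, .claims_schema, "claims")
    for (col in c("person_id", "family_id", "code", "record_type")) {
      data.table::set(claims, j = col, value = as.character(claims[[col]]))
    }
    claims[, service_date := as.Date(service_date)]
    mother_claims <- claims[record_type == "mother"]
    infant_claims <- claims[record_type == "infant"]
    enrollment <- data.table::fread(config$enrollment_path)
    validate_schema(enrollment, .enroll_schema, "enrollment")
    enrollment[, `:=`(span_start = as.Date(span_start),
                      span_end = as.Date(span_end))]
  }
  validate_schema(mother_claims, .claims_schema, "mother claims")
  validate_schema(enrollment, .enroll_schema, "enrollment")

  episodes <- build_episodes(mother_claims, config$gap_live,
                             config$gap_loss, config$max_span)
  cohort <- build_cohort(episodes, enrollment, infant_claims,
                         config$culmination_window, config$age_range,
                         config$pre_days, config$post_days,
                         config$link_window)
  analysis <- build_analysis_table(cohort, mother_claims, infant_claims,
                                   enrollment, config$pre_days,
                                   config$post_days)
  maternal <- analysis[in_maternal_cohort == TRUE]
  birth <- analysis[in_birth_cohort == TRUE]

  prevalence_pct <- period_prevalence(sum(maternal$exposed), nrow(maternal))
  burden_tab <- maternal[exposed == TRUE, .N, by = .(n_diagnoses)][
    order(n_diagnoses)]
  burden_tab[, pct := round_half_up(100 * N / sum(N), 2L)]

  demographics <- demographic_table(maternal)
  mat_out <- outcome_table(maternal, .maternal_outcomes)
  birth_out <- birth_outcome_table(birth)
  forest_maternal <- fit_maternal_models(maternal)
  forest_birth <- if (nrow(birth) > 0L) fit_birth_models(birth) else NULL

  run_log <- data.table::data.table(
    item = c("n_women_input", "n_episodes", "n_cohort", "n_maternal_cohort",
            "n_birth_cohort", "prevalence_pct", "seed"),
    value = as.character(c(
      data.table::uniqueN(mother_claims$person_id), nrow(episodes),
      nrow(cohort$members), nrow(maternal), nrow(birth), prevalence_pct,
      if (!is.null(config$simulate)) config$simulate$seed else NA)))

  list(flowchart = emit_flowchart(cohort$cascade),
       demographics = demographics, burden = burden_tab,
       maternal_outcomes = mat_out, birth_outcomes = birth_out,
       forest_maternal = forest_maternal, forest_birth = forest_birth,
       analysis = analysis, prevalence_pct = prevalence_pct,
       run_log = run_log)
}

# demographic comparison by exposure with chi-squared p-values (and a
# pooled t-test for age)
demographic_table <- function(maternal) {
  vars <- c("age_group", "ga_group", "race_ethnicity", "division",
            "aso", "cdhp", "health_exchange", "product")
  rows <- list()
  a <- maternal[exposed == TRUE, age]
  b <- maternal[exposed == FALSE, age]
  if (length(a) >= 2L && length(b) >= 2L) {
    tt <- students_t_test(b, a)
    rows$age <- data.table::data.table(
      variable = "age_years", level = "mean",
      n_total = length(a) + length(b),
      unexposed = round_half_up(tt$mean_a, 2L),
      exposed = round_half_up(tt$mean_b, 2L),
      unexposed_pct = NA_real_, exposed_pct = NA_real_,
      p_value = tt$p_value)
  }
  for (v in vars) {
    ct <- tryCatch(crosstab(maternal, v, "exposed"), error = function(e) NULL)
    if (is.null(ct)) next
    p <- tryCatch(chi_squared_test(ct)$p_value, error = function(e) NA_real_)
    cn <- colnames(ct$counts)
    ue <- which(cn == "FALSE"); ex <- which(cn == "TRUE")
    rows[[v]] <- data.table::data.table(
      variable = v, level = rownames(ct$counts),
      n_total = rowSums(ct$counts),
      unexposed = if (length(ue)) ct$counts[, ue] else NA_integer_,
      exposed = if (length(ex)) ct$counts[, ex] else NA_integer_,
      unexposed_pct = if (length(ue)) ct$col_pct[, ue] else NA_real_,
      exposed_pct = if (length(ex)) ct$col_pct[, ex] else NA_real_,
      p_value = p)
  }
  data.table::rbindlist(rows)
}

outcome_table <- function(maternal, outcomes) {
  rows <- list()
  for (oc in outcomes) {
    ct <- tryCatch(crosstab(maternal, oc, "exposed"), error = function(e) NULL)
    if (is.null(ct)) next
    p <- tryCatch(chi_squared_test(ct)$p_value, error = function(e) NA_real_)
    cn <- colnames(ct$counts)
    ue <- which(cn == "FALSE"); ex <- which(cn == "TRUE")
    rows[[oc]] <- data.table::data.table(
      outcome = oc, level = rownames(ct$counts),
      unexposed = if (length(ue)) ct$counts[, ue] else NA_integer_,
      exposed = if (length(ex)) ct$counts[, ex] else NA_integer_,
      unexposed_pct = if (length(ue)) ct$col_pct[, ue] else NA_real_,
      exposed_pct = if (length(ex)) ct$col_pct[, ex] else NA_real_,
      p_value = p)
  }
  data.table::rbindlist(rows)
}

birth_outcome_table <- function(birth) {
  if (nrow(birth) == 0L) return(NULL)
  out <- outcome_table(birth, names(.birth_axes))
  data.table::setnames(out, "outcome", "axis")
  out
}

#' Write an artifact bundle to delimited files
#'
#' Writes every tabular element of a [run_pipeline()] bundle as a TSV into
#' `dir`. Output is deterministic: identical bundles produce byte-identical
#' files.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.null(x)) next
    if (!is.data.frame(x)) {
      x <- data.table::data.table(item = nm, value = x)
    }
    p <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(x, p, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
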