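# Adjusted-model front end: reference-level coding, complete-case
# handling, and tidy odds-ratio tables for the maternal (binary) and birth
# (multinomial) models.

.default_references <- list(
  age_group = "26-34", race_ethnicity = "White", division = "South Atlantic",
  aso = "no", cdhp = "none", health_exchange = "no", product = "POS",
  infant_sex = "F"
)
.maternal_adjustment <- c("age_group", "race_ethnicity", "division",
                          "aso", "cdhp", "health_exchange", "product")
.birth_adjustment <- c(.maternal_adjustment, "infant_sex",
                       "gestational_diabetes", "gestational_hypertension",
                       "preeclampsia", "cesarean")

# build a design matrix with an intercept, exposure term(s) first, and
# dummy-coded covariates under the configured reference levels; rows with
# any missing value are dropped (complete-case analysis)
build_design <- function(data, exposure_cols, covariates,
                         references = .default_references) {
  dt <- data.table::as.data.table(data)
  cols <- c(exposure_cols, covariates)
  dt <- dt[, ..cols]
  for (v in covariates) {
    x <- dt[[v]]
    if (is.logical(x)) {
      data.table::set(dt, j = v, value = as.integer(x))
    } else if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      if (!is.null(references[[v]]) && references[[v]] %in% levels(x)) {
        x <- stats::relevel(x, ref = references[[v]])
      }
      data.table::set(dt, j = v, value = x)
    }
  }
  cc <- complete.cases(dt)
  dt <- dt[cc]
  form <- as.formula(paste("~", paste(cols, collapse = " + ")))
  X <- model.matrix(form, data = dt)
  list(X = X, rows = which(cc), n_dropped = sum(!cc))
}

#' Fit the adjusted maternal-outcome models
#'
#' One multivariable binary logistic model per maternal outcome, with
#' sleep-disorder exposure (dichotomous, or burden indicators when
#' `dose_response = TRUE`) plus the demographic and insurance covariates.
#' Complete-case rows only; the reference levels default to age 26-34,
#' White, South Atlantic, POS product, and "no"/"none" for the remaining
#' insurance attributes.
#'
#' @param analysis person-level analysis table restricted to the
#'   maternal-outcome cohort.
#' @param outcomes outcome columns to model (default all six).
#' @param covariates adjustment set.
#' @param dose_response model burden (0/1/2+) instead of yes/no exposure.
#' @param references named list of reference levels.
#' @return data.table: `outcome`, `term`, `estimate`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `n_used`, `converged`.
#' @export
fit_maternal_models <- function(analysis,
                                outcomes = .maternal_outcomes,
                                covariates = .maternal_adjustment,
                                dose_response = FALSE,
                                references = .default_references) {
  d <- data.table::copy(data.table::as.data.table(analysis))
  if (dose_response) {
    dd <- dose_response_coding(d$burden)
    d[, `:=`(burden1 = dd[, 1], burden2plus = dd[, 2])]
    expo <- c("burden1", "burden2plus")
  } else {
    d[, exposed_yes := as.integer(exposed)]
    expo <- "exposed_yes"
  }
  # one design for all outcomes; outcome-specific missingness subsets rows
  des <- build_design(d, expo, covariates, references)
  out <- list()
  for (oc in outcomes) {
    y <- as.integer(d[[oc]])[des$rows]
    ok <- !is.na(y)
    fit <- fit_binary_logistic(des$X[ok, , drop = FALSE], y[ok])
    out[[oc]] <- data.table::data.table(
      outcome = oc, term = names(fit$coefficients),
      estimate = fit$coefficients, se = fit$se, or = fit$or,
      ci_low = fit$ci_low, ci_high = fit$ci_high, p = fit$p_value,
      n_used = fit$n_used, converged = fit$converged)
  }
  data.table::rbindlist(out)
}

#' Fit the adjusted birth-outcome models
#'
#' One baseline-category multinomial logistic model per birth-outcome axis
#' (size for gestational age, birthweight, gestation period), with the
#' maternal adjustment set plus infant sex and the pregnancy complications
#' (gestational diabetes, gestational hypertension, preeclampsia, cesarean
#' delivery). Reference outcome levels are AGA / normal / term.
#'
#' @param analysis analysis table restricted to the birth-outcome cohort.
#' @param axes axis columns to model.
#' @param covariates adjustment set.
#' @param dose_response model burden instead of yes/no exposure.
#' @param references named list of reference levels.
#' @return data.table: `axis`, `level`, `term`, `estimate`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `n_used`, `converged`.
#' @export
fit_birth_models <- function(analysis,
                             axes = names(.birth_axes),
                             covariates = .birth_adjustment,
                             dose_response = FALSE,
                             references = .default_references) {
  d <- data.table::copy(data.table::as.data.table(analysis))
  if (dose_response) {
    dd <- dose_response_coding(d$burden)
    d[, `:=`(burden1 = dd[, 1], burden2plus = dd[, 2])]
    expo <- c("burden1", "burden2plus")
  } else {
    d[, exposed_yes := as.integer(exposed)]
    expo <- "exposed_yes"
  }
  des <- build_design(d, expo, covariates, references)
  out <- list()
  for (ax in axes) {
    yall <- d[[ax]][des$rows]
    ok <- !is.na(yall)
    ref <- .birth_axes[[ax]][["ref"]]
    fit <- fit_multinomial_logistic(des$X[ok, , drop = FALSE], yall[ok],
                                    reference = ref)
    for (lv in colnames(fit$coefficients)) {
      out[[paste(ax, lv)]] <- data.table::data.table(
        axis = ax, level = lv, term = rownames(fit$coefficients),
        estimate = fit$coefficients[, lv], se = fit$se[, lv],
        or = fit$or[, lv], ci_low = fit$ci_low[, lv],
        ci_high = fit$ci_high[, lv], p = fit$p_value[, lv],
        n_used = fit$n_used, converged = fit$converged)
    }
  }
  data.table::rbindlist(out)
}
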