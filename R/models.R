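# Descriptive statistics, period prevalence, contingency measures, and
# binary / baseline-category multinomial logistic regression with Wald 95%
# confidence intervals. The logistic fitters are implemented directly
# (IRLS and Newton-Raphson on the stacked coefficient vector) because the
# estimator is the analytical core of the pipeline; standard tests wrap
# base R.

#' Round half away from zero
#'
#' Plain decimal rounding with halves going up (printed-table style),
#' rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Period prevalence as a percentage
#'
#' 100 times the count of unique affected persons over the total eligible
#' count, reported to two decimals (round half up).
#'
#' @param n_exposed_unique unique persons with the condition in the period.
#' @param n_total total eligible persons.
#' @return Percentage, rounded to two decimals.
#' @export
period_prevalence <- function(n_exposed_unique, n_total) {
  if (length(n_total) != 1L || is.na(n_total) || n_total <= 0L) {
    stop("n_total must be a positive count")
  }
  if (n_exposed_unique < 0L || n_exposed_unique > n_total) {
    stop("n_exposed_unique must lie in [0, n_total]")
  }
  round_half_up(100 * n_exposed_unique / n_total, 2L)
}

#' Cross-tabulate two categorical variables with column percentages
#'
#' Counts are tabulated over rows where both variables are non-missing;
#' missing rows are excluded from the percentage denominators and counted
#' separately. Column percentages are reported to two decimals.
#'
#' @param data a data.frame.
#' @param row_var,col_var column names.
#' @return List of class `perisleep_crosstab`: `counts` (matrix),
#'   `col_pct`, `n_missing`, `n_used`.
#' @export
crosstab <- function(data, row_var, col_var) {
  r <- data[[row_var]]
  cc <- data[[col_var]]
  keep <- !is.na(r) & !is.na(cc)
  n_missing <- sum(!keep)
  if (!any(keep)) stop("no non-missing rows to tabulate (",
                       n_missing, " rows missing)")
  counts <- table(factor(r[keep]), factor(cc[keep]))
  counts <- unclass(counts)
  pct <- round_half_up(100 * sweep(counts, 2L, colSums(counts), "/"), 2L)
  structure(list(counts = counts, col_pct = pct,
                 n_missing = n_missing, n_used = sum(keep),
                 row_var = row_var, col_var = col_var),
            class = "perisleep_crosstab")
}

#' @export
print.perisleep_crosstab <- function(x, ...) {
  cat(x$row_var, "by", x$col_var, " (n =", x$n_used,
      ", missing =", x$n_missing, ")\n")
  print(x$counts)
  cat("column %:\n")
  print(x$col_pct)
  invisible(x)
}

#' Pearson chi-squared test of independence
#'
#' Classic Pearson statistic without continuity correction, with
#' df = (r-1)(c-1). Tables with a zero expected cell are rejected rather
#' than silently corrected.
#'
#' @param tab contingency table (matrix of counts) or a
#'   `perisleep_crosstab`.
#' @return List `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(tab) {
  if (inherits(tab, "perisleep_crosstab")) tab <- tab$counts
  tab <- as.matrix(tab)
  if (sum(tab) <= 0) stop("empty table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected cell count; test undefined")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Two-sample Student t-test (pooled variance)
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return List `t`, `df`, `p_value`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
students_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                mean_a = mean(a), mean_b = mean(b),
                sd_a = stats::sd(a), sd_b = stats::sd(b)))
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero pooled variance with unequal means")
  }
  res <- t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b))
}

#' Unadjusted odds ratio with Wald 95% CI from a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` for a table laid out as rows =
#' outcome yes/no, columns = unexposed/exposed (or any 2x2 orientation);
#' the Wald interval uses `SE = sqrt(1/a + 1/b + 1/c + 1/d)` on the log
#' scale. Zero cells are rejected (no Haldane correction).
#'
#' @param tab 2x2 matrix of counts.
#' @return List `or`, `ci_low`, `ci_high`, `log_or`, `se`.
#' @export
odds_ratio_ci <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab <= 0)) stop("all four cells must be positive")
  lor <- log(tab[1, 1]) + log(tab[2, 2]) - log(tab[1, 2]) - log(tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(0.975)
  list(or = exp(lor), ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
       log_or = lor, se = se)
}

#' Indicator coding for the diagnosis-burden dose-response analysis
#'
#' @param burden character/factor vector with levels "0", "1", "2+".
#' @return Matrix with columns `burden1`, `burden2plus` (zero diagnoses is
#'   the reference).
#' @export
dose_response_coding <- function(burden) {
  burden <- as.character(burden)
  if (!all(burden %in% c("0", "1", "2+"))) stop("burden must be 0, 1 or 2+")
  cbind(burden1 = as.integer(burden == "1"),
        burden2plus = as.integer(burden == "2+"))
}

.check_design <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  X
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with convergence declared when the
#' maximum absolute score falls below `tol_score` (1e-8) or the relative
#' log-likelihood change falls below `tol_ll` (1e-10), within `max_iter`
#' iterations. Wald 95% CIs come from the observed-information covariance.
#' Coefficients with |beta| > 15 are flagged as separated and the fit is
#' marked non-converged.
#'
#' @param X design matrix (including intercept column), complete cases.
#' @param y 0/1 response vector.
#' @param max_iter,tol_score,tol_ll convergence controls.
#' @return Object of class `logistic_fit`: `coefficients`, `vcov`, `se`,
#'   `or`, `ci_low`, `ci_high`, `z`, `p_value`, `loglik`, `converged`,
#'   `separation`, `n_used`, `iterations`.
#' @export
fit_binary_logistic <- function(X, y, max_iter = 100L,
                                tol_score = 1e-8, tol_ll = 1e-10) {
  X <- .check_design(as.matrix(X))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    score <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    if (max(abs(score)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) < tol_ll * (abs(ll_old) + 1e-12))) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    beta <- beta + solve(H, score)
    ll_old <- ll
  }
  separation <- abs(beta) > 15
  vc <- solve(H)
  se <- sqrt(diag(vc))
  z <- stats::qnorm(0.975)
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta, vcov = vc, se = setNames(se, colnames(X)),
    or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    z = beta / se, p_value = 2 * stats::pnorm(-abs(beta / se)),
    loglik = ll, converged = converged && !any(separation),
    separation = setNames(separation, colnames(X)),
    n_used = nrow(X), iterations = iter, model = "binary_logistic"
  ), class = "logistic_fit")
}

#' Baseline-category multinomial logistic regression by Newton-Raphson
#'
#' Fits the baseline-category logit model: for each non-reference level j,
#' log(P(y=j)/P(y=ref)) = X beta_j. The full (K-1)p coefficient vector is
#' updated with full Newton steps on the exact block Hessian, under the
#' same convergence contract as the binary fitter. With K = 2 the fit
#' reduces to binary logistic regression.
#'
#' @param X design matrix (including intercept), complete cases.
#' @param y factor (or coercible) response with K >= 2 observed levels.
#' @param reference the baseline level (default: first level of `y`).
#' @param max_iter,tol_score,tol_ll convergence controls.
#' @return Object of class `multinomial_fit`: per-level coefficient
#'   matrices and Wald statistics, `vcov` of the stacked vector,
#'   `fitted_probs`, `loglik`, `converged`, `n_used`.
#' @export
fit_multinomial_logistic <- function(X, y, reference = NULL, max_iter = 100L,
                                     tol_score = 1e-8, tol_ll = 1e-10) {
  X <- .check_design(as.matrix(X))
  y <- factor(y)
  if (any(table(y) == 0L)) stop("empty outcome level: ",
                                paste(levels(y)[table(y) == 0L], collapse = ", "))
  if (is.null(reference)) reference <- levels(y)[1L]
  if (!reference %in% levels(y)) stop("reference level not present in data")
  y <- stats::relevel(y, ref = reference)
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L) stop("need at least two outcome levels")
  n <- nrow(X); p <- ncol(X); m <- K - 1L
  Y <- matrix(0, n, m)
  for (j in seq_len(m)) Y[, j] <- as.numeric(y == lev[j + 1L])
  B <- matrix(0, p, m)                       # columns = non-reference levels
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    Eta <- X %*% B
    M <- Reduce(pmax, lapply(seq_len(m), function(j) Eta[, j]), init = rep(0, n))
    denom <- exp(-M) + rowSums(exp(Eta - M))
    P <- exp(Eta - M) / denom                 # P(y = level j)
    ll <- sum(rowSums(Y * Eta)) - sum(M + log(denom))
    score <- as.vector(crossprod(X, Y - P))
    H <- matrix(0, m * p, m * p)
    for (j in seq_len(m)) {
      for (k in j:m) {
        w <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
        blk <- crossprod(X, X * w)
        ri <- (j - 1L) * p + seq_len(p); ci <- (k - 1L) * p + seq_len(p)
        H[ri, ci] <- blk
        if (j != k) H[ci, ri] <- t(blk)
      }
    }
    if (max(abs(score)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) < tol_ll * (abs(ll_old) + 1e-12))) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    B <- B + matrix(solve(H, score), p, m)
    ll_old <- ll
  }
  separation <- abs(B) > 15
  vc <- solve(H)
  se <- matrix(sqrt(diag(vc)), p, m)
  z <- stats::qnorm(0.975)
  dimnames(B) <- dimnames(se) <- list(colnames(X), lev[-1L])
  structure(list(
    coefficients = B, se = se, vcov = vc,
    or = exp(B), ci_low = exp(B - z * se), ci_high = exp(B + z * se),
    p_value = 2 * stats::pnorm(-abs(B / se)),
    fitted_probs = {
      fp <- cbind(exp(-M) / denom, P)
      colnames(fp) <- lev
      fp
    },
    loglik = ll, converged = converged && !any(separation),
    separation = separation, reference = reference, levels = lev,
    n_used = n, iterations = iter, model = "multinomial_logistic"
  ), class = "multinomial_fit")
}

#' Fitted category probabilities from a multinomial fit
#'
#' @param fit a `multinomial_fit`.
#' @param X design matrix.
#' @return Matrix of category probabilities (columns in level order,
#'   reference first); rows sum to one.
#' @export
predict_multinomial <- function(fit, X) {
  Eta <- as.matrix(X) %*% fit$coefficients
  M <- Reduce(pmax, lapply(seq_len(ncol(Eta)), function(j) Eta[, j]),
              init = rep(0, nrow(Eta)))
  denom <- exp(-M) + rowSums(exp(Eta - M))
  P <- cbind(exp(-M), exp(Eta - M)) / denom
  colnames(P) <- fit$levels
  P
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("binary logistic fit: n =", x$n_used, ", iterations =", x$iterations,
      ", converged =", x$converged, "\n")
  print(data.frame(estimate = x$coefficients, se = x$se, or = x$or,
                   ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value))
  invisible(x)
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat("multinomial logistic fit (reference =", x$reference, "): n =",
      x$n_used, ", converged =", x$converged, "\n")
  for (l in colnames(x$coefficients)) {
    cat("level", l, "\n")
    print(data.frame(estimate = x$coefficients[, l], se = x$se[, l],
                     or = x$or[, l], ci_low = x$ci_low[, l],
                     ci_high = x$ci_high[, l], p = x$p_value[, l]))
  }
  invisible(x)
}
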