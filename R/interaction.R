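# Country-by-factor interaction analysis: nested federated fits, the
# likelihood-ratio test on the interaction block, and per-country hazard
# ratios derived from the full model by the delta method.

#' Fit the nested model pair for one country-by-factor interaction
#'
#' The reduced model is the base specification (which must contain both
#' `country` and `factor` as main effects); the full model adds the
#' country-by-factor interaction block. Both are fitted federatedly on the
#' same cohorts, so they share one event grid and are strictly nested.
#'
#' @param fed A `federation`.
#' @param base_spec Adjustment specification (typically
#'   [multivariable_spec()]).
#' @param factor Cohort variable to interact with country.
#' @param control See [fed_cox_control()].
#' @return List with elements `full` and `reduced` (`fed_cox_fit`s) and
#'   `factor`.
#' @export
fit_interaction_model <- function(fed, base_spec, factor,
                                  control = fed_cox_control()) {
  stopifnot(inherits(base_spec, "fedsurv_spec"))
  if (!factor %in% names(base_spec$blocks))
    stopf("factor '%s' is not a main effect of the base specification", factor)
  if (!"country" %in% names(base_spec$blocks))
    stopf("base specification lacks a 'country' main effect")
  full_spec <- add_interaction(base_spec, factor, with = "country")
  reduced <- fit_federated_cox(fed, base_spec, control)
  full <- fit_federated_cox(fed, full_spec, control)
  list(full = full, reduced = reduced, factor = factor)
}

#' Likelihood-ratio test of nested federated Cox fits
#'
#' `statistic = 2 (ll_full - ll_reduced)` (floored at zero against roundoff)
#' referred to a chi-square with df = the difference in column counts. The
#' test is joint over all interaction columns of the factor.
#'
#' @param full,reduced Converged `fed_cox_fit`s; the reduced model's columns
#'   must be a subset of the full model's, fitted on the same data.
#' @param label Optional factor label carried into the result.
#' @return Object of class `fed_lrt`: `statistic`, `df`, `p_value`, `label`.
#' @export
lrt <- function(full, reduced, label = NULL) {
  stopifnot(inherits(full, "fed_cox_fit"), inherits(reduced, "fed_cox_fit"))
  if (!all(reduced$labels %in% full$labels))
    stopf("models are not nested: reduced has columns the full model lacks")
  if (!identical(reduced$grid$deci, full$grid$deci) ||
      !isTRUE(all.equal(reduced$n, full$n)))
    stopf("models were not fitted on the same data")
  df <- length(full$labels) - length(reduced$labels)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  # identical specifications: a degenerate but well-defined comparison
  p <- if (df == 0) as.numeric(stat <= 1e-8) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 label = label %||% setdiff(full$labels, reduced$labels)[1]),
            class = "fed_lrt")
}

#' @export
print.fed_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test (%s): chi2 = %.4f, df = %d, p = %.4g\n",
              x$label, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-country hazard ratios from an interaction model
#'
#' All hazard ratios are relative to the (reference level, Taiwan) cell:
#' for a factor level l, the Taiwan HR is `exp(beta_l)` and the Netherlands
#' HR is `exp(beta_country + beta_l + beta_country:l)`; standard errors come
#' from the delta method on the coefficient sum (i.e. the variance of
#' `a' beta` under the full covariance).
#'
#' @param full Converged `fed_cox_fit` containing the country-by-factor
#'   interaction block.
#' @param factor The interacted cohort variable.
#' @param level Confidence level.
#' @return Data frame `(country, level, reference, hr, lo, hi)`; the
#'   reference cell has `hr = 1` exactly.
#' @export
country_specific_hrs <- function(full, factor, level = 0.95) {
  stopifnot(inherits(full, "fed_cox_fit"))
  spec <- full$spec
  has <- any(vapply(spec$interactions %||% list(),
                    function(ia) identical(ia, c("country", factor)), TRUE))
  if (!has) stopf("fit has no country x %s interaction block", factor)
  if (is.null(full$var)) stopf("fit carries no covariance matrix")
  z <- stats::qnorm(1 - (1 - level) / 2)
  cb <- spec$blocks[["country"]]
  fb <- spec$blocks[[factor]]
  countries <- cb$levels
  beta <- full$coefficients
  V <- full$var
  p <- length(beta)
  rows <- list()
  for (ctry in countries) {
    for (lvl in fb$levels) {
      a <- stats::setNames(numeric(p), full$labels)
      if (ctry != cb$ref) a[paste0("country=", ctry)] <- 1
      if (lvl != fb$ref) a[paste0(factor, "=", lvl)] <- 1
      if (ctry != cb$ref && lvl != fb$ref)
        a[paste0("country=", ctry, ":", factor, "=", lvl)] <- 1
      est <- sum(a * beta)
      se <- sqrt(drop(t(a) %*% V %*% a))
      ref <- ctry == cb$ref && lvl == fb$ref
      rows[[length(rows) + 1L]] <- data.frame(
        country = ctry, level = lvl, reference = ref,
        hr = if (ref) 1 else exp(est),
        lo = if (ref) NA_real_ else exp(est - z * se),
        hi = if (ref) NA_real_ else exp(est + z * se),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the interaction analysis for several prognostic factors
#'
#' For each factor: fit the nested pair, test the interaction block by
#' likelihood ratio, and tabulate per-country hazard ratios.
#'
#' @param fed A `federation`.
#' @param base_spec Adjustment specification.
#' @param factors Cohort variables to test, one at a time (default: the five
#'   factors examined in the study).
#' @param control See [fed_cox_control()].
#' @return List with `tests` (data frame: factor, statistic, df, p_value)
#'   and `country_hrs` (long data frame across factors).
#' @export
interaction_analysis <- function(fed, base_spec = multivariable_spec(),
                                 factors = c("age_cat", "stage_group",
                                             "grade_cat", "treatment",
                                             "volume_cat"),
                                 control = fed_cox_control()) {
  tests <- list(); hrs <- list()
  for (f in factors) {
    pair <- fit_interaction_model(fed, base_spec, f, control)
    lr <- lrt(pair$full, pair$reduced, label = f)
    tests[[f]] <- data.frame(factor = f, statistic = lr$statistic,
                             df = lr$df, p_value = lr$p_value,
                             stringsAsFactors = FALSE)
    h <- country_specific_hrs(pair$full, f)
    h$factor <- f
    hrs[[f]] <- h
  }
  list(tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       country_hrs = do.call(rbind, c(hrs, make.row.names = FALSE)))
}
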