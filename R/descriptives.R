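# Federated descriptive statistics: frequency tables assembled from
# per-site level counts, between-country chi-square comparisons, and
# federated means from (sum, count) pairs.

#' Federated frequency table for a categorical cohort variable
#'
#' Each node returns only its level counts; the server assembles counts,
#' column percentages and totals. Sites must agree on the level set.
#'
#' @param fed A `federation`.
#' @param variable A categorical cohort variable.
#' @return Object of class `fed_freq_table`: `variable`, `levels`, `counts`
#'   (levels x sites), `pct` (column percentages), `totals`.
#' @export
federated_frequency_table <- function(fed, variable) {
  res <- fed_submit(fed, "level_counts", payload = list(variable = variable))
  counts <- lapply(res, `[[`, "aggregate")
  names(counts) <- vapply(res, `[[`, "", "site_id")
  lev <- names(counts[[1]])
  for (i in seq_along(counts)) {
    if (!identical(names(counts[[i]]), lev)) {
      dif <- union(setdiff(names(counts[[i]]), lev),
                   setdiff(lev, names(counts[[i]])))
      stopf("sites disagree on the levels of '%s': %s", variable,
            paste(dif, collapse = ", "))
    }
  }
  m <- do.call(cbind, counts)
  totals <- colSums(m)
  pct <- sweep(m, 2, ifelse(totals == 0, 1, totals), "/") * 100
  structure(list(variable = variable, levels = lev, counts = m, pct = pct,
                 totals = totals),
            class = "fed_freq_table")
}

#' @export
print.fed_freq_table <- function(x, ...) {
  cat(sprintf("Frequency table: %s\n", x$variable))
  show <- matrix("", nrow(x$counts), ncol(x$counts),
                 dimnames = dimnames(x$counts))
  for (j in seq_len(ncol(x$counts)))
    show[, j] <- sprintf("%d (%.1f%%)", x$counts[, j], x$pct[, j])
  print(as.data.frame(show))
  invisible(x)
}

#' Pearson chi-square test on a frequency table
#'
#' Pearson statistic `sum (O - E)^2 / E` without continuity correction, with
#' expected counts from the row/column margins and
#' `df = (rows - 1)(cols - 1)`.
#'
#' @param table A `fed_freq_table` or a counts matrix (levels x groups).
#' @return Object of class `fed_chisq`: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  m <- if (inherits(table, "fed_freq_table")) table$counts else as.matrix(table)
  keep <- rowSums(m) > 0
  if (!all(keep)) m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stopf("chi-square needs at least a 2 x 2 table with nonzero margins")
  if (any(colSums(m) == 0)) stopf("zero column margin")
  small <- sum(m < 10)
  if (small > 0)
    message(sprintf("chi_square: %d cell(s) with count < 10", small))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value)),
            class = "fed_chisq")
}

#' @export
print.fed_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square: %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Federated mean of a numeric cohort variable
#'
#' Each node returns exactly two scalars, its sum and its non-missing
#' count; the server divides the pooled sum by the pooled count.
#'
#' @param fed A `federation`.
#' @param variable Numeric cohort variable.
#' @return List `mean`, `n`, plus per-site `site_n`.
#' @export
federated_mean <- function(fed, variable) {
  res <- fed_submit(fed, "column_sums", payload = list(variable = variable))
  sums <- vapply(res, function(r) r$aggregate[["sum"]], 0)
  ns <- vapply(res, function(r) r$aggregate[["n"]], 0)
  if (sum(ns) == 0) stopf("no non-missing values of '%s'", variable)
  list(mean = sum(sums) / sum(ns), n = sum(ns),
       site_n = stats::setNames(ns, vapply(res, `[[`, "", "site_id")))
}

#' Descriptive comparison of the sites, one row block per variable
#'
#' Builds federated frequency tables for every categorical cohort variable,
#' attaches the between-site chi-square p-value, and reports the federated
#' mean for numeric variables.
#'
#' @param fed A `federation`.
#' @param variables Categorical variables (default: all cohort factors
#'   except country).
#' @return Data frame in long form: `variable, level`, one count and one
#'   percentage column per site, `p_value` (repeated within variable).
#' @export
describe_cohorts <- function(fed, variables = NULL) {
  dom <- cohort_domains()
  variables <- variables %||% setdiff(names(dom), "country")
  out <- list()
  for (v in variables) {
    ft <- federated_frequency_table(fed, v)
    pv <- tryCatch(chi_square(ft)$p_value, error = function(e) NA_real_)
    df <- data.frame(variable = v, level = ft$levels,
                     stringsAsFactors = FALSE)
    for (s in colnames(ft$counts)) {
      df[[paste0("n_", s)]] <- ft$counts[, s]
      df[[paste0("pct_", s)]] <- round(ft$pct[, s], 1)
    }
    df$p_value <- pv
    out[[v]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
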