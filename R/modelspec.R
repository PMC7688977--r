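#' Canonical categorical domains of an analysis cohort row
#'
#' Every derived cohort table uses the same closed set of categorical
#' variables and levels. The first level of each variable is the reference
#' level used by the default model specifications, matching the reference
#' rows of the published univariable/multivariable hazard-ratio tables
#' (Taiwan, age < 60, female, period 2004-2007, early stage, tongue,
#' well differentiated, primary surgery alone, volume >= 100/year).
#'
#' @return Named list of character vectors; names are cohort variables,
#'   values their ordered levels (reference first).
#' @export
cohort_domains <- function() {
  list(
    country     = c("TW", "NL"),
    age_cat     = c("lt60", "60_69", "ge70"),
    sex         = c("female", "male"),
    period      = c("2004_2007", "2008_2011", "2012_2016"),
    stage_group = c("early", "advanced", "unknown"),
    location    = c("tongue", "lip", "floor_gum", "hard_palate", "buccal_other"),
    grade_cat   = c("well", "moderate", "poor_undiff", "unknown"),
    treatment   = c("surgery_only", "surgery_adjuvant"),
    volume_cat  = c("ge100", "v50_99", "lt50")
  )
}

#' Build a Cox model specification
#'
#' A model specification is an ordered list of covariate blocks, each a
#' categorical variable with an ordered level list and a reference level,
#' plus optional country-by-factor interaction blocks. The design matrix it
#' induces has one 0/1 dummy column per non-reference level per block, in
#' block order, followed by product columns for each interaction block.
#'
#' @param blocks Named list. Each element is either a character vector of
#'   levels (the first is the reference) or a list with elements `levels`
#'   and `ref`. Names are the cohort variables.
#' @param interactions Optional list of two-element character vectors
#'   `c(variable_a, variable_b)`; both must appear in `blocks`. Interaction
#'   dummies are products of the non-reference dummies of the two variables.
#' @param label Short label used in caching and output files.
#' @return An object of class `fedsurv_spec`.
#' @examples
#' spec <- model_spec(list(sex = c("female", "male"),
#'                         age_cat = c("lt60", "60_69", "ge70")))
#' spec_columns(spec)
#' @export
model_spec <- function(blocks, interactions = NULL, label = "model") {
  if (length(blocks) == 0 || is.null(names(blocks)) || any(names(blocks) == ""))
    stopf("'blocks' must be a non-empty named list")
  if (anyDuplicated(names(blocks)))
    stopf("duplicate variable in model specification: %s",
          names(blocks)[duplicated(names(blocks))][1])
  norm <- lapply(names(blocks), function(v) {
    b <- blocks[[v]]
    if (is.character(b)) b <- list(levels = b, ref = b[1])
    if (!all(c("levels", "ref") %in% names(b)))
      stopf("block '%s' needs 'levels' and 'ref'", v)
    if (!b$ref %in% b$levels)
      stopf("reference level '%s' not among levels of '%s'", b$ref, v)
    if (anyDuplicated(b$levels))
      stopf("duplicate levels in block '%s'", v)
    if (length(b$levels) < 2)
      stopf("block '%s' needs at least two levels", v)
    list(variable = v, levels = b$levels, ref = b$ref)
  })
  names(norm) <- names(blocks)
  if (!is.null(interactions)) {
    interactions <- lapply(interactions, function(ia) {
      ia <- as.character(ia)
      if (length(ia) != 2) stopf("an interaction block must pair two variables")
      missing <- setdiff(ia, names(norm))
      if (length(missing))
        stopf("interaction variable '%s' has no main-effect block", missing[1])
      ia
    })
  }
  structure(list(blocks = norm, interactions = interactions, label = label),
            class = "fedsurv_spec")
}

block_dummy_labels <- function(block) {
  lv <- setdiff(block$levels, block$ref)
  paste0(block$variable, "=", lv)
}

#' Column labels of the design matrix induced by a specification
#'
#' @param spec A `fedsurv_spec`.
#' @return Character vector of dummy-column labels, `variable=level` for main
#'   effects and `varA=levA:varB=levB` for interaction columns.
#' @export
spec_columns <- function(spec) {
  stopifnot(inherits(spec, "fedsurv_spec"))
  main <- unlist(lapply(spec$blocks, block_dummy_labels), use.names = FALSE)
  inter <- unlist(lapply(spec$interactions, function(ia) {
    a <- block_dummy_labels(spec$blocks[[ia[1]]])
    b <- block_dummy_labels(spec$blocks[[ia[2]]])
    as.vector(t(outer(a, b, paste, sep = ":")))
  }), use.names = FALSE)
  c(main, inter)
}

#' Add a country-by-factor interaction block to a specification
#'
#' @param spec A `fedsurv_spec` containing main-effect blocks for both
#'   variables.
#' @param variable Factor to interact with `with` (default `"country"`).
#' @param with First variable of the interaction pair.
#' @return A new `fedsurv_spec` with the extra interaction block and a
#'   derived label.
#' @export
add_interaction <- function(spec, variable, with = "country") {
  stopifnot(inherits(spec, "fedsurv_spec"))
  for (v in c(with, variable))
    if (!v %in% names(spec$blocks))
      stopf("variable '%s' has no main-effect block in this specification", v)
  spec$interactions <- c(spec$interactions, list(c(with, variable)))
  spec$label <- paste0(spec$label, "+", with, "x", variable)
  spec
}

#' Default multivariable model specification
#'
#' All nine cohort covariates (country, age, sex, period of diagnosis, stage
#' group, tumour location, grade, treatment, hospital volume) with the
#' canonical reference levels; its design matrix has 18 dummy columns.
#'
#' @return A `fedsurv_spec`.
#' @export
multivariable_spec <- function() {
  model_spec(cohort_domains(), label = "multivariable")
}

#' One single-covariate specification per cohort variable
#'
#' @param variables Cohort variables to include (default: all nine).
#' @return Named list of single-block `fedsurv_spec` objects, used for
#'   univariable (unadjusted) fits.
#' @export
univariable_specs <- function(variables = names(cohort_domains())) {
  dom <- cohort_domains()
  missing <- setdiff(variables, names(dom))
  if (length(missing)) stopf("unknown cohort variable '%s'", missing[1])
  out <- lapply(variables, function(v)
    model_spec(dom[v], label = paste0("uni_", v)))
  names(out) <- variables
  out
}

#' Build the 0/1 design matrix for a cohort under a specification
#'
#' One dummy column per non-reference level per block, in specification
#' order; interaction blocks append products of the paired variables'
#' non-reference dummies. A row with all variables at their reference level
#' maps to the zero row.
#'
#' @param cohort Data frame of cohort rows; must contain every variable
#'   named in `spec`, with values drawn from the block's level list.
#' @param spec A `fedsurv_spec`.
#' @return Numeric matrix with `length(spec_columns(spec))` columns and
#'   labelled colnames.
#' @export
build_design_matrix <- function(cohort, spec) {
  stopifnot(inherits(spec, "fedsurv_spec"), is.data.frame(cohort))
  n <- nrow(cohort)
  block_cols <- lapply(spec$blocks, function(b) {
    v <- b$variable
    if (!v %in% names(cohort)) stopf("cohort has no column '%s'", v)
    x <- as.character(cohort[[v]])
    bad <- which(!x %in% b$levels)
    if (length(bad))
      stopf("row %d: level '%s' of variable '%s' not in specification",
            bad[1], x[bad[1]], v)
    lv <- setdiff(b$levels, b$ref)
    m <- matrix(0, n, length(lv), dimnames = list(NULL, paste0(v, "=", lv)))
    for (j in seq_along(lv)) m[, j] <- as.numeric(x == lv[j])
    m
  })
  names(block_cols) <- names(spec$blocks)
  X <- do.call(cbind, block_cols)
  if (length(spec$interactions)) {
    inter <- lapply(spec$interactions, function(ia) {
      A <- block_cols[[ia[1]]]
      B <- block_cols[[ia[2]]]
      m <- do.call(cbind, lapply(seq_len(ncol(A)), function(i) {
        mm <- A[, i] * B
        colnames(mm) <- paste(colnames(A)[i], colnames(B), sep = ":")
        mm
      }))
      m
    })
    X <- do.call(cbind, c(list(X), inter))
  }
  if (n == 0) X <- matrix(0, 0, length(spec_columns(spec)),
                          dimnames = list(NULL, spec_columns(spec)))
  stopifnot(identical(colnames(X), spec_columns(spec)))
  X
}

#' @export
print.fedsurv_spec <- function(x, ...) {
  cat("Cox model specification '", x$label, "'\n", sep = "")
  for (b in x$blocks)
    cat(sprintf("  %-12s %s (ref %s)\n", b$variable,
                paste(b$levels, collapse = "/"), b$ref))
  for (ia in x$interactions)
    cat(sprintf("  interaction %s x %s\n", ia[1], ia[2]))
  cat(sprintf("  design columns: %d\n", length(spec_columns(x))))
  invisible(x)
}
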