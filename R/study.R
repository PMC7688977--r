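# End-to-end study driver: cohort build -> descriptives -> univariable and
# multivariable fits (per-site and combined, same code path) -> interaction
# analyses, with all outputs and a checksummed run manifest on disk.

write_delim_out <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

hr_rows <- function(fit, column) {
  tab <- hazard_ratios(fit)
  tab$column <- column
  tab
}

# A fit cannot estimate levels the data never observes; keep the
# specification's order and reference but drop unobserved levels (the
# reference falls back to the first observed level when needed). Blocks
# left with a single level are dropped; returns NULL when nothing remains.
prune_spec <- function(spec, cohort) {
  blocks <- lapply(spec$blocks, function(b) {
    seen <- b$levels[b$levels %in% unique(as.character(cohort[[b$variable]]))]
    list(levels = seen, ref = if (b$ref %in% seen) b$ref else seen[1])
  })
  names(blocks) <- names(spec$blocks)
  blocks <- Filter(function(b) length(b$levels) >= 2, blocks)
  if (length(blocks) == 0) return(NULL)
  model_spec(blocks, label = paste0(spec$label, "_obs"))
}

# Same pruning for a whole federation, using only aggregate level counts.
prune_spec_federated <- function(spec, fed) {
  blocks <- lapply(spec$blocks, function(b) {
    ft <- federated_frequency_table(fed, b$variable)
    seen <- b$levels[b$levels %in% ft$levels[rowSums(ft$counts) > 0]]
    list(levels = seen, ref = if (b$ref %in% seen) b$ref else seen[1])
  })
  names(blocks) <- names(spec$blocks)
  blocks <- Filter(function(b) length(b$levels) >= 2, blocks)
  if (length(blocks) == 0) return(NULL)
  model_spec(blocks, label = paste0(spec$label, "_obs"))
}

#' Run the full federated study on per-site registry extracts
#'
#' Stages: (1) load or simulate raw registries; (2) build each site's
#' analysis cohort (selection filters, survival, covariates, hospital
#' volume), writing cohorts and exclusion logs; (3) federated descriptive
#' table with between-site chi-square p-values; (4) univariable fits --
#' per-site fits are single-site federations and the combined column a
#' multi-site federation, all through the same code path, unadjusted; (5)
#' the combined multivariable fit (all covariate blocks); (6)
#' country-by-factor interaction analyses. Any stage error aborts with the
#' stage name after persisting a partial manifest.
#'
#' @param config List with either `sim` (a [sim_config()]) or `sites` (named
#'   character vector of registry file paths), plus optional `cutoff`,
#'   `factors` (interaction factors), `control` (see [fed_cox_control()]).
#'   A path to a YAML file with a `sim` block is also accepted.
#' @param out_dir Output directory (created if needed).
#' @return A run-manifest list (also written as `manifest.json`).
#' @export
run_study <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$sim)) {
      # YAML 1.1 reads a bare `n:` key as boolean FALSE; undo that
      nm <- names(cfg$sim)
      nm[nm == "FALSE"] <- "n"
      names(cfg$sim) <- nm
      cfg$sim <- do.call(sim_config, cfg$sim)
    }
    config <- cfg
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cutoff <- as.Date(config$cutoff %||% "2019-01-31")
  control <- config$control %||% fed_cox_control()
  factors <- config$factors %||% c("age_cat", "stage_group", "grade_cat",
                                   "treatment", "volume_cat")
  manifest <- list(
    package = "fedsurv",
    version = as.character(utils::packageVersion("fedsurv")),
    seed = config$sim$seed %||% NA,
    year_length_days = 365.25,
    time_rounding = "half-away-from-zero to one decimal year",
    cutoff = as.character(cutoff),
    stages = list(), outputs = character()
  )
  stage <- "setup"
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on_fail <- function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    persist()
    stopf("study aborted in stage '%s': %s", stage, conditionMessage(e))
  }
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    invisible(path)
  }
  tryCatch({
    stage <- "load"
    registries <- if (!is.null(config$sim)) generate_registry(config$sim)
    else {
      stopifnot(!is.null(config$sites), !is.null(names(config$sites)))
      lapply(config$sites, read_registry)
    }
    manifest$stages$load <- list(sites = names(registries),
                                 n_raw = vapply(registries, nrow, 0L))

    stage <- "cohort"
    cohorts <- list()
    for (cn in names(registries)) {
      co <- build_cohort(registries[[cn]], country = cn, cutoff = cutoff)
      add_output(write_delim_out(co, file.path(out_dir,
                                               paste0("cohort_", cn, ".csv"))))
      add_output(write_delim_out(exclusion_log(co),
                                 file.path(out_dir,
                                           paste0("exclusions_", cn, ".csv"))))
      cohorts[[cn]] <- co
    }
    manifest$stages$cohort <- list(
      n = vapply(cohorts, nrow, 0L),
      n_excluded = vapply(cohorts, function(x) nrow(exclusion_log(x)), 0L))

    stage <- "descriptives"
    fed <- federation(cohorts, audit_file = file.path(out_dir, "audit.jsonl"))
    add_output(file.path(out_dir, "audit.jsonl"))
    desc <- describe_cohorts(fed)
    add_output(write_delim_out(desc, file.path(out_dir, "table1.csv")))

    stage <- "univariable"
    unis <- univariable_specs()
    uni_rows <- list()
    for (v in names(unis)) {
      if (v != "country") {
        for (cn in names(cohorts)) {
          sp <- prune_spec(unis[[v]], cohorts[[cn]])
          if (is.null(sp)) next  # no variation at this site
          one <- federation(cohorts[cn])
          f <- fit_federated_cox(one, sp, control)
          uni_rows[[paste(v, cn)]] <- hr_rows(f, cn)
        }
      }
      sp <- prune_spec_federated(unis[[v]], fed)
      if (is.null(sp)) next
      fc <- fit_federated_cox(fed, sp, control)
      uni_rows[[paste(v, "combined")]] <- hr_rows(fc, "combined")
    }
    uni <- do.call(rbind, c(uni_rows, make.row.names = FALSE))
    add_output(write_delim_out(uni, file.path(out_dir,
                                              "table2_univariable.csv")))

    stage <- "multivariable"
    mspec <- prune_spec_federated(multivariable_spec(), fed)
    if (is.null(mspec)) stopf("no estimable covariate in the pooled cohort")
    multi_rows <- list()
    site_mspec <- model_spec(cohort_domains()[setdiff(names(cohort_domains()),
                                                      "country")],
                             label = "multivariable_site")
    for (cn in names(cohorts)) {
      sp <- prune_spec(site_mspec, cohorts[[cn]])
      if (is.null(sp)) next
      one <- federation(cohorts[cn])
      f <- fit_federated_cox(one, sp, control)
      multi_rows[[cn]] <- hr_rows(f, cn)
    }
    mfit <- fit_federated_cox(fed, mspec, control)
    multi_rows$combined <- hr_rows(mfit, "combined")
    add_output(write_delim_out(
      do.call(rbind, c(multi_rows, make.row.names = FALSE)),
      file.path(out_dir, "table3_multivariable.csv")))
    manifest$stages$multivariable <- list(
      columns = length(spec_columns(mspec)),
      iterations = mfit$iterations, converged = mfit$converged,
      loglik = mfit$loglik, loglik_null = mfit$loglik_null,
      criterion = control$criterion, tol = control$tol)

    stage <- "interactions"
    factors <- intersect(factors, names(mspec$blocks))
    ia <- interaction_analysis(fed, mspec, factors, control)
    add_output(write_delim_out(ia$tests, file.path(out_dir,
                                                   "interactions.csv")))
    add_output(write_delim_out(ia$country_hrs,
                               file.path(out_dir, "country_hrs.csv")))

    stage <- "audit"
    aud <- audit_report(fed)
    manifest$stages$audit <- list(payloads = nrow(aud),
                                  all_pass = all(aud$pass))

    stage <- "manifest"
    sums <- tools::md5sum(manifest$outputs)
    manifest$checksums <- as.list(sums)
    persist()
    manifest
  }, error = on_fail)
}
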