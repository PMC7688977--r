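# Shared fixtures, built in code.

# Three-patient toy site: times 1.0 (event), 2.0 (event), 3.0 (censored),
# scalar covariate z = 1, 0, 1. Risk sets: {1,2,3} at t=1, {2,3} at t=2.
toy_site <- function() {
  list(time = c(1.0, 2.0, 3.0), event = c(1L, 1L, 0L),
       X = matrix(c(1, 0, 1), ncol = 1, dimnames = list(NULL, "z")))
}

toy_cohort <- function() {
  data.frame(time = c(1.0, 2.0, 3.0), event = c(1L, 1L, 0L),
             z = factor(c("b", "a", "b"), levels = c("a", "b")))
}

# Default category probabilities with the hospital-volume profile collapsed
# to the < 50 stratum, so small simulated cohorts are feasible; used by
# tests whose model does not involve hospital volume.
lt50_probs <- function() {
  probs <- fedsurv:::default_category_probs()
  for (cn in names(probs))
    probs[[cn]]$volume <- c(ge100 = 0, v50_99 = 0, lt50 = 1)
  probs
}

# A small raw-registry row with valid defaults; override fields as needed.
make_record <- function(..., id = "r1") {
  rec <- list(patient_id = id, record_id = id, tumour_sequence = 1L,
              topography = "C02.1", morphology = 8070L,
              diagnosis_date = "2010-06-15", vital_status = "alive",
              end_date = "2018-06-15", sex = "male", age_at_diagnosis = 55L,
              stage = "I", grade = "well", treatment = "surgery_only",
              hospital_id = "H1", surgery = TRUE)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# n=2000 two-registry configuration under the default (study-shaped)
# marginals; the NL/TW split keeps every volume stratum feasible.
study_scaled_config <- function(seed, n = c(NL = 1100, TW = 900), ...) {
  sim_config(n = n, seed = seed, ...)
}

cohort_columns <- function() {
  c("time", "event", "country", "age_cat", "sex", "period", "stage_group",
    "location", "grade_cat", "treatment", "volume_cat")
}

pooled_cohort <- function(cohorts) {
  do.call(rbind, c(lapply(cohorts, function(x) x[cohort_columns()]),
                   make.row.names = FALSE))
}
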