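# Synthetic two-registry generator. Emulates the categorical structure of
# the published two-country cohort (per-country marginal frequencies) with
# survival times drawn from a proportional-hazards model with exponential
# (optionally Weibull) baseline, administrative censoring at the follow-up
# cutoff, and hospital-year cells constructed so that the derived
# hospital-volume categories land in a configured volume profile.
# Covariates are drawn independently per variable: only marginals of the
# real registries are emulated, not their joint distribution.

# Per-country marginal probabilities proportional to the published
# patient-characteristics table (counts over 7,766 NL / 33,867 TW cases).
default_category_probs <- function() {
  pr <- function(x) x / sum(x)
  list(
    NL = list(
      age_cat   = pr(c(lt60 = 2709, `60_69` = 2542, ge70 = 2515)),
      sex       = pr(c(female = 3410, male = 4356)),
      period    = pr(c(`2004_2007` = 2148, `2008_2011` = 2400,
                       `2012_2016` = 3218)),
      stage     = pr(c(I = 3392, II = 1220, III = 827, IVA = 2208,
                       IVB = 64, IVC = 17, unknown = 38)),
      location  = pr(c(tongue = 3215, lip = 114, floor_gum = 3234,
                       hard_palate = 117, buccal_other = 1086)),
      grade_cat = pr(c(well = 1183, moderate = 4084, poor_undiff = 1075,
                       unknown = 1424)),
      treatment = pr(c(surgery_only = 4876, surgery_adjuvant = 2890)),
      volume    = pr(c(ge100 = 740, v50_99 = 2560, lt50 = 4466))
    ),
    TW = list(
      age_cat   = pr(c(lt60 = 24493, `60_69` = 6196, ge70 = 3178)),
      sex       = pr(c(female = 2954, male = 30913)),
      period    = pr(c(`2004_2007` = 7873, `2008_2011` = 10528,
                       `2012_2016` = 15466)),
      stage     = pr(c(I = 11239, II = 6918, III = 3946, IVA = 10269,
                       IVB = 969, IVC = 81, unknown = 445)),
      location  = pr(c(tongue = 12282, lip = 728, floor_gum = 5049,
                       hard_palate = 636, buccal_other = 15172)),
      grade_cat = pr(c(well = 11285, moderate = 17677, poor_undiff = 2355,
                       unknown = 2550)),
      treatment = pr(c(surgery_only = 18570, surgery_adjuvant = 15297)),
      volume    = pr(c(ge100 = 21603, v50_99 = 6992, lt50 = 5272))
    )
  )
}

# True log hazard ratios aligned with the default multivariable
# specification; defaults are the log of the combined-cohort multivariable
# hazard ratios of the study the generator emulates.
default_true_loghr <- function(spec = multivariable_spec()) {
  hr <- c(
    "country=NL" = 1.06,
    "age_cat=60_69" = 1.31, "age_cat=ge70" = 2.40,
    "sex=male" = 1.23,
    "period=2008_2011" = 0.85, "period=2012_2016" = 0.73,
    "stage_group=advanced" = 2.19, "stage_group=unknown" = 1.46,
    "location=lip" = 1.06, "location=floor_gum" = 1.01,
    "location=hard_palate" = 1.30, "location=buccal_other" = 1.00,
    "grade_cat=moderate" = 1.38, "grade_cat=poor_undiff" = 1.92,
    "grade_cat=unknown" = 1.24,
    "treatment=surgery_adjuvant" = 1.40,
    "volume_cat=v50_99" = 1.01, "volume_cat=lt50" = 1.13
  )
  log(hr[spec_columns(spec)])
}

#' Configuration of the synthetic two-registry generator
#'
#' Defaults reproduce the study conditions: per-country cohort sizes equal
#' to the published registry sizes, category probabilities proportional to
#' the published per-country frequency table, true log hazard ratios equal
#' to the log of the published combined multivariable hazard ratios, an
#' exponential baseline hazard, and administrative censoring at the
#' 2019-01-31 follow-up cutoff.
#'
#' @param n Named integer vector of per-country cohort sizes.
#' @param probs Per-country category probabilities (see
#'   `fedsurv:::default_category_probs` for the shape).
#' @param spec Truth-alignment specification; `beta` is named by its design
#'   columns.
#' @param beta True log hazard ratios, named by `spec_columns(spec)`.
#' @param rate Baseline hazard rate per year for a reference-level patient
#'   (default 0.06/year, i.e. about 26% baseline mortality at 5 years,
#'   a plausible scale for a surgically treated cohort).
#' @param baseline `"exponential"` or `"weibull"`.
#' @param weibull_shape Shape when `baseline = "weibull"`.
#' @param cutoff Follow-up cutoff date; each patient is censored at the
#'   earlier of `horizon` years and the cutoff.
#' @param horizon Optional extra censoring horizon in years (default none:
#'   censoring is driven by the diagnosis date and the cutoff).
#' @param age_stage_logodds Dependence hook (default 0 = independent
#'   draws, the study-shaped setting): log-odds shift towards advanced
#'   stage applied in full to patients 70+ and at half strength to ages
#'   60-69, for stress-testing covariate dependence.
#' @param n_contaminants Per-country count of deliberately invalid records
#'   (wrong morphology/topography/year/sequence/no surgery) added to
#'   exercise the selection filters and exclusion log.
#' @param seed Optional RNG seed; a fixed seed makes generation
#'   byte-identical.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = c(NL = 7766, TW = 33867),
                       probs = default_category_probs(),
                       spec = multivariable_spec(),
                       beta = default_true_loghr(spec),
                       rate = 0.06,
                       baseline = c("exponential", "weibull"),
                       weibull_shape = 1,
                       cutoff = as.Date("2019-01-31"),
                       horizon = NULL,
                       age_stage_logodds = 0,
                       n_contaminants = 0L,
                       seed = NULL) {
  baseline <- match.arg(baseline)
  # tolerate YAML/JSON-shaped input (named lists instead of vectors)
  if (is.list(n)) n <- unlist(n)
  probs <- lapply(probs, function(cp) lapply(cp, unlist))
  stopifnot(length(n) >= 1, !is.null(names(n)), all(n >= 1), rate > 0,
            inherits(spec, "fedsurv_spec"))
  if (!all(names(n) %in% names(probs)))
    stopf("no category probabilities for country '%s'",
          setdiff(names(n), names(probs))[1])
  if (!identical(names(beta), spec_columns(spec)))
    stopf("names(beta) must equal spec_columns(spec)")
  for (cn in names(n)) for (v in names(probs[[cn]])) {
    p <- probs[[cn]][[v]]
    if (abs(sum(p) - 1) > 1e-8)
      stopf("probabilities for %s/%s do not sum to 1", cn, v)
  }
  structure(list(n = n, probs = probs, spec = spec, beta = beta, rate = rate,
                 baseline = baseline, weibull_shape = weibull_shape,
                 cutoff = as.Date(cutoff), horizon = horizon,
                 age_stage_logodds = age_stage_logodds,
                 n_contaminants = n_contaminants, seed = seed),
            class = "sim_config")
}

# Split n into k parts differing by at most one.
split_sizes <- function(n, k) {
  sz <- rep(n %/% k, k)
  if (n %% k > 0) sz[seq_len(n %% k)] <- sz[seq_len(n %% k)] + 1L
  sz
}

# Build hospital-year cells realising the volume profile: cells of size
# <= 49 for the lt50 stratum, 50-99 for v50_99, >= 100 for ge100. Each cell
# is one (hospital, diagnosis-year) pair; the cell's year is drawn from the
# period distribution. Errors when a requested stratum cannot be realised.
assign_hospitals <- function(country, stratum, period_probs) {
  n_all <- length(stratum)
  hospital <- character(n_all)
  year <- integer(n_all)
  period_bins <- list(`2004_2007` = 2004:2007, `2008_2011` = 2008:2011,
                      `2012_2016` = 2012:2016)
  draw_year <- function(k) {
    bin <- sample(names(period_probs), k, TRUE, period_probs)
    vapply(bin, function(b) sample(period_bins[[b]], 1L), 0L)
  }
  for (st in unique(stratum)) {
    idx <- which(stratum == st)
    ns <- length(idx)
    k <- switch(st,
      lt50 = ceiling(ns / 49),
      v50_99 = {
        if (ns < 50)
          stopf("infeasible volume profile: %d patients cannot fill a 50-99 hospital-year cell", ns)
        ceiling(ns / 99)
      },
      ge100 = {
        k0 <- ns %/% 100
        if (k0 == 0)
          stopf("infeasible volume profile: %d patients cannot fill a >=100 hospital-year cell", ns)
        k0
      },
      stopf("unknown volume stratum '%s'", st))
    sizes <- split_sizes(ns, k)
    if (st == "v50_99" && any(sizes < 50 | sizes > 99))
      stopf("infeasible volume profile for the 50-99 stratum (n = %d)", ns)
    idx <- sample(idx)
    years <- draw_year(k)
    off <- 0L
    for (ci in seq_len(k)) {
      cell <- idx[(off + 1L):(off + sizes[ci])]
      hospital[cell] <- sprintf("%s_%s_H%03d", country, st, ci)
      year[cell] <- years[ci]
      off <- off + sizes[ci]
    }
  }
  list(hospital = hospital, year = year)
}

# Draw raw per-patient attributes for one country.
draw_country <- function(country, n, probs, cutoff, age_stage_logodds = 0) {
  draw <- function(p) factor(sample(names(p), n, TRUE, p), levels = names(p))
  age_cat <- draw(probs$age_cat)
  age <- integer(n)
  age[age_cat == "lt60"] <- sample(25:59, sum(age_cat == "lt60"), TRUE)
  age[age_cat == "60_69"] <- sample(60:69, sum(age_cat == "60_69"), TRUE)
  age[age_cat == "ge70"] <- sample(70:94, sum(age_cat == "ge70"), TRUE)
  # volume strata by largest-remainder quota: the realized profile is exact
  # and feasibility depends on n alone, not on sampling noise
  quota <- floor(n * probs$volume)
  rem <- n * probs$volume - quota
  short <- n - sum(quota)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    quota[top] <- quota[top] + 1
  }
  stratum <- sample(rep(names(probs$volume), quota))
  hosp <- assign_hospitals(country, stratum, probs$period)
  doy <- sample(0:364, n, TRUE)
  diagnosis_date <- as.Date(sprintf("%d-01-01", hosp$year)) + doy
  diagnosis_date <- pmin(diagnosis_date, cutoff - 1L)
  stage <- if (age_stage_logodds == 0) draw(probs$stage) else {
    adv <- names(probs$stage) %in% c("III", "IVA", "IVB", "IVC")
    tilt <- c(lt60 = 0, `60_69` = 0.5, ge70 = 1) * age_stage_logodds
    lev <- vapply(seq_len(n), function(i) {
      p <- probs$stage * ifelse(adv, exp(tilt[[as.character(age_cat[i])]]), 1)
      sample(names(probs$stage), 1L, prob = p / sum(p))
    }, "")
    factor(lev, levels = names(probs$stage))
  }
  data.frame(
    country = country,
    age = age, age_cat = age_cat,
    sex = draw(probs$sex),
    stage = stage,
    location = draw(probs$location),
    grade_cat = draw(probs$grade_cat),
    treatment = draw(probs$treatment),
    volume_cat = factor(stratum, levels = names(probs$volume)),
    hospital_id = hosp$hospital,
    diagnosis_date = diagnosis_date,
    stringsAsFactors = FALSE
  )
}

# Proportional-hazards event times for linear predictor lp.
draw_event_times <- function(lp, rate, baseline, shape) {
  n <- length(lp)
  u <- stats::runif(n)
  h <- rate * exp(lp)
  if (baseline == "exponential") -log(u) / h
  else (-log(u) / h)^(1 / shape)   # Weibull with H0(t) = rate * t^shape
}

sim_cohort_frame <- function(raw, config) {
  dom <- cohort_domains()
  year <- as.integer(format(raw$diagnosis_date, "%Y"))
  cohort <- data.frame(
    country = factor(raw$country, levels = dom$country),
    age_cat = factor(as.character(raw$age_cat), levels = dom$age_cat),
    sex = factor(as.character(raw$sex), levels = dom$sex),
    period = cut(year, c(-Inf, 2007, 2011, Inf), labels = dom$period),
    stage_group = stage_group_of(raw$stage),
    location = factor(as.character(raw$location), levels = dom$location),
    grade_cat = factor(as.character(raw$grade_cat), levels = dom$grade_cat),
    treatment = factor(as.character(raw$treatment), levels = dom$treatment),
    volume_cat = factor(as.character(raw$volume_cat), levels = dom$volume_cat)
  )
  X <- build_design_matrix(cohort, config$spec)
  lp <- drop(X %*% config$beta)
  T <- draw_event_times(lp, config$rate, config$baseline, config$weibull_shape)
  hmax <- years_between(raw$diagnosis_date, config$cutoff)
  if (!is.null(config$horizon)) hmax <- pmin(hmax, config$horizon)
  event <- as.integer(T <= hmax)
  cbind(data.frame(time = round1(pmin(T, hmax)), event = event),
        cohort,
        data.frame(T_latent = T, diagnosis_date = raw$diagnosis_date,
                   hospital_id = raw$hospital_id, age = raw$age,
                   stage = raw$stage))
}

#' Generate per-country synthetic analysis cohorts
#'
#' Draws covariates independently per variable from the per-country
#' probabilities, assigns hospital-year cells realising the volume profile,
#' and draws proportional-hazards survival censored at the follow-up
#' cutoff. The returned tables are ready for [federation()].
#'
#' @param config A [sim_config()].
#' @return Named list of cohort data frames (one per country) with a
#'   `truth` attribute (see [known_truth()]). The frames carry auxiliary
#'   columns (`T_latent`, `diagnosis_date`, `hospital_id`, `age`, `stage`)
#'   beyond the analysis columns.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- lapply(names(config$n), function(cn) {
    raw <- draw_country(cn, config$n[[cn]], config$probs[[cn]], config$cutoff,
                        config$age_stage_logodds %||% 0)
    sim_cohort_frame(raw, config)
  })
  names(out) <- names(config$n)
  attr(out, "truth") <- known_truth(config)
  out
}

topo_codes <- list(
  lip = c("C00.3", "C00.4", "C00.5"),
  tongue = paste0("C02.", c(0, 1, 2, 3, 8, 9)),
  floor_gum = c("C03.0", "C03.1", "C03.9", "C04.0", "C04.1", "C04.8", "C04.9"),
  hard_palate = c("C05.0", "C05.8", "C05.9"),
  buccal_other = paste0("C06.", c(0, 1, 2, 8, 9))
)

contaminant_records <- function(country, k, start_id) {
  kinds <- c("morphology", "topography", "year", "sequence", "surgery")
  kind <- rep_len(kinds, k)
  data.frame(
    patient_id = sprintf("%s_BAD%05d", country, seq_len(k) + start_id),
    record_id = sprintf("%s_BAD%05d", country, seq_len(k) + start_id),
    tumour_sequence = ifelse(kind == "sequence", 2L, 1L),
    topography = ifelse(kind == "topography", "C05.1", "C02.1"),
    morphology = ifelse(kind == "morphology", 8090L, 8070L),
    diagnosis_date = as.character(
      as.Date(ifelse(kind == "year", "2003-06-01", "2010-06-01"))),
    vital_status = "alive",
    end_date = "2019-01-01",
    sex = "male", age_at_diagnosis = 55L, stage = "I", grade = "well",
    treatment = "surgery_only", hospital_id = paste0(country, "_bad_H1"),
    surgery = kind != "surgery",
    stringsAsFactors = FALSE
  )
}

#' Generate per-country synthetic raw registry extracts
#'
#' Converts the simulated cohorts into dated patient records (topography
#' codes sampled within location groups, morphology uniform in 8050-8089,
#' end dates from the censored survival times) so the whole cohort pipeline
#' ([build_cohort()]) can run end-to-end. Optional contaminant records
#' violate one selection filter each.
#'
#' @param config A [sim_config()].
#' @return Named list of raw registry data frames with a `truth` attribute.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cohorts <- generate_cohorts(config)
  out <- lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    n <- nrow(co)
    topo <- vapply(as.character(co$location), function(g)
      sample(topo_codes[[g]], 1L), "")
    hmax <- years_between(co$diagnosis_date, config$cutoff)
    if (!is.null(config$horizon)) hmax <- pmin(hmax, config$horizon)
    end_date <- co$diagnosis_date + round(pmin(co$T_latent, hmax) * 365.25)
    end_date <- pmin(end_date, config$cutoff)
    rec <- data.frame(
      patient_id = sprintf("%s%06d", cn, seq_len(n)),
      record_id = sprintf("%s%06d", cn, seq_len(n)),
      tumour_sequence = 1L,
      topography = topo,
      morphology = sample(8050:8089, n, TRUE),
      diagnosis_date = as.character(co$diagnosis_date),
      vital_status = ifelse(co$event == 1, "dead", "alive"),
      end_date = as.character(end_date),
      sex = as.character(co$sex),
      age_at_diagnosis = co$age,
      stage = as.character(co$stage),
      grade = as.character(co$grade_cat),
      treatment = as.character(co$treatment),
      hospital_id = co$hospital_id,
      surgery = TRUE,
      stringsAsFactors = FALSE
    )
    k <- if (length(config$n_contaminants) > 1)
      config$n_contaminants[[cn]] else config$n_contaminants
    if (k > 0) rec <- rbind(rec, contaminant_records(cn, k, n))
    rec
  })
  names(out) <- names(cohorts)
  attr(out, "truth") <- attr(cohorts, "truth")
  out
}

#' True hazard ratios of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Data frame `(label, log_hr, hr)` aligned with the configuration's
#'   model specification, for parameter-recovery assertions.
#' @export
known_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(label = names(config$beta), log_hr = unname(config$beta),
             hr = exp(unname(config$beta)), stringsAsFactors = FALSE)
}
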