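# Registry records -> analysis cohort: selection filters, survival
# derivation, covariate coding, hospital-volume categories.

patient_record_columns <- function() {
  c("patient_id", "tumour_sequence", "topography", "morphology",
    "diagnosis_date", "vital_status", "end_date", "sex", "age_at_diagnosis",
    "stage", "grade", "treatment", "hospital_id", "surgery")
}

# Normalise an ICD-O-3 topography code to dot-free form ("C02.1" -> "C021").
# Returns NA for anything that does not look like a C-code.
normalize_topography <- function(code) {
  x <- toupper(gsub("[[:space:].]", "", as.character(code)))
  ok <- grepl("^C[0-9]{2}[0-9]?$", x)
  x[!ok] <- NA_character_
  x
}

# Map normalised topography codes to the study's location groups.
# Matching is prefix-based at the 3-character level for C02/C03/C04/C06 and
# exact at 4 characters for the enumerated lip (C00.3-5) and hard-palate
# (C05.0/.8/.9) subsites; anything else (e.g. soft palate C05.1) is excluded.
topography_location <- function(code_norm) {
  three <- substr(code_norm, 1, 3)
  out <- rep(NA_character_, length(code_norm))
  out[code_norm %in% c("C003", "C004", "C005")] <- "lip"
  out[three == "C02"] <- "tongue"
  out[three %in% c("C03", "C04")] <- "floor_gum"
  out[code_norm %in% c("C050", "C058", "C059")] <- "hard_palate"
  out[three == "C06"] <- "buccal_other"
  out[is.na(code_norm)] <- NA_character_
  out
}

record_ids <- function(records) {
  if (!is.null(records$record_id)) as.character(records$record_id)
  else sprintf("row%06d", seq_len(nrow(records)))
}

as_record_date <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d)) stopf("unparseable %s (ISO-8601 dates expected)", what)
  d
}

#' Apply the study's cohort-selection filters to raw registry records
#'
#' Retains surgically treated first-primary oral-cavity squamous cell
#' carcinomas: topography in C00.3-5, C02, C03, C04, C05.0/.8/.9, C06;
#' morphology 8050-8089; diagnosis year 2004-2016; `surgery` true;
#' `tumour_sequence == 1`; and at most one record per patient (earliest
#' diagnosis date, ties broken by lexicographically smallest record id).
#' Records with unparseable topography are rejected record-by-record and
#' logged, never crash the run.
#'
#' @param records Data frame of raw registry rows (see
#'   [patient_record_columns()]); an optional `record_id` column is used in
#'   the exclusion log.
#' @param year_range Inclusive diagnosis-year window.
#' @param morphology_range Inclusive ICD-O-3 morphology window.
#' @return The retained rows, with an `exclusions` attribute: a data frame
#'   `(record_id, reason)` giving each dropped record's first failed rule
#'   (see [exclusion_log()]).
#' @export
select_cohort <- function(records, year_range = c(2004L, 2016L),
                          morphology_range = c(8050L, 8089L)) {
  stopifnot(is.data.frame(records))
  need <- setdiff(c("patient_id", "tumour_sequence", "topography",
                    "morphology", "diagnosis_date", "surgery"),
                  names(records))
  if (length(need)) stopf("records lack column '%s'", need[1])
  ids <- record_ids(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  topo <- normalize_topography(records$topography)
  loc <- topography_location(topo)
  diag_date <- as_record_date(records$diagnosis_date, "diagnosis_date")
  year <- as.integer(format(diag_date, "%Y"))
  morph <- as.integer(records$morphology)
  surgery <- as.logical(records$surgery)

  mark <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    hit <- bad & is.na(reason)
    reason[hit] <<- why
  }
  mark(is.na(topo), "topography_unparseable")
  mark(!is.na(topo) & is.na(loc), "topography_not_included")
  mark(is.na(morph) | morph < morphology_range[1] | morph > morphology_range[2],
       "morphology_out_of_range")
  mark(year < year_range[1] | year > year_range[2], "diagnosis_year_out_of_range")
  mark(is.na(surgery) | !surgery, "no_surgery")
  mark(as.integer(records$tumour_sequence) != 1L, "not_first_primary")

  # first-primary dedup: earliest diagnosis, tie -> smallest record id
  keep <- which(is.na(reason))
  if (length(keep)) {
    ord <- keep[order(as.character(records$patient_id[keep]),
                      diag_date[keep], ids[keep])]
    dup <- ord[duplicated(as.character(records$patient_id[ord]))]
    reason[dup] <- "duplicate_patient"
  }

  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  excl <- data.frame(record_id = ids[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  attr(kept, "exclusions") <- excl
  kept
}

#' Exclusion log of a cohort selection
#'
#' @param x Result of [select_cohort()] or [build_cohort()].
#' @return Data frame `(record_id, reason)`, one row per dropped record.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions") %||%
    data.frame(record_id = character(), reason = character())
}

#' Derive follow-up time and event indicator
#'
#' Survival runs from diagnosis to death or last follow-up, administratively
#' censored at `cutoff` (the information horizon: an end date recorded after
#' the cutoff censors the record at the cutoff regardless of vital status).
#' Raw time in days is converted with a 365.25-day year and rounded
#' half-away-from-zero to one decimal.
#'
#' @param records Selected registry rows.
#' @param cutoff Follow-up cutoff date (`Date` or ISO string); default the
#'   study horizon 2019-01-31.
#' @return Data frame `(time, event)`; `time` a nonnegative multiple of 0.1
#'   year, `event` 1 for an observed death on or before the cutoff.
#' @export
derive_survival <- function(records, cutoff = as.Date("2019-01-31")) {
  cutoff <- as_record_date(cutoff, "cutoff")
  diag_date <- as_record_date(records$diagnosis_date, "diagnosis_date")
  end_date <- as_record_date(records$end_date, "end_date")
  if (any(end_date < diag_date))
    stopf("end_date precedes diagnosis_date for record %s",
          record_ids(records)[which(end_date < diag_date)[1]])
  if (any(diag_date > cutoff))
    stopf("diagnosis after the follow-up cutoff for record %s",
          record_ids(records)[which(diag_date > cutoff)[1]])
  vital <- as.character(records$vital_status)
  event <- as.integer(vital == "dead" & end_date <= cutoff)
  time <- round1(years_between(diag_date, pmin(end_date, cutoff)))
  data.frame(time = time, event = event)
}

stage_group_of <- function(stage) {
  stage <- as.character(stage)
  out <- rep("unknown", length(stage))
  out[stage %in% c("I", "II")] <- "early"
  out[stage %in% c("III", "IVA", "IVB", "IVC")] <- "advanced"
  factor(out, levels = cohort_domains()$stage_group)
}

#' Code the categorical covariates of selected records
#'
#' Age bins (<60, 60-69, >=70), period of diagnosis (2004-2007, 2008-2011,
#' 2012-2016), stage group (early = I-II, advanced = III-IVC, otherwise
#' unknown -- unknown is an explicit analysis level, never dropped), location
#' group from topography, grade and treatment passed through as factors.
#'
#' @param records Selected registry rows.
#' @return Data frame of factor columns `age_cat, sex, period, stage_group,
#'   location, grade_cat, treatment` with canonical levels.
#' @export
categorize <- function(records) {
  dom <- cohort_domains()
  age <- as.integer(records$age_at_diagnosis)
  age_cat <- cut(age, c(-Inf, 59, 69, Inf), labels = dom$age_cat)
  year <- as.integer(format(as_record_date(records$diagnosis_date,
                                           "diagnosis_date"), "%Y"))
  period <- cut(year, c(-Inf, 2007, 2011, Inf), labels = dom$period)
  loc <- topography_location(normalize_topography(records$topography))
  chk <- function(x, lev, what) {
    bad <- which(!as.character(x) %in% lev)
    if (length(bad)) stopf("record %s: '%s' is not a valid %s",
                           record_ids(records)[bad[1]], x[bad[1]], what)
    factor(as.character(x), levels = lev)
  }
  data.frame(
    age_cat = age_cat,
    sex = chk(records$sex, dom$sex, "sex"),
    period = period,
    stage_group = stage_group_of(records$stage),
    location = chk(loc, dom$location, "location"),
    grade_cat = chk(records$grade, dom$grade_cat, "grade"),
    treatment = chk(records$treatment, dom$treatment, "treatment")
  )
}

#' Hospital-volume category per record
#'
#' Volume is the number of retained oral-cavity-cancer surgeries performed
#' in the treating hospital in the patient's diagnosis year, computed within
#' one registry (never across registries), categorised < 50 / 50-99 / >= 100
#' per year.
#'
#' @param records One site's selected registry rows.
#' @return Factor `lt50/v50_99/ge100`, one value per record.
#' @export
compute_hospital_volume <- function(records) {
  year <- format(as_record_date(records$diagnosis_date, "diagnosis_date"), "%Y")
  key <- paste(records$hospital_id, year, sep = "\r")
  n <- ave(rep(1L, nrow(records)), key, FUN = sum)
  cut(n, c(-Inf, 49, 99, Inf), labels = c("lt50", "v50_99", "ge100"))
}

#' Build one site's analysis cohort from raw registry records
#'
#' Runs selection, survival derivation, covariate coding and hospital-volume
#' categorisation, and attaches the site's country label.
#'
#' @param records Raw registry rows for one site.
#' @param country `"NL"` or `"TW"` (any level of the `country` domain).
#' @param cutoff Follow-up cutoff date.
#' @return Cohort data frame (`time, event, country, age_cat, sex, period,
#'   stage_group, location, grade_cat, treatment, volume_cat`) with the
#'   selection's `exclusions` attribute.
#' @export
build_cohort <- function(records, country, cutoff = as.Date("2019-01-31")) {
  dom <- cohort_domains()
  stopifnot(country %in% dom$country)
  sel <- select_cohort(records)
  surv <- derive_survival(sel, cutoff)
  cov <- categorize(sel)
  vol <- compute_hospital_volume(sel)
  out <- cbind(surv,
               data.frame(country = factor(country, levels = dom$country)),
               cov,
               data.frame(volume_cat = factor(as.character(vol),
                                              levels = dom$volume_cat)))
  attr(out, "exclusions") <- exclusion_log(sel)
  out
}

#' Read a delimited registry extract
#'
#' Accepts comma- or tab-separated files with a header row holding the raw
#' record fields; dates must be ISO-8601.
#'
#' @param path File path.
#' @return Data frame of raw registry rows.
#' @export
read_registry <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- setdiff(c("patient_id", "topography", "diagnosis_date"), names(rec))
  if (length(need)) stopf("registry file lacks column '%s'", need[1])
  rec
}
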