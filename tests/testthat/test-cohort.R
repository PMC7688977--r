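test_that("cohort selection keeps included codes and rejects the rest", {
  recs <- make_records(
    make_record(id = "keep1"),                                   # C02.1/8070
    make_record(id = "morph", morphology = 8090L),               # 8089 + 1
    make_record(id = "soft_palate", topography = "C05.1"),       # not listed
    make_record(id = "hard_palate", topography = "C05.0"),
    make_record(id = "lip", topography = "C00.4"),
    make_record(id = "early_year", diagnosis_date = "2003-12-31"),
    make_record(id = "late_year", diagnosis_date = "2017-01-01"),
    make_record(id = "no_surgery", surgery = FALSE),
    make_record(id = "second_primary", tumour_sequence = 2L),
    make_record(id = "bad_code", topography = "X99"),
    make_record(id = "morph_low", morphology = 8049L)
  )
  kept <- select_cohort(recs)
  expect_setequal(kept$record_id, c("keep1", "hard_palate", "lip"))
  log <- exclusion_log(kept)
  reason <- setNames(log$reason, log$record_id)
  expect_equal(reason[["morph"]], "morphology_out_of_range")
  expect_equal(reason[["morph_low"]], "morphology_out_of_range")
  expect_equal(reason[["soft_palate"]], "topography_not_included")
  expect_equal(reason[["early_year"]], "diagnosis_year_out_of_range")
  expect_equal(reason[["late_year"]], "diagnosis_year_out_of_range")
  expect_equal(reason[["no_surgery"]], "no_surgery")
  expect_equal(reason[["second_primary"]], "not_first_primary")
  expect_equal(reason[["bad_code"]], "topography_unparseable")
})

test_that("selection is idempotent and keeps one record per patient", {
  recs <- make_records(
    make_record(id = "a1", patient_id = "p1", diagnosis_date = "2010-06-15"),
    make_record(id = "a2", patient_id = "p1", diagnosis_date = "2008-01-01"),
    make_record(id = "b2", patient_id = "p2", diagnosis_date = "2012-03-03"),
    make_record(id = "b1", patient_id = "p2", diagnosis_date = "2012-03-03")
  )
  kept <- select_cohort(recs)
  # earliest diagnosis wins; date tie broken by smallest record id
  expect_setequal(kept$record_id, c("a2", "b1"))
  again <- select_cohort(kept)
  expect_equal(again$record_id, kept$record_id)
  expect_equal(nrow(exclusion_log(again)), 0)
})

test_that("survival derivation follows calendar arithmetic and the cutoff", {
  # 912 days / 365.25 = 2.4969 -> 2.5
  r <- make_record(diagnosis_date = "2010-01-01", vital_status = "dead",
                   end_date = "2012-07-01")
  expect_equal(derive_survival(r), data.frame(time = 2.5, event = 1L))
  # death on the diagnosis day
  r0 <- make_record(diagnosis_date = "2010-05-05", vital_status = "dead",
                    end_date = "2010-05-05")
  expect_equal(derive_survival(r0), data.frame(time = 0, event = 1L))
  # alive with follow-up recorded beyond the cutoff: censored at the cutoff
  rc <- make_record(diagnosis_date = "2016-06-15", vital_status = "alive",
                    end_date = "2019-06-01")
  got <- derive_survival(rc, cutoff = as.Date("2019-01-31"))
  expect_equal(got$event, 0L)
  expect_equal(got$time, round(as.numeric(as.Date("2019-01-31") -
                                            as.Date("2016-06-15")) / 365.25, 1))
  # a recorded death after the cutoff is not yet observed information
  rd <- make_record(diagnosis_date = "2016-06-15", vital_status = "dead",
                    end_date = "2019-06-01")
  expect_equal(derive_survival(rd, cutoff = as.Date("2019-01-31"))$event, 0L)
  expect_error(derive_survival(
    make_record(diagnosis_date = "2012-01-01", end_date = "2011-01-01")),
    "precedes")
})

test_that("rounded follow-up stays within half a tenth of exact time", {
  set.seed(42)
  d0 <- as.Date("2004-01-01") + sample(0:4000, 200, TRUE)
  d1 <- d0 + sample(0:5000, 200, TRUE)
  recs <- do.call(rbind, lapply(seq_along(d0), function(i)
    make_record(id = paste0("r", i), diagnosis_date = as.character(d0[i]),
                vital_status = "dead", end_date = as.character(d1[i]))))
  got <- derive_survival(recs, cutoff = as.Date("2030-01-01"))
  exact <- as.numeric(d1 - d0) / 365.25
  expect_true(all(abs(got$time - exact) <= 0.05 + 1e-9))
  expect_true(all(got$time >= 0))
  expect_equal(fedsurv:::deci(got$time) / 10, got$time)
})

test_that("covariate coding matches the published bins", {
  recs <- make_records(
    make_record(id = "a59", age_at_diagnosis = 59L),
    make_record(id = "a60", age_at_diagnosis = 60L),
    make_record(id = "a70", age_at_diagnosis = 70L),
    make_record(id = "ivb", stage = "IVB"),
    make_record(id = "sunk", stage = "unknown"),
    make_record(id = "p07", diagnosis_date = "2007-12-31"),
    make_record(id = "p08", diagnosis_date = "2008-01-01"),
    make_record(id = "floor", topography = "C04.0")
  )
  cov <- categorize(recs)
  expect_equal(as.character(cov$age_cat[1:3]), c("lt60", "60_69", "ge70"))
  expect_equal(as.character(cov$stage_group[4]), "advanced")
  # unknown stage is retained as its own level, not dropped
  expect_equal(as.character(cov$stage_group[5]), "unknown")
  expect_equal(as.character(cov$period[6:7]), c("2004_2007", "2008_2011"))
  expect_equal(as.character(cov$location[8]), "floor_gum")
})

test_that("stage groups partition any cohort", {
  set.seed(7)
  stages <- sample(c("I", "II", "III", "IVA", "IVB", "IVC", "unknown"),
                   500, TRUE)
  g <- fedsurv:::stage_group_of(stages)
  expect_equal(sum(table(g)), 500)
  expect_equal(sum(g == "early"), sum(stages %in% c("I", "II")))
  expect_equal(sum(g == "advanced"),
               sum(stages %in% c("III", "IVA", "IVB", "IVC")))
})

test_that("hospital volume is counted per hospital and diagnosis year", {
  mk <- function(n, hosp, year, tag)
    do.call(rbind, lapply(seq_len(n), function(i)
      make_record(id = sprintf("%s%03d", tag, i),
                  patient_id = sprintf("%s%03d", tag, i),
                  hospital_id = hosp,
                  diagnosis_date = sprintf("%d-06-01", year))))
  recs <- rbind(mk(3, "small", 2010, "s"),
                mk(50, "mid", 2010, "m"),
                mk(100, "big", 2010, "b"),
                mk(40, "mixed", 2010, "x"),
                mk(120, "mixed", 2011, "y"))
  vol <- compute_hospital_volume(recs)
  expect_equal(as.character(vol[1:3]), rep("lt50", 3))
  expect_equal(as.character(vol[4:53]), rep("v50_99", 50))      # exactly 50
  expect_equal(as.character(vol[54:153]), rep("ge100", 100))    # exactly 100
  expect_equal(as.character(vol[154:193]), rep("lt50", 40))     # 2010 cell
  expect_equal(as.character(vol[194:313]), rep("ge100", 120))   # 2011 cell
})

test_that("build_cohort produces a typed analysis table end to end", {
  cfg <- sim_config(n = c(NL = 120), probs = lt50_probs(), seed = 3,
                    n_contaminants = 6)
  reg <- generate_registry(cfg)$NL
  co <- build_cohort(reg, "NL")
  expect_equal(nrow(co), 120)
  expect_equal(nrow(exclusion_log(co)), 6)
  expect_named(co, cohort_columns())
  dom <- cohort_domains()
  for (v in setdiff(cohort_columns(), c("time", "event")))
    expect_true(all(as.character(co[[v]]) %in% dom[[v]]))
})
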