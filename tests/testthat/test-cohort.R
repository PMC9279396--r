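cfg <- study_config()
ccsr <- toy_ccsr()

test_that("encounter rule counts distinct dx-carrying discharge dates", {
  # 5 outpatient encounters on 5 distinct dates -> qualifies
  expect_true(encounter_criterion(simple_patient_ehr(k = 5), cfg)[["p1"]])
  expect_false(encounter_criterion(simple_patient_ehr(k = 4), cfg)[["p1"]])

  # 2 emergency encounters on the same date -> distinct-date rule fails
  same_day <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    list(list("e1", "p1", "emergency", "2016-03-01"),
         list("e2", "p1", "emergency", "2016-03-01")),
    list(list("e1", "F329"), list("e2", "F329")))
  expect_false(encounter_criterion(same_day, cfg)[["p1"]])

  # 2 emergency encounters on different dates -> qualifies
  expect_true(
    encounter_criterion(simple_patient_ehr(k = 2, type = "emergency"),
                        cfg)[["p1"]])

  # 4 distinct dates, one emergency -> neither route passes
  mixed <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    list(list("e1", "p1", "emergency", "2016-01-01"),
         list("e2", "p1", "outpatient_other", "2016-02-01"),
         list("e3", "p1", "outpatient_other", "2016-03-01"),
         list("e4", "p1", "inpatient", "2016-04-01")),
    lapply(paste0("e", 1:4), function(e) list(e, "F329")))
  expect_false(encounter_criterion(mixed, cfg)[["p1"]])

  # encounters without diagnosis codes are not counted
  nodx <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    c(lapply(1:4, function(i) {
        list(paste0("e", i), "p1", "outpatient_other",
             as.character(as.Date("2016-01-01") + i * 10))
      }),
      list(list("e5", "p1", "outpatient_other", "2016-06-01"))),
    lapply(paste0("e", 1:4), function(e) list(e, "F329")))
  expect_false(encounter_criterion(nodx, cfg)[["p1"]])
})

test_that("mental-disorder profile applies age window and category grouping", {
  p <- simple_patient_ehr(code = "F329")   # depressive at age ~31
  prof <- mental_disorder_profile(p, ccsr, cfg)
  expect_equal(prof$categories[[1]], "MBD002")
  expect_equal(prof$n_groups, 1L)
  expect_false(prof$has_bipolar)

  # diagnosis only at age 17 -> empty profile
  minor <- simple_patient_ehr(birth = "1999-06-01")  # 16-17 during 2016
  prof_m <- mental_disorder_profile(minor, ccsr, cfg)
  expect_equal(prof_m$n_groups, 0L)
  expect_length(prof_m$categories[[1]], 0)

  # two substance categories collapse into one combined group
  subst <- toy_ehr(
    list(list("p1", "male", "1985-01-01")),
    list(list("e1", "p1", "outpatient_other", "2016-01-01"),
         list("e2", "p1", "outpatient_other", "2016-02-01")),
    list(list("e1", "F1010"),   # MBD017
         list("e2", "F1210")))  # MBD019
  prof_s <- mental_disorder_profile(subst, ccsr, cfg)
  expect_setequal(prof_s$categories[[1]], c("MBD017", "MBD019"))
  expect_equal(prof_s$n_groups, 1L)

  # suicidal pair counts as one group and raises the flag
  sui <- toy_ehr(
    list(list("p1", "male", "1985-01-01")),
    list(list("e1", "p1", "emergency", "2016-01-01"),
         list("e2", "p1", "emergency", "2016-02-01")),
    list(list("e1", "R45851"),  # MBD012
         list("e2", "X789")))   # MBD027
  prof_u <- mental_disorder_profile(sui, ccsr, cfg)
  expect_true(prof_u$has_suicidal_selfharm)
  expect_equal(prof_u$n_groups, 1L)

  # unmapped codes are ignored, not an error
  unk <- simple_patient_ehr(code = "Z9999")
  expect_equal(mental_disorder_profile(unk, ccsr, cfg)$n_groups, 0L)
})

test_that("exclusion rule: BoPD code ever, organic/intellectual in period", {
  # F60.3 dated before the study period still excludes ("ever" rule)
  prior <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    list(list("e0", "p1", "outpatient_other", "2014-01-01"),
         list("e1", "p1", "outpatient_other", "2016-01-01")),
    list(list("e0", "F603"), list("e1", "F329")))
  ex <- exclusion_criterion(prior, cfg)
  expect_true(ex$excluded)
  expect_equal(ex$reason, "prior BoPD code")

  # the ICD-9 BoPD code excludes too; the same digits under ICD-10 do not
  icd9 <- simple_patient_ehr(code = "9:30183")
  expect_true(exclusion_criterion(icd9, cfg)$excluded)
  icd10_lookalike <- simple_patient_ehr(code = "30183")
  expect_false(exclusion_criterion(icd10_lookalike, cfg)$excluded)

  # organic range: F05 inside the period excludes; outside it does not
  expect_true(exclusion_criterion(simple_patient_ehr(code = "F059"), cfg)$excluded)
  pre_period <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    list(list("e0", "p1", "outpatient_other", "2014-01-01")),
    list(list("e0", "F059")))
  expect_false(exclusion_criterion(pre_period, cfg)$excluded)

  # F10 (substance) is outside F01-F09; F72 (intellectual) is inside F70-F79
  expect_false(exclusion_criterion(simple_patient_ehr(code = "F1020"), cfg)$excluded)
  expect_true(exclusion_criterion(simple_patient_ehr(code = "F72"), cfg)$excluded)
})

test_that("potential-cohort selection combines the staged rules", {
  # bipolar + 5 encounter dates, no exclusions -> included
  bip <- simple_patient_ehr(code = "F319")
  res <- select_potential_cohort(bip, ccsr, cfg)
  expect_equal(res$included_ids, "p1")

  # 2 categories, no bipolar/suicidal -> the >=3-category rule fails
  two_cat <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    lapply(1:5, function(i) {
      list(paste0("e", i), "p1", "outpatient_other",
           as.character(as.Date("2016-01-01") + i * 15))
    }),
    list(list("e1", "F329"), list("e2", "F419"),
         list("e3", "F329"), list("e4", "F419"), list("e5", "F329")))
  expect_length(select_potential_cohort(two_cat, ccsr, cfg)$included_ids, 0)

  # 3 categories without bipolar/suicidal -> included
  three_cat <- toy_ehr(
    list(list("p1", "female", "1985-01-01")),
    lapply(1:5, function(i) {
      list(paste0("e", i), "p1", "outpatient_other",
           as.character(as.Date("2016-01-01") + i * 15))
    }),
    list(list("e1", "F329"), list("e2", "F419"), list("e3", "F4310"),
         list("e4", "F329"), list("e5", "F419")))
  expect_equal(select_potential_cohort(three_cat, ccsr, cfg)$included_ids, "p1")

  # a BoPD code anywhere dominates everything else
  bopd <- simple_patient_ehr(code = "F319")
  bopd$diagnoses$code[1] <- "F603"
  expect_length(select_potential_cohort(bopd, ccsr, cfg)$included_ids, 0)
})

test_that("funnel counts are monotone and the trace matches inclusion", {
  gen <- generate_cohort(sim_config(n_patients = 300, seed = 11))
  res <- select_potential_cohort(gen$ehr, gen$ccsr_map, cfg)
  expect_true(all(diff(res$counts_per_stage) <= 0))
  expect_lte(res$counts_per_stage[[1]], nrow(res$trace))
  recomputed <- res$trace$patient_id[
    res$trace$mental_disorder_present & res$trace$sufficient_history &
      res$trace$symptom_or_categories & res$trace$not_excluded]
  expect_equal(sort(res$included_ids), sort(recomputed))

  # determinism: identical inputs give identical results
  res2 <- select_potential_cohort(gen$ehr, gen$ccsr_map, cfg)
  expect_identical(res, res2)
})

test_that("diagnosed cohort requires in-period F60.3 plus the shared rules", {
  base_enc <- lapply(1:5, function(i) {
    list(paste0("e", i), "p1", "outpatient_other",
         as.character(as.Date("2016-01-01") + i * 15))
  })
  dx_ok <- list(list("e1", "F603"), list("e2", "F329"), list("e3", "F329"),
                list("e4", "F329"), list("e5", "F329"))
  ok <- toy_ehr(list(list("p1", "female", "1985-01-01")), base_enc, dx_ok)
  expect_equal(select_diagnosed_cohort(ok, ccsr, cfg)$included_ids, "p1")

  # too few encounter dates
  short <- toy_ehr(list(list("p1", "female", "1985-01-01")), base_enc[1:3],
                   dx_ok[1:3])
  expect_length(select_diagnosed_cohort(short, ccsr, cfg)$included_ids, 0)

  # intellectual-disability code excludes from the diagnosed cohort too
  excl <- toy_ehr(list(list("p1", "female", "1985-01-01")), base_enc,
                  c(dx_ok[1:4], list(list("e5", "F70"))))
  expect_length(select_diagnosed_cohort(excl, ccsr, cfg)$included_ids, 0)
})

test_that("silver positives re-apply the symptom rule without the BoPD code", {
  base_enc <- lapply(1:5, function(i) {
    list(paste0("e", i), "p1", "outpatient_other",
         as.character(as.Date("2016-01-01") + i * 15))
  })
  mk <- function(dx) toy_ehr(list(list("p1", "female", "1985-01-01")),
                             base_enc, dx)

  # diagnosed patient with bipolar -> retained
  bip <- mk(list(list("e1", "F603"), list("e2", "F319"), list("e3", "F329"),
                 list("e4", "F329"), list("e5", "F329")))
  expect_equal(select_silver_positives(bip, "p1", ccsr, cfg), "p1")

  # only 2 other categories, no bipolar/suicidal -> dropped
  two <- mk(list(list("e1", "F603"), list("e2", "F329"), list("e3", "F419"),
                 list("e4", "F329"), list("e5", "F419")))
  expect_length(select_silver_positives(two, "p1", ccsr, cfg), 0)

  # the only mental-disorder code is F60.3 itself -> empty profile, dropped
  # (F60.3 maps to the personality-disorder category, which must not count)
  only <- mk(list(list("e1", "F603"), list("e2", "F603"), list("e3", "F603"),
                  list("e4", "F603"), list("e5", "F603")))
  expect_length(select_silver_positives(only, "p1", ccsr, cfg), 0)

  # other personality-disorder codes still count after ignoring F60.3
  pd <- mk(list(list("e1", "F603"), list("e2", "F609"), list("e3", "F329"),
                list("e4", "F419"), list("e5", "F329")))
  expect_equal(select_silver_positives(pd, "p1", ccsr, cfg), "p1")
})

test_that("potential and diagnosed cohorts are disjoint on random cohorts", {
  for (s in 1:5) {
    gen <- generate_cohort(sim_config(n_patients = 250, seed = 100 + s))
    pot <- select_potential_cohort(gen$ehr, gen$ccsr_map, cfg)
    dia <- select_diagnosed_cohort(gen$ehr, gen$ccsr_map, cfg)
    expect_length(intersect(pot$included_ids, dia$included_ids), 0)
  }
})
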