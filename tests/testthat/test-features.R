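cfg <- study_config()
ccsr <- toy_ccsr()
assoc <- toy_assoc()

# n_a patients with code1, rest with filler; returns combined ehr + id sets
prevalence_ehr <- function(spec_list) {
  # spec_list: list of list(ids, code) — each patient gets 1 encounter
  pats <- list(); enc <- list(); dx <- list()
  for (s in spec_list) {
    for (id in s$ids) {
      pats[[id]] <- list(id, "female", "1985-01-01")
      eid <- paste0(id, "-e1")
      enc[[eid]] <- list(eid, id, "outpatient_other", "2016-06-01")
      dx[[length(dx) + 1]] <- list(eid, s$code)
    }
  }
  toy_ehr(unname(pats), unname(enc), dx)
}

test_that("prevalent-code selection takes the union with inclusive cutoff", {
  a_ids <- sprintf("a%02d", 1:20)   # cohort A: 20 patients
  b_ids <- sprintf("b%02d", 1:100)  # cohort B: 100 patients
  ehr <- prevalence_ehr(list(
    list(ids = a_ids[1:2], code = "F329"),    # 10% of A, 0% of B
    list(ids = b_ids[1], code = "F419"),      # 1% of B only
    list(ids = b_ids[2:6], code = "F439"),    # exactly 5% of B
    list(ids = a_ids[3:20], code = "I10"),    # filler, 90% of A
    list(ids = b_ids[7:100], code = "I10")))
  got <- select_prevalent_codes(ehr, a_ids, b_ids, cfg)
  expect_true("F329" %in% got)        # union: prevalent in A alone suffices
  expect_false("F419" %in% got)       # below cutoff everywhere
  expect_true("F439" %in% got)        # 5.0% exactly: >= is inclusive
  expect_true("I10" %in% got)
  expect_error(select_prevalent_codes(ehr, character(), b_ids, cfg),
               "non-empty")
})

test_that("the BoPD code is never a feature candidate", {
  a_ids <- sprintf("a%02d", 1:10)
  b_ids <- sprintf("b%02d", 1:10)
  ehr <- prevalence_ehr(list(list(ids = a_ids, code = "F603"),
                             list(ids = b_ids, code = "F329")))
  got <- select_prevalent_codes(ehr, a_ids, b_ids, cfg)
  expect_false("F603" %in% got)
  expect_true("F329" %in% got)
})

test_that("feature spec partitions codes into category x rating cells", {
  gen <- generate_cohort(sim_config(n_patients = 200, seed = 2))
  train_ids <- gen$ehr$patients$patient_id[1:100]

  # F329 -> (MBD002, positive), F339 -> (MBD002, unsure): two cells
  spec <- build_feature_spec(c("F329", "F339"), ccsr, assoc, gen$ehr,
                             train_ids, cfg)
  dxf <- Filter(function(f) f$kind == "diagnosis_group", spec$features)
  expect_setequal(vapply(dxf, `[[`, "", "name"),
                  c("dx_MBD002_positive", "dx_MBD002_unsure"))
  expect_equal(dxf[[1]]$codes, "F329")
  expect_equal(dxf[[2]]$codes, "F339")

  # member code sets are disjoint and non-empty by construction
  codes <- unlist(lapply(dxf, `[[`, "codes"))
  expect_false(anyDuplicated(codes) > 0)
  expect_true(all(vapply(dxf, function(f) length(f$codes) >= 1, logical(1))))

  # demographic / encounter features present regardless of codes
  expect_true(all(c("age_18_39", "age_40_59", "age_60_65", "gender_female",
                    "enc_freq_low", "enc_freq_median", "enc_freq_high",
                    "enc_type_emergency", "enc_type_inpatient",
                    "enc_type_outpatient_other") %in% spec$feature_names))

  # unmapped code goes to the reserved UNMAPPED cell with a warning
  expect_warning(
    spec_u <- build_feature_spec(c("F329", "ZZZ9"), ccsr, assoc, gen$ehr,
                                 train_ids, cfg),
    "UNMAPPED")
  expect_true("dx_UNMAPPED_unsure" %in% spec_u$feature_names)
})

test_that("featurization encodes booleans per the stored definitions", {
  p <- toy_ehr(
    list(list("p1", "male", "1991-01-01")),
    list(list("e1", "p1", "outpatient_other", "2016-05-01"),
         list("e2", "p1", "inpatient", "2016-06-01")),
    list(list("e1", "F329"), list("e2", "I10")))
  gen <- generate_cohort(sim_config(n_patients = 150, seed = 4))
  spec <- build_feature_spec(c("F329", "I10", "F419"), ccsr, assoc, gen$ehr,
                             gen$ehr$patients$patient_id, cfg)
  m <- featurize(p, "p1", spec, cfg)
  expect_type(m[1, ], "logical")
  expect_true(m["p1", "dx_MBD002_positive"])
  expect_false(m["p1", "dx_MBD005_positive"])
  # 25-year-old male at his last encounter
  expect_true(m["p1", "age_18_39"])
  expect_false(m["p1", "age_40_59"])
  expect_false(m["p1", "gender_female"])
  expect_true(m["p1", "enc_type_inpatient"])
  expect_false(m["p1", "enc_type_emergency"])
  # exactly one frequency bin
  expect_equal(sum(m[1, c("enc_freq_low", "enc_freq_median", "enc_freq_high")]),
               1)
})

test_that("tertile boundary counts fall into the lower frequency bin", {
  # 9 patients with 1..9 distinct encounter dates: tertiles at 3.67 and 6.33
  pats <- list(); enc <- list(); dx <- list()
  for (i in 1:9) {
    id <- paste0("p", i)
    pats[[id]] <- list(id, "female", "1985-01-01")
    for (j in seq_len(i)) {
      eid <- sprintf("%s-e%d", id, j)
      enc[[eid]] <- list(eid, id, "outpatient_other",
                         as.character(as.Date("2016-01-01") + j * 7))
      dx[[length(dx) + 1]] <- list(eid, "F329")
    }
  }
  ehr <- toy_ehr(unname(pats), unname(enc), dx)
  spec <- build_feature_spec("F329", ccsr, assoc, ehr,
                             paste0("p", 1:9), cfg)
  counts <- 1:9
  q <- unname(quantile(counts, c(1, 2) / 3, type = 7))
  expect_equal(spec$freq_cutoffs, q)
  m <- featurize(ehr, paste0("p", 1:9), spec, cfg)
  expect_equal(unname(m[, "enc_freq_low"]), counts <= q[1])
  expect_equal(unname(m[, "enc_freq_median"]), counts > q[1] & counts <= q[2])
  expect_equal(unname(m[, "enc_freq_high"]), counts > q[2])

  # a count exactly at a cutoff belongs to the lower bin
  ehr4 <- toy_ehr(unname(pats), unname(enc), dx)
  spec4 <- spec
  spec4$freq_cutoffs <- c(4, 7)
  m4 <- featurize(ehr4, "p4", spec4, cfg)
  expect_true(m4["p4", "enc_freq_low"])
  expect_false(m4["p4", "enc_freq_median"])
})

test_that("adding a diagnosis event never flips a feature true -> false", {
  gen <- generate_cohort(sim_config(n_patients = 120, seed = 6))
  ids <- gen$ehr$patients$patient_id
  codes <- select_prevalent_codes(gen$ehr, ids[1:60], ids[61:120], cfg)
  spec <- build_feature_spec(codes, gen$ccsr_map, gen$association_ratings,
                             gen$ehr, ids, cfg)
  before <- featurize(gen$ehr, ids, spec, cfg)

  # add one in-period diagnosis to an existing encounter of each patient
  in_period <- gen$ehr$encounters$discharge_date >= cfg$study_start &
    gen$ehr$encounters$discharge_date <= cfg$study_end
  extra <- gen$ehr$encounters[in_period, ]
  extra <- extra[!duplicated(extra$patient_id), ]
  add <- data.frame(patient_id = extra$patient_id,
                    encounter_id = extra$encounter_id,
                    code_system = "ICD10CM", code = "F329")
  aug <- ehr_data(gen$ehr$patients, gen$ehr$encounters,
                  rbind(gen$ehr$diagnoses[, names(add)], add))
  after <- featurize(aug, ids, spec, cfg)
  dx_cols <- grep("^dx_", colnames(before), value = TRUE)
  expect_true(all(after[, dx_cols] >= before[, dx_cols]))
})

test_that("feature spec round-trips through JSON with identical featurization", {
  gen <- generate_cohort(sim_config(n_patients = 150, seed = 9))
  ids <- gen$ehr$patients$patient_id
  codes <- select_prevalent_codes(gen$ehr, ids[1:75], ids[76:150], cfg)
  spec <- build_feature_spec(codes, gen$ccsr_map, gen$association_ratings,
                             gen$ehr, ids, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_spec(spec, path)
  back <- read_feature_spec(path)
  expect_equal(back$feature_names, spec$feature_names)
  expect_equal(back$freq_cutoffs, spec$freq_cutoffs)
  expect_identical(featurize(gen$ehr, ids, back, cfg),
                   featurize(gen$ehr, ids, spec, cfg))
})

test_that("planted code prevalences are recovered above the cutoff", {
  # plant codes with known independent prevalences in a 2000-patient cohort
  set.seed(77)
  n <- 2000
  plant <- c(F329 = 0.30, F419 = 0.12, F4310 = 0.08, F339 = 0.02,
             I10 = 0.25, M545 = 0.035)
  pats <- lapply(seq_len(n), function(i) {
    list(sprintf("q%04d", i), "female", "1985-01-01")
  })
  enc <- list(); dx <- list()
  for (i in seq_len(n)) {
    id <- sprintf("q%04d", i)
    eid <- paste0(id, "-e1")
    enc[[eid]] <- list(eid, id, "outpatient_other", "2016-06-01")
    hit <- names(plant)[runif(length(plant)) < plant]
    if (!length(hit)) hit <- "R51"
    for (h in hit) dx[[length(dx) + 1]] <- list(eid, h)
  }
  ehr <- toy_ehr(pats, unname(enc), dx)
  ids <- sprintf("q%04d", seq_len(n))
  got <- select_prevalent_codes(ehr, ids[1:1000], ids[1001:2000], cfg)
  expect_true(all(c("F329", "F419", "F4310", "I10") %in% got))
  expect_false("F339" %in% got)   # 2% is clear of the 5% cutoff
})
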