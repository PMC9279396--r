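# Rule engine: potential-BoPD cohort, EHR-diagnosed cohort, silver positives.
#
# All rules are evaluated on normalized codes.  "Study period" membership is
# inclusive of both boundary dates.  Only encounters carrying at least one
# diagnosis code count towards the encounter-history rule.

bopd_icd10 <- "F603"
bopd_icd9 <- "30183"

in_study_period <- function(date, config) {
  date >= config$study_start & date <= config$study_end
}

# distinct discharge dates per patient, restricted to encounters that carry
# >= 1 diagnosis code and fall in the study period
distinct_date_counts <- function(ehr, config, type = NULL) {
  enc <- ehr$encounters
  keep <- in_study_period(enc$discharge_date, config) &
    enc$encounter_id %in% ehr$diagnoses$encounter_id
  if (!is.null(type)) keep <- keep & enc$encounter_type == type
  enc <- enc[keep, c("patient_id", "discharge_date")]
  enc <- unique(enc)
  cnt <- table(factor(enc$patient_id, levels = ehr$patients$patient_id))
  stats::setNames(as.integer(cnt), ehr$patients$patient_id)
}

#' Encounter-history inclusion rule
#'
#' A patient qualifies with at least `min_encounter_dates` distinct discharge
#' dates of any encounter type, or at least `min_emergency_dates` distinct
#' emergency discharge dates, within the study period.  Encounters without a
#' diagnosis code are not counted.
#'
#' @param ehr an [ehr_data()] container.
#' @param config a [study_config()].
#' @return named logical vector over all patients in `ehr`.
#' @export
encounter_criterion <- function(ehr, config = study_config()) {
  all_dates <- distinct_date_counts(ehr, config)
  em_dates <- distinct_date_counts(ehr, config, type = "emergency")
  all_dates >= config$min_encounter_dates |
    em_dates >= config$min_emergency_dates
}

#' Mental-disorder comorbidity profile
#'
#' For each patient, collects the mental-disorder CCSR categories observed at
#' a qualifying age (a diagnosis event counts when the patient was between
#' `age_low` and `age_high` completed years at the encounter's discharge
#' date, within the study period), and summarizes them as counting groups:
#' the eight substance-related categories collapse to one group and the two
#' suicidal/self-harm categories to another, matching the category rows the
#' selection rules are phrased on.
#'
#' @param ehr an [ehr_data()] container.
#' @param ccsr_map named character vector from [read_ccsr_map()].
#' @param config a [study_config()].
#' @param ignore_codes normalized codes whose events are disregarded (used to
#'   profile the diagnosed cohort as if the BoPD code were absent).
#' @return data frame with one row per patient: `patient_id`, list-column
#'   `categories` (raw CCSR categories present), `n_groups` (number of
#'   counting groups), `has_suicidal_selfharm`, `has_bipolar`.
#' @export
mental_disorder_profile <- function(ehr, ccsr_map, config = study_config(),
                                    ignore_codes = character()) {
  dx <- ehr$diagnoses
  keep <- dx$code_system == "ICD10CM" &
    in_study_period(dx$discharge_date, config) &
    !(dx$code %in% ignore_codes)
  dx <- dx[keep, , drop = FALSE]

  bidx <- match(dx$patient_id, ehr$patients$patient_id)
  if (nrow(dx)) {
    age <- age_at(ehr$patients$birth_date[bidx], dx$discharge_date)
    dx <- dx[age >= config$age_low & age <= config$age_high, , drop = FALSE]
  }

  cat_of <- unname(ccsr_map[dx$code])   # NA for unmapped codes (ignored)
  relevant <- !is.na(cat_of) & cat_of %in% ccsr_mental_categories()
  pc <- unique(data.frame(patient_id = dx$patient_id[relevant],
                          category = cat_of[relevant],
                          stringsAsFactors = FALSE))

  ids <- ehr$patients$patient_id
  cats <- split(pc$category, factor(pc$patient_id, levels = ids))
  groups <- lapply(cats, function(x) unique(ccsr_category_group(x)))
  res <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  res$categories <- unname(cats)
  res$n_groups <- vapply(groups, length, integer(1))
  res$has_suicidal_selfharm <- vapply(
    cats, function(x) any(x %in% ccsr_suicidal_categories), logical(1))
  res$has_bipolar <- vapply(
    cats, function(x) ccsr_bipolar_category %in% x, logical(1))
  rownames(res) <- NULL
  res
}

#' Exclusion rule
#'
#' A patient is excluded if a BoPD diagnosis code (ICD-10-CM F60.3 or
#' ICD-9-CM 301.83) appears anywhere in the record — including outside the
#' study period — or if any ICD-10-CM code in the ranges F01-F09 (mental
#' disorders due to known physiological conditions) or F70-F79 (intellectual
#' disabilities) appears within the study period.  Range matching uses the
#' 3-character category prefix of the normalized code.
#'
#' @inheritParams encounter_criterion
#' @return data frame with `patient_id`, logical `excluded`, and `reason`
#'   (`NA` when not excluded; the BoPD-code reason takes precedence).
#' @export
exclusion_criterion <- function(ehr, config = study_config()) {
  dx <- ehr$diagnoses
  bopd_ever <- (dx$code_system == "ICD10CM" & dx$code == bopd_icd10) |
    (dx$code_system == "ICD9CM" & dx$code == bopd_icd9)
  organic <- dx$code_system == "ICD10CM" &
    in_study_period(dx$discharge_date, config) &
    (in_prefix_range(dx$code, "F01", "F09") |
       in_prefix_range(dx$code, "F70", "F79"))

  ids <- ehr$patients$patient_id
  has_bopd <- ids %in% dx$patient_id[bopd_ever]
  has_org <- ids %in% dx$patient_id[organic]
  reason <- rep(NA_character_, length(ids))
  reason[has_org] <- "organic or intellectual-disability code in study period"
  reason[has_bopd] <- "prior BoPD code"
  data.frame(patient_id = ids, excluded = has_bopd | has_org,
             reason = reason, stringsAsFactors = FALSE)
}

new_cohort_selection <- function(which, ids, trace, stages) {
  counts <- integer(length(stages))
  surviving <- rep(TRUE, nrow(trace))
  for (k in seq_along(stages)) {
    surviving <- surviving & trace[[stages[k]]]
    counts[k] <- sum(surviving)
  }
  structure(list(
    which = which,
    included_ids = ids,
    trace = trace,
    counts_per_stage = stats::setNames(counts, stages)
  ), class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("cohort_selection ('%s'): %d of %d patients included\n",
              x$which, length(x$included_ids), nrow(x$trace)))
  cat("  selection funnel:\n")
  cat(sprintf("    %-28s %d\n", "screened", nrow(x$trace)))
  for (s in names(x$counts_per_stage)) {
    cat(sprintf("    %-28s %d\n", s, x$counts_per_stage[[s]]))
  }
  invisible(x)
}

#' Select the potential-BoPD cohort
#'
#' Applies the staged selection funnel: (1) at least one qualifying
#' mental-disorder diagnosis (Table-2 CCSR category, age window, study
#' period); (2) sufficient encounter history ([encounter_criterion()]);
#' (3) bipolar or suicidal/self-harm codes present, or otherwise at least
#' `min_other_categories` category groups; (4) no exclusion
#' ([exclusion_criterion()]).  The result records a per-patient trace of each
#' rule and the surviving count after each stage.
#'
#' @inheritParams mental_disorder_profile
#' @return a `cohort_selection` object with `included_ids`, `trace` and
#'   `counts_per_stage`.
#' @export
select_potential_cohort <- function(ehr, ccsr_map, config = study_config()) {
  prof <- mental_disorder_profile(ehr, ccsr_map, config)
  enc_ok <- encounter_criterion(ehr, config)
  excl <- exclusion_criterion(ehr, config)
  symptom_ok <- prof$has_suicidal_selfharm | prof$has_bipolar |
    prof$n_groups >= config$min_other_categories

  trace <- data.frame(
    patient_id = ehr$patients$patient_id,
    mental_disorder_present = prof$n_groups >= 1L,
    sufficient_history = unname(enc_ok),
    symptom_or_categories = symptom_ok,
    not_excluded = !excl$excluded,
    stringsAsFactors = FALSE
  )
  stages <- c("mental_disorder_present", "sufficient_history",
              "symptom_or_categories", "not_excluded")
  inc <- trace$mental_disorder_present & trace$sufficient_history &
    trace$symptom_or_categories & trace$not_excluded
  new_cohort_selection("potential", trace$patient_id[inc], trace, stages)
}

#' Select the EHR-diagnosed BoPD cohort
#'
#' Patients carrying the ICD-10-CM BoPD code F60.3 within the study period,
#' subject to the same encounter-history requirement, at least one qualifying
#' Table-2 category diagnosis in the age window, and the organic /
#' intellectual-disability exclusion.  The BoPD code itself is of course not
#' an exclusion here.
#'
#' @inheritParams mental_disorder_profile
#' @return a `cohort_selection` object.
#' @export
select_diagnosed_cohort <- function(ehr, ccsr_map, config = study_config()) {
  dx <- ehr$diagnoses
  f603 <- dx$code_system == "ICD10CM" & dx$code == bopd_icd10 &
    in_study_period(dx$discharge_date, config)
  has_f603 <- ehr$patients$patient_id %in% dx$patient_id[f603]

  prof <- mental_disorder_profile(ehr, ccsr_map, config)
  enc_ok <- encounter_criterion(ehr, config)
  organic <- dx$code_system == "ICD10CM" &
    in_study_period(dx$discharge_date, config) &
    (in_prefix_range(dx$code, "F01", "F09") |
       in_prefix_range(dx$code, "F70", "F79"))
  has_org <- ehr$patients$patient_id %in% dx$patient_id[organic]

  trace <- data.frame(
    patient_id = ehr$patients$patient_id,
    bopd_code_in_period = has_f603,
    sufficient_history = unname(enc_ok),
    mental_disorder_present = prof$n_groups >= 1L,
    not_excluded = !has_org,
    stringsAsFactors = FALSE
  )
  stages <- c("bopd_code_in_period", "sufficient_history",
              "mental_disorder_present", "not_excluded")
  inc <- trace$bopd_code_in_period & trace$sufficient_history &
    trace$mental_disorder_present & trace$not_excluded
  new_cohort_selection("diagnosed", trace$patient_id[inc], trace, stages)
}

#' Rule-based silver positives
#'
#' From the EHR-diagnosed BoPD cohort, retains patients who would satisfy the
#' potential-cohort symptom rule when the BoPD diagnosis code is disregarded:
#' bipolar or suicidal/self-harm codes present, or at least
#' `min_other_categories` category groups.  Patients whose profile is driven
#' only by the BoPD code itself are dropped.
#'
#' @param ehr an [ehr_data()] container restricted to (or containing) the
#'   diagnosed cohort.
#' @param diagnosed_ids patient ids of the diagnosed cohort.
#' @inheritParams mental_disorder_profile
#' @return character vector of silver-positive patient ids.
#' @export
select_silver_positives <- function(ehr, diagnosed_ids, ccsr_map,
                                    config = study_config()) {
  sub <- ehr[diagnosed_ids]
  prof <- mental_disorder_profile(sub, ccsr_map, config,
                                  ignore_codes = bopd_icd10)
  keep <- prof$has_suicidal_selfharm | prof$has_bipolar |
    prof$n_groups >= config$min_other_categories
  prof$patient_id[keep]
}
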