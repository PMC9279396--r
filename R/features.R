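# Boolean feature engineering: prevalence-filtered ICD-10-CM codes grouped
# by (CCSR category x expert association rating), plus demographic,
# encounter-frequency and encounter-type features.

#' Select prevalent diagnosis codes from two cohorts
#'
#' Computes patient-level prevalence of every ICD-10-CM code (fraction of
#' cohort patients with at least one study-period event of the code) in each
#' cohort separately, keeps codes at or above `cutoff` in either cohort, and
#' returns the union.  The BoPD code F60.3 itself is never a feature
#' candidate: it defines the diagnosed cohort, is absent by construction
#' from the screening population, and would leak the silver label.
#'
#' @param ehr an [ehr_data()] container holding both cohorts.
#' @param cohort_a_ids,cohort_b_ids patient id vectors (both non-empty);
#'   conventionally the EHR-diagnosed and the potential cohort.
#' @param config a [study_config()]; `config$prevalence_cutoff` is the
#'   inclusive threshold.
#' @return sorted character vector of normalized codes.
#' @export
select_prevalent_codes <- function(ehr, cohort_a_ids, cohort_b_ids,
                                   config = study_config()) {
  if (!length(cohort_a_ids) || !length(cohort_b_ids)) {
    stopf("both cohorts must be non-empty")
  }
  prev_codes <- function(ids) {
    dx <- ehr$diagnoses
    keep <- dx$patient_id %in% ids & dx$code_system == "ICD10CM" &
      in_study_period(dx$discharge_date, config)
    pc <- unique(dx[keep, c("patient_id", "code")])
    cnt <- table(pc$code)
    names(cnt)[as.numeric(cnt) / length(ids) >= config$prevalence_cutoff]
  }
  codes <- union(prev_codes(cohort_a_ids), prev_codes(cohort_b_ids))
  sort(setdiff(codes, bopd_icd10))
}

#' Build the Boolean feature specification
#'
#' Partitions the selected codes into diagnosis-group features, one per
#' non-empty (CCSR category x association rating) cell; codes absent from
#' the CCSR map fall into a reserved `UNMAPPED` category (with a warning),
#' and unrated codes default to `unsure`.  Adds the fixed demographic
#' features (age bands 18-39 / 40-59 / 60-65, female gender), the
#' encounter-frequency bins low / median / high — whose numeric cutoffs are
#' the tertiles of distinct-discharge-date encounter counts in the training
#' cohort, frozen into the spec so later featurization is deterministic —
#' and the three encounter-type presence features.
#'
#' @param codes normalized codes from [select_prevalent_codes()].
#' @param ccsr_map named character vector from [read_ccsr_map()].
#' @param ratings named character vector from [read_association_ratings()]
#'   (may be partial).
#' @param ehr an [ehr_data()] container.
#' @param training_ids cohort whose encounter-count distribution defines the
#'   frequency cutoffs.
#' @param config a [study_config()].
#' @return a `feature_spec` object: ordered feature definitions plus the
#'   stored frequency cutoffs.
#' @export
build_feature_spec <- function(codes, ccsr_map, ratings, ehr, training_ids,
                               config = study_config()) {
  cat_of <- unname(ccsr_map[codes])
  if (anyNA(cat_of)) {
    warnf("%d code(s) missing from the CCSR map assigned to category UNMAPPED",
          sum(is.na(cat_of)))
    cat_of[is.na(cat_of)] <- "UNMAPPED"
  }
  rat_of <- unname(ratings[codes])
  rat_of[is.na(rat_of)] <- "unsure"

  cell <- paste0("dx_", cat_of, "_", rat_of)
  members <- split(codes, cell)
  dx_features <- lapply(sort(names(members)), function(nm) {
    list(name = nm, kind = "diagnosis_group", codes = sort(members[[nm]]))
  })

  counts <- distinct_date_counts(ehr[training_ids], config)
  cuts <- unname(stats::quantile(counts, probs = c(1, 2) / 3, type = 7))

  fixed <- list(
    list(name = "age_18_39", kind = "age_band", band = "18-39"),
    list(name = "age_40_59", kind = "age_band", band = "40-59"),
    list(name = "age_60_65", kind = "age_band", band = "60-65"),
    list(name = "gender_female", kind = "gender"),
    list(name = "enc_freq_low", kind = "encounter_freq", bin = "low"),
    list(name = "enc_freq_median", kind = "encounter_freq", bin = "median"),
    list(name = "enc_freq_high", kind = "encounter_freq", bin = "high"),
    list(name = "enc_type_emergency", kind = "encounter_type", type = "emergency"),
    list(name = "enc_type_inpatient", kind = "encounter_type", type = "inpatient"),
    list(name = "enc_type_outpatient_other", kind = "encounter_type",
         type = "outpatient_other")
  )
  feats <- c(fixed, dx_features)
  structure(list(features = feats,
                 feature_names = vapply(feats, `[[`, "", "name"),
                 freq_cutoffs = cuts),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat(sprintf("feature_spec: %d Boolean features (%d diagnosis groups)\n",
              length(x$features), sum(kinds == "diagnosis_group")))
  cat(sprintf("  encounter-frequency cutoffs: low <= %.2f < median <= %.2f < high\n",
              x$freq_cutoffs[1], x$freq_cutoffs[2]))
  invisible(x)
}

#' Write / read a feature spec as JSON
#'
#' The on-disk form round-trips: featurization with a re-read spec is
#' bit-identical.
#'
#' @param spec a `feature_spec` object.
#' @param path JSON file path.
#' @return `write_feature_spec` the path, invisibly; `read_feature_spec` a
#'   `feature_spec`.
#' @export
write_feature_spec <- function(spec, path) {
  jsonlite::write_json(list(features = spec$features,
                            freq_cutoffs = spec$freq_cutoffs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- lapply(raw$features, function(f) {
    if (!is.null(f$codes)) f$codes <- as.character(unlist(f$codes))
    f
  })
  structure(list(features = feats,
                 feature_names = vapply(feats, `[[`, "", "name"),
                 freq_cutoffs = as.numeric(unlist(raw$freq_cutoffs))),
            class = "feature_spec")
}

#' Featurize a cohort
#'
#' Produces the Boolean design matrix for a set of patients under a frozen
#' [build_feature_spec()] spec.  A diagnosis-group feature is true iff the
#' patient has at least one study-period event of any member code; age-band
#' features bracket the age at the last study-period encounter; the gender
#' feature is true iff female; encounter-frequency bins apply the stored
#' cutoffs to the distinct-discharge-date count, with boundary counts
#' falling to the lower bin; encounter-type features flag at least one
#' study-period encounter of the type.  A patient with no study-period
#' events gets an all-false row of diagnosis and encounter features.
#'
#' @param ehr an [ehr_data()] container.
#' @param ids patients to featurize (row order of the result).
#' @param spec a `feature_spec`.
#' @param config a [study_config()].
#' @return logical matrix, rows named by `ids`, columns by feature name.
#' @export
featurize <- function(ehr, ids, spec, config = study_config()) {
  ids <- as.character(ids)
  sub <- ehr[ids]
  m <- matrix(FALSE, nrow = length(ids), ncol = length(spec$feature_names),
              dimnames = list(ids, spec$feature_names))

  # diagnosis-group features via a code -> column lookup
  code2col <- list()
  for (f in spec$features) {
    if (f$kind == "diagnosis_group") {
      code2col[f$codes] <- f$name
    }
  }
  dx <- sub$diagnoses
  keep <- dx$code_system == "ICD10CM" &
    in_study_period(dx$discharge_date, config) &
    dx$code %in% names(code2col)
  if (any(keep)) {
    hit <- unique(data.frame(
      patient_id = dx$patient_id[keep],
      col = unlist(code2col[dx$code[keep]], use.names = FALSE),
      stringsAsFactors = FALSE
    ))
    m[cbind(hit$patient_id, hit$col)] <- TRUE
  }

  # age at last study-period encounter
  enc <- sub$encounters[in_study_period(sub$encounters$discharge_date, config), ]
  if (nrow(enc)) {
    last <- tapply(enc$discharge_date, factor(enc$patient_id, levels = ids), max)
    has <- !is.na(last)
    age <- rep(NA_integer_, length(ids))
    age[has] <- age_at(
      sub$patients$birth_date[match(ids[has], sub$patients$patient_id)],
      as.Date(as.numeric(last[has]), origin = "1970-01-01"))
    band <- as.character(age_band_of(age))
    m[, "age_18_39"] <- !is.na(band) & band == "18-39"
    m[, "age_40_59"] <- !is.na(band) & band == "40-59"
    m[, "age_60_65"] <- !is.na(band) & band == "60-65"

    for (tp in c("emergency", "inpatient", "outpatient_other")) {
      m[, paste0("enc_type_", tp)] <-
        ids %in% enc$patient_id[enc$encounter_type == tp]
    }
  }

  m[, "gender_female"] <-
    sub$patients$gender[match(ids, sub$patients$patient_id)] == "female"

  counts <- distinct_date_counts(sub, config)[ids]
  q <- spec$freq_cutoffs
  m[, "enc_freq_low"] <- counts <= q[1]
  m[, "enc_freq_median"] <- counts > q[1] & counts <= q[2]
  m[, "enc_freq_high"] <- counts > q[2]

  m
}
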