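# Stratified sampling of chart-review sets, and ingestion of expert ratings.
#
# Strata cross gender, an age band, and a diagnostic-history class:
#   N  — no bipolar/suicidal code and >= 3 category groups
#   Y1 — bipolar/suicidal code and >= 3 category groups
#   Y2 — bipolar/suicidal code and  < 3 category groups
# (groups counted including the bipolar and suicidal/self-harm groups).

history_class_of <- function(has_bip_sui, n_groups, min_cat) {
  cls <- rep(NA_character_, length(has_bip_sui))
  cls[!has_bip_sui & n_groups >= min_cat] <- "N"
  cls[has_bip_sui & n_groups >= min_cat] <- "Y1"
  cls[has_bip_sui & n_groups < min_cat] <- "Y2"
  cls
}

age_band_of <- function(age) {
  cut(age, breaks = c(-Inf, 39, 59, Inf),
      labels = c("18-39", "40-59", "60-65"))
}

#' Assign sampling strata to cohort patients
#'
#' Computes, for each patient of a (potential) cohort, the stratum used for
#' chart-review sampling: gender x age band (18-39, 40-59, 60-65; taken at
#' the last study-period encounter) x diagnostic-history class (N / Y1 / Y2,
#' see Details).  Patients with `unknown_other` gender are not strata members
#' and must be filtered out by the caller; passing one is an error.
#'
#' @details History classes: `N` — no bipolar or suicidal/self-harm code and
#'   at least `min_other_categories` category groups; `Y1` — bipolar or
#'   suicidal/self-harm code and at least that many groups; `Y2` — bipolar
#'   or suicidal/self-harm code and fewer groups.
#'
#' @param ehr an [ehr_data()] container.
#' @param ids patient ids of the cohort to stratify.
#' @param ccsr_map named character vector from [read_ccsr_map()].
#' @param config a [study_config()].
#' @return data frame with `patient_id`, `gender`, `age_band`,
#'   `history_class` and the combined `stratum` label.
#' @export
assign_stratum <- function(ehr, ids, ccsr_map, config = study_config()) {
  sub <- ehr[ids]
  if (any(sub$patients$gender == "unknown_other")) {
    stopf("cannot stratify patients with 'unknown_other' gender: %s",
          paste(utils::head(
            sub$patients$patient_id[sub$patients$gender == "unknown_other"], 5),
            collapse = ", "))
  }
  prof <- mental_disorder_profile(sub, ccsr_map, config)
  has_bs <- prof$has_suicidal_selfharm | prof$has_bipolar
  cls <- history_class_of(has_bs, prof$n_groups, config$min_other_categories)
  if (anyNA(cls)) {
    stopf("patient %s has neither bipolar/suicidal codes nor %d category groups; not a cohort member",
          prof$patient_id[is.na(cls)][1], config$min_other_categories)
  }

  enc <- sub$encounters[in_study_period(sub$encounters$discharge_date, config), ]
  last_date <- tapply(enc$discharge_date, factor(enc$patient_id,
                                                 levels = prof$patient_id),
                      max)
  if (anyNA(last_date)) {
    stopf("patient %s has no study-period encounter",
          prof$patient_id[is.na(last_date)][1])
  }
  age <- age_at(sub$patients$birth_date[match(prof$patient_id,
                                              sub$patients$patient_id)],
                as.Date(as.numeric(last_date), origin = "1970-01-01"))
  band <- as.character(age_band_of(age))
  gender <- sub$patients$gender[match(prof$patient_id, sub$patients$patient_id)]
  data.frame(
    patient_id = prof$patient_id, gender = gender, age_band = band,
    history_class = cls,
    stratum = paste(gender, band, cls, sep = "/"),
    stringsAsFactors = FALSE
  )
}

# per-stratum allocation of n by largest remainder, in sorted stratum order
stratum_allocation <- function(stratum, n) {
  sizes <- table(stratum)
  alloc <- largest_remainder(as.numeric(sizes), n)
  stats::setNames(alloc, names(sizes))
}

#' Stratified random sample from a cohort
#'
#' Allocates `n` across strata proportionally to stratum prevalence, rounded
#' by largest remainder so allocations sum exactly to `n`, then draws a
#' simple random sample without replacement within each stratum.
#'
#' @param strata data frame from [assign_stratum()] (needs `patient_id` and
#'   `stratum`).
#' @param n total sample size; must not exceed the cohort size.
#' @param seed integer seed; the draw is reproducible and leaves the
#'   session's RNG state untouched.
#' @return character vector of sampled patient ids.
#' @export
stratified_sample <- function(strata, n, seed) {
  if (n > nrow(strata)) {
    stopf("requested sample of %d exceeds cohort size %d", n, nrow(strata))
  }
  alloc <- stratum_allocation(strata$stratum, n)
  with_seed(seed, {
    picks <- lapply(names(alloc), function(s) {
      ids <- strata$patient_id[strata$stratum == s]
      k <- alloc[[s]]
      if (k == 0L) return(character())
      ids[sample.int(length(ids), k)]
    })
    sort(unlist(picks))
  })
}

#' Paired stratified samples with identical demographic margins
#'
#' Draws disjoint training and testing chart-review sets of `n` patients
#' each as a single stratified sample of `2n`, allocated per stratum by
#' largest remainder on `n` and doubled, then split evenly at random within
#' each stratum.  By construction the two sets have identical per-stratum
#' counts, hence identical gender and age margins.
#'
#' @inheritParams stratified_sample
#' @param n size of each of the two samples.
#' @return list with character vectors `train` and `test` (disjoint).
#' @export
stratified_sample_pair <- function(strata, n, seed) {
  if (2L * n > nrow(strata)) {
    stopf("paired sample of 2 x %d exceeds cohort size %d", n, nrow(strata))
  }
  alloc <- stratum_allocation(strata$stratum, n)
  sizes <- table(strata$stratum)
  short <- names(alloc)[2L * alloc > as.integer(sizes[names(alloc)])]
  if (length(short)) {
    stopf("stratum '%s' too small for a paired draw (need %d, have %d)",
          short[1], 2L * alloc[[short[1]]], sizes[[short[1]]])
  }
  with_seed(seed, {
    train <- character()
    test <- character()
    for (s in names(alloc)) {
      k <- alloc[[s]]
      if (k == 0L) next
      ids <- strata$patient_id[strata$stratum == s]
      drawn <- ids[sample.int(length(ids), 2L * k)]
      train <- c(train, drawn[seq_len(k)])
      test <- c(test, drawn[k + seq_len(k)])
    }
    list(train = sort(train), test = sort(test))
  })
}

#' Read expert chart-review rating labels
#'
#' Ratings assign each reviewed patient to one of the mutually exclusive
#' categories `A` (not likely BoPD — primarily physical condition), `B` (not
#' likely — severe psychotic/substance abuse), `C` (unsure), `D` (possible
#' BoPD), `E` (most likely BoPD), with an optional `classic` flag marking the
#' classic-BoPD subset of `E`.  The binary screening target is
#' `positive <=> category == "E"`.
#'
#' @param path CSV with columns `patient_id, category, classic`.
#' @return data frame with `patient_id`, `category`, logical `classic` and
#'   derived logical `positive`.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  validate_ratings(df)
}

validate_ratings <- function(df) {
  miss <- setdiff(c("patient_id", "category", "classic"), names(df))
  if (length(miss)) stopf("ratings missing column(s): %s",
                          paste(miss, collapse = ", "))
  category <- toupper(trimws(as.character(df$category)))
  bad <- !(category %in% c("A", "B", "C", "D", "E"))
  if (any(bad)) stopf("rating category '%s' outside A-E", category[bad][1])
  classic <- as.logical(df$classic)
  if (anyNA(classic)) {
    classic <- trimws(tolower(as.character(df$classic))) %in% c("true", "t", "1", "yes")
  }
  if (any(classic & category != "E")) {
    stopf("classic flag set for non-E category (patient %s)",
          df$patient_id[classic & category != "E"][1])
  }
  out <- data.frame(patient_id = as.character(df$patient_id),
                    category = category, classic = classic,
                    positive = category == "E", stringsAsFactors = FALSE)
  if (anyDuplicated(out$patient_id)) {
    stopf("patient %s rated more than once",
          out$patient_id[anyDuplicated(out$patient_id)][1])
  }
  out
}
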