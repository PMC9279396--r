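#' Study configuration
#'
#' Bundles every tunable constant of the screening study: the study window,
#' the encounter-history requirements, the age window for qualifying
#' diagnoses, the comorbidity-category minimum, the feature prevalence
#' cutoff, the gold-label class ratio used to size the silver-negative draw,
#' the decision threshold, and the cross-validation / bootstrap settings.
#'
#' Defaults reproduce the published screening algorithm: at least 5 distinct
#' encounter discharge dates (or 2 distinct emergency dates), qualifying
#' diagnoses between ages 18 and 65, at least 3 mental-disorder category
#' groups for patients without bipolar or suicidal/self-harm codes, a 0.05
#' prevalence cutoff for feature codes, a 66:162 gold positive-to-negative
#' ratio, a 0.5 screening threshold, 10-fold cross-validation and 1000
#' bootstrap replicates at the 95% level.
#'
#' @param study_start,study_end inclusive bounds of the study period
#'   (`Date` or ISO-8601 strings).
#' @param min_encounter_dates minimum distinct discharge dates over all
#'   encounter types.
#' @param min_emergency_dates minimum distinct emergency discharge dates
#'   (alternative route into the cohort).
#' @param age_low,age_high inclusive age window, in completed years, within
#'   which a diagnosis event counts towards the mental-disorder profile.
#' @param min_other_categories minimum number of mental-disorder category
#'   groups for patients without bipolar or suicidal/self-harm codes.
#' @param prevalence_cutoff minimum patient-level prevalence for a diagnosis
#'   code to become a feature candidate.
#' @param gold_ratio_pos,gold_ratio_neg positive and negative counts defining
#'   the gold-label class ratio that the silver set replicates.
#' @param decision_threshold probability above which (strictly) a patient
#'   screens positive.
#' @param cv_folds folds for cross-validated selection of the lasso penalty.
#' @param bootstrap_reps bootstrap replicates for confidence intervals.
#' @param ci_level confidence level for bootstrap percentile intervals.
#' @param random_seed default seed used when a function is not given one.
#' @return an object of class `study_config` (a validated list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$min_encounter_dates
study_config <- function(study_start = as.Date("2015-10-01"),
                         study_end = as.Date("2018-07-11"),
                         min_encounter_dates = 5L,
                         min_emergency_dates = 2L,
                         age_low = 18L,
                         age_high = 65L,
                         min_other_categories = 3L,
                         prevalence_cutoff = 0.05,
                         gold_ratio_pos = 66L,
                         gold_ratio_neg = 162L,
                         decision_threshold = 0.5,
                         cv_folds = 10L,
                         bootstrap_reps = 1000L,
                         ci_level = 0.95,
                         random_seed = 1L) {
  cfg <- list(
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    min_encounter_dates = as.integer(min_encounter_dates),
    min_emergency_dates = as.integer(min_emergency_dates),
    age_low = as.integer(age_low), age_high = as.integer(age_high),
    min_other_categories = as.integer(min_other_categories),
    prevalence_cutoff = as.numeric(prevalence_cutoff),
    gold_ratio_pos = as.integer(gold_ratio_pos),
    gold_ratio_neg = as.integer(gold_ratio_neg),
    decision_threshold = as.numeric(decision_threshold),
    cv_folds = as.integer(cv_folds),
    bootstrap_reps = as.integer(bootstrap_reps),
    ci_level = as.numeric(ci_level),
    random_seed = as.integer(random_seed)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  if (is.na(cfg$study_start) || is.na(cfg$study_end)) {
    stopf("study_start and study_end must be valid dates")
  }
  if (!(cfg$study_start < cfg$study_end)) {
    stopf("study_start (%s) must precede study_end (%s)",
          cfg$study_start, cfg$study_end)
  }
  counts <- c("min_encounter_dates", "min_emergency_dates",
              "min_other_categories", "gold_ratio_pos", "gold_ratio_neg",
              "cv_folds", "bootstrap_reps")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stopf("%s must be a positive count", f)
  }
  if (!(cfg$decision_threshold > 0 && cfg$decision_threshold < 1)) {
    stopf("decision_threshold must lie strictly in (0, 1)")
  }
  if (!(cfg$ci_level > 0 && cfg$ci_level < 1)) {
    stopf("ci_level must lie strictly in (0, 1)")
  }
  if (cfg$age_low < 0 || cfg$age_high > 120 || cfg$age_low >= cfg$age_high) {
    stopf("age window must satisfy 0 <= age_low < age_high <= 120")
  }
  if (cfg$prevalence_cutoff < 0 || cfg$prevalence_cutoff > 1) {
    stopf("prevalence_cutoff must be in [0, 1]")
  }
  invisible(cfg)
}

#' Read a study configuration from a YAML or JSON file
#'
#' The file holds a flat mapping of `study_config()` argument names to
#' values; unspecified fields take their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  do.call(study_config, vals)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  study period:      %s .. %s (inclusive)\n", x$study_start, x$study_end))
  cat(sprintf("  encounter rule:    >= %d distinct dates, or >= %d emergency dates\n",
              x$min_encounter_dates, x$min_emergency_dates))
  cat(sprintf("  diagnosis age:     %d-%d years\n", x$age_low, x$age_high))
  cat(sprintf("  category minimum:  %d groups (without bipolar/suicidal codes)\n",
              x$min_other_categories))
  cat(sprintf("  prevalence cutoff: %.3f\n", x$prevalence_cutoff))
  cat(sprintf("  gold class ratio:  %d:%d\n", x$gold_ratio_pos, x$gold_ratio_neg))
  cat(sprintf("  threshold:         %.2f;  CV folds: %d;  bootstrap: %d at %.0f%%\n",
              x$decision_threshold, x$cv_folds, x$bootstrap_reps, 100 * x$ci_level))
  invisible(x)
}

# --- CCSR category groups used by the selection rules ---------------------
# The mental-disorder CCSR categories relevant to BoPD screening, and how
# they collapse into counting groups: the eight substance-related categories
# count as one combined group, and the two suicidal/self-harm categories
# count as one group.

ccsr_suicidal_categories <- c("MBD012", "MBD027")
ccsr_bipolar_category <- "MBD003"
ccsr_substance_categories <- c("MBD017", "MBD018", "MBD019", "MBD020",
                               "MBD021", "MBD022", "MBD023", "MBD025")
ccsr_single_categories <- c("MBD002", "MBD003", "MBD004", "MBD005",
                            "MBD007", "MBD008", "MBD009")

#' Mental-disorder CCSR categories used by the selection rules
#'
#' @return character vector of the CCSR category codes that qualify a
#'   diagnosis as a relevant mental-disorder event.
#' @export
ccsr_mental_categories <- function() {
  c(ccsr_single_categories, ccsr_suicidal_categories, ccsr_substance_categories)
}

# Map a CCSR category code to its counting group.  Substance categories
# collapse to "SUBSTANCE", suicidal/self-harm to "SUICIDAL_SELFHARM";
# categories outside the relevant list map to NA.
ccsr_category_group <- function(category) {
  out <- rep(NA_character_, length(category))
  out[category %in% ccsr_single_categories] <-
    category[category %in% ccsr_single_categories]
  out[category %in% ccsr_substance_categories] <- "SUBSTANCE"
  out[category %in% ccsr_suicidal_categories] <- "SUICIDAL_SELFHARM"
  out
}
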