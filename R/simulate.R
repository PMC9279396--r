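# Synthetic EHR generator.
#
# Emits cohorts with the statistical structure the screening pipeline
# assumes: latent patient classes mirroring the expert rating categories
# (bopd_like -> E, psychotic_substance -> B, physical_primary -> A,
# other_mental -> C/D, healthy), class-conditional encounter histories and
# ICD-10-CM-shaped diagnosis codes drawn through a miniature CCSR-style code
# table, and a configurable fraction of bopd_like patients carrying the
# F60.3 diagnosis (the EHR-diagnosed cohort).

sim_classes <- c("bopd_like", "psychotic_substance", "physical_primary",
                 "other_mental", "healthy")

#' Miniature CCSR-style code table
#'
#' Roughly sixty ICD-10-CM-shaped diagnosis codes spanning the
#' mental-disorder CCSR categories used by the selection rules, plus
#' psychotic-disorder codes (category MBD001), physical-illness codes, and
#' the organic / intellectual-disability codes matched by the exclusion
#' ranges.  A full CCSR table can be substituted via [read_ccsr_map()].
#'
#' @return data frame with `code` (normalized), `ccsr_category` and the
#'   expert `association` rating used for the ratings fixture.
#' @export
builtin_code_table <- function() {
  tab <- rbind(
    # depressive disorders
    c("F320", "MBD002", "positive"), c("F321", "MBD002", "positive"),
    c("F329", "MBD002", "positive"), c("F331", "MBD002", "positive"),
    c("F339", "MBD002", "unsure"),
    # bipolar and related
    c("F300", "MBD003", "positive"), c("F309", "MBD003", "positive"),
    c("F319", "MBD003", "positive"), c("F3181", "MBD003", "positive"),
    # other mood
    c("F341", "MBD004", "unsure"), c("F348", "MBD004", "unsure"),
    c("F39", "MBD004", "unsure"),
    # anxiety and fear-related
    c("F410", "MBD005", "positive"), c("F411", "MBD005", "unsure"),
    c("F419", "MBD005", "positive"), c("F4010", "MBD005", "unsure"),
    # trauma- and stressor-related
    c("F4310", "MBD007", "positive"), c("F4312", "MBD007", "positive"),
    c("F4321", "MBD007", "unsure"), c("F439", "MBD007", "positive"),
    # disruptive / impulse-control
    c("F639", "MBD008", "positive"), c("F919", "MBD008", "unsure"),
    # personality disorders (F60.3 itself is mapped but never a feature)
    c("F603", "MBD009", "positive"),
    c("F600", "MBD009", "positive"), c("F609", "MBD009", "positive"),
    c("F21", "MBD009", "unsure"),
    # suicidal ideation / intentional self-harm
    c("R45851", "MBD012", "positive"), c("T1491", "MBD012", "positive"),
    c("X789", "MBD027", "positive"), c("X710", "MBD027", "positive"),
    # substance-related
    c("F1010", "MBD017", "unsure"), c("F1020", "MBD017", "negative"),
    c("F1110", "MBD018", "unsure"), c("F1120", "MBD018", "negative"),
    c("F1210", "MBD019", "unsure"), c("F1220", "MBD019", "negative"),
    c("F1310", "MBD020", "negative"), c("F1510", "MBD021", "negative"),
    c("F1610", "MBD022", "negative"), c("F1810", "MBD023", "negative"),
    c("F1910", "MBD025", "unsure"), c("F1920", "MBD025", "negative"),
    # schizophrenia spectrum / psychotic (not a selection category)
    c("F209", "MBD001", "negative"), c("F250", "MBD001", "negative"),
    c("F29", "MBD001", "negative"),
    # organic mental disorders and intellectual disabilities (exclusions)
    c("F059", "MBD031", "unrelated"), c("F0630", "MBD031", "unrelated"),
    c("F70", "MBD026", "unrelated"), c("F72", "MBD026", "unrelated"),
    # physical illness
    c("E119", "END002", "unrelated"), c("E039", "END002", "unrelated"),
    c("E669", "END009", "unrelated"), c("I10", "CIR007", "unrelated"),
    c("I2510", "CIR011", "unrelated"), c("J45909", "RSP009", "unrelated"),
    c("J069", "RSP006", "unrelated"), c("M545", "MUS010", "unrelated"),
    c("M179", "MUS006", "unrelated"), c("K219", "DIG004", "unrelated"),
    c("R51", "SYM006", "unrelated"), c("N390", "GEN004", "unrelated")
  )
  data.frame(code = tab[, 1], ccsr_category = tab[, 2],
             association = tab[, 3], stringsAsFactors = FALSE)
}

# per-class sampling weights over code-table categories; "PHYS" spreads over
# all physical-illness categories, "PSYCH" over MBD001
sim_category_weights <- function() {
  w <- function(...) c(...)
  list(
    bopd_like = w(MBD002 = 0.22, MBD003 = 0.14, MBD004 = 0.04, MBD005 = 0.12,
                  MBD007 = 0.12, MBD008 = 0.04, MBD009 = 0.05,
                  SUICIDAL = 0.12, SUBSTANCE = 0.07, PSYCH = 0.01,
                  PHYS = 0.07),
    psychotic_substance = w(MBD002 = 0.14, MBD003 = 0.02, MBD004 = 0.06,
                            MBD005 = 0.09, MBD007 = 0.03,
                            SUICIDAL = 0.04, SUBSTANCE = 0.27, PSYCH = 0.27,
                            PHYS = 0.08),
    physical_primary = w(MBD002 = 0.10, MBD005 = 0.08, MBD004 = 0.04,
                         PHYS = 0.78),
    other_mental = w(MBD002 = 0.20, MBD004 = 0.08, MBD005 = 0.20,
                     MBD007 = 0.13, MBD008 = 0.07, MBD009 = 0.02,
                     MBD003 = 0.02, SUICIDAL = 0.01, SUBSTANCE = 0.05,
                     PHYS = 0.22),
    healthy = w(MBD005 = 0.05, PHYS = 0.95)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic-EHR generator.  Defaults emulate a screening
#' population in which roughly three patients in ten entering the potential
#' cohort are most-likely-BoPD, encounter counts are overdispersed
#' (negative-binomial) with class-specific means, and a quarter of the
#' BoPD-like class already carries the F60.3 diagnosis.
#'
#' @param n_patients number of patients to simulate.
#' @param study_start,study_end study window (inclusive).
#' @param class_weights mixture weights over the latent classes
#'   `bopd_like`, `psychotic_substance`, `physical_primary`, `other_mental`,
#'   `healthy`; must sum to 1.
#' @param encounter_mu,encounter_size per-class negative-binomial mean and
#'   dispersion of the encounter count.
#' @param emergency_frac,inpatient_frac per-class encounter-type mix
#'   (remainder is outpatient/other).
#' @param female_prob per-class probability of female gender.
#' @param diagnosed_prob fraction of `bopd_like` patients carrying F60.3
#'   within the study period.
#' @param exclusion_prob per-class probability of an organic /
#'   intellectual-disability code (triggering the exclusion rule).
#' @param prior_bopd_prob probability that a `bopd_like` patient carries an
#'   old F60.3 before the study window (excluded "ever" rule).
#' @param rating_noise probability that an expert rating deviates from the
#'   latent class's canonical category.
#' @param classic_quantile severity quantile above which a `bopd_like`
#'   patient is flagged classic when rated E.
#' @param seed integer seed.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_patients = 2000L,
                       study_start = as.Date("2015-10-01"),
                       study_end = as.Date("2018-07-11"),
                       class_weights = c(bopd_like = 0.13,
                                         psychotic_substance = 0.07,
                                         physical_primary = 0.31,
                                         other_mental = 0.18,
                                         healthy = 0.31),
                       encounter_mu = c(bopd_like = 11, psychotic_substance = 10,
                                        physical_primary = 7, other_mental = 6,
                                        healthy = 2.5),
                       encounter_size = 3,
                       emergency_frac = c(bopd_like = 0.30,
                                          psychotic_substance = 0.25,
                                          physical_primary = 0.12,
                                          other_mental = 0.15, healthy = 0.08),
                       inpatient_frac = 0.08,
                       female_prob = c(bopd_like = 0.72,
                                       psychotic_substance = 0.45,
                                       physical_primary = 0.58,
                                       other_mental = 0.62, healthy = 0.55),
                       diagnosed_prob = 0.25,
                       exclusion_prob = c(bopd_like = 0.01,
                                          psychotic_substance = 0.03,
                                          physical_primary = 0.04,
                                          other_mental = 0.01, healthy = 0.01),
                       prior_bopd_prob = 0.005,
                       rating_noise = 0.05,
                       classic_quantile = 0.8,
                       seed = 1L) {
  expand <- function(x) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(sim_classes)), sim_classes)
    if (!all(sim_classes %in% names(x))) {
      stopf("per-class parameter must name all classes: %s",
            paste(sim_classes, collapse = ", "))
    }
    x[sim_classes]
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    class_weights = expand(class_weights),
    encounter_mu = expand(encounter_mu),
    encounter_size = as.numeric(encounter_size),
    emergency_frac = expand(emergency_frac),
    inpatient_frac = expand(inpatient_frac),
    female_prob = expand(female_prob),
    diagnosed_prob = as.numeric(diagnosed_prob),
    exclusion_prob = expand(exclusion_prob),
    prior_bopd_prob = as.numeric(prior_bopd_prob),
    rating_noise = as.numeric(rating_noise),
    classic_quantile = as.numeric(classic_quantile),
    seed = as.integer(seed)
  )
  bad <- character()
  if (cfg$n_patients <= 0L) bad <- c(bad, "n_patients")
  if (abs(sum(cfg$class_weights) - 1) > 1e-8) bad <- c(bad, "class_weights")
  probs <- c(cfg$emergency_frac, cfg$inpatient_frac, cfg$female_prob,
             cfg$diagnosed_prob, cfg$exclusion_prob, cfg$prior_bopd_prob,
             cfg$rating_noise, cfg$classic_quantile)
  if (any(probs < 0 | probs > 1)) bad <- c(bad, "probabilities")
  if (any(cfg$encounter_mu <= 0) || cfg$encounter_size <= 0) {
    bad <- c(bad, "encounter rates")
  }
  if (!(cfg$study_start < cfg$study_end)) bad <- c(bad, "study window")
  if (length(bad)) stopf("invalid sim_config field(s): %s",
                         paste(unique(bad), collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic EHR cohort
#'
#' Samples latent classes, demographics, encounter histories and diagnosis
#' events per [sim_config()], and returns the EHR container together with
#' the ground truth and the knowledge-table fixtures.
#'
#' @param sim a [sim_config()].
#' @return list with components `ehr` ([ehr_data()]), `truth` (data frame
#'   `patient_id`, `class`, `severity`, `diagnosed`), `ccsr_map` and
#'   `association_ratings` (named vectors over the builtin code table).
#' @export
generate_cohort <- function(sim = sim_config()) {
  stopifnot(inherits(sim, "sim_config"))
  tab <- builtin_code_table()
  phys_cats <- setdiff(unique(tab$ccsr_category),
                       c(ccsr_mental_categories(), "MBD001", "MBD031", "MBD026"))
  cat_codes <- split(tab$code, tab$ccsr_category)
  weights <- sim_category_weights()

  with_seed(sim$seed, {
    n <- sim$n_patients
    ids <- sprintf("P%05d", seq_len(n))
    cls <- sample(sim_classes, n, replace = TRUE, prob = sim$class_weights)
    severity <- stats::runif(n)
    gender <- ifelse(stats::runif(n) < sim$female_prob[cls], "female", "male")
    # a sliver of unknown gender, as real extracts have
    gender[stats::runif(n) < 0.004] <- "unknown_other"
    age_at_start <- sample(16:68, n, replace = TRUE)
    birth_date <- sim$study_start - round(age_at_start * 365.25) -
      sample.int(364, n, replace = TRUE)

    n_enc <- pmax(1L, stats::rnbinom(n, mu = sim$encounter_mu[cls],
                                     size = sim$encounter_size))
    window_days <- as.integer(sim$study_end - sim$study_start)

    pat_idx <- rep.int(seq_len(n), n_enc)
    total_enc <- length(pat_idx)
    enc_id <- sprintf("%s-e%d", ids[pat_idx],
                      unlist(lapply(n_enc, seq_len), use.names = FALSE))
    # ~3% of encounters predate the study window ("entire period of the EHR")
    pre <- stats::runif(total_enc) < 0.03
    offs <- integer(total_enc)
    offs[!pre] <- sample.int(window_days + 1L, sum(!pre), replace = TRUE) - 1L
    offs[pre] <- -sample.int(1000L, sum(pre), replace = TRUE)
    disch <- sim$study_start + offs
    u <- stats::runif(total_enc)
    em <- sim$emergency_frac[cls[pat_idx]]
    ip <- sim$inpatient_frac[cls[pat_idx]]
    etype <- ifelse(u < em, "emergency",
                    ifelse(u < em + ip, "inpatient", "outpatient_other"))

    encounters <- data.frame(
      encounter_id = enc_id, patient_id = ids[pat_idx],
      encounter_type = etype, discharge_date = disch,
      stringsAsFactors = FALSE
    )

    # diagnosis codes: 1-3 per encounter, class-conditional category draw
    n_dx <- 1L + stats::rpois(total_enc, 0.8)
    dx_enc <- rep.int(seq_len(total_enc), n_dx)
    total_dx <- length(dx_enc)
    dx_cls <- cls[pat_idx[dx_enc]]
    dx_cat <- character(total_dx)
    for (cl in sim_classes) {
      w <- weights[[cl]]
      sel <- dx_cls == cl
      if (!any(sel)) next
      dx_cat[sel] <- sample(names(w), sum(sel), replace = TRUE, prob = w)
    }
    # resolve meta-categories, then a uniform code within the category
    meta_phys <- dx_cat == "PHYS"
    dx_cat[meta_phys] <- sample(phys_cats, sum(meta_phys), replace = TRUE)
    dx_cat[dx_cat == "PSYCH"] <- "MBD001"
    is_sui <- dx_cat == "SUICIDAL"
    dx_cat[is_sui] <- sample(ccsr_suicidal_categories, sum(is_sui),
                             replace = TRUE)
    is_sub <- dx_cat == "SUBSTANCE"
    dx_cat[is_sub] <- sample(ccsr_substance_categories, sum(is_sub),
                             replace = TRUE)
    code <- character(total_dx)
    for (cat in unique(dx_cat)) {
      pool <- setdiff(cat_codes[[cat]], bopd_icd10)
      sel <- dx_cat == cat
      code[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
    diagnoses <- data.frame(
      patient_id = ids[pat_idx[dx_enc]], encounter_id = enc_id[dx_enc],
      code_system = "ICD10CM", code = code, stringsAsFactors = FALSE
    )

    # exclusion codes on a random encounter of flagged patients
    excl_pat <- which(stats::runif(n) < sim$exclusion_prob[cls])
    excl_rows <- lapply(excl_pat, function(i) {
      encs <- enc_id[pat_idx == i]
      data.frame(patient_id = ids[i],
                 encounter_id = encs[sample.int(length(encs), 1L)],
                 code_system = "ICD10CM",
                 code = sample(c("F059", "F0630", "F70", "F72"), 1L),
                 stringsAsFactors = FALSE)
    })

    # F60.3 labelling of the diagnosed subset of bopd_like (in-period
    # encounter), and rare pre-period BoPD codes triggering the ever-rule
    bopd_idx <- which(cls == "bopd_like")
    diagnosed <- rep(FALSE, n)
    f603_rows <- list()
    for (i in bopd_idx) {
      encs_in <- which(pat_idx == i & offs >= 0)
      if (length(encs_in) && stats::runif(1) < sim$diagnosed_prob) {
        diagnosed[i] <- TRUE
        f603_rows[[length(f603_rows) + 1L]] <- data.frame(
          patient_id = ids[i],
          encounter_id = enc_id[encs_in[sample.int(length(encs_in), 1L)]],
          code_system = "ICD10CM", code = bopd_icd10,
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < sim$prior_bopd_prob) {
        encs_pre <- which(pat_idx == i & offs < 0)
        if (length(encs_pre)) {
          f603_rows[[length(f603_rows) + 1L]] <- data.frame(
            patient_id = ids[i],
            encounter_id = enc_id[encs_pre[sample.int(length(encs_pre), 1L)]],
            code_system = "ICD10CM", code = bopd_icd10,
            stringsAsFactors = FALSE)
        }
      }
    }
    diagnoses <- do.call(rbind, c(list(diagnoses), excl_rows, f603_rows))

    patients <- data.frame(patient_id = ids, gender = gender,
                           birth_date = birth_date, stringsAsFactors = FALSE)
    ehr <- suppressWarnings(ehr_data(patients, encounters, diagnoses))
    truth <- data.frame(patient_id = ids, class = cls, severity = severity,
                        diagnosed = diagnosed, stringsAsFactors = FALSE)
    list(
      ehr = ehr, truth = truth,
      ccsr_map = stats::setNames(tab$ccsr_category, tab$code),
      association_ratings = stats::setNames(tab$association, tab$code)
    )
  })
}

#' Generate expert ratings for synthetic patients
#'
#' Maps each patient's latent class to its canonical chart-review category
#' (`bopd_like -> E`, with a classic flag for the most severe profiles,
#' `psychotic_substance -> B`, `physical_primary -> A`, `other_mental -> C`
#' or `D`, `healthy -> C`), then flips the rating to a random other category
#' with probability `rating_noise`.
#'
#' @param ids patients to rate (must appear in `truth`).
#' @param truth the `truth` component of [generate_cohort()].
#' @param sim the [sim_config()] used for generation.
#' @param seed integer seed (defaults to a seed derived from `sim$seed`).
#' @return data frame in the [read_ratings()] layout with the derived
#'   `positive` column.
#' @export
generate_ratings <- function(ids, truth, sim = sim_config(),
                             seed = derive_seed(sim$seed, "ratings")) {
  idx <- match(ids, truth$patient_id)
  if (anyNA(idx)) stopf("patient %s missing from truth", ids[is.na(idx)][1])
  cls <- truth$class[idx]
  sev <- truth$severity[idx]
  with_seed(seed, {
    category <- character(length(ids))
    category[cls == "bopd_like"] <- "E"
    category[cls == "psychotic_substance"] <- "B"
    category[cls == "physical_primary"] <- "A"
    category[cls == "other_mental"] <-
      ifelse(stats::runif(sum(cls == "other_mental")) < 0.6, "D", "C")
    category[cls == "healthy"] <- "C"
    flip <- stats::runif(length(ids)) < sim$rating_noise
    if (any(flip)) {
      category[flip] <- vapply(category[flip], function(cur) {
        sample(setdiff(c("A", "B", "C", "D", "E"), cur), 1L)
      }, character(1))
    }
    classic <- !flip & cls == "bopd_like" & category == "E" &
      sev >= sim$classic_quantile
    data.frame(patient_id = ids, category = category, classic = classic,
               positive = category == "E", stringsAsFactors = FALSE)
  })
}

#' Write the knowledge-table fixtures
#'
#' Writes `ccsr_map.csv` and `association_ratings.csv` for the builtin code
#' table under `dir`, in the layouts [read_ccsr_map()] and
#' [read_association_ratings()] expect.
#'
#' @param dir output directory.
#' @return invisibly, the two paths.
#' @export
write_knowledge_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- builtin_code_table()
  p1 <- file.path(dir, "ccsr_map.csv")
  p2 <- file.path(dir, "association_ratings.csv")
  utils::write.csv(tab[, c("code", "ccsr_category")], p1, row.names = FALSE)
  utils::write.csv(data.frame(code = tab$code, rating = tab$association),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
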