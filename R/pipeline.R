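# End-to-end driver on synthetic data: simulate -> select -> sample ->
# featurize -> train -> predict -> evaluate.

#' Run the full screening pipeline on synthetic data
#'
#' Executes every stage in pipeline order: generate a synthetic cohort,
#' select the potential and EHR-diagnosed cohorts (logging the selection
#' funnels), derive the rule-based silver positives, draw paired gold
#' training/testing chart-review samples, generate expert ratings, build the
#' feature specification from the two cohorts' prevalent codes, fit the
#' semi-supervised screening model, score the gold test set, and evaluate it
#' with bootstrap confidence intervals.
#'
#' A single master seed fans out to derived per-stage seeds, so a rerun with
#' the same inputs reproduces identical outputs.
#'
#' @param config a [study_config()].
#' @param sim a [sim_config()] (its own seed is overridden by `seed`).
#' @param seed master integer seed.
#' @param n_gold size of each gold chart-review sample.
#' @param out optional directory; when given, writes `scores.csv`,
#'   `report.json`, `funnel.json` and `manifest.json`.
#' @return an object of class `bopd_run`: the fitted model, test scores,
#'   [evaluate_screening()] report, cohort selections and a run manifest.
#' @export
run_end_to_end <- function(config = study_config(), sim = sim_config(),
                           seed = config$random_seed, n_gold = 228L,
                           out = NULL) {
  validate_study_config(config)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    t1 <- Sys.time()
    timings[[stage]] <<- as.numeric(difftime(t1, t0, units = "secs"))
    t0 <<- t1
  }

  sim$seed <- derive_seed(seed, "simulate")
  gen <- generate_cohort(sim)
  tick("simulate")

  potential <- select_potential_cohort(gen$ehr, gen$ccsr_map, config)
  diagnosed <- select_diagnosed_cohort(gen$ehr, gen$ccsr_map, config)
  silver_pos_ids <- select_silver_positives(gen$ehr, diagnosed$included_ids,
                                            gen$ccsr_map, config)
  message(sprintf("potential cohort: %d; diagnosed cohort: %d; silver positives: %d",
                  length(potential$included_ids), length(diagnosed$included_ids),
                  length(silver_pos_ids)))
  message("potential-cohort funnel: ",
          paste(sprintf("%s=%d", names(potential$counts_per_stage),
                        potential$counts_per_stage), collapse = ", "))
  tick("select")

  # chart-review frame: cohort members with known gender
  genders <- gen$ehr$patients$gender[match(potential$included_ids,
                                           gen$ehr$patients$patient_id)]
  frame_ids <- potential$included_ids[genders != "unknown_other"]
  if (length(frame_ids) < length(potential$included_ids)) {
    message(sprintf("excluded %d cohort patient(s) with unknown/other gender",
                    length(potential$included_ids) - length(frame_ids)))
  }
  strata <- assign_stratum(gen$ehr, frame_ids, gen$ccsr_map, config)
  pair <- stratified_sample_pair(strata, n_gold, derive_seed(seed, "sample"))
  ratings_train <- generate_ratings(pair$train, gen$truth, sim,
                                    derive_seed(seed, "ratings"))
  ratings_test <- generate_ratings(pair$test, gen$truth, sim,
                                   derive_seed(seed, "ratings") + 1L)
  tick("sample")

  codes <- select_prevalent_codes(gen$ehr, diagnosed$included_ids,
                                  potential$included_ids, config)
  spec <- build_feature_spec(codes, gen$ccsr_map, gen$association_ratings,
                             gen$ehr, potential$included_ids, config)
  gold_train_x <- featurize(gen$ehr, pair$train, spec, config)
  gold_test_x <- featurize(gen$ehr, pair$test, spec, config)
  pool_ids <- setdiff(potential$included_ids, c(pair$train, pair$test))
  pool_x <- featurize(gen$ehr, pool_ids, spec, config)
  silver_pos_x <- featurize(gen$ehr, silver_pos_ids, spec, config)
  tick("featurize")

  fit <- suppressWarnings(
    bopd_screen(gold_train_x, ratings_train, pool_x, silver_pos_x,
                config, seed = seed))
  tick("train")

  scores <- predict(fit, gold_test_x)
  lab <- ratings_test$positive[match(scores$patient_id,
                                     ratings_test$patient_id)]
  classic <- ratings_test$classic[match(scores$patient_id,
                                        ratings_test$patient_id)]
  report <- evaluate_screening(scores$p_final, lab, classic, config,
                               seed = derive_seed(seed, "bootstrap"))
  tick("evaluate")

  manifest <- list(
    seed = seed,
    stage_seeds = vapply(
      c("simulate", "sample", "ratings", "silver", "model1", "model2",
        "model3", "bootstrap"),
      function(s) derive_seed(seed, s), integer(1)),
    n_patients = sim$n_patients,
    n_gold = n_gold,
    counts = list(
      potential = length(potential$included_ids),
      diagnosed = length(diagnosed$included_ids),
      silver_pos = fit$silver$n_pos,
      silver_neg = fit$silver$n_neg
    ),
    funnel = as.list(potential$counts_per_stage),
    timings_sec = as.list(round(unlist(timings), 3))
  )

  run <- structure(list(
    fit = fit, scores = scores, report = report,
    potential = potential, diagnosed = diagnosed,
    silver_pos_ids = silver_pos_ids,
    gold = list(train = pair$train, test = pair$test,
                ratings_train = ratings_train, ratings_test = ratings_test),
    spec = spec, manifest = manifest
  ), class = "bopd_run")

  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(report$metrics, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_feature_spec(spec, file.path(out, "feature_spec.json"))
  }
  run
}

#' @export
print.bopd_run <- function(x, ...) {
  cat("End-to-end screening run on synthetic data\n")
  cat(sprintf("  cohorts: potential %d, diagnosed %d; silver %d:%d\n",
              x$manifest$counts$potential, x$manifest$counts$diagnosed,
              x$manifest$counts$silver_pos, x$manifest$counts$silver_neg))
  cat(sprintf("  gold sets: %d train / %d test\n",
              length(x$gold$train), length(x$gold$test)))
  print(x$report)
  invisible(x)
}
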