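# The semi-supervised screening pipeline:
#   Model 1 (seed)       — L1 logistic on gold labels (E vs A-D)
#   silver construction  — rule-based positives + seed-model negatives at the
#                          gold class ratio
#   Model 2 (main)       — L1 logistic on the silver set
#   Model 3 (adjustment) — L1 logistic on the gold E-vs-B subset
#   combination          — p_final = p2 if p3 > 0.5, else p2 * p3

lambda_grid_default <- function() 10^seq(0, -6, length.out = 13)

#' Fit an L1-regularized logistic regression with CV-selected penalty
#'
#' The penalty is chosen from a fixed grid of 13 log-spaced strengths
#' spanning six orders of magnitude by mean validation-fold AUROC over
#' stratified k-fold cross-validation (`config$cv_folds`), with ties broken
#' towards the stronger penalty (sparser model).  The final model is refit
#' on all rows at the chosen strength.  Deterministic under a fixed seed.
#'
#' @param x Boolean (or numeric) design matrix with column names.
#' @param y binary response (logical or 0/1); both classes must be present
#'   with at least `cv_folds` rows each.
#' @param config a [study_config()].
#' @param seed integer seed governing the fold assignment.
#' @param lambda penalty grid (decreasing order recommended).
#' @return an object of class `l1_logreg`: coefficients, intercept, chosen
#'   penalty, the CV AUROC table, and the retained feature names.
#' @export
train_l1_logreg <- function(x, y, config = study_config(), seed = config$random_seed,
                            lambda = lambda_grid_default()) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stopf("both classes must be present in y")
  if (min(table(y)) < config$cv_folds) {
    stopf("need at least %d rows per class for %d-fold CV",
          config$cv_folds, config$cv_folds)
  }
  x <- as.matrix(x) * 1
  if (is.null(colnames(x))) stopf("x must have column names")

  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    warnf("dropping %d constant feature(s): %s", sum(const),
          paste(utils::head(colnames(x)[const], 5), collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2L) stopf("need at least 2 non-constant features")
  lambda <- sort(lambda, decreasing = TRUE)

  folds <- with_seed(seed, stratified_folds(y, config$cv_folds))
  cv_auc <- matrix(NA_real_, nrow = config$cv_folds, ncol = length(lambda))
  for (k in seq_len(config$cv_folds)) {
    tr <- folds != k
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 1, lambda = lambda, standardize = FALSE)
    p <- stats::predict(fit, newx = x[!tr, , drop = FALSE], s = lambda,
                        type = "response")
    cv_auc[k, ] <- apply(p, 2, function(pk) auroc(pk, y[!tr]))
  }
  mean_auc <- colMeans(cv_auc)
  best <- max(mean_auc)
  # ties -> smallest index = largest lambda = strongest penalty
  pick <- which(mean_auc == best)[1]

  full <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         lambda = lambda, standardize = FALSE)
  beta <- as.numeric(stats::coef(full, s = lambda[pick]))
  names(beta) <- rownames(stats::coef(full, s = lambda[pick]))
  if (any(!is.finite(beta))) stopf("non-finite coefficients in fitted model")

  structure(list(
    intercept = unname(beta[1]),
    coefficients = beta[-1],
    lambda = lambda[pick],
    lambda_grid = lambda,
    cv_auc = stats::setNames(mean_auc, signif(lambda, 4)),
    feature_names = colnames(x),
    n = nrow(x), class_counts = table(y)
  ), class = "l1_logreg")
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' @export
print.l1_logreg <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("l1_logreg: n = %d (%s), lambda = %.3g, %d/%d nonzero coefficients\n",
              x$n, paste(x$class_counts, collapse = ":"), x$lambda,
              nz, length(x$coefficients)))
  cat(sprintf("  mean CV AUROC at chosen penalty: %.3f\n",
              max(x$cv_auc)))
  invisible(x)
}

#' @export
coef.l1_logreg <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predicted positive-class probabilities
#'
#' @param object an `l1_logreg` fit.
#' @param newx matrix whose columns include the model's features (matched by
#'   name; extra columns ignored).
#' @param ... ignored.
#' @return named numeric vector of probabilities.
#' @export
predict.l1_logreg <- function(object, newx, ...) {
  newx <- as.matrix(newx) * 1
  miss <- setdiff(object$feature_names, colnames(newx))
  if (length(miss)) {
    stopf("newx is missing model feature(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  eta <- object$intercept +
    drop(newx[, object$feature_names, drop = FALSE] %*% object$coefficients)
  stats::setNames(stats::plogis(eta), rownames(newx))
}

#' Number of silver negatives for a given number of silver positives
#'
#' The silver set replicates the gold-label class ratio
#' (`gold_ratio_pos : gold_ratio_neg`, 66:162 by default):
#' `floor(n_pos * gold_ratio_neg / gold_ratio_pos)`.
#'
#' @param n_pos number of silver positives (> 0).
#' @param config a [study_config()].
#' @return integer count of silver negatives.
#' @export
#' @examples
#' silver_negative_count(66)    # 162
#' silver_negative_count(5961)  # 14631
silver_negative_count <- function(n_pos, config = study_config()) {
  if (length(n_pos) != 1L || is.na(n_pos) || n_pos <= 0) {
    stopf("n_pos must be a single positive count")
  }
  as.integer(floor(n_pos * as.numeric(config$gold_ratio_neg) /
                     config$gold_ratio_pos))
}

#' Assemble the silver-labelled training set
#'
#' Applies the seed model to the unlabelled pool (the potential cohort with
#' the gold-label patients removed), takes the patients predicted negative
#' (probability strictly below the decision threshold), and draws a simple
#' random sample of [silver_negative_count()] of them as silver negatives to
#' pair with the rule-selected silver positives.
#'
#' @param model1 the seed `l1_logreg` fit on gold labels.
#' @param pool_x feature matrix of the unlabelled pool, rows named by
#'   patient id; must not contain gold-label patients.
#' @param silver_pos_x feature matrix of the rule-selected silver positives.
#' @param config a [study_config()].
#' @param seed integer seed for the negative draw.
#' @param gold_ids patient ids of the gold sets, used to enforce the
#'   pool-exclusion precondition.
#' @return a list with the stacked feature matrix `x`, labels `y`,
#'   `provenance = "silver"`, and the counts `n_pos`, `n_neg`.
#' @export
build_silver_set <- function(model1, pool_x, silver_pos_x,
                             config = study_config(), seed = config$random_seed,
                             gold_ids = character()) {
  overlap <- intersect(rownames(pool_x), gold_ids)
  if (length(overlap)) {
    stopf("unlabelled pool contains %d gold-label patient(s), e.g. %s",
          length(overlap), overlap[1])
  }
  n_pos <- nrow(silver_pos_x)
  need <- silver_negative_count(n_pos, config)
  p1 <- predict(model1, pool_x)
  neg_ids <- rownames(pool_x)[p1 < config$decision_threshold]
  if (length(neg_ids) < need) {
    stopf("only %d predicted negatives in pool; need %d (short by %d)",
          length(neg_ids), need, need - length(neg_ids))
  }
  picked <- with_seed(seed, sort(neg_ids[sample.int(length(neg_ids), need)]))
  x <- rbind(silver_pos_x, pool_x[picked, , drop = FALSE])
  list(x = x, y = c(rep(1L, n_pos), rep(0L, need)),
       provenance = "silver", n_pos = n_pos, n_neg = need)
}

#' Fit the semi-supervised BoPD screening model
#'
#' The main fitting function.  Trains the seed model (Model 1) on the
#' gold-labelled chart-review set (positive = category E), assembles the
#' silver set ([build_silver_set()]), trains the main model (Model 2) on it,
#' trains the adjustment model (Model 3) on the gold subset restricted to
#' categories E and B (positive = E), and packages the three fits with the
#' decision threshold.  All three models share one feature specification.
#'
#' @param gold_x Boolean feature matrix of the gold training set, rows named
#'   by patient id.
#' @param gold_ratings data frame from [read_ratings()] covering every row
#'   of `gold_x` (categories A-E; both E and B must be present).
#' @param pool_x feature matrix of the potential cohort minus the gold sets.
#' @param silver_pos_x feature matrix of the rule-selected silver positives.
#' @param config a [study_config()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return an object of class `bopd_screen` with components `model1`,
#'   `model2`, `model3`, `threshold`, `silver` (counts), `feature_names`.
#' @seealso [predict.bopd_screen()], [combine_probabilities()]
#' @export
bopd_screen <- function(gold_x, gold_ratings, pool_x, silver_pos_x,
                        config = study_config(), seed = config$random_seed) {
  ridx <- match(rownames(gold_x), gold_ratings$patient_id)
  if (anyNA(ridx)) {
    stopf("gold_ratings missing patient(s): %s",
          paste(utils::head(rownames(gold_x)[is.na(ridx)], 5), collapse = ", "))
  }
  cat_gold <- gold_ratings$category[ridx]
  y_gold <- gold_ratings$positive[ridx]
  if (!any(cat_gold == "E") || !any(cat_gold == "B")) {
    stopf("gold training set must contain both category E and category B rows")
  }

  model1 <- train_l1_logreg(gold_x, y_gold, config,
                            seed = derive_seed(seed, "model1"))
  silver <- build_silver_set(model1, pool_x, silver_pos_x, config,
                             seed = derive_seed(seed, "silver"),
                             gold_ids = rownames(gold_x))
  model2 <- train_l1_logreg(silver$x, silver$y, config,
                            seed = derive_seed(seed, "model2"))

  sub <- cat_gold %in% c("E", "B")
  model3 <- train_l1_logreg(gold_x[sub, , drop = FALSE],
                            cat_gold[sub] == "E", config,
                            seed = derive_seed(seed, "model3"))

  structure(list(
    model1 = model1, model2 = model2, model3 = model3,
    threshold = config$decision_threshold,
    silver = list(n_pos = silver$n_pos, n_neg = silver$n_neg),
    adjustment_n = sum(sub),
    feature_names = colnames(gold_x),
    config = config
  ), class = "bopd_screen")
}

#' Combine main and adjustment probabilities
#'
#' The final screening probability keeps the main model's probability when
#' the adjustment model is confident the patient is not a severe
#' psychotic/substance presentation (`p3 > 0.5`), and otherwise shrinks it
#' multiplicatively: `p_final = p2` if `p3 > 0.5`, else `p2 * p3`.  Hence
#' `p_final <= p2` always — the adjustment can only remove positives.
#'
#' @param p2,p3 probabilities from the main and adjustment models (recycled).
#' @return numeric vector of combined probabilities.
#' @export
#' @examples
#' combine_probabilities(0.8, 0.6)  # 0.8
#' combine_probabilities(0.8, 0.4)  # 0.32
combine_probabilities <- function(p2, p3) {
  stopifnot(all(p2 >= 0 & p2 <= 1, na.rm = TRUE),
            all(p3 >= 0 & p3 <= 1, na.rm = TRUE))
  ifelse(p3 > 0.5, p2, p2 * p3)
}

#' Screening decision
#'
#' Positive iff the final probability strictly exceeds the decision
#' threshold; a probability exactly at the threshold screens negative.
#'
#' @param p_final numeric probabilities.
#' @param config a [study_config()].
#' @return logical vector.
#' @export
screen_positive <- function(p_final, config = study_config()) {
  p_final > config$decision_threshold
}

#' Score patients with a fitted screening model
#'
#' @param object a [bopd_screen()] fit.
#' @param newx Boolean feature matrix conforming to the fit's feature
#'   specification, rows named by patient id.
#' @param ... ignored.
#' @return data frame with `patient_id`, `p2`, `p3`, `p_final` and logical
#'   `screen_positive`.
#' @export
predict.bopd_screen <- function(object, newx, ...) {
  p2 <- predict(object$model2, newx)
  p3 <- predict(object$model3, newx)
  p_final <- combine_probabilities(p2, p3)
  data.frame(
    patient_id = rownames(newx),
    p2 = unname(p2), p3 = unname(p3), p_final = unname(p_final),
    screen_positive = unname(p_final > object$threshold),
    stringsAsFactors = FALSE
  )
}

#' @export
print.bopd_screen <- function(x, ...) {
  cat("Semi-supervised BoPD screening model\n")
  cat(sprintf("  seed model (gold):        n = %d (%s)\n", x$model1$n,
              paste(x$model1$class_counts, collapse = ":")))
  cat(sprintf("  main model (silver):      n = %d (%d pos : %d neg)\n",
              x$model2$n, x$silver$n_pos, x$silver$n_neg))
  cat(sprintf("  adjustment model (E v B): n = %d\n", x$adjustment_n))
  cat(sprintf("  decision threshold:       %.2f\n", x$threshold))
  invisible(x)
}

#' @export
summary.bopd_screen <- function(object, ...) {
  nz <- function(m) sum(m$coefficients != 0)
  print(object)
  cat(sprintf("  nonzero coefficients: model1 %d, model2 %d, model3 %d (of %d features)\n",
              nz(object$model1), nz(object$model2), nz(object$model3),
              length(object$feature_names)))
  cat(sprintf("  chosen penalties: %.3g / %.3g / %.3g\n",
              object$model1$lambda, object$model2$lambda, object$model3$lambda))
  invisible(object)
}

#' @export
coef.bopd_screen <- function(object, ...) {
  feats <- c("(Intercept)", object$feature_names)
  out <- matrix(0, nrow = length(feats), ncol = 3,
                dimnames = list(feats, c("model1", "model2", "model3")))
  for (nm in colnames(out)) {
    m <- object[[nm]]
    out["(Intercept)", nm] <- m$intercept
    out[names(m$coefficients), nm] <- m$coefficients
  }
  out
}
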