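# Evaluation metrics with bootstrap percentile confidence intervals.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly chosen positive receives a higher score
#' than a uniformly chosen negative, with ties counted one half — computed
#' via midranks, equivalent to the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores.
#' @param labels binary labels (logical or 0/1); both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at the decision threshold
#'
#' Dichotomizes scores at `config$decision_threshold` (strictly greater is
#' positive) and reports accuracy, positive predictive value, sensitivity,
#' specificity, and — when classic flags are supplied — the sensitivity
#' restricted to classic-flagged positives.  With no predicted positives the
#' PPV is undefined and reported as `NA` with a warning.
#'
#' @param scores numeric screening probabilities.
#' @param labels binary labels.
#' @param classic_flags optional logical vector; flagged rows must be
#'   labelled positive.
#' @param config a [study_config()].
#' @return named numeric vector `accuracy, ppv, sensitivity, specificity`
#'   (plus `classic_sensitivity` when flags are given).
#' @export
threshold_metrics <- function(scores, labels, classic_flags = NULL,
                              config = study_config()) {
  labels <- as.logical(labels)
  pred <- scores > config$decision_threshold
  if (!is.null(classic_flags)) {
    classic_flags <- as.logical(classic_flags)
    if (any(classic_flags & !labels)) {
      stopf("classic flags must be a subset of the positive labels")
    }
  }
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  ppv <- if (tp + fp == 0L) {
    warnf("no predicted positives; PPV undefined")
    NA_real_
  } else tp / (tp + fp)
  out <- c(
    accuracy = (tp + tn) / length(labels),
    ppv = ppv,
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  )
  if (!is.null(classic_flags)) {
    out <- c(out, classic_sensitivity = if (any(classic_flags)) {
      sum(pred & classic_flags) / sum(classic_flags)
    } else NA_real_)
  }
  out
}

metric_vector <- function(scores, labels, classic_flags, config) {
  m <- suppressWarnings(
    threshold_metrics(scores, labels, classic_flags, config))
  a <- if (length(unique(as.logical(labels))) == 2L) {
    auroc(scores, labels)
  } else NA_real_
  c(auroc = a, m)
}

#' Evaluate a screening model with bootstrap confidence intervals
#'
#' Computes AUROC and the threshold metrics on a labelled test set, and
#' attaches percentile bootstrap confidence intervals from
#' `config$bootstrap_reps` row resamples (patients resampled with
#' replacement).  Replicates on which a metric is undefined — a single-class
#' resample for AUROC/sensitivity/specificity, no predicted positives for
#' PPV, no classic rows for classic sensitivity — are skipped for that
#' metric and counted; a metric undefined on more than half the replicates
#' gets a missing interval.
#'
#' @inheritParams threshold_metrics
#' @param seed integer seed for the resampling.
#' @return an `evaluation_report`: data frame of estimates and intervals
#'   plus the run metadata (`n`, threshold, replicates, seed, skip counts).
#' @export
evaluate_screening <- function(scores, labels, classic_flags = NULL,
                               config = study_config(),
                               seed = config$random_seed) {
  labels <- as.logical(labels)
  n <- length(scores)
  if (n < 2L) stopf("need at least 2 observations")
  point <- metric_vector(scores, labels, classic_flags, config)

  reps <- config$bootstrap_reps
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      metric_vector(scores[i], labels[i],
                    if (is.null(classic_flags)) NULL else classic_flags[i],
                    config)
    }, numeric(length(point)))
  })
  boot <- matrix(boot, nrow = length(point),
                 dimnames = list(names(point), NULL))

  alpha <- 1 - config$ci_level
  skipped <- apply(boot, 1, function(v) sum(is.na(v)))
  ci <- t(apply(boot, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < reps / 2) return(c(NA_real_, NA_real_))
    stats::quantile(v[ok], probs = c(alpha / 2, 1 - alpha / 2),
                    names = FALSE, type = 7)
  }))

  tab <- data.frame(
    metric = names(point), estimate = unname(point),
    lower = ci[, 1], upper = ci[, 2],
    skipped_replicates = unname(skipped),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(metrics = tab, n = n,
                 threshold = config$decision_threshold,
                 bootstrap_reps = reps, ci_level = config$ci_level,
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Screening evaluation: n = %d, threshold %.2f, %d bootstrap reps (%.0f%% CI)\n",
              x$n, x$threshold, x$bootstrap_reps, 100 * x$ci_level))
  for (i in seq_len(nrow(x$metrics))) {
    r <- x$metrics[i, ]
    ci <- if (is.na(r$lower)) "CI unavailable" else
      sprintf("[%.3f, %.3f]", r$lower, r$upper)
    cat(sprintf("  %-20s %6.3f  %s%s\n", r$metric, r$estimate, ci,
                if (r$skipped_replicates > 0)
                  sprintf("  (%d replicates skipped)", r$skipped_replicates)
                else ""))
  }
  invisible(x)
}
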