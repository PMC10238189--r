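#' Youden-optimal univariate threshold
#'
#' Scans candidate thresholds at the midpoints between adjacent distinct
#' observed values (plus -Inf and +Inf) and returns the one maximizing
#' Youden's J = TPR - FPR, where a sample is called positive when its value
#' is strictly greater than the threshold. Ties in J are broken toward the
#' higher threshold (higher specificity).
#'
#' @param case_values,control_values Marker values in each group.
#' @return The selected threshold (may be `-Inf`/`Inf`).
#' @examples
#' univariate_threshold(c(10, 20, 30), c(0, 0, 1))  # 5.5
#' @export
univariate_threshold <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("both groups must contain at least one value.", class = "dmspr_domain_error")
  }
  v <- sort(unique(c(case_values, control_values)))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  j <- vapply(cand, function(t)
    mean(case_values > t) - mean(control_values > t), numeric(1))
  cand[max(which(j == max(j)))]
}

#' Clinical sensitivity and specificity
#'
#' Sensitivity is the fraction of cases called positive, specificity the
#' fraction of controls called negative, both in percent. Printed clinical
#' percentages are conventionally integers, so the rounded values
#' (round-half-away-from-zero) are reported alongside the exact ones.
#'
#' @param calls Logical vector of positive calls.
#' @param labels Vector with values "case"/"control" (or a logical with
#'   `TRUE` = case), aligned with `calls`.
#' @return One-row tibble: `sensitivity`, `specificity` (exact percent),
#'   `sensitivity_pct`, `specificity_pct` (integer percent), `n_case`,
#'   `n_control`.
#' @examples
#' # 35 of 39 cases and 6 of 33 controls called positive -> 90% / 82%
#' calls <- c(rep(c(TRUE, FALSE), c(35, 4)), rep(c(TRUE, FALSE), c(6, 27)))
#' labels <- rep(c("case", "control"), c(39, 33))
#' sensitivity_specificity(calls, labels)
#' @export
sensitivity_specificity <- function(calls, labels) {
  is_case <- if (is.logical(labels)) labels else labels == "case"
  if (length(calls) != length(is_case)) {
    abort("calls and labels must be aligned.", class = "dmspr_schema_error")
  }
  n_case <- sum(is_case); n_control <- sum(!is_case)
  if (n_case == 0 || n_control == 0) {
    abort("both classes must be present.", class = "dmspr_undefined_metric_error")
  }
  sens <- sum(calls[is_case]) / n_case * 100
  spec <- sum(!calls[!is_case]) / n_control * 100
  round_half_up <- function(x) floor(x + 0.5)
  tibble(sensitivity = sens, specificity = spec,
         sensitivity_pct = as.integer(round_half_up(sens)),
         specificity_pct = as.integer(round_half_up(spec)),
         n_case = n_case, n_control = n_control)
}

#' Univariate marker evaluation over a cohort
#'
#' Applies [univariate_threshold()] and [sensitivity_specificity()] to each
#' marker column.
#'
#' @param cohort A cohort tibble with a `label` column ("case"/"control")
#'   and one value column per marker.
#' @param markers Marker column names; default every numeric column except
#'   covariates `age`/`pack_years`.
#' @return A tibble with one row per marker.
#' @export
evaluate_markers <- function(cohort, markers = NULL) {
  markers <- markers %||% setdiff(
    names(cohort)[vapply(cohort, is.numeric, logical(1))],
    c("age", "pack_years"))
  is_case <- cohort$label == "case"
  purrr::map_dfr(markers, function(m) {
    thr <- univariate_threshold(cohort[[m]][is_case], cohort[[m]][!is_case])
    met <- sensitivity_specificity(cohort[[m]] > thr, cohort$label)
    dplyr::bind_cols(tibble(marker = m, threshold = thr), met)
  })
}

# IRLS logistic regression with ridge jitter on the Hessian so separable
# folds stay solvable; returns coefficients and convergence flag.
.fit_logistic_irls <- function(X, y, max_iter = 200, ridge = 1e-6, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  const <- which(apply(Xd[, -1, drop = FALSE], 2, function(v) diff(range(v)) == 0))
  if (length(const) > 0) {
    warn(sprintf("dropping constant feature(s): %s",
                 paste(colnames(X)[const], collapse = ", ")))
    Xd <- Xd[, c(1L, setdiff(seq_len(ncol(X)) + 1L, const + 1L)), drop = FALSE]
  }
  p <- ncol(Xd)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    H <- crossprod(Xd, Xd * w) + diag(ridge, p)
    g <- crossprod(Xd, y - mu)
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn("logistic IRLS did not converge within the iteration budget; using the last iterate.")
  }
  list(coefficients = stats::setNames(drop(beta), colnames(Xd)),
       converged = converged, n_iterations = it, dropped = names(const))
}

#' Full-data logistic fit (IRLS)
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares with a 1e-6 ridge jitter on the Hessian, which keeps perfectly
#' separated data solvable (coefficients then grow until the step tolerance
#' or iteration budget stops them).
#'
#' @param cohort A cohort tibble with `label` and feature columns.
#' @param feature_set Feature column names.
#' @param max_iter,ridge IRLS controls.
#' @return List with `coefficients`, `converged`, `n_iterations`.
#' @export
fit_panel_logistic <- function(cohort, feature_set, max_iter = 200, ridge = 1e-6) {
  X <- as.matrix(cohort[feature_set])
  y <- as.numeric(cohort$label == "case")
  .fit_logistic_irls(X, y, max_iter = max_iter, ridge = ridge)
}

#' Leave-one-out cross-validated logistic panel probabilities
#'
#' For each sample, a logistic model on the remaining samples predicts the
#' held-out sample's case probability. These held-out probabilities - not
#' refit thresholds - are what enters the ROC.
#'
#' @inheritParams fit_panel_logistic
#' @return A tibble `sample_id` (when present), `label`, `prob`.
#' @export
loocv_logistic <- function(cohort, feature_set, max_iter = 200, ridge = 1e-6) {
  n <- nrow(cohort)
  if (n < 10) abort("need at least 10 samples for LOOCV.", class = "dmspr_domain_error")
  if (!all(feature_set %in% names(cohort))) {
    abort("feature_set contains unknown columns.", class = "dmspr_schema_error")
  }
  X <- as.matrix(cohort[feature_set])
  y <- as.numeric(cohort$label == "case")
  prob <- vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(
      .fit_logistic_irls(X[-i, , drop = FALSE], y[-i],
                         max_iter = max_iter, ridge = ridge))
    keep <- setdiff(names(fit$coefficients), "(Intercept)")
    eta <- fit$coefficients[["(Intercept)"]] +
      sum(X[i, keep] * fit$coefficients[keep])
    1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
  }, numeric(1))
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  out <- tibble(label = cohort$label, prob = prob)
  if ("sample_id" %in% names(cohort)) {
    out <- dplyr::bind_cols(tibble(sample_id = cohort$sample_id), out)
  }
  out
}

#' ROC curve and AUC
#'
#' Sweeps the distinct predicted probabilities as thresholds (a sample is
#' positive when its probability is >= the threshold; equal probabilities
#' collapse into a single ROC vertex) and integrates the resulting monotone
#' step curve by the trapezoidal rule, which equals the Mann-Whitney
#' statistic with ties counted one half.
#'
#' @param probabilities Predicted case probabilities (any monotone score
#'   works; the AUC is invariant to strictly monotone transforms).
#' @param labels "case"/"control" (or logical, `TRUE` = case).
#' @return List of class `roc_result`: `roc` (tibble `threshold`, `fpr`,
#'   `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(probabilities, labels) {
  is_case <- if (is.logical(labels)) labels else labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present.", class = "dmspr_undefined_metric_error")
  }
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probabilities[is_case] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(probabilities[!is_case] >= t) / n0, numeric(1))
  roc <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc, n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d cases, %d controls, %d vertices)\n",
              x$auc, x$n_case, x$n_control, nrow(x$roc)))
  invisible(x)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Cases and controls are resampled within class (so both classes are
#' present in every resample) and the percentile interval of the resampled
#' AUCs is returned.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; same seed, same interval.
#' @param level Confidence level.
#' @return One-row tibble `auc`, `ci_low`, `ci_high`, `n_boot`, `level`.
#' @export
bootstrap_auc_ci <- function(probabilities, labels, n_boot = 2000,
                             seed = NULL, level = 0.95) {
  if (n_boot < 100) abort("n_boot must be >= 100.", class = "dmspr_domain_error")
  is_case <- if (is.logical(labels)) labels else labels == "case"
  p1 <- probabilities[is_case]; p0 <- probabilities[!is_case]
  n1 <- length(p1); n0 <- length(p0)
  run <- function() {
    vapply(seq_len(n_boot), function(b) {
      b1 <- p1[sample.int(n1, n1, replace = TRUE)]
      b0 <- p0[sample.int(n0, n0, replace = TRUE)]
      .auc_rank(b1, b0)
    }, numeric(1))
  }
  aucs <- if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
  qs <- quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble(auc = .auc_rank(p1, p0), ci_low = qs[1], ci_high = qs[2],
         n_boot = as.integer(n_boot), level = level)
}

# Mann-Whitney AUC with ties counted one half
.auc_rank <- function(p_case, p_control) {
  r <- rank(c(p_case, p_control))
  n1 <- length(p_case); n0 <- length(p_control)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a marker panel end to end
#'
#' LOOCV logistic probabilities, ROC/AUC, stratified bootstrap CI, and the
#' panel operating point (Youden-optimal threshold on the held-out
#' probabilities) with its sensitivity and specificity, plus the univariate
#' per-marker table.
#'
#' @param cohort A cohort tibble.
#' @param markers Marker columns forming the panel.
#' @param covariates Optional additional feature columns (e.g. `age`,
#'   `pack_years`).
#' @param n_boot,seed,level Bootstrap controls, see [bootstrap_auc_ci()].
#' @return An object of class `panel_eval`; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
evaluate_panel <- function(cohort, markers, covariates = NULL,
                           n_boot = 2000, seed = NULL, level = 0.95) {
  features <- c(markers, covariates)
  probs <- loocv_logistic(cohort, features)
  roc <- roc_auc(probs$prob, probs$label)
  ci <- bootstrap_auc_ci(probs$prob, probs$label, n_boot = n_boot,
                         seed = seed, level = level)
  is_case <- probs$label == "case"
  op_thr <- univariate_threshold(probs$prob[is_case], probs$prob[!is_case])
  op <- sensitivity_specificity(probs$prob > op_thr, probs$label)
  structure(list(markers = markers, covariates = covariates,
                 probabilities = probs, roc = roc, auc = roc$auc,
                 auc_ci_low = ci$ci_low, auc_ci_high = ci$ci_high,
                 n_boot = n_boot, seed = seed, level = level,
                 operating_threshold = op_thr, operating_point = op,
                 univariate = evaluate_markers(cohort, markers)),
            class = "panel_eval")
}

#' @export
print.panel_eval <- function(x, ...) {
  cat(sprintf("<panel_eval> %s\n", paste(x$markers, collapse = " + ")))
  cat(sprintf("  LOOCV AUC %.3f (%d%% CI %.3f-%.3f, %d stratified resamples)\n",
              x$auc, round(x$level * 100), x$auc_ci_low, x$auc_ci_high, x$n_boot))
  cat(sprintf("  operating point: sensitivity %d%%, specificity %d%%\n",
              x$operating_point$sensitivity_pct, x$operating_point$specificity_pct))
  invisible(x)
}

#' @method tidy panel_eval
#' @export
tidy.panel_eval <- function(x, ...) x$univariate

#' @method glance panel_eval
#' @export
glance.panel_eval <- function(x, ...) {
  tibble(panel = paste(x$markers, collapse = "+"),
         auc = x$auc, ci_low = x$auc_ci_low, ci_high = x$auc_ci_high,
         sensitivity_pct = x$operating_point$sensitivity_pct,
         specificity_pct = x$operating_point$specificity_pct,
         n_case = x$operating_point$n_case,
         n_control = x$operating_point$n_control,
         n_boot = as.integer(x$n_boot))
}

#' @method autoplot panel_eval
#' @export
autoplot.panel_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("LOOCV ROC, AUC %.2f (%.2f-%.2f)",
                                  object$auc, object$auc_ci_low, object$auc_ci_high))
}

#' Exhaustive marker-subset search ranked by LOOCV AUC
#'
#' Evaluates every nonempty subset of the candidate markers with
#' [loocv_logistic()] + [roc_auc()] and ranks subsets by AUC (ties broken
#' toward the smaller subset).
#'
#' @param cohort A cohort tibble.
#' @param candidate_markers Up to `max_markers` marker columns.
#' @param max_markers Combinatorial guard on the exhaustive search.
#' @return A tibble `markers` (collapsed with "+"), `n_markers`, `auc`,
#'   sorted by decreasing AUC.
#' @export
panel_search <- function(cohort, candidate_markers, max_markers = 8) {
  k <- length(candidate_markers)
  if (k > max_markers) {
    abort(sprintf("%d candidate markers exceed the exhaustive-search limit of %d.",
                  k, max_markers),
          class = "dmspr_combinatorial_limit_error")
  }
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(candidate_markers, m, simplify = FALSE)), recursive = FALSE)
  res <- purrr::map_dfr(subsets, function(ms) {
    probs <- loocv_logistic(cohort, ms)
    tibble(markers = paste(ms, collapse = "+"), n_markers = length(ms),
           auc = roc_auc(probs$prob, probs$label)$auc)
  })
  dplyr::arrange(res, dplyr::desc(.data$auc), .data$n_markers)
}
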