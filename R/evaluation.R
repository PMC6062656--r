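#' ROC curve over the discrete score support
#'
#' EWS aggregate scores are small integers, so the ROC curve is computed over
#' the observed score cutoffs only: for each cutoff `c` the alerting rule
#' "score >= c" yields one (false-positive rate, sensitivity) point. The
#' curve is anchored at (0, 0) (cutoff above the maximum score) and (1, 1)
#' (alert on everything).
#'
#' @param scores numeric vector of scores (higher = more at risk).
#' @param labels logical (or 0/1) outcome labels.
#' @return data.frame with columns `cutoff`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  z <- check_two_class(scores, labels)
  cutoffs <- sort(unique(z$scores), decreasing = TRUE)
  tp <- vapply(cutoffs, function(ct) sum(z$scores >= ct & z$labels), numeric(1))
  fp <- vapply(cutoffs, function(ct) sum(z$scores >= ct & !z$labels), numeric(1))
  data.frame(cutoff = c(Inf, cutoffs),
             fpr = c(0, fp / z$n_neg),
             tpr = c(0, tp / z$n_pos))
}

#' Precision-recall curve over the discrete score support
#'
#' @inheritParams roc_curve
#' @return data.frame with columns `cutoff`, `recall` (sensitivity) and
#'   `precision` (positive predictive value), ordered by increasing recall.
#' @export
pr_curve <- function(scores, labels) {
  z <- check_two_class(scores, labels, need_neg = FALSE)
  cutoffs <- sort(unique(z$scores), decreasing = TRUE)
  tp <- vapply(cutoffs, function(ct) sum(z$scores >= ct & z$labels), numeric(1))
  pred <- vapply(cutoffs, function(ct) sum(z$scores >= ct), numeric(1))
  data.frame(cutoff = cutoffs, recall = tp / z$n_pos, precision = tp / pred)
}

#' Area under the ROC curve (trapezoidal, mid-rank tie handling)
#'
#' Computed by the trapezoidal rule over the discrete-cutoff ROC points of
#' [roc_curve()]. Because each tied score group contributes a single diagonal
#' segment, this equals the Mann-Whitney concordance probability
#' `P(s+ > s-) + 0.5 P(s+ = s-)` exactly (the mid-rank convention).
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_curve(scores, labels)
  trapezoid_area(pts$fpr, pts$tpr)
}

trapezoid_area <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average-precision convention: `sum over cutoffs of
#' (recall_c - recall_{c-1}) * precision_c`, descending through the score
#' support. Trapezoidal interpolation of PR curves is a known optimistic
#' bias and is deliberately not used. For a constant (uninformative) score
#' this reduces to the prevalence.
#'
#' @inheritParams roc_curve
#' @return AUC-PR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  pts <- pr_curve(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

check_two_class <- function(scores, labels, need_neg = TRUE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || length(scores) == 0L)
    stop("scores and labels must be non-empty vectors of equal length")
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must not contain missing values")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L)
    stop("evaluation needs at least one positive label")
  if (need_neg && n_neg == 0L)
    stop("evaluation needs at least one negative label")
  list(scores = scores, labels = labels, n_pos = n_pos, n_neg = n_neg)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance estimate of the Mann-Whitney AUC from the
#' positive- and negative-class placement values (DeLong et al. 1988),
#' with a normal-approximation interval clipped to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `se`, and `ci` (length-2 vector).
#' @export
delong_auc_ci <- function(scores, labels, level = 0.95) {
  z <- check_two_class(scores, labels)
  stopifnot(level > 0, level < 1)
  x <- z$scores[z$labels]; y <- z$scores[!z$labels]
  m <- length(x); n <- length(y)
  sy <- sort(y); sx <- sort(x)
  # placements: fraction of the other class below (mid-rank at ties)
  v10 <- (findInterval(x, sy, left.open = TRUE) + findInterval(x, sy)) / (2 * n)
  v01 <- 1 - (findInterval(y, sx, left.open = TRUE) + findInterval(y, sx)) / (2 * m)
  auc <- mean(v10)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(max(var_auc, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       ci = c(max(0, auc - zq * se), min(1, auc + zq * se)))
}

#' Stratified bootstrap confidence interval for a score-based metric
#'
#' Resamples positives and negatives separately (keeping the class balance),
#' recomputes `stat_fn(scores, labels)` on each resample, and reports the
#' percentile interval. Seeded and reproducible bit-for-bit.
#'
#' @inheritParams roc_curve
#' @param stat_fn function of `(scores, labels)`, e.g. [roc_auc()] or
#'   [pr_auc()].
#' @param n_boot number of resamples (default 2000).
#' @param seed integer seed for the resampling RNG.
#' @param level confidence level (default 0.95).
#' @return list with `estimate`, `ci`, and the vector of bootstrap `replicates`.
#' @export
bootstrap_metric_ci <- function(scores, labels, stat_fn = roc_auc,
                                n_boot = 2000L, seed = 1L, level = 0.95) {
  z <- check_two_class(scores, labels)
  stopifnot(n_boot >= 10L, level > 0, level < 1)
  ip <- which(z$labels); ineg <- which(!z$labels)
  est <- stat_fn(z$scores, z$labels)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    stat_fn(z$scores[idx], z$labels[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  list(estimate = est,
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7)),
       replicates = reps)
}

#' Full discrimination evaluation of a score vector
#'
#' Bundles ROC and precision-recall analyses: AUC (trapezoidal over the
#' integer score support, equal to the mid-rank Mann-Whitney concordance)
#' with its DeLong confidence interval, and AUC-PR (average precision) with a
#' stratified-bootstrap interval. A bootstrap AUC interval is also returned
#' as a cross-check on DeLong.
#'
#' @inheritParams roc_curve
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples for the AUC-PR interval (default 2000;
#'   set to 0 to skip bootstrap intervals).
#' @param seed seed for the bootstrap RNG.
#' @return object of class `ews_evaluation`: `auc`, `auc_ci`, `auc_ci_boot`,
#'   `auc_pr`, `auc_pr_ci`, `roc_points`, `pr_points`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(scores, labels, level = 0.95, n_boot = 2000L,
                            seed = 1L) {
  z <- check_two_class(scores, labels)
  roc_pts <- roc_curve(scores, labels)
  pr_pts <- pr_curve(scores, labels)
  auc <- trapezoid_area(roc_pts$fpr, roc_pts$tpr)
  dl <- delong_auc_ci(scores, labels, level)
  auc_pr <- sum(diff(c(0, pr_pts$recall)) * pr_pts$precision)
  if (n_boot > 0L) {
    bpr <- bootstrap_metric_ci(scores, labels, pr_auc, n_boot, seed, level)
    bauc <- bootstrap_metric_ci(scores, labels, roc_auc, n_boot, seed + 1L, level)
    auc_pr_ci <- bpr$ci; auc_ci_boot <- bauc$ci
  } else {
    auc_pr_ci <- c(NA_real_, NA_real_); auc_ci_boot <- c(NA_real_, NA_real_)
  }
  structure(list(auc = auc, auc_ci = dl$ci, auc_se = dl$se,
                 auc_ci_boot = auc_ci_boot,
                 auc_pr = auc_pr, auc_pr_ci = auc_pr_ci,
                 roc_points = roc_pts, pr_points = pr_pts,
                 n_pos = z$n_pos, n_neg = z$n_neg, level = level),
            class = "ews_evaluation")
}

#' @export
print.ews_evaluation <- function(x, ...) {
  cat(sprintf("Score evaluation: %d positives / %d negatives\n",
              x$n_pos, x$n_neg))
  cat(sprintf("  AUC    %.3f (%.0f%% CI %.3f-%.3f, DeLong)\n",
              x$auc, 100 * x$level, x$auc_ci[1], x$auc_ci[2]))
  if (!anyNA(x$auc_pr_ci))
    cat(sprintf("  AUC-PR %.3f (%.0f%% CI %.3f-%.3f, bootstrap)\n",
                x$auc_pr, 100 * x$level, x$auc_pr_ci[1], x$auc_pr_ci[2]))
  else cat(sprintf("  AUC-PR %.3f\n", x$auc_pr))
  invisible(x)
}

#' Threshold-substitution analysis between two EWS definitions
#'
#' Quantifies which vital signs drive the performance difference between a
#' base scoring system and a donor system: for each scored variable in turn,
#' the base definition is rebuilt with that single variable's band table
#' taken from the donor (everything else unchanged), the labeled
#' observations are rescored, and the relative AUC change
#' `(AUC_hybrid - AUC_base) / AUC_base * 100` (in percent) is reported.
#'
#' @param base,donor [ews_definition()]s sharing the same variable set.
#' @param observations data.frame of complete (preprocessed) observation
#'   sets.
#' @param labels logical outcome labels aligned with `observations` rows.
#' @return object of class `substitution_report`: `base_auc` and a
#'   data.frame `by_variable` with `variable`, `auc`, `pct_change`.
#' @export
substitution_analysis <- function(base, donor, observations, labels) {
  stopifnot(inherits(base, "ews_definition"), inherits(donor, "ews_definition"))
  if (!setequal(names(base$tables), names(donor$tables)))
    stop("substitution_analysis: base and donor must score the same variables")
  base_auc <- roc_auc(score_observations(observations, base), labels)
  vars <- names(base$tables)
  auc_i <- vapply(vars, function(v) {
    hybrid <- base
    hybrid$tables[[v]] <- donor$tables[[v]]
    hybrid$name <- sprintf("%s [%s from %s]", base$name, v, donor$name)
    roc_auc(score_observations(observations, hybrid), labels)
  }, numeric(1))
  structure(list(base_auc = base_auc,
                 by_variable = data.frame(
                   variable = vars,
                   auc = unname(auc_i),
                   pct_change = unname((auc_i - base_auc) / base_auc * 100))),
            class = "substitution_report")
}

#' @export
print.substitution_report <- function(x, ...) {
  cat(sprintf("Substitution analysis (base AUC %.3f)\n", x$base_auc))
  df <- x$by_variable
  df$auc <- sprintf("%.3f", df$auc)
  df$pct_change <- sprintf("%+.2f%%", df$pct_change)
  print(df, row.names = FALSE)
  invisible(x)
}
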