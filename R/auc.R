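# Discrimination: ROC curve, Mann-Whitney AUC, DeLong confidence interval.
# Orientation throughout: the positive class is technical FAILURE and higher
# scores predict failure, so a well-behaved difficulty score has AUC > 0.5.

#' Mann-Whitney AUC
#'
#' AUC as the probability that a random positive-class case outranks a
#' random negative-class case, with ties counted half:
#' \deqn{AUC = [\sum_{(f,s)} 1(x_f > x_s) + 0.5 \cdot 1(x_f = x_s)] /
#' (n_f n_s)} computed via midranks in O(n log n). Identical to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores numeric predictor, oriented so higher predicts the
#'   positive class.
#' @param outcomes logical (or 0/1) positive-class indicator.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mann_whitney(c(3, 2, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE, FALSE))
auc_mann_whitney <- function(scores, outcomes) {
  outcomes <- .as_outcome(outcomes, scores)
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need at least one case in each outcome class")
  }
  r <- rank(scores)  # midranks
  (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.as_outcome <- function(outcomes, scores) {
  if (is.numeric(outcomes)) {
    stopifnot(all(outcomes %in% c(0, 1)))
    outcomes <- outcomes == 1
  }
  stopifnot(is.logical(outcomes), length(outcomes) == length(scores),
            !anyNA(outcomes), !anyNA(scores))
  outcomes
}

#' ROC curve points
#'
#' Sensitivity/specificity at every threshold, thresholds descending so the
#' curve runs from (0, 0) to (1, 1) in ROC space. A case is called positive
#' when its score is >= the threshold.
#'
#' @inheritParams auc_mann_whitney
#' @return data.frame with columns `threshold`, `sensitivity`,
#'   `specificity`; first row is the all-negative corner (threshold Inf).
#' @export
roc_points <- function(scores, outcomes) {
  outcomes <- .as_outcome(outcomes, scores)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[outcomes] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!outcomes] < t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Trapezoidal area under the ROC curve
#'
#' Provided as the geometric route to the same quantity as
#' [auc_mann_whitney()]; the two agree to machine precision.
#'
#' @inheritParams auc_mann_whitney
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(scores, outcomes) {
  pts <- roc_points(scores, outcomes)
  fpr <- 1 - pts$specificity
  tpr <- pts$sensitivity
  ord <- order(fpr, tpr)
  fpr <- c(fpr[ord], 1)
  tpr <- c(tpr[ord], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from the positive- and
#' negative-class placement values (DeLong's structural components), with a
#' normal-approximation interval truncated to \[0, 1\]. A seeded bootstrap
#' (percentile) interval is available as an alternative.
#'
#' @inheritParams auc_mann_whitney
#' @param level confidence level in (0, 1), default 0.95.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps bootstrap replicates (default 2000).
#' @param boot_seed seed for the bootstrap resampling.
#' @return list of class `auc_ci` with `auc`, `ci_low`, `ci_high`, `se`,
#'   `level`, `method`, `n_pos`, `n_neg`.
#' @export
auc_ci <- function(scores, outcomes, level = 0.95, method = c("delong", "bootstrap"),
                   boot_reps = 2000L, boot_seed = 1L) {
  method <- match.arg(method)
  outcomes <- .as_outcome(outcomes, scores)
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  if (n_pos < 2 || n_neg < 2) {
    stop("DeLong interval needs at least 2 cases in each outcome class")
  }
  auc <- auc_mann_whitney(scores, outcomes)
  if (method == "delong") {
    x <- scores[outcomes]
    y <- scores[!outcomes]
    # placement of each positive among negatives and vice versa, via ranks
    rx <- rank(c(x, y))
    v10 <- (rx[seq_len(n_pos)] - rank(x)) / n_neg          # per-positive
    v01 <- 1 - (rx[n_pos + seq_len(n_neg)] - rank(y)) / n_pos  # per-negative
    se <- sqrt(var(v10) / n_pos + var(v01) / n_neg)
    z <- qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
  } else {
    set.seed(as.integer(boot_seed))
    idx_pos <- which(outcomes)
    idx_neg <- which(!outcomes)
    reps <- vapply(seq_len(boot_reps), function(i) {
      ii <- c(sample(idx_pos, n_pos, replace = TRUE),
              sample(idx_neg, n_neg, replace = TRUE))
      auc_mann_whitney(scores[ii], outcomes[ii])
    }, numeric(1))
    se <- sd(reps)
    qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- max(0, min(qs[1], auc))
    hi <- min(1, max(qs[2], auc))
  }
  structure(list(auc = auc, ci_low = lo, ci_high = hi, se = se,
                 level = level, method = method,
                 n_pos = n_pos, n_neg = n_neg),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%d%% CI %.3f-%.3f, %s; n_pos=%d, n_neg=%d)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$method, x$n_pos, x$n_neg))
  invisible(x)
}
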