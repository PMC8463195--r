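# Calibration: univariate logistic recalibration of a score, then the
# Hosmer-Lemeshow goodness-of-fit test on the fitted probabilities.

#' Univariate logistic recalibration of a score
#'
#' An additive difficulty score is an integer, not a probability; the
#' Hosmer-Lemeshow test needs predicted probabilities. This fits
#' P(event) = 1 / (1 + exp(-(a + b * score))) by maximum likelihood
#' (iteratively reweighted least squares, i.e. Newton-Raphson for the
#' logistic log-likelihood) and returns the per-case fitted probabilities.
#' Complete or quasi-complete separation is detected — fitted probabilities
#' indistinguishable from 0/1 or a diverging slope — and flagged rather
#' than silently returned.
#'
#' @param scores numeric predictor.
#' @param outcomes logical (or 0/1) event indicator.
#' @return list of class `logistic_recal`: `intercept`, `slope`,
#'   `probabilities`, `converged`, `separation`.
#' @export
logistic_recalibration <- function(scores, outcomes) {
  outcomes <- .as_outcome(outcomes, scores)
  if (all(outcomes) || !any(outcomes)) {
    stop("degenerate outcomes: need both classes to fit a logistic model")
  }
  boundary_warning <- FALSE
  fit <- withCallingHandlers(
    glm(outcomes ~ scores, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        boundary_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p <- as.numeric(fitted(fit))
  separation <- boundary_warning ||
    abs(coef(fit)[2]) > 20 ||
    all(p[outcomes] > 1 - 1e-8) && all(p[!outcomes] < 1e-8)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 probabilities = p,
                 converged = fit$converged,
                 separation = separation),
            class = "logistic_recal")
}

#' @export
print.logistic_recal <- function(x, ...) {
  cat(sprintf("logistic recalibration: logit(p) = %.4f + %.4f * score%s%s\n",
              x$intercept, x$slope,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION]" else ""))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Cases are sorted by predicted probability and split into `n_groups`
#' near-equal groups on the quantiles of the grouping variable; tied values
#' stay together and duplicate cut-points are collapsed, so the realized
#' group count G can be below `n_groups`. The statistic is
#' \deqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))}
#' referred to a chi-square with G - 2 degrees of freedom. When G < 3 the
#' degrees of freedom degenerate; the statistic is still reported with
#' `df_degenerate = TRUE` and no p-value.
#'
#' @param probabilities predicted event probabilities in \[0, 1\].
#' @param outcomes logical (or 0/1) event indicator.
#' @param n_groups requested number of groups (default 10, the usual
#'   deciles of risk); must be >= 3.
#' @param group_by optional alternative grouping variable (same order as
#'   `probabilities`); defaults to the probabilities themselves. The
#'   statistic is invariant to strictly increasing transforms of it.
#' @return list of class `hl_result`: `statistic`, `df`, `p_value`,
#'   `group_table` (per-group n, observed, expected), `df_degenerate`.
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, n_groups = 10L,
                            group_by = probabilities) {
  outcomes <- .as_outcome(outcomes, probabilities)
  stopifnot(all(probabilities >= 0 & probabilities <= 1),
            length(group_by) == length(probabilities))
  if (n_groups < 3) stop("n_groups must be >= 3")
  n <- length(group_by)
  # near-equal groups by rank; tied grouping values share the bin of their
  # first occurrence, so ties never straddle a cut-point
  first_rank <- rank(group_by, ties.method = "first")
  min_rank <- stats::ave(first_rank, group_by, FUN = min)
  bin <- ceiling(min_rank * n_groups / n)
  grp <- factor(bin, levels = sort(unique(bin)))
  n_g <- as.vector(table(grp))
  obs <- tapply(outcomes, grp, sum)
  exp_g <- tapply(probabilities, grp, sum)
  lo <- tapply(group_by, grp, min)
  hi <- tapply(group_by, grp, max)
  g_names <- sprintf("%d [%g, %g]", seq_along(n_g), lo, hi)
  bad <- which(exp_g <= 0 | exp_g >= n_g)
  if (length(bad) > 0) {
    stop(sprintf("Hosmer-Lemeshow group '%s' has expected events E=%g with n=%d; statistic undefined",
                 g_names[bad[1]], exp_g[bad[1]], n_g[bad[1]]))
  }
  statistic <- sum((obs - exp_g)^2 / (exp_g * (1 - exp_g / n_g)))
  g <- length(n_g)
  df <- g - 2L
  degenerate <- df < 1L
  p <- if (degenerate) NA_real_ else pchisq(statistic, df, lower.tail = FALSE)
  structure(list(statistic = unname(statistic), df = df, p_value = unname(p),
                 group_table = data.frame(group = g_names, n = n_g,
                                          observed = as.vector(obs),
                                          expected = as.vector(exp_g)),
                 df_degenerate = degenerate),
            class = "hl_result")
}

#' @export
print.hl_result <- function(x, ...) {
  if (x$df_degenerate) {
    cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d realized group(s); df degenerate, no p-value\n",
                x$statistic, nrow(x$group_table)))
  } else {
    cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3f (%d groups)\n",
                x$statistic, x$df, x$p_value, nrow(x$group_table)))
  }
  invisible(x)
}
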