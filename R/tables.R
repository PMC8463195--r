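# Summary tables and the group-comparison tests used to describe a cohort.

#' Percentage rounded half-up to one decimal
#'
#' The display convention used throughout the cohort tables. Computed in
#' exact integer arithmetic, so 131/144 gives 91.0 (not 90.9) regardless of
#' floating-point representation.
#'
#' @param numerator non-negative integer(s).
#' @param denominator positive integer(s).
#' @return 100 * numerator / denominator rounded half-up to 1 decimal.
#' @export
#' @examples
#' percent(131, 144)  # 91.0
percent <- function(numerator, denominator) {
  stopifnot(all(denominator > 0), all(numerator >= 0),
            all(numerator == round(numerator)),
            all(denominator == round(denominator)))
  v10 <- (1000 * numerator) %/% denominator
  rem <- (1000 * numerator) %% denominator
  (v10 + (2 * rem >= denominator)) / 10
}

#' Per-tier success table
#'
#' Groups a scored cohort by operator-CTO difficulty tier and reports, per
#' tier, the number of procedures and the technical and procedural success
#' counts and percentages ([percent()] convention). Tiers with no cases are
#' reported with n = 0 and NA percentages rather than 0.
#'
#' @param cohort a `cto_cohort` (or data.frame with the schema columns).
#' @return data.frame of class `tier_table` with one row per tier.
#' @export
tier_success_table <- function(cohort) {
  tier <- classify_difficulty(score_operator_cto(cohort))
  out <- data.frame(tier = factor(.tier_levels, levels = .tier_levels,
                                  ordered = TRUE))
  out$n <- as.vector(table(tier))
  out$technical_success <- as.vector(tapply(cohort$technical_success, tier, sum,
                                            default = 0L))
  out$procedural_success <- as.vector(tapply(cohort$procedural_success, tier, sum,
                                             default = 0L))
  out$technical_pct <- ifelse(out$n > 0,
                              percent(out$technical_success, pmax(out$n, 1)),
                              NA_real_)
  out$procedural_pct <- ifelse(out$n > 0,
                               percent(out$procedural_success, pmax(out$n, 1)),
                               NA_real_)
  class(out) <- c("tier_table", "data.frame")
  out
}

#' Pearson chi-square test on an r x c count table
#'
#' Classical Pearson statistic without continuity correction; errors on a
#' zero row or column margin (expected counts undefined).
#'
#' @param table matrix of non-negative counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square test undefined: zero row or column margin")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Fisher's exact test on a 2 x 2 count table
#'
#' Two-sided p-value from the hypergeometric distribution, summing the
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  fisher.test(table)$p.value
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with equal-variance F test.
#' Degenerate inputs are resolved explicitly: zero variance everywhere with
#' equal group means gives F = 0; with unequal means the statistic is
#' infinite and flagged.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `statistic` (F), `df1`, `df2`, `p_value`,
#'   `infinite_f`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 1))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  stopifnot(length(y) > nlevels(g))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  means <- tapply(y, g, mean)
  ss_between <- sum(tapply(y, g, length) * (means - mean(y))^2)
  ss_within <- sum((y - means[g])^2)
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(list(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                  infinite_f = FALSE))
    }
    return(list(statistic = Inf, df1 = df1, df2 = df2, p_value = 0,
                infinite_f = TRUE))
  }
  fit <- anova(aov(y ~ g))
  list(statistic = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p_value = fit$`Pr(>F)`[1], infinite_f = FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction, referred to a chi-square
#' with k - 1 degrees of freedom. When every value is identical the
#' statistic is 0 (no evidence of location differences) rather than the
#' 0/0 of the tie-corrected formula.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  y <- unlist(groups)
  df <- length(groups) - 1L
  if (length(unique(y)) == 1L) {
    return(list(statistic = 0, df = df, p_value = 1))
  }
  res <- kruskal.test(groups)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}
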