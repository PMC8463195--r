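# Synthetic cohort generator. Emulates the statistical structure of a
# 144-procedure CTO-PCI registry: marginal lesion-feature prevalences, a
# ten-operator mix across five experience groups, and tier-conditional
# technical-success probabilities. One root seed is split into independent
# substreams per stage, so adding a stage never perturbs earlier draws.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the registry the package models: 144 procedures,
#' lesion-feature prevalences of the observed angiographic table, operator
#' group procedure weights proportional to (5, 6, 13, 75, 45), and
#' tier-conditional technical success probabilities (0.990, 0.875, 0.538,
#' 0.250) for the simple/medium/difficult/extremely-difficult tiers.
#'
#' Prevalences the registry does not report are fixed modeling choices:
#' probability of a previously failed attempt 0.15, severe calcification
#' given any calcification 0.5, severe angulation given a bend >= 45 degrees
#' 1/3. Occlusion length is truncated normal (at 0) with sd `length_sd_mm`
#' and mean solved so that P(length >= 20 mm) equals `length_p_ge20`.
#'
#' @param n_cases number of procedures to generate.
#' @param seed integer root seed.
#' @param feature_prevalences named numeric vector of Bernoulli prevalences;
#'   names as in the default. `calcification_severe` and `severe_angulation`
#'   are conditional on their implied parent so the logical implications hold
#'   by construction.
#' @param vessel_probs probabilities of target vessel LAD/LCX/RCA/LM.
#' @param rentrop_lt2_prob probability of collateral Rentrop grade < 2.
#' @param operator_group_weights probability a procedure is performed by an
#'   operator of groups I-V; must sum to 1.
#' @param operator_group_counts number of operators in each of groups I-V
#'   (defaults 2, 1, 2, 3, 2; ten operators in all).
#' @param tier_success_probs technical success probability per difficulty
#'   tier, simple to extremely difficult.
#' @param procedural_given_technical probability of procedural success given
#'   technical success (default 128/131).
#' @param length_sd_mm,length_p_ge20 occlusion-length distribution controls.
#' @param age_mean,age_sd age distribution (years), truncated at 18.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_cases = 144L,
    seed = 1L,
    feature_prevalences = c(
      blunt_stump = 0.576,
      calcification = 0.333,
      calcification_severe = 0.5,   # given calcification
      bend_ge45 = 0.910,
      severe_angulation = 1 / 3,    # given bend_ge45
      distal_disease = 0.542,
      ostial = 0.479,
      in_stent = 0.139,
      prior_mi = 0.308,
      prior_failed_attempt = 0.15,
      prior_cabg_target_vessel = 1 / 144
    ),
    vessel_probs = c(LAD = 0.424, LCX = 0.097, RCA = 0.472, LM = 0.007),
    rentrop_lt2_prob = 0.319,
    operator_group_weights = c(5, 6, 13, 75, 45) / 144,
    operator_group_counts = c(2L, 1L, 2L, 3L, 2L),
    tier_success_probs = c(0.990, 0.875, 0.538, 0.250),
    procedural_given_technical = 128 / 131,
    length_sd_mm = 17,
    length_p_ge20 = 0.882,
    age_mean = 62.81,
    age_sd = 11.27) {
  cfg <- list(n_cases = as.integer(n_cases), seed = as.integer(seed),
              feature_prevalences = feature_prevalences,
              vessel_probs = vessel_probs / sum(vessel_probs),
              rentrop_lt2_prob = rentrop_lt2_prob,
              operator_group_weights = operator_group_weights,
              operator_group_counts = as.integer(operator_group_counts),
              tier_success_probs = tier_success_probs,
              procedural_given_technical = procedural_given_technical,
              length_sd_mm = length_sd_mm, length_p_ge20 = length_p_ge20,
              age_mean = age_mean, age_sd = age_sd)
  probs <- c(cfg$feature_prevalences, cfg$vessel_probs, cfg$rentrop_lt2_prob,
             cfg$tier_success_probs, cfg$procedural_given_technical,
             cfg$length_p_ge20)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$n_cases >= 0,
            length(cfg$operator_group_weights) == 5,
            all(cfg$operator_group_weights >= 0),
            abs(sum(cfg$operator_group_weights) - 1) < 1e-9,
            length(cfg$operator_group_counts) == 5,
            length(cfg$tier_success_probs) == 4)
  class(cfg) <- "generator_config"
  cfg
}

# Deterministic substream seeds derived from the root seed, kept < 2^31.
.stage_seed <- function(seed, stage) {
  offsets <- c(operators = 101L, features = 211L, assignment = 307L,
               outcomes = 401L, extra = 503L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

# Polynomial rolling hash of the serialized config, for provenance stamps.
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Inverse-CDF draw from a normal truncated below at `lower`.
.rtnorm <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  qnorm(plo + runif(n) * (1 - plo), mean, sd)
}

# Mean of a 0-truncated normal with fixed sd such that P(X >= 20) hits the
# configured target.
.length_mean <- function(sd, p_ge20) {
  f <- function(mu) {
    (1 - pnorm(20, mu, sd)) / (1 - pnorm(0, mu, sd)) - p_ge20
  }
  uniroot(f, lower = 0, upper = 200)$root
}

#' Generate the operator panel
#'
#' Ten operators split across experience groups I-V with counts from the
#' configuration. Experience variables are drawn uniformly within each
#' group's defining box: years in \[1, 4\] (low) or \[5, 15\] (high), annual
#' volume in \[20, 59\] or \[60, 120\], last-year success rate in
#' \[0.70, 0.89\] or \[0.90, 0.99\].
#'
#' @param config a [generator_config()].
#' @return data.frame of operator profiles with the derived `group_label`.
#' @export
generate_operators <- function(config) {
  set.seed(.stage_seed(config$seed, "operators"))
  counts <- config$operator_group_counts
  groups <- rep(c("I", "II", "III", "IV", "V"), counts)
  n <- length(groups)
  hi_years <- groups %in% c("III", "IV", "V")
  hi_vol <- groups %in% c("II", "IV", "V")
  hi_rate <- groups == "V"
  years <- ifelse(hi_years, sample(5:15, n, replace = TRUE),
                  sample(1:4, n, replace = TRUE))
  vol <- ifelse(hi_vol, sample(60:120, n, replace = TRUE),
                sample(20:59, n, replace = TRUE))
  rate <- ifelse(hi_rate, runif(n, 0.90, 0.99), runif(n, 0.70, 0.89))
  data.frame(
    operator_id = sprintf("op%02d", seq_len(n)),
    years_performing = as.integer(years),
    annual_volume = as.integer(vol),
    last_year_success_rate = rate,
    group_label = factor(groups, levels = c("I", "II", "III", "IV", "V"))
  )
}

#' Generate case features
#'
#' Independent Bernoulli draws at the configured prevalences; implications
#' (severe calcification requires calcification, severe angulation requires a
#' bend >= 45 degrees) hold by construction because the severe variants are
#' drawn conditional on their parent. Occlusion length is truncated normal
#' calibrated to the configured P(>= 20 mm); target vessel is multinomial;
#' the Rentrop grade is < 2 with the configured probability, with a 50/50
#' sub-grade split on either side.
#'
#' @param config a [generator_config()].
#' @param n number of cases; defaults to `config$n_cases`.
#' @return data.frame of feature columns, one row per case.
#' @export
generate_case_features <- function(config, n = config$n_cases) {
  set.seed(.stage_seed(config$seed, "features"))
  p <- config$feature_prevalences
  draw <- function(name) runif(n) < p[[name]]
  blunt <- draw("blunt_stump")
  calc <- draw("calcification")
  calc_sev <- calc & draw("calcification_severe")
  bend <- draw("bend_ge45")
  sev_ang <- bend & draw("severe_angulation")
  lt2 <- runif(n) < config$rentrop_lt2_prob
  rentrop <- ifelse(lt2, sample(0:1, n, replace = TRUE),
                    sample(2:3, n, replace = TRUE))
  mu <- .length_mean(config$length_sd_mm, config$length_p_ge20)
  data.frame(
    age_years = pmax(18L, as.integer(round(
      .rtnorm(n, config$age_mean, config$age_sd, 18)))),
    prior_mi = draw("prior_mi"),
    prior_failed_attempt = draw("prior_failed_attempt"),
    prior_cabg_target_vessel = draw("prior_cabg_target_vessel"),
    target_vessel = sample(names(config$vessel_probs), n, replace = TRUE,
                           prob = config$vessel_probs),
    blunt_stump = blunt,
    calcification = calc,
    calcification_severe = calc_sev,
    bend_ge45 = bend,
    severe_angulation = sev_ang,
    occlusion_length_mm = .rtnorm(n, mu, config$length_sd_mm, 0),
    distal_disease = draw("distal_disease"),
    rentrop_grade = as.integer(rentrop),
    in_stent = draw("in_stent"),
    ostial = draw("ostial")
  )
}

#' Generate outcomes from difficulty tiers
#'
#' Technical success is Bernoulli with the tier's configured probability;
#' procedural success is technical success times an independent Bernoulli
#' with probability `procedural_given_technical`, so the endpoint nesting
#' holds by construction.
#'
#' @param tier ordered factor of difficulty tiers (as from
#'   [classify_difficulty()]).
#' @param config a [generator_config()].
#' @return data.frame with logical columns `technical_success`,
#'   `procedural_success`.
#' @export
generate_outcomes <- function(tier, config) {
  set.seed(.stage_seed(config$seed, "outcomes"))
  n <- length(tier)
  p <- config$tier_success_probs[as.integer(tier)]
  technical <- runif(n) < p
  procedural <- technical & (runif(n) < config$procedural_given_technical)
  data.frame(technical_success = technical, procedural_success = procedural)
}

#' Generate a complete synthetic cohort
#'
#' Composition of the stage generators: draw the operator panel, draw case
#' features, assign each case an operator (group chosen with the configured
#' procedure weights, then uniformly within the group), score every case,
#' and draw outcomes from the difficulty tier. Deterministic given the
#' configuration (which includes the seed).
#'
#' @param config a [generator_config()].
#' @return A validated [as_cohort()] data.frame with provenance recording
#'   the seed and a hash of the configuration.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_cases = 50, seed = 7))
#' table(classify_difficulty(score_operator_cto(cohort)))
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_cases
  ops <- generate_operators(config)
  feats <- generate_case_features(config, n)

  set.seed(.stage_seed(config$seed, "assignment"))
  grp_of_case <- sample(levels(ops$group_label), n, replace = TRUE,
                        prob = config$operator_group_weights)
  op_row <- vapply(grp_of_case, function(g) {
    rows <- which(ops$group_label == g)
    if (length(rows) == 1L) rows else sample(rows, 1L)
  }, integer(1))

  cases <- cbind(
    case_id = sprintf("case%05d", seq_len(max(n, 1L))[seq_len(n)]),
    operator_id = ops$operator_id[op_row],
    ops[op_row, c("years_performing", "annual_volume",
                  "last_year_success_rate")],
    feats
  )
  rownames(cases) <- NULL
  if (n == 0L) {
    cases <- cbind(cases,
                   technical_success = logical(0),
                   procedural_success = logical(0))
  } else {
    tier <- classify_difficulty(score_operator_cto(cases))
    cases <- cbind(cases, generate_outcomes(tier, config))
  }
  as_cohort(cases, provenance = sprintf("generated: seed=%d n=%d config=%s",
                                        config$seed, n, .config_hash(config)))
}

#' Tier-based score/outcome benchmark generator
#'
#' Desk-scale benchmark for discrimination: each case draws a difficulty
#' tier with probabilities (103, 24, 13, 4)/144, then a score within tier
#' (uniform on \{0,1,2\} for simple; 3 for medium; 4 for difficult; uniform
#' on \{5,6\} for extremely difficult), then a technical failure indicator
#' with tier failure probabilities 0.010, 0.125, 0.462, 0.750.
#'
#' @param n number of cases.
#' @param seed integer seed.
#' @return data.frame with columns `score` (integer) and
#'   `technical_failure` (logical).
#' @seealso [auc_mann_whitney()] for scoring the benchmark.
#' @export
generate_auc_benchmark <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  w <- c(103, 24, 13, 4) / 144
  fail_p <- c(0.010, 0.125, 0.462, 0.750)
  score_sets <- list(0:2, 3L, 4L, 5:6)
  tier <- sample.int(4L, n, replace = TRUE, prob = w)
  score <- vapply(tier, function(t) {
    s <- score_sets[[t]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, integer(1))
  failure <- runif(n) < fail_p[tier]
  data.frame(score = score, technical_failure = failure)
}

#' Paired categorical ratings with controlled agreement
#'
#' Fixture generator for inter-rater agreement: rater A is uniform over the
#' categories; rater B copies rater A with probability `agreement` and
#' otherwise draws uniformly from the remaining categories. For k
#' categories the asymptotic kappa of this mixture is
#' (agreement - 1/k) / (1 - 1/k).
#'
#' @param n number of rated cases.
#' @param agreement copy probability in \[0, 1\].
#' @param n_categories number of categories (>= 2).
#' @param seed integer seed.
#' @return data.frame with integer columns `rater_a`, `rater_b`.
#' @export
generate_rating_pairs <- function(n, agreement, n_categories, seed) {
  stopifnot(n >= 1, n_categories >= 2, agreement >= 0, agreement <= 1)
  set.seed(as.integer(seed))
  a <- sample.int(n_categories, n, replace = TRUE)
  copy <- runif(n) < agreement
  b <- a
  redraw <- which(!copy)
  if (length(redraw) > 0) {
    b[redraw] <- vapply(a[redraw], function(ai) {
      pool <- setdiff(seq_len(n_categories), ai)
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, integer(1))
  }
  data.frame(rater_a = a, rater_b = b)
}
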