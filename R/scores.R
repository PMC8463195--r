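# The operator-CTO score, its difficulty tiers, and the five comparator
# scores (J-CTO, PROGRESS, ORA, RECHARGE, CL). All scorers are vectorized
# over the rows of a case data.frame (a cto_cohort or any data.frame with
# the needed columns).

.tier_levels <- c("simple", "medium", "difficult", "extremely_difficult")

#' Operator experience credit
#'
#' The operator side of the operator-CTO score. Each criterion is applied
#' independently with an inclusive boundary: annual CTO-PCI volume >= 60
#' cases gives -1, >= 5 years performing CTO-PCI gives -1, and a last-year
#' technical success rate >= 90\% gives -2. No tolerance is applied at the
#' boundaries (a rate of 0.8999 earns nothing).
#'
#' @param years_performing integer years as lead operator of CTO-PCI
#'   (a duration over six months counts as one year).
#' @param annual_volume average CTO-PCI cases per year.
#' @param last_year_success_rate last year's technical success rate in
#'   \[0, 1\].
#' @return Integer vector of credits in \{0, -1, -2, -3, -4\}.
#' @export
#' @examples
#' operator_credit(5, 60, 0.90)   # all boundaries inclusive: -4
#' operator_credit(4, 59, 0.89)   # nothing met: 0
operator_credit <- function(years_performing, annual_volume,
                            last_year_success_rate) {
  stopifnot(all(last_year_success_rate >= 0 & last_year_success_rate <= 1),
            all(years_performing >= 0), all(annual_volume >= 0))
  as.integer(-1L * (annual_volume >= 60) +
             -1L * (years_performing >= 5) +
             -2L * (last_year_success_rate >= 0.90))
}

#' Operator-CTO score
#'
#' Sum of one point for each adverse variable — prior CABG on the target
#' vessel, blunt stump, calcification (any), curvature (severe angulation:
#' at least two bends over 70 degrees or one over 90), occlusion length >=
#' 20 mm, distal vessel disease, collateral Rentrop grade < 2, in-stent
#' occlusion, ostial location — plus the operator credit
#' ([operator_credit()]). The total lies in \[-4, 9\].
#'
#' @param cases data.frame with the feature and operator columns of
#'   [cohort_columns()] (outcome columns are not needed).
#' @return Integer vector of scores, one per row.
#' @seealso [classify_difficulty()] for the tier mapping,
#'   [score_panel()] for all six scores at once.
#' @export
score_operator_cto <- function(cases) {
  adverse <-
    (cases$prior_cabg_target_vessel) +
    (cases$blunt_stump) +
    (cases$calcification) +
    (cases$severe_angulation) +
    (cases$occlusion_length_mm >= 20) +
    (cases$distal_disease) +
    (cases$rentrop_grade < 2) +
    (cases$in_stent) +
    (cases$ostial)
  as.integer(adverse) + operator_credit(cases$years_performing,
                                        cases$annual_volume,
                                        cases$last_year_success_rate)
}

#' Map an operator-CTO score to its difficulty tier
#'
#' Tiers: simple (score <= 2), medium (3), difficult (4), extremely
#' difficult (>= 5).
#'
#' @param score integer operator-CTO score(s) in \[-4, 9\].
#' @return Ordered factor with levels simple < medium < difficult <
#'   extremely_difficult.
#' @export
classify_difficulty <- function(score) {
  if (any(score < -4 | score > 9)) {
    stop("operator-CTO score must lie in [-4, 9]; got ",
         paste(score[score < -4 | score > 9], collapse = ", "))
  }
  tier <- ifelse(score <= 2, "simple",
          ifelse(score == 3, "medium",
          ifelse(score == 4, "difficult", "extremely_difficult")))
  factor(tier, levels = .tier_levels, ordered = TRUE)
}

#' J-CTO score
#'
#' One point each for blunt stump, lesion length > 20 mm, calcification,
#' any bend >= 45 degrees, and a previously failed attempt on the lesion.
#' Range 0-5. Note the strict > 20 mm boundary, unlike the operator-CTO
#' score's >= 20 mm.
#'
#' @inheritParams score_operator_cto
#' @return Integer vector in \[0, 5\].
#' @export
score_jcto <- function(cases) {
  as.integer((cases$blunt_stump) +
             (cases$occlusion_length_mm > 20) +
             (cases$calcification) +
             (cases$bend_ge45) +
             (cases$prior_failed_attempt))
}

#' PROGRESS-CTO score
#'
#' One point each for blunt stump, moderate/severe tortuosity (severe
#' angulation), lack of usable collaterals (Rentrop grade < 2), and a
#' circumflex-artery CTO. Range 0-4.
#'
#' @inheritParams score_operator_cto
#' @return Integer vector in \[0, 4\].
#' @export
score_progress <- function(cases) {
  as.integer((cases$blunt_stump) +
             (cases$severe_angulation) +
             (cases$rentrop_grade < 2) +
             (cases$target_vessel == "LCX"))
}

#' ORA score
#'
#' One point each for age >= 75 years (inclusive), ostial location, and
#' collateral Rentrop grade < 2. Range 0-3.
#'
#' @inheritParams score_operator_cto
#' @return Integer vector in \[0, 3\].
#' @export
score_ora <- function(cases) {
  as.integer((cases$age_years >= 75) +
             (cases$ostial) +
             (cases$rentrop_grade < 2))
}

#' RECHARGE score
#'
#' One point each for blunt stump, lesion length > 20 mm, calcification,
#' bend >= 45 degrees, distal vessel disease, and prior CABG on the target
#' vessel. Range 0-6.
#'
#' @inheritParams score_operator_cto
#' @return Integer vector in \[0, 6\].
#' @export
score_recharge <- function(cases) {
  as.integer((cases$blunt_stump) +
             (cases$occlusion_length_mm > 20) +
             (cases$calcification) +
             (cases$bend_ge45) +
             (cases$distal_disease) +
             (cases$prior_cabg_target_vessel))
}

#' CL score
#'
#' Weighted sum: blunt stump (1), lesion length > 20 mm (1.5), severe
#' calcification (2), non-LAD target vessel (1), prior CABG on the target
#' vessel (1.5), prior myocardial infarction (1). Range 0-8 in half-point
#' steps. CL is the only comparator that distinguishes severe from any
#' calcification.
#'
#' @inheritParams score_operator_cto
#' @return Numeric vector in \[0, 8\] with 0.5 granularity.
#' @export
score_cl <- function(cases) {
  (cases$blunt_stump) * 1 +
    (cases$occlusion_length_mm > 20) * 1.5 +
    (cases$calcification_severe) * 2 +
    (cases$target_vessel != "LAD") * 1 +
    (cases$prior_cabg_target_vessel) * 1.5 +
    (cases$prior_mi) * 1
}

#' Classify an operator into experience groups I-V
#'
#' Groups follow the three experience thresholds (5 years, 60 cases/year,
#' 90\% last-year success): I = below all three; II = volume only; III =
#' years only; IV = years and volume; V = all three. Combinations outside
#' these five (a sub-threshold operator with a >= 90\% success rate) are
#' resolved by the success-rate criterion first and flagged in the
#' `"flagged"` attribute.
#'
#' @inheritParams operator_credit
#' @return Factor with levels I-V; attribute `flagged` is a logical vector
#'   marking operators whose combination is not one of the five canonical
#'   boxes.
#' @export
classify_operator_group <- function(years_performing, annual_volume,
                                    last_year_success_rate) {
  hi_years <- years_performing >= 5
  hi_vol <- annual_volume >= 60
  hi_rate <- last_year_success_rate >= 0.90
  grp <- ifelse(hi_rate, "V",
         ifelse(hi_years & hi_vol, "IV",
         ifelse(hi_years, "III",
         ifelse(hi_vol, "II", "I"))))
  flagged <- hi_rate & !(hi_years & hi_vol)
  structure(factor(grp, levels = c("I", "II", "III", "IV", "V")),
            flagged = flagged)
}

#' Compute all six scores and the difficulty tier
#'
#' @inheritParams score_operator_cto
#' @return data.frame with columns `operator_cto`, `jcto`, `progress`,
#'   `ora`, `recharge`, `cl` and the ordered factor `tier`, one row per
#'   case.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_cases = 5, seed = 1))
#' score_panel(cohort)
score_panel <- function(cases) {
  op <- score_operator_cto(cases)
  data.frame(
    operator_cto = op,
    jcto = score_jcto(cases),
    progress = score_progress(cases),
    ora = score_ora(cases),
    recharge = score_recharge(cases),
    cl = score_cl(cases),
    tier = classify_difficulty(op)
  )
}
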