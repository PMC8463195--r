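# Scoring models: worked examples, boundary behaviour, and the algebraic
# structure of the additive scores.

test_that("operator credit applies its three criteria independently with inclusive boundaries", {
  expect_identical(operator_credit(5, 60, 0.90), -4L)
  expect_identical(operator_credit(4, 59, 0.89), 0L)
  expect_identical(operator_credit(6, 30, 0.95), -3L)
  expect_identical(operator_credit(3, 40, 0.85), 0L)
  expect_identical(operator_credit(6, 70, 0.92), -4L)
  # just below each boundary earns nothing; no tolerance on the rate
  expect_identical(operator_credit(4.9, 59.9, 0.8999), 0L)
})

test_that("operator-CTO score sums adverse points plus operator credit", {
  # all nine adverse variables, credit-0 operator: the full score of 9
  all_adverse <- adverse_case(9)
  expect_identical(score_operator_cto(all_adverse), 9L)
  # benign case with a fully credited operator: the floor of -4
  floor_case <- make_cases(years_performing = 6, annual_volume = 70,
                           last_year_success_rate = 0.92)
  expect_identical(score_operator_cto(floor_case), -4L)
  # five adverse variables against a fully credited operator: 5 - 4 = 1
  worked <- make_cases(blunt_stump = TRUE, calcification = TRUE,
                       occlusion_length_mm = 25, distal_disease = TRUE,
                       rentrop_grade = 1L,
                       years_performing = 6, annual_volume = 70,
                       last_year_success_rate = 0.92)
  expect_identical(score_operator_cto(worked), 1L)
  # length boundary is inclusive at exactly 20 mm
  expect_identical(score_operator_cto(make_cases(occlusion_length_mm = 20)), 1L)
})

test_that("difficulty tiers split at 2/3/4/5 and reject out-of-range scores", {
  expect_equal(as.character(classify_difficulty(c(-4, 0, 2))),
               rep("simple", 3))
  expect_equal(as.character(classify_difficulty(3)), "medium")
  expect_equal(as.character(classify_difficulty(4)), "difficult")
  expect_equal(as.character(classify_difficulty(c(5, 9))),
               rep("extremely_difficult", 2))
  expect_true(is.ordered(classify_difficulty(0)))
  expect_error(classify_difficulty(10), "\\[-4, 9\\]")
  expect_error(classify_difficulty(-5), "\\[-4, 9\\]")
})

test_that("comparator scores match their published point assignments", {
  # J-CTO: blunt + calcification + length 25 mm -> 3; strict > 20 mm
  expect_identical(score_jcto(make_cases(blunt_stump = TRUE,
                                         calcification = TRUE,
                                         occlusion_length_mm = 25)), 3L)
  expect_identical(score_jcto(make_cases(occlusion_length_mm = 20)), 0L)
  expect_identical(score_jcto(make_cases()), 0L)
  # PROGRESS: LCX + blunt, Rentrop 2, no severe bend -> 2
  expect_identical(score_progress(make_cases(target_vessel = "LCX",
                                             blunt_stump = TRUE,
                                             rentrop_grade = 2L)), 2L)
  expect_identical(score_progress(make_cases(target_vessel = "RCA",
                                             rentrop_grade = 3L)), 0L)
  # ORA: age boundary at 75 is inclusive
  expect_identical(score_ora(make_cases(age_years = 80, ostial = TRUE,
                                        rentrop_grade = 1L)), 3L)
  expect_identical(score_ora(make_cases(age_years = 75, rentrop_grade = 2L)), 1L)
  expect_identical(score_ora(make_cases(age_years = 60, rentrop_grade = 3L)), 0L)
  # RECHARGE: blunt + length 30 + prior CABG -> 3
  expect_identical(score_recharge(make_cases(blunt_stump = TRUE,
                                             occlusion_length_mm = 30,
                                             prior_cabg_target_vessel = TRUE)), 3L)
  # CL: severe calcification (2) + length 25 (1.5) + RCA (1) -> 4.5
  expect_equal(score_cl(make_cases(calcification = TRUE,
                                   calcification_severe = TRUE,
                                   occlusion_length_mm = 25,
                                   target_vessel = "RCA")), 4.5)
  expect_equal(score_cl(make_cases()), 0)
  # CL maximum 8 = 1 + 1.5 + 2 + 1 + 1.5 + 1
  expect_equal(score_cl(make_cases(blunt_stump = TRUE,
                                   occlusion_length_mm = 25,
                                   calcification = TRUE,
                                   calcification_severe = TRUE,
                                   target_vessel = "RCA",
                                   prior_cabg_target_vessel = TRUE,
                                   prior_mi = TRUE)), 8)
})

test_that("score_panel reproduces each scorer and the joint maxima", {
  # all-adverse LCX case, age >= 75, credit-0 operator: every score maximal
  x <- adverse_case(9, target_vessel = "LCX", age_years = 80,
                    prior_mi = TRUE, prior_failed_attempt = TRUE,
                    calcification_severe = TRUE)
  p <- score_panel(x)
  expect_identical(p$operator_cto, 9L)
  expect_identical(p$jcto, 5L)
  expect_identical(p$progress, 4L)
  expect_identical(p$ora, 3L)
  expect_identical(p$recharge, 6L)
  expect_equal(p$cl, 8)
  expect_equal(as.character(p$tier), "extremely_difficult")
  # all-benign case with full credit
  y <- make_cases(years_performing = 10, annual_volume = 90,
                  last_year_success_rate = 0.95)
  q <- score_panel(y)
  expect_equal(unlist(q[1, 1:6], use.names = FALSE), c(-4, 0, 0, 0, 0, 0))
  expect_equal(as.character(q$tier), "simple")
  # panel equals calling scorers individually on random inputs
  r <- random_cases(200, seed = 303)
  pr <- score_panel(r)
  expect_identical(pr$operator_cto, score_operator_cto(r))
  expect_identical(pr$jcto, score_jcto(r))
  expect_identical(pr$cl, score_cl(r))
})

test_that("operator groups I-V follow the experience thresholds; off-grid combinations are flagged", {
  expect_equal(as.character(classify_operator_group(3, 40, 0.80)), "I")
  expect_equal(as.character(classify_operator_group(3, 80, 0.80)), "II")
  expect_equal(as.character(classify_operator_group(7, 40, 0.80)), "III")
  expect_equal(as.character(classify_operator_group(7, 80, 0.89)), "IV")
  expect_equal(as.character(classify_operator_group(7, 80, 0.93)), "V")
  # high success rate with sub-threshold experience resolves rate-first, flagged
  g <- classify_operator_group(3, 40, 0.95)
  expect_equal(as.character(g), "V")
  expect_true(attr(g, "flagged"))
  expect_false(any(attr(classify_operator_group(c(3, 7), c(40, 80),
                                                c(0.80, 0.93)), "flagged")))
})

test_that("every score stays inside its closed range on random valid inputs", {
  r <- random_cases(2000, seed = 99)
  p <- score_panel(r)
  expect_true(all(p$operator_cto >= -4 & p$operator_cto <= 9))
  expect_true(all(p$jcto >= 0 & p$jcto <= 5))
  expect_true(all(p$progress >= 0 & p$progress <= 4))
  expect_true(all(p$ora >= 0 & p$ora <= 3))
  expect_true(all(p$recharge >= 0 & p$recharge <= 6))
  expect_true(all(p$cl >= 0 & p$cl <= 8))
  expect_true(all(p$cl * 2 == round(p$cl * 2)))  # 0.5 granularity
})

test_that("flipping any adverse feature on never decreases any score; more experience never increases the operator-CTO score", {
  r <- random_cases(150, seed = 7)
  flags <- c("prior_mi", "prior_failed_attempt", "prior_cabg_target_vessel",
             "blunt_stump", "calcification", "calcification_severe",
             "bend_ge45", "severe_angulation", "distal_disease",
             "in_stent", "ostial")
  base <- score_panel(r)[, 1:6]
  for (f in flags) {
    up <- r
    up[[f]] <- TRUE
    # keep implications valid
    if (f == "calcification_severe") up$calcification <- TRUE
    if (f == "severe_angulation") up$bend_ge45 <- TRUE
    flipped <- score_panel(up)[, 1:6]
    expect_true(all(as.matrix(flipped) >= as.matrix(base)),
                info = paste("feature:", f))
  }
  more_exp <- r
  more_exp$years_performing <- r$years_performing + 5
  more_exp$annual_volume <- r$annual_volume + 60
  more_exp$last_year_success_rate <- pmin(1, r$last_year_success_rate + 0.2)
  expect_true(all(score_operator_cto(more_exp) <= score_operator_cto(r)))
})

test_that("tier classification is non-decreasing in the score", {
  tiers <- classify_difficulty(-4:9)
  expect_true(all(diff(as.integer(tiers)) >= 0))
})

test_that("exhaustive enumeration over the 12 binary score variables matches the bit-count-plus-credit oracle", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 12))
  names(grid) <- c("prior_cabg_target_vessel", "blunt_stump", "calcification",
                   "severe_angulation", "long", "distal_disease", "poor_coll",
                   "in_stent", "ostial", "hi_vol", "hi_years", "hi_rate")
  cases <- make_cases(nrow(grid))
  for (f in c("prior_cabg_target_vessel", "blunt_stump", "calcification",
              "severe_angulation", "distal_disease", "in_stent", "ostial")) {
    cases[[f]] <- grid[[f]]
  }
  cases$bend_ge45 <- grid$severe_angulation
  cases$occlusion_length_mm <- ifelse(grid$long, 25, 10)
  cases$rentrop_grade <- ifelse(grid$poor_coll, 1L, 3L)
  cases$annual_volume <- ifelse(grid$hi_vol, 60L, 20L)
  cases$years_performing <- ifelse(grid$hi_years, 5L, 1L)
  cases$last_year_success_rate <- ifelse(grid$hi_rate, 0.95, 0.80)
  scores <- score_operator_cto(cases)
  oracle <- rowSums(grid[, 1:9]) - grid$hi_vol - grid$hi_years - 2 * grid$hi_rate
  expect_identical(scores, as.integer(oracle))
  expect_identical(max(scores), 9L)
  expect_identical(min(scores), -4L)
  expect_identical(sort(unique(scores)), -4:9)
})
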