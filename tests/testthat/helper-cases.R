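# Fixture builders. All constructed in code; no stored data.

.bool_cols_test <- function() {
  c("prior_mi", "prior_failed_attempt", "prior_cabg_target_vessel",
    "blunt_stump", "calcification", "calcification_severe", "bend_ge45",
    "severe_angulation", "distal_disease", "in_stent", "ostial",
    "technical_success", "procedural_success")
}

# One benign case row (score 0 everywhere) with a zero-credit operator.
make_cases <- function(n = 1L, ...) {
  base <- data.frame(
    case_id = sprintf("c%04d", seq_len(n)),
    operator_id = "op01",
    years_performing = 1L,
    annual_volume = 20L,
    last_year_success_rate = 0.80,
    age_years = 60L,
    prior_mi = FALSE,
    prior_failed_attempt = FALSE,
    prior_cabg_target_vessel = FALSE,
    target_vessel = "LAD",
    blunt_stump = FALSE,
    calcification = FALSE,
    calcification_severe = FALSE,
    bend_ge45 = FALSE,
    severe_angulation = FALSE,
    occlusion_length_mm = 10,
    distal_disease = FALSE,
    rentrop_grade = 3L,
    in_stent = FALSE,
    ostial = FALSE,
    technical_success = TRUE,
    procedural_success = TRUE,
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# A case whose operator-CTO score is exactly k (0..9), by switching on the
# first k adverse variables in a fixed order; operator credit stays 0.
adverse_case <- function(k, ...) {
  stopifnot(k >= 0, k <= 9)
  x <- make_cases(1L, ...)
  flags <- c("prior_cabg_target_vessel", "blunt_stump", "calcification",
             "severe_angulation", "length", "distal_disease", "rentrop",
             "in_stent", "ostial")
  for (f in utils::head(flags, k)) {
    if (f == "length") x$occlusion_length_mm <- 25
    else if (f == "rentrop") x$rentrop_grade <- 1L
    else x[[f]] <- TRUE
  }
  x$bend_ge45 <- x$bend_ge45 | x$severe_angulation
  x
}

# Independent random valid inputs for property tests (deliberately not the
# package generator).
random_cases <- function(n, seed) {
  set.seed(seed)
  coin <- function(p = 0.5) runif(n) < p
  calc <- coin()
  bend <- coin()
  df <- make_cases(n)
  df$age_years <- sample(18:95, n, replace = TRUE)
  df$prior_mi <- coin()
  df$prior_failed_attempt <- coin()
  df$prior_cabg_target_vessel <- coin()
  df$target_vessel <- sample(c("LAD", "LCX", "RCA", "LM"), n, replace = TRUE)
  df$blunt_stump <- coin()
  df$calcification <- calc
  df$calcification_severe <- calc & coin()
  df$bend_ge45 <- bend
  df$severe_angulation <- bend & coin()
  df$occlusion_length_mm <- runif(n, 0, 60)
  df$distal_disease <- coin()
  df$rentrop_grade <- sample(0:3, n, replace = TRUE)
  df$in_stent <- coin()
  df$ostial <- coin()
  df$years_performing <- sample(0:15, n, replace = TRUE)
  df$annual_volume <- sample(0:120, n, replace = TRUE)
  df$last_year_success_rate <- runif(n)
  df
}

# Back-solved tier fixture: per-tier (n, technical successes) =
# (103, 102), (24, 21), (13, 7), (4, 1); total 144 cases, 131 successes.
tier_fixture_cohort <- function() {
  blocks <- list(c(score = 2, n = 103, succ = 102),
                 c(score = 3, n = 24, succ = 21),
                 c(score = 4, n = 13, succ = 7),
                 c(score = 5, n = 4, succ = 1))
  rows <- do.call(rbind, lapply(blocks, function(b) {
    x <- adverse_case(b[["score"]])
    x <- x[rep(1, b[["n"]]), ]
    x$technical_success <- seq_len(b[["n"]]) <= b[["succ"]]
    x$procedural_success <- x$technical_success
    x
  }))
  rows$case_id <- sprintf("c%04d", seq_len(nrow(rows)))
  rownames(rows) <- NULL
  as_cohort(rows)
}
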