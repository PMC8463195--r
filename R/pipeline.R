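# End-to-end pipeline: obtain a cohort (generate or load), score every case
# with every model, evaluate calibration/discrimination/agreement, and emit
# a report. Deterministic given the run configuration.

#' Pipeline run configuration
#'
#' @param mode `"generate"` (build a synthetic cohort from `generator`) or
#'   `"load"` (read `cohort_path`).
#' @param generator a [generator_config()]; used when `mode = "generate"`.
#' @param cohort_path CSV path; used when `mode = "load"`.
#' @param comparators non-empty subset of
#'   `c("jcto", "progress", "ora", "recharge", "cl")` evaluated alongside
#'   the operator-CTO score.
#' @param level confidence level for AUC intervals (default 0.95).
#' @param hl_groups requested Hosmer-Lemeshow group count (default 10).
#' @param rating_n,rating_agreement,rating_categories parameters of the
#'   re-rating agreement exercise simulated in `generate` mode (default: 30
#'   cases, copy probability 0.85, 4 categories).
#' @param seed root seed for all randomness in the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("generate", "load"),
                       generator = generator_config(),
                       cohort_path = NULL,
                       comparators = c("jcto", "progress", "ora", "recharge", "cl"),
                       level = 0.95,
                       hl_groups = 10L,
                       rating_n = 30L,
                       rating_agreement = 0.85,
                       rating_categories = 4L,
                       seed = 1L) {
  mode <- match.arg(mode)
  comparators <- match.arg(comparators,
                           c("jcto", "progress", "ora", "recharge", "cl"),
                           several.ok = TRUE)
  if (length(comparators) == 0) stop("comparator set must be non-empty")
  if (mode == "load" && is.null(cohort_path)) {
    stop("mode 'load' requires cohort_path")
  }
  structure(list(mode = mode, generator = generator,
                 cohort_path = cohort_path, comparators = comparators,
                 level = level, hl_groups = as.integer(hl_groups),
                 rating_n = as.integer(rating_n),
                 rating_agreement = rating_agreement,
                 rating_categories = as.integer(rating_categories),
                 seed = as.integer(seed)),
            class = "run_config")
}

.score_fun <- function(name) {
  switch(name,
         operator_cto = score_operator_cto,
         jcto = score_jcto,
         progress = score_progress,
         ora = score_ora,
         recharge = score_recharge,
         cl = score_cl,
         stop("unknown score: ", name))
}

#' Evaluate every selected score on a cohort
#'
#' For each score: mean and sd over the cohort; discrimination of technical
#' failure (positive class = failure, higher score predicts failure) as
#' Mann-Whitney AUC with a DeLong interval; calibration as a univariate
#' logistic recalibration followed by the Hosmer-Lemeshow test. Cohorts
#' where every case has the same technical outcome produce a partial report
#' with per-score skip reasons instead of an error.
#'
#' @param cohort a `cto_cohort`.
#' @param comparators comparator score names (see [run_config()]).
#' @param level confidence level for the AUC interval.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return list keyed by score name; each entry has `mean`, `sd`, and
#'   either `auc`/`hl` results or a `skipped` reason.
#' @export
evaluate_scores <- function(cohort, comparators = c("jcto", "progress",
                                                    "ora", "recharge", "cl"),
                            level = 0.95, hl_groups = 10L) {
  failure <- !cohort$technical_success
  degenerate <- length(unique(failure)) < 2
  out <- list()
  for (nm in c("operator_cto", comparators)) {
    s <- .score_fun(nm)(cohort)
    entry <- list(mean = mean(s), sd = sd(s))
    if (degenerate) {
      entry$skipped <- "single outcome class: AUC and calibration undefined"
    } else if (sum(failure) < 2 || sum(!failure) < 2) {
      entry$skipped <- "fewer than 2 cases in an outcome class"
    } else {
      ci <- auc_ci(s, failure, level = level)
      entry$auc <- list(auc = ci$auc, ci_low = ci$ci_low,
                        ci_high = ci$ci_high, level = level)
      recal <- logistic_recalibration(s, failure)
      if (recal$separation) {
        entry$hl <- list(skipped = "separation in logistic recalibration")
      } else {
        hl <- hosmer_lemeshow(recal$probabilities, failure,
                              n_groups = hl_groups)
        entry$hl <- list(statistic = hl$statistic, df = hl$df,
                         p_value = hl$p_value,
                         df_degenerate = hl$df_degenerate)
      }
    }
    out[[nm]] <- entry
  }
  out
}

#' Run the full pipeline
#'
#' Generate or load the cohort, score all cases, and assemble the
#' evaluation report: cohort summary (n, success percentages), per-tier
#' success table, per-score discrimination and calibration, operator-group
#' comparison, and (in generate mode) a simulated re-rating agreement
#' kappa. All randomness flows from `config$seed`.
#'
#' @param config a [run_config()].
#' @return list of class `evaluation_report`.
#' @export
#' @examples
#' cfg <- run_config(generator = generator_config(n_cases = 144, seed = 11))
#' report <- run_pipeline(cfg)
#' report$cohort_summary
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "generate") {
    gen <- config$generator
    gen$seed <- config$seed
    cohort <- generate_cohort(gen)
  } else {
    cohort <- read_cohort(config$cohort_path)
  }
  n <- nrow(cohort)
  tech <- sum(cohort$technical_success)
  proc <- sum(cohort$procedural_success)
  report <- list(
    meta = list(package_version = as.character(packageVersion("ctoscore")),
                seed = config$seed,
                mode = config$mode,
                config_hash = .config_hash(config),
                comparators = config$comparators),
    cohort_summary = list(
      n = n,
      technical_success = tech,
      technical_success_pct = if (n > 0) percent(tech, n) else NA_real_,
      technical_success_rate = if (n > 0) tech / n else NA_real_,
      procedural_success = proc,
      procedural_success_pct = if (n > 0) percent(proc, n) else NA_real_),
    tier_table = as.data.frame(tier_success_table(cohort)),
    scores = evaluate_scores(cohort, config$comparators,
                             level = config$level,
                             hl_groups = config$hl_groups),
    operator_groups = .group_comparison(cohort)
  )
  if (config$mode == "generate") {
    ratings <- generate_rating_pairs(config$rating_n, config$rating_agreement,
                                     config$rating_categories,
                                     seed = .stage_seed(config$seed, "extra"))
    k <- cohen_kappa(ratings$rater_a, ratings$rater_b)
    report$rating_agreement <- list(kappa = k$kappa,
                                    observed_agreement = k$observed_agreement,
                                    n = k$n)
  }
  class(report) <- "evaluation_report"
  report
}

# Per-operator-group counts, success rates, mean scores, and the
# between-group tests (success by chi-square, score by ANOVA/rank-sum).
.group_comparison <- function(cohort) {
  if (nrow(cohort) == 0) return(list(skipped = "empty cohort"))
  grp <- classify_operator_group(cohort$years_performing,
                                 cohort$annual_volume,
                                 cohort$last_year_success_rate)
  op_score <- score_operator_cto(cohort)
  n_g <- as.vector(table(grp))
  tech_g <- as.vector(tapply(cohort$technical_success, grp, sum, default = 0L))
  summary <- data.frame(
    group = levels(grp),
    n = n_g,
    technical_success = tech_g,
    technical_pct = ifelse(n_g > 0, percent(tech_g, pmax(n_g, 1)), NA_real_),
    mean_operator_cto = as.vector(tapply(op_score, grp, mean))
  )
  out <- list(summary = summary)
  present <- levels(grp)[n_g > 0]
  if (length(present) >= 2) {
    tab <- table(factor(grp, levels = present), cohort$technical_success)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      out$success_chi_square <- chi_square_test(tab)
    } else {
      out$success_chi_square <- list(skipped = "degenerate success margin")
    }
    groups <- split(op_score, factor(grp, levels = present))
    if (length(unlist(groups)) > length(groups)) {
      out$score_anova <- one_way_anova(groups)
      out$score_kruskal <- kruskal_wallis(groups)
    }
  } else {
    out$tests_skipped <- "fewer than 2 operator groups present"
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("CTO-PCI evaluation report (seed %d, %s mode)\n",
              x$meta$seed, x$meta$mode))
  cat(sprintf("  n = %d; technical success %s%%, procedural success %s%%\n",
              cs$n, cs$technical_success_pct, cs$procedural_success_pct))
  cat("  per-tier technical success (%):",
      paste(x$tier_table$technical_pct, collapse = " / "), "\n")
  for (nm in names(x$scores)) {
    e <- x$scores[[nm]]
    if (!is.null(e$skipped)) {
      cat(sprintf("  %-12s mean %.2f +/- %.2f  [skipped: %s]\n",
                  nm, e$mean, e$sd, e$skipped))
    } else {
      hl_txt <- if (!is.null(e$hl$skipped)) {
        paste0("HL skipped: ", e$hl$skipped)
      } else if (isTRUE(e$hl$df_degenerate)) {
        sprintf("HL chi2 %.3f (df degenerate)", e$hl$statistic)
      } else {
        sprintf("HL chi2 %.3f p %.3f", e$hl$statistic, e$hl$p_value)
      }
      cat(sprintf("  %-12s mean %.2f +/- %.2f  AUC %.3f (%.3f-%.3f)  %s\n",
                  nm, e$mean, e$sd, e$auc$auc, e$auc$ci_low, e$auc$ci_high,
                  hl_txt))
    }
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON output is byte-stable across runs with an identical configuration;
#' Markdown mirrors the per-tier and per-group summary table layout (one
#' row per difficulty tier / operator group). Partial reports keep their
#' skip reasons in the output.
#'
#' @param report an `evaluation_report` from [run_pipeline()].
#' @param path output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
emit_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "evaluation_report"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = 12, pretty = TRUE, na = "null")
  } else {
    lines <- c("# CTO-PCI cohort evaluation", "",
               sprintf("- seed: %d, mode: %s, package %s", report$meta$seed,
                       report$meta$mode, report$meta$package_version),
               sprintf("- n = %d; technical success %s%%; procedural success %s%%",
                       report$cohort_summary$n,
                       report$cohort_summary$technical_success_pct,
                       report$cohort_summary$procedural_success_pct),
               "", "## Success by difficulty tier", "",
               "| tier | n | technical | technical % | procedural | procedural % |",
               "|---|---|---|---|---|---|")
    tt <- report$tier_table
    for (i in seq_len(nrow(tt))) {
      lines <- c(lines, sprintf("| %s | %d | %d | %s | %d | %s |",
                                tt$tier[i], tt$n[i], tt$technical_success[i],
                                tt$technical_pct[i], tt$procedural_success[i],
                                tt$procedural_pct[i]))
    }
    lines <- c(lines, "", "## Score evaluation", "",
               "| score | mean | sd | AUC | CI | HL chi2 | HL p | note |",
               "|---|---|---|---|---|---|---|---|")
    for (nm in names(report$scores)) {
      e <- report$scores[[nm]]
      if (!is.null(e$skipped)) {
        lines <- c(lines, sprintf("| %s | %.2f | %.2f | - | - | - | - | %s |",
                                  nm, e$mean, e$sd, e$skipped))
      } else {
        hl_stat <- if (is.null(e$hl$statistic)) "-" else sprintf("%.3f", e$hl$statistic)
        hl_p <- if (is.null(e$hl$p_value) || is.na(e$hl$p_value)) "-" else sprintf("%.3f", e$hl$p_value)
        note <- if (!is.null(e$hl$skipped)) e$hl$skipped else ""
        lines <- c(lines, sprintf("| %s | %.2f | %.2f | %.3f | %.3f-%.3f | %s | %s | %s |",
                                  nm, e$mean, e$sd, e$auc$auc, e$auc$ci_low,
                                  e$auc$ci_high, hl_stat, hl_p, note))
      }
    }
    og <- report$operator_groups
    if (!is.null(og$summary)) {
      lines <- c(lines, "", "## Operator groups", "",
                 "| group | n | technical | technical % | mean operator-CTO |",
                 "|---|---|---|---|---|")
      gs <- og$summary
      for (i in seq_len(nrow(gs))) {
        lines <- c(lines, sprintf("| %s | %d | %d | %s | %s |",
                                  gs$group[i], gs$n[i], gs$technical_success[i],
                                  ifelse(is.na(gs$technical_pct[i]), "-",
                                         gs$technical_pct[i]),
                                  ifelse(is.na(gs$mean_operator_cto[i]), "-",
                                         sprintf("%.2f", gs$mean_operator_cto[i]))))
      }
    }
    if (!is.null(report$rating_agreement)) {
      lines <- c(lines, "", sprintf(
        "Re-rating agreement: kappa %.3f over %d cases.",
        report$rating_agreement$kappa, report$rating_agreement$n))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
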