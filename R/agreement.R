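# Inter-rater agreement: unweighted Cohen's kappa.

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with
#' expected agreement p_e from the product of the two raters' marginal
#' distributions. Used here to quantify intra-/inter-observer consistency
#' of angiographic score adjudication.
#'
#' When both raters are constant and identical, p_e = 1 and the formula is
#' 0/0; kappa is then defined as 1 and flagged.
#'
#' @param ratings_a,ratings_b equal-length vectors of category labels.
#' @return list of class `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n`, `degenerate`.
#' @export
#' @examples
#' r <- generate_rating_pairs(200, agreement = 0.85, n_categories = 4, seed = 2)
#' cohen_kappa(r$rater_a, r$rater_b)
cohen_kappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) >= 1,
            !anyNA(ratings_a), !anyNA(ratings_b))
  n <- length(ratings_a)
  cats <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = cats)
  b <- factor(as.character(ratings_b), levels = cats)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  degenerate <- p_e >= 1 - 1e-12
  kappa <- if (degenerate) 1 else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = unname(kappa), observed_agreement = p_o,
                 expected_agreement = unname(p_e), n = n,
                 degenerate = degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)%s\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n,
              if (x$degenerate) " [both raters constant]" else ""))
  invisible(x)
}
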