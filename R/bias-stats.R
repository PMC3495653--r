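# Pearson chi-squared tests for codon (pair) usage bias.
#
# Two nulls are supported per unit (amino acid or amino-acid pair):
#   uniform  -- synonymous codon (pair) usage in the gene set is unbiased;
#   vs_all   -- usage in the high-expression set equals usage in all genes.
# Units with a single synonymous codon (pair) are "singular" (Met, Trp and
# pairs composed only of them) and carry no statistic; units where any
# expected count falls below 5 are "unevaluated", the standard adequacy
# rule for Pearson's test.

new_bias_result <- function(unit, test, chi2 = NA_real_, df = NA_integer_,
                            p_value = NA_real_, category) {
  structure(
    list(unit = unit, test = test, chi2 = chi2, df = df,
         p_value = p_value, category = category),
    class = "bias_test_result"
  )
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat(sprintf("<bias_test %s/%s> chi2 = %.4g, df = %s, p = %.4g -> %s\n",
              x$unit, x$test, x$chi2, x$df, x$p_value, x$category))
  invisible(x)
}

#' Chi-squared test of a unit against the uniform null
#'
#' Tests whether the observed synonymous codon (pair) counts of one amino
#' acid (pair) deviate from the unbiased uniform distribution. The expected
#' count per cell is `N / n` for `N` total observations over `n` synonymous
#' codons; the statistic is compared against the chi-squared distribution
#' with `n - 1` degrees of freedom (one constraint: counts sum to `N`).
#'
#' @param observed Nonnegative integer vector of synonymous counts for one
#'   unit; its length is the unit's degeneracy.
#' @param unit Optional unit label carried into the result.
#' @param alpha Significance cutoff for the biased/unbiased call.
#' @param min_expected Adequacy threshold: any expected cell below this
#'   makes the unit `unevaluated` (default 5).
#' @return A `bias_test_result` with fields `unit`, `test`, `chi2`, `df`,
#'   `p_value` and `category` in `{biased, unbiased, singular, unevaluated}`.
#' @examples
#' chi2_uniform(c(15, 5))   # chi2 = 5, df = 1, p ~ 0.025 -> biased
#' @export
chi2_uniform <- function(observed, unit = NA_character_, alpha = 0.05,
                         min_expected = 5) {
  check_counts(observed)
  n <- length(observed)
  if (n == 1L) return(new_bias_result(unit, "uniform", category = "singular"))
  N <- sum(observed)
  expected <- rep(N / n, n)
  if (any(expected < min_expected)) {
    return(new_bias_result(unit, "uniform", category = "unevaluated"))
  }
  finish_chi2(observed, expected, unit, "uniform", alpha)
}

#' Chi-squared test of high-expression usage against all-genes usage
#'
#' Tests whether the synonymous codon (pair) usage of one unit in the
#' high-expression gene set differs from its usage in all genes. Expected
#' counts are the all-genes counts rescaled to the high-expression total,
#' `E_i = O_i^All * N^High / N^All`, then the Pearson statistic is formed
#' as in [chi2_uniform()] with `n - 1` degrees of freedom.
#'
#' @param observed_high,observed_all Nonnegative integer count vectors for
#'   the same unit, aligned cell by cell.
#' @inheritParams chi2_uniform
#' @return A `bias_test_result` (test `"vs_all"`).
#' @examples
#' chi2_vs_all(c(20, 0), c(50, 50))   # E = (10, 10), chi2 = 20 -> biased
#' @export
chi2_vs_all <- function(observed_high, observed_all, unit = NA_character_,
                        alpha = 0.05, min_expected = 5) {
  check_counts(observed_high)
  check_counts(observed_all)
  if (length(observed_high) != length(observed_all)) {
    stop("high and all-genes count vectors must align cell by cell")
  }
  n <- length(observed_high)
  if (n == 1L) return(new_bias_result(unit, "vs_all", category = "singular"))
  N_all <- sum(observed_all)
  if (N_all == 0) {
    return(new_bias_result(unit, "vs_all", category = "unevaluated"))
  }
  expected <- observed_all * sum(observed_high) / N_all
  if (any(expected < min_expected)) {
    return(new_bias_result(unit, "vs_all", category = "unevaluated"))
  }
  finish_chi2(observed_high, expected, unit, "vs_all", alpha)
}

check_counts <- function(x) {
  if (!is.numeric(x) || length(x) == 0L || any(x < 0) ||
      any(x != round(x)) || anyNA(x)) {
    stop("counts must be nonnegative integers")
  }
}

finish_chi2 <- function(observed, expected, unit, test, alpha) {
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  new_bias_result(unit, test, chi2, df, p,
                  if (p < alpha) "biased" else "unbiased")
}

#' Codon (pair) usage bias tests over a whole gene set
#'
#' Runs the per-unit chi-squared test for every amino acid (level
#' `"codon"`, 21 units) or every amino-acid pair (level `"pair"`, 420
#' units). With `all_genes` supplied the null is equality with the
#' all-genes usage; otherwise the uniform null is tested.
#'
#' @param high_genes Gene set (list of [codon_seq()]) whose usage is tested,
#'   typically the host's high-expression genes.
#' @param all_genes Optional gene set defining the comparison usage.
#' @param level `"codon"` for individual codon usage, `"pair"` for codon
#'   context.
#' @param alpha,min_expected Passed to the per-unit tests.
#' @param correction P-value adjustment method (see [stats::p.adjust()]);
#'   default `"none"`, mirroring a raw per-unit cutoff.
#' @param code A [genetic_code()] object.
#' @return A data.frame with one row per unit: `unit`, `test`, `chi2`,
#'   `df`, `p_value`, `category`.
#' @export
codon_bias_test <- function(high_genes, all_genes = NULL,
                            level = c("codon", "pair"),
                            alpha = 0.05, min_expected = 5,
                            correction = "none", code = default_code()) {
  level <- match.arg(level)
  if (level == "codon") {
    units <- code$amino_acids
    counts_of <- function(genes) {
      d <- icu_distribution(genes, code)
      split(unname(d$codon_counts), factor(unname(code$codon_to_aa), levels = units))
    }
  } else {
    units <- code$aa_pairs
    counts_of <- function(genes) {
      d <- cc_distribution(genes, code)
      split(unname(d$codon_counts), factor(translate_pairs(code), levels = units))
    }
  }
  high <- counts_of(high_genes)
  all_c <- if (!is.null(all_genes)) counts_of(all_genes)
  res <- lapply(units, function(u) {
    if (is.null(all_genes)) chi2_uniform(high[[u]], unit = u,
                                         alpha = alpha, min_expected = min_expected)
    else chi2_vs_all(high[[u]], all_c[[u]], unit = u,
                     alpha = alpha, min_expected = min_expected)
  })
  df <- do.call(rbind, lapply(res, function(r) {
    data.frame(unit = r$unit, test = r$test, chi2 = r$chi2, df = r$df,
               p_value = r$p_value, category = r$category,
               stringsAsFactors = FALSE)
  }))
  if (correction != "none") {
    ok <- !is.na(df$p_value)
    df$p_value[ok] <- stats::p.adjust(df$p_value[ok], method = correction)
    df$category[ok] <- ifelse(df$p_value[ok] < alpha, "biased", "unbiased")
  }
  df
}

#' Tabulate bias-test categories
#'
#' Collapses a per-unit bias report into category counts (biased, unbiased,
#' singular, unevaluated). A complete individual-codon-usage run sums to 21
#' units; a complete codon-context run to 420.
#'
#' @param results Data.frame from [codon_bias_test()], or a list of
#'   `bias_test_result` objects.
#' @return Named integer vector over the four categories plus `total`.
#' @export
summarize_bias <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      data.frame(unit = r$unit, category = r$category, stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(results$unit)) {
    stop("duplicate units in bias results: ",
         paste(unique(results$unit[duplicated(results$unit)]), collapse = ", "))
  }
  cats <- c("biased", "unbiased", "singular", "unevaluated")
  out <- vapply(cats, function(cc) sum(results$category == cc), integer(1))
  c(out, total = nrow(results))
}
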