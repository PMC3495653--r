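# Non-iterative individual-codon-usage optimizer (ICO) and the
# random-codon-assignment (RCA) control.
#
# ICO exploits the independence of codon positions under the ICU measure:
# the fitness depends only on realized per-codon counts, so the optimal
# design reduces to (1) computing the real-valued target count of each
# codon, reference frequency times the protein's count of the encoded
# amino acid, (2) rounding those targets to integers within each amino
# acid, and (3) placing the resulting codon multiset randomly along the
# sequence. Rounding uses largest-remainder (Hamilton) apportionment, which
# preserves every per-amino-acid total and minimizes the L1 distance to
# the real-valued optimum, so the result attains the global ICU optimum
# among integer-count designs.

#' Optimal per-codon counts for a target protein
#'
#' Multiplies each codon's reference ICU frequency by the protein's count
#' of the encoded amino acid, then rounds within each amino acid by
#' largest-remainder apportionment so synonymous budgets sum exactly to
#' that amino acid's residue count. Remainder ties are broken by a random
#' draw from the current RNG stream (seed it for reproducibility).
#'
#' @param protein Amino-acid sequence (string or character vector; `*`
#'   allowed as a terminal stop).
#' @param reference A `usage_dist` of kind `"ICU"` for the host.
#' @param uniform_fallback If `TRUE`, amino acids absent from the reference
#'   are budgeted with uniform synonymous frequencies instead of raising an
#'   error.
#' @param code A [genetic_code()] object.
#' @return Named integer vector over the 64 codons (class `codon_budget`).
#' @examples
#' ref <- icu_distribution(codon_seq(c("AAA", "AAA", "AAA", "AAG")))
#' optimal_codon_counts("KKKK", ref)[c("AAA", "AAG")]
#' @export
optimal_codon_counts <- function(protein, reference, uniform_fallback = FALSE,
                                 code = default_code()) {
  if (!inherits(reference, "usage_dist") || reference$kind != "ICU") {
    stop("`reference` must be a usage_dist of kind ICU")
  }
  protein <- validate_protein(protein, code)
  aa_tab <- table(factor(protein, levels = code$amino_acids))
  freq <- reference$freq
  budget <- integer(64)
  names(budget) <- code$codons
  for (aa in names(aa_tab)[aa_tab > 0L]) {
    syn <- code$aa_to_codons[[aa]]
    p <- freq[syn]
    if (sum(p) == 0) {
      if (!uniform_fallback) {
        stop(sprintf(paste0(
          "amino acid '%s' has no reference usage; rerun with ",
          "uniform_fallback = TRUE to budget its codons uniformly"), aa))
      }
      p <- rep(1 / length(syn), length(syn))
    }
    budget[syn] <- largest_remainder(p * as.integer(aa_tab[[aa]]),
                                     as.integer(aa_tab[[aa]]))
  }
  structure(budget, class = c("codon_budget", "integer"))
}

# Hamilton apportionment: floor the quotas, then hand the leftover units to
# the largest remainders; equal remainders are ordered by a random draw.
largest_remainder <- function(quota, total) {
  base <- floor(quota + 1e-9)
  left <- total - sum(base)
  if (left > 0L) {
    rem <- quota - base
    ord <- order(rem, stats::runif(length(rem)), decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Design a sequence with optimal individual codon usage (ICO)
#'
#' Computes the rounded codon budget with [optimal_codon_counts()] and
#' scatters each amino acid's codon multiset uniformly at random over that
#' amino acid's positions. Every admissible arrangement of the budget is
#' equally likely; all arrangements share the same (optimal) ICU fitness.
#'
#' @inheritParams optimal_codon_counts
#' @param seed Optional integer seed; when given the design is reproducible.
#' @param id Identifier for the returned sequence.
#' @return A [codon_seq()] whose per-codon counts equal the budget exactly.
#' @export
solve_ico <- function(protein, reference, seed = NULL,
                      uniform_fallback = FALSE, id = "x_ICO",
                      code = default_code()) {
  if (!is.null(seed)) set.seed(seed)
  protein <- validate_protein(protein, code)
  budget <- optimal_codon_counts(protein, reference, uniform_fallback, code)
  out <- character(length(protein))
  for (aa in unique(protein)) {
    pos <- which(protein == aa)
    syn <- code$aa_to_codons[[aa]]
    pool <- rep(syn, budget[syn])
    out[pos] <- if (length(pool) > 1L) sample(pool) else pool
  }
  codon_seq(out, id = id, code = code)
}

#' Random codon assignment (RCA) control sequence
#'
#' Back-translates a protein by assigning each residue a synonymous codon
#' independently -- uniformly at random by default, or proportionally to a
#' reference ICU distribution. Serves as the unoptimized control in method
#' comparisons.
#'
#' @inheritParams solve_ico
#' @param source `"uniform"` (default) draws synonyms equiprobably;
#'   `"reference"` draws them from `reference`'s conditional frequencies.
#' @param reference Required when `source = "reference"`.
#' @return A [codon_seq()] translating to `protein`.
#' @export
rca_sequence <- function(protein, seed = NULL,
                         source = c("uniform", "reference"),
                         reference = NULL, id = "x_RCA",
                         code = default_code()) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  protein <- validate_protein(protein, code)
  out <- character(length(protein))
  for (aa in unique(protein)) {
    pos <- which(protein == aa)
    syn <- code$aa_to_codons[[aa]]
    prob <- NULL
    if (source == "reference") {
      if (is.null(reference) || reference$kind != "ICU") {
        stop("`reference` (ICU usage_dist) required when source = 'reference'")
      }
      prob <- reference$freq[syn]
      if (sum(prob) == 0) prob <- NULL
    }
    out[pos] <- if (length(syn) == 1L) syn else {
      sample(syn, length(pos), replace = TRUE, prob = prob)
    }
  }
  codon_seq(out, id = id, code = code)
}
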