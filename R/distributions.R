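# ICU and CC usage distributions and the fitness measures built on them.
#
# Both distributions are *conditional* frequencies: each codon's frequency
# is taken relative to the count of the amino acid it encodes, and each
# codon pair's frequency relative to the count of its amino-acid pair.
# An amino acid (pair) never observed in a gene set has all its synonymous
# frequencies defined as 0, which keeps the fitness sums total; those terms
# are constant in the design variables, so optimizer rankings are unaffected.

as_gene_list <- function(genes) {
  if (inherits(genes, "codon_seq")) genes <- list(genes)
  if (!is.list(genes) || length(genes) == 0L ||
      !all(vapply(genes, inherits, logical(1), "codon_seq"))) {
    stop("`genes` must be a codon_seq or a nonempty list of codon_seq objects")
  }
  genes
}

new_usage_dist <- function(kind, freq, aa_counts, codon_counts, code) {
  structure(
    list(kind = kind, freq = freq, aa_counts = aa_counts,
         codon_counts = codon_counts, code = code),
    class = "usage_dist"
  )
}

#' Individual codon usage (ICU) distribution of a gene set
#'
#' Pools codon counts across all sequences and divides each codon's count by
#' the pooled count of the amino acid it encodes, giving the conditional
#' synonymous-codon frequencies `p^k` for all 64 codons. Codons of amino
#' acids absent from the gene set get frequency 0.
#'
#' @param genes A `codon_seq` or a nonempty list of them.
#' @param code A [genetic_code()] object.
#' @return A `usage_dist` of kind `"ICU"` with `freq` (named, 64 codons),
#'   `codon_counts` and `aa_counts` (named, 21 symbols).
#' @examples
#' d <- icu_distribution(codon_seq(c("AUG", "AAA", "AAA", "AAG", "UGG")))
#' d$freq[c("AAA", "AAG")]
#' @export
icu_distribution <- function(genes, code = default_code()) {
  genes <- as_gene_list(genes)
  codon_counts <- integer(64)
  for (g in genes) {
    codon_counts <- codon_counts + tabulate(codon_index(g$codons, code), 64L)
  }
  names(codon_counts) <- code$codons
  caa <- codon_aa_index(code)
  aa_counts <- as.integer(rowsum(codon_counts, caa)[as.character(1:21), 1L])
  aa_counts[is.na(aa_counts)] <- 0L
  names(aa_counts) <- code$amino_acids
  denom <- aa_counts[caa]
  freq <- ifelse(denom > 0L, codon_counts / denom, 0)
  names(freq) <- code$codons
  new_usage_dist("ICU", freq, aa_counts, codon_counts, code)
}

#' Codon context (CC) distribution of a gene set
#'
#' Counts the overlapping adjacent codon pairs of every sequence (a gene of
#' n codons contributes n - 1 pairs), pools them, and divides each codon
#' pair's count by the pooled count of its amino-acid pair, giving the
#' conditional codon-pair frequencies `q^k` over the 3904 pairs whose first
#' codon is a sense codon.
#'
#' @inheritParams icu_distribution
#' @return A `usage_dist` of kind `"CC"` with `freq` (named, 3904 codon
#'   pairs), `codon_counts` (3904) and `aa_counts` (420 amino-acid pairs).
#' @export
cc_distribution <- function(genes, code = default_code()) {
  genes <- as_gene_list(genes)
  dense <- numeric(4096)
  for (g in genes) {
    if (length(g$codons) < 2L) {
      stop(sprintf("sequence%s has fewer than 2 codons: no codon pairs",
                   if (is.null(g$id)) "" else paste0(" '", g$id, "'")))
    }
    pc <- pair_code(codon_index(g$codons, code))
    dense <- dense + tabulate(pc, 4096L)
  }
  vp <- valid_pair_codes(code)
  if (any(dense[-vp] > 0)) {
    stop("codon pair with a stop in first position encountered")
  }
  codon_counts <- dense[vp]
  names(codon_counts) <- code$codon_pairs
  pair_aa <- translate_pairs(code)            # aa pair per codon pair (3904)
  aa_counts <- tapply(codon_counts, factor(pair_aa, levels = code$aa_pairs), sum)
  aa_counts <- as.integer(ifelse(is.na(aa_counts), 0L, aa_counts))
  names(aa_counts) <- code$aa_pairs
  denom <- aa_counts[match(pair_aa, code$aa_pairs)]
  freq <- ifelse(denom > 0L, codon_counts / denom, 0)
  names(freq) <- code$codon_pairs
  new_usage_dist("CC", freq, aa_counts, codon_counts, code)
}

# amino-acid pair encoded by each of the 3904 codon pairs, enumeration order
translate_pairs <- function(code = default_code()) {
  key <- paste0("tp_", substr(digest_code(code), 1L, 8L))
  if (is.null(.code_cache[[key]])) {
    c1 <- substr(code$codon_pairs, 1L, 3L)
    c2 <- substr(code$codon_pairs, 4L, 6L)
    .code_cache[[key]] <- paste0(
      code$codon_to_aa[match(c1, code$codons)],
      code$codon_to_aa[match(c2, code$codons)]
    )
  }
  .code_cache[[key]]
}

digest_code <- function(code) paste(code$codon_to_aa, collapse = "")

#' @export
print.usage_dist <- function(x, ...) {
  used <- sum(x$codon_counts > 0)
  cat(sprintf("<usage_dist %s> %d units, %d observed, %d pooled counts\n",
              x$kind, length(x$freq), used, sum(x$codon_counts)))
  invisible(x)
}

check_kind <- function(reference, subject, kind) {
  if (!inherits(reference, "usage_dist") || !inherits(subject, "usage_dist")) {
    stop("both arguments must be usage_dist objects")
  }
  if (reference$kind != kind || subject$kind != kind) {
    stop(sprintf("expected two %s distributions, got %s and %s",
                 kind, reference$kind, subject$kind))
  }
}

#' ICU fitness of a subject distribution against a reference
#'
#' The negative mean absolute difference between the two conditional codon
#' frequency vectors, averaged over all 64 codons:
#' `psi_ICU = -(1/64) * sum_k |p0^k - p1^k|`. The maximum 0 is attained
#' exactly when the two distributions coincide on every codon.
#'
#' @param reference,subject `usage_dist` objects of kind `"ICU"`.
#' @return A single number in `[-2 * 21 / 64, 0]`.
#' @export
icu_fitness <- function(reference, subject) {
  check_kind(reference, subject, "ICU")
  -sum(abs(reference$freq - subject$freq)) / 64
}

#' CC fitness of a subject distribution against a reference
#'
#' The negative mean absolute difference between conditional codon-pair
#' frequency vectors over the 3904 codon pairs:
#' `psi_CC = -(1/3904) * sum_k |q0^k - q1^k|`.
#'
#' @param reference,subject `usage_dist` objects of kind `"CC"`.
#' @return A single number in `[-2 * 420 / 3904, 0]`.
#' @export
cc_fitness <- function(reference, subject) {
  check_kind(reference, subject, "CC")
  -sum(abs(reference$freq - subject$freq)) / 3904
}

#' ICU and CC fitness of a candidate sequence
#'
#' Convenience wrapper: builds the subject's own ICU and CC distributions
#' and evaluates them against host references.
#'
#' @param x A [codon_seq()] (or list of them, pooled).
#' @param reference_icu,reference_cc Host reference distributions; either
#'   may be `NULL` to skip that objective.
#' @param code A [genetic_code()] object.
#' @return A `fitness_pair` list with `psi_icu` and `psi_cc` (NA when the
#'   corresponding reference was not supplied).
#' @export
fitness_pair <- function(x, reference_icu = NULL, reference_cc = NULL,
                         code = default_code()) {
  psi_icu <- psi_cc <- NA_real_
  if (!is.null(reference_icu)) {
    psi_icu <- icu_fitness(reference_icu, icu_distribution(x, code))
  }
  if (!is.null(reference_cc)) {
    psi_cc <- cc_fitness(reference_cc, cc_distribution(x, code))
  }
  structure(list(psi_icu = psi_icu, psi_cc = psi_cc), class = "fitness_pair")
}

#' @export
print.fitness_pair <- function(x, ...) {
  cat(sprintf("<fitness_pair> psi_ICU = %.6g, psi_CC = %.6g\n",
              x$psi_icu, x$psi_cc))
  invisible(x)
}

#' Write a usage distribution to TSV
#'
#' One row per unit (codon or codon pair) with its amino acid (pair),
#' pooled count and conditional frequency; readable back with
#' [read_usage_tsv()].
#'
#' @param dist A `usage_dist`.
#' @param path Output file path.
#' @export
write_usage_tsv <- function(dist, path) {
  stopifnot(inherits(dist, "usage_dist"))
  code <- dist$code
  aa <- if (dist$kind == "ICU") {
    unname(code$codon_to_aa[match(names(dist$freq), code$codons)])
  } else {
    translate_pairs(code)
  }
  df <- data.frame(
    unit = names(dist$freq),
    amino_acid = aa,
    count = as.integer(dist$codon_counts),
    frequency = as.numeric(dist$freq),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a usage distribution from TSV
#'
#' @param path File written by [write_usage_tsv()].
#' @param code A [genetic_code()] object.
#' @return A `usage_dist` (kind inferred from the number of rows).
#' @export
read_usage_tsv <- function(path, code = default_code()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 64L) {
    kind <- "ICU"; units <- code$codons
    unit_aa <- unname(code$codon_to_aa[match(units, code$codons)])
    aa_levels <- code$amino_acids
  } else if (nrow(df) == 3904L) {
    kind <- "CC"; units <- code$codon_pairs
    unit_aa <- translate_pairs(code)
    aa_levels <- code$aa_pairs
  } else {
    stop("expected 64 (ICU) or 3904 (CC) rows, got ", nrow(df))
  }
  m <- match(units, df$unit)
  if (anyNA(m)) stop("file does not enumerate every unit of the code")
  codon_counts <- as.integer(df$count[m]); names(codon_counts) <- units
  freq <- as.numeric(df$frequency[m]); names(freq) <- units
  aa_counts <- tapply(codon_counts, factor(unit_aa, levels = aa_levels), sum)
  aa_counts <- as.integer(ifelse(is.na(aa_counts), 0L, aa_counts))
  names(aa_counts) <- aa_levels
  new_usage_dist(kind, freq, aa_counts, codon_counts, code)
}
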