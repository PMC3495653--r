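# Genetic-code tables and sequence primitives consumed by every other module.
# Internal canonical alphabet is RNA; DNA input is converted on read.

STOP_SYMBOL <- "*"

#' Genetic code table
#'
#' Builds the codon/amino-acid lookup tables used throughout the package:
#' the 64 RNA codons, the 21 amino-acid symbols (20 amino acids plus the
#' stop symbol `*`), the synonymous-codon table, and the enumerations of
#' the 420 amino-acid pairs and 3904 codon pairs (pairs whose first element
#' is a stop are excluded, since nothing can follow a termination signal).
#'
#' @param table Optional named character vector mapping all 64 RNA codons to
#'   single-letter amino-acid symbols (stops as `"*"`), e.g. a table from
#'   [Biostrings::getGeneticCode()] with `U` substituted for `T`. Defaults to
#'   the standard genetic code (translation table 1).
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character, 64 entries), `aa_to_codons` (named list,
#'   21 entries), `codons`, `amino_acids`, `aa_pairs` (420), `codon_pairs`
#'   (3904), and `degeneracy` (named integer, synonymous-codon count per
#'   amino-acid symbol).
#'
#' @examples
#' gc <- genetic_code()
#' gc$degeneracy[c("M", "W", "L", "*")]
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    table <- Biostrings::RNA_GENETIC_CODE
  }
  if (!is.character(table) || is.null(names(table)) || length(table) != 64) {
    stop("`table` must be a named character vector of 64 codon -> amino-acid entries")
  }
  codons <- sort(names(table))
  if (!identical(codons, sort_codons_all())) {
    stop("`table` must cover exactly the 64 RNA codons over {A,C,G,U}")
  }
  codon_to_aa <- table[codons]
  aas <- sort(setdiff(unique(unname(codon_to_aa)), STOP_SYMBOL))
  amino_acids <- c(aas, STOP_SYMBOL)
  if (length(amino_acids) != 21) {
    stop("genetic code must map onto 21 amino-acid symbols (20 amino acids + '*')")
  }
  aa_to_codons <- split(codons, factor(codon_to_aa, levels = amino_acids))
  degeneracy <- vapply(aa_to_codons, length, integer(1))
  sense <- codons[codon_to_aa != STOP_SYMBOL]
  non_stop_aa <- setdiff(amino_acids, STOP_SYMBOL)

  # ordered pairs; stop never occupies the first position
  aa_pairs <- as.vector(t(outer(non_stop_aa, amino_acids, paste0)))
  codon_pairs <- as.vector(t(outer(sense, codons, paste0)))

  structure(
    list(
      codon_to_aa = codon_to_aa,
      aa_to_codons = aa_to_codons,
      codons = codons,
      amino_acids = amino_acids,
      aa_pairs = aa_pairs,
      codon_pairs = codon_pairs,
      degeneracy = degeneracy
    ),
    class = "genetic_code"
  )
}

sort_codons_all <- function() {
  b <- c("A", "C", "G", "U")
  sort(apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1L, paste0, collapse = ""))
}

.code_cache <- new.env(parent = emptyenv())

default_code <- function() {
  if (is.null(.code_cache$std)) .code_cache$std <- genetic_code()
  .code_cache$std
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> 64 codons -> 21 symbols;",
      length(x$aa_pairs), "amino-acid pairs,",
      length(x$codon_pairs), "codon pairs\n")
  invisible(x)
}

#' Enumerate the unit sets of the genetic code
#'
#' Returns the four enumerations every distribution and test in the package
#' is indexed by: the 64 codons, the 21 amino-acid symbols, the 420 ordered
#' amino-acid pairs and the 3904 ordered codon pairs (a stop can only occupy
#' the second position of a pair).
#'
#' @param code A [genetic_code()] object.
#' @return A list with elements `codons`, `amino_acids`, `aa_pairs`,
#'   `codon_pairs`.
#' @examples
#' lengths(enumerate_units())
#' @export
enumerate_units <- function(code = default_code()) {
  list(
    codons = code$codons,
    amino_acids = code$amino_acids,
    aa_pairs = code$aa_pairs,
    codon_pairs = code$codon_pairs
  )
}

normalize_codons <- function(codons) {
  codons <- toupper(as.character(codons))
  gsub("T", "U", codons, fixed = TRUE)
}

#' Translate a codon sequence
#'
#' @param codons Character vector of codon triplets (RNA or DNA alphabet,
#'   case-insensitive), or a [codon_seq()] object.
#' @param code A [genetic_code()] object.
#' @return Character vector of single-letter amino-acid symbols, stop as `*`.
#' @examples
#' translate_codons(c("AUG", "AGA", "UUU"))
#' @export
translate_codons <- function(codons, code = default_code()) {
  if (inherits(codons, "codon_seq")) codons <- codons$codons
  codons <- normalize_codons(codons)
  idx <- match(codons, code$codons)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("invalid codon '%s' at position %d: not a triplet over {A,C,G,U}",
                 codons[bad], bad))
  }
  unname(code$codon_to_aa[idx])
}

#' Codon sequence
#'
#' A protein-coding sequence represented as an ordered list of codon
#' triplets -- the unit of design that the optimizers manipulate. The
#' translated protein is stored alongside and kept consistent by
#' construction.
#'
#' @param codons Character vector of codon triplets (DNA or RNA alphabet),
#'   or a single nucleotide string whose length is divisible by 3.
#' @param id Optional sequence identifier.
#' @param code A [genetic_code()] object.
#' @return An object of class `codon_seq` with elements `codons` (RNA
#'   triplets), `protein` (amino-acid symbols) and `id`.
#' @examples
#' s <- codon_seq("ATGAGATTTTGA", id = "demo")
#' s$protein
#' @export
codon_seq <- function(codons, id = NULL, code = default_code()) {
  if (length(codons) == 1L && nchar(codons[1L]) > 3L) {
    n <- nchar(codons)
    if (n %% 3L != 0L) {
      stop(sprintf("sequence%s has length %d, not divisible by 3",
                   if (is.null(id)) "" else paste0(" '", id, "'"), n))
    }
    codons <- substring(codons, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  }
  codons <- normalize_codons(codons)
  if (length(codons) == 0L) stop("empty codon sequence")
  protein <- translate_codons(codons, code)
  structure(list(codons = codons, protein = protein, id = id),
            class = "codon_seq")
}

#' @export
print.codon_seq <- function(x, ...) {
  n <- length(x$codons)
  cat(sprintf("<codon_seq%s> %d codons: %s -> %s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id), n,
              paste(utils::head(x$codons, 5L), collapse = " "),
              paste(utils::head(x$protein, 5L), collapse = "")))
  invisible(x)
}

#' @export
length.codon_seq <- function(x) length(x$codons)

#' Adjacent codon and amino-acid pairs of a sequence
#'
#' The n - 1 overlapping pairs of adjacent codons (and their translated
#' amino-acid pairs) that the codon-context statistics are computed from.
#'
#' @param x A [codon_seq()] object.
#' @return List with `codon_pairs` and `aa_pairs`, each of length
#'   `length(x) - 1` (character, concatenated without separator).
#' @export
sequence_pairs <- function(x) {
  stopifnot(inherits(x, "codon_seq"))
  n <- length(x$codons)
  if (n < 2L) {
    return(list(codon_pairs = character(0), aa_pairs = character(0)))
  }
  list(
    codon_pairs = paste0(x$codons[-n], x$codons[-1L]),
    aa_pairs = paste0(x$protein[-n], x$protein[-1L])
  )
}

validate_protein <- function(protein, code = default_code()) {
  if (length(protein) == 1L && nchar(protein[1L]) > 1L) {
    protein <- strsplit(protein, "", fixed = TRUE)[[1L]]
  }
  protein <- toupper(protein)
  bad <- which(!(protein %in% code$amino_acids))
  if (length(bad)) {
    stop(sprintf("invalid amino-acid symbol '%s' at position %d",
                 protein[bad[1L]], bad[1L]))
  }
  protein
}

#' Size of the synonymous design space, on the log10 scale
#'
#' The number of distinct coding sequences for a protein is the product of
#' per-residue degeneracies; for an average 300-residue protein it reaches
#' the order of 10^100, which is why the codon-context optimizer is
#' heuristic. Returned on the log10 scale to avoid overflow.
#'
#' @param protein Amino-acid sequence (single string or character vector of
#'   symbols; `*` allowed).
#' @param code A [genetic_code()] object.
#' @return log10 of the number of synonymous coding sequences.
#' @examples
#' count_coding_sequences_log10("MW")   # 0: both residues have one codon
#' count_coding_sequences_log10("L")    # log10(6)
#' @export
count_coding_sequences_log10 <- function(protein, code = default_code()) {
  protein <- validate_protein(protein, code)
  if (length(protein) == 0L) stop("empty protein")
  sum(log10(code$degeneracy[protein]))
}
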