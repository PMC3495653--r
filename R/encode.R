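# Integer encodings used by the hot paths (fitness evaluation, the GA).
# Codons are coded 1..64 in sorted order; an adjacent codon pair (c1, c2)
# gets the dense code (c1 - 1) * 64 + c2 in 1..4096 (of which the 3904
# codes with a sense first codon are valid).

codon_index <- function(codons, code = default_code()) {
  idx <- match(normalize_codons(codons), code$codons)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("invalid codon '%s' at position %d", codons[bad], bad))
  }
  idx
}

aa_index <- function(protein, code = default_code()) {
  idx <- match(protein, code$amino_acids)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("invalid amino-acid symbol '%s' at position %d",
                 protein[bad[1L]], bad[1L]))
  }
  idx
}

pair_code <- function(ci) {
  n <- length(ci)
  (ci[-n] - 1L) * 64L + ci[-1L]
}

# dense codes (1..4096) of the 3904 valid codon pairs, in enumeration order
valid_pair_codes <- function(code = default_code()) {
  sense <- which(code$codon_to_aa != STOP_SYMBOL)
  as.vector(t(outer(sense - 1L, 1:64, function(a, b) a * 64L + b)))
}

# per-codon index of the amino acid it encodes (1..21)
codon_aa_index <- function(code = default_code()) {
  match(unname(code$codon_to_aa), code$amino_acids)
}
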