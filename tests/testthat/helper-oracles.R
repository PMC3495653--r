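# Independent oracles and fixture builders used across the test files.
# Oracles deliberately avoid the code paths they check: fitness is
# re-counted from raw sequences through the public distribution builders,
# Pareto sets are found by explicit pairwise peeling, and optima are found
# by exhaustive enumeration.

gc_std <- genetic_code()

# all synonymous codon sequences of a protein (list of character vectors);
# only for tiny proteins
enumerate_synonymous <- function(protein) {
  protein <- strsplit(paste(protein, collapse = ""), "")[[1L]]
  opts <- lapply(protein, function(a) gc_std$aa_to_codons[[a]])
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

# fitness by re-count from the raw sequence through the public builders
psi_icu_recount <- function(codons, reference) {
  icu_fitness(reference, icu_distribution(codon_seq(codons)))
}
psi_cc_recount <- function(codons, reference) {
  cc_fitness(reference, cc_distribution(codon_seq(codons)))
}

# exhaustive optima over the synonymous design space
brute_max_psi_icu <- function(protein, reference) {
  max(vapply(enumerate_synonymous(protein), psi_icu_recount, numeric(1),
             reference = reference))
}
brute_max_psi_cc <- function(protein, reference) {
  max(vapply(enumerate_synonymous(protein), psi_cc_recount, numeric(1),
             reference = reference))
}

# brute-force Pareto set: member i is nondominated iff no j dominates it,
# established by explicit scalar comparisons
pareto_set_oracle <- function(icu, cc) {
  n <- length(icu)
  vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) {
      if (j == i) next
      better_eq <- icu[j] >= icu[i] && cc[j] >= cc[i]
      strictly <- icu[j] > icu[i] || cc[j] > cc[i]
      if (better_eq && strictly) return(FALSE)
    }
    TRUE
  }, logical(1))
}

# small deterministic host gene set for reference distributions
make_toy_genes <- function(n_genes = 8L, mean_length = 40L, seed = 42L,
                           cc_mode = "markov") {
  spec <- synthetic_host_spec(n_genes = n_genes, mean_length = mean_length,
                              cc_mode = cc_mode, seed = seed)
  generate_gene_set(spec)$genes
}

# lightweight direct evaluations of the fitness formulas, fast enough for
# exhaustive scans over tens of thousands of candidate sequences
.codon_aa <- unname(gc_std$codon_to_aa[gc_std$codons])

fast_psi_icu <- function(codons, ref_freq) {
  cnt <- tabulate(match(codons, gc_std$codons), 64L)
  aacnt <- as.vector(rowsum(cnt, .codon_aa)[match(.codon_aa,
                                                  sort(unique(.codon_aa))), ])
  p1 <- ifelse(aacnt > 0, cnt / aacnt, 0)
  -sum(abs(ref_freq - p1)) / 64
}

fast_psi_cc <- function(codons, ref_freq, ref_total = sum(ref_freq)) {
  n <- length(codons)
  sup <- paste0(codons[-n], codons[-1L])
  aap <- paste0(gc_std$codon_to_aa[codons[-n]],
                gc_std$codon_to_aa[codons[-1L]])
  pair_tab <- table(sup)
  aap_tab <- table(aap)
  up <- names(pair_tab)
  up_aap <- paste0(gc_std$codon_to_aa[substr(up, 1, 3)],
                   gc_std$codon_to_aa[substr(up, 4, 6)])
  q1 <- as.numeric(pair_tab) / as.numeric(aap_tab[up_aap])
  q0 <- ref_freq[up]
  -(ref_total - sum(q0) + sum(abs(q0 - q1))) / 3904
}

brute_max_psi_icu_fast <- function(protein, ref) {
  max(vapply(enumerate_synonymous(protein), fast_psi_icu, numeric(1),
             ref_freq = ref$freq))
}

brute_max_psi_cc_fast <- function(protein, ref) {
  S0 <- sum(ref$freq)
  max(vapply(enumerate_synonymous(protein), fast_psi_cc, numeric(1),
             ref_freq = ref$freq, ref_total = S0))
}

random_protein <- function(n, stop_tail = FALSE) {
  aa <- setdiff(gc_std$amino_acids, "*")
  p <- sample(aa, n, replace = TRUE)
  if (stop_tail) c(p, "*") else p
}
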