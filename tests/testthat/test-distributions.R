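test_that("ICU distribution matches a hand count", {
  d <- icu_distribution(codon_seq(c("AUG", "AAA", "AAA", "AAG", "UGG")))
  expect_equal(unname(d$freq[c("AAA", "AAG", "AUG", "UGG")]),
               c(2 / 3, 1 / 3, 1, 1))
  # all codons of absent amino acids sit at zero
  expect_true(all(d$freq[!names(d$freq) %in%
                           c("AAA", "AAG", "AUG", "UGG")] == 0))
  expect_identical(unname(d$aa_counts[c("K", "M", "W")]), c(3L, 1L, 1L))
})

test_that("pooling genes equals counting their concatenation (ICU)", {
  g1 <- codon_seq(c("AAA", "AAG", "CUG"))
  g2 <- codon_seq(c("AAA", "CUA", "CUG"))
  pooled <- icu_distribution(list(g1, g2))
  concat <- icu_distribution(codon_seq(c(g1$codons, g2$codons)))
  expect_equal(pooled$freq, concat$freq)
  expect_equal(pooled$codon_counts, concat$codon_counts)
})

test_that("CC distribution counts the n - 1 overlapping pairs", {
  g <- codon_seq(c("AUG", "UGG", "AUG"))
  d <- cc_distribution(g)
  expect_equal(unname(d$freq[c("AUGUGG", "UGGAUG")]), c(1, 1))
  expect_equal(sum(d$codon_counts), length(g) - 1L)
  expect_true(all(d$freq[setdiff(names(d$freq),
                                 c("AUGUGG", "UGGAUG"))] == 0))
  expect_error(cc_distribution(codon_seq("AUG")), "fewer than 2")
})

test_that("conditional normalization holds for both kinds", {
  genes <- make_toy_genes(n_genes = 6L, mean_length = 50L, seed = 9L)
  icu <- icu_distribution(genes)
  for (aa in names(icu$aa_counts)[icu$aa_counts > 0L]) {
    expect_equal(sum(icu$freq[gc_std$aa_to_codons[[aa]]]), 1,
                 tolerance = 1e-12)
  }
  cc <- cc_distribution(genes)
  pair_aa <- paste0(
    gc_std$codon_to_aa[substr(names(cc$freq), 1, 3)],
    gc_std$codon_to_aa[substr(names(cc$freq), 4, 6)]
  )
  sums <- tapply(cc$freq, pair_aa, sum)
  present <- names(cc$aa_counts)[cc$aa_counts > 0L]
  expect_equal(as.vector(sums[present]), rep(1, length(present)),
               tolerance = 1e-12)
  # synonymous codon counts sum to the amino-acid count
  caa <- unname(gc_std$codon_to_aa[names(icu$codon_counts)])
  expect_equal(as.vector(tapply(icu$codon_counts, caa, sum)[names(icu$aa_counts)]),
               as.vector(icu$aa_counts), ignore_attr = TRUE)
})

test_that("fitness is zero at identity, symmetric, and matches hand values", {
  genes <- make_toy_genes(n_genes = 4L, mean_length = 30L, seed = 2L)
  icu <- icu_distribution(genes)
  cc <- cc_distribution(genes)
  expect_identical(icu_fitness(icu, icu), 0)
  expect_identical(cc_fitness(cc, cc), 0)

  # reference Lys usage 0.75/0.25 vs an all-AAA subject
  ref <- icu_distribution(codon_seq(c("AAA", "AAA", "AAA", "AAG")))
  subj <- icu_distribution(codon_seq(c("AAA", "AAA")))
  expect_equal(icu_fitness(ref, subj), -(0.25 + 0.25) / 64)
  expect_equal(icu_fitness(subj, ref), icu_fitness(ref, subj))

  # disjoint codon-pair support on one amino-acid pair contributes 2/3904
  r <- cc_distribution(codon_seq(c("AAA", "AAA")))
  s <- cc_distribution(codon_seq(c("AAG", "AAG")))
  expect_equal(cc_fitness(r, s), -2 / 3904)

  expect_error(icu_fitness(icu, cc), "ICU")
  expect_error(cc_fitness(cc, icu), "CC")
})

test_that("fitness respects its theoretical bounds on random sequences", {
  set.seed(21)
  genes <- make_toy_genes(n_genes = 5L, mean_length = 40L, seed = 8L)
  ricu <- icu_distribution(genes)
  rcc <- cc_distribution(genes)
  for (rep in 1:10) {
    prot <- random_protein(sample(2:40, 1), stop_tail = TRUE)
    cand <- rca_sequence(prot)
    f <- fitness_pair(cand, ricu, rcc)
    expect_gte(f$psi_icu, -2 * 21 / 64)
    expect_lte(f$psi_icu, 0)
    expect_gte(f$psi_cc, -2 * 420 / 3904)
    expect_lte(f$psi_cc, 0)
  }
})

test_that("the GA's dense evaluators agree with a raw re-count", {
  genes <- make_toy_genes(n_genes = 5L, mean_length = 35L, seed = 13L)
  ricu <- icu_distribution(genes)
  rcc <- cc_distribution(genes)
  set.seed(5)
  for (rep in 1:10) {
    prot <- random_protein(sample(3:30, 1), stop_tail = TRUE)
    cand <- rca_sequence(prot)
    ctx <- codonopt:::ga_context(prot, ricu, rcc)
    x <- codonopt:::codon_index(cand$codons)
    expect_equal(codonopt:::eval_icu(x, ctx),
                 psi_icu_recount(cand$codons, ricu))
    expect_equal(codonopt:::eval_cc(x, ctx),
                 psi_cc_recount(cand$codons, rcc))
  }
})

test_that("usage distributions survive a TSV round trip", {
  genes <- make_toy_genes(n_genes = 3L, mean_length = 25L, seed = 31L)
  for (build in list(icu_distribution, cc_distribution)) {
    d <- build(genes)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_usage_tsv(d, path)
    d2 <- read_usage_tsv(path)
    expect_identical(d2$kind, d$kind)
    expect_equal(d2$freq, d$freq)
    expect_equal(d2$codon_counts, d$codon_counts)
    expect_equal(d2$aa_counts, d$aa_counts)
  }
})
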