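test_that("domination rules follow the four-rule comparison", {
  expect_identical(dominates(c(-0.1, -0.2), c(-0.2, -0.2)), "first")
  expect_identical(dominates(c(-0.2, -0.2), c(-0.2, -0.1)), "second")
  expect_identical(dominates(c(-0.1, -0.3), c(-0.2, -0.2)), "neither")
  expect_identical(dominates(c(-0.1, -0.1), c(-0.1, -0.1)), "neither")
  f1 <- structure(list(psi_icu = -0.05, psi_cc = -0.01),
                  class = "fitness_pair")
  f2 <- structure(list(psi_icu = -0.06, psi_cc = -0.01),
                  class = "fitness_pair")
  expect_identical(dominates(f1, f2), "first")
})

test_that("domination-count rank 0 equals the brute-force Pareto set", {
  expect_identical(nondominated_rank(-0.1, -0.1), 0L)

  # totally ordered chain: ranks count the dominators above each point
  icu <- c(-0.1, -0.2, -0.3, -0.4)
  expect_identical(nondominated_rank(icu, icu), c(0L, 1L, 2L, 3L))

  expect_identical(nondominated_rank(rep(-0.2, 5), rep(-0.3, 5)),
                   rep(0L, 5))

  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    icu <- -round(runif(n, 0, 0.3), 2)  # rounding forces ties
    cc <- -round(runif(n, 0, 0.2), 2)
    rank <- nondominated_rank(icu, cc)
    expect_identical(rank == 0L, pareto_set_oracle(icu, cc))
  }
})

test_that("termination reacts to convergence, improvement and perfection", {
  cfg <- ga_config(termination_window = 100, termination_threshold = 0.005,
                   max_generations = 5000)
  flat <- rep(-0.5, 150)
  expect_true(check_termination(flat, cfg))
  # 1% improvement per window keeps the run alive
  improving <- -0.5 * 0.99^(0:149 / 100)
  expect_false(check_termination(improving, cfg))
  expect_true(check_termination(c(-0.5, -0.2, 0), cfg))  # perfect fitness
  expect_true(check_termination(rep(-0.5, 5000), ga_config()))  # cap
  expect_false(check_termination(numeric(0), cfg))
})

test_that("ga_step preserves the protein, the population size and elites", {
  genes <- make_toy_genes(n_genes = 5L, mean_length = 20L, seed = 37L)
  rcc <- cc_distribution(genes)
  prot <- random_protein(12, stop_tail = TRUE)
  set.seed(8)
  pop <- lapply(1:10, function(i) rca_sequence(prot))
  nxt <- ga_step(pop, reference_cc = rcc, objective_mode = "CC",
                 config = ga_config(population_size = 10))
  expect_length(nxt, 10)
  for (s in nxt) expect_identical(s$protein, unname(prot))
  # elitist selection: the best parent's fitness survives into the new pop
  best_old <- max(vapply(pop, function(s) psi_cc_recount(s$codons, rcc),
                         numeric(1)))
  best_new <- max(vapply(nxt, function(s) psi_cc_recount(s$codons, rcc),
                         numeric(1)))
  expect_gte(best_new, best_old)

  mixed <- c(pop[1:9], list(rca_sequence(random_protein(12, TRUE))))
  expect_error(ga_step(mixed, reference_cc = rcc), "same protein")
})

test_that("a zero-degeneracy protein collapses the GA to one sequence", {
  rcc <- cc_distribution(codon_seq(c("AUG", "UGG", "AUG", "UGG")))
  pop <- lapply(1:6, function(i) codon_seq(c("AUG", "UGG", "AUG", "UGG")))
  nxt <- ga_step(pop, reference_cc = rcc,
                 config = ga_config(population_size = 6))
  for (s in nxt) {
    expect_identical(s$codons, c("AUG", "UGG", "AUG", "UGG"))
  }
})

test_that("one-point crossover recombines at a codon boundary", {
  genes <- make_toy_genes(n_genes = 4L, mean_length = 15L, seed = 41L)
  ctx <- codonopt:::ga_context(c("K", "K"), reference_cc = cc_distribution(genes))
  parents <- cbind(codonopt:::codon_index(c("AAA", "AAA")),
                   codonopt:::codon_index(c("AAG", "AAG")))
  cfg <- ga_config(population_size = 4, mutation_per_offspring = 0)
  set.seed(2)
  kids <- codonopt:::make_offspring(parents, ctx, cfg, 2L)
  got <- apply(kids, 2, function(x) paste(gc_std$codons[x], collapse = "-"))
  expect_setequal(got, c("AAA-AAG", "AAG-AAA"))
})

test_that("best CC fitness is monotone under elitism and runs are reproducible", {
  genes <- make_toy_genes(n_genes = 5L, mean_length = 30L, seed = 43L)
  rcc <- cc_distribution(genes)
  prot <- random_protein(25, stop_tail = TRUE)
  cfg <- ga_config(population_size = 20, max_generations = 60, seed = 99)
  x1 <- solve_cco(prot, rcc, cfg)
  x2 <- solve_cco(prot, rcc, cfg)
  expect_identical(x1$codons, x2$codons)
  hist <- attr(x1, "history")$best_cc
  expect_true(all(diff(hist) >= 0))
  expect_identical(x1$protein, unname(prot))
})

test_that("CCO recovers a reference gene from its own distribution", {
  gene <- make_toy_genes(n_genes = 1L, mean_length = 25L, seed = 47L)[[1]]
  rcc <- cc_distribution(gene)
  x <- solve_cco(gene$protein, rcc,
                 ga_config(population_size = 60, seed = 7))
  expect_equal(attr(x, "psi_cc"), 0)
})

test_that("the GA finds the exhaustive CC optimum on small peptides", {
  genes <- make_toy_genes(n_genes = 6L, mean_length = 40L, seed = 53L)
  rcc <- cc_distribution(genes)
  set.seed(15)
  hits <- 0L
  for (rep in 1:5) {
    prot <- random_protein(4)
    best <- brute_max_psi_cc(prot, rcc)
    x <- solve_cco(prot, rcc, ga_config(population_size = 200, seed = rep))
    if (isTRUE(all.equal(attr(x, "psi_cc"), best, tolerance = 1e-12))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 4L)
})

test_that("MOCO returns a mutually nondominated front and a near-ideal pick", {
  # degenerate protein: front of exactly one sequence
  ricu <- icu_distribution(codon_seq(c("AUG", "UGG")))
  rcc <- cc_distribution(codon_seq(c("AUG", "UGG")))
  m <- solve_moco(c("M", "W"), ricu, rcc,
                  ga_config(population_size = 8, max_generations = 10,
                            seed = 3))
  expect_identical(nrow(m$front), 1L)
  expect_identical(m$solution$codons, c("AUG", "UGG"))

  genes <- make_toy_genes(n_genes = 6L, mean_length = 30L, seed = 59L)
  ricu <- icu_distribution(genes)
  rcc <- cc_distribution(genes)
  prot <- random_protein(4)
  cfg <- ga_config(population_size = 40, max_generations = 150, seed = 21)
  m <- solve_moco(prot, ricu, rcc, cfg)
  expect_true(all(pareto_set_oracle(m$front$psi_icu, m$front$psi_cc)))
  expect_true(all(m$front$psi_icu <= 0 & m$front$psi_icu >= -2 * 21 / 64))
  expect_true(all(m$front$psi_cc <= 0 & m$front$psi_cc >= -2 * 420 / 3904))
  # reported fitness of the picked solution matches a raw re-count
  expect_equal(attr(m$solution, "psi_icu"),
               psi_icu_recount(m$solution$codons, ricu))
  expect_equal(attr(m$solution, "psi_cc"),
               psi_cc_recount(m$solution$codons, rcc))
  # reproducibility
  m2 <- solve_moco(prot, ricu, rcc, cfg)
  expect_identical(m$solution$codons, m2$solution$codons)
})
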