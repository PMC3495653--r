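# Elitist genetic algorithm shared by the codon-context optimizer (CCO)
# and the multi-objective optimizer (MOCO).
#
# Individuals are codon sequences of the target protein, represented
# internally as integer codon indices. Crossover happens only at codon
# boundaries and mutation only substitutes synonymous codons, so every
# individual in every generation encodes the target protein by
# construction. Fitness evaluation runs on dense count vectors (64 codons,
# 4096 codon-pair codes), making a single evaluation O(sequence length +
# constant) with vectorized arithmetic.

#' Genetic-algorithm configuration
#'
#' @param population_size Even integer >= 4; the fittest half survives each
#'   generation as parents ("top 50%" elitism).
#' @param max_generations Safety cap on the number of generations.
#' @param termination_window Number of generations over which improvement
#'   is measured for convergence (default 100).
#' @param termination_threshold Relative improvement in best fitness over
#'   the window below which the run is considered converged (default 0.005,
#'   i.e. less than 0.5% improvement across the window).
#' @param mutation_per_offspring Number of synonymous point substitutions
#'   applied to each offspring (default 1).
#' @param crowding If `TRUE`, ties within a domination rank (multi-objective
#'   mode) are broken by NSGA-II crowding distance instead of a random
#'   shuffle. Off by default.
#' @param seed Optional integer seed applied at the start of a solve.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, max_generations = 5000L,
                      termination_window = 100L,
                      termination_threshold = 0.005,
                      mutation_per_offspring = 1L,
                      crowding = FALSE, seed = NULL) {
  population_size <- as.integer(population_size)
  if (population_size < 4L || population_size %% 2L != 0L) {
    stop("population_size must be an even integer >= 4")
  }
  if (termination_threshold <= 0 || termination_window < 1L) {
    stop("termination window and threshold must be positive")
  }
  structure(
    list(population_size = population_size,
         max_generations = as.integer(max_generations),
         termination_window = as.integer(termination_window),
         termination_threshold = termination_threshold,
         mutation_per_offspring = as.integer(mutation_per_offspring),
         crowding = isTRUE(crowding),
         seed = seed),
    class = "ga_config"
  )
}

#' Domination relation between two fitness pairs
#'
#' A solution dominates another when it is at least as good in both
#' objectives and strictly better in at least one (objectives are
#' maximized; both `psi` values are <= 0 with optimum 0). Equal pairs
#' dominate neither way.
#'
#' @param f1,f2 `fitness_pair` objects or numeric vectors
#'   `c(psi_icu, psi_cc)`.
#' @return `"first"`, `"second"` or `"neither"`.
#' @export
dominates <- function(f1, f2) {
  f1 <- as_psi(f1); f2 <- as_psi(f2)
  if ((f1[1L] > f2[1L] && f1[2L] >= f2[2L]) ||
      (f1[1L] >= f2[1L] && f1[2L] > f2[2L])) return("first")
  if ((f1[1L] < f2[1L] && f1[2L] <= f2[2L]) ||
      (f1[1L] <= f2[1L] && f1[2L] < f2[2L])) return("second")
  "neither"
}

as_psi <- function(f) {
  if (inherits(f, "fitness_pair")) c(f$psi_icu, f$psi_cc) else as.numeric(f)
}

#' Domination-count ranking of a population
#'
#' Ranks every member by the number of members that dominate it, so rank 0
#' is exactly the nondominated (Pareto-optimal) subset of the population.
#' Storing one count per member needs only O(n) memory, unlike bookkeeping
#' of full dominated sets.
#'
#' @param psi_icu,psi_cc Numeric vectors of the two objectives (maximized),
#'   or a two-column matrix/data.frame passed as `psi_icu`.
#' @return Integer vector of domination counts (0 = nondominated).
#' @export
nondominated_rank <- function(psi_icu, psi_cc = NULL) {
  if (is.null(psi_cc)) {
    m <- as.matrix(psi_icu)
    psi_icu <- m[, 1L]; psi_cc <- m[, 2L]
  }
  gt1 <- outer(psi_icu, psi_icu, ">")
  ge1 <- outer(psi_icu, psi_icu, ">=")
  gt2 <- outer(psi_cc, psi_cc, ">")
  ge2 <- outer(psi_cc, psi_cc, ">=")
  dom <- (gt1 & ge2) | (ge1 & gt2)   # dom[j, i]: j dominates i
  as.integer(colSums(dom))
}

#' Convergence test on a best-fitness history
#'
#' The run has converged when the relative improvement in best fitness over
#' the trailing window falls below the threshold,
#' `|f(r + W) - f(r)| / max(|f(r)|, eps) < threshold`, when a perfect
#' fitness of 0 is reached, or when `max_generations` is exhausted.
#'
#' @param history Numeric vector of best fitness per generation (values
#'   <= 0).
#' @param config A [ga_config()].
#' @return `TRUE` when the run should stop.
#' @export
check_termination <- function(history, config) {
  len <- length(history)
  if (len == 0L) return(FALSE)
  if (history[len] >= 0) return(TRUE)          # global optimum reached
  if (len >= config$max_generations) return(TRUE)
  w <- config$termination_window
  if (len <= w) return(FALSE)
  old <- history[len - w]
  rel <- abs(history[len] - old) / max(abs(old), 1e-12)
  rel < config$termination_threshold
}

# ---- internal engine -------------------------------------------------------

# Precomputed per-protein context for fast fitness evaluation.
ga_context <- function(protein, reference_icu = NULL, reference_cc = NULL,
                       code = default_code()) {
  n <- length(protein)
  aa_idx <- aa_index(protein, code)
  stop_i <- match(STOP_SYMBOL, code$amino_acids)
  if (any(aa_idx[-n] == stop_i)) {
    stop("internal stop codon in target protein; only a terminal '*' is allowed")
  }
  syn_by_aa <- lapply(code$aa_to_codons, codon_index, code = code)
  syn <- syn_by_aa[aa_idx]
  caa <- codon_aa_index(code)
  icu_denom <- tabulate(aa_idx, 21L)[caa]

  ctx <- list(n = n, aa_idx = aa_idx, syn = syn,
              mutable = which(lengths(syn) > 1L),
              icu_denom = icu_denom)
  if (!is.null(reference_icu)) {
    stopifnot(reference_icu$kind == "ICU")
    ctx$p0 <- unname(reference_icu$freq)
  }
  if (!is.null(reference_cc)) {
    stopifnot(reference_cc$kind == "CC")
    if (n < 2L) stop("codon-context optimization needs at least 2 codons")
    q0 <- numeric(4096)
    q0[valid_pair_codes(code)] <- unname(reference_cc$freq)
    aap <- (aa_idx[-n] - 1L) * 21L + aa_idx[-1L]
    aap_counts <- tabulate(aap, 441L)
    c1 <- rep(1:64, each = 64L); c2 <- rep.int(1:64, 64L)
    ctx$cc_denom <- aap_counts[(caa[c1] - 1L) * 21L + caa[c2]]
    ctx$q0 <- q0
  }
  ctx
}

eval_icu <- function(x, ctx) {
  cnt <- tabulate(x, 64L)
  p1 <- numeric(64)
  nz <- ctx$icu_denom > 0L
  p1[nz] <- cnt[nz] / ctx$icu_denom[nz]
  -sum(abs(ctx$p0 - p1)) / 64
}

eval_cc <- function(x, ctx) {
  cnt <- tabulate(pair_code(x), 4096L)
  q1 <- numeric(4096)
  nz <- ctx$cc_denom > 0L
  q1[nz] <- cnt[nz] / ctx$cc_denom[nz]
  -sum(abs(ctx$q0 - q1)) / 3904
}

random_individual <- function(ctx) {
  vapply(ctx$syn, function(s) if (length(s) == 1L) s else sample(s, 1L),
         integer(1))
}

mutate_individual <- function(x, ctx, times) {
  if (length(ctx$mutable) == 0L) return(x)
  for (k in seq_len(times)) {
    i <- ctx$mutable[sample.int(length(ctx$mutable), 1L)]
    s <- ctx$syn[[i]]
    alt <- s[s != x[i]]
    x[i] <- if (length(alt) == 1L) alt else alt[sample.int(length(alt), 1L)]
  }
  x
}

# One-point crossover of randomly paired parents followed by synonymous
# mutation; returns exactly n_off offspring columns.
make_offspring <- function(parents, ctx, config, n_off) {
  n <- ctx$n
  np <- ncol(parents)
  kids <- matrix(0L, nrow = n, ncol = n_off)
  made <- 0L
  if (np < 2L) {   # degenerate: clone the single parent
    for (j in seq_len(n_off)) {
      kids[, j] <- mutate_individual(parents[, 1L], ctx,
                                     config$mutation_per_offspring)
    }
    return(kids)
  }
  while (made < n_off) {
    ord <- sample.int(np)
    for (j in seq(1L, np - 1L, by = 2L)) {
      if (made >= n_off) break
      p1 <- parents[, ord[j]]; p2 <- parents[, ord[j + 1L]]
      if (n > 1L) {
        b <- sample.int(n - 1L, 1L)
        c1 <- c(p1[seq_len(b)], p2[seq.int(b + 1L, n)])
        c2 <- c(p2[seq_len(b)], p1[seq.int(b + 1L, n)])
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (made >= n_off) break
        made <- made + 1L
        kids[, made] <- mutate_individual(child, ctx,
                                          config$mutation_per_offspring)
      }
    }
  }
  kids
}

crowding_distance <- function(icu, cc) {
  n <- length(icu)
  d <- numeric(n)
  for (v in list(icu, cc)) {
    ord <- order(v)
    rng <- v[ord[n]] - v[ord[1L]]
    d[ord[c(1L, n)]] <- Inf
    if (n > 2L && rng > 0) {
      mid <- ord[2:(n - 1L)]
      d[mid] <- d[mid] + (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

select_parents <- function(pop, fit, mode, config) {
  P <- ncol(pop)
  half <- P %/% 2L
  if (mode == "cc") {
    ord <- order(fit$cc, decreasing = TRUE)
  } else {
    rank <- nondominated_rank(fit$icu, fit$cc)
    tie <- if (config$crowding) -crowding_distance(fit$icu, fit$cc)
           else stats::runif(P)
    ord <- order(rank, tie)
  }
  keep <- ord[seq_len(half)]
  list(pop = pop[, keep, drop = FALSE],
       icu = fit$icu[keep], cc = fit$cc[keep])
}

evaluate_population <- function(pop, ctx, mode) {
  cc <- if (!is.null(ctx$q0)) apply(pop, 2L, eval_cc, ctx = ctx) else NULL
  icu <- if (!is.null(ctx$p0)) apply(pop, 2L, eval_icu, ctx = ctx) else NULL
  list(icu = icu, cc = cc)
}

ga_engine <- function(protein, reference_icu = NULL, reference_cc = NULL,
                      mode = c("cc", "multi"), config = ga_config(),
                      code = default_code()) {
  mode <- match.arg(mode)
  if (!is.null(config$seed)) set.seed(config$seed)
  ctx <- ga_context(protein, reference_icu, reference_cc, code)
  P <- config$population_size
  pop <- vapply(seq_len(P), function(i) random_individual(ctx),
                integer(ctx$n))
  if (ctx$n == 1L) pop <- matrix(pop, nrow = 1L)
  fit <- evaluate_population(pop, ctx, mode)
  hist_cc <- numeric(0); hist_icu <- numeric(0); hist_mean <- numeric(0)
  repeat {
    if (mode == "cc") {
      hist_cc <- c(hist_cc, max(fit$cc))
      hist_mean <- c(hist_mean, mean(fit$cc))
      done <- check_termination(hist_cc, config)
    } else {
      hist_cc <- c(hist_cc, max(fit$cc))
      hist_icu <- c(hist_icu, max(fit$icu))
      hist_mean <- c(hist_mean, mean(fit$cc))
      done <- check_termination(hist_cc, config) &&
        check_termination(hist_icu, config)
      done <- done || length(hist_cc) >= config$max_generations
    }
    if (done) break
    sel <- select_parents(pop, fit, mode, config)
    kids <- make_offspring(sel$pop, ctx, config, P - ncol(sel$pop))
    kfit <- evaluate_population(kids, ctx, mode)
    pop <- cbind(sel$pop, kids)
    fit <- list(icu = c(sel$icu, kfit$icu), cc = c(sel$cc, kfit$cc))
  }
  list(pop = pop, fit = fit, ctx = ctx,
       history = list(best_cc = hist_cc, best_icu = hist_icu,
                      mean_cc = hist_mean))
}

codons_from_index <- function(x, code) code$codons[x]

# ---- public solvers --------------------------------------------------------

#' One generation of the codon-design genetic algorithm
#'
#' Applies a single selection / crossover / mutation cycle to a population
#' of synonymous codon sequences: the fittest half survives as parents (by
#' CC fitness in `"CC"` mode, by domination rank in `"multi"` mode), and
#' offspring are produced by one-point crossover at a random codon boundary
#' followed by synonymous point mutation. Uses the current RNG stream.
#'
#' @param population List of [codon_seq()] objects, all encoding the same
#'   protein.
#' @param reference_icu,reference_cc Host reference distributions
#'   (`reference_icu` only needed in `"multi"` mode).
#' @param objective_mode `"CC"` or `"multi"`.
#' @param config A [ga_config()].
#' @param code A [genetic_code()] object.
#' @return List of [codon_seq()] of the same size: parents followed by
#'   offspring.
#' @export
ga_step <- function(population, reference_icu = NULL, reference_cc,
                    objective_mode = c("CC", "multi"),
                    config = ga_config(), code = default_code()) {
  objective_mode <- match.arg(objective_mode)
  mode <- if (objective_mode == "CC") "cc" else "multi"
  stopifnot(is.list(population), length(population) >= 2L)
  prots <- vapply(population, function(s) paste(s$protein, collapse = ""),
                  character(1))
  if (length(unique(prots)) != 1L) {
    stop("all population members must encode the same protein")
  }
  protein <- population[[1L]]$protein
  ctx <- ga_context(protein,
                    if (mode == "multi") reference_icu else NULL,
                    reference_cc, code)
  pop <- vapply(population, function(s) codon_index(s$codons, code),
                integer(ctx$n))
  if (ctx$n == 1L) pop <- matrix(pop, nrow = 1L)
  fit <- evaluate_population(pop, ctx, mode)
  sel <- select_parents(pop, fit, mode, config)
  kids <- make_offspring(sel$pop, ctx, config, ncol(pop) - ncol(sel$pop))
  out <- cbind(sel$pop, kids)
  lapply(seq_len(ncol(out)), function(j) {
    codon_seq(codons_from_index(out[, j], code), code = code)
  })
}

#' Codon-context optimization (CCO) by genetic algorithm
#'
#' Evolves a population of synonymous coding sequences toward the host's
#' reference codon-pair usage: elitist top-50% selection on CC fitness,
#' one-point crossover at codon boundaries, synonymous point mutation, and
#' convergence when best fitness improves by less than the configured
#' fraction across the termination window.
#'
#' @param protein Target amino-acid sequence (string or character vector; a
#'   terminal `*` designs the stop codon too).
#' @param reference_cc Host `usage_dist` of kind `"CC"`.
#' @param config A [ga_config()]; set `config$seed` for reproducibility.
#' @param id Identifier for the returned sequence.
#' @param code A [genetic_code()] object.
#' @return A [codon_seq()] (the best member at termination) with attributes
#'   `psi_cc` (its CC fitness), `generations`, and `history` (best and mean
#'   CC fitness per generation).
#' @export
solve_cco <- function(protein, reference_cc, config = ga_config(),
                      id = "x_CCO", code = default_code()) {
  protein <- validate_protein(protein, code)
  res <- ga_engine(protein, reference_cc = reference_cc, mode = "cc",
                   config = config, code = code)
  best <- which.max(res$fit$cc)
  out <- codon_seq(codons_from_index(res$pop[, best], code), id = id,
                   code = code)
  attr(out, "psi_cc") <- res$fit$cc[best]
  attr(out, "generations") <- length(res$history$best_cc)
  attr(out, "history") <- data.frame(
    generation = seq_along(res$history$best_cc),
    best_cc = res$history$best_cc,
    mean_cc = res$history$mean_cc
  )
  out
}

#' Multi-objective codon optimization (MOCO)
#'
#' Nondominated-sorting genetic algorithm over the two objectives
#' (ICU fitness, CC fitness): members are ranked by domination count
#' (rank 0 = Pareto set), the best-ranked half survives, and the run stops
#' when the best value of *both* objectives has converged. From the final
#' rank-0 front, the reported solution is the member closest (Euclidean
#' distance) to the ideal point -- the pair of per-objective best values --
#' after min-max normalization of each objective across the front.
#'
#' @inheritParams solve_cco
#' @param reference_icu Host `usage_dist` of kind `"ICU"`.
#' @param normalize If `TRUE` (default) the ideal-point distance is taken
#'   on min-max normalized objectives; `FALSE` uses the raw psi scale.
#' @return A list of class `moco_result`: `solution` (a [codon_seq()],
#'   `x_MOCO`), `front` (data.frame of the final nondominated set:
#'   sequence, psi_icu, psi_cc), `generations`, `history`.
#' @export
solve_moco <- function(protein, reference_icu, reference_cc,
                       config = ga_config(), normalize = TRUE,
                       id = "x_MOCO", code = default_code()) {
  protein <- validate_protein(protein, code)
  res <- ga_engine(protein, reference_icu = reference_icu,
                   reference_cc = reference_cc, mode = "multi",
                   config = config, code = code)
  rank <- nondominated_rank(res$fit$icu, res$fit$cc)
  idx <- which(rank == 0L)
  # distinct sequences only: clones are frequent once the front stabilizes
  idx <- idx[!duplicated(apply(res$pop[, idx, drop = FALSE], 2L, paste,
                               collapse = ","))]
  icu <- res$fit$icu[idx]; cc <- res$fit$cc[idx]
  sel <- ideal_point_pick(icu, cc, normalize)
  seqs <- vapply(idx, function(j) {
    paste(codons_from_index(res$pop[, j], code), collapse = "")
  }, character(1))
  solution <- codon_seq(codons_from_index(res$pop[, idx[sel]], code),
                        id = id, code = code)
  attr(solution, "psi_icu") <- icu[sel]
  attr(solution, "psi_cc") <- cc[sel]
  structure(
    list(solution = solution,
         front = data.frame(sequence = seqs, psi_icu = icu, psi_cc = cc,
                            stringsAsFactors = FALSE),
         generations = length(res$history$best_cc),
         history = data.frame(
           generation = seq_along(res$history$best_cc),
           best_icu = res$history$best_icu,
           best_cc = res$history$best_cc)),
    class = "moco_result"
  )
}

ideal_point_pick <- function(icu, cc, normalize = TRUE) {
  if (length(icu) == 1L) return(1L)
  if (normalize) {
    icu <- minmax_scale(icu); cc <- minmax_scale(cc)
    ideal <- c(1, 1)
  } else {
    ideal <- c(max(icu), max(cc))
  }
  which.min((ideal[1L] - icu)^2 + (ideal[2L] - cc)^2)
}

minmax_scale <- function(v) {
  rng <- max(v) - min(v)
  if (rng == 0) rep(1, length(v)) else (v - min(v)) / rng
}

#' @export
print.moco_result <- function(x, ...) {
  cat(sprintf(
    "<moco_result> front of %d solution(s), %d generations; x_MOCO: psi_ICU = %.5g, psi_CC = %.5g\n",
    nrow(x$front), x$generations,
    attr(x$solution, "psi_icu"), attr(x$solution, "psi_cc")))
  invisible(x)
}
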