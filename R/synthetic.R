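# Synthetic host generator: gene sets with controllable individual-codon
# bias and first-order codon-pair (codon-context) structure, plus a padded
# expression table, so every pipeline in the package can be exercised
# end-to-end without external genome or microarray data.
#
# The codon-context model is a first-order Markov chain over codons,
# conditioned on the amino-acid sequence: the codon at position i + 1 is
# drawn from a transition kernel T(next codon | previous codon, next amino
# acid). This is the minimal generative process whose stationary pair
# statistics the CC distribution estimates. The advertised ICU target is
# the stationary per-amino-acid codon marginal of that chain, and the CC
# target is stationary-marginal times kernel, so both are exactly
# recoverable by the estimators as the gene set grows.

# average amino-acid composition of well-annotated proteomes, used as the
# default protein composition
.default_aa_freq <- c(
  A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
  I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
  R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
)

#' Specification of a synthetic host gene set
#'
#' @param n_genes Number of high-expression genes to generate.
#' @param mean_length Mean protein length in residues (a terminal stop
#'   codon is appended on top).
#' @param icu_concentration Dirichlet concentration of the per-amino-acid
#'   synonymous codon preferences; small values give strongly biased codon
#'   usage, large values approach uniform usage.
#' @param cc_mode `"markov"` draws each codon conditional on the previous
#'   codon (first-order codon-pair structure); `"independent"` draws codons
#'   independently from the ICU target, the null model under which codon
#'   context carries no information beyond individual usage.
#' @param cc_concentration Dirichlet concentration of the codon-pair
#'   transition preferences (markov mode); small values give strong
#'   context structure.
#' @param aa_frequencies Named probability vector over the 20 amino acids
#'   for protein composition; defaults to an average proteome composition.
#' @param seed Integer seed; the whole host (targets and gene set) is a
#'   deterministic function of the spec.
#' @return A `synthetic_host_spec` list.
#' @export
synthetic_host_spec <- function(n_genes = 30L, mean_length = 300L,
                                icu_concentration = 0.5,
                                cc_mode = c("markov", "independent"),
                                cc_concentration = 0.2,
                                aa_frequencies = NULL, seed = 1L) {
  cc_mode <- match.arg(cc_mode)
  if (is.null(aa_frequencies)) aa_frequencies <- .default_aa_freq
  if (is.null(names(aa_frequencies)) || length(aa_frequencies) != 20L ||
      any(aa_frequencies < 0) || sum(aa_frequencies) <= 0) {
    stop("aa_frequencies must be a named nonnegative 20-vector")
  }
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  if (n_genes < 1L || mean_length < 2L) {
    stop("need n_genes >= 1 and mean_length >= 2")
  }
  if (icu_concentration <= 0 || cc_concentration <= 0) {
    stop("concentrations must be positive")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         mean_length = as.integer(mean_length),
         icu_concentration = icu_concentration,
         cc_mode = cc_mode,
         cc_concentration = cc_concentration,
         aa_frequencies = aa_frequencies,
         seed = as.integer(seed)),
    class = "synthetic_host_spec"
  )
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) {
    # numerical underflow at tiny concentration: the Dirichlet limit is a
    # point mass on a vertex drawn proportionally to alpha
    x[sample.int(length(alpha), 1L, prob = alpha)] <- 1
  }
  x / sum(x)
}

#' Sample a synthetic host's codon-preference targets
#'
#' Draws the host's synonymous codon preferences and (in markov mode) the
#' codon-pair transition kernel, then derives the implied stationary ICU
#' target and the CC target over the 3904 codon pairs. Seeded by the spec,
#' so identical specs give identical hosts.
#'
#' @param spec A [synthetic_host_spec()].
#' @param code A [genetic_code()] object.
#' @return A `synthetic_host` list: `icu` (named frequency vector, 64
#'   codons, conditional per amino acid), `cc` (named frequency vector,
#'   3904 codon pairs, conditional per amino-acid pair), `transition`
#'   (64 x 64 kernel, rows = previous codon, columns normalized within
#'   each next amino acid's synonymous block), and `spec`.
#' @export
sample_host <- function(spec, code = default_code()) {
  stopifnot(inherits(spec, "synthetic_host_spec"))
  set.seed(spec$seed)
  sample_host_impl(spec, code)
}

sample_host_impl <- function(spec, code) {
  syn <- code$aa_to_codons
  # base synonymous preferences, one simplex per amino-acid symbol
  base <- numeric(64); names(base) <- code$codons
  for (aa in code$amino_acids) {
    base[syn[[aa]]] <- rdirichlet1(rep(spec$icu_concentration,
                                       length(syn[[aa]])))
  }
  Tm <- matrix(0, 64L, 64L, dimnames = list(code$codons, code$codons))
  if (spec$cc_mode == "independent") {
    Tm[] <- rep(base, each = 64L)
    icu <- base
  } else {
    # Transition rows are Dirichlet draws centered on the host's synonymous
    # preferences: the codon marginal keeps its individual-usage bias (as in
    # real hosts, where both biases coexist) while each previous-codon
    # context perturbs the preferences with strength 1 / cc_concentration.
    for (c1 in code$codons) {
      for (aa in code$amino_acids) {
        s <- syn[[aa]]
        Tm[c1, s] <- rdirichlet1(spec$cc_concentration * length(s) * base[s])
      }
    }
    icu <- stationary_marginal(base, Tm, spec$aa_frequencies, code)
  }
  cc <- pair_target(icu, Tm, code)
  structure(list(icu = icu, cc = cc, transition = Tm, spec = spec),
            class = "synthetic_host")
}

# Fixed point of mu(c2 | a2) = sum_{a1, c1} pi(a1) mu(c1 | a1) T(c2 | c1, a2),
# the per-amino-acid codon marginal of the stationary chain (amino acids
# are drawn i.i.d., so the mixture over the previous position is the same
# for every a2).
stationary_marginal <- function(base, Tm, aa_freq, code) {
  syn <- code$aa_to_codons
  sense_aa <- setdiff(code$amino_acids, STOP_SYMBOL)
  pi_c <- function(mu) {      # weight of each previous codon
    w <- numeric(64)
    for (aa in sense_aa) {
      w[match(syn[[aa]], code$codons)] <-
        aa_freq[[aa]] * mu[syn[[aa]]]
    }
    w
  }
  mu <- base
  for (iter in 1:200) {
    nxt <- as.vector(pi_c(mu) %*% Tm)   # already normalized per aa block
    names(nxt) <- code$codons
    if (sum(abs(nxt - mu)) < 1e-13) { mu <- nxt; break }
    mu <- nxt
  }
  mu
}

# q(c1 c2 | a1 a2) = mu(c1 | a1) * T(c2 | c1, a2), over the 3904 pairs
pair_target <- function(icu, Tm, code) {
  c1 <- substr(code$codon_pairs, 1L, 3L)
  c2 <- substr(code$codon_pairs, 4L, 6L)
  q <- icu[c1] * Tm[cbind(c1, c2)]
  names(q) <- code$codon_pairs
  q
}

#' @export
print.synthetic_host <- function(x, ...) {
  cat(sprintf("<synthetic_host> mode = %s, icu conc = %g, cc conc = %g\n",
              x$spec$cc_mode, x$spec$icu_concentration,
              x$spec$cc_concentration))
  invisible(x)
}

#' Generate a synthetic high-expression gene set
#'
#' Draws proteins i.i.d. from the spec's amino-acid composition with
#' negative-binomially dispersed lengths around `mean_length` (plus a
#' terminal stop), then back-translates each protein from the host's
#' codon model: the first codon from the ICU target, each following codon
#' from the transition kernel given the previous codon. An expression
#' table is returned in which the generated genes are padded with enough
#' low-expression decoy entries that they constitute exactly the top 5%.
#'
#' @param spec A [synthetic_host_spec()].
#' @param host Optional `synthetic_host` from [sample_host()]; sampled
#'   from `spec` when omitted.
#' @param code A [genetic_code()] object.
#' @return A `synthetic_gene_set` list: `genes` (list of [codon_seq()]),
#'   `expression` (data.frame `gene_id`, `expression` including decoys),
#'   `host`, `spec`.
#' @export
generate_gene_set <- function(spec, host = NULL, code = default_code()) {
  stopifnot(inherits(spec, "synthetic_host_spec"))
  if (is.null(host)) {
    host <- sample_host(spec, code)   # seeds the stream; generation continues it
  } else {
    set.seed(spec$seed + 1000003L)
  }
  syn <- code$aa_to_codons
  sense_aa <- setdiff(code$amino_acids, STOP_SYMBOL)
  genes <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    len <- max(2L, stats::rnbinom(1L, size = 20, mu = spec$mean_length))
    protein <- c(sample(names(spec$aa_frequencies), len, replace = TRUE,
                        prob = spec$aa_frequencies), STOP_SYMBOL)
    codons <- character(len + 1L)
    s1 <- syn[[protein[1L]]]
    codons[1L] <- draw1(s1, host$icu[s1])
    for (i in seq.int(2L, len + 1L)) {
      s <- syn[[protein[i]]]
      codons[i] <- draw1(s, host$transition[codons[i - 1L], s])
    }
    genes[[g]] <- codon_seq(codons, id = sprintf("synth_gene_%03d", g),
                            code = code)
  }
  n_decoy <- as.integer(ceiling(spec$n_genes / 0.05) - spec$n_genes)
  expression <- data.frame(
    gene_id = c(vapply(genes, `[[`, character(1), "id"),
                sprintf("decoy_gene_%04d", seq_len(n_decoy))),
    expression = c(stats::runif(spec$n_genes, 1e3, 1e4),
                   stats::runif(n_decoy, 1, 100)),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, expression = expression, host = host,
                 spec = spec),
            class = "synthetic_gene_set")
}

draw1 <- function(choices, weights) {
  if (length(choices) == 1L) return(choices)
  if (sum(weights) <= 0) weights <- rep(1, length(choices))
  choices[sample.int(length(choices), 1L, prob = weights)]
}

#' @export
print.synthetic_gene_set <- function(x, ...) {
  cat(sprintf("<synthetic_gene_set> %d genes (mode %s), %d expression rows\n",
              length(x$genes), x$spec$cc_mode, nrow(x$expression)))
  invisible(x)
}
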