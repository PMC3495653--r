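---
title: "Designing coding sequences by individual codon usage and codon context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing coding sequences by individual codon usage and codon context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
```

## The design problem

A protein of `n` residues can be encoded by any of `prod(degeneracy)`
coding sequences — for an average 300-residue protein on the order of
10^100 (`count_coding_sequences_log10()`). Heterologous expression hosts do
not use synonymous codons interchangeably: highly expressed genes show
strong *individual codon usage* (ICU) bias and, independently, strong
*codon context* (CC) bias, i.e. preferences over which codons sit next to
each other, usually attributed to tRNA–tRNA interactions in the ribosome.
`codonopt` designs coding sequences whose ICU and/or CC statistics match
those of a host's high-expression genes, and provides the statistical and
cross-validation machinery to compare the resulting design strategies.

## Usage distributions and fitness

Both usage summaries are *conditional* frequency vectors.

* ICU: for codon $k$ encoding amino acid $j$,
  $p^k = \theta_C^k / \theta_A^j$, over all 64 codons
  (`icu_distribution()`). Amino acids never observed get frequency 0 for
  all their codons.
* CC: for the 3904 ordered codon pairs whose first codon is a sense codon,
  $q^k = \theta_{CC}^k / \theta_{AA}^j$ conditional on the amino-acid pair
  (`cc_distribution()`). A gene of $n$ codons contributes its $n-1$
  overlapping adjacent pairs.

The fitness of a candidate sequence against a host reference is the
negative mean absolute difference of the two vectors,

$$\Psi_\mathrm{ICU} = -\tfrac{1}{64}\sum_{k=1}^{64}\lvert p_0^k - p_1^k\rvert,
\qquad
\Psi_\mathrm{CC} = -\tfrac{1}{3904}\sum_{k=1}^{3904}\lvert q_0^k - q_1^k\rvert,$$

maximal at 0 exactly when subject and reference coincide
(`icu_fitness()`, `cc_fitness()`, `fitness_pair()`). When an amino acid
(pair) is absent from one side, its frequencies are defined as 0 and the
block contributes a term that is constant in the design variables, so
optimizer rankings are unaffected; this makes both sums total functions.
The attainable ranges are $[-2\cdot21/64, 0]$ and $[-2\cdot420/3904, 0]$.

## The three optimizers

**ICO** (`solve_ico()`) is non-iterative. Because $\Psi_\mathrm{ICU}$
depends only on realized codon counts, the optimum is found by computing
each codon's target count — reference frequency × the protein's count of
the encoded amino acid — rounding within each amino acid, and placing the
resulting multiset randomly along the sequence. Rounding uses
largest-remainder (Hamilton) apportionment, which preserves every
per-amino-acid total and minimizes the L1 deviation from the real-valued
target, so the design attains the global integer-count optimum; ties among
equal remainders are broken by a seeded random draw. Placement is a uniform
random permutation of each amino acid's codon multiset, so every admissible
arrangement (all with identical fitness) is equally likely.

**CCO** (`solve_cco()`) cannot use that shortcut: adjacent pairs overlap,
so codon choices interact. It runs an elitist genetic algorithm over codon
sequences of the target protein: the fittest half of the population
survives each generation, offspring arise from one-point crossover at a
random codon boundary of randomly paired parents, and each offspring
receives a fixed number of synonymous point substitutions (default 1).
Because crossover respects codon boundaries and mutation consults the
synonymous-codon table, every individual in every generation encodes the
target protein by construction.

**MOCO** (`solve_moco()`) maximizes both objectives with nondominated
sorting. A member's rank is the *number of members dominating it* — O(n)
storage instead of keeping dominated sets — and rank 0 is provably the
Pareto set of the population. Domination follows the strict/weak
two-objective rules; equal fitness pairs dominate neither way. From the
final rank-0 front the reported solution `x_MOCO` is the member nearest
(Euclidean) to the ideal point, after min–max normalization of each
objective across the front (`normalize = FALSE` uses the raw $\Psi$ scale;
the default domination-count ranking omits NSGA-II crowding distance,
which can be enabled with `ga_config(crowding = TRUE)` as an extension).

### Tunable parameters

`ga_config()` collects the knobs that matter:

* `population_size` (default 100, even): elitism keeps the top 50%.
* `termination_window` = 100 generations and `termination_threshold` =
  0.005: the run stops when best fitness improves by less than 0.5%
  (relative) across the window. The criterion is evaluated on
  $|\Psi^{(r+W)} - \Psi^{(r)}| / \max(|\Psi^{(r)}|, 10^{-12})$; a ratio of
  raw negative fitness values would be ill-behaved, and a perfect fitness
  of 0 terminates immediately. MOCO stops only when *both* objectives'
  best values satisfy the criterion.
* `max_generations` (default 5000) is a safety cap.
* `mutation_per_offspring` (default 1) synonymous substitutions; positions
  with degeneracy 1 are re-drawn a bounded number of times, then accepted
  as a no-op.
* `seed`: identical config + seed gives bit-identical runs.

Population size and mutation count are design choices of this package;
defaults were fixed once from small-instance convergence behavior.

## Bias testing

`codon_bias_test()` applies Pearson's chi-squared test per amino acid (21
units) or per amino-acid pair (420 units). Two nulls are available: the
*uniform* null (synonymous usage is unbiased; expected count $N_j/n_j$)
and, when an all-genes set is supplied, the *vs-all* null (high-expression
usage equals genome-wide usage; expected counts are the all-genes counts
rescaled by $N_j^H/N_j^A$). In both cases the statistic is referred to
$\chi^2$ with $n_j - 1$ degrees of freedom — the single constraint is that
counts sum to the amino-acid total, and the same constraint applies under
both nulls. Units with one synonymous codon (Met, Trp, and the four pairs
composed of them) are *singular* and carry no statistic; any expected cell
below 5 marks the unit *unevaluated*, the standard adequacy rule. The raw
0.05 cutoff is applied per unit, mirroring common practice in codon-bias
surveys; `correction = "bonferroni"` (or any `p.adjust` method) is
available but off by default.

## Cross-validation

`loocv()` holds out each gene of a high-expression set in turn, rebuilds
the reference distributions from the remainder, designs the held-out
protein with each method (ICO, CCO, MOCO, and the uniform random-codon
control RCA), and scores the design by `percent_match()` — the percentage
$P_M$ of codon positions agreeing with the native sequence, stop codon
included by default. `tournament()` turns the per-gene $P_M$ table into a
matrix of pairwise strict wins; wins + losses + draws equal the gene count
for every pair. When a training fold lacks an amino acid present in the
held-out protein, ICO automatically falls back to uniform synonymous
frequencies for that amino acid (with a message), so folds cannot fail on
rare residues.

## The synthetic host

`synthetic_host_spec()` / `sample_host()` / `generate_gene_set()` emulate
a host's high-expression gene set so that every stage is testable without
genome downloads.

The generative model is a first-order Markov chain over codons conditioned
on the amino-acid sequence — the minimal process whose stationary pair
statistics the CC distribution estimates. Per amino acid, synonymous
preferences are Dirichlet draws with concentration `icu_concentration`
(small = strongly biased; the limits recover uniform usage and
one-amino-acid-one-codon usage). In `markov` mode each transition row
$T(\cdot \mid \text{prev codon}, \text{next aa})$ is a Dirichlet draw
*centered on those preferences* with total mass
`cc_concentration × degeneracy`: the stationary codon marginal keeps its
individual-usage bias — as in real hosts, where both biases coexist —
while small `cc_concentration` makes the context structure strong. The
advertised ICU target is the chain's stationary per-amino-acid marginal
(computed by fixed-point iteration), and the CC target is marginal ×
kernel, so both targets are exactly what the estimators converge to as the
gene set grows. In `independent` mode codons are drawn i.i.d. from the ICU
target, the null under which codon-pair usage factorizes into the ICU
product and context optimization has no extra information to exploit.

Protein lengths are negative-binomially dispersed (size 20) around
`mean_length` — geometric lengths would put many 2-codon genes next to
1000-codon ones — a terminal stop codon is appended, and amino-acid
composition defaults to an average proteome composition. The expression
table pads the generated genes with 19× as many low-expression decoy
entries, so the generated genes are exactly the top 5% that
`select_extreme_genes()` recovers.

What the generator does *not* emulate: microarray noise, GC-content
gradients, length–expression correlations, horizontally transferred genes,
or organism-specific tRNA pools. Passing tests therefore demonstrate that
the estimators and optimizers behave correctly under a controlled model of
codon bias, not that any particular organism's Table-style counts are
reproduced — those require the organism's transcriptome and genome data.

## Worked comparison

```{r headline, eval = FALSE}
spec <- synthetic_host_spec()        # 30 genes, ~300 codons, markov context
genes <- generate_gene_set(spec)$genes
report <- loocv(genes, methods = c("ico", "cco", "moco", "rca"),
                config = ga_config(population_size = 100,
                                   max_generations = 2000),
                seed = 1)
report
```

On such context-structured hosts the mean $P_M$ ordering is
CCO > ICO > RCA, and each optimized method beats the RCA control on
essentially every gene — the qualitative signature that codon context
carries design information beyond individual codon usage. On
`independent`-mode hosts the CCO–ICO gap shrinks toward zero, which is the
built-in negative control for that claim. The default scale (30 genes,
mean length 300, population 100) was chosen so a full four-method
cross-validation completes in minutes on a single core; the same seed
always reproduces the same report.

## Numerical and degenerate-input choices

* Frequencies of absent units are 0 (see above); conditional
  normalization of present units is exact to 1e-12 and tested.
* Largest-remainder rounding adds 1e-9 before flooring to absorb
  floating-point quota error.
* Internal stop codons are rejected in optimization targets (only a
  terminal `*` is designed); FASTA records with internal stops warn by
  default.
* Proteins made entirely of Met/Trp have a design space of one sequence;
  crossover and mutation degenerate to no-ops and all optimizers return
  the unique solution.
* The stationary-marginal fixed point iterates to an L1 tolerance of
  1e-13 (at most 200 iterations; convergence is geometric).
* Expression ties are broken lexicographically by gene id so top/bottom
  selections are deterministic.

## Known limitations

* The GA is heuristic: on long proteins CCO converges to near-optimal, not
  certified-optimal, codon-pair fitness (small instances are verified
  exhaustively in the test suite).
* $P_M$ measures similarity to native high-expression genes, a proxy for
  expressivity; the package makes no in-vivo expression predictions.
* Restriction sites, mRNA secondary structure, repeats and
  oligonucleotide assembly constraints are out of scope; outputs should be
  post-processed by standard gene-synthesis tools where those matter.
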