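# Leave-one-out cross-validation of the design methods against a
# high-expression gene set. Each gene is held out in turn, the reference
# ICU/CC distributions are rebuilt from the remaining genes, every method
# re-designs the held-out protein, and the design is scored by the
# percentage of codon positions matching the native sequence (P_M).

#' Percent codon match between a designed and a native sequence
#'
#' @param native,designed [codon_seq()] objects of equal length encoding
#'   the same protein.
#' @param include_stop If `FALSE`, a terminal stop codon position is
#'   excluded from the comparison.
#' @return Percentage in `[0, 100]` of codon positions that agree.
#' @examples
#' a <- codon_seq(c("AAA", "AAG", "UGG"))
#' b <- codon_seq(c("AAA", "AAA", "UGG"))
#' percent_match(a, b)   # 66.67
#' @export
percent_match <- function(native, designed, include_stop = TRUE) {
  stopifnot(inherits(native, "codon_seq"), inherits(designed, "codon_seq"))
  if (length(native) != length(designed)) {
    stop("sequences differ in length: ", length(native), " vs ",
         length(designed))
  }
  if (!identical(native$protein, designed$protein)) {
    stop("sequences do not encode the same protein")
  }
  keep <- seq_along(native$codons)
  if (!include_stop && native$protein[length(native)] == STOP_SYMBOL) {
    keep <- keep[-length(keep)]
  }
  100 * mean(native$codons[keep] == designed$codons[keep])
}

#' Leave-one-out cross-validation of codon design methods
#'
#' For each gene in the set, builds reference ICU and CC distributions from
#' the remaining genes, designs a sequence for the held-out gene's protein
#' with each requested method, and records the percent codon match (P_M)
#' against the native sequence. If a training fold lacks an amino acid
#' present in the held-out protein, ICO falls back to uniform synonymous
#' frequencies for that amino acid (with a message).
#'
#' @param genes List of [codon_seq()] (>= 3 genes); genes shorter than 2
#'   codons are skipped with a warning.
#' @param methods Subset of `c("ico", "cco", "moco", "rca")`.
#' @param config A [ga_config()] for the GA-based methods; its `seed` field
#'   is ignored in favor of `seed`.
#' @param seed Integer seed driving every stochastic step (fold-level seeds
#'   are drawn from it).
#' @param include_stop Passed to [percent_match()].
#' @param code A [genetic_code()] object.
#' @return A `crossval_report`: list with `per_gene` (data.frame gene x
#'   method of P_M values), `tournament` (win-count matrix), `mean_pm`
#'   (named vector), and `designs` (per gene, the designed `codon_seq`s).
#' @export
loocv <- function(genes, methods = c("ico", "cco", "moco", "rca"),
                  config = ga_config(), seed = 1L, include_stop = TRUE,
                  code = default_code()) {
  genes <- as_gene_list(genes)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(genes) < 3L) stop("leave-one-out needs at least 3 genes")
  ids <- vapply(seq_along(genes), function(i) {
    if (is.null(genes[[i]]$id)) paste0("gene", i) else genes[[i]]$id
  }, character(1))
  ok <- lengths(lapply(genes, `[[`, "codons")) >= 2L
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " gene(s) shorter than 2 codons: ",
            paste(ids[!ok], collapse = ", "))
    genes <- genes[ok]; ids <- ids[ok]
  }
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(genes))
  pm <- matrix(NA_real_, nrow = length(genes), ncol = length(methods),
               dimnames = list(ids, methods))
  designs <- vector("list", length(genes)); names(designs) <- ids
  for (i in seq_along(genes)) {
    native <- genes[[i]]
    train <- genes[-i]
    protein <- native$protein
    ref_icu <- icu_distribution(train, code)
    ref_cc <- cc_distribution(train, code)
    fallback <- any(ref_icu$aa_counts[unique(protein)] == 0L)
    if (fallback) {
      message("fold ", ids[i],
              ": training set lacks some amino acid(s); ",
              "using uniform fallback for ICO")
    }
    fold <- list()
    for (m in methods) {
      sd_m <- (fold_seeds[i] + match(m, c("ico", "cco", "moco", "rca"))) %%
        .Machine$integer.max
      cfg <- config; cfg$seed <- sd_m
      d <- switch(
        m,
        ico = solve_ico(protein, ref_icu, seed = sd_m,
                        uniform_fallback = fallback, code = code),
        cco = solve_cco(protein, ref_cc, config = cfg, code = code),
        moco = solve_moco(protein, ref_icu, ref_cc, config = cfg,
                          code = code)$solution,
        rca = rca_sequence(protein, seed = sd_m, code = code)
      )
      pm[i, m] <- percent_match(native, d, include_stop)
      fold[[m]] <- d
    }
    designs[[i]] <- fold
  }
  per_gene <- data.frame(gene = ids, pm, row.names = NULL,
                         check.names = FALSE)
  report <- structure(
    list(per_gene = per_gene, methods = methods, designs = designs),
    class = "crossval_report"
  )
  report$tournament <- tournament(report)
  report$mean_pm <- colMeans(pm)
  report
}

#' Tournament matrix of pairwise method wins
#'
#' Cell (row, column) counts the genes on which the row method achieved a
#' strictly greater P_M than the column method. Wins plus losses plus draws
#' equal the number of genes for every method pair.
#'
#' @param report A `crossval_report` from [loocv()], or a data.frame whose
#'   first column is the gene id and remaining columns are per-method P_M
#'   values.
#' @return Integer matrix of win counts (rows beat columns).
#' @export
tournament <- function(report) {
  per_gene <- if (inherits(report, "crossval_report")) report$per_gene
              else report
  methods <- setdiff(colnames(per_gene), "gene")
  if (any(is.na(per_gene[methods]))) stop("missing P_M entries")
  wins <- matrix(0L, length(methods), length(methods),
                 dimnames = list(methods, methods))
  for (a in methods) for (b in methods) {
    if (a != b) wins[a, b] <- sum(per_gene[[a]] > per_gene[[b]])
  }
  wins
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("<crossval_report>", nrow(x$per_gene), "genes,",
      length(x$methods), "methods\n")
  cat("mean P_M (%):\n")
  print(round(x$mean_pm, 2))
  cat("tournament (row beats column):\n")
  print(x$tournament)
  invisible(x)
}
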