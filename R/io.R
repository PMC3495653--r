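# FASTA / TSV readers and writers and expression-based gene selection.

#' Read coding sequences from FASTA
#'
#' Reads DNA or RNA coding sequences (case-insensitive; `T` is normalized
#' to `U`), validates that every record's length is divisible by 3 and
#' that all triplets are unambiguous codons, and returns them as
#' [codon_seq()] objects. Records with internal stop codons trigger a
#' warning by default (set `internal_stop = "error"` to reject them).
#'
#' @param path FASTA file path.
#' @param internal_stop `"warn"` (default) or `"error"`.
#' @param code A [genetic_code()] object.
#' @return Named list of [codon_seq()].
#' @export
read_cds_fasta <- function(path, internal_stop = c("warn", "error"),
                           code = default_code()) {
  internal_stop <- match.arg(internal_stop)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    s <- toupper(as.character(recs[[i]]))
    if (nchar(s) %% 3L != 0L) {
      stop(sprintf("record '%s' has length %d, not divisible by 3",
                   ids[i], nchar(s)))
    }
    cs <- codon_seq(s, id = ids[i], code = code)
    n <- length(cs)
    if (n > 1L && any(cs$protein[-n] == STOP_SYMBOL)) {
      msg <- sprintf("record '%s' contains an internal stop codon", ids[i])
      if (internal_stop == "error") stop(msg) else warning(msg)
    }
    out[[i]] <- cs
  }
  names(out) <- ids
  out
}

#' Write codon sequences to FASTA
#'
#' @param genes A [codon_seq()] or list of them.
#' @param path Output file path.
#' @param alphabet `"dna"` (default, U written as T) or `"rna"`.
#' @export
write_cds_fasta <- function(genes, path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  genes <- as_gene_list(genes)
  seqs <- vapply(genes, function(g) paste(g$codons, collapse = ""),
                 character(1))
  if (alphabet == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- vapply(seq_along(genes), function(i) {
    if (is.null(genes[[i]]$id)) paste0("seq", i) else genes[[i]]$id
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene-expression table
#'
#' Expects a TSV whose first column is the gene id and whose remaining
#' column(s) are numeric expression values; multiple condition columns are
#' collapsed to one value per gene by the mean (or median).
#'
#' @param path TSV file path (header required).
#' @param aggregate `"mean"` (default) or `"median"` across condition
#'   columns.
#' @return A data.frame with columns `gene_id` and `expression`.
#' @export
read_expression_table <- function(path, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs an id and a value column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in expression table: ",
         paste(utils::head(unique(ids[duplicated(ids)])), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("expression columns must be numeric")
  agg <- if (aggregate == "mean") rowMeans(vals) else
    apply(vals, 1L, stats::median)
  if (any(!is.finite(agg))) stop("non-finite expression values")
  data.frame(gene_id = ids, expression = unname(agg),
             stringsAsFactors = FALSE)
}

#' Select extreme-expression genes
#'
#' Returns the ids of the top (or bottom) `fraction` of genes by expression
#' value -- the top 5% being the conventional high-expression reference
#' set. The selection size is `ceiling(fraction * n)`; ties in expression
#' are broken deterministically by gene id.
#'
#' @param table Data.frame with columns `gene_id` and `expression` (e.g.
#'   from [read_expression_table()]).
#' @param fraction Fraction in (0, 1); default 0.05.
#' @param tail `"top"` (default) or `"bottom"`.
#' @return Character vector of selected gene ids.
#' @export
select_extreme_genes <- function(table, fraction = 0.05,
                                 tail = c("top", "bottom")) {
  tail <- match.arg(tail)
  if (!all(c("gene_id", "expression") %in% colnames(table))) {
    stop("`table` must have columns gene_id and expression")
  }
  if (nrow(table) == 0L) stop("empty expression table")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  k <- as.integer(ceiling(fraction * nrow(table)))
  ord <- if (tail == "top") {
    order(-table$expression, table$gene_id)
  } else {
    order(table$expression, table$gene_id)
  }
  table$gene_id[ord[seq_len(k)]]
}
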