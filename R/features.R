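# DEG identification and tumor/normal expression-ratio features.
#
# Differential expression is normally ingested from an external results
# table (e.g. a negative-binomial GLM analysis done elsewhere); the
# built-in paired test below is a clearly labelled fallback, not a
# reimplementation of such models.

#' Differential-expression results table
#'
#' @param gene character gene ids, unique.
#' @param log2fc per-gene log2 fold change (tumor vs. normal).
#' @param padj adjusted p-values in `[0, 1]`.
#' @param lfc_cut,padj_cut thresholds used to set the `is_deg` flag.
#' @return data.frame of class `de_table` with columns `gene`, `log2fc`,
#'   `padj`, `is_deg`.
#' @export
de_table <- function(gene, log2fc, padj, lfc_cut = 2, padj_cut = 0.05) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stopf("de_table: duplicate gene ids")
  if (length(log2fc) != length(gene) || length(padj) != length(gene))
    stopf("de_table: column lengths differ")
  if (any(!is.finite(padj)) || any(padj < 0 | padj > 1))
    stopf("de_table: padj must lie in [0, 1]")
  structure(data.frame(
    gene = gene, log2fc = as.numeric(log2fc), padj = as.numeric(padj),
    is_deg = abs(log2fc) > lfc_cut & padj < padj_cut,
    stringsAsFactors = FALSE
  ), class = c("de_table", "data.frame"))
}

#' Read / write a DE table as TSV
#'
#' Columns `gene`, `log2fc`, `padj`.
#' @param path TSV path.
#' @param ... passed to [de_table()] (thresholds).
#' @return a `de_table`.
#' @export
read_de_table <- function(path, ...) {
  tab <- read.table(path, sep = delim_for(path), header = TRUE,
                    stringsAsFactors = FALSE)
  for (v in c("gene", "log2fc", "padj"))
    if (!v %in% names(tab)) stopf("DE table %s lacks column '%s'", path, v)
  de_table(tab$gene, tab$log2fc, tab$padj, ...)
}

#' @rdname read_de_table
#' @param table a `de_table`.
#' @export
write_de_table <- function(table, path) {
  write.table(table[, c("gene", "log2fc", "padj")], path,
              sep = delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identify differentially expressed genes
#'
#' A gene is a DEG when `|log2fc| > lfc_cut` AND `padj < padj_cut`, both
#' inequalities strict.
#'
#' @param table a `de_table`.
#' @param lfc_cut absolute log2 fold-change threshold (default 2).
#' @param padj_cut adjusted p-value threshold (default 0.05).
#' @return character vector of DEG ids (in table order).
#' @export
identify_degs <- function(table, lfc_cut = 2, padj_cut = 0.05) {
  if (!inherits(table, "de_table")) stopf("identify_degs: need a de_table")
  table$gene[abs(table$log2fc) > lfc_cut & table$padj < padj_cut]
}

#' Paired differential-expression fallback test
#'
#' Per-gene paired t-test (default) or Wilcoxon signed-rank test on
#' `log2(x + 1)` tumor - normal differences across matched patients, with
#' Benjamini-Hochberg adjustment. This is a simple paired location test
#' on log-transformed values, intended for self-contained runs when no
#' external DE results table is available; it is not a count-model
#' analysis.
#'
#' @param tumor_expr,normal_expr raw nonnegative samples x genes matrices.
#'   Without `pairing`, row i of each matrix is taken to be the same
#'   patient.
#' @param pairing optional `list(tumor = ids, normal = ids)` of patient
#'   ids per row; normal rows are realigned to the tumor patients, and
#'   patients missing from either side are an error.
#' @param method `"ttest"` (default) or `"wilcoxon"`.
#' @return a `de_table` with `log2fc` = mean paired log2 difference; the
#'   `method` attribute records the fallback used.
#' @export
paired_de_fallback <- function(tumor_expr, normal_expr, pairing = NULL,
                               method = c("ttest", "wilcoxon")) {
  method <- match.arg(method)
  tumor_expr <- as.matrix(tumor_expr)
  normal_expr <- as.matrix(normal_expr)
  if (!is.null(pairing)) {
    if (!is.list(pairing) || !all(c("tumor", "normal") %in% names(pairing)))
      stopf("paired_de_fallback: pairing must be list(tumor =, normal =)")
    idx <- match(pairing$tumor, pairing$normal)
    if (anyNA(idx))
      stopf("paired_de_fallback: %d tumor patient(s) lack a normal sample",
            sum(is.na(idx)))
    normal_expr <- normal_expr[idx, , drop = FALSE]
  }
  if (!identical(dim(tumor_expr), dim(normal_expr)))
    stopf("paired_de_fallback: matrices must have identical dimensions")
  n <- nrow(tumor_expr)
  if (n < 3) stopf("paired_de_fallback: need at least 3 pairs")
  if (min(tumor_expr) < 0 || min(normal_expr) < 0)
    stopf("paired_de_fallback: expression must be nonnegative")
  d <- log2(tumor_expr + 1) - log2(normal_expr + 1)
  lfc <- colMeans(d)
  if (method == "ttest") {
    s <- sqrt(colSums(sweep(d, 2, lfc, "-")^2) / (n - 1))
    tt <- ifelse(s == 0, ifelse(lfc == 0, 0, Inf * sign(lfc)), lfc / (s / sqrt(n)))
    p <- 2 * pt(-abs(tt), df = n - 1)
  } else {
    p <- apply(d, 2, function(col) wilcoxon_signedrank(col, numeric(length(col)))$p.value)
  }
  out <- de_table(colnames(tumor_expr), lfc, benjamini_hochberg(p))
  attr(out, "method") <- paste0("paired-", method, "-fallback")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1),
#' delegated to [stats::p.adjust()].
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("benjamini_hochberg: p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Patient-wise expression ratio
#'
#' Natural-log ratio of a patient's tumor expression to the same
#' patient's normal expression, after adding a pseudocount on the raw
#' scale. Vectorized elementwise over matrices of matching shape.
#'
#' @param tumor,normal nonnegative expression values (scalars, vectors or
#'   samples x genes matrices of equal shape).
#' @param pseudocount added to both arguments before the ratio
#'   (default 1; values must be positive afterwards).
#' @return `ln((tumor + pseudocount) / (normal + pseudocount))`.
#' @export
ratio_individual <- function(tumor, normal, pseudocount = 1) {
  if (length(tumor) != length(normal))
    stopf("ratio_individual: arguments must match in shape")
  t1 <- tumor + pseudocount
  n1 <- normal + pseudocount
  if (any(t1 <= 0) || any(n1 <= 0))
    stopf("ratio_individual: nonpositive value after pseudocount")
  log(t1 / n1)
}

#' Median-reference expression ratio
#'
#' Natural-log ratio of a patient's tumor expression to the cohort median
#' normal expression of that gene, after the pseudocount.
#'
#' @param tumor samples x genes matrix (or vector for a single gene).
#' @param normal samples x genes matrix whose per-gene medians form the
#'   reference (or vector for a single gene).
#' @param pseudocount as in [ratio_individual()].
#' @return matrix (or vector) of `ln((tumor + pc) / (median(normal) + pc))`.
#' @export
ratio_median <- function(tumor, normal, pseudocount = 1) {
  if (is.matrix(tumor)) {
    if (!is.matrix(normal) || ncol(normal) != ncol(tumor))
      stopf("ratio_median: normal must have the same genes as tumor")
    med <- apply(normal, 2, median)
    t1 <- tumor + pseudocount
    m1 <- med + pseudocount
    if (any(t1 <= 0) || any(m1 <= 0))
      stopf("ratio_median: nonpositive value after pseudocount")
    sweep(log(t1), 2, log(m1), "-")
  } else {
    m1 <- median(normal) + pseudocount
    t1 <- tumor + pseudocount
    if (any(t1 <= 0) || m1 <= 0)
      stopf("ratio_median: nonpositive value after pseudocount")
    log(t1) - log(m1)
  }
}

#' Rank genes by absolute log2 fold change
#'
#' Descending `|log2fc|`; ties broken by lexicographic gene id so the
#' ordering is deterministic under row permutation.
#'
#' @param table a `de_table`.
#' @return character vector of gene ids, most changed first.
#' @export
rank_by_abs_lfc <- function(table) {
  if (!inherits(table, "de_table")) stopf("rank_by_abs_lfc: need a de_table")
  table$gene[order(-abs(table$log2fc), table$gene)]
}
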