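#' Survival cohort container
#'
#' Bundles an expression matrix (samples in rows, genes in columns) with
#' survival outcomes and clinical covariates for one tissue type of one
#' cohort. Expression values are expected to be nonnegative (FPKM-like)
#' before standardization; after [standardize_genes()] each gene has mean
#' 0 and population standard deviation 1.
#'
#' @param expression numeric matrix, samples x genes, with dimnames.
#' @param time positive follow-up time per sample (days or arbitrary units).
#' @param event integer 0/1 per sample; 1 = deceased.
#' @param clinical data.frame of per-sample covariates; must contain
#'   `age` (years) and `stage` (ordinal 1-4); `metastasis` (0/1) optional.
#' @param tissue `"tumor"` or `"normal"`.
#' @param pairing optional character vector of patient ids, one per sample,
#'   linking tumor and normal samples from the same patient.
#' @param cohort_id optional label used in reports.
#'
#' @return An object of class `survival_cohort`: a list with elements
#'   `expression`, `gene_ids`, `sample_ids`, `time`, `event`, `clinical`,
#'   `tissue`, `pairing`, `cohort_id`.
#' @export
survival_cohort <- function(expression, time, event, clinical, tissue,
                            pairing = NULL, cohort_id = NULL) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression)) stopf("expression must be numeric")
  n <- nrow(expression)
  if (is.null(rownames(expression)))
    rownames(expression) <- paste0("S", seq_len(n))
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("g", seq_len(ncol(expression)))
  if (anyDuplicated(colnames(expression)))
    stopf("duplicate gene ids in expression matrix")
  check_time_event(time, event)
  if (length(time) != n)
    stopf("expression has %d samples but %d survival times given", n, length(time))
  tissue <- match.arg(tissue, c("tumor", "normal"))
  clinical <- as.data.frame(clinical)
  if (nrow(clinical) != n) stopf("clinical table must have one row per sample")
  for (v in c("age", "stage"))
    if (!v %in% names(clinical)) stopf("clinical table lacks column '%s'", v)
  if (!is.null(pairing) && length(pairing) != n)
    stopf("pairing must give one patient id per sample")
  structure(list(
    expression = expression,
    gene_ids = colnames(expression),
    sample_ids = rownames(expression),
    time = as.numeric(time),
    event = as.integer(event),
    clinical = clinical,
    tissue = tissue,
    pairing = pairing,
    cohort_id = cohort_id
  ), class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %s%s, %d samples x %d genes, %d events (%.0f%%)\n",
              x$tissue,
              if (is.null(x$cohort_id)) "" else paste0(" [", x$cohort_id, "]"),
              length(x$sample_ids), length(x$gene_ids),
              sum(x$event), 100 * mean(x$event)))
  invisible(x)
}

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression table with a header row and an id column.
#' The file may store genes in rows (the common public-repository layout)
#' or samples in rows; either way the returned matrix is samples x genes.
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return numeric matrix, samples x genes, with dimnames.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- delim_for(path)
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stopf("ragged row in %s: line %d has %d fields, expected %d",
          path, bad, nf[bad], nf[1])
  }
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = NA)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stopf("duplicate id '%s' in %s (line %d)", dup, path,
          which(ids == dup)[2] + 1L)
  }
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num) && !anyNA(col))
        stopf("non-numeric cell in %s: column '%s', line %d",
              path, names(vals)[j], which(is.na(num))[1] + 1L)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "genes_in_rows") m <- t(m)
  m
}

#' Write an expression matrix in the dialect `read_expression` reads
#'
#' @param mat samples x genes numeric matrix with dimnames.
#' @param path output path; `.csv` gives comma separation, else tab.
#' @param orientation layout of the written file.
#' @param id_column name for the leading id column.
#' @export
write_expression <- function(mat, path,
                             orientation = c("genes_in_rows", "samples_in_rows"),
                             id_column = "id") {
  orientation <- match.arg(orientation)
  out <- if (orientation == "genes_in_rows") t(mat) else mat
  df <- data.frame(rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns `patient_id`, `time`, `event`, `age`, `stage` and
#' optionally `metastasis` and `tissue`.
#'
#' @param path TSV/CSV path.
#' @return data.frame with validated columns.
#' @export
read_clinical <- function(path) {
  tab <- read.table(path, sep = delim_for(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event", "age", "stage")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("clinical table %s lacks columns: %s",
                          path, paste(miss, collapse = ", "))
  check_time_event(tab$time, tab$event)
  tab
}

#' Drop genes with zero mean expression
#'
#' Genes whose mean across samples is exactly zero (all-zero columns for
#' nonnegative data) carry no information and are removed before
#' standardization. Gene order is preserved.
#'
#' @param x a `survival_cohort` or a samples x genes matrix.
#' @return object of the same class with zero-mean genes removed.
#' @export
filter_zero_mean_genes <- function(x) UseMethod("filter_zero_mean_genes")

#' @export
filter_zero_mean_genes.default <- function(x) {
  x <- as.matrix(x)
  keep <- colMeans(x) != 0
  x[, keep, drop = FALSE]
}

#' @export
filter_zero_mean_genes.survival_cohort <- function(x) {
  keep <- colMeans(x$expression) != 0
  if (!all(keep))
    logf("filter_zero_mean_genes: removed %d of %d genes", sum(!keep), length(keep))
  x$expression <- x$expression[, keep, drop = FALSE]
  x$gene_ids <- colnames(x$expression)
  x
}

#' Standardize genes to mean 0, sd 1
#'
#' Column-wise (per-gene) standardization using the population standard
#' deviation (divisor n). Genes with zero variance are undefined under
#' standardization and are dropped with a warning.
#'
#' @param x a `survival_cohort` or a samples x genes matrix.
#' @return object of the same class, standardized.
#' @export
standardize_genes <- function(x) UseMethod("standardize_genes")

#' @export
standardize_genes.default <- function(x) {
  x <- as.matrix(x)
  ms <- col_means_sds(x)
  drop <- ms$sd == 0
  if (any(drop)) {
    warnf("standardize_genes: dropping %d zero-variance gene(s)", sum(drop))
    x <- x[, !drop, drop = FALSE]
  }
  scale_columns(x, ms$mean[!drop], ms$sd[!drop])
}

#' @export
standardize_genes.survival_cohort <- function(x) {
  x$expression <- standardize_genes(x$expression)
  x$gene_ids <- colnames(x$expression)
  x
}

#' Restrict two cohorts to their common genes
#'
#' Both cohorts are subset to the sorted intersection of their gene ids,
#' in identical order, mirroring the retention of genes present in both a
#' discovery and an external screening dataset.
#'
#' @param a,b `survival_cohort` objects (or samples x genes matrices).
#' @return list with elements `a` and `b`.
#' @export
intersect_genes <- function(a, b) {
  ga <- if (inherits(a, "survival_cohort")) a$gene_ids else colnames(a)
  gb <- if (inherits(b, "survival_cohort")) b$gene_ids else colnames(b)
  common <- sort(intersect(ga, gb))
  if (length(common) == 0L) stopf("cohorts share no genes")
  subset_genes <- function(x) {
    if (inherits(x, "survival_cohort")) {
      x$expression <- x$expression[, common, drop = FALSE]
      x$gene_ids <- common
      x
    } else x[, common, drop = FALSE]
  }
  list(a = subset_genes(a), b = subset_genes(b))
}

#' Match expression samples to clinical records
#'
#' Joins a samples x genes matrix to a clinical table by exact id string;
#' unmatched samples on either side are dropped with a logged count.
#'
#' @param expression samples x genes matrix with sample ids as rownames.
#' @param clinical data.frame with a `patient_id` column.
#' @return list of aligned `expression` and `clinical`.
#' @export
match_samples <- function(expression, clinical) {
  ids <- intersect(rownames(expression), clinical$patient_id)
  dropped <- (nrow(expression) - length(ids)) +
    (nrow(clinical) - length(ids))
  if (dropped > 0)
    logf("match_samples: dropped %d unmatched record(s)", dropped)
  if (length(ids) == 0L) stopf("no samples match between expression and clinical")
  list(expression = expression[ids, , drop = FALSE],
       clinical = clinical[match(ids, clinical$patient_id), , drop = FALSE])
}

#' Write a simulated paired study to disk
#'
#' Writes tumor and normal expression matrices and the shared clinical
#' table in the TSV dialect [read_expression()] and [read_clinical()]
#' accept, plus the ground-truth planting information as a JSON sidecar.
#'
#' @param study a `paired_study` from [simulate_paired_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    tumor = file.path(dir, "expression_tumor.tsv"),
    normal = file.path(dir, "expression_normal.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(study$tumor$expression, paths[["tumor"]])
  write_expression(study$normal$expression, paths[["normal"]])
  clin <- cbind(patient_id = study$pairing$patient_id,
                time = study$tumor$time, event = study$tumor$event,
                study$tumor$clinical)
  write.table(clin, paths[["clinical"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Build a simulation configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [simulation_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `simulation_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stopf("config %s is not a YAML mapping", path)
  if (!is.null(vals$clin_effects)) vals$clin_effects <- unlist(vals$clin_effects)
  do.call(simulation_config, vals)
}
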