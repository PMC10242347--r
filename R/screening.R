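# Distance-correlation gene screening. Genes are ranked by the distance
# correlation between their expression and the linear predictor of a
# clinical-covariate Cox model fitted on an external (screening) cohort;
# the ranking is then applied to the discovery cohort's gene universe.

# Double-centered absolute-difference matrix of a 1-d sample.
dcenter <- function(x) {
  A <- abs(outer(x, x, "-"))
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, length(x))) - outer(rep(1, length(x)), rm_) + mean(A)
}

#' Distance correlation (Szekely's sample dCor)
#'
#' V-statistic estimator: pairwise absolute-difference matrices of each
#' variable are double-centered (row means, column means, grand mean);
#' `dCov^2` is the mean of their elementwise product and
#' `dCor = dCov / sqrt(sqrt(dVar_x * dVar_y))`. Captures nonlinear as
#' well as linear association; 0 iff independence in the population
#' version. A constant argument has `dVar = 0` and returns 0 by
#' convention (a constant gene carries no signal and must not rank).
#'
#' @param x,y numeric vectors of equal length `n >= 2`, finite.
#' @return distance correlation in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("distance_correlation: unequal lengths")
  if (length(x) < 2) stopf("distance_correlation: need n >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("distance_correlation: inputs must be finite")
  A <- dcenter(x)
  B <- dcenter(y)
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) return(0)
  dcov2 <- mean(A * B)
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvar_x * dvar_y))
}

#' Clinical-covariate Cox risk predictor
#'
#' Fits a Cox model on clinical covariates only (age, tumor stage, and
#' metastasis when the cohort records it) and returns the per-sample
#' linear predictor used as the reference variable for
#' distance-correlation screening.
#'
#' @param cohort a `survival_cohort`.
#' @param covariates character vector of clinical columns to use;
#'   defaults to `age`, `stage` plus `metastasis` if present.
#'   Zero-variance columns are dropped; if none remain this is an error.
#' @return list of class `cox_predictor`: `scores` (per-sample risk),
#'   `fit` (the `cox_fit`), `predictor_spec` (covariates used),
#'   `cohort_id`.
#' @export
clinical_cox_predictor <- function(cohort, covariates = NULL) {
  if (!inherits(cohort, "survival_cohort"))
    stopf("clinical_cox_predictor: need a survival_cohort")
  if (is.null(covariates)) {
    covariates <- c("age", "stage")
    if ("metastasis" %in% names(cohort$clinical))
      covariates <- c(covariates, "metastasis")
  }
  miss <- setdiff(covariates, names(cohort$clinical))
  if (length(miss)) stopf("clinical covariates missing: %s",
                          paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(lapply(cohort$clinical[covariates], as.numeric)))
  keep <- apply(X, 2, function(v) length(unique(v)) > 1)
  if (!any(keep)) stopf("clinical_cox_predictor: all clinical covariates constant")
  if (!all(keep))
    logf("clinical_cox_predictor: dropping constant covariate(s): %s",
         paste(covariates[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  fit <- fit_cox(X, cohort$time, cohort$event)
  if (!fit$converged)
    stopf("clinical_cox_predictor: Cox fit did not converge (max|score|=%.3g after %d iterations)",
          fit$score_max, fit$n_iterations)
  structure(list(scores = linear_predictor(fit, X),
                 fit = fit,
                 predictor_spec = colnames(X),
                 cohort_id = cohort$cohort_id),
            class = "cox_predictor")
}

#' Rank genes by distance correlation with a risk predictor
#'
#' Computes the distance correlation of every gene's expression with the
#' per-sample risk predictor and ranks genes in decreasing order, ties
#' broken by lexicographic gene id.
#'
#' @param expression samples x genes matrix (standardized expression by
#'   convention; dCor is invariant to per-gene location/scale so this
#'   only matters for interpretability).
#' @param predictor numeric per-sample risk score, or a `cox_predictor`.
#' @return data.frame of class `screening_ranking` with columns `gene`,
#'   `dcor`, `rank`, plus attributes `predictor_spec` and `cohort_id`
#'   when available.
#' @export
screen_genes <- function(expression, predictor) {
  spec <- NULL
  cid <- NULL
  if (inherits(predictor, "cox_predictor")) {
    spec <- predictor$predictor_spec
    cid <- predictor$cohort_id
    predictor <- predictor$scores
  }
  expression <- as.matrix(expression)
  if (nrow(expression) != length(predictor))
    stopf("screen_genes: expression rows must match predictor length")
  B <- dcenter(predictor)
  dvar_y <- mean(B * B)
  dc <- vapply(seq_len(ncol(expression)), function(j) {
    A <- dcenter(expression[, j])
    dvar_x <- mean(A * A)
    if (dvar_x <= 0 || dvar_y <= 0) return(0)
    sqrt(max(mean(A * B), 0)) / sqrt(sqrt(dvar_x * dvar_y))
  }, numeric(1))
  genes <- colnames(expression)
  o <- order(-dc, genes)
  structure(data.frame(gene = genes[o], dcor = dc[o], rank = seq_along(o),
                       stringsAsFactors = FALSE),
            class = c("screening_ranking", "data.frame"),
            predictor_spec = spec, cohort_id = cid)
}

#' Top-k genes of a screening ranking
#'
#' @param ranking a `screening_ranking` (or any data.frame with a `gene`
#'   column ordered by rank).
#' @param k number of genes, `1 <= k <= nrow(ranking)`.
#' @return character vector of the first `k` gene ids.
#' @export
top_k <- function(ranking, k) {
  if (!is_count(k) || k > nrow(ranking))
    stopf("top_k: k must be an integer in [1, %d]", nrow(ranking))
  ranking$gene[seq_len(k)]
}

#' Write a screening ranking / top-k gene list
#'
#' The ranking is written as TSV (gene, dcor, rank); a top-k list as
#' plain text, one gene id per line, for use by external enrichment
#' tools.
#'
#' @param ranking a `screening_ranking`.
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param genes character vector (e.g. from [top_k()]).
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
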