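# Evaluation protocols: repeated hold-out comparison across data types
# and models (one split shared by every model within a repetition),
# informative-gene density, feature-size sweeps, median-risk KM
# grouping, cross-cohort prognostic similarity, and the fold-change vs.
# Cox-coefficient correlation.

standardize_modes <- c("train", "global", "none")

apply_standardization <- function(X_train, X_test, mode) {
  if (mode == "train") {
    ms <- col_means_sds(X_train)
    list(train = scale_columns(X_train, ms$mean, ms$sd),
         test = scale_columns(X_test, ms$mean, ms$sd))
  } else {
    list(train = X_train, test = X_test)
  }
}

#' Repeated hold-out evaluation
#'
#' For each repetition one event-stratified 70/30 (by default) split is
#' drawn and reused for every data type and model, so that paired
#' statistical comparison across rows is valid; the test-set concordance
#' index is recorded per (data type, model, repetition). A repetition
#' whose test fold has no comparable pairs is redrawn (logged).
#'
#' @param datasets named list of samples x features matrices over the
#'   same samples in the same order.
#' @param time,event shared survival outcome.
#' @param models named list of [survival_model()] objects.
#' @param n_repeats number of repetitions (default 50).
#' @param train_frac training fraction (default 0.7).
#' @param seed master seed; the full table is reproducible from it.
#' @param standardize `"train"` (fit standardization on the training
#'   fold and apply it to the test fold; leakage-safe default),
#'   `"global"` (standardize each full matrix once up front), or
#'   `"none"`.
#' @return data.frame of class `eval_table` with columns `data_type`,
#'   `model`, `repetition`, `split_id`, `c_index`.
#' @export
repeated_holdout <- function(datasets, time, event, models,
                             n_repeats = 50, train_frac = 0.7, seed = 1,
                             standardize = c("train", "global", "none")) {
  standardize <- match.arg(standardize)
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stopf("repeated_holdout: datasets must be a named list")
  if (is.null(names(models)) || any(names(models) == ""))
    stopf("repeated_holdout: models must be a named list")
  datasets <- lapply(datasets, as.matrix)
  n <- length(time)
  if (!all(vapply(datasets, nrow, integer(1)) == n))
    stopf("repeated_holdout: all datasets must cover the same %d samples", n)
  check_time_event(time, event)
  if (standardize == "global")
    datasets <- lapply(datasets, standardize_genes)
  rows <- vector("list", n_repeats * length(datasets) * length(models))
  ri <- 0L
  for (r in seq_len(n_repeats)) {
    split <- NULL
    for (attempt in 0:19) {
      cand <- event_stratified_split(event, train_frac,
                                     seed = seed + r + 100000L * attempt)
      if (has_comparable_pairs(time[cand$test], event[cand$test])) {
        split <- cand
        if (attempt > 0)
          logf("repeated_holdout: repetition %d redrawn %d time(s)", r, attempt)
        break
      }
    }
    if (is.null(split))
      stopf("repeated_holdout: could not draw a usable test fold for repetition %d", r)
    split_id <- sprintf("r%03d_h%d", r, sum(split$train))
    for (dt in names(datasets)) {
      Xd <- datasets[[dt]]
      sd_ <- apply_standardization(Xd[split$train, , drop = FALSE],
                                   Xd[split$test, , drop = FALSE],
                                   if (standardize == "train") "train" else "none")
      for (mn in names(models)) {
        mod <- models[[mn]]
        obj <- mod$fit(sd_$train, time[split$train], event[split$train])
        risk <- mod$predict_risk(obj, sd_$test)
        ci <- concordance_index(time[split$test], event[split$test], risk)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(data_type = dt, model = mn, repetition = r,
                                 split_id = split_id, c_index = ci,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  class(out) <- c("eval_table", "data.frame")
  out
}

#' Per-gene univariate concordance and informative-gene fraction
#'
#' Fits a univariate Cox model per gene and evaluates its concordance
#' index on the same cohort. Genes whose fit fails are assigned C = 0.5
#' and counted. A gene is "informative" when its C-index departs from
#' 0.5 by at least `tau` in either direction.
#'
#' @param expression standardized samples x genes matrix (or a
#'   `survival_cohort`).
#' @param time,event outcome (taken from the cohort when one is given).
#' @param tau informative threshold on `|C - 0.5|` (default 0.1).
#' @return list with `c_index` (named per-gene vector),
#'   `informative_fraction`, `tau`, `n_failed`.
#' @export
informative_gene_density <- function(expression, time = NULL, event = NULL,
                                     tau = 0.1) {
  if (inherits(expression, "survival_cohort")) {
    time <- expression$time
    event <- expression$event
    expression <- expression$expression
  }
  expression <- as.matrix(expression)
  n_failed <- 0L
  cs <- vapply(seq_len(ncol(expression)), function(j) {
    tryCatch({
      fit <- fit_cox(expression[, j, drop = FALSE], time, event)
      concordance_index(time, event, expression[, j] * fit$coefficients[1])
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      0.5
    })
  }, numeric(1))
  names(cs) <- colnames(expression)
  if (n_failed > 0)
    logf("informative_gene_density: %d gene fit(s) failed, assigned C = 0.5", n_failed)
  list(c_index = cs,
       informative_fraction = mean(abs(cs - 0.5) >= tau),
       tau = tau, n_failed = n_failed)
}

#' Feature-size sweep over a gene ranking
#'
#' Runs the repeated hold-out protocol restricted to the top-k genes of
#' a ranking for each requested size, alongside the all-gene baseline
#' evaluated under the same splits.
#'
#' @param ranking a `screening_ranking` (or data.frame with `gene`
#'   ordered by rank); genes absent from `X` are dropped from the
#'   ranking first.
#' @param sizes integer feature sizes, each within the ranked-gene count.
#' @param X samples x genes matrix.
#' @param time,event outcome.
#' @param model a [survival_model()].
#' @param n_iter repetitions per size (default 20).
#' @param train_frac,seed,standardize as in [repeated_holdout()].
#' @return list of class `feature_sweep`: `sweep` (data.frame `size`,
#'   `mean_c_index`), `baseline` (all-gene mean C), `best_size`,
#'   `evals` (per-size `eval_table`s).
#' @export
feature_size_sweep <- function(ranking, sizes, X, time, event, model,
                               n_iter = 20, train_frac = 0.7, seed = 1,
                               standardize = "train") {
  X <- as.matrix(X)
  genes <- ranking$gene[ranking$gene %in% colnames(X)]
  if (length(genes) == 0L) stopf("feature_size_sweep: ranking shares no genes with X")
  if (any(sizes < 1 | sizes > length(genes)))
    stopf("feature_size_sweep: sizes must lie in [1, %d]", length(genes))
  run <- function(cols, label) {
    repeated_holdout(stats::setNames(list(X[, cols, drop = FALSE]), label),
                     time, event,
                     models = stats::setNames(list(model), model$label),
                     n_repeats = n_iter, train_frac = train_frac,
                     seed = seed, standardize = standardize)
  }
  evals <- lapply(sizes, function(k) run(genes[seq_len(k)], sprintf("top%d", k)))
  base_eval <- run(colnames(X), "all")
  means <- vapply(evals, function(e) mean(e$c_index), numeric(1))
  structure(list(
    sweep = data.frame(size = sizes, mean_c_index = means),
    baseline = mean(base_eval$c_index),
    best_size = sizes[which.max(means)],
    evals = c(stats::setNames(evals, sprintf("top%d", sizes)),
              list(baseline = base_eval))
  ), class = "feature_sweep")
}

#' Median-split risk grouping with Kaplan-Meier curves and log-rank test
#'
#' Splits samples at the median risk score (ties at the median go to the
#' low-risk group), estimates a Kaplan-Meier curve per group and tests
#' their separation by the log-rank test.
#'
#' @param risk numeric model output per sample.
#' @param time,event outcome (`>= 4` samples).
#' @return list with `group` (factor `low`/`high`), `km` (list of two
#'   `kaplan_meier` frames), `logrank`, `p.value`.
#' @export
median_risk_grouping <- function(risk, time, event) {
  if (length(risk) < 4) stopf("median_risk_grouping: need at least 4 samples")
  check_time_event(time, event)
  med <- median(risk)
  low <- risk <= med
  if (all(low) || !any(low))
    stopf("median_risk_grouping: risk scores do not split at the median")
  lr <- logrank_test(time[!low], event[!low], time[low], event[low])
  list(group = factor(ifelse(low, "low", "high"), levels = c("low", "high")),
       km = list(low = kaplan_meier(time[low], event[low]),
                 high = kaplan_meier(time[!low], event[!low])),
       logrank = lr,
       p.value = lr$p.value)
}

#' Cross-cohort prognostic similarity
#'
#' For every shared gene, fits a univariate Cox model on the screening
#' cohort, records its concordance index there (train C) and on the
#' evaluation cohort using the same fitted coefficient (test C), and
#' returns the Pearson correlation of the two across genes: the degree
#' to which per-gene prognostic value transfers between cohorts.
#'
#' @param screen_cohort,eval_cohort `survival_cohort`s restricted to a
#'   common gene universe (see [intersect_genes()]); expression is
#'   standardized internally before fitting.
#' @return list with `table` (gene, train_c, test_c), `r` (Pearson
#'   correlation), `n_skipped` (genes whose fit failed).
#' @export
cross_cohort_similarity <- function(screen_cohort, eval_cohort) {
  if (!identical(screen_cohort$gene_ids, eval_cohort$gene_ids))
    stopf("cross_cohort_similarity: cohorts must share an identical gene universe")
  Xs <- standardize_genes(screen_cohort$expression)
  Xe <- standardize_genes(eval_cohort$expression)
  common <- intersect(colnames(Xs), colnames(Xe))
  n_skipped <- 0L
  rows <- lapply(common, function(g) {
    tryCatch({
      fit <- fit_cox(Xs[, g, drop = FALSE], screen_cohort$time, screen_cohort$event)
      b <- fit$coefficients[1]
      data.frame(gene = g,
                 train_c = concordance_index(screen_cohort$time,
                                             screen_cohort$event, Xs[, g] * b),
                 test_c = concordance_index(eval_cohort$time,
                                            eval_cohort$event, Xe[, g] * b),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      n_skipped <<- n_skipped + 1L
      NULL
    })
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (n_skipped > 0)
    logf("cross_cohort_similarity: skipped %d gene(s)", n_skipped)
  list(table = tab,
       r = pearson_correlation(tab$train_c, tab$test_c),
       n_skipped = n_skipped)
}

#' Correlation between log fold change and Cox coefficient
#'
#' Per-gene univariate Cox coefficients on the given cohort's
#' (standardized) expression, correlated with the DE table's log2 fold
#' changes over the shared genes.
#'
#' @param de a `de_table`.
#' @param cohort a `survival_cohort` (tissue of interest).
#' @return list with `r`, `n_genes`, `table` (gene, log2fc, coef).
#' @export
lfc_vs_coef_correlation <- function(de, cohort) {
  common <- intersect(de$gene, cohort$gene_ids)
  if (length(common) < 3) stopf("lfc_vs_coef_correlation: fewer than 3 shared genes")
  X <- standardize_genes(cohort$expression[, common, drop = FALSE])
  common <- colnames(X)
  coefs <- vapply(common, function(g) {
    tryCatch(fit_cox(X[, g, drop = FALSE], cohort$time, cohort$event)$coefficients[1],
             error = function(e) NA_real_)
  }, numeric(1))
  lfc <- de$log2fc[match(common, de$gene)]
  ok <- !is.na(coefs)
  r <- pearson_correlation(lfc[ok], coefs[ok])
  list(r = r, n_genes = sum(ok),
       table = data.frame(gene = common[ok], log2fc = lfc[ok], coef = coefs[ok],
                          stringsAsFactors = FALSE))
}

match_rows <- function(eval_table, spec) {
  keep <- rep(TRUE, nrow(eval_table))
  for (f in names(spec)) {
    if (!f %in% names(eval_table)) stopf("compare_groups: no column '%s'", f)
    keep <- keep & eval_table[[f]] == spec[[f]]
  }
  eval_table[keep, , drop = FALSE]
}

#' Compare evaluation groups by Wilcoxon tests with BH adjustment
#'
#' Each comparison selects two groups of rows from an `eval_table` (by
#' `data_type` and/or `model`) and compares their per-repetition
#' C-indices. When the two groups share exactly the same split ids the
#' comparison is paired (Wilcoxon signed-rank across shared splits);
#' otherwise the rank-sum test is used. Adjusted p-values are
#' Benjamini-Hochberg over the family of comparisons in the call.
#'
#' @param eval_table an `eval_table` from [repeated_holdout()].
#' @param comparisons one `list(a = spec, b = spec)` or a list of such;
#'   a spec is a named list, e.g. `list(data_type = "normal",
#'   model = "nn")`.
#' @param adjust only `"bh"` is provided.
#' @return data.frame with one row per comparison: `a`, `b`, `test`,
#'   `delta` (mean C difference a - b), `p`, `p_adj`.
#' @export
compare_groups <- function(eval_table, comparisons, adjust = "bh") {
  if (!identical(adjust, "bh")) stopf("compare_groups: only BH adjustment is provided")
  if (!is.null(names(comparisons)) && setequal(names(comparisons), c("a", "b")))
    comparisons <- list(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    ga <- match_rows(eval_table, cmp$a)
    gb <- match_rows(eval_table, cmp$b)
    if (nrow(ga) == 0L || nrow(gb) == 0L)
      stopf("compare_groups: empty group (a: %d rows, b: %d rows)",
            nrow(ga), nrow(gb))
    paired <- nrow(ga) == nrow(gb) &&
      setequal(ga$split_id, gb$split_id) &&
      !anyDuplicated(ga$split_id) && !anyDuplicated(gb$split_id)
    if (paired) {
      gb <- gb[match(ga$split_id, gb$split_id), , drop = FALSE]
      tst <- wilcoxon_signedrank(ga$c_index, gb$c_index)
      test <- "signed-rank"
    } else {
      tst <- wilcoxon_ranksum(ga$c_index, gb$c_index)
      test <- "rank-sum"
    }
    data.frame(
      a = paste(unlist(cmp$a), collapse = "/"),
      b = paste(unlist(cmp$b), collapse = "/"),
      test = test,
      delta = mean(ga$c_index) - mean(gb$c_index),
      p = tst$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p)
  out
}

#' Write an evaluation table / run manifest
#'
#' @param eval_table an `eval_table`.
#' @param path TSV path.
#' @export
write_eval_table <- function(eval_table, path) {
  write.table(as.data.frame(eval_table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' End-to-end screening benchmark on a simulated paired study
#'
#' Runs the full protocol on one simulated discovery study and its
#' external screening cohort: distance-correlation screening of each
#' tissue against the screening cohort's clinical Cox predictor,
#' repeated hold-out evaluation of the Cox neural network on tumor and
#' normal expression with and without the screened top-k restriction
#' (optionally with DEG-ratio and clinical arms), and the paired
#' Wilcoxon comparisons between arms.
#'
#' @param config a [simulation_config()]; its defaults define the study
#'   conditions.
#' @param k screened feature-set size (default: the number of planted
#'   normal-prognostic genes).
#' @param n_repeats hold-out repetitions (default 20).
#' @param nn_config [train_config()] for the Cox neural network.
#' @param include_ratios also evaluate individual- and median-ratio DEG
#'   features (DEGs from the built-in paired fallback test) and a
#'   clinical-only Cox arm.
#' @param seed master seed for splits.
#' @return list with `study`, `screening_cohort`, `rankings` (per
#'   tissue), `selected` (top-k genes per tissue), `eval` (pooled
#'   `eval_table`), `comparisons` (from [compare_groups()]).
#' @export
run_screening_benchmark <- function(config = simulation_config(),
                                    k = config$n_prog_normal,
                                    n_repeats = 20,
                                    nn_config = train_config(lambda_l2 = 1e-3,
                                                             max_epochs = 300,
                                                             seed = 1),
                                    include_ratios = FALSE, seed = 1) {
  study <- simulate_paired_study(config)
  screen <- simulate_screening_cohort(study, config)
  rankings <- list()
  selected <- list()
  for (tissue in c("normal", "tumor")) {
    pred <- clinical_cox_predictor(screen[[tissue]])
    rankings[[tissue]] <- screen_genes(standardize_genes(screen[[tissue]]$expression),
                                       pred)
    selected[[tissue]] <- top_k(rankings[[tissue]], k)
  }
  datasets <- list(
    normal = study$normal$expression,
    tumor = study$tumor$expression,
    normal_screened = study$normal$expression[, selected$normal, drop = FALSE],
    tumor_screened = study$tumor$expression[, selected$tumor, drop = FALSE]
  )
  models <- list(nn = model_cox_nn(nn_config))
  ev <- repeated_holdout(datasets, study$normal$time, study$normal$event,
                         models, n_repeats = n_repeats, seed = seed)
  if (include_ratios) {
    de <- paired_de_fallback(study$tumor$expression, study$normal$expression)
    degs <- identify_degs(de)
    if (length(degs) >= 2) {
      ratio_sets <- list(
        ratio_individual = ratio_individual(study$tumor$expression[, degs, drop = FALSE],
                                            study$normal$expression[, degs, drop = FALSE]),
        ratio_median = ratio_median(study$tumor$expression[, degs, drop = FALSE],
                                    study$normal$expression[, degs, drop = FALSE])
      )
      ev <- rbind(ev, repeated_holdout(ratio_sets, study$normal$time,
                                       study$normal$event, models,
                                       n_repeats = n_repeats, seed = seed))
    } else {
      logf("run_screening_benchmark: %d DEG(s) found; ratio arms skipped",
           length(degs))
    }
    clin <- as.matrix(study$normal$clinical[, c("age", "stage")])
    ev <- rbind(ev, repeated_holdout(list(clinical = clin), study$normal$time,
                                     study$normal$event,
                                     list(cox = model_cox()),
                                     n_repeats = n_repeats, seed = seed))
    class(ev) <- c("eval_table", "data.frame")
  }
  comparisons <- compare_groups(ev, list(
    list(a = list(data_type = "normal"), b = list(data_type = "tumor")),
    list(a = list(data_type = "normal_screened"), b = list(data_type = "normal")),
    list(a = list(data_type = "tumor_screened"), b = list(data_type = "tumor"))
  ))
  list(study = study, screening_cohort = screen, rankings = rankings,
       selected = selected, eval = ev, comparisons = comparisons)
}
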