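make_eval_study <- function(seed = 301) {
  simulate_paired_study(simulation_config(
    n_patients = 120, n_genes = 60, n_prog_normal = 10, n_deg = 8, seed = seed))
}

test_that("the harness reproduces a direct single-split computation", {
  st <- make_eval_study()
  clin <- as.matrix(st$tumor$clinical[, c("age", "stage")])
  tab <- repeated_holdout(list(clinical = clin), st$tumor$time, st$tumor$event,
                          models = list(cox = model_cox()),
                          n_repeats = 1, seed = 5, standardize = "none")
  expect_equal(nrow(tab), 1L)
  # recompute outside the harness on the identical split
  sp <- pairsurv:::event_stratified_split(st$tumor$event, 0.7, seed = 5 + 1)
  fit <- fit_cox(clin[sp$train, ], st$tumor$time[sp$train], st$tumor$event[sp$train])
  ci <- concordance_index(st$tumor$time[sp$test], st$tumor$event[sp$test],
                          linear_predictor(fit, clin[sp$test, ]))
  expect_equal(tab$c_index, ci)
})

test_that("every model and data type shares the split within a repetition", {
  st <- make_eval_study()
  Xn <- st$normal$expression
  Xt <- st$tumor$expression
  tab <- repeated_holdout(
    list(normal = Xn, tumor = Xt), st$tumor$time, st$tumor$event,
    models = list(cox = model_cox(ridge_lambda = 5),
                  nn = model_cox_nn(train_config(max_epochs = 20, seed = 1))),
    n_repeats = 3, seed = 11)
  expect_s3_class(tab, "eval_table")
  expect_equal(nrow(tab), 3 * 2 * 2)
  by_rep <- split(tab$split_id, tab$repetition)
  for (ids in by_rep) expect_length(unique(ids), 1L)
  expect_true(all(tab$c_index >= 0 & tab$c_index <= 1))
  # end-to-end reproducibility from the master seed
  tab2 <- repeated_holdout(
    list(normal = Xn, tumor = Xt), st$tumor$time, st$tumor$event,
    models = list(cox = model_cox(ridge_lambda = 5),
                  nn = model_cox_nn(train_config(max_epochs = 20, seed = 1))),
    n_repeats = 3, seed = 11)
  expect_identical(tab, tab2)
})

test_that("permuted survival times pull every data type to chance", {
  st <- make_eval_study()
  n <- length(st$tumor$time)
  tabs <- lapply(1:5, function(k) {
    perm <- withr::with_seed(13 + k, sample(n))
    repeated_holdout(
      list(normal = st$normal$expression, tumor = st$tumor$expression),
      st$tumor$time[perm], st$tumor$event[perm],
      models = list(cox = model_cox(ridge_lambda = 10)),
      n_repeats = 10, seed = 17 + k)
  })
  tab <- do.call(rbind, tabs)
  means <- tapply(tab$c_index, tab$data_type, mean)
  expect_true(all(abs(means - 0.5) < 0.03))
})

test_that("informative-gene density flags strong univariate predictors", {
  withr::with_seed(19, {
    n <- 80
    time <- sort(rexp(n) + 0.01)
    expr <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4)))
  })
  expr[, 2] <- -log(time)  # monotone in survival: near-perfect ranking
  dens <- suppressWarnings(suppressMessages(informative_gene_density(
    standardize_genes(expr), time, rep(1L, n))))
  expect_length(dens$c_index, 4L)
  expect_gt(dens$c_index[["g2"]], 0.95)
  expect_true(dens$informative_fraction >= 0.25)
})

test_that("feature sweep at full size equals the baseline and validates sizes", {
  st <- make_eval_study()
  X <- st$normal$expression
  rk <- data.frame(gene = sort(colnames(X)))
  sw <- feature_size_sweep(rk, c(5, ncol(X)), X, st$normal$time, st$normal$event,
                           model_cox(ridge_lambda = 5), n_iter = 3, seed = 23)
  expect_equal(sw$sweep$mean_c_index[2], sw$baseline)
  expect_true(sw$best_size %in% c(5, ncol(X)))
  expect_error(
    feature_size_sweep(rk, ncol(X) + 1, X, st$normal$time, st$normal$event,
                       model_cox(), n_iter = 2),
    "sizes")
})

test_that("median-risk grouping separates planted risk and rejects constants", {
  withr::with_seed(29, {
    n <- 120
    risk <- rnorm(n)
    time <- -log(runif(n)) / (0.1 * exp(1.5 * risk))
    event <- rep(1L, n)
  })
  grp <- median_risk_grouping(risk, time, event)
  expect_equal(sum(grp$group == "low"), 60L)
  expect_lt(grp$p.value, 0.05)
  expect_true(all(diff(grp$km$high$survival) <= 1e-12))
  expect_error(median_risk_grouping(rep(1, 10), rexp(10) + 0.1, rep(1L, 10)),
               "median")
  # null risks: separation should rarely be significant
  ps <- withr::with_seed(31, replicate(40, {
    r <- rnorm(60)
    t <- rexp(60) + 0.01
    median_risk_grouping(r, t, rep(1L, 60))$p.value
  }))
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("cross-cohort similarity is exact in the identity case", {
  st <- make_eval_study()
  out <- suppressMessages(cross_cohort_similarity(st$normal, st$normal))
  expect_equal(out$table$train_c, out$table$test_c)
  expect_equal(out$r, 1)
})

test_that("fold changes correlate with coefficients only under aligned planting", {
  cfg_al <- simulation_config(n_patients = 250, n_genes = 120, n_prog_normal = 15,
                              beta_normal = 0.8, align_deg_with_prognostic = TRUE,
                              deg_log2fc = 3, prog_cor = 0, seed = 37)
  st_al <- simulate_paired_study(cfg_al)
  de_al <- de_table(names(st_al$truth$deg_log2fc),
                    st_al$truth$deg_log2fc + withr::with_seed(1, rnorm(120, 0, 0.1)),
                    rep(0.01, 120))
  r_al <- lfc_vs_coef_correlation(de_al, st_al$normal)$r
  expect_gt(r_al, 0.3)
  cfg_in <- simulation_config(n_patients = 250, n_genes = 400, n_prog_normal = 15,
                              beta_normal = 0.8, n_deg = 20, deg_log2fc = 3,
                              prog_cor = 0, seed = 38)
  st_in <- simulate_paired_study(cfg_in)
  de_in <- de_table(names(st_in$truth$deg_log2fc),
                    st_in$truth$deg_log2fc + withr::with_seed(2, rnorm(400, 0, 0.1)),
                    rep(0.01, 400))
  expect_lt(abs(lfc_vs_coef_correlation(de_in, st_in$normal)$r), 0.2)
  de0 <- de_table(st_in$normal$gene_ids, rep(0, 400), rep(0.5, 400))
  expect_error(lfc_vs_coef_correlation(de0, st_in$normal), "zero variance")
})

test_that("group comparisons pair shared splits and adjust across the family", {
  tab <- data.frame(
    data_type = rep(c("normal", "tumor"), each = 50),
    model = "nn",
    repetition = rep(1:50, 2),
    split_id = rep(sprintf("r%03d", 1:50), 2),
    c_index = c(withr::with_seed(41, runif(50, 0.55, 0.75))),
    stringsAsFactors = FALSE)
  tab$c_index[tab$data_type == "tumor"] <-
    tab$c_index[tab$data_type == "normal"] - 0.1 +
    withr::with_seed(42, rnorm(50, 0, 0.02))
  class(tab) <- c("eval_table", "data.frame")
  res <- compare_groups(tab, list(a = list(data_type = "normal"),
                                  b = list(data_type = "tumor")))
  expect_equal(res$test, "signed-rank")
  expect_lt(res$p_adj, 0.05)
  expect_equal(res$p, res$p_adj)  # single comparison: adjustment is identity
  # identical groups give p = 1
  same <- compare_groups(tab, list(a = list(data_type = "normal"),
                                   b = list(data_type = "normal")))
  expect_equal(same$p, 1)
  expect_error(compare_groups(tab, list(a = list(data_type = "ratio"),
                                        b = list(data_type = "tumor"))),
               "empty group")
})

test_that("eval tables serialize to TSV", {
  tab <- data.frame(data_type = "normal", model = "cox", repetition = 1L,
                    split_id = "r001", c_index = 0.7)
  class(tab) <- c("eval_table", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_table(tab, f)
  expect_equal(read.table(f, header = TRUE)$c_index, 0.7)
})
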