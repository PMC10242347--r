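# Paired tumor/normal study simulator. Survival follows a proportional-
# hazards model whose linear predictor combines clinical covariates with
# latent standardized signals planted in a chosen set of prognostic
# genes; expression is the latent signal mapped through exp() so
# matrices are FPKM-like (nonnegative, right-skewed). Tumor stage is
# coupled to the latent disease severity so that a clinical-only Cox
# predictor carries a trace of the planted genes -- the property that
# makes external-cohort distance-correlation screening meaningful.

#' Simulation configuration
#'
#' @param n_patients number of patients (each contributes one tumor and
#'   one paired normal sample).
#' @param n_genes number of genes.
#' @param n_prog_normal,n_prog_tumor numbers of genes whose normal-tissue
#'   (resp. tumor-tissue) latent signal enters the hazard; the two
#'   planted sets are disjoint and together at most `n_genes`.
#' @param beta_normal,beta_tumor per-gene log-hazard effect sizes.
#' @param n_deg number of planted differentially expressed genes.
#' @param deg_log2fc planted tumor-vs-normal log2 fold change.
#' @param clin_effects named log-hazard effects `c(age = , stage = )`,
#'   per year (age centered at 62.5) and per stage level (centered at 2).
#' @param baseline_hazard events per time unit at linear predictor 0.
#' @param censor_rate expected censored fraction in `[0, 1)`; censoring
#'   times are independent exponentials whose rate is solved so the
#'   expected censored fraction equals this value.
#' @param noise_sd residual log-scale expression noise.
#' @param prog_cor in `[0, 1)`: loading of planted prognostic genes on a
#'   shared latent severity factor (co-expression within the prognostic
#'   module); 0 = independent genes.
#' @param stage_coupling in `[0, 1]`: correlation between latent disease
#'   severity (the standardized gene contribution to the hazard) and the
#'   continuous score that is discretized into tumor stage.
#' @param shared_normal_fraction in `[0, 1]`: weight with which a
#'   screening cohort preserves this study's normal-tissue gene effects.
#' @param tumor_divergence in `[0, 1]`: weight with which a screening
#'   cohort re-draws the tumor-tissue gene effects.
#' @param align_deg_with_prognostic when `TRUE` the planted DEGs are the
#'   normal-prognostic genes themselves (fold change aligned with the
#'   hazard effect); default `FALSE` plants DEGs independently.
#' @param seed integer seed; identical seeds give bit-identical studies.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 300, n_genes = 500,
                              n_prog_normal = 30, n_prog_tumor = 0,
                              beta_normal = 0.6, beta_tumor = 0.6,
                              n_deg = 40, deg_log2fc = 3,
                              clin_effects = c(age = 0.02, stage = 0.3),
                              baseline_hazard = 0.05, censor_rate = 0.3,
                              noise_sd = 0.3, prog_cor = 0.3,
                              stage_coupling = 0.8,
                              shared_normal_fraction = 0.9,
                              tumor_divergence = 0.9,
                              align_deg_with_prognostic = FALSE,
                              seed = 1) {
  if (!is_count(n_patients) || n_patients < 2)
    stopf("simulation_config: n_patients must be an integer >= 2")
  if (!is_count(n_genes)) stopf("simulation_config: n_genes must be a positive integer")
  for (v in c(n_prog_normal, n_prog_tumor, n_deg))
    if (!(is.numeric(v) && length(v) == 1 && v >= 0 && v == round(v)))
      stopf("simulation_config: planted counts must be nonnegative integers")
  if (n_prog_normal + n_prog_tumor > n_genes)
    stopf("simulation_config: n_prog_normal + n_prog_tumor exceeds n_genes")
  if (n_deg > n_genes) stopf("simulation_config: n_deg exceeds n_genes")
  if (censor_rate < 0 || censor_rate >= 1)
    stopf("simulation_config: censor_rate must lie in [0, 1)")
  if (baseline_hazard <= 0) stopf("simulation_config: baseline_hazard must be > 0")
  if (noise_sd < 0) stopf("simulation_config: noise_sd must be >= 0")
  for (v in c(prog_cor, stage_coupling, shared_normal_fraction, tumor_divergence))
    if (v < 0 || v > 1) stopf("simulation_config: fractions must lie in [0, 1]")
  if (prog_cor >= 1) stopf("simulation_config: prog_cor must be < 1")
  if (!all(c("age", "stage") %in% names(clin_effects)))
    stopf("simulation_config: clin_effects needs named entries 'age' and 'stage'")
  structure(as.list(environment()), class = "simulation_config")
}

#' Draw proportional-hazards event times
#'
#' Inverse-transform sampling from an exponential baseline: the event
#' time of subject i is `-log(U_i) / (baseline_hazard * exp(lp_i))`, so
#' doubling `exp(lp)` halves both the mean and the median time.
#'
#' @param lp linear predictor per subject.
#' @param baseline_hazard positive baseline rate.
#' @return numeric event times (no censoring applied).
#' @export
sample_ph_times <- function(lp, baseline_hazard) {
  if (baseline_hazard <= 0) stopf("sample_ph_times: baseline_hazard must be > 0")
  -log(runif(length(lp))) / (baseline_hazard * exp(lp))
}

# Censoring rate c solving mean(c / (c + h)) = censor_rate for the
# realized hazards h (exponential event and censoring times).
solve_censor_rate <- function(h, censor_rate) {
  f <- function(logc) mean(exp(logc) / (exp(logc) + h)) - censor_rate
  lo <- min(log(h)) - 30
  hi <- max(log(h)) + 30
  exp(uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

stage_probs <- c(0.30, 0.35, 0.25, 0.10)

# Core generator shared by the discovery and screening cohorts: takes
# full-length per-gene effect vectors and gene baselines, returns a
# paired_study. Must be called inside a seeded context.
generate_paired_cohorts <- function(config, b_norm, b_tum, lfc, mu,
                                    cohort_id) {
  n <- config$n_patients
  G <- config$n_genes
  genes <- names(mu)
  L_n <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, genes))
  L_t <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, genes))
  a <- config$prog_cor
  if (a > 0) {
    for (L_b in c("n", "t")) {
      b <- if (L_b == "n") b_norm else b_tum
      supp <- which(b != 0)
      if (length(supp) >= 2) {
        f <- rnorm(n)
        if (L_b == "n") {
          L_n[, supp] <- a * f + sqrt(1 - a^2) * L_n[, supp]
        } else {
          L_t[, supp] <- a * f + sqrt(1 - a^2) * L_t[, supp]
        }
      }
    }
  }
  gene_lp <- drop(L_n %*% b_norm + L_t %*% b_tum)
  severity <- if (sd(gene_lp) > 0) (gene_lp - mean(gene_lp)) / sd(gene_lp)
              else numeric(n)
  sc <- config$stage_coupling
  stage_score <- sc * severity + sqrt(1 - sc^2) * rnorm(n)
  stage <- findInterval(stage_score, qnorm(cumsum(stage_probs)[1:3])) + 1L
  age <- runif(n, 40, 85)
  lp <- config$clin_effects[["age"]] * (age - 62.5) +
    config$clin_effects[["stage"]] * (stage - 2) + gene_lp
  t_event <- sample_ph_times(lp, config$baseline_hazard)
  if (config$censor_rate > 0) {
    h <- config$baseline_hazard * exp(lp)
    crate <- solve_censor_rate(h, config$censor_rate)
    t_cens <- -log(runif(n)) / crate
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  expr_n <- exp(sweep(L_n + config$noise_sd * matrix(rnorm(n * G), n, G),
                      2, mu, "+"))
  expr_t <- exp(sweep(L_t + config$noise_sd * matrix(rnorm(n * G), n, G),
                      2, mu + log(2) * lfc, "+"))
  pid <- sprintf("P%04d", seq_len(n))
  rownames(expr_n) <- paste0(pid, "_N")
  rownames(expr_t) <- paste0(pid, "_T")
  clinical <- data.frame(age = age, stage = stage)
  truth <- list(
    prognostic_normal = genes[b_norm != 0],
    prognostic_tumor = genes[b_tum != 0],
    degs = genes[lfc != 0],
    beta_normal = b_norm,
    beta_tumor = b_tum,
    deg_log2fc = lfc,
    gene_means = mu,
    linear_predictor = lp,
    config = config
  )
  structure(list(
    tumor = survival_cohort(expr_t, time, event, clinical, "tumor",
                            pairing = pid, cohort_id = cohort_id),
    normal = survival_cohort(expr_n, time, event, clinical, "normal",
                             pairing = pid, cohort_id = cohort_id),
    pairing = data.frame(patient_id = pid,
                         tumor_sample = paste0(pid, "_T"),
                         normal_sample = paste0(pid, "_N"),
                         stringsAsFactors = FALSE),
    truth = truth
  ), class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("paired_study: %d patients x %d genes ",
                     "(%d normal-prognostic, %d tumor-prognostic, %d DEGs), ",
                     "%d events\n"),
              cfg$n_patients, cfg$n_genes,
              length(x$truth$prognostic_normal),
              length(x$truth$prognostic_tumor),
              length(x$truth$degs), sum(x$tumor$event)))
  invisible(x)
}

#' Simulate a paired tumor/normal study
#'
#' Generates paired tumor and adjacent-normal expression with planted
#' prognostic genes, planted DEG fold changes, clinical covariates, and
#' proportional-hazards survival with independent censoring calibrated
#' to the configured rate. The returned `truth` element lists the
#' planted structure for downstream validation.
#'
#' @param config a [simulation_config()].
#' @return list of class `paired_study`: `tumor` and `normal`
#'   (`survival_cohort`s sharing patients, times, events and clinical
#'   covariates), `pairing` (patient id map), `truth`.
#' @export
simulate_paired_study <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stopf("simulate_paired_study: need a simulation_config")
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  withr::with_seed(config$seed, {
    prog_n <- sample(genes, config$n_prog_normal)
    prog_t <- sample(setdiff(genes, prog_n), config$n_prog_tumor)
    degs <- if (config$align_deg_with_prognostic) prog_n
            else sample(genes, config$n_deg)
    b_norm <- stats::setNames(numeric(config$n_genes), genes)
    b_norm[prog_n] <- config$beta_normal
    b_tum <- stats::setNames(numeric(config$n_genes), genes)
    b_tum[prog_t] <- config$beta_tumor
    lfc <- stats::setNames(numeric(config$n_genes), genes)
    lfc[degs] <- config$deg_log2fc
    # log-scale gene baselines: exp(3) ~ 20 FPKM-like median expression
    mu <- stats::setNames(rnorm(config$n_genes, mean = 3, sd = 1), genes)
    generate_paired_cohorts(config, b_norm, b_tum, lfc, mu,
                            cohort_id = "discovery")
  })
}

#' Simulate an external screening cohort
#'
#' Draws a second paired cohort over the same gene universe whose
#' normal-tissue gene effects are a `shared_normal_fraction`-weighted
#' blend of the source study's effects with a freshly planted effect
#' vector, and whose tumor-tissue effects are re-drawn with weight
#' `tumor_divergence`. This emulates an external dataset in which the
#' prognostic structure of adjacent normal tissue transfers across
#' cohorts while tumor-tissue structure is cohort-specific.
#'
#' @param study the source `paired_study` (must carry `truth`).
#' @param config a [simulation_config()]; `shared_normal_fraction`,
#'   `tumor_divergence` and the cohort dimensions are taken from it.
#' @param seed seed for the screening cohort; defaults to
#'   `config$seed + 1`.
#' @return a `paired_study` for the screening cohort.
#' @export
simulate_screening_cohort <- function(study, config, seed = NULL) {
  if (is.null(study$truth))
    stopf("simulate_screening_cohort: study carries no truth element")
  if (is.null(seed)) seed <- config$seed + 1L
  genes <- names(study$truth$beta_normal)
  s <- config$shared_normal_fraction
  d <- config$tumor_divergence
  withr::with_seed(seed, {
    b_n_new <- stats::setNames(numeric(length(genes)), genes)
    b_n_new[sample(genes, config$n_prog_normal)] <- config$beta_normal
    b_t_new <- stats::setNames(numeric(length(genes)), genes)
    if (config$n_prog_tumor > 0)
      b_t_new[sample(genes, config$n_prog_tumor)] <- config$beta_tumor
    b_norm <- s * study$truth$beta_normal + (1 - s) * b_n_new
    b_tum <- (1 - d) * study$truth$beta_tumor + d * b_t_new
    generate_paired_cohorts(config, b_norm, b_tum,
                            study$truth$deg_log2fc,
                            study$truth$gene_means,
                            cohort_id = "screening")
  })
}
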