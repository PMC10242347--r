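# Independent oracles used across tests. Each reimplements a definition
# directly (loops, enumeration, closed form) and must stay independent of
# the package's own computational path.

# Szekely's dCov^2 / dCor by the definitional S1 + S2 - 2*S3 sums,
# written as explicit loops over index tuples.
naive_dcov2 <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n)
  b <- matrix(0, n, n)
  for (k in 1:n) for (l in 1:n) {
    a[k, l] <- abs(x[k] - x[l])
    b[k, l] <- abs(y[k] - y[l])
  }
  S1 <- 0
  S2a <- 0
  S2b <- 0
  for (k in 1:n) for (l in 1:n) {
    S1 <- S1 + a[k, l] * b[k, l]
    S2a <- S2a + a[k, l]
    S2b <- S2b + b[k, l]
  }
  S1 <- S1 / n^2
  S2 <- (S2a / n^2) * (S2b / n^2)
  S3 <- 0
  for (k in 1:n) for (l in 1:n) for (m in 1:n)
    S3 <- S3 + a[k, l] * b[k, m]
  S3 <- S3 / n^3
  S1 + S2 - 2 * S3
}

naive_dcor <- function(x, y) {
  v2 <- naive_dcov2(x, y)
  vx <- naive_dcov2(x, x)
  vy <- naive_dcov2(y, y)
  if (vx <= 0 || vy <= 0) return(0)
  sqrt(max(v2, 0)) / sqrt(sqrt(vx * vy))
}

# Harrell's C by exhaustive pair enumeration.
exhaustive_cindex <- function(time, event, risk) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Cox partial log-likelihood (Breslow ties) by direct summation over
# events and risk sets.
naive_cox_pll <- function(beta, X, time, event) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[rs])))
  }
  ll
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
exact_ranksum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Brute-force Benjamini-Hochberg by the max-min step-up definition.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(o == i)  # rank position of p[i]
    adj[i] <- min(1, min(p[o[k:m]] * m / (k:m)))
  }
  adj
}

# Flatten/unflatten a cox_nn parameter vector (mirrors the layout used
# by the package but computed here independently for finite differences).
nn_unflatten <- function(model, v) {
  i <- 1L
  for (l in seq_along(model$weights)) {
    k <- length(model$weights[[l]])
    model$weights[[l]][] <- v[i:(i + k - 1L)]
    i <- i + k
  }
  for (l in seq_along(model$biases)) {
    k <- length(model$biases[[l]])
    model$biases[[l]][] <- v[i:(i + k - 1L)]
    i <- i + k
  }
  model
}

nn_flatten <- function(model) unlist(c(model$weights, model$biases), use.names = FALSE)

# Central finite-difference gradient of the penalized NN loss.
nn_numeric_grad <- function(model, X, time, event, lambda, eps = 1e-6) {
  th <- nn_flatten(model)
  g <- numeric(length(th))
  for (i in seq_along(th)) {
    up <- th
    up[i] <- up[i] + eps
    dn <- th
    dn[i] <- dn[i] - eps
    mu <- nn_unflatten(model, up)
    md <- nn_unflatten(model, dn)
    g[i] <- (cox_nn_loss(nn_forward(mu, X), time, event, lambda, mu) -
             cox_nn_loss(nn_forward(md, X), time, event, lambda, md)) / (2 * eps)
  }
  g
}

# Two-group exponential proportional-hazards data with a binary covariate.
make_two_group_data <- function(n, log_hr, censor_rate = 0.25, seed = 1) {
  withr::with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    t0 <- -log(runif(n)) / (0.1 * exp(log_hr * x))
    cens <- if (censor_rate > 0) -log(runif(n)) / (0.1 * censor_rate / (1 - censor_rate))
            else rep(Inf, n)
    list(x = x, time = pmin(t0, cens), event = as.integer(t0 <= cens))
  })
}

# Random censored survival instance for C-index / KM checks.
random_survival_instance <- function(n, tie_prob = 0.3) {
  time <- if (runif(1) < tie_prob) sample(1:5, n, replace = TRUE)
          else round(rexp(n, 0.3), 3) + 0.001
  event <- rbinom(n, 1, 0.6)
  if (sum(event) == 0) event[sample(n, 1)] <- 1L
  risk <- if (runif(1) < tie_prob) sample(1:4, n, replace = TRUE) else rnorm(n)
  list(time = time, event = event, risk = risk)
}

# Tiny survival cohort with expression for module-level tests.
make_test_cohort <- function(n = 60, g = 20, seed = 1, tissue = "normal",
                             beta = NULL) {
  withr::with_seed(seed, {
    expr <- matrix(rexp(n * g, 0.2), n, g,
                   dimnames = list(sprintf("P%03d", 1:n), sprintf("g%03d", 1:g)))
    lp <- if (is.null(beta)) rep(0, n) else drop(scale(log(expr + 1)) %*% beta)
    t0 <- -log(runif(n)) / (0.1 * exp(lp))
    cens <- -log(runif(n)) / 0.04
    clin <- data.frame(age = runif(n, 40, 85), stage = sample(1:4, n, TRUE))
    survival_cohort(expr, pmin(t0, cens), as.integer(t0 <= cens), clin, tissue,
                    pairing = rownames(expr))
  })
}
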