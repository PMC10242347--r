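# Cox partial-likelihood neural network: a small feed-forward network
# whose scalar output is a per-sample log-relative-hazard, trained by
# full-batch gradient descent on the negative Cox partial log-likelihood
# with an L2 penalty. Architecture follows the square-root rule: two
# hidden layers of width ceiling(sqrt(input_dim)).

#' Training configuration for the Cox neural network
#'
#' @param lambda_l2 L2 penalty multiplier on all parameters (>= 0). The
#'   penalized objective is `(-partial_loglik + lambda_l2 * ||theta||^2)`.
#' @param learning_rate positive step size (applied to the per-event
#'   normalized gradient so it transfers across sample sizes).
#' @param max_epochs number of full-batch epochs.
#' @param seed integer seed controlling weight initialization (training
#'   itself is deterministic).
#' @param activation `"tanh"` (default) or `"relu"`, one activation for
#'   both hidden layers.
#' @param hidden integer vector of hidden-layer widths; `NULL` (default)
#'   applies the square-root rule `rep(ceiling(sqrt(d)), 2)`; use
#'   `integer(0)` for a depth-0 (linear) model.
#' @param optimizer `"gd"` (plain gradient descent, default) or
#'   `"adam"`.
#' @param patience optional early-stopping patience: when set, a
#'   `validation_fraction` event-stratified hold-out is monitored and
#'   training stops after `patience` epochs without improvement,
#'   returning the best weights.
#' @param validation_fraction fraction held out when `patience` is set.
#' @return list of class `train_config`.
#' @export
train_config <- function(lambda_l2 = 1e-4, learning_rate = 0.05,
                         max_epochs = 300, seed = 1,
                         activation = c("tanh", "relu"), hidden = NULL,
                         optimizer = c("gd", "adam"), patience = NULL,
                         validation_fraction = 0.2) {
  if (lambda_l2 < 0) stopf("train_config: lambda_l2 must be >= 0")
  if (learning_rate <= 0) stopf("train_config: learning_rate must be > 0")
  if (!is_count(max_epochs)) stopf("train_config: max_epochs must be a positive integer")
  structure(list(lambda_l2 = lambda_l2, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 activation = match.arg(activation), hidden = hidden,
                 optimizer = match.arg(optimizer), patience = patience,
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Initialize a Cox neural network
#'
#' Weights are drawn uniformly on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`
#' under the given seed; biases start at zero.
#'
#' @param input_dim number of input features.
#' @param hidden hidden widths (`NULL` = square-root rule, two layers).
#' @param activation `"tanh"` or `"relu"`.
#' @param seed integer seed.
#' @return list of class `cox_nn` with `weights`, `biases`,
#'   `layer_widths`, `activation`.
#' @export
cox_nn <- function(input_dim, hidden = NULL, activation = c("tanh", "relu"),
                   seed = 1) {
  activation <- match.arg(activation)
  if (is.null(hidden)) hidden <- rep(ceiling(sqrt(input_dim)), 2)
  widths <- c(input_dim, hidden, 1L)
  nl <- length(widths) - 1L
  weights <- vector("list", nl)
  biases <- vector("list", nl)
  withr::with_seed(seed, {
    for (l in seq_len(nl)) {
      s <- 1 / sqrt(widths[l])
      weights[[l]] <- matrix(runif(widths[l] * widths[l + 1], -s, s),
                             widths[l], widths[l + 1])
      biases[[l]] <- numeric(widths[l + 1])
    }
  })
  structure(list(weights = weights, biases = biases,
                 layer_widths = widths, activation = activation),
            class = "cox_nn")
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}

act_grad <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - tanh(z)^2
}

# Forward pass keeping pre-activations and layer inputs for backprop.
nn_forward_cache <- function(model, X) {
  nl <- length(model$weights)
  A <- vector("list", nl + 1L)
  Z <- vector("list", nl)
  A[[1]] <- X
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(A[[l]] %*% model$weights[[l]], 2, model$biases[[l]], "+")
    A[[l + 1]] <- if (l < nl) act_fun(Z[[l]], model$activation) else Z[[l]]
  }
  list(h = drop(A[[nl + 1L]]), A = A, Z = Z)
}

#' Forward pass of a Cox neural network
#'
#' @param model a `cox_nn`.
#' @param X samples x features matrix with `ncol(X)` equal to the input
#'   width.
#' @return numeric risk score per sample (log-relative-hazard scale).
#' @export
nn_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_widths[1])
    stopf("nn_forward: X has %d columns, model expects %d",
          ncol(X), model$layer_widths[1])
  nn_forward_cache(model, X)$h
}

flatten_params <- function(model) {
  unlist(c(model$weights, model$biases), use.names = FALSE)
}

#' Cox partial-likelihood network loss
#'
#' Negative penalized partial log-likelihood
#' `-(sum_{i: E_i=1} h_i - sum_k d_k log sum_{j: t_j >= tau_k} exp(h_j))
#' + lambda_l2 * ||theta||^2`, with the risk set of an event at time
#' `tau_k` being all samples still under observation (`t_j >= tau_k`),
#' tied event times sharing one risk set (Breslow), and the log-sum-exp
#' computed stably.
#'
#' @param h per-sample network outputs.
#' @param time,event survival outcome; at least one event required.
#' @param lambda_l2 penalty multiplier.
#' @param theta optional parameter vector (or a `cox_nn`) entering the
#'   penalty; omitted or `NULL` means no penalty term.
#' @return scalar loss in the sum form of the objective (not averaged
#'   over events); training divides gradients by the event count only to
#'   normalize the step size.
#' @export
cox_nn_loss <- function(h, time, event, lambda_l2 = 0, theta = NULL) {
  check_time_event(time, event)
  if (length(h) != length(time)) stopf("cox_nn_loss: lengths differ")
  if (sum(event) == 0) stopf("cox_nn_loss: no events")
  o <- order(time)
  hs <- h[o]
  ts <- time[o]
  es <- event[o]
  m <- max(hs)
  w <- exp(hs - m)
  n <- length(hs)
  first <- c(TRUE, ts[-1] != ts[-n])
  block_start <- which(first)
  block_id <- cumsum(first)
  cw <- rev_cumsum(w)
  d_per_block <- tapply(es, block_id, sum)
  ev_blocks <- which(d_per_block > 0)
  log_s <- log(cw[block_start[ev_blocks]]) + m
  pll <- sum(hs[es == 1]) - sum(d_per_block[ev_blocks] * log_s)
  pen <- 0
  if (!is.null(theta) && lambda_l2 > 0) {
    if (inherits(theta, "cox_nn")) theta <- flatten_params(theta)
    pen <- lambda_l2 * sum(theta^2)
  }
  -pll + pen
}

# Gradient of the (unpenalized) negative partial log-likelihood wrt h.
cox_nn_grad_h <- function(h, time, event) {
  o <- order(time)
  hs <- h[o]
  ts <- time[o]
  es <- event[o]
  n <- length(hs)
  m <- max(hs)
  w <- exp(hs - m)
  first <- c(TRUE, ts[-1] != ts[-n])
  block_start <- which(first)
  block_id <- cumsum(first)
  cw <- rev_cumsum(w)
  d_per_block <- as.numeric(tapply(es, block_id, sum))
  ratio <- d_per_block / cw[block_start]   # d_k / S_k (shifted scale)
  cum_ratio <- cumsum(ratio)               # over blocks in time order
  g_sorted <- -es + w * cum_ratio[block_id]
  g <- numeric(n)
  g[o] <- g_sorted
  g
}

# Full gradient of the penalized objective wrt all weights and biases.
cox_nn_backprop <- function(model, X, time, event, lambda_l2) {
  fc <- nn_forward_cache(model, X)
  gh <- cox_nn_grad_h(fc$h, time, event)
  nl <- length(model$weights)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- matrix(gh, ncol = 1)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(fc$A[[l]], delta) + 2 * lambda_l2 * model$weights[[l]]
    gb[[l]] <- colSums(delta) + 2 * lambda_l2 * model$biases[[l]]
    if (l > 1)
      delta <- (delta %*% t(model$weights[[l]])) * act_grad(fc$Z[[l - 1]], model$activation)
  }
  list(gW = gW, gb = gb, h = fc$h)
}

#' Train a Cox neural network
#'
#' Full-batch gradient descent (or Adam, by flag) on the penalized
#' negative partial log-likelihood. The gradient step is normalized by
#' the number of events so `learning_rate` transfers across sample
#' sizes. Training is deterministic given `config$seed` and the data.
#'
#' @param X standardized samples x features matrix.
#' @param time,event survival outcome.
#' @param config a [train_config()].
#' @return a trained `cox_nn` with a `training` element: a data.frame of
#'   `(epoch, loss)` on the per-event scale (and `val_loss` when early
#'   stopping is active).
#' @export
train_cox_nn <- function(X, time, event, config = train_config()) {
  X <- as.matrix(X)
  check_time_event(time, event)
  if (sum(event) == 0) stopf("train_cox_nn: no events")
  model <- cox_nn(ncol(X), hidden = config$hidden,
                  activation = config$activation, seed = config$seed)
  val_idx <- integer(0)
  if (!is.null(config$patience)) {
    folds <- event_stratified_split(event, 1 - config$validation_fraction,
                                    config$seed)
    val_idx <- folds$test
  }
  tr_idx <- setdiff(seq_along(time), val_idx)
  Xt <- X[tr_idx, , drop = FALSE]
  tt <- time[tr_idx]
  et <- event[tr_idx]
  ne <- sum(et)
  nl <- length(model$weights)
  mW <- lapply(model$weights, function(w) w * 0)
  vW <- mW
  mb <- lapply(model$biases, function(b) b * 0)
  vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  log_rows <- vector("list", config$max_epochs)
  best <- list(loss = Inf, weights = model$weights, biases = model$biases,
               since = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    bp <- cox_nn_backprop(model, Xt, tt, et, config$lambda_l2)
    loss <- cox_nn_loss(bp$h, tt, et, config$lambda_l2, model) / ne
    if (!is.finite(loss))
      stopf("train_cox_nn: loss diverged at epoch %d; reduce learning_rate", epoch)
    for (l in seq_len(nl)) {
      gW <- bp$gW[[l]] / ne
      gb <- bp$gb[[l]] / ne
      if (config$optimizer == "adam") {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        c1 <- 1 - b1^epoch
        c2 <- 1 - b2^epoch
        model$weights[[l]] <- model$weights[[l]] -
          config$learning_rate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        model$biases[[l]] <- model$biases[[l]] -
          config$learning_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      } else {
        model$weights[[l]] <- model$weights[[l]] - config$learning_rate * gW
        model$biases[[l]] <- model$biases[[l]] - config$learning_rate * gb
      }
    }
    row <- data.frame(epoch = epoch, loss = loss)
    if (length(val_idx)) {
      hv <- nn_forward(model, X[val_idx, , drop = FALSE])
      vl <- cox_nn_loss(hv, time[val_idx], event[val_idx],
                        config$lambda_l2, model) / max(1, sum(event[val_idx]))
      row$val_loss <- vl
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, weights = model$weights,
                     biases = model$biases, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) {
          log_rows[[epoch]] <- row
          model$weights <- best$weights
          model$biases <- best$biases
          break
        }
      }
    }
    log_rows[[epoch]] <- row
  }
  model$training <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  model$config <- config
  model
}

#' Save / load a Cox neural network checkpoint as JSON
#'
#' @param model a `cox_nn`.
#' @param path JSON path.
#' @export
save_cox_nn <- function(model, path) {
  jsonlite::write_json(list(
    layer_widths = model$layer_widths,
    activation = model$activation,
    weights = lapply(model$weights, function(w) apply(w, 1, identity, simplify = FALSE)),
    biases = model$biases
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_cox_nn
#' @export
load_cox_nn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  widths <- as.integer(unlist(obj$layer_widths))
  nl <- length(widths) - 1L
  weights <- lapply(seq_len(nl), function(l) {
    rows <- lapply(obj$weights[[l]], function(r) as.numeric(unlist(r)))
    matrix(unlist(rows), widths[l], widths[l + 1], byrow = TRUE)
  })
  biases <- lapply(seq_len(nl), function(l) as.numeric(unlist(obj$biases[[l]])))
  structure(list(weights = weights, biases = biases,
                 layer_widths = widths, activation = obj$activation),
            class = "cox_nn")
}

#' Survival model adapter contract
#'
#' A uniform fit/predict interface so the evaluation harness treats the
#' built-in models and external learners (e.g. random survival forests
#' or survival SVMs from other packages) identically. `fit` receives
#' `(X, time, event)` and returns any object; `predict_risk` receives
#' `(object, X)` and returns one numeric risk score per row, higher
#' meaning shorter expected survival.
#'
#' @param fit function `(X, time, event) -> object`.
#' @param predict_risk function `(object, X) -> numeric`.
#' @param label character label used in evaluation tables.
#' @return list of class `survival_model`.
#' @export
survival_model <- function(fit, predict_risk, label = "model") {
  if (!is.function(fit) || !is.function(predict_risk))
    stopf("survival_model: fit and predict_risk must be functions")
  structure(list(fit = fit, predict_risk = predict_risk, label = label),
            class = "survival_model")
}

#' Built-in model adapters
#'
#' `model_cox()` wraps the ridge Cox fit; `model_cox_nn()` wraps the Cox
#' partial-likelihood network.
#'
#' @param ridge_lambda,ties passed to [fit_cox()].
#' @return a `survival_model`.
#' @export
model_cox <- function(ridge_lambda = 0, ties = "breslow") {
  survival_model(
    fit = function(X, time, event)
      fit_cox(X, time, event, ridge_lambda = ridge_lambda, ties = ties),
    predict_risk = function(object, X) linear_predictor(object, X),
    label = "cox"
  )
}

#' @rdname model_cox
#' @param config a [train_config()].
#' @export
model_cox_nn <- function(config = train_config()) {
  survival_model(
    fit = function(X, time, event) train_cox_nn(X, time, event, config),
    predict_risk = function(object, X) nn_forward(object, X),
    label = "nn"
  )
}

# Event-stratified train/test split: events and censored samples are
# split separately so both folds keep events.
event_stratified_split <- function(event, train_frac, seed) {
  withr::with_seed(seed, {
    ev <- sample(which(event == 1))
    ce <- sample(which(event == 0))
  })
  n_ev <- max(1L, round(train_frac * length(ev)))
  if (length(ev) > 1L) n_ev <- min(n_ev, length(ev) - 1L)
  n_ce <- round(train_frac * length(ce))
  train <- c(ev[seq_len(n_ev)], if (n_ce > 0) ce[seq_len(n_ce)])
  list(train = sort(train), test = sort(setdiff(seq_along(event), train)))
}

# Event-stratified k folds; resampled until every fold keeps >= 1 event.
event_stratified_folds <- function(event, k, seed) {
  n <- length(event)
  if (sum(event) < k)
    stopf("need at least %d events for %d folds", k, k)
  for (attempt in 1:20) {
    fold <- integer(n)
    withr::with_seed(seed + attempt - 1L, {
      ev <- sample(which(event == 1))
      ce <- sample(which(event == 0))
    })
    fold[ev] <- rep_len(seq_len(k), length(ev))
    fold[ce] <- rep_len(seq_len(k), length(ce))
    ok <- all(vapply(seq_len(k), function(f)
      sum(event[fold == f]) >= 1 && sum(event[fold != f]) >= 1, logical(1)))
    if (ok) return(fold)
  }
  stopf("could not build %d event-stratified folds", k)
}

#' Hyperparameter selection by k-fold cross-validation
#'
#' Event-stratified k-fold cross-validation over a candidate grid;
#' selects the candidate maximizing mean validation concordance. A
#' candidate failing on some folds keeps its remaining folds; one
#' failing on all folds is excluded with a warning. Ties go to the first
#' candidate in grid order.
#'
#' @param model_factory function taking one grid entry and returning a
#'   [survival_model()].
#' @param grid nonempty list of candidate parameter sets.
#' @param X,time,event training data.
#' @param k number of folds (default 3).
#' @param seed integer seed for fold assignment.
#' @return list with `best_params`, `best_index`, and `scores` (mean
#'   validation C-index per candidate, NA when excluded).
#' @export
cv_select_hyperparams <- function(model_factory, grid, X, time, event,
                                  k = 3, seed = 1) {
  if (length(grid) == 0L) stopf("cv_select_hyperparams: empty grid")
  X <- as.matrix(X)
  fold <- event_stratified_folds(event, k, seed)
  scores <- rep(NA_real_, length(grid))
  for (ci in seq_along(grid)) {
    model <- model_factory(grid[[ci]])
    cs <- vapply(seq_len(k), function(f) {
      tryCatch({
        tr <- fold != f
        obj <- model$fit(X[tr, , drop = FALSE], time[tr], event[tr])
        risk <- model$predict_risk(obj, X[!tr, , drop = FALSE])
        concordance_index(time[!tr], event[!tr], risk)
      }, error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(cs))) {
      warnf("cv_select_hyperparams: candidate %d failed on all folds; excluded", ci)
    } else {
      scores[ci] <- mean(cs, na.rm = TRUE)
    }
  }
  if (all(is.na(scores))) stopf("cv_select_hyperparams: all candidates failed")
  best <- which.max(scores)  # first maximum in grid order
  list(best_params = grid[[best]], best_index = best, scores = scores)
}
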