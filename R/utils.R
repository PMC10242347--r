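# Internal helpers shared across modules.

# Column means / population (ddof 0) standard deviations. Standardization
# throughout the package uses the population convention so that repeated
# application is exactly idempotent.
col_means_sds <- function(x) {
  m <- colMeans(x)
  v <- colMeans(x^2) - m^2
  v[v < 0] <- 0
  list(mean = m, sd = sqrt(v))
}

# Apply column scaling with a guard for constant columns (sd -> 1).
scale_columns <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Progress/log note to stderr; suppressible via suppressMessages().
logf <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_time_event <- function(time, event) {
  if (length(time) != length(event))
    stopf("time and event must have equal length")
  if (!all(is.finite(time)) || any(time <= 0))
    stopf("follow-up times must be finite and positive")
  if (!all(event %in% c(0, 1)))
    stopf("event indicators must be 0 or 1")
  invisible(TRUE)
}

# TRUE when at least one usable (comparable) pair exists under Harrell's
# convention: an event at time t_i strictly before some other time t_j.
has_comparable_pairs <- function(time, event) {
  ev <- which(event == 1)
  if (length(ev) == 0L) return(FALSE)
  any(vapply(ev, function(i) any(time > time[i]), logical(1)))
}
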