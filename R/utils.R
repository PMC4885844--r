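# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# If `seed` is NULL the expression runs on the current stream, so callers can
# thread a single set.seed() through a whole experiment.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# log(sum(exp(x))) with max-shift; x may be a matrix (row-wise -> vector).
log_sum_exp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
  } else {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
}

# Row-wise softmax of a matrix (or softmax of a vector), numerically stable.
softmax <- function(x) {
  if (is.matrix(x)) {
    e <- exp(x - apply(x, 1L, max))
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a finite numeric scalar")
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop_invalid(name, " must be ", if (strict) "> " else ">= ", lower)
  }
  invisible(x)
}

# Mean and standard deviation of a normal(mu, sigma) truncated to [0, Inf).
# Used both by the Gaussian model generator (as a cross-check) and by the
# analytic membrane-potential statistics.
truncnorm_moments <- function(mu, sigma) {
  if (sigma == 0) return(list(mean = mu, sd = 0))
  a <- -mu / sigma                      # standardized truncation point
  lambda <- dnorm(a) / (1 - pnorm(a))   # inverse Mills ratio
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 - lambda * (lambda - a))
  list(mean = m, sd = sqrt(v))
}

# Rejection sampler for normal(mu, sigma) truncated to [0, Inf).
# Resampling (not clipping) avoids an atom at zero.
rtruncnorm0 <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  out <- rnorm(n, mu, sigma)
  bad <- which(out < 0)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < 0]
  }
  out
}

# Rejection sampler for lognormal(meanlog, sdlog) truncated to (lmin, lmax).
rtrunclnorm <- function(n, meanlog, sdlog, lmin, lmax) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(out <= lmin | out >= lmax)
  while (length(bad) > 0L) {
    out[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] <= lmin | out[bad] >= lmax]
  }
  out
}
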