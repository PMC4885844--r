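#' @title External world models driving the input layer
#' @description
#' An `external_model` holds the tuning structure of the "world" the network
#' has to infer: `p` hidden states presented uniformly at random, and for
#' each state a row of mean input-layer responses \eqn{\theta_{j\mu}}
#' (states-by-inputs, `p x M`). The natural parameters
#' \eqn{q_{j\mu} = h(\theta_{j\mu})} are precomputed, as is the per-input
#' noise scale vector for Gaussian models (constant unless an inhomogeneous
#' noise profile is attached).
#'
#' Normalization: Gaussian models are scaled per state so the root mean
#' square rate is `rX0` (\eqn{\frac1M\sum_j\theta_{j\mu}^2 = (r_X^o)^2});
#' Poisson models so the mean rate is `rX0`
#' (\eqn{\frac1M\sum_j\theta_{j\mu} = r_X^o}).
#' @name external_model
NULL

new_external_model <- function(theta, theta_tilde, family, rX0, sigma_x,
                               params = list()) {
  p <- nrow(theta); M <- ncol(theta)
  if (family$name == "gaussian") {
    if (length(sigma_x) == 1L) sigma_x <- rep(sigma_x, M)
    stopifnot(length(sigma_x) == M)
    q <- sweep(theta, 2L, sigma_x^2, "/")
  } else {
    sigma_x <- rep(NA_real_, M)
    q <- log(theta)
  }
  structure(list(
    theta = theta, theta_tilde = theta_tilde, q = q,
    p = p, M = M, rX0 = rX0,
    family = family,
    sigma_x = sigma_x,
    sigma_x_base = if (family$name == "gaussian") family$sigma_x else NA_real_,
    params = params
  ), class = "external_model")
}

# Per-state RMS normalization used by all Gaussian constructors.
normalize_rms <- function(theta_tilde, rX0) {
  z <- sqrt(rowMeans(theta_tilde^2)) / rX0
  theta_tilde / z
}

#' Gaussian world model with truncated-normal tuning
#'
#' Raw tuning values \eqn{\tilde\theta_{j\mu}} are drawn independently from a
#' normal distribution \eqn{N(\mu_M, \sigma_M)} truncated to \eqn{[0,\infty)}
#' (negatives are resampled, not clipped), then each state's row is rescaled
#' so that \eqn{\frac1M\sum_j \theta_{j\mu}^2 = (r_X^o)^2}.
#'
#' @param p Number of hidden states (>= 2).
#' @param M Number of input neurons.
#' @param mu_M,sigma_M Location and scale of the truncated normal from which
#'   raw tuning is drawn.
#' @param rX0 Target root-mean-square input rate (> 0).
#' @param sigma_x Input noise scale; a scalar, or a length-`M` vector for
#'   input-dependent noise (see [make_inhomogeneous_noise()]).
#' @param seed Optional integer seed (local to this call).
#' @return An `external_model`.
#' @examples
#' m <- make_gaussian_model(p = 4, M = 50, seed = 1)
#' rowMeans(m$theta^2)   # all equal rX0^2 = 1
#' @seealso [make_poisson_model()], [make_mixed_model()],
#'   [make_structured_binary_model()], [sample_episode()]
#' @export
make_gaussian_model <- function(p = 10, M = 200, mu_M = 1, sigma_M = 1,
                                rX0 = 1, sigma_x = 1, seed = NULL) {
  if (p < 2) stop_invalid("p must be >= 2")
  check_scalar(M, "M", 1)
  check_scalar(sigma_M, "sigma_M", 0)
  check_scalar(rX0, "rX0", 0, strict = TRUE)
  with_seed(seed, {
    theta_tilde <- matrix(rtruncnorm0(p * M, mu_M, sigma_M), p, M)
    theta <- normalize_rms(theta_tilde, rX0)
    base <- if (length(sigma_x) == 1L) sigma_x else {
      exp(mean(log(sigma_x)))  # geometric mean as the reference scale
    }
    new_external_model(theta, theta_tilde, gaussian_family(base), rX0,
                       sigma_x,
                       params = list(mu_M = mu_M, sigma_M = sigma_M))
  })
}

#' Poisson world model with truncated log-normal tuning
#'
#' Raw tuning is drawn from a log-normal distribution truncated to
#' `(lmin, lmax)`, then each state's row is rescaled so the mean rate is
#' `rX0`. The family's reference rate is set to
#' \eqn{\theta_o = \frac12 \min_{j\mu}\theta_{j\mu}}, which keeps the optimal
#' weights \eqn{\log(\theta_{j\mu}/\theta_o)} strictly positive.
#'
#' @inheritParams make_gaussian_model
#' @param mu_Mp,sigma_Mp Log-scale location and scale of the log-normal.
#' @param lmin,lmax Truncation bounds, `0 < lmin < lmax`.
#' @return An `external_model` with a `poisson` family.
#' @export
make_poisson_model <- function(p = 10, M = 200, mu_Mp = 0, sigma_Mp = 1,
                               lmin = 0.2, lmax = 20, rX0 = 0.3,
                               seed = NULL) {
  if (p < 2) stop_invalid("p must be >= 2")
  if (!(lmin > 0 && lmin < lmax)) stop_invalid("need 0 < lmin < lmax")
  check_scalar(rX0, "rX0", 0, strict = TRUE)
  with_seed(seed, {
    theta_tilde <- matrix(rtrunclnorm(p * M, mu_Mp, sigma_Mp, lmin, lmax),
                          p, M)
    theta <- theta_tilde * (rX0 / rowMeans(theta_tilde))
    fam <- poisson_family(theta_o = 0.5 * min(theta))
    new_external_model(theta, theta_tilde, fam, rX0, NA_real_,
                       params = list(mu_Mp = mu_Mp, sigma_Mp = sigma_Mp,
                                     lmin = lmin, lmax = lmax))
  })
}

#' Mixed world model with constant and variable tuning components
#'
#' Used for dynamic environments: the tuning matrix is the normalized mixture
#' \eqn{\theta_{j\mu} = \frac1Z[\kappa_m\theta^{const}_{j\mu} +
#' (1-\kappa_m)\theta^{var}_{j\mu}]}, with `Z` chosen per state so the RMS
#' rate equals `rX0`. Re-calling this with a freshly drawn `theta_var`
#' implements an environment switch while the constant component persists.
#'
#' @param theta_const,theta_var Raw (non-normalized) component matrices of
#'   identical shape, e.g. the `theta_tilde` of two independent Gaussian
#'   models.
#' @param kappa_m Mixing ratio in `[0, 1]`; 1 keeps only the constant
#'   component.
#' @inheritParams make_gaussian_model
#' @return A Gaussian `external_model`.
#' @export
make_mixed_model <- function(theta_const, theta_var, kappa_m,
                             rX0 = 1, sigma_x = 1) {
  if (!all(dim(theta_const) == dim(theta_var))) {
    stop_invalid("theta_const and theta_var must have the same shape")
  }
  if (kappa_m < 0 || kappa_m > 1) stop_invalid("kappa_m must be in [0, 1]")
  mix <- kappa_m * theta_const + (1 - kappa_m) * theta_var
  theta <- normalize_rms(mix, rX0)
  m <- new_external_model(theta, mix, gaussian_family(sigma_x), rX0, sigma_x,
                          params = list(kappa_m = kappa_m))
  m$params$theta_const <- theta_const
  m$params$theta_var <- theta_var
  m
}

#' Input-dependent noise profile
#'
#' Draws per-input Gaussian noise scales
#' \eqn{\sigma_{X,j} = \sigma_X \exp(2\zeta_j\log\sigma_r)/\sigma_r} with
#' \eqn{\zeta_j} uniform on `[0, 1)`, so scales span
#' \eqn{[\sigma_X/\sigma_r, \sigma_X\sigma_r)} with geometric mean
#' \eqn{\sigma_X}. Attach the result to a Gaussian model with [set_noise()].
#'
#' @param M Number of inputs.
#' @param sigma_x Baseline noise scale.
#' @param sigma_r Spread factor, >= 1; 1 gives constant noise.
#' @param seed Optional integer seed.
#' @return Length-`M` vector of noise scales.
#' @export
make_inhomogeneous_noise <- function(M, sigma_x = 1, sigma_r = 4,
                                     seed = NULL) {
  if (sigma_r < 1) stop_invalid("sigma_r must be >= 1")
  with_seed(seed, {
    zeta <- runif(M)
    sigma_x * exp(2 * zeta * log(sigma_r)) / sigma_r
  })
}

#' @rdname make_inhomogeneous_noise
#' @param model A Gaussian `external_model`.
#' @param sigma Scalar or length-`M` vector of noise scales; `q` is
#'   recomputed as \eqn{\theta_{j\mu}/\sigma_{X,j}^2}. The family's reference
#'   `sigma_x` (used by thresholds and analytic summaries) keeps the original
#'   baseline value.
#' @export
set_noise <- function(model, sigma) {
  stopifnot(inherits(model, "external_model"),
            model$family$name == "gaussian")
  if (length(sigma) == 1L) sigma <- rep(sigma, model$M)
  stopifnot(length(sigma) == model$M)
  model$sigma_x <- sigma
  model$q <- sweep(model$theta, 2L, sigma^2, "/")
  model
}

#' Structured world model with a constant-response input group
#'
#' A quarter of the inputs respond at a constant high level `theta_const`
#' for every hidden state (and therefore carry no information); each of the
#' remaining inputs responds at `theta_high` or `theta_low` independently
#' with probability 1/2 per state. Rows are then RMS-normalized as in
#' [make_gaussian_model()]. Large uninformative synapses make weight-ranked
#' pruning (cut-off coding) fail while probabilistic dual coding degrades
#' gracefully.
#'
#' @inheritParams make_gaussian_model
#' @param theta_const,theta_high,theta_low Raw response levels with
#'   `theta_low < theta_high < theta_const`.
#' @return A Gaussian `external_model`; `params$constant_inputs` holds the
#'   indices of the constant group.
#' @export
make_structured_binary_model <- function(p = 10, M = 200,
                                         theta_const = 1.5,
                                         theta_high = 1, theta_low = 0.25,
                                         rX0 = 1, sigma_x = 1, seed = NULL) {
  if (!(theta_low < theta_high && theta_high < theta_const)) {
    stop_invalid("need theta_low < theta_high < theta_const")
  }
  with_seed(seed, {
    n_const <- round(M / 4)
    theta_tilde <- matrix(0, p, M)
    theta_tilde[, seq_len(n_const)] <- theta_const
    n_var <- M - n_const
    draws <- matrix(runif(p * n_var) < 0.5, p, n_var)
    theta_tilde[, (n_const + 1):M] <- ifelse(draws, theta_high, theta_low)
    theta <- normalize_rms(theta_tilde, rX0)
    m <- new_external_model(theta, theta_tilde, gaussian_family(sigma_x),
                            rX0, sigma_x,
                            params = list(theta_const = theta_const,
                                          theta_high = theta_high,
                                          theta_low = theta_low,
                                          constant_inputs = seq_len(n_const)))
    m
  })
}

#' Sample a stimulus/response episode
#'
#' Draws `T` time steps: hidden states i.i.d. uniform on `1..p`, then input
#' rates from the model's emission family (Gaussian:
#' \eqn{r_{X,j} = \theta_{j s^t} + \sigma_{X,j}\zeta}; Poisson: integer
#' counts with mean \eqn{\theta_{j s^t}}).
#'
#' @param model An `external_model`.
#' @param T_len Number of time steps (>= 1).
#' @param seed Optional integer seed.
#' @return An `episode`: list with integer vector `s` (length `T_len`,
#'   values in `1..p`) and rate matrix `r_X` (`T_len x M`).
#' @export
sample_episode <- function(model, T_len, seed = NULL) {
  stopifnot(inherits(model, "external_model"))
  if (T_len < 1) stop_invalid("T_len must be >= 1")
  with_seed(seed, {
    s <- sample.int(model$p, T_len, replace = TRUE)
    mu <- model$theta[s, , drop = FALSE]
    r_X <- if (model$family$name == "gaussian") {
      mu + matrix(rnorm(T_len * model$M), T_len, model$M) *
        rep(model$sigma_x, each = T_len)
    } else {
      matrix(rpois(T_len * model$M, mu), T_len, model$M)
    }
    structure(list(s = s, r_X = r_X, p = model$p, M = model$M),
              class = "episode")
  })
}

#' @export
print.external_model <- function(x, ...) {
  cat(sprintf("<external_model> %s family: p = %d states, M = %d inputs, rX0 = %g\n",
              x$family$name, x$p, x$M, x$rX0))
  invisible(x)
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode> %d steps, %d inputs, %d states\n",
              length(x$s), x$M, x$p))
  invisible(x)
}
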