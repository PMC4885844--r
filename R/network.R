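#' @title Output-layer network
#' @description
#' A `network` bundles the learnable feedforward system: binary connectivity
#' `C` (`N x M`, `C[i, j]` = connection from input `j` to output `i`),
#' non-negative weights `W` (zero wherever `C` is zero), connection
#' probabilities `P` in `[0, 1]`, the input threshold `h_w`, the output rate
#' scale `rY0`, the membrane floor parameter `v_d`, and the construction-time
#' selectivity map \eqn{\sigma_i = \lfloor p\,i/N \rfloor} assigning output
#' neuron `i` to a hidden state.
#' @name network
NULL

#' Construction-time selectivity map
#'
#' Output neuron `i` (1-based) represents hidden state
#' \eqn{\mu = \lfloor p (i-1) / N \rfloor + 1}; with `p | N` this gives
#' `N/p` neurons per state.
#'
#' @param p Number of hidden states.
#' @param N Number of output neurons.
#' @return Integer vector of length `N` with values in `1..p`.
#' @export
selectivity_map <- function(p, N) {
  as.integer(floor(p * (seq_len(N) - 1) / N)) + 1L
}

new_network <- function(C, W, P, model, h_w, rY0 = 1, v_d = 60,
                        gamma = NA_real_, rho_o = NA_real_,
                        strategy = "custom") {
  N <- nrow(C); M <- ncol(C)
  stopifnot(all(dim(W) == c(N, M)), model$M == M)
  W[C == 0] <- 0
  structure(list(
    C = C, W = W, P = P,
    N = N, M = M, p = model$p,
    selectivity = selectivity_map(model$p, N),
    h_w = h_w, rY0 = rY0, v_d = abs(v_d),
    rho_bar = mean(C),
    gamma = gamma, rho_o = rho_o,
    q_bar = mean(model$q),
    strategy = strategy
  ), class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf(
    "<network> %s coding: N = %d outputs, M = %d inputs, p = %d states\n",
    x$strategy, x$N, x$M, x$p))
  cat(sprintf("  realized connectivity %.3f, h_w = %.4g, rY0 = %g\n",
              x$rho_bar, x$h_w, x$rY0))
  invisible(x)
}

# Resolve the named threshold presets used across the experiments:
# qbar_over_gamma (static coding and dual-rule learning), qbar_over_rho
# (non-dual static coding), rX0_over_gamma (dynamic/spine protocols), or a
# numeric value (0 recovers the exact Bayes decoder for dense optimal
# weights).
resolve_h_w <- function(preset, model, gamma = NA, rho_o = NA) {
  if (is.numeric(preset)) return(preset)
  q_bar <- model_q_bar(model)  # base-sigma convention under input noise
  switch(preset,
    qbar_over_gamma = q_bar / gamma,
    qbar_over_rho   = q_bar / rho_o,
    rX0_over_gamma  = model$rX0 / gamma,
    zero            = 0,
    stop_invalid("unknown h_w preset: ", preset)
  )
}

#' Membrane potentials
#'
#' Computes \eqn{v_i = \sum_j c_{ij}(w_{ij} g(r_{X,j}) - h_w)} and then
#' applies the floor \eqn{v_i \ge \max_\ell v_\ell - |v_d|}, which bounds how
#' far any output can fall below the momentary winner (a numerical guard on
#' the unnormalized log-likelihood). The floor is applied before the global
#' inhibition term so the softmax normalization below remains exact.
#'
#' @param network A `network`.
#' @param r_X Length-`M` input rate vector.
#' @param family A `family_spec` supplying `g` (identity for both built-in
#'   families); defaults to identity.
#' @return Length-`N` vector of (clipped) membrane potentials.
#' @export
membrane_potentials <- function(network, r_X, family = NULL) {
  if (length(r_X) != network$M) {
    stop_invalid("r_X must have length M = ", network$M)
  }
  g <- if (is.null(family)) identity else family$g
  v <- as.vector((network$C * network$W) %*% g(r_X)) -
    rowSums(network$C) * network$h_w
  pmax(v, max(v) - network$v_d)
}

#' Softmax output rates
#'
#' Global inhibition \eqn{I_{inh} = \log\sum_\ell e^{v_\ell}} turns membrane
#' potentials into a probabilistic winner-take-all:
#' \eqn{r_{Y,i} = r_Y^o \exp(v_i - I_{inh})}, so rates are positive and sum
#' exactly to `rY0`.
#'
#' @param v Membrane potential vector (or `T x N` matrix, handled row-wise).
#' @param rY0 Total output rate.
#' @return Output rates with the same shape as `v`.
#' @export
output_rates <- function(v, rY0 = 1) {
  rY0 * softmax(v)
}

#' Decode an episode with a network
#'
#' Vectorized dynamics over a whole episode: membrane potentials (with the
#' `v_d` floor applied per time step), then softmax rates.
#'
#' @param network A `network`.
#' @param episode An `episode`, or a `T x M` rate matrix.
#' @return `T x N` matrix of output rates.
#' @export
network_rates <- function(network, episode) {
  r_X <- if (inherits(episode, "episode")) episode$r_X else episode
  V <- r_X %*% t(network$C * network$W)
  V <- sweep(V, 2L, rowSums(network$C) * network$h_w, "-")
  V <- pmax(V, apply(V, 1L, max) - network$v_d)
  network$rY0 * softmax(V)
}

#' Optimal dense weights
#'
#' For an all-to-all network, setting \eqn{w_{ij} = q_{j\sigma_i}}
#' (Gaussian: \eqn{\theta_{j\sigma_i}/\sigma_{X,j}^2}; Poisson:
#' \eqn{\log(\theta_{j\sigma_i}/\theta_o)}) makes the softmax output
#' reproduce the exact Bayes posterior over hidden states (with `h_w = 0`),
#' because the per-state log-partition sums are equalized by the model
#' normalization.
#'
#' @param model An `external_model`.
#' @param N Number of output neurons.
#' @return `N x M` weight matrix.
#' @export
optimal_dense_weights <- function(model, N) {
  sel <- selectivity_map(model$p, N)
  if (model$family$name == "gaussian") {
    model$q[sel, , drop = FALSE]
  } else {
    theta_o <- model$family$theta_o
    if (theta_o >= min(model$theta)) {
      stop_invalid("theta_o must be < min(theta) for positive weights")
    }
    log(model$theta[sel, , drop = FALSE] / theta_o)
  }
}

#' All-to-all network with optimal weights
#'
#' @inheritParams optimal_dense_weights
#' @param h_w Threshold value or preset name (default 0, the exact-decoder
#'   setting).
#' @param rY0,v_d Output rate scale and membrane floor magnitude.
#' @return A `network` whose grouped output rates equal the Bayes posterior.
#' @export
make_dense_network <- function(model, N, h_w = 0, rY0 = 1, v_d = 60) {
  C <- matrix(1, N, model$M)
  W <- optimal_dense_weights(model, N)
  new_network(C, W, P = matrix(1, N, model$M), model,
              h_w = resolve_h_w(h_w, model, gamma = 1, rho_o = 1),
              rY0 = rY0, v_d = v_d, strategy = "dense_optimal")
}

#' Exact Bayes posterior over hidden states
#'
#' The reference decoder: with a uniform prior,
#' \deqn{\log p(s=\mu \mid r_X) = \sum_j [q_{j\mu} g(r_{X,j}) -
#'   \alpha_j(q_{j\mu})] + const,}
#' normalized by log-sum-exp. Terms constant across states (`B(r)` and the
#' prior) cancel.
#'
#' @param model An `external_model`.
#' @param r_X Length-`M` rate vector or `T x M` matrix.
#' @return Length-`p` probability vector (or `T x p` matrix), each summing
#'   to 1.
#' @export
bayes_posterior <- function(model, r_X) {
  one <- is.vector(r_X)
  R <- if (one) matrix(r_X, 1L) else r_X
  if (ncol(R) != model$M) stop_invalid("r_X must have M = ", model$M,
                                       " columns")
  alpha <- if (model$family$name == "gaussian") {
    sweep(model$q^2, 2L, model$sigma_x^2, "*") / 2
  } else {
    model$theta
  }
  L <- sweep(R %*% t(model$q), 2L, rowSums(alpha), "-")
  post <- softmax(L)
  if (one) as.vector(post) else post
}
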