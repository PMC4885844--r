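#' @title Static coding strategies
#' @description
#' Five ways of writing the tuning structure `q` into a sparse network:
#' in the weights only (`weight`), in the connection probabilities only
#' (`connectivity`), in both (`dual`), by pruning the smallest optimal
#' weights (`cutoff`), or not at all (`random`). Sparseness is controlled by
#' `gamma` (mean connectivity \eqn{\rho = \gamma\bar q}) or directly by a
#' target density `rho_o`.
#' @name coding
NULL

# Mean normalized response q-bar. Under input-dependent Gaussian noise the
# baseline sigma_x is used (not the per-input scales), which suppresses the
# contribution of low-noise inputs to the normalization.
model_q_bar <- function(model) {
  if (model$family$name == "gaussian") {
    mean(model$theta) / model$family$sigma_x^2
  } else {
    mean(model$q)
  }
}

# Shared scaffolding: sample C from a probability matrix and assemble.
build_from_probs <- function(model, N, P, W, h_w, gamma, rho_o, strategy,
                             rY0, v_d) {
  C <- matrix(as.numeric(runif(N * model$M) < P), N, model$M)
  net <- new_network(C, W, P, model,
                     h_w = resolve_h_w(h_w, model, gamma = gamma,
                                       rho_o = rho_o),
                     rY0 = rY0, v_d = v_d, gamma = gamma, rho_o = rho_o,
                     strategy = strategy)
  net
}

#' Build a network under one of the five static coding strategies
#'
#' @param model An `external_model`.
#' @param gamma Sparseness parameter; the mean connectivity is
#'   \eqn{\rho = \gamma\bar q} (capped at 1).
#' @param N Number of output neurons.
#' @param h_w Threshold preset (see Details) or a numeric value.
#' @param rY0,v_d Output rate scale and membrane floor magnitude.
#' @param seed Optional integer seed (local to the call).
#'
#' @details
#' \describe{
#'   \item{`build_weight_coding`}{connections i.i.d. with probability
#'     \eqn{\rho=\gamma\bar q}; weights \eqn{w_{ij}=q_{j\sigma_i}/\rho} carry
#'     the tuning.}
#'   \item{`build_connectivity_coding`}{constant weights \eqn{1/\gamma};
#'     connection probabilities \eqn{\min(\gamma q_{j\sigma_i}, 1)} carry the
#'     tuning.}
#'   \item{`build_dual_coding`}{both: \eqn{\Pr[c_{ij}=1]=\min(\gamma
#'     q_{j\sigma_i},1)} and \eqn{w_{ij}=q_{j\sigma_i}/\bar\rho} with
#'     \eqn{\bar\rho=\gamma\bar q}.}
#'   \item{`build_cutoff_coding`}{weights \eqn{q_{j\sigma_i}/\rho_o}; each
#'     output keeps exactly `round(M * rho_o)` largest-weight connections
#'     (ties broken uniformly at random).}
#'   \item{`build_random_coding`}{weights \eqn{q_{j\sigma_i}/\rho_o};
#'     connections i.i.d. with probability `rho_o`, independent of tuning.}
#' }
#' Default thresholds follow the simulation conventions:
#' \eqn{h_w=\bar q/\gamma} for weight/connectivity/dual coding and
#' \eqn{h_w=\bar q/\rho_o} for cut-off/random coding.
#'
#' @return A `network`.
#' @examples
#' m <- make_gaussian_model(p = 5, M = 60, seed = 1)
#' net <- build_dual_coding(m, gamma = 0.3, N = 20, seed = 2)
#' mean(net$C)            # close to 0.3 * mean(m$q)
#' @export
build_weight_coding <- function(model, gamma, N = 100,
                                h_w = "qbar_over_gamma",
                                rY0 = 1, v_d = 60, seed = NULL) {
  check_scalar(gamma, "gamma", 0, strict = TRUE)
  with_seed(seed, {
    q_bar <- model_q_bar(model)
    rho <- min(gamma * q_bar, 1)
    sel <- selectivity_map(model$p, N)
    W <- model$q[sel, , drop = FALSE] / rho
    build_from_probs(model, N, P = matrix(rho, N, model$M), W = W,
                     h_w = h_w, gamma = gamma, rho_o = rho,
                     strategy = "weight", rY0 = rY0, v_d = v_d)
  })
}

#' @rdname build_weight_coding
#' @export
build_connectivity_coding <- function(model, gamma, N = 100,
                                      h_w = "qbar_over_gamma",
                                      rY0 = 1, v_d = 60, seed = NULL) {
  check_scalar(gamma, "gamma", 0, strict = TRUE)
  with_seed(seed, {
    sel <- selectivity_map(model$p, N)
    P <- pmin(gamma * model$q[sel, , drop = FALSE], 1)
    W <- matrix(1 / gamma, N, model$M)
    build_from_probs(model, N, P = P, W = W, h_w = h_w, gamma = gamma,
                     rho_o = min(gamma * model_q_bar(model), 1),
                     strategy = "connectivity", rY0 = rY0, v_d = v_d)
  })
}

#' @rdname build_weight_coding
#' @export
build_dual_coding <- function(model, gamma, N = 100,
                              h_w = "qbar_over_gamma",
                              rY0 = 1, v_d = 60, seed = NULL) {
  check_scalar(gamma, "gamma", 0, strict = TRUE)
  with_seed(seed, {
    q_bar <- model_q_bar(model)
    rho_bar <- min(gamma * q_bar, 1)
    sel <- selectivity_map(model$p, N)
    P <- pmin(gamma * model$q[sel, , drop = FALSE], 1)
    W <- model$q[sel, , drop = FALSE] / rho_bar
    build_from_probs(model, N, P = P, W = W, h_w = h_w, gamma = gamma,
                     rho_o = rho_bar, strategy = "dual",
                     rY0 = rY0, v_d = v_d)
  })
}

#' @rdname build_weight_coding
#' @param rho_o Target connection density in `(0, 1]` for cut-off and random
#'   coding.
#' @export
build_cutoff_coding <- function(model, rho_o, N = 100,
                                h_w = "qbar_over_rho",
                                rY0 = 1, v_d = 60, seed = NULL) {
  if (rho_o <= 0 || rho_o > 1) stop_invalid("rho_o must be in (0, 1]")
  with_seed(seed, {
    sel <- selectivity_map(model$p, N)
    W <- model$q[sel, , drop = FALSE] / rho_o
    k <- round(model$M * rho_o)
    C <- matrix(0, N, model$M)
    for (i in seq_len(N)) {
      keep <- order(-W[i, ], runif(model$M))[seq_len(k)]
      C[i, keep] <- 1
    }
    net <- new_network(C, W, P = C, model,
                       h_w = resolve_h_w(h_w, model, gamma = NA,
                                         rho_o = rho_o),
                       rY0 = rY0, v_d = v_d, rho_o = rho_o,
                       strategy = "cutoff")
    net
  })
}

#' @rdname build_weight_coding
#' @export
build_random_coding <- function(model, rho_o, N = 100,
                                h_w = "qbar_over_rho",
                                rY0 = 1, v_d = 60, seed = NULL) {
  if (rho_o <= 0 || rho_o > 1) stop_invalid("rho_o must be in (0, 1]")
  with_seed(seed, {
    sel <- selectivity_map(model$p, N)
    W <- model$q[sel, , drop = FALSE] / rho_o
    build_from_probs(model, N, P = matrix(rho_o, N, model$M), W = W,
                     h_w = h_w, gamma = NA, rho_o = rho_o,
                     strategy = "random", rY0 = rY0, v_d = v_d)
  })
}

#' Random initial network for plasticity experiments
#'
#' The starting point of the learning simulations: connections i.i.d. with
#' probability \eqn{\gamma\bar q}, weights \eqn{(1+\sigma_w^{init}\zeta)/
#' \gamma} with standard-normal \eqn{\zeta}, and connection probabilities
#' initialized at the same uniform density.
#'
#' @inheritParams build_weight_coding
#' @param sigma_w_init Relative jitter of initial weights.
#' @export
build_plastic_network <- function(model, gamma, N = 100,
                                  h_w = "qbar_over_gamma",
                                  sigma_w_init = 0.1,
                                  rY0 = 1, v_d = 60, seed = NULL) {
  check_scalar(gamma, "gamma", 0, strict = TRUE)
  with_seed(seed, {
    rho <- min(gamma * model_q_bar(model), 1)
    W <- matrix((1 + sigma_w_init * rnorm(N * model$M)) / gamma, N, model$M)
    W <- pmax(W, 1e-12)
    net <- build_from_probs(model, N, P = matrix(rho, N, model$M), W = W,
                            h_w = h_w, gamma = gamma, rho_o = rho,
                            strategy = "plastic_init", rY0 = rY0, v_d = v_d)
    net
  })
}
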