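#' @title Hebbian weight and wiring plasticity
#' @description
#' The learning machinery: Hebbian weight updates with a homeostatic term,
#' two wiring-plasticity rules updating per-pair connection probabilities
#' (the activity-dependent dual Hebbian rule and its spine-size-driven
#' approximation), and detailed-balance rewiring that creates absent
#' connections with probability \eqn{\rho_{ij}/\tau_c} and eliminates
#' existing ones with probability \eqn{(1-\rho_{ij})/\tau_c} per step, so the
#' stationary occupancy of every potential synapse equals \eqn{\rho_{ij}}.
#' @name plasticity
NULL

#' Plasticity configuration
#'
#' @param rule One of `"weight_only"` (weights learn on a frozen wiring
#'   diagram), `"dual_hebbian"` (weights plus activity-dependent connection
#'   probabilities), `"approx_dual"` (weights plus the spine-size-driven
#'   probability rule), or `"rewire_only"` (no dynamics or learning, just
#'   the rewiring chain on a frozen `P` — a diagnostic mode for studying
#'   the spine turnover process in isolation).
#' @param eta_x Weight learning rate (divided by `gamma` in the update, since
#'   mean weights scale as `1/gamma`).
#' @param b_h Homeostatic strength pulling each output's rate toward
#'   `rY0 / N`.
#' @param eta_rho Wiring-plasticity learning rate.
#' @param tau_c Rewiring timescale in steps; creation/elimination
#'   probabilities per step are `P/tau_c` and `(1-P)/tau_c`.
#' @param sigma_w_init Relative jitter of the weight assigned to a newly
#'   created spine, \eqn{w = (1+\sigma_w^{init}\zeta) w_o}.
#' @param w_o Expected mean synaptic weight; if `NULL`, resolved at training
#'   time as `rX0/gamma` (Gaussian) or `1/gamma` (Poisson).
#' @param elimination_multiplier Factor applied to the elimination
#'   probability only (training protocols increase elimination fivefold).
#' @param weight_floor Strictly positive lower bound keeping weights > 0.
#' @param rewire Set `FALSE` to update probabilities without structural
#'   turnover.
#' @return A `plasticity_config`.
#' @export
plasticity_config <- function(rule = c("dual_hebbian", "weight_only",
                                       "approx_dual", "rewire_only"),
                              eta_x = 0.01, b_h = 0.1, eta_rho = 0.001,
                              tau_c = 1e6, sigma_w_init = 0.1, w_o = NULL,
                              elimination_multiplier = 1,
                              weight_floor = 1e-12, rewire = TRUE) {
  rule <- match.arg(rule)
  check_scalar(eta_x, "eta_x", 0, strict = TRUE)
  check_scalar(eta_rho, "eta_rho", 0, strict = TRUE)
  check_scalar(b_h, "b_h", 0)
  check_scalar(tau_c, "tau_c", 1)
  structure(list(rule = rule, eta_x = eta_x, b_h = b_h, eta_rho = eta_rho,
                 tau_c = tau_c, sigma_w_init = sigma_w_init, w_o = w_o,
                 elimination_multiplier = elimination_multiplier,
                 weight_floor = weight_floor, rewire = rewire),
            class = "plasticity_config")
}

# Resolve w_o and gamma for a network/model pair.
resolve_cfg <- function(cfg, network, model) {
  gamma <- network$gamma
  if (is.na(gamma)) gamma <- network$rho_bar / model_q_bar(model)
  if (is.null(cfg$w_o)) {
    cfg$w_o <- if (model$family$name == "gaussian") {
      model$rX0 / gamma
    } else {
      1 / gamma
    }
  }
  cfg$gamma <- gamma
  cfg
}

# alpha'(rho * w) elementwise for a weight matrix, honoring per-input noise.
drive_matrix <- function(W_or_P, rho, model) {
  if (model$family$name == "gaussian") {
    sweep(rho * W_or_P, 2L, model$sigma_x^2, "*")
  } else {
    model$family$theta_o * exp(rho * W_or_P)
  }
}

#' One Hebbian weight update
#'
#' \deqn{\Delta w_{ij} = \frac{\eta_X}{\gamma}\left( r_{Y,i}[g(r_{X,j}) -
#'   \alpha'(\bar\rho w_{ij})] + b_h[r_Y^o/N - r_{Y,i}] \right)}
#' applied where `C = 1`, then floored at `weight_floor` so weights stay
#' strictly positive. \eqn{\bar\rho} is the mean connectivity measured from
#' the initial wiring diagram (`network$rho_bar`). The first term is
#' stochastic gradient descent on the KL divergence between the true and the
#' weight-encoded input model; the second is a heuristic homeostatic pull
#' toward the uniform rate `rY0 / N`.
#'
#' @param network A `network` (supplies `C`, `W`, `rho_bar`, `gamma`).
#' @param r_X Length-`M` input rates for the current step.
#' @param r_Y Length-`N` output rates for the current step.
#' @param model The `external_model` (supplies the family and noise scales).
#' @param cfg A [plasticity_config()].
#' @return The updated `N x M` weight matrix.
#' @export
weight_update <- function(network, r_X, r_Y, model, cfg) {
  cfg <- resolve_cfg(cfg, network, model)
  g <- model$family$g(r_X)
  D <- drive_matrix(network$W, network$rho_bar, model)
  dW <- (cfg$eta_x / cfg$gamma) *
    (r_Y * sweep(-D, 2L, g, "+") + cfg$b_h * (network$rY0 / network$N - r_Y))
  W <- network$W + dW * network$C
  W[network$C == 1] <- pmax(W[network$C == 1], cfg$weight_floor)
  W * network$C
}

#' One dual Hebbian connection-probability update
#'
#' \deqn{\Delta\rho_{ij} = \eta_\rho\, r_{Y,i}[g(r_{X,j}) -
#'   \alpha'(\rho_{ij} w_o)]}
#' applied to every pair (the probability of a potential synapse is defined
#' whether or not it currently exists), then clipped to `[0, 1]`.
#'
#' @inheritParams weight_update
#' @return The updated `N x M` probability matrix.
#' @export
prob_update_dual <- function(network, r_X, r_Y, model, cfg) {
  cfg <- resolve_cfg(cfg, network, model)
  g <- model$family$g(r_X)
  D <- drive_matrix(network$P, cfg$w_o, model)  # alpha'(P * w_o)
  P <- network$P + cfg$eta_rho * r_Y * sweep(-D, 2L, g, "+")
  pmin(pmax(P, 0), 1)
}

#' One approximated (spine-size-driven) probability update
#'
#' Existing spines relax toward a size-proportional probability,
#' \eqn{\rho \leftarrow \rho + \eta_\rho(\gamma^2 w_{ij} - \rho)}; absent
#' pairs are reset to the baseline \eqn{\gamma^2 w_o} (an assignment, not an
#' increment). No pre/postsynaptic activity enters: spine creation is purely
#' random, and Hebbian selectivity leaks in only through the weights.
#'
#' @inheritParams weight_update
#' @return The updated `N x M` probability matrix.
#' @export
prob_update_approx <- function(network, model, cfg) {
  cfg <- resolve_cfg(cfg, network, model)
  P <- network$P
  on <- network$C == 1
  P[on] <- P[on] + cfg$eta_rho * (cfg$gamma^2 * network$W[on] - P[on])
  P[!on] <- cfg$gamma^2 * cfg$w_o
  pmin(pmax(P, 0), 1)
}

#' One detailed-balance rewiring sweep
#'
#' Visits every (input j, output i) pair in column-major order, drawing one
#' uniform deviate per pair: an existing connection is eliminated with
#' probability `elimination_multiplier * (1 - P[i,j]) / tau_c` (weight set to
#' 0); an absent one is created with probability `P[i,j] / tau_c` and
#' assigned weight \eqn{(1+\sigma_w^{init}\zeta) w_o}, floored at
#' `weight_floor`. This is the R reference implementation of the step used
#' inside the compiled training loop and reproduces its draw order exactly.
#'
#' @inheritParams weight_update
#' @param step Step index stored with the emitted events.
#' @return List with updated `C`, `W` and an `events` data frame
#'   (`step`, `i`, `j`, `type` with `+1` = created, `-1` = eliminated).
#' @export
rewire <- function(network, model, cfg, step = 0L) {
  cfg <- resolve_cfg(cfg, network, model)
  C <- network$C; W <- network$W; P <- network$P
  ev <- list()
  c_p <- 1 / cfg$tau_c
  e_p <- cfg$elimination_multiplier / cfg$tau_c
  for (j in seq_len(network$M)) {
    for (i in seq_len(network$N)) {
      u <- runif(1)
      if (C[i, j] == 1) {
        if (u < e_p * (1 - P[i, j])) {
          C[i, j] <- 0; W[i, j] <- 0
          ev[[length(ev) + 1L]] <- c(step, i, j, -1)
        }
      } else if (u < c_p * P[i, j]) {
        C[i, j] <- 1
        W[i, j] <- max((1 + cfg$sigma_w_init * rnorm(1)) * cfg$w_o,
                       cfg$weight_floor)
        ev[[length(ev) + 1L]] <- c(step, i, j, 1)
      }
    }
  }
  events <- if (length(ev)) {
    as.data.frame(setNames(as.data.frame(do.call(rbind, ev)),
                           c("step", "i", "j", "type")))
  } else {
    data.frame(step = numeric(0), i = numeric(0), j = numeric(0),
               type = numeric(0))
  }
  list(C = C, W = W, events = events)
}

#' One full plasticity step (R reference)
#'
#' Executes a complete simulation step in the fixed order used throughout:
#' sample the stimulus and input rates, compute output rates, update weights,
#' update connection probabilities (rule-dependent), rewire. Draws random
#' deviates in exactly the same sequence as the compiled loop, so trajectories
#' agree bitwise; use [train()] for anything longer than a few steps.
#'
#' @inheritParams weight_update
#' @param step Step index recorded with rewiring events.
#' @return List with the updated `network`, the sampled `s`, `r_X`, `r_Y`,
#'   and rewiring `events`.
#' @export
plasticity_step <- function(network, model, cfg, step = 0L) {
  cfg <- resolve_cfg(cfg, network, model)
  s <- floor(runif(1) * model$p) + 1
  r_X <- if (model$family$name == "gaussian") {
    model$theta[s, ] + model$sigma_x * rnorm(model$M)
  } else {
    rpois(model$M, model$theta[s, ])
  }
  v <- membrane_potentials(network, r_X, model$family)
  r_Y <- output_rates(v, network$rY0)
  network$W <- weight_update(network, r_X, r_Y, model, cfg)
  if (cfg$rule == "dual_hebbian") {
    network$P <- prob_update_dual(network, r_X, r_Y, model, cfg)
  } else if (cfg$rule == "approx_dual") {
    network$P <- prob_update_approx(network, model, cfg)
  }
  events <- NULL
  if (cfg$rule != "weight_only" && cfg$rewire) {
    rw <- rewire(network, model, cfg, step = step)
    network$C <- rw$C
    network$W <- rw$W
    events <- rw$events
  }
  list(network = network, s = s, r_X = r_X, r_Y = r_Y, events = events)
}

rule_code <- function(rule) {
  switch(rule, weight_only = 0L, dual_hebbian = 1L, approx_dual = 2L,
         rewire_only = 3L, stop_invalid("unknown rule: ", rule))
}

#' Train a network
#'
#' Runs the per-step simulation loop (compiled) for `steps` steps: sample
#' stimulus and input rates, softmax dynamics, weight update, rule-dependent
#' probability update, detailed-balance rewiring. All randomness comes from
#' R's generator, so `set.seed()` (or `seed`) makes runs reproducible.
#'
#' @inheritParams weight_update
#' @param steps Number of time steps (>= 1).
#' @param record_rY If `TRUE`, the full `steps x N` output-rate history is
#'   returned (memory permitting) together with the stimulus sequence.
#' @param trace_every If positive, mean connectivity and mean weight are
#'   recorded every `trace_every` steps.
#' @param step_offset Added to recorded step indices (for stitching
#'   multi-segment protocols).
#' @param rewire_mode `"thinned"` (default) samples the rewiring events by
#'   exact thinning of the per-pair Bernoulli process; `"sweep"` draws one
#'   deviate per potential synapse per step, matching the draw order of the
#'   R reference implementation. The two are identical in distribution.
#' @param seed Optional integer seed (local to the call).
#' @return List with the final `network`, integer stimulus sequence `s`,
#'   optional rate history `rY`, spine `events` data frame, event counts
#'   `n_created` / `n_eliminated`, per-neuron `mean_rates`, and the `trace`
#'   data frame (`step`, `connectivity`, `mean_weight`).
#' @export
train <- function(network, model, steps, cfg, record_rY = FALSE,
                  trace_every = 0, step_offset = 0,
                  rewire_mode = c("thinned", "sweep"), seed = NULL) {
  rewire_mode <- match.arg(rewire_mode)
  stopifnot(inherits(network, "network"), inherits(model, "external_model"),
            inherits(cfg, "plasticity_config"))
  if (steps < 1) stop_invalid("steps must be >= 1")
  cfg <- resolve_cfg(cfg, network, model)
  with_seed(seed, {
    res <- run_segment_cpp(
      model$theta, model$q,
      as.integer(model$family$name == "poisson"),
      if (model$family$name == "gaussian") model$sigma_x else
        rep(1, model$M),
      if (model$family$name == "poisson") model$family$theta_o else 0,
      network$C, network$W, network$P,
      rule_code(cfg$rule),
      list(eta_x = cfg$eta_x, b_h = cfg$b_h, eta_rho = cfg$eta_rho,
           tau_c = cfg$tau_c, gamma = cfg$gamma, rho_bar = network$rho_bar,
           w_o = cfg$w_o, h_w = network$h_w, rY0 = network$rY0,
           v_d = network$v_d, sigma_w_init = cfg$sigma_w_init,
           elim_mult = cfg$elimination_multiplier,
           weight_floor = cfg$weight_floor,
           rewire = as.integer(cfg$rewire)),
      as.integer(steps), record_rY, as.integer(trace_every),
      as.numeric(step_offset),
      as.integer(rewire_mode == "thinned"))
    network$C <- res$C
    network$W <- res$W
    network$P <- res$P
    events <- as.data.frame(res$events)
    names(events) <- c("step", "i", "j", "type")
    trace <- as.data.frame(res$trace)
    if (ncol(trace) == 3L) names(trace) <- c("step", "connectivity",
                                             "mean_weight")
    list(network = network,
         s = res$s,
         rY = if (record_rY) res$rY else NULL,
         events = events,
         n_created = res$n_created,
         n_eliminated = res$n_eliminated,
         mean_rates = res$rate_sum / steps,
         trace = trace)
  })
}
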