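#' @title Decoding performance and information measures
#' @description
#' Quantitative read-outs of a network: bootstrap decoding accuracy from
#' output activity, transfer entropy of the feedforward projection, model
#' error of the structure encoded in weights and/or connectivity, and the
#' KL-divergence measures of connectivity optimality.
#' @name evaluation
NULL

# Normalized group-membership matrix (N x p); empty groups give zero columns.
group_matrix <- function(groups, p) {
  N <- length(groups)
  G <- matrix(0, N, p)
  G[cbind(seq_len(N), groups)] <- 1
  n <- colSums(G)
  sweep(G, 2L, pmax(n, 1), "/")
}

#' Assign output selectivity from activity
#'
#' Each output neuron is assigned to the hidden state for which its mean
#' firing rate (conditioned on that state) is highest. Ties, and states never
#' shown in the window, resolve to the lowest state index.
#'
#' @param rY `T x N` output-rate matrix.
#' @param s Length-`T` integer stimulus sequence (values `1..p`).
#' @param p Number of hidden states.
#' @return Integer vector of length `N` with group labels in `1..p`.
#' @export
assign_selectivity <- function(rY, s, p) {
  if (length(s) == 0L || nrow(rY) == 0L) {
    stop_invalid("empty activity window")
  }
  cond <- matrix(-Inf, p, ncol(rY))
  for (mu in seq_len(p)) {
    idx <- which(s == mu)
    if (length(idx)) cond[mu, ] <- colMeans(rY[idx, , drop = FALSE])
  }
  apply(cond, 2L, which.max)
}

#' Score decoding accuracy from activity
#'
#' A step is counted correct when the mean rate of the group selective for
#' the presented state strictly exceeds every other group's mean rate.
#' Steps whose true state has an empty group score as failures.
#'
#' @inheritParams assign_selectivity
#' @param groups Length-`N` selectivity labels (from a preceding,
#'   non-overlapping window).
#' @return Fraction of correctly decoded steps.
#' @export
estimate_accuracy <- function(rY, s, groups, p) {
  if (p == 1L) return(1)
  G <- group_matrix(groups, p)
  empty <- colSums(G) == 0
  GM <- rY %*% G
  GM[, empty] <- -Inf
  true_val <- GM[cbind(seq_along(s), s)]
  GM[cbind(seq_along(s), s)] <- -Inf
  best_other <- apply(GM, 1L, max)
  mean(is.finite(true_val) & true_val > best_other)
}

#' Bootstrap decoding accuracy of a network
#'
#' Samples an episode of `2 * T_o` steps, determines selectivity from the
#' first `T_o` steps, and scores accuracy on the following `T_o` steps — the
#' bootstrap split used throughout the evaluation.
#'
#' @param model An `external_model`.
#' @param network A `network`.
#' @param T_o Half-window length (default 1000).
#' @param seed Optional integer seed.
#' @return List with `accuracy`, the measured `groups`, and the scored
#'   window's `rY` and `s`.
#' @export
bootstrap_accuracy <- function(model, network, T_o = 1000, seed = NULL) {
  with_seed(seed, {
    ep <- sample_episode(model, 2 * T_o)
    rY <- network_rates(network, ep)
    half <- seq_len(T_o)
    groups <- assign_selectivity(rY[half, , drop = FALSE], ep$s[half],
                                 model$p)
    acc <- estimate_accuracy(rY[-half, , drop = FALSE], ep$s[-half],
                             groups, model$p)
    list(accuracy = acc, groups = groups,
         rY = rY[-half, , drop = FALSE], s = ep$s[-half])
  })
}

# Per-state alpha values, honoring per-input noise; p x M.
alpha_matrix <- function(model) {
  if (model$family$name == "gaussian") {
    sweep(model$q^2, 2L, model$sigma_x^2, "*") / 2
  } else {
    model$theta
  }
}

#' Transfer entropy of the feedforward projection
#'
#' Monte-Carlo estimate of \eqn{TE = \langle H(s) - H(s \mid r_X, C)\rangle}
#' in nats: for each sampled input, every output neuron forms a posterior
#' over states from its connected inputs using the true model parameters,
#' posteriors are averaged within each selectivity group, and the residual
#' entropy of that group-readout is subtracted from \eqn{\log p}. Bounded
#' above by \eqn{\log p}.
#'
#' @inheritParams bootstrap_accuracy
#' @param n_samples Number of Monte-Carlo input draws.
#' @param groups Selectivity labels; defaults to the construction-time map.
#' @return Transfer entropy in nats.
#' @export
transfer_entropy <- function(model, network, n_samples = 1000,
                             groups = NULL, seed = NULL) {
  if (n_samples < 1) stop_invalid("n_samples must be >= 1")
  if (is.null(groups)) groups <- network$selectivity
  with_seed(seed, {
    ep <- sample_episode(model, n_samples)
    C <- network$C
    qT <- t(model$q)                       # M x p
    Aalpha <- C %*% t(alpha_matrix(model)) # N x p
    G <- group_matrix(groups, model$p)
    H <- numeric(n_samples)
    for (t in seq_len(n_samples)) {
      L <- C %*% (qT * ep$r_X[t, ]) - Aalpha
      post <- softmax(L)
      phat <- colSums(G * post)
      nz <- phat > 0
      H[t] <- -sum(phat[nz] * log(phat[nz]))
    }
    log(model$p) - mean(H)
  })
}

#' Model error of the learned structure
#'
#' Reconstructs the tuning matrix from the network and compares it to the
#' true one: \eqn{d = \frac{1}{pM}\sum_{\mu j}(\tilde\theta_{j\mu} -
#' \theta_{j\mu})^2}. The raw estimate per mode is
#' \describe{
#'   \item{combined}{\eqn{\bar\theta_{j\mu} = \sum_{i\in\Omega_\mu} c_{ij}
#'     w_{ij} / (\langle c\rangle |\Omega_\mu|)} — what weights and wiring
#'     jointly encode;}
#'   \item{connectivity_only}{\eqn{\sum_{i\in\Omega_\mu} c_{ij} /
#'     (\langle c\rangle |\Omega_\mu|)};}
#'   \item{weight_only}{\eqn{\sum_{i\in\Omega_\mu} c_{ij} w_{ij} /
#'     \sum_{i\in\Omega_\mu} c_{ij}} (0 where no spine exists).}
#' }
#' Each state's estimate is then rescaled to the model's RMS rate before
#' comparison, so a global weight rescaling leaves `d` unchanged.
#'
#' @inheritParams bootstrap_accuracy
#' @param groups Selectivity labels; defaults to the construction-time map.
#' @param mode One of `"combined"`, `"connectivity_only"`, `"weight_only"`.
#' @param theta Optional alternative reference tuning matrix (e.g. the
#'   constant or variable component of a mixed model, RMS-normalized before
#'   use).
#' @return The mean squared error `d`.
#' @export
model_error <- function(model, network, groups = NULL,
                        mode = c("combined", "connectivity_only",
                                 "weight_only"),
                        theta = NULL) {
  mode <- match.arg(mode)
  if (is.null(groups)) groups <- network$selectivity
  p <- model$p
  ref <- if (is.null(theta)) model$theta else normalize_rms(theta, model$rX0)
  cmean <- mean(network$C)
  est <- matrix(0, p, model$M)
  for (mu in seq_len(p)) {
    idx <- which(groups == mu)
    if (length(idx) == 0L) stop_invalid("group ", mu, " is empty")
    Cg <- network$C[idx, , drop = FALSE]
    est[mu, ] <- switch(mode,
      combined = colSums(Cg * network$W[idx, , drop = FALSE]) /
        (cmean * length(idx)),
      connectivity_only = colSums(Cg) / (cmean * length(idx)),
      weight_only = {
        num <- colSums(Cg * network$W[idx, , drop = FALSE])
        den <- colSums(Cg)
        ifelse(den > 0, num / pmax(den, 1), 0)
      })
  }
  rms <- sqrt(rowMeans(est^2))
  est <- est * ifelse(rms > 0, model$rX0 / pmax(rms, .Machine$double.eps), 0)
  mean((est - ref)^2)
}

# Scaled tuning theta / sigma_x (p x M); the Gram matrices of its
# connection-masked rows give the posterior exponents phi + psi / 2.
theta_scaled <- function(model) {
  if (model$family$name != "gaussian") {
    stop_invalid("connectivity-optimality measures require a Gaussian model")
  }
  sweep(model$theta, 2L, model$sigma_x, "/")
}

# Per-neuron posterior exponent matrices S_i[mu, nu] = sum_j c_ij
# theta_mu_j theta_nu_j / sigma_j^2, equal to phi_{mu nu} + psi_mu / 2 with
# phi = sum_j c_ij (2 theta_mu theta_nu - theta_mu^2) / (2 sigma^2) and
# psi = sum_j c_ij (theta_mu / sigma)^2. Returns an N-list of p x p
# matrices.
neuron_exponents <- function(ts, C) {
  N <- nrow(C)
  lapply(seq_len(N), function(i) {
    tcrossprod(sweep(ts, 2L, C[i, ], "*"), ts)
  })
}

# Group-averaged posterior matrix PM[mu, nu] = p_nu(s = mu | C):
# mean over i in group mu of softmax_mu(S_i[, nu]).
posterior_matrix <- function(S_list, groups, p) {
  PM <- matrix(0, p, p)
  n <- integer(p)
  for (i in seq_along(S_list)) {
    g <- groups[i]
    post <- t(softmax(t(S_list[[i]])))   # softmax over mu for each nu
    PM[g, ] <- PM[g, ] + post[g, ]
    n[g] <- n[g] + 1L
  }
  sweep(PM, 1L, pmax(n, 1L), "/")
}

kl_rows <- function(P_ref, P_cmp, p) {
  eps <- 1e-300
  sum(P_ref * (log(P_ref + eps) - log(P_cmp + eps))) / p
}

#' KL-divergence gap of a connection structure
#'
#' \eqn{I(C_{all}, C)}: the mean (over true states) KL divergence between the
#' group-averaged posterior of the fully connected network and that of `C`.
#' The closed form integrates the Gaussian input noise analytically via the
#' per-neuron exponents \eqn{\phi_{\mu\nu} + \psi_\mu/2}; the Monte-Carlo
#' mode averages the same group posteriors over sampled noise and is used as
#' an independent check.
#'
#' @param model A Gaussian `external_model`.
#' @param C `N x M` binary connectivity matrix.
#' @param groups Selectivity labels for the `N` outputs; defaults to the
#'   construction map.
#' @param mode `"closed_form"` or `"monte_carlo"`.
#' @param n_samples Noise draws per true state for the Monte-Carlo mode.
#' @param seed Optional integer seed.
#' @return Non-negative divergence in nats (0 iff the posteriors coincide).
#' @export
kl_gap <- function(model, C, groups = NULL,
                   mode = c("closed_form", "monte_carlo"),
                   n_samples = 200, seed = NULL) {
  mode <- match.arg(mode)
  N <- nrow(C)
  if (is.null(groups)) groups <- selectivity_map(model$p, N)
  p <- model$p
  if (mode == "closed_form") {
    ts <- theta_scaled(model)
    S_all <- tcrossprod(ts, ts)
    post_all <- t(softmax(t(S_all)))
    PM_all <- matrix(0, p, p)
    for (mu in seq_len(p)) PM_all[mu, ] <- post_all[mu, ]
    PM_C <- posterior_matrix(neuron_exponents(ts, C), groups, p)
    kl_rows(PM_all, PM_C, p)
  } else {
    with_seed(seed, {
      G <- group_matrix(groups, p)
      qT <- t(model$q)
      Aalpha_C <- C %*% t(alpha_matrix(model))
      Aalpha_all <- matrix(rowSums(alpha_matrix(model)), N, p, byrow = TRUE)
      PM_all <- matrix(0, p, p)
      PM_C <- matrix(0, p, p)
      for (nu in seq_len(p)) {
        for (k in seq_len(n_samples)) {
          r <- model$theta[nu, ] + model$sigma_x * rnorm(model$M)
          qr <- qT * r
          post_C <- softmax(C %*% qr - Aalpha_C)
          post_all <- softmax(matrix(colSums(qr), N, p, byrow = TRUE) -
                                Aalpha_all)
          PM_C[, nu] <- PM_C[, nu] + colSums(G * post_C)
          PM_all[, nu] <- PM_all[, nu] + colSums(G * post_all)
        }
      }
      kl_rows(PM_all / n_samples, PM_C / n_samples, p)
    })
  }
}

#' Information gain of single connections
#'
#' \eqn{\Delta I_{ij} = \langle I(C_{all}, C) - I(C_{all}, C + \eta_{ij})
#' \rangle_C}, the mean reduction in the KL gap achieved by adding the single
#' connection `(i, j)` to a random structure of density `rho`. Positive
#' values mean the connection is informative. `info_gain_profile()` evaluates
#' a whole set of pairs on a shared structure ensemble (the efficient route
#' for weight-vs-gain scatters).
#'
#' @param model A Gaussian `external_model`.
#' @param i,j Output / input index of the connection.
#' @param n_structures Number of random structures averaged over.
#' @param rho Density of the random structures.
#' @param N Number of output neurons.
#' @param seed Optional integer seed.
#' @return `info_gain()`: a single \eqn{\Delta I_{ij}}.
#' @export
info_gain <- function(model, i, j, n_structures = 200, rho = 0.1,
                      N = 100, seed = NULL) {
  info_gain_profile(model, cbind(i, j), n_structures, rho, N, seed)$delta_I
}

#' @rdname info_gain
#' @param pairs Two-column matrix of (output, input) index pairs.
#' @return `info_gain_profile()`: data frame with `i`, `j`, the optimal dense
#'   weight `w` of each pair, and `delta_I`.
#' @export
info_gain_profile <- function(model, pairs, n_structures = 200, rho = 0.1,
                              N = 100, seed = NULL) {
  if (n_structures < 1) stop_invalid("n_structures must be >= 1")
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  p <- model$p; M <- model$M
  groups <- selectivity_map(p, N)
  ts <- theta_scaled(model)
  S_all <- tcrossprod(ts, ts)
  post_all <- t(softmax(t(S_all)))
  gains <- matrix(0, nrow(pairs), n_structures)
  with_seed(seed, {
    for (b in seq_len(n_structures)) {
      C <- matrix(as.numeric(runif(N * M) < rho), N, M)
      S_list <- neuron_exponents(ts, C)
      PM <- posterior_matrix(S_list, groups, p)
      counts <- tabulate(groups, p)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        if (C[i, j] == 1) next       # adding an existing connection: no-op
        g <- groups[i]
        S_new <- S_list[[i]] + tcrossprod(ts[, j], ts[, j])
        post_old <- t(softmax(t(S_list[[i]])))
        post_new <- t(softmax(t(S_new)))
        row_new <- PM[g, ] + (post_new[g, ] - post_old[g, ]) / counts[g]
        # Only row g of PM changes, so only that row of the KL sum moves.
        gains[k, b] <-
          sum(post_all[g, ] * (log(row_new + 1e-300) -
                                 log(PM[g, ] + 1e-300))) / p
      }
    }
  })
  sel <- groups[pairs[, 1L]]
  w <- model$q[cbind(sel, pairs[, 2L])]
  data.frame(i = pairs[, 1L], j = pairs[, 2L], w = w,
             delta_I = rowMeans(gains))
}

#' Greedy connectivity optimization
#'
#' Hill-climbs \eqn{I(C_{all}, C)} downward by repeatedly proposing to move
#' one connection within an output row (preserving the connection count) and
#' accepting proposals that reduce the divergence; the best structure over
#' random restarts is returned. The result is a lower bound on the optimal
#' achievable performance, not a certificate of optimality.
#'
#' @param model A Gaussian `external_model`.
#' @param density Connection density in (0, 1).
#' @param N Number of output neurons.
#' @param restarts Independent restarts.
#' @param n_proposals Proposal sweeps per restart.
#' @param seed Optional integer seed.
#' @return List with the best `C`, its divergence `I`, and the per-restart
#'   accepted-objective traces (each non-increasing).
#' @export
hillclimb_connectivity <- function(model, density, N = 100, restarts = 2,
                                   n_proposals = 2000, seed = NULL) {
  if (density <= 0 || density > 1) stop_invalid("density must be in (0, 1]")
  p <- model$p; M <- model$M
  groups <- selectivity_map(p, N)
  ts <- theta_scaled(model)
  S_all <- tcrossprod(ts, ts)
  post_all <- t(softmax(t(S_all)))
  PM_all <- post_all   # rows mu
  counts <- tabulate(groups, p)
  k_row <- round(density * M)
  if (k_row == M) {
    return(list(C = matrix(1, N, M), I = 0, traces = list(numeric(0))))
  }
  best <- NULL
  traces <- vector("list", restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      C <- matrix(0, N, M)
      for (i in seq_len(N)) C[i, sample.int(M, k_row)] <- 1
      S_list <- neuron_exponents(ts, C)
      PM <- posterior_matrix(S_list, groups, p)
      obj <- kl_rows(PM_all, PM, p)
      tr <- obj
      for (it in seq_len(n_proposals)) {
        i <- sample.int(N, 1L)
        on <- which(C[i, ] == 1)
        off <- which(C[i, ] == 0)
        if (!length(on) || !length(off)) next
        j_out <- on[sample.int(length(on), 1L)]
        j_in <- off[sample.int(length(off), 1L)]
        g <- groups[i]
        S_new <- S_list[[i]] -
          tcrossprod(ts[, j_out], ts[, j_out]) +
          tcrossprod(ts[, j_in], ts[, j_in])
        post_old <- t(softmax(t(S_list[[i]])))
        post_new <- t(softmax(t(S_new)))
        PM_new <- PM
        PM_new[g, ] <- PM[g, ] + (post_new[g, ] - post_old[g, ]) / counts[g]
        obj_new <- obj +
          sum(post_all[g, ] * (log(PM[g, ] + 1e-300) -
                                 log(PM_new[g, ] + 1e-300))) / p
        if (obj_new < obj) {
          C[i, j_out] <- 0; C[i, j_in] <- 1
          S_list[[i]] <- S_new
          PM <- PM_new
          obj <- obj_new
          tr <- c(tr, obj)
        }
      }
      traces[[r]] <- tr
      if (is.null(best) || obj < best$I) best <- list(C = C, I = obj)
    }
  })
  c(best, list(traces = traces))
}

#' Alignment of the dual Hebbian wiring rule with the transfer-entropy
#' gradient
#'
#' Compares, over sampled inputs, the dual Hebbian probability update
#' direction \eqn{r_{Y,i} w_o [g(r_{X,j}) - \alpha'(\rho_{ij} w_o)]} with the
#' stochastic gradient of the estimated transfer entropy,
#' \eqn{(1 + \log(r_{Y,i}/r_Y^o))\, r_{Y,i} [g(r_{X,j}) -
#' \alpha(q_{\mu j})/q_{\mu j} + B(r_{X,j})/q_{\mu j}]}, and returns the mean
#' cosine similarity of the two update matrices. Positive alignment means
#' wiring plasticity does not, on average, destroy transfer entropy.
#'
#' @inheritParams bootstrap_accuracy
#' @param n_samples Sampled steps to average over.
#' @param w_o Expected mean weight; defaults to `rX0 / gamma`.
#' @return Mean cosine similarity (zero-norm updates skipped).
#' @export
te_gradient_alignment <- function(model, network, n_samples = 200,
                                  w_o = NULL, seed = NULL) {
  stopifnot(model$family$name == "gaussian")
  if (is.null(w_o)) {
    gamma <- network$gamma
    if (is.na(gamma)) gamma <- network$rho_bar / model_q_bar(model)
    w_o <- model$rX0 / gamma
  }
  with_seed(seed, {
    ep <- sample_episode(model, n_samples)
    sel <- network$selectivity
    qsel <- model$q[sel, , drop = FALSE]              # N x M
    alpha_sel <- alpha_matrix(model)[sel, , drop = FALSE]
    cosines <- numeric(0)
    for (t in seq_len(n_samples)) {
      r <- ep$r_X[t, ]
      v <- membrane_potentials(network, r, model$family)
      rY <- output_rates(v, network$rY0)
      D <- drive_matrix(network$P, w_o, model)
      d13 <- w_o * rY * sweep(-D, 2L, r, "+")
      B <- -r^2 / (2 * model$sigma_x^2)
      targ <- matrix(r, network$N, network$M, byrow = TRUE) +
        (matrix(B, network$N, network$M, byrow = TRUE) - alpha_sel) / qsel
      d15 <- (1 + log(pmax(rY, 1e-300) / network$rY0)) * rY * targ
      n13 <- sqrt(sum(d13^2)); n15 <- sqrt(sum(d15^2))
      if (n13 > 0 && n15 > 0) {
        cosines <- c(cosines, sum(d13 * d15) / (n13 * n15))
      }
    }
    mean(cosines)
  })
}
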