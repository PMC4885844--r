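#' @title Experiment protocols
#' @description
#' Drivers for the multi-phase experiments: dynamic environments in which
#' part of the input structure is resampled at fixed intervals, motor-style
#' training protocols comparing spine turnover between control and training
#' conditions, and spine-dynamics statistics under the approximated wiring
#' rule. Days are a bookkeeping unit of `day_len` simulation steps;
#' connectivity snapshots are taken exactly at day boundaries and transient
#' rewiring within a day is ignored, as in chronic imaging.
#' @name protocols
NULL

# Gaussian model from a raw (non-normalized) tuning matrix.
model_from_tilde <- function(tilde, rX0 = 1, sigma_x = 1) {
  new_external_model(normalize_rms(tilde, rX0), tilde,
                     gaussian_family(sigma_x), rX0, sigma_x)
}

#' Unstructured-input surrogate model
#'
#' A "blank slate" control: every input fires at the constant level
#' \eqn{0.75\mu_M} regardless of the hidden state, with noise
#' \eqn{\sqrt{\sigma_X^2+\sigma_M^2}} matching the marginal variability of a
#' structured model. Carries no decodable information.
#'
#' @inheritParams make_gaussian_model
#' @return A Gaussian `external_model`.
#' @export
make_unstructured_model <- function(p = 10, M = 200, mu_M = 1, sigma_M = 1,
                                    sigma_x = 1) {
  tilde <- matrix(0.75 * mu_M, p, M)
  sx <- sqrt(sigma_x^2 + sigma_M^2)
  m <- new_external_model(tilde, tilde, gaussian_family(sx), 0.75 * mu_M,
                          sx)
  m$params$unstructured <- TRUE
  m
}

# Accuracy from a recorded window: selectivity from the first half,
# scoring on the second half.
window_accuracy <- function(rY, s, p) {
  half <- seq_len(floor(nrow(rY) / 2))
  groups <- assign_selectivity(rY[half, , drop = FALSE], s[half], p)
  list(accuracy = estimate_accuracy(rY[-half, , drop = FALSE], s[-half],
                                    groups, p),
       groups = groups)
}

#' Dynamic-environment protocol
#'
#' The tuning matrix is a normalized mixture of a fixed component
#' `theta_const` (weight `kappa_m`) and a variable component resampled at
#' the start of every epoch of `T_2` steps. Early-phase accuracy is scored
#' from the activity right after each switch (a window of `2 * T_o` steps)
#' and late-phase accuracy from the last `2 * T_o` steps before the next
#' switch; plasticity stays on throughout. Under the dual Hebbian rule the
#' wiring gradually absorbs the constant component, so the early-phase
#' (trough) accuracy climbs across epochs, while weight-only learning
#' relearns from scratch every epoch.
#'
#' @param epochs Number of scored environment epochs.
#' @param burnin_epochs Unscored epochs run first, so the scored window
#'   reflects the cyclic regime rather than the initial self-organization
#'   transient (both rules improve steeply from a random network, which
#'   masks the wiring-specific accumulation).
#' @param T_2 Steps per epoch (variable component fixed within an epoch).
#' @param kappa_m Weight of the constant component in the mixture.
#' @param rule Plasticity rule (see [plasticity_config()]).
#' @param p,M,N,gamma,rX0,sigma_x Model and network parameters.
#' @param eta_rho,tau_c Wiring-plasticity parameters.
#' @param T_o Accuracy half-window (needs `T_2 >= 4 * T_o`).
#' @param seed Optional integer seed.
#' @return List with `history` (per-epoch early/late accuracy and end-of-
#'   epoch connectivity), end-of-run model errors computed from connectivity
#'   and from weights against both components, the final `network`, the
#'   measured `groups`, and the final `rho_w` pairs data frame.
#' @export
run_dynamic_environment <- function(epochs = 10, burnin_epochs = 0,
                                    T_2 = 1e4, kappa_m = 0.5,
                                    rule = "dual_hebbian",
                                    p = 10, M = 200, N = 100, gamma = 0.6,
                                    rX0 = 1, sigma_x = 1,
                                    eta_rho = 0.001, tau_c = 2e4,
                                    T_o = 1e3, seed = NULL) {
  if (T_2 < 4 * T_o) stop_invalid("T_2 must be >= 4 * T_o")
  with_seed(seed, {
    theta_const <- matrix(rtruncnorm0(p * M, 1, 1), p, M)
    draw_var <- function() matrix(rtruncnorm0(p * M, 1, 1), p, M)
    theta_var <- draw_var()
    model <- make_mixed_model(theta_const, theta_var, kappa_m, rX0, sigma_x)
    network <- build_plastic_network(model, gamma, N,
                                     h_w = "rX0_over_gamma")
    cfg <- plasticity_config(rule = rule, eta_rho = eta_rho, tau_c = tau_c)
    win <- 2 * T_o
    hist <- data.frame(epoch = seq_len(epochs), early = NA_real_,
                       late = NA_real_, connectivity = NA_real_)
    groups <- network$selectivity
    offset <- 0
    for (e in seq_len(burnin_epochs)) {
      if (e > 1) {
        theta_var <- draw_var()
        model <- make_mixed_model(theta_const, theta_var, kappa_m, rX0,
                                  sigma_x)
      }
      bb <- train(network, model, T_2 - win, cfg, step_offset = offset)
      cc <- train(bb$network, model, win, cfg, record_rY = TRUE,
                  step_offset = offset + T_2 - win)
      network <- cc$network
      groups <- window_accuracy(cc$rY, cc$s, p)$groups
      offset <- offset + T_2
    }
    # Bootstrap convention: selectivity always comes from the T_o window
    # preceding the scored one, so the early-phase score right after a
    # switch uses the selectivity measured at the end of the previous epoch.
    for (e in seq_len(epochs)) {
      if (e > 1 || burnin_epochs > 0) {
        theta_var <- draw_var()
        model <- make_mixed_model(theta_const, theta_var, kappa_m, rX0,
                                  sigma_x)
      }
      a <- train(network, model, T_o, cfg, record_rY = TRUE,
                 step_offset = offset)
      network <- a$network
      hist$early[e] <- estimate_accuracy(a$rY, a$s, groups, p)
      b <- train(network, model, T_2 - T_o - win, cfg,
                 step_offset = offset + T_o)
      network <- b$network
      cc <- train(network, model, win, cfg, record_rY = TRUE,
                  step_offset = offset + T_2 - win)
      network <- cc$network
      wl <- window_accuracy(cc$rY, cc$s, p)
      hist$late[e] <- wl$accuracy
      groups <- wl$groups
      hist$connectivity[e] <- mean(network$C)
      offset <- offset + T_2
    }
    list(history = hist,
         err_conn_const = model_error(model, network, groups,
                                      "connectivity_only",
                                      theta = theta_const),
         err_conn_var = model_error(model, network, groups,
                                    "connectivity_only", theta = theta_var),
         err_w_const = model_error(model, network, groups, "weight_only",
                                   theta = theta_const),
         err_w_var = model_error(model, network, groups, "weight_only",
                                 theta = theta_var),
         network = network, groups = groups,
         rho_w = data.frame(rho = as.vector(network$P),
                            w = as.vector(network$W),
                            connected = as.vector(network$C) == 1))
  })
}

#' Training protocol with daily spine snapshots
#'
#' Burn-in on a structured control model (`burnin_days`), then an
#' observation period of `obs_days` days starting at day 0. Under
#' `condition = "training"` the input structure switches to an independent
#' (or `kappa_m`-mixed) training model for days 1..`train_days`;
#' `"control"` stays on the control model; `"unstructured"` replaces the
#' whole history with the constant surrogate of
#' [make_unstructured_model()]. An elimination multiplier can be applied
#' during the training days. Connectivity is snapshotted at every day
#' boundary from day 0 on.
#'
#' @param condition `"training"`, `"control"`, or `"unstructured"`.
#' @param kappa_m Similarity between control and training structures
#'   (0 = independent, 1 = identical).
#' @param train_days Days of exposure to the training structure.
#' @param obs_days Observation days after onset (>= `train_days` for
#'   short-training designs; after `train_days` the input reverts to
#'   control).
#' @param burnin_days Days of pre-onset burn-in.
#' @param day_len Steps per day. The plasticity defaults (`eta_x`,
#'   `eta_rho`, `tau_c`) form a scaled preset for the default
#'   `day_len = 1e4`: the probability relaxation time is 0.1 day and the
#'   rewiring timescale 3 days, preserving the per-day dynamics of a
#'   full-scale run with 1e5-step days.
#' @param eta_x,eta_rho,tau_c Plasticity parameters (see
#'   [plasticity_config()]).
#' @param elim_mult Elimination multiplier during training days.
#' @param test_phase If `TRUE`, a 7000-step test on the training model is
#'   appended and scored from the 2000–7000 window (selectivity from steps
#'   2001–4500, accuracy from 4501–7000).
#' @inheritParams run_dynamic_environment
#' @return List with `snapshots` (day-indexed list of `C`), `events`,
#'   `network`, `models`, `day_len`, and optionally `test_accuracy`.
#' @export
run_training_protocol <- function(condition = c("training", "control",
                                                "unstructured"),
                                  kappa_m = 0, train_days = 7, obs_days = 7,
                                  burnin_days = 20, day_len = 1e4,
                                  rule = "approx_dual",
                                  p = 10, M = 200, N = 100, gamma = 0.6,
                                  rX0 = 1, sigma_x = 1,
                                  eta_x = 0.1, eta_rho = 1e-3, tau_c = 3e4,
                                  elim_mult = 1, test_phase = FALSE,
                                  seed = NULL) {
  condition <- match.arg(condition)
  with_seed(seed, {
    tilde_ctrl <- matrix(rtruncnorm0(p * M, 1, 1), p, M)
    tilde_ind <- matrix(rtruncnorm0(p * M, 1, 1), p, M)
    model_ctrl <- model_from_tilde(tilde_ctrl, rX0, sigma_x)
    model_train <- model_from_tilde(
      kappa_m * tilde_ctrl + (1 - kappa_m) * tilde_ind, rX0, sigma_x)
    base_model <- if (condition == "unstructured") {
      make_unstructured_model(p, M, 1, 1, sigma_x)
    } else {
      model_ctrl
    }
    network <- build_plastic_network(base_model, gamma, N,
                                     h_w = "rX0_over_gamma")
    cfg <- plasticity_config(rule = rule, eta_x = eta_x, eta_rho = eta_rho,
                             tau_c = tau_c)
    events <- list()
    run_days <- function(network, model, n_days, offset, mult = 1) {
      cfg_d <- cfg
      cfg_d$elimination_multiplier <- mult
      snaps <- vector("list", n_days)
      for (d in seq_len(n_days)) {
        res <- train(network, model, day_len, cfg_d,
                     step_offset = offset + (d - 1) * day_len)
        network <- res$network
        events[[length(events) + 1L]] <<- res$events
        snaps[[d]] <- network$C
      }
      list(network = network, snaps = snaps)
    }
    bi <- run_days(network, base_model, burnin_days, 0)
    network <- bi$network
    snapshots <- list("0" = network$C)
    onset <- burnin_days * day_len
    for (d in seq_len(obs_days)) {
      in_training <- condition == "training" && d <= train_days
      model_d <- if (in_training) model_train else base_model
      res <- run_days(network, model_d, 1L, onset + (d - 1) * day_len,
                      mult = if (in_training) elim_mult else 1)
      network <- res$network
      snapshots[[as.character(d)]] <- network$C
    }
    out <- list(snapshots = snapshots,
                events = do.call(rbind, events),
                network = network,
                models = list(control = model_ctrl, training = model_train),
                day_len = day_len, onset = onset, condition = condition)
    if (test_phase) {
      test <- train(network, model_train, 7000, cfg, record_rY = TRUE,
                    step_offset = onset + obs_days * day_len)
      sel_win <- 2001:4500
      score_win <- 4501:7000
      groups <- assign_selectivity(test$rY[sel_win, , drop = FALSE],
                                   test$s[sel_win], p)
      out$test_accuracy <- estimate_accuracy(
        test$rY[score_win, , drop = FALSE], test$s[score_win], groups, p)
      out$network <- test$network
    }
    out
  })
}

#' Spine survival curves from daily snapshots
#'
#' Two cohorts are tracked from the snapshots of a training protocol:
#' pre-existing spines (present at day 0 and still present at day 2) and new
#' spines (absent at day 0, present at day 2). Survival at day `d >= 2` is
#' the fraction of each cohort present in the day-`d` snapshot.
#'
#' @param snapshots Day-indexed list of connectivity matrices (names
#'   `"0"`, `"1"`, ...), as returned by [run_training_protocol()].
#' @return Data frame with columns `day`, `pre`, `new`.
#' @export
survival_curves <- function(snapshots) {
  c0 <- snapshots[["0"]] == 1
  c2 <- snapshots[["2"]] == 1
  pre <- c0 & c2
  new <- (!c0) & c2
  days <- sort(as.integer(names(snapshots)))
  days <- days[days >= 2]
  data.frame(
    day = days,
    pre = vapply(days, function(d) {
      cd <- snapshots[[as.character(d)]] == 1
      sum(pre & cd) / max(sum(pre), 1)
    }, numeric(1)),
    new = vapply(days, function(d) {
      cd <- snapshots[[as.character(d)]] == 1
      sum(new & cd) / max(sum(new), 1)
    }, numeric(1)))
}

#' Spine-turnover summary ratios
#'
#' The three ratios used to relate turnover to performance, computed from
#' the day-0, day-2 and day-7 snapshots:
#' \describe{
#'   \item{new_persist7}{new spines formed during the first two days that
#'     persist at day 7, \eqn{\sum c(7d)[1-c(0d)]c(2d) / \sum c(7d)};}
#'   \item{total_new7}{total new spines at day 7,
#'     \eqn{\sum c(7d)[1-c(0d)] / \sum c(7d)};}
#'   \item{elim_existing}{eliminated pre-existing spines,
#'     \eqn{\sum c(0d)[1-c(7d)] / \sum c(0d)}.}
#' }
#' Zero denominators yield `NA`.
#'
#' @inheritParams survival_curves
#' @return Named list of the three ratios.
#' @export
survival_metrics <- function(snapshots) {
  c0 <- snapshots[["0"]]
  c2 <- snapshots[["2"]]
  c7 <- snapshots[["7"]]
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    new_persist7 = safe(sum(c7 * (1 - c0) * c2), sum(c7)),
    total_new7 = safe(sum(c7 * (1 - c0)), sum(c7)),
    elim_existing = safe(sum(c0 * (1 - c7)), sum(c0))
  )
}

#' Spine-dynamics statistics under the approximated rule
#'
#' Runs the approximated dual Hebbian rule on a static Gaussian model and
#' summarizes the spine behavior: the relative change of connection
#' probability over one day-equivalent interval, binned by the initial
#' probability (eliminated spines reported as relative change -1), and the
#' dependence of mean connection probability and 5-day survival on spine
#' age at a reference day.
#'
#' @param burn_days Days before the reference snapshot.
#' @param interval Steps over which the relative probability change is
#'   measured (one day).
#' @inheritParams run_dynamic_environment
#' @param day_len Steps per day; defaults form the same scaled preset as in
#'   [run_training_protocol()].
#' @param eta_x Weight learning rate.
#' @return List with `rel_change` (per-spine data frame: initial `rho0`,
#'   `rel_change`, `eliminated`), and `age_stats` (per-spine data frame at
#'   the reference day: `age_days`, `rho`, `survived5`).
#' @export
run_spine_statistics <- function(burn_days = 10, day_len = 1e4,
                                 interval = day_len,
                                 p = 10, M = 200, N = 100, gamma = 0.6,
                                 rX0 = 1, sigma_x = 1,
                                 eta_x = 0.1, eta_rho = 1e-3, tau_c = 3e4,
                                 seed = NULL) {
  with_seed(seed, {
    model <- model_from_tilde(matrix(rtruncnorm0(p * M, 1, 1), p, M),
                              rX0, sigma_x)
    network <- build_plastic_network(model, gamma, N,
                                     h_w = "rX0_over_gamma")
    cfg <- plasticity_config(rule = "approx_dual", eta_x = eta_x,
                             eta_rho = eta_rho, tau_c = tau_c)
    created_at <- matrix(0, N, M)   # step of last creation; 0 = initial
    track <- function(events) {
      for (k in seq_len(nrow(events))) {
        if (events$type[k] == 1) {
          created_at[events$i[k], events$j[k]] <<- events$step[k]
        }
      }
    }
    res <- train(network, model, burn_days * day_len, cfg)
    network <- res$network
    track(res$events)
    ref_step <- burn_days * day_len
    C0 <- network$C; P0 <- network$P
    age_days <- (ref_step - created_at) / day_len

    res <- train(network, model, interval, cfg, step_offset = ref_step)
    network <- res$network
    track(res$events)
    C1 <- network$C; P1 <- network$P

    on0 <- C0 == 1
    rel <- ifelse(C1 == 1, (P1 - P0) / P0, -1)
    rel_change <- data.frame(rho0 = P0[on0], rel_change = rel[on0],
                             eliminated = (C1 == 0)[on0])

    rest <- 5 * day_len - interval
    if (rest > 0) {
      res <- train(network, model, rest, cfg,
                   step_offset = ref_step + interval)
      network <- res$network
    }
    age_stats <- data.frame(age_days = age_days[on0], rho = P0[on0],
                            survived5 = (network$C == 1)[on0])
    list(rel_change = rel_change, age_stats = age_stats,
         network = network)
  })
}
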