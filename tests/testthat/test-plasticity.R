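# Learning rules: single-step algebra, R/C++ trajectory agreement, rewiring
# chain statistics, and short learning runs.

test_that("weight update vanishes at its fixed point", {
  m <- manual_model(matrix(1, 2, 4))
  net <- manual_network(m, C = matrix(1, 2, 4), W = matrix(2, 2, 4),
                        gamma = 0.5)
  net$rho_bar <- 0.5
  cfg <- plasticity_config("weight_only", b_h = 0.3)
  # r_Y at the homeostatic target and g(r_X) = alpha'(rho_bar w) = 1
  rY <- rep(net$rY0 / net$N, net$N)
  W2 <- weight_update(net, rep(1, 4), rY, m, cfg)
  expect_equal(W2, net$W, tolerance = 1e-12)
})

test_that("Gaussian weight update matches hand arithmetic", {
  # Delta w = (eta/gamma) (rY [r - sigma^2 rho_bar w] + b_h (rY0/N - rY))
  m <- manual_model(matrix(1, 2, 2))
  net <- manual_network(m, C = matrix(1, 2, 2), W = matrix(2, 2, 2),
                        gamma = 0.5)
  net$rho_bar <- 0.5
  cfg <- plasticity_config("weight_only", eta_x = 0.01, b_h = 0)
  W2 <- weight_update(net, r_X = c(2, 2), r_Y = c(1, 1), m, cfg)
  expect_equal(W2, net$W + (0.01 / 0.5) * (2 - 0.5 * 2), tolerance = 1e-12)
  # updates act only where connections exist, and weights stay positive
  net$C[1, 1] <- 0; net$W[1, 1] <- 0
  W3 <- weight_update(net, r_X = c(-100, -100), r_Y = c(1, 1), m, cfg)
  expect_equal(W3[1, 1], 0)
  expect_true(all(W3[net$C == 1] >= cfg$weight_floor))
})

test_that("dual probability update has the stated fixed point and zero-rate
          gate", {
  m <- manual_model(matrix(1, 2, 4))
  net <- manual_network(m, C = matrix(1, 2, 4), W = matrix(2, 2, 4),
                        P = matrix(0.5, 2, 4), gamma = 0.5)
  cfg <- plasticity_config("dual_hebbian", w_o = 2)
  # rho w_o sigma^2 = 1 = r_X -> no change
  P2 <- prob_update_dual(net, rep(1, 4), c(1, 1), m, cfg)
  expect_equal(P2, net$P, tolerance = 1e-12)
  # silent outputs never move their probabilities
  P3 <- prob_update_dual(net, rep(100, 4), c(0, 1), m, cfg)
  expect_equal(P3[1, ], net$P[1, ])
  expect_true(all(P3[2, ] > net$P[2, ]))
  expect_true(all(P3 >= 0 & P3 <= 1))
})

test_that("approximated update relaxes to gamma^2 w and resets absent
          pairs", {
  m <- manual_model(matrix(1, 2, 4))
  C <- matrix(1, 2, 4); C[1, 1] <- 0
  net <- manual_network(m, C = C, W = matrix(2, 2, 4) * C,
                        P = matrix(0.1, 2, 4), gamma = 0.6)
  cfg <- plasticity_config("approx_dual", eta_rho = 0.2, w_o = 1.5)
  P <- net$P
  for (k in 1:200) {
    net$P <- P
    P <- prob_update_approx(net, m, cfg)
  }
  expect_equal(P[2, 1], 0.36 * 2, tolerance = 1e-6)   # gamma^2 w = 0.72
  expect_equal(P[1, 1], 0.36 * 1.5)                    # absent: gamma^2 w_o
})

test_that("rewiring respects the probability boundaries", {
  m <- manual_model(matrix(1, 2, 3))
  C <- matrix(c(1, 1, 0, 0, 1, 0), 2, 3)
  net <- manual_network(m, C = C, W = C * 2,
                        P = matrix(c(1, 1, 0, 0, 1, 0), 2, 3), gamma = 0.5)
  cfg <- plasticity_config("dual_hebbian", tau_c = 1)
  set.seed(50)
  for (k in 1:20) {
    rw <- rewire(net, m, cfg)
    # P = 1 connections are permanent; P = 0 holes never fill
    expect_equal(rw$C[C == 1 & net$P == 1], rep(1, 3))
    expect_equal(rw$C[C == 0 & net$P == 0], rep(0, 3))
  }
})

test_that("C++ loop reproduces the R reference step for every rule", {
  m <- make_gaussian_model(p = 3, M = 12, seed = 51)
  net0 <- build_plastic_network(m, gamma = 0.5, N = 9, seed = 52)
  for (rule in c("weight_only", "dual_hebbian", "approx_dual")) {
    cfg <- plasticity_config(rule, tau_c = 25, eta_rho = 0.01)
    set.seed(53)
    netR <- net0
    for (t in 1:120) netR <- plasticity_step(netR, m, cfg, step = t)$network
    set.seed(53)
    res <- train(net0, m, 120, cfg, rewire_mode = "sweep")
    expect_identical(res$network$C, netR$C)
    expect_lt(max(abs(res$network$W - netR$W)), 1e-9)
    expect_lt(max(abs(res$network$P - netR$P)), 1e-9)
  }
  # Poisson family, weight learning
  mp <- make_poisson_model(p = 3, M = 10, seed = 54)
  np <- build_plastic_network(mp, gamma = 0.5, N = 6, seed = 55)
  cfgp <- plasticity_config("weight_only")
  set.seed(56)
  netR <- np
  for (t in 1:100) netR <- plasticity_step(netR, mp, cfgp)$network
  set.seed(56)
  expect_lt(max(abs(train(np, mp, 100, cfgp)$network$W - netR$W)), 1e-9)
})

test_that("thinned and sweep rewiring have matching event statistics", {
  m <- manual_model(matrix(1, 2, 30))
  P <- matrix(0.4, 20, 30)
  C <- matrix(0, 20, 30)
  net <- manual_network(m, C = C, W = C, P = P, gamma = 0.5)
  cfg <- plasticity_config("rewire_only", tau_c = 10)
  set.seed(57)
  a <- train(net, m, 2000, cfg, rewire_mode = "sweep")
  b <- train(net, m, 2000, cfg, rewire_mode = "thinned")
  # both chains relax to occupancy 0.4 with comparable event counts
  expect_lt(abs(mean(a$network$C) - 0.4), 0.06)
  expect_lt(abs(mean(b$network$C) - 0.4), 0.06)
  expect_lt(abs(a$n_created / b$n_created - 1), 0.15)
})

test_that("frozen-probability rewiring reaches the detailed-balance
          occupancy", {
  # two-state chain: stationary occupancy = rho for each pair
  m <- manual_model(matrix(1, 2, 10))
  net <- manual_network(m, C = matrix(0, 10, 10), W = matrix(0, 10, 10),
                        P = matrix(0.3, 10, 10), gamma = 0.5)
  cfg <- plasticity_config("rewire_only", tau_c = 10)
  set.seed(58)
  occ <- 0
  n_snap <- 150
  state <- net
  for (k in 1:n_snap) {
    state <- train(state, m, 50, cfg)$network   # 5 tau_c between snapshots
    occ <- occ + mean(state$C)
  }
  occ <- occ / n_snap
  se <- sqrt(0.3 * 0.7 / (n_snap * 100))  # 100 pairs per snapshot
  expect_lt(abs(occ - 0.3), 3 * se * 3)   # snapshots not fully independent
})

test_that("weight-only training never rewires and tracks the weight-coding
          fixed point", {
  m <- make_gaussian_model(p = 4, M = 40, seed = 59)
  net <- build_plastic_network(m, gamma = 0.8, N = 20, seed = 60)
  cfg <- plasticity_config("weight_only")
  res <- train(net, m, 6e4, cfg, seed = 61)
  expect_identical(res$network$C, net$C)
  expect_equal(nrow(res$events), 0L)
  # learned weights approach q_{j mu} / rho_bar for strongly tuned inputs
  sel <- assign_selectivity(
    network_rates(res$network, sample_episode(m, 800, seed = 62)),
    sample_episode(m, 800, seed = 62)$s, m$p)
  W <- res$network$W
  err <- c()
  for (i in seq_len(20)) {
    mu <- sel[i]
    strong <- m$q[mu, ] > stats::median(m$q[mu, ]) & res$network$C[i, ] == 1
    target <- m$q[mu, strong] / net$rho_bar
    err <- c(err, abs(W[i, strong] - target) / target)
  }
  expect_lt(stats::median(err), 0.1)
})

test_that("homeostasis narrows the distribution of mean output rates", {
  m <- make_gaussian_model(p = 4, M = 40, seed = 63)
  net <- build_plastic_network(m, gamma = 0.8, N = 20, seed = 64)
  r_h <- train(net, m, 3e4, plasticity_config("weight_only", b_h = 0.1),
               seed = 65)
  r_0 <- train(net, m, 3e4, plasticity_config("weight_only", b_h = 0),
               seed = 65)
  expect_lt(var(r_h$mean_rates), var(r_0$mean_rates))
})

test_that("new spines start near w_o with the configured jitter", {
  m <- make_gaussian_model(p = 3, M = 20, seed = 66)
  net <- build_plastic_network(m, gamma = 0.4, N = 10, seed = 67)
  cfg <- plasticity_config("dual_hebbian", tau_c = 50, sigma_w_init = 0.1)
  res <- train(net, m, 2000, cfg, seed = 68)
  born <- res$events[res$events$type == 1, ]
  expect_gt(nrow(born), 10)
  w_o <- m$rX0 / 0.4
  # weights of spines created in the last few steps are still near birth size
  late <- born[born$step > 1950, ]
  if (nrow(late) > 0) {
    w_new <- res$network$W[cbind(late$i, late$j)]
    w_new <- w_new[w_new > 0]
    expect_true(all(abs(w_new / w_o - 1) < 0.6))
  }
})
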