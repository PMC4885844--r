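# The five static coding strategies.

test_that("weight coding: density gamma*q_bar, weights q/rho on existing
          connections", {
  m <- make_gaussian_model(p = 5, M = 100, seed = 21)
  q_bar <- mean(m$q)
  gamma <- 0.3
  net <- build_weight_coding(m, gamma, N = 50, seed = 22)
  rho <- gamma * q_bar
  # realized connectivity within a binomial 99% CI
  expect_lt(abs(mean(net$C) - rho), 3 * sqrt(rho * (1 - rho) / 5000))
  sel <- net$selectivity
  on <- net$C == 1
  expect_equal(net$W[on], (m$q[sel, ] / rho)[on])
  expect_true(all(net$W[!on] == 0))
  # gamma large enough for full density: all-to-all with w = q
  net1 <- build_weight_coding(m, gamma = 5, N = 10, seed = 23)
  expect_true(all(net1$C == 1))
  expect_equal(net1$W, m$q[net1$selectivity, ])
})

test_that("weight coding arithmetic on a constant-tuning toy", {
  # q_jmu = 2 everywhere, gamma = 0.25 -> rho = 0.5, w = 4
  m <- manual_model(matrix(2, 2, 10))
  net <- build_weight_coding(m, gamma = 0.25, N = 4, seed = 24)
  expect_equal(net$rho_o, 0.5)
  expect_true(all(net$W[net$C == 1] == 4))
})

test_that("connectivity coding: constant weights 1/gamma, tuned
          probabilities", {
  m <- make_gaussian_model(p = 5, M = 100, seed = 25)
  net <- build_connectivity_coding(m, gamma = 0.3, N = 50, seed = 26)
  expect_true(all(net$W[net$C == 1] == 1 / 0.3))
  expect_equal(net$P, pmin(0.3 * m$q[net$selectivity, ], 1))
  # zero-response inputs are never connected
  th <- matrix(c(0, 1, 2, 0.5), 2, 2)
  mz <- manual_model(th)
  netz <- build_connectivity_coding(mz, gamma = 0.4, N = 4, seed = 27)
  expect_true(all(netz$C[, 1][netz$selectivity == 1] == 0))
  # empirical per-pair connection frequency tracks min(gamma q, 1)
  freq <- Reduce(`+`, lapply(1:200, function(k)
    build_connectivity_coding(m, gamma = 0.3, N = 5, seed = 1000 + k)$C)) /
    200
  pm <- pmin(0.3 * m$q[selectivity_map(5, 5), ], 1)
  se <- sqrt(pm * (1 - pm) / 200)
  expect_gt(mean(abs(freq - pm) <= 3 * se + 1e-9), 0.98)
})

test_that("dual coding couples probabilities and weights", {
  m <- make_gaussian_model(p = 5, M = 100, seed = 28)
  gamma <- 0.25
  net <- build_dual_coding(m, gamma, N = 50, seed = 29)
  rho_bar <- gamma * mean(m$q)
  sel <- net$selectivity
  expect_equal(net$W[net$C == 1], (m$q[sel, ] / rho_bar)[net$C == 1])
  expect_equal(net$P, pmin(gamma * m$q[sel, ], 1))
  # weights positively correlated with connection probability across pairs
  expect_gt(cor(as.vector(net$P), as.vector(m$q[sel, ] / rho_bar)), 0.99)
  # expected in-degree gamma * sum_j q_j_mu when gamma q_max <= 1
  indeg <- rowSums(net$C)
  expect_equal(mean(indeg), gamma * mean(rowSums(m$q[sel, ])),
               tolerance = 0.1)
  # homogeneous tuning degenerates to uniform-probability wiring
  mh <- manual_model(matrix(1.5, 3, 12))
  neth <- build_dual_coding(mh, gamma = 0.3, N = 6, seed = 30)
  expect_equal(unname(neth$P), matrix(0.45, 6, 12))
  expect_true(all(neth$W[neth$C == 1] == neth$W[neth$C == 1][1]))
})

test_that("cut-off coding keeps exactly the top round(M rho_o) weights per
          output", {
  m <- make_gaussian_model(p = 5, M = 100, seed = 31)
  net <- build_cutoff_coding(m, rho_o = 0.23, N = 20, seed = 32)
  expect_true(all(rowSums(net$C) == 23))
  # kept entries dominate dropped entries row-wise
  for (i in c(1, 10)) {
    expect_gte(min(net$W[i, net$C[i, ] == 1]),
               max(net$W[i, net$C[i, ] == 0]))
  }
  # top-k on a hand row: weights [0.3, 0.1, 0.2, 0.0], rho_o = 0.5
  mm <- manual_model(matrix(c(0.3, 0.1, 0.2, 0.0), 1, 4)[c(1, 1), ])
  netm <- build_cutoff_coding(mm, rho_o = 0.5, N = 2, seed = 33)
  expect_equal(unname(netm$C[1, ]), c(1, 0, 1, 0))
  # rho_o = 1 is all-to-all
  expect_true(all(build_cutoff_coding(m, 1, N = 5, seed = 34)$C == 1))
})

test_that("cut-off tie-breaking is random but preserves the exact count", {
  mm <- manual_model(matrix(1, 2, 10))  # all weights tie
  picks <- sapply(1:40, function(k)
    which(build_cutoff_coding(mm, 0.3, N = 2, seed = 40 + k)$C[1, ] == 1))
  expect_true(all(colSums(matrix(picks, 3)) > 0))
  expect_gt(length(unique(as.vector(picks))), 5)  # ties land on many inputs
})

test_that("random coding is tuning-independent at the target density", {
  m <- make_gaussian_model(p = 5, M = 100, seed = 35)
  net <- build_random_coding(m, rho_o = 0.3, N = 50, seed = 36)
  expect_lt(abs(mean(net$C) - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  r <- cor(as.vector(net$C), as.vector(m$q[net$selectivity, ]))
  expect_lt(abs(r), 3 / sqrt(5000))
  expect_equal(net$W[net$C == 1],
               (m$q[net$selectivity, ] / 0.3)[net$C == 1])
})

test_that("all strategies yield non-negative weights masked by C", {
  m <- tiny_gauss()
  nets <- list(build_weight_coding(m, 0.3, N = 8, seed = 1),
               build_connectivity_coding(m, 0.3, N = 8, seed = 2),
               build_dual_coding(m, 0.3, N = 8, seed = 3),
               build_cutoff_coding(m, 0.3, N = 8, seed = 4),
               build_random_coding(m, 0.3, N = 8, seed = 5))
  for (net in nets) {
    expect_true(all(net$W >= 0))
    expect_true(all(net$W[net$C == 0] == 0))
    expect_true(all(net$P >= 0 & net$P <= 1))
  }
})

test_that("at full density the tuned strategies recover the Bayes oracle", {
  m <- tiny_gauss()
  ep <- sample_episode(m, 100, seed = 6)
  post <- bayes_posterior(m, ep$r_X)
  N <- 8
  G <- matrix(0, N, m$p); G[cbind(1:N, selectivity_map(m$p, N))] <- 1
  for (build in list(
    function() build_weight_coding(m, gamma = 10, N = N, h_w = 0, seed = 7),
    function() build_dual_coding(m, gamma = 1.05 / min(m$q), N = N,
                                 h_w = 0, seed = 8),
    function() build_cutoff_coding(m, 1, N = N, h_w = 0, seed = 9),
    function() build_random_coding(m, 1, N = N, h_w = 0, seed = 10))) {
    net <- build()
    expect_lt(max(abs(network_rates(net, ep) %*% G - post)), 1e-10)
  }
})

test_that("matched densities give comparable synapse counts across
          strategies", {
  m <- make_gaussian_model(p = 5, M = 100, seed = 37)
  gamma <- 0.3
  rho <- gamma * mean(m$q)
  n_w <- sum(build_weight_coding(m, gamma, N = 50, seed = 38)$C)
  n_d <- sum(build_dual_coding(m, gamma, N = 50, seed = 39)$C)
  n_r <- sum(build_random_coding(m, rho, N = 50, seed = 40)$C)
  n_exp <- 5000 * rho
  se <- 3 * sqrt(5000 * rho * (1 - rho))
  expect_lt(abs(n_w - n_exp), se)
  expect_lt(abs(n_d - n_exp), se)
  expect_lt(abs(n_r - n_exp), se)
})
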