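# Decoding accuracy, transfer entropy, model error, KL-gap machinery.

test_that("selectivity assignment recovers diagonal structure and breaks
          ties low", {
  s <- rep(1:3, each = 4)
  rY <- matrix(0.1, 12, 3)
  for (mu in 1:3) rY[s == mu, mu] <- 1   # neuron mu fires for state mu
  expect_equal(assign_selectivity(rY, s, 3), 1:3)
  # constant activity: every neuron ties across states -> state 1
  expect_equal(assign_selectivity(matrix(1, 12, 3), s, 3), rep(1, 3))
  expect_error(assign_selectivity(matrix(1, 0, 3), integer(0), 3), "empty")
})

test_that("accuracy scoring uses strict group-mean comparisons", {
  s <- c(1, 2, 1, 2)
  rY <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.2, 0.8))
  groups <- c(1, 2)
  # step 3 is a tie -> failure under the strict inequality
  expect_equal(estimate_accuracy(rY, s, groups, 2), 3 / 4)
  expect_equal(estimate_accuracy(rY, s, groups, 1), 1)  # p = 1 trivially
  # a state with no assigned neurons scores as failure
  expect_equal(estimate_accuracy(rY, s, c(1, 1), 2), 2 / 4)
})

test_that("noiseless inputs with optimal weights decode perfectly", {
  m <- set_noise(tiny_gauss(), 1e-6)
  net <- make_dense_network(m, N = 8, h_w = 0)
  expect_equal(bootstrap_accuracy(m, net, T_o = 200, seed = 70)$accuracy, 1)
})

test_that("untrained random connectivity sits near chance level", {
  m <- make_gaussian_model(p = 10, M = 100, seed = 71)
  net <- build_random_coding(m, rho_o = 0.3, N = 50, seed = 72)
  net$W <- matrix(1, 50, 100) * net$C   # uninformative constant weights
  acc <- bootstrap_accuracy(m, net, T_o = 500, seed = 73)$accuracy
  expect_lt(acc, 0.25)
  expect_gt(acc, 0.0)
})

test_that("transfer entropy is bounded by log p and saturates for dense
          noiseless networks", {
  m <- tiny_gauss()
  net <- build_dual_coding(m, 0.3, N = 8, seed = 74)
  te <- transfer_entropy(m, net, n_samples = 300, seed = 75)
  expect_lte(te, log(4) + 1e-9)
  expect_gt(te, 0)
  m0 <- set_noise(tiny_gauss(), 0.05)
  net0 <- make_dense_network(m0, N = 8, h_w = 0)
  expect_gt(transfer_entropy(m0, net0, n_samples = 300, seed = 76),
            0.98 * log(4))
})

test_that("transfer entropy matches a dense numerical-integration oracle on
          a tiny model", {
  # p = 2, M = 2 Gaussian model: H(s | r, C_all) by 2-d quadrature
  th <- matrix(c(0.5, 1.5, 1.5, 0.5), 2, 2)
  m <- manual_model(th)
  net <- make_dense_network(m, N = 2, h_w = 0)
  grid <- seq(-6, 8, length.out = 241)
  h <- grid[2] - grid[1]
  H_cond <- 0
  for (mu in 1:2) {
    for (r1 in grid) {
      # joint density of (r1, r2) under each candidate state, r2 on the grid
      lik <- rbind(dnorm(r1, th[1, 1]) * dnorm(grid, th[1, 2]),
                   dnorm(r1, th[2, 1]) * dnorm(grid, th[2, 2]))
      post <- t(lik) / colSums(lik)           # posterior per grid point
      Hr <- -rowSums(post * log(pmax(post, 1e-300)))
      # weight by the density under the true state mu; states are uniform
      H_cond <- H_cond + 0.5 * sum(Hr * lik[mu, ]) * h^2
    }
  }
  te_oracle <- log(2) - H_cond
  te_mc <- transfer_entropy(m, net, n_samples = 4000, seed = 77)
  expect_lt(abs(te_mc - te_oracle), 0.03)   # ~3 MC standard errors
})

test_that("model error is zero for a faithful encoding and scale
          invariant", {
  m <- tiny_gauss()
  net <- make_dense_network(m, N = 8, h_w = 0)
  expect_equal(model_error(m, net, mode = "combined"), 0, tolerance = 1e-12)
  net2 <- net
  net2$W <- net$W * 7.3
  expect_equal(model_error(m, net2, mode = "combined"), 0,
               tolerance = 1e-12)
  expect_error(model_error(m, net, groups = rep(1, 8)), "empty")
})

test_that("connectivity-mode model error sees tuned wiring", {
  m <- make_gaussian_model(p = 5, M = 80, seed = 78)
  d_tuned <- mean(sapply(1:5, function(k) model_error(
    m, build_connectivity_coding(m, 0.15, N = 40, seed = 80 + k),
    mode = "connectivity_only")))
  d_rand <- mean(sapply(1:5, function(k) model_error(
    m, build_random_coding(m, 0.15 * mean(m$q), N = 40, seed = 90 + k),
    mode = "connectivity_only")))
  expect_lt(d_tuned, d_rand)
})

test_that("KL gap is zero for the full structure and positive otherwise", {
  m <- tiny_gauss()
  C_all <- matrix(1, 8, m$M)
  expect_equal(kl_gap(m, C_all), 0, tolerance = 1e-12)
  set.seed(95)
  C <- matrix(as.numeric(runif(8 * m$M) < 0.2), 8, m$M)
  expect_gt(kl_gap(m, C), 0)
  # The closed form integrates the noise as a ratio of expectations — a
  # rough approximation of the sampled noise-averaged posterior used to
  # rank candidate structures. Both routes must agree that sparser
  # structures lose more information, and must co-vary across structures.
  m2 <- make_gaussian_model(p = 4, M = 30, seed = 96)
  set.seed(97)
  dens <- seq(0.08, 0.7, length.out = 12)
  cf <- mc <- numeric(12)
  for (k in seq_along(dens)) {
    Ck <- matrix(as.numeric(runif(8 * 30) < dens[k]), 8, 30)
    cf[k] <- kl_gap(m2, Ck, mode = "closed_form")
    mc[k] <- kl_gap(m2, Ck, mode = "monte_carlo", n_samples = 400,
                    seed = 100 + k)
  }
  expect_true(all(cf >= 0) && all(mc >= -1e-9))
  expect_lt(cor(cf, dens, method = "spearman"), 0)
  expect_lt(cor(mc, dens, method = "spearman"), 0)
  expect_gt(cor(cf, mc, method = "spearman"), 0.5)
})

test_that("information gain follows tuning strength", {
  m <- make_gaussian_model(p = 4, M = 40, seed = 97)
  # weaken one input to near zero response
  m$theta[, 7] <- 1e-4
  m$q[, 7] <- 1e-4
  prof <- info_gain_profile(m, pairs = cbind(c(3, 3), c(7, 1)),
                            n_structures = 60, rho = 0.15, N = 16,
                            seed = 98)
  expect_lt(abs(prof$delta_I[1]), 1e-4)    # uninformative input: no gain
  # across many pairs, gain increases with the optimal weight
  set.seed(99)
  pairs <- cbind(sample(16, 30, TRUE), sample(40, 30, TRUE))
  prof2 <- info_gain_profile(m, pairs, n_structures = 60, rho = 0.15,
                             N = 16, seed = 100)
  expect_gt(cor(prof2$w, prof2$delta_I, method = "spearman"), 0.3)
})

test_that("constant-response inputs have large weights but little gain", {
  m <- make_structured_binary_model(p = 4, M = 40, seed = 101)
  const <- m$params$constant_inputs
  pairs <- cbind(2, c(const[1:5], setdiff(1:40, const)[1:5]))
  prof <- info_gain_profile(m, pairs, n_structures = 80, rho = 0.1, N = 16,
                            seed = 102)
  gain_const <- mean(prof$delta_I[1:5])
  gain_var <- mean(prof$delta_I[6:10])
  expect_gt(mean(prof$w[1:5]), mean(prof$w[6:10]))  # big synapses...
  expect_lt(gain_const, gain_var)                   # ...but less information
})

test_that("hill climbing only improves the objective", {
  m <- make_gaussian_model(p = 3, M = 24, seed = 103)
  hc <- hillclimb_connectivity(m, density = 0.25, N = 9, restarts = 2,
                               n_proposals = 400, seed = 104)
  for (tr in hc$traces) expect_true(all(diff(tr) <= 1e-12))
  expect_equal(rowSums(hc$C), rep(6, 9))
  # full density returns the all-to-all structure with zero gap
  hc1 <- hillclimb_connectivity(m, density = 1, N = 9)
  expect_equal(hc1$I, 0)
  # beats random structures of the same density on average
  set.seed(105)
  rand_I <- mean(sapply(1:10, function(k) {
    C <- matrix(0, 9, 24)
    for (i in 1:9) C[i, sample(24, 6)] <- 1
    kl_gap(m, C)
  }))
  expect_lt(hc$I, rand_I)
})

test_that("wiring-rule updates align with the transfer-entropy gradient", {
  m <- make_gaussian_model(p = 4, M = 60, seed = 106)
  net <- build_dual_coding(m, gamma = 0.3, N = 16, seed = 107)
  cosine <- te_gradient_alignment(m, net, n_samples = 150, seed = 108)
  expect_gt(cosine, 0)
  expect_lte(cosine, 1)
})

test_that("removing connections cannot add transfer entropy on average", {
  m <- make_gaussian_model(p = 4, M = 60, seed = 109)
  te_full <- transfer_entropy(m, make_dense_network(m, 16, h_w = 0),
                              n_samples = 400, seed = 110)
  te_sub <- mean(sapply(1:4, function(k) {
    net <- build_random_coding(m, 0.3, N = 16, seed = 110 + k)
    transfer_entropy(m, net, n_samples = 400, seed = 120 + k)
  }))
  expect_gt(te_full, te_sub)
})
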