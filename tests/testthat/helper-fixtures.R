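# Small fixtures shared across test files. Everything is generated in code;
# seeds are fixed so expectations are stable.

tiny_gauss <- function(p = 4, M = 30, seed = 101, ...) {
  make_gaussian_model(p = p, M = M, seed = seed, ...)
}

tiny_poisson <- function(p = 4, M = 30, seed = 102, ...) {
  make_poisson_model(p = p, M = M, seed = seed, ...)
}

# A hand-built model with a prescribed theta matrix (bypasses the random
# constructors; used for arithmetic checks).
manual_model <- function(theta, sigma_x = 1, rX0 = NULL) {
  if (is.null(rX0)) rX0 <- sqrt(mean(theta[1, ]^2))
  dualHebb:::new_external_model(theta, theta, gaussian_family(sigma_x),
                                rX0, sigma_x)
}

# A hand-built network around a model.
manual_network <- function(model, C, W, h_w = 0, P = NULL, gamma = NA) {
  if (is.null(P)) P <- C
  net <- dualHebb:::new_network(C, W, P, model, h_w = h_w, gamma = gamma)
  net
}

expect_no_na <- function(x) expect_false(anyNA(x))
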