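#' @title Closed-form performance theory
#' @description
#' For the Gaussian model, the membrane potential
#' \eqn{u_i = \sum_j c_{ij}(w_{ij} r_{X,j} - w_o)} of a selective and a
#' non-selective output neuron is approximately bivariate Gaussian; its
#' moments admit closed forms under both the weight-coding and the
#' connectivity-coding scheme, from which decoding accuracy and the
#' coefficient of variation of the signal follow. These formulas treat the
#' tuning entries as i.i.d. draws with the moments of the truncated normal,
#' normalized in the large-`M` (ensemble) sense; [sample_membrane_potentials()]
#' draws from exactly that ensemble and serves as the simulation check.
#' @name analytic
NULL

#' Analytic moments of membrane potentials
#'
#' First the tuning moments: for raw values from a normal
#' \eqn{N(\mu_M, \sigma_M)} truncated to \eqn{[0,\infty)} with truncated
#' mean/SD \eqn{(m, s)}, normalization to RMS rate `rX0` gives
#' \deqn{\mu_\theta = \frac{m\, r_X^o}{\sqrt{m^2+s^2}}, \qquad
#'   \sigma_\theta^2 = \frac{s^2 (r_X^o)^2}{m^2+s^2},}
#' so \eqn{\mu_\theta^2+\sigma_\theta^2 = (r_X^o)^2}. The selective mean is
#' \eqn{M\sigma_\theta^2/\sigma_X^2} and the non-selective mean 0 in both
#' schemes; variances and the covariance differ between the schemes — the
#' signal variance grows as \eqn{1/\rho} under weight coding but stays
#' bounded under connectivity coding, which is why connectivity coding wins
#' at sparse density.
#'
#' @param M Number of input neurons.
#' @param rho Mean connection density (determines `gamma` via
#'   \eqn{\rho = \gamma\mu_\theta/\sigma_X^2}).
#' @param scheme `"weight"` or `"connectivity"`.
#' @param mu_M,sigma_M Parameters of the truncated normal from which raw
#'   tuning is drawn.
#' @param sigma_x Input noise scale.
#' @param rX0 RMS input rate.
#' @return A `membrane_moments` list: `mean_sel`, `mean_nonsel`, `var_sel`,
#'   `var_nonsel`, `cov`, plus the tuning moments (`mu_theta`,
#'   `sigma_theta2`), the scheme, and the implied `gamma` and threshold
#'   `w_o`.
#' @export
analytic_moments <- function(M, rho, scheme = c("weight", "connectivity"),
                             mu_M = 1, sigma_M = 1, sigma_x = 1, rX0 = 1) {
  scheme <- match.arg(scheme)
  if (rho <= 0) stop_invalid("rho must be > 0")
  tm <- truncnorm_moments(mu_M, sigma_M)
  norm2 <- tm$mean^2 + tm$sd^2
  mu_t <- tm$mean * rX0 / sqrt(norm2)
  s2_t <- tm$sd^2 * rX0^2 / norm2
  sx2 <- sigma_x^2
  mean_sel <- M * s2_t / sx2
  gamma <- rho * sx2 / mu_t
  if (scheme == "weight") {
    var_sel <- M * (mu_t^2 + s2_t) / (rho * sx2) +
      M * s2_t * (2 * (2 * mu_t^2 + s2_t) + (1 - rho) * s2_t) / (rho * sx2^2)
    var_nonsel <- M * (mu_t^2 + s2_t) / (rho * sx2) +
      M * s2_t * (2 * mu_t^2 + s2_t) / (rho * sx2^2)
    covar <- M * mu_t^2 / sx2
    w_o <- mu_t^2 / (rho * sx2)
  } else {
    var_sel <- M * mu_t / gamma +
      M * s2_t * (mu_t * sx2 - gamma * s2_t) / (gamma * sx2^2)
    var_nonsel <- M * mu_t / gamma + M * mu_t * s2_t / (gamma * sx2)
    covar <- M * mu_t^2 / sx2 + M * mu_t^2 * s2_t / sx2^2
    w_o <- mu_t / gamma
  }
  structure(list(mean_sel = mean_sel, mean_nonsel = 0,
                 var_sel = var_sel, var_nonsel = var_nonsel, cov = covar,
                 mu_theta = mu_t, sigma_theta2 = s2_t,
                 scheme = scheme, M = M, rho = rho, gamma = gamma,
                 sigma_x = sigma_x, rX0 = rX0, w_o = w_o),
            class = "membrane_moments")
}

#' Monte-Carlo membrane potentials for the analytic ensemble
#'
#' Draws membrane potentials of one selective and one non-selective output
#' neuron under the stated coding scheme; every sample gets fresh tuning
#' rows, connections and input noise, and the pair shares the input noise so
#' their covariance is meaningful. Two tuning ensembles are available:
#' \describe{
#'   \item{`"model"`}{faithful to the generator — truncated-normal rows,
#'     each normalized to RMS `rX0` exactly as in [make_gaussian_model()];}
#'   \item{`"iid_gaussian"`}{the ensemble under which the closed forms are
#'     derived — entries i.i.d. normal with the truncated distribution's
#'     mean and SD, normalized only in expectation. Connectivity-coding
#'     probabilities are clipped to `[0, 1]`, which that derivation
#'     neglects.}
#' }
#' The two differ in their second moments by a few percent (the generator
#' pins each row's sum of squares, while its truncated entries have heavier
#' fourth moments), which bounds how closely the closed forms can reproduce
#' either.
#'
#' @inheritParams analytic_moments
#' @param n Number of samples.
#' @param tuning Tuning ensemble, `"model"` (default) or `"iid_gaussian"`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `u_sel` and `u_nonsel`.
#' @export
sample_membrane_potentials <- function(M, rho,
                                       scheme = c("weight", "connectivity"),
                                       n = 10000, mu_M = 1, sigma_M = 1,
                                       sigma_x = 1, rX0 = 1,
                                       tuning = c("model", "iid_gaussian"),
                                       seed = NULL) {
  scheme <- match.arg(scheme)
  tuning <- match.arg(tuning)
  mom <- analytic_moments(M, rho, scheme, mu_M, sigma_M, sigma_x, rX0)
  with_seed(seed, {
    if (tuning == "model") {
      th_mu <- normalize_rms(matrix(rtruncnorm0(n * M, mu_M, sigma_M),
                                    n, M), rX0)
      th_nu <- normalize_rms(matrix(rtruncnorm0(n * M, mu_M, sigma_M),
                                    n, M), rX0)
    } else {
      th_mu <- matrix(rnorm(n * M, mom$mu_theta, sqrt(mom$sigma_theta2)),
                      n, M)
      th_nu <- matrix(rnorm(n * M, mom$mu_theta, sqrt(mom$sigma_theta2)),
                      n, M)
    }
    R <- th_mu + sigma_x * matrix(rnorm(n * M), n, M)
    if (scheme == "weight") {
      Ci <- matrix(runif(n * M) < rho, n, M)
      Cl <- matrix(runif(n * M) < rho, n, M)
      Wi <- th_mu / (rho * sigma_x^2)
      Wl <- th_nu / (rho * sigma_x^2)
    } else {
      Ci <- matrix(runif(n * M), n, M) <
        pmin(pmax(mom$gamma * th_mu / sigma_x^2, 0), 1)
      Cl <- matrix(runif(n * M), n, M) <
        pmin(pmax(mom$gamma * th_nu / sigma_x^2, 0), 1)
      Wi <- Wl <- matrix(1 / mom$gamma, n, M)
    }
    data.frame(u_sel = rowSums(Ci * (Wi * R - mom$w_o)),
               u_nonsel = rowSums(Cl * (Wl * R - mom$w_o)))
  })
}

#' Analytic decoding accuracy and signal variability
#'
#' An estimate fails when a non-selective output fires more than the
#' selective one; under the bivariate Gaussian approximation the pairwise
#' error is the normal tail of the difference,
#' \eqn{\epsilon_w = \Phi(-\Delta\mu/\sigma_\Delta)}, and with `p - 1`
#' independent distractors the accuracy is \eqn{(1-\epsilon_w)^{p-1}}. The
#' coefficient of variation of the signal is
#' \eqn{\sqrt{Var(u_{sel})}/E[u_{sel}]}.
#'
#' @param moments A `membrane_moments` object.
#' @param p Number of hidden states.
#' @return List with `eps_w`, `accuracy`, and `cv`.
#' @export
analytic_accuracy <- function(moments, p) {
  dvar <- moments$var_sel + moments$var_nonsel - 2 * moments$cov
  if (dvar <= 0) stop_invalid("non-positive variance of the difference")
  dmu <- moments$mean_sel - moments$mean_nonsel
  eps_w <- pnorm(-dmu / sqrt(dvar))
  list(eps_w = eps_w,
       accuracy = (1 - eps_w)^(p - 1),
       cv = sqrt(moments$var_sel) / moments$mean_sel)
}

#' Information capacity of connections versus weights
#'
#' For `M x N` potential synapses at density `rho`, the wiring diagram can
#' store \eqn{I_C = \log\binom{MN}{\rho MN} \approx MN\,H(\rho)} nats
#' (entropy function \eqn{H(\rho) = -\rho\log\rho - (1-\rho)\log(1-\rho)}),
#' while weights with `b` distinguishable states store
#' \eqn{I_w = \rho MN \log b}. The capacities break even at
#' \eqn{b^* = \exp[H(\rho)/\rho]}, i.e. \eqn{\log_2 b^*} bits per synapse;
#' sparser wiring raises the break-even point, favoring connectivity as a
#' storage medium.
#'
#' @param M,N Layer sizes.
#' @param rho Connection density in `[0, 1]`.
#' @param b Number of distinguishable synaptic weight states (>= 2).
#' @return List with exact `I_C` (log-binomial, nats), the entropy
#'   approximation `I_C_approx`, `I_w`, the break-even state count
#'   `break_even_b` and `break_even_bits`, and a `boundary` flag for
#'   degenerate densities.
#' @export
info_capacity <- function(M, N, rho, b = 2) {
  if (rho < 0 || rho > 1) stop_invalid("rho must be in [0, 1]")
  if (b < 2) stop_invalid("b must be >= 2")
  n_pairs <- M * N
  boundary <- rho %in% c(0, 1)
  if (boundary) {
    return(list(I_C = 0, I_C_approx = 0, I_w = rho * n_pairs * log(b),
                break_even_b = NA_real_, break_even_bits = NA_real_,
                boundary = TRUE))
  }
  H <- -rho * log(rho) - (1 - rho) * log(1 - rho)
  list(I_C = lchoose(n_pairs, round(rho * n_pairs)),
       I_C_approx = n_pairs * H,
       I_w = rho * n_pairs * log(b),
       break_even_b = exp(H / rho),
       break_even_bits = H / (rho * log(2)),
       boundary = FALSE)
}
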