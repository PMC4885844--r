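#' Exponential-family emission specifications
#'
#' The input layer emits firing rates from a one-parameter exponential family
#' \deqn{f(r \mid \theta) = \exp[h(\theta) g(r) - A(\theta) + B(r)],}
#' where \eqn{h} is the link from the mean response \eqn{\theta} to the
#' natural parameter \eqn{q = h(\theta)}, \eqn{g} the sufficient statistic,
#' \eqn{A} the log-partition function and \eqn{B} the base measure. The
#' reparameterized log-partition \eqn{\alpha(q) = A(h^{-1}(q))} and its
#' derivative \eqn{\alpha'} drive both the Bayes decoder and the plasticity
#' rules.
#'
#' Two families are provided:
#' \describe{
#'   \item{Gaussian}{\eqn{h(\theta)=\theta/\sigma_X^2}, \eqn{g(r)=r},
#'     \eqn{\alpha(q)=\sigma_X^2 q^2/2 + \log(\sqrt{2\pi}\sigma_X)}; rates are
#'     real-valued with additive noise of scale \eqn{\sigma_X}.}
#'   \item{Poisson}{\eqn{h(\theta)=\log\theta}, \eqn{g(r)=r},
#'     \eqn{\alpha(q)=e^q}; rates are integer counts. Weights are measured
#'     relative to a reference rate \eqn{\theta_o} with
#'     \eqn{0 < \theta_o < \min\theta} so that optimal weights
#'     \eqn{\log(\theta/\theta_o)} stay positive. (Some sources write the
#'     same constant as \eqn{\theta_{\min}}; here it is always `theta_o`.)}
#' }
#'
#' `drive(w, rho, sigma)` evaluates \eqn{\alpha'} at the natural parameter a
#' synapse of weight `w` encodes under mean connectivity `rho`
#' (\eqn{\sigma^2\rho w} for Gaussian, \eqn{\theta_o e^{\rho w}} for
#' Poisson); it is the "expected input" term subtracted in the Hebbian
#' updates.
#'
#' @param sigma_x Gaussian noise scale \eqn{\sigma_X > 0}.
#' @param theta_o Poisson reference rate; must satisfy
#'   \eqn{0 < \theta_o < \min_{j\mu}\theta_{j\mu}} for the model it is used
#'   with.
#' @return An object of class `family_spec`: a list of the functions above
#'   plus the family `name` and its noise/reference constant.
#' @examples
#' fam <- gaussian_family(sigma_x = 1)
#' fam$alpha(fam$h(2)) == fam$A(2)
#' @export
gaussian_family <- function(sigma_x = 1) {
  check_scalar(sigma_x, "sigma_x", 0, strict = TRUE)
  structure(list(
    name = "gaussian",
    sigma_x = sigma_x,
    h     = function(theta, sigma = sigma_x) theta / sigma^2,
    h_inv = function(q, sigma = sigma_x) q * sigma^2,
    g     = function(r) r,
    A     = function(theta, sigma = sigma_x)
      theta^2 / (2 * sigma^2) + log(sqrt(2 * pi) * sigma),
    B     = function(r, sigma = sigma_x) -r^2 / (2 * sigma^2),
    alpha = function(q, sigma = sigma_x)
      sigma^2 * q^2 / 2 + log(sqrt(2 * pi) * sigma),
    alpha_prime = function(q, sigma = sigma_x) sigma^2 * q,
    drive = function(w, rho, sigma = sigma_x) sigma^2 * rho * w
  ), class = "family_spec")
}

#' @rdname gaussian_family
#' @export
poisson_family <- function(theta_o = 0.1) {
  check_scalar(theta_o, "theta_o", 0, strict = TRUE)
  structure(list(
    name = "poisson",
    theta_o = theta_o,
    h     = function(theta, ...) log(theta),
    h_inv = function(q, ...) exp(q),
    g     = function(r) r,
    A     = function(theta, ...) theta,
    B     = function(r, ...) -lgamma(r + 1),
    alpha = function(q, ...) exp(q),
    alpha_prime = function(q, ...) exp(q),
    drive = function(w, rho, ...) theta_o * exp(rho * w)
  ), class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  const <- if (x$name == "gaussian") {
    sprintf("sigma_x = %g", x$sigma_x)
  } else {
    sprintf("theta_o = %g", x$theta_o)
  }
  cat(sprintf("<family_spec> %s (%s)\n", x$name, const))
  invisible(x)
}
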