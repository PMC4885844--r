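#' @title Model, network and episode serialization
#' @description Plain-text round-trips: models and networks as JSON
#'   documents (full double precision), episodes as CSV time series, so that
#'   any run can be replayed or inspected outside R.
#' @name serialization
NULL

#' Write / read an external model as JSON
#'
#' Stores the family name and constants, the tuning matrices, noise scales
#' and normalization target; [read_model()] reconstructs the derived fields
#' (`q`, the family closure) from them.
#'
#' @param model An `external_model`.
#' @param path File path.
#' @return `read_model()` returns the reconstructed `external_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    type = "external_model",
    family = model$family$name,
    p = model$p, M = model$M, rX0 = model$rX0,
    theta = model$theta,
    theta_tilde = model$theta_tilde,
    sigma_x = model$sigma_x,
    sigma_x_base = model$sigma_x_base,
    theta_o = if (model$family$name == "poisson") model$family$theta_o else
      NULL,
    params = Filter(Negate(is.matrix), model$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(doc$type, "external_model"))
  fam <- if (doc$family == "gaussian") {
    gaussian_family(doc$sigma_x_base)
  } else {
    poisson_family(doc$theta_o)
  }
  m <- new_external_model(doc$theta, doc$theta_tilde, fam, doc$rX0,
                          if (doc$family == "gaussian") doc$sigma_x else
                            NA_real_,
                          params = as.list(doc$params))
  m
}

#' Write / read a network as JSON
#'
#' @param network A `network`.
#' @param model The `external_model` it was built for (needed to rebuild the
#'   object on read).
#' @param path File path.
#' @return `read_network()` returns the reconstructed `network`;
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  doc <- list(
    type = "network",
    N = network$N, M = network$M, p = network$p,
    C = network$C, W = network$W, P = network$P,
    h_w = network$h_w, rY0 = network$rY0, v_d = network$v_d,
    rho_bar = network$rho_bar, gamma = network$gamma,
    rho_o = network$rho_o, strategy = network$strategy
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, model) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(doc$type, "network"))
  net <- new_network(doc$C, doc$W, doc$P, model, h_w = doc$h_w,
                     rY0 = doc$rY0, v_d = doc$v_d, gamma = doc$gamma,
                     rho_o = doc$rho_o, strategy = doc$strategy)
  net$rho_bar <- doc$rho_bar   # preserve the construction-time reference
  net
}

#' Write / read an episode as CSV
#'
#' Columns: `t`, the hidden state `s`, and one `r_X_<j>` column per input.
#'
#' @param episode An `episode`.
#' @param path File path.
#' @return `read_episode_csv()` returns the reconstructed `episode`;
#'   `write_episode_csv()` returns `path` invisibly.
#' @export
write_episode_csv <- function(episode, path) {
  df <- data.frame(t = seq_along(episode$s), s = episode$s)
  rx <- as.data.frame(episode$r_X)
  names(rx) <- paste0("r_X_", seq_len(ncol(rx)))
  write.csv(cbind(df, rx), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_episode_csv
#' @param p Number of hidden states for the reconstructed episode.
#' @export
read_episode_csv <- function(path, p) {
  df <- read.csv(path)
  r_X <- as.matrix(df[, grep("^r_X_", names(df)), drop = FALSE])
  dimnames(r_X) <- NULL
  structure(list(s = as.integer(df$s), r_X = r_X, p = p,
                 M = ncol(r_X)), class = "episode")
}
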