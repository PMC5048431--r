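#' Gauss-Hermite rule in standard-normal form
#'
#' Rescales the classical Gauss-Hermite rule (weight `exp(-t^2)`) to the
#' probabilists' convention: nodes `theta = sqrt(2) t`, log weights
#' `log(w) - log(pi)/2`, so the weights sum to one and the rule integrates
#' against the standard normal density.
#'
#' @param order Number of nodes per dimension.
#' @return A list with `nodes` (length `order`) and `log_weights`.
#' @keywords internal
gauss_hermite_rule <- function(order) {
  stopifnot(order >= 1)
  gh <- pracma::gaussHermite(order)
  list(nodes = sqrt(2) * gh$x, log_weights = log(gh$w) - 0.5 * log(pi))
}

# Tensor-product grid over m dimensions: nodes K x m, log weights length K
gauss_hermite_grid <- function(order, m) {
  gh <- gauss_hermite_rule(order)
  if (m == 1L) {
    return(list(nodes = matrix(gh$nodes, ncol = 1L),
                log_weights = gh$log_weights))
  }
  idx <- expand.grid(rep(list(seq_len(order)), m), KEEP.OUT.ATTRS = FALSE)
  idx <- as.matrix(idx)
  nodes <- matrix(gh$nodes[idx], ncol = m)
  lw <- rowSums(matrix(gh$log_weights[idx], ncol = m))
  list(nodes = nodes, log_weights = lw)
}

check_theta <- function(theta, mirt) {
  theta <- as.numeric(theta)
  if (length(theta) != mirt$latent_dim) {
    stop("theta has length ", length(theta), " but the model has ",
         mirt$latent_dim, " latent dimensions", call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  theta
}

#' Conditional probability of a configuration given the latent variables
#'
#' Under the latent representation the items are locally independent:
#' `p(x | theta) = prod_i exp(x_i eta_i) / (2 cosh(eta_i))` with linear
#' predictor `eta_i = delta_i + a_i' theta`.  For a single latent dimension
#' with unit loadings this is the Rasch model's conditional distribution.
#'
#' @param x A +1/-1 configuration of length N.
#' @param theta Latent coordinates of length m (may be length 0 when
#'   `latent_dim` is 0).
#' @param mirt A `mirt_model`.
#' @param log If `TRUE` return the log probability.
#' @return A probability (scalar).
#' @export
conditional_pmf <- function(x, theta, mirt, log = FALSE) {
  stopifnot(inherits(mirt, "mirt_model"))
  x <- check_spin(x, mirt$n_items)
  theta <- check_theta(theta, mirt)
  eta <- mirt$delta + drop(mirt$a_matrix %*% theta)
  lp <- sum(x * eta - log2cosh(eta))
  if (log) lp else exp(lp)
}

#' Log normalising constant of the latent density
#'
#' Computes `log Int exp(-theta' theta / 2) prod_i 2 cosh(delta_i + a_i'
#' theta) dtheta` by Gauss-Hermite quadrature on a tensor grid.
#'
#' @param mirt A `mirt_model` with `latent_dim <= 4`.
#' @param order Quadrature order per dimension.
#' @return The log of the integral.
#' @export
latent_log_norm_const <- function(mirt, order = 30) {
  stopifnot(inherits(mirt, "mirt_model"))
  m <- mirt$latent_dim
  if (m == 0L) return(sum(log2cosh(mirt$delta)))
  if (m > 4L) {
    stop("tensor-product quadrature is limited to 4 latent dimensions; ",
         "the collider route gives the same pmf without integration",
         call. = FALSE)
  }
  grid <- gauss_hermite_grid(order, m)
  eta <- mirt$delta + mirt$a_matrix %*% t(grid$nodes)  # N x K
  s <- colSums(log2cosh(eta))
  0.5 * m * log(2 * pi) + logsumexp(grid$log_weights + s)
}

#' Density of the latent variables
#'
#' The latent density induced by the augmentation is
#' `f(theta) proportional to exp(-theta' theta / 2) prod_i 2 cosh(delta_i +
#' a_i' theta)`: a standard-normal kernel tilted by the item terms.  The
#' unnormalised value is cheap and log-domain stable; the normalised value
#' pays one quadrature pass for the constant.
#'
#' @param theta Latent coordinates (length m).
#' @param mirt A `mirt_model`.
#' @param log If `TRUE` return the log density.
#' @param normalised If `TRUE` divide by the quadrature-computed constant
#'   (requires `latent_dim <= 4`).
#' @param order Quadrature order used when `normalised = TRUE`.
#' @return Density value (scalar).
#' @export
latent_density <- function(theta, mirt, log = FALSE, normalised = FALSE,
                           order = 30) {
  stopifnot(inherits(mirt, "mirt_model"))
  theta <- check_theta(theta, mirt)
  eta <- mirt$delta + drop(mirt$a_matrix %*% theta)
  lf <- -0.5 * sum(theta^2) + sum(log2cosh(eta))
  if (normalised) lf <- lf - latent_log_norm_const(mirt, order)
  if (log) lf else exp(lf)
}

#' Marginal pmf of the latent representation by quadrature
#'
#' Recovers the manifest distribution `p(x) = Int p(x | theta) f(theta)
#' dtheta` numerically.  In the joint weight the `2 cosh` normalisers of the
#' conditional cancel against the tilt of `f`, leaving
#' `p(x) proportional to E_(theta ~ N(0, I))[exp(x' (delta + A theta))]`,
#' which is evaluated on a Gauss-Hermite tensor grid of the stated order and
#' renormalised at the end, so quadrature error is absorbed into the
#' normalising constant rather than into probability ratios.
#'
#' @param mirt A `mirt_model` with `latent_dim <= 4` and `n_items <= 20`.
#' @param order Quadrature order per dimension (default 30).
#' @return A `pmf_table` in canonical configuration order.
#' @export
#' @examples
#' m <- as_mirt(curie_weiss(c(0, 0), log(2)))
#' marginal_pmf_quadrature(m, order = 40)$prob  # ~ 0.4 0.1 0.1 0.4
marginal_pmf_quadrature <- function(mirt, order = 30) {
  stopifnot(inherits(mirt, "mirt_model"), order >= 1)
  check_enum_cap(mirt$n_items)
  configs <- spin_configs(mirt$n_items)
  m <- mirt$latent_dim
  if (m == 0L) {
    return(new_pmf_table(configs, drop(configs %*% mirt$delta)))
  }
  if (m > 4L) {
    stop("tensor-product quadrature is limited to 4 latent dimensions ",
         "(cost grows as order^m); the collider route gives the same pmf ",
         "without integration", call. = FALSE)
  }
  grid <- gauss_hermite_grid(order, m)
  n_nodes <- nrow(grid$nodes)
  n_cfg <- nrow(configs)
  # chunk over nodes to bound the 2^N x K working matrix
  chunk <- max(1L, min(n_nodes, as.integer(2^22 / n_cfg)))
  log_acc <- rep(-Inf, n_cfg)
  for (start in seq(1L, n_nodes, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_nodes)
    eta <- mirt$delta + mirt$a_matrix %*% t(grid$nodes[idx, , drop = FALSE])
    lp <- configs %*% eta  # n_cfg x |idx|
    lp <- sweep(lp, 2L, grid$log_weights[idx], "+")
    row_max <- apply(lp, 1L, max)
    chunk_lse <- row_max + log(rowSums(exp(lp - row_max)))
    big <- pmax(log_acc, chunk_lse)
    log_acc <- big + log(exp(log_acc - big) + exp(chunk_lse - big))
    log_acc[!is.finite(big)] <- -Inf
  }
  new_pmf_table(configs, log_acc)
}

#' Exact Gaussian posterior of the latent variables given a configuration
#'
#' Completing the square in the augmented joint gives
#' `theta | x ~ Normal(A' x, I)` under the standard-normal scaling: the
#' posterior mean is the loading-weighted score and the covariance is the
#' identity, with no quadrature involved.
#'
#' @param x A +1/-1 configuration of length N.
#' @param mirt A `mirt_model`.
#' @return An object of class `gaussian_posterior` with fields `mean`
#'   (length m) and `covariance` (the m x m identity).
#' @export
posterior_theta <- function(x, mirt) {
  stopifnot(inherits(mirt, "mirt_model"))
  x <- check_spin(x, mirt$n_items)
  m <- mirt$latent_dim
  structure(list(mean = drop(crossprod(mirt$a_matrix, x)),
                 covariance = diag(1, m), latent_dim = m),
            class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat("Gaussian posterior of theta | x: Normal(mean, I)\n")
  cat("  mean:", format(x$mean, digits = 6), "\n")
  invisible(x)
}

#' Draw from the posterior of the latent variables given a configuration
#'
#' i.i.d. draws from `Normal(A' x, I)`; this is the latent half of the
#' augmented Gibbs sweep held at a fixed configuration.
#'
#' @param mirt A `mirt_model`.
#' @param x A +1/-1 configuration.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return An `n` x m numeric matrix.
#' @export
sample_posterior_theta <- function(mirt, x, n, seed = NULL) {
  stopifnot(n >= 1)
  post <- posterior_theta(x, mirt)
  if (!is.null(seed)) set.seed(seed)
  m <- mirt$latent_dim
  matrix(rnorm(n * m), n, m) +
    matrix(post$mean, n, m, byrow = TRUE)
}
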