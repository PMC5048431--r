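#' Eigenvalue representation of an Ising model
#'
#' Because the diagonal of the coupling matrix is arbitrary, it can be
#' shifted so the matrix becomes positive semi-definite:
#' `sigma + c I = Q diag(lambda) Q'` with all `lambda_r >= 0`.  The minimal
#' shift `c = max(0, -lambda_min(sigma))` is used, so when `sigma` has a
#' negative eigenvalue the shifted matrix has smallest eigenvalue exactly 0.
#' The number of eigenvalues above the rank tolerance is the number of
#' latent dimensions (equivalently, of collider effect variables) in the
#' other two representations.
#'
#' Eigenvectors are made deterministic by a sign convention: the
#' largest-magnitude entry of each column is made positive, ties broken by
#' the lowest index.
#'
#' @param model An `ising_model`.
#' @param rank_tol Relative rank tolerance: eigenvalues above
#'   `rank_tol * max(lambda)` count towards the rank. Default 1e-10.
#' @return An object of class `eigen_rep` with fields `shift_c`, `q_matrix`
#'   (N x N orthonormal columns), `lambdas` (descending, clamped at 0),
#'   `rank_m`, `rank_tol` and `n_items`.
#' @seealso [to_mirt()], [to_collider()]
#' @export
#' @examples
#' eigen_representation(curie_weiss(rep(0, 4), 0.3))$rank_m  # 1
eigen_representation <- function(model, rank_tol = 1e-10) {
  stopifnot(inherits(model, "ising_model"), rank_tol >= 0)
  es <- eigen(model$sigma, symmetric = TRUE)
  shift_c <- max(0, -min(es$values))
  lambdas <- es$values + shift_c
  lambdas[lambdas < 0] <- 0
  q <- es$vectors
  for (r in seq_len(ncol(q))) {
    j <- which.max(abs(q[, r]))
    if (q[j, r] < 0) q[, r] <- -q[, r]
  }
  rank_m <- if (max(lambdas) > 0) sum(lambdas > rank_tol * max(lambdas)) else 0L
  structure(list(shift_c = shift_c, q_matrix = q, lambdas = lambdas,
                 rank_m = as.integer(rank_m), rank_tol = rank_tol,
                 n_items = model$n_items),
            class = "eigen_rep")
}

#' @export
print.eigen_rep <- function(x, ...) {
  cat("Eigenvalue representation\n")
  cat("  items:   ", x$n_items, "\n")
  cat("  shift c: ", format(x$shift_c, digits = 6), "\n")
  cat("  rank m:  ", x$rank_m, "\n")
  cat("  lambda:  ", format(x$lambdas[seq_len(min(5, length(x$lambdas)))],
                            digits = 4),
      if (length(x$lambdas) > 5) "...\n" else "\n")
  invisible(x)
}

#' Convert to the latent-variable (multidimensional IRT) representation
#'
#' Applying the Gaussian identity `exp(a^2) = pi^(-1/2) Int exp(-t^2 + 2 a t)
#' dt` to each squared eigen-component of the Ising exponent introduces one
#' standard-normal latent variable per retained eigenvalue.  Under the
#' standard-normal scaling the discrimination matrix is
#' `A = Q_m diag(sqrt(lambda_m))`, so that `A A' = sigma + c I`.  Columns for
#' numerically zero eigenvalues are dropped; their factors are constants and
#' cancel in the normalisation.
#'
#' @param eig An `eigen_rep`.
#' @param delta Main-effect vector (passed through unchanged).
#' @return An object of class `mirt_model` with fields `delta`, `a_matrix`
#'   (N x m), `latent_dim` and `shift_c`.
#' @export
to_mirt <- function(eig, delta) {
  stopifnot(inherits(eig, "eigen_rep"))
  delta <- as.numeric(delta)
  if (length(delta) != eig$n_items) {
    stop("delta length does not match the eigen representation", call. = FALSE)
  }
  m <- eig$rank_m
  a <- eig$q_matrix[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(eig$lambdas[seq_len(m)]), m)
  structure(list(delta = delta, a_matrix = a, latent_dim = m,
                 shift_c = eig$shift_c, n_items = eig$n_items),
            class = "mirt_model")
}

#' @export
print.mirt_model <- function(x, ...) {
  cat("Multidimensional IRT (latent-variable) representation\n")
  cat("  items:             ", x$n_items, "\n")
  cat("  latent dimensions: ", x$latent_dim, "\n")
  invisible(x)
}

#' Convert back from the latent-variable representation
#'
#' Reconstructs the network form: `sigma = A A'` with the diagonal zeroed
#' (the discarded diagonal is a constant in the exponent, absorbed by the
#' partition function).  The round trip Ising -> MIRT -> Ising preserves the
#' probability table.
#'
#' @param mirt A `mirt_model`.
#' @return An `ising_model`.
#' @export
from_mirt <- function(mirt) {
  stopifnot(inherits(mirt, "mirt_model"))
  sigma <- tcrossprod(mirt$a_matrix)
  if (mirt$latent_dim == 0L) sigma <- matrix(0, mirt$n_items, mirt$n_items)
  diag(sigma) <- 0
  ising_model(mirt$delta, sigma)
}

#' Convert to the collider (common-effect) representation
#'
#' One binary effect variable is attached per retained eigenvalue, with
#' loading vector `sqrt(lambda_r) q_r` and success probability
#' `p(e_r = 1 | x) = exp(0.5 * (l_r' x)^2 - log M_r)`.  The bound
#' `log M_r = 0.5 * lambda_r * N` is sufficient because `(q_r' x)^2 <= N`
#' for a unit vector `q_r` and +1/-1 spins; the conditional distribution of
#' the causes given all effects present does not depend on the bound.
#'
#' @param eig An `eigen_rep`.
#' @param delta Main effects of the marginally independent causes.
#' @return An object of class `collider_model` with fields `delta`,
#'   `loadings` (N x m, one column per effect), `log_bounds` (length m) and
#'   `n_effects`.
#' @export
to_collider <- function(eig, delta) {
  stopifnot(inherits(eig, "eigen_rep"))
  delta <- as.numeric(delta)
  if (length(delta) != eig$n_items) {
    stop("delta length does not match the eigen representation", call. = FALSE)
  }
  m <- eig$rank_m
  lam <- eig$lambdas[seq_len(m)]
  loadings <- eig$q_matrix[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m)
  structure(list(delta = delta, loadings = loadings,
                 log_bounds = 0.5 * lam * eig$n_items,
                 n_effects = m, n_items = eig$n_items),
            class = "collider_model")
}

#' @export
print.collider_model <- function(x, ...) {
  cat("Collider (common-effect) representation\n")
  cat("  causes:  ", x$n_items, "\n")
  cat("  effects: ", x$n_effects, "\n")
  invisible(x)
}

#' Convert back from the collider representation
#'
#' @param coll A `collider_model`.
#' @return An `ising_model` whose pmf equals the collider's conditional
#'   distribution given all effects present.
#' @export
from_collider <- function(coll) {
  stopifnot(inherits(coll, "collider_model"))
  sigma <- tcrossprod(coll$loadings)
  if (coll$n_effects == 0L) sigma <- matrix(0, coll$n_items, coll$n_items)
  diag(sigma) <- 0
  ising_model(coll$delta, sigma)
}

#' One-step conversions from the network form
#'
#' Convenience wrappers composing [eigen_representation()] with [to_mirt()]
#' or [to_collider()].
#'
#' @param model An `ising_model`.
#' @param rank_tol Passed to [eigen_representation()].
#' @return A `mirt_model` or `collider_model`.
#' @export
as_mirt <- function(model, rank_tol = 1e-10) {
  to_mirt(eigen_representation(model, rank_tol), model$delta)
}

#' @rdname as_mirt
#' @export
as_collider <- function(model, rank_tol = 1e-10) {
  to_collider(eigen_representation(model, rank_tol), model$delta)
}

#' Detect the Rasch special case
#'
#' The latent representation collapses to the Rasch model when there is a
#' single latent dimension and all items load on it equally (a common
#' discrimination can be absorbed into the scale of the latent trait).  This
#' is exactly what the Curie-Weiss model produces: rank one with loadings
#' `sqrt(s)` for every item.
#'
#' @param mirt A `mirt_model`.
#' @param tol Absolute tolerance for equality of the loadings.
#' @return A list of class `rasch_report` with elements `is_rasch`
#'   (logical), `common_loading` (the mean loading if `is_rasch`, else `NA`)
#'   and `reason`.
#' @export
#' @examples
#' rasch_special_case(as_mirt(curie_weiss(rep(0, 4), 0.3)))$is_rasch  # TRUE
rasch_special_case <- function(mirt, tol = 1e-8) {
  stopifnot(inherits(mirt, "mirt_model"))
  if (mirt$latent_dim != 1L) {
    out <- list(is_rasch = FALSE, common_loading = NA_real_,
                reason = paste0("latent dimension is ", mirt$latent_dim,
                                ", not 1"))
  } else {
    a <- drop(mirt$a_matrix)
    spread <- max(a) - min(a)
    if (spread <= tol) {
      out <- list(is_rasch = TRUE, common_loading = mean(a),
                  reason = paste0("single latent dimension with common ",
                                  "loading ", format(mean(a), digits = 10)))
    } else {
      out <- list(is_rasch = FALSE, common_loading = NA_real_,
                  reason = paste0("loadings differ by ",
                                  format(spread, digits = 4)))
    }
  }
  structure(out, class = "rasch_report")
}

#' @export
print.rasch_report <- function(x, ...) {
  cat(if (x$is_rasch) "Rasch special case: yes\n" else
        "Rasch special case: no\n")
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}
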