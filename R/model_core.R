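#' isingtriad: three equivalent representations of the Ising model
#'
#' The Ising model for a vector of N binary (+1/-1) variables assigns
#' probability proportional to `exp(delta' x + sum_{i<j} sigma_ij x_i x_j)`.
#' The same distribution admits two further parameterisations: a
#' multidimensional item response theory (latent-variable) form, obtained by
#' linearising the quadratic interaction with a Gaussian integral, and a
#' collider (common-effect) form in which marginally independent causes are
#' conditioned on a set of effect variables all being present.  This package
#' implements all three forms, exact conversions between them, exact and
#' Monte Carlo sampling under each, and a numerical engine that certifies the
#' distribution-level equivalence in total variation.
#'
#' @useDynLib isingtriad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom plogis sd cor
#' @keywords internal
"_PACKAGE"

# Exact enumeration is capped: 2^N configurations are materialised.
.enum_cap <- 20L

check_enum_cap <- function(n_items) {
  if (n_items > .enum_cap) {
    stop("exact enumeration requires n_items <= ", .enum_cap,
         " (got ", n_items, "); use a sampler for larger models",
         call. = FALSE)
  }
  invisible(n_items)
}

#' Enumerate all spin configurations
#'
#' Returns the full set of `2^N` configurations of `N` spins in a fixed
#' canonical order: lexicographic with `-1` before `+1`, item 1 varying
#' slowest.  Every probability table in the package uses this order, so
#' tables from different representations are directly comparable row by row.
#'
#' @param n_items Number of binary variables (N, at most 20).
#' @return An integer matrix with `2^N` rows and `N` columns of +1/-1 values.
#' @export
#' @examples
#' spin_configs(2)
spin_configs <- function(n_items) {
  n_items <- as.integer(n_items)
  stopifnot(n_items >= 1L)
  check_enum_cap(n_items)
  grid <- expand.grid(rep(list(c(-1L, 1L)), n_items), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid[, rev(seq_len(n_items)), drop = FALSE])
  dimnames(m) <- list(NULL, paste0("x_", seq_len(n_items)))
  m
}

check_spin <- function(x, n_items) {
  x <- as.numeric(x)
  if (length(x) != n_items) {
    stop("configuration has length ", length(x), ", model has ", n_items,
         " items", call. = FALSE)
  }
  if (!all(x %in% c(-1, 1))) {
    stop("spin values must be exactly +1 or -1", call. = FALSE)
  }
  x
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# log(2*cosh(x)), overflow-safe for |x| beyond ~700
log2cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x)))

#' Construct an Ising model (network representation)
#'
#' Stores the main-effect vector `delta` and the symmetric pairwise coupling
#' matrix `sigma` in canonical form.  Because `x_i * x_i = 1` for +1/-1
#' spins, any diagonal of `sigma` only adds a constant to the exponent and is
#' cancelled by the partition function; the constructor therefore zeroes the
#' diagonal, which is what makes the diagonal-shift trick behind the other
#' two representations legitimate.
#'
#' @param delta Numeric vector of N main effects.
#' @param sigma Symmetric N x N numeric matrix of pairwise couplings.
#'   Symmetry is enforced to within 1e-12; the diagonal is discarded.
#' @return An object of class `ising_model` with fields `delta`, `sigma`
#'   (zero diagonal) and `n_items`.
#' @seealso [curie_weiss()], [random_ising()], [pmf_table()],
#'   [eigen_representation()]
#' @export
#' @examples
#' m <- ising_model(c(0, 0), matrix(c(0, log(2), log(2), 0), 2))
#' pmf_table(m)$prob
ising_model <- function(delta, sigma) {
  delta <- as.numeric(delta)
  n <- length(delta)
  if (n < 1L) stop("delta must have length >= 1", call. = FALSE)
  sigma <- as.matrix(sigma)
  if (!is.numeric(sigma) || nrow(sigma) != ncol(sigma)) {
    stop("sigma must be a square numeric matrix", call. = FALSE)
  }
  if (nrow(sigma) != n) {
    stop("delta has length ", n, " but sigma is ", nrow(sigma), " x ",
         ncol(sigma), call. = FALSE)
  }
  if (anyNA(sigma) || any(!is.finite(sigma)) || any(!is.finite(delta))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  asym <- abs(sigma - t(sigma))
  if (any(asym > 1e-12)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop("sigma is not symmetric: sigma[", ij[1L], ",", ij[2L],
         "] != sigma[", ij[2L], ",", ij[1L], "]", call. = FALSE)
  }
  sigma <- (sigma + t(sigma)) / 2
  diag(sigma) <- 0
  dimnames(sigma) <- NULL
  structure(list(delta = delta, sigma = sigma, n_items = n),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  nz <- sum(x$sigma[upper.tri(x$sigma)] != 0)
  cat("Ising model (network representation)\n")
  cat("  items:          ", x$n_items, "\n")
  cat("  nonzero pairs:  ", nz, " of ", choose(x$n_items, 2), "\n", sep = "")
  invisible(x)
}

#' Curie-Weiss model: equal couplings between all pairs
#'
#' The Curie-Weiss model is the Ising model in which every off-diagonal
#' coupling equals the same constant, so the interaction term depends on the
#' configuration only through the sum of the spins.  It is the bridge case:
#' its shifted coupling matrix has rank one, so its latent representation is
#' unidimensional and, with equal main effects scaling, reduces to the Rasch
#' model.
#'
#' @param delta Numeric vector of N main effects.
#' @param coupling Common pairwise coupling (any finite real).
#' @return An `ising_model`.
#' @export
#' @examples
#' cw <- curie_weiss(rep(0, 4), 0.3)
curie_weiss <- function(delta, coupling) {
  delta <- as.numeric(delta)
  stopifnot(length(coupling) == 1L, is.finite(coupling))
  n <- length(delta)
  sigma <- matrix(coupling, n, n)
  diag(sigma) <- 0
  ising_model(delta, sigma)
}

#' Random Ising model generator
#'
#' Draws a reproducible random model: each off-diagonal pair is nonzero with
#' probability `density`, nonzero couplings and the main effects are
#' independent normal with standard deviation `scale`.
#'
#' @param n_items Number of variables (>= 1).
#' @param density Probability in \[0, 1\] that a pair is coupled.
#' @param scale Standard deviation of couplings and main effects (> 0).
#' @param seed Optional integer seed; fixed seed gives identical parameters.
#' @return An `ising_model`.
#' @export
random_ising <- function(n_items, density = 1, scale = 0.5, seed = NULL) {
  n_items <- as.integer(n_items)
  stopifnot(n_items >= 1L, density >= 0, density <= 1, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  delta <- rnorm(n_items, sd = scale)
  sigma <- matrix(0, n_items, n_items)
  if (n_items > 1L) {
    up <- upper.tri(sigma)
    k <- sum(up)
    vals <- rnorm(k, sd = scale) * (runif(k) < density)
    sigma[up] <- vals
    sigma <- sigma + t(sigma)
  }
  ising_model(delta, sigma)
}

#' Random low-rank Ising model generator
#'
#' Draws a model whose shifted coupling matrix has an exact low rank: a
#' random N x m loading matrix is drawn and its rows rescaled to a common
#' length `scale`, so `L L'` has constant diagonal `scale^2`.  Zeroing that
#' diagonal gives the canonical coupling matrix, and the canonical diagonal
#' shift restores exactly `L L'`, of rank `rank`.  These are the natural test
#' models for the latent (quadrature) route, whose cost grows with the
#' number of latent dimensions.
#'
#' @param n_items Number of variables (> `rank`).
#' @param rank Number of latent dimensions (>= 1).
#' @param scale Common row length of the loading matrix (> 0).
#' @param seed Optional integer seed.
#' @return An `ising_model` whose [eigen_representation()] has `rank_m ==
#'   rank` and `shift_c == scale^2`.
#' @export
random_low_rank_ising <- function(n_items, rank, scale = 0.4, seed = NULL) {
  n_items <- as.integer(n_items)
  rank <- as.integer(rank)
  stopifnot(rank >= 1L, n_items > rank, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- matrix(rnorm(n_items * rank), n_items, rank)
  L <- L * (scale / sqrt(rowSums(L^2)))
  delta <- rnorm(n_items, sd = scale)
  sigma <- L %*% t(L)
  diag(sigma) <- 0
  ising_model(delta, sigma)
}

#' Log unnormalised weight of a configuration
#'
#' Computes `H(x) = sum_i delta_i x_i + sum_{i<j} sigma_ij x_i x_j`, each
#' unordered pair counted once.  The probability of `x` is
#' `exp(H(x) - log Z)`.
#'
#' @param model An `ising_model`.
#' @param x A +1/-1 vector of length N, or a matrix with one configuration
#'   per row.
#' @return A numeric scalar (or vector, for matrix input).
#' @export
log_weight <- function(model, x) {
  stopifnot(inherits(model, "ising_model"))
  if (is.matrix(x)) {
    apply(x, 1L, function(r) log_weight(model, r))
  } else {
    x <- check_spin(x, model$n_items)
    # diagonal is zero, so the quadratic form double-counts each pair once
    sum(model$delta * x) + 0.5 * drop(x %*% model$sigma %*% x)
  }
}

# log weights for all 2^N configurations, in canonical order
all_log_weights <- function(model, configs = NULL) {
  if (is.null(configs)) configs <- spin_configs(model$n_items)
  drop(configs %*% model$delta) +
    0.5 * rowSums((configs %*% model$sigma) * configs)
}

new_pmf_table <- function(configs, log_weights) {
  lz <- logsumexp(log_weights)
  lp <- log_weights - lz
  structure(list(configs = configs, prob = exp(lp), log_prob = lp,
                 log_partition = lz, n_items = ncol(configs)),
            class = "pmf_table")
}

#' Log partition function by exact enumeration
#'
#' Log-sum-exp of the log weights over all `2^N` configurations; stable for
#' exponents up to about 700 in magnitude.
#'
#' @param model An `ising_model`.
#' @return `log Z`, a numeric scalar.
#' @export
#' @examples
#' log_partition(ising_model(c(0, 0), matrix(0, 2, 2)))  # log(4)
log_partition <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  check_enum_cap(model$n_items)
  logsumexp(all_log_weights(model))
}

#' Exact probability table of an Ising model
#'
#' Enumerates all `2^N` configurations (canonical order, see
#' [spin_configs()]) and returns their exact probabilities together with the
#' log partition function.  This table is the common currency in which the
#' equivalence of the three representations is certified.
#'
#' @param model An `ising_model`.
#' @return An object of class `pmf_table` with fields `configs` (2^N x N),
#'   `prob`, `log_prob`, `log_partition` and `n_items`.
#' @export
#' @examples
#' pmf_table(curie_weiss(c(0, 0), log(2)))$prob  # 0.4 0.1 0.1 0.4
pmf_table <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  check_enum_cap(model$n_items)
  configs <- spin_configs(model$n_items)
  new_pmf_table(configs, all_log_weights(model, configs))
}

#' @export
print.pmf_table <- function(x, ...) {
  cat("Exact pmf over ", nrow(x$configs), " configurations of ",
      x$n_items, " spins\n", sep = "")
  cat("  log Z = ", format(x$log_partition, digits = 15), "\n", sep = "")
  cat("  max p = ", format(max(x$prob), digits = 6),
      ", min p = ", format(min(x$prob), digits = 6), "\n", sep = "")
  invisible(x)
}

#' First and second moments of a binary distribution
#'
#' Computes `E[X_i]`, `E[X_i X_j]` and the Pearson correlations, either
#' exactly from a probability table or empirically from a matrix of +1/-1
#' draws (one configuration per row).
#'
#' @param x A `pmf_table`, a `sample_set`, or a +1/-1 matrix of draws.
#' @param ... Unused.
#' @return An object of class `moment_summary` with fields `means`
#'   (length N), `pair_products` (N x N, unit diagonal) and `correlations`
#'   (N x N, unit diagonal).
#' @export
moments <- function(x, ...) UseMethod("moments")

moment_summary_from <- function(configs, w) {
  means <- unname(drop(crossprod(configs, w)))
  pair <- unname(crossprod(configs, configs * w))
  pair <- (pair + t(pair)) / 2
  diag(pair) <- 1
  v <- 1 - means^2
  denom <- sqrt(outer(v, v))
  corr <- (pair - outer(means, means)) / denom
  corr[denom == 0] <- 0
  diag(corr) <- 1
  structure(list(means = means, pair_products = pair, correlations = corr),
            class = "moment_summary")
}

#' @rdname moments
#' @export
moments.pmf_table <- function(x, ...) {
  moment_summary_from(x$configs, x$prob)
}

#' @rdname moments
#' @export
moments.matrix <- function(x, ...) {
  stopifnot(all(x %in% c(-1, 1)))
  moment_summary_from(x, rep(1 / nrow(x), nrow(x)))
}

#' @rdname moments
#' @export
moments.sample_set <- function(x, ...) moments.matrix(x$draws)

#' @export
print.moment_summary <- function(x, ...) {
  cat("Moment summary for", length(x$means), "spins\n")
  cat("  means:", format(x$means, digits = 4), "\n")
  off <- x$correlations[upper.tri(x$correlations)]
  if (length(off)) {
    cat("  correlations in [", format(min(off), digits = 4), ", ",
        format(max(off), digits = 4), "]\n", sep = "")
  }
  invisible(x)
}
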