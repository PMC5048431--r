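new_sample_set <- function(draws, method, seed, n_burnin = 0L, n_thin = 1L,
                           latent_draws = NULL, effect_draws = NULL,
                           acceptance_rate = NULL) {
  structure(list(draws = draws, latent_draws = latent_draws,
                 effect_draws = effect_draws, seed = seed, method = method,
                 n_burnin = n_burnin, n_thin = n_thin,
                 acceptance_rate = acceptance_rate),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("Sample set: ", nrow(x$draws), " draws of ", ncol(x$draws),
      " spins (method: ", x$method, ")\n", sep = "")
  if (!is.null(x$acceptance_rate)) {
    cat("  acceptance rate: ", format(x$acceptance_rate, digits = 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Exact i.i.d. sampling from an enumerated pmf
#'
#' Inverse-probability sampling over the enumerated configuration table;
#' empirical frequencies converge to the table at the usual root-n rate.
#'
#' @param pmf A `pmf_table`.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return A `sample_set` whose `draws` are an `n` x N +1/-1 matrix.
#' @export
exact_sample <- function(pmf, n, seed = NULL) {
  stopifnot(inherits(pmf, "pmf_table"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(pmf$configs), size = n, replace = TRUE,
                    prob = pmf$prob)
  new_sample_set(pmf$configs[idx, , drop = FALSE], "exact", seed)
}

#' Single-site Gibbs sampler for the network representation
#'
#' Systematic-scan Gibbs with the exact full conditional
#' `p(x_i = +1 | x_-i) = logistic(2 (delta_i + sum_j sigma_ij x_j))`.
#' The inner loop is compiled; R's RNG is used throughout, so a fixed seed
#' replays the chain exactly.
#'
#' @param model An `ising_model`.
#' @param n Number of retained draws.
#' @param burnin Burn-in sweeps discarded first (default 1000).
#' @param thin Keep every `thin`-th sweep (default 1).
#' @param seed Optional integer seed.
#' @return A `sample_set`.
#' @export
gibbs_sample <- function(model, n, burnin = 1000, thin = 1, seed = NULL) {
  stopifnot(inherits(model, "ising_model"), n >= 1, burnin >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  x0 <- sample(c(-1L, 1L), model$n_items, replace = TRUE)
  draws <- gibbs_ising_cpp(model$delta, model$sigma, as.integer(n),
                           as.integer(burnin), as.integer(thin), x0)
  new_sample_set(draws, "gibbs", seed, as.integer(burnin), as.integer(thin))
}

#' Data-augmentation Gibbs sampler for the latent representation
#'
#' Alternates the two exact conditionals of the augmented joint:
#' `theta | x ~ Normal(A' x, I)` and, given `theta`, independent item draws
#' with success probability `logistic(2 (delta_i + a_i' theta))`.  Returns
#' paired manifest and latent draws; the manifest margin targets the same
#' Ising pmf as the network sampler.
#'
#' @param mirt A `mirt_model`.
#' @param n Number of retained draws.
#' @param burnin Burn-in sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep (default 1).
#' @param seed Optional integer seed.
#' @return A `sample_set` with both `draws` and `latent_draws`.
#' @export
augmented_gibbs <- function(mirt, n, burnin = 1000, thin = 1, seed = NULL) {
  stopifnot(inherits(mirt, "mirt_model"), n >= 1, burnin >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  x0 <- sample(c(-1L, 1L), mirt$n_items, replace = TRUE)
  res <- gibbs_augmented_cpp(mirt$delta, mirt$a_matrix, as.integer(n),
                             as.integer(burnin), as.integer(thin), x0)
  new_sample_set(res$draws, "augmented", seed, as.integer(burnin),
                 as.integer(thin), latent_draws = res$latent_draws)
}

# vectorised batch of independent cause draws: B x N matrix of +1/-1
draw_causes <- function(delta, batch) {
  n <- length(delta)
  p_plus <- plogis(2 * delta)
  u <- matrix(runif(batch * n), batch, n)
  ifelse(sweep(u, 2L, p_plus, "<"), 1L, -1L)
}

#' Forward-then-select sampler for the collider representation
#'
#' Implements the selection mechanism literally: draw cause configurations
#' from the independent marginal, draw each effect given the causes, and
#' keep a configuration only when every effect is present.  Kept draws are
#' exactly distributed as [conditional_on_effects()]; the realised
#' acceptance rate is recorded.  If the running acceptance rate falls below
#' `accept_floor` the sampler refuses, pointing at the conservative bound
#' choice (`log M_r = lambda_r N / 2`) that drives acceptance down for
#' strongly coupled models.
#'
#' @param coll A `collider_model`.
#' @param n_selected Number of accepted draws required (>= 1).
#' @param seed Optional integer seed.
#' @param accept_floor Minimum tolerated acceptance rate (default 1e-6).
#' @param batch Proposal batch size (default 10000).
#' @return A `sample_set` with `acceptance_rate` set.
#' @export
collider_forward_sample <- function(coll, n_selected, seed = NULL,
                                    accept_floor = 1e-6, batch = 10000) {
  stopifnot(inherits(coll, "collider_model"), n_selected >= 1)
  if (!is.null(seed)) set.seed(seed)
  kept <- matrix(0L, 0L, coll$n_items)
  tries <- 0
  accepted <- 0
  while (nrow(kept) < n_selected) {
    x <- draw_causes(coll$delta, batch)
    if (coll$n_effects > 0L) {
      s <- x %*% coll$loadings
      log_acc <- rowSums(0.5 * s^2) - sum(coll$log_bounds)
      ok <- log(runif(batch)) < log_acc
    } else {
      ok <- rep(TRUE, batch)
    }
    tries <- tries + batch
    accepted <- accepted + sum(ok)
    sel <- x[ok, , drop = FALSE]
    if (nrow(sel) > 0L) {
      take <- min(nrow(sel), n_selected - nrow(kept))
      kept <- rbind(kept, sel[seq_len(take), , drop = FALSE])
    }
    if (tries >= 1e6 && (accepted + 1) / tries < accept_floor) {
      stop("collider forward sampling acceptance rate ",
           format(accepted / tries, digits = 3), " is below the floor ",
           format(accept_floor, digits = 3),
           "; the conservative bound log M_r = lambda_r * N / 2 makes ",
           "selection inefficient for strongly coupled models",
           call. = FALSE)
    }
  }
  new_sample_set(kept, "collider_forward", seed,
                 acceptance_rate = accepted / tries)
}

#' Joint forward sampling of causes and effects
#'
#' Draws `(x, e)` pairs from the unconditional collider joint: causes from
#' the independent marginal, then each effect given the causes.  Useful for
#' checking that unselected causes show no associations.
#'
#' @param coll A `collider_model`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A `sample_set` with `draws` (causes) and `effect_draws` (0/1).
#' @export
collider_joint_sample <- function(coll, n, seed = NULL) {
  stopifnot(inherits(coll, "collider_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- draw_causes(coll$delta, n)
  e <- NULL
  if (coll$n_effects > 0L) {
    s <- x %*% coll$loadings
    lp <- sweep(0.5 * s^2, 2L, coll$log_bounds, "-")
    e <- matrix(as.integer(log(runif(length(lp))) < lp), n,
                coll$n_effects)
  }
  new_sample_set(x, "collider_joint", seed, effect_draws = e)
}

#' Monte Carlo standard errors of moment estimates
#'
#' Standard errors for the empirical `E[X_i]` and `E[X_i X_j]` from a set of
#' draws.  For i.i.d. draws the naive `sd / sqrt(n)` is used; for Markov
#' chain draws the batch-means estimator (default 50 batches) accounts for
#' autocorrelation.
#'
#' @param draws An `n` x N +1/-1 matrix or a `sample_set`.
#' @param method `"iid"` or `"batch"`.
#' @param n_batches Number of batches for the batch-means estimator.
#' @return A list with `se_means` (length N) and `se_pairs` (N x N, zero
#'   diagonal).
#' @export
moment_se <- function(draws, method = c("iid", "batch"), n_batches = 50) {
  if (inherits(draws, "sample_set")) draws <- draws$draws
  method <- match.arg(method)
  n <- nrow(draws)
  p <- ncol(draws)
  stat_mat <- function(x) {
    prods <- matrix(0, nrow(x), p * (p - 1) / 2)
    k <- 0L
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      k <- k + 1L
      prods[, k] <- x[, i] * x[, j]
    }
    cbind(x, prods)
  }
  stats <- stat_mat(draws)
  if (method == "iid") {
    se <- apply(stats, 2L, sd) / sqrt(n)
  } else {
    nb <- min(n_batches, n)
    size <- floor(n / nb)
    idx <- rep(seq_len(nb), each = size)
    used <- seq_len(nb * size)
    bm <- rowsum(stats[used, , drop = FALSE], idx) / size
    se <- apply(bm, 2L, sd) / sqrt(nb)
  }
  se_means <- se[seq_len(p)]
  se_pairs <- matrix(0, p, p)
  k <- p
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    k <- k + 1L
    se_pairs[i, j] <- se[k]
    se_pairs[j, i] <- se[k]
  }
  list(se_means = se_means, se_pairs = se_pairs)
}

#' Compare sampler moments against exact moments
#'
#' Computes z-scores `(empirical - exact) / SE` for all N means and
#' N(N-1)/2 pairwise products, and the fraction of checks within a stated
#' multiple of the Monte Carlo standard error.
#'
#' @param draws A `sample_set` or +1/-1 matrix.
#' @param exact A `moment_summary` from the exact pmf.
#' @param method SE method, see [moment_se()].
#' @param z_max Threshold in SE units (default 4).
#' @return A list with `z_means`, `z_pairs` (upper triangle), `frac_within`
#'   and `n_checks`.
#' @export
moment_check <- function(draws, exact, method = c("iid", "batch"),
                         z_max = 4) {
  method <- match.arg(method)
  emp <- moments(if (inherits(draws, "sample_set")) draws$draws else draws)
  se <- moment_se(draws, method)
  p <- length(emp$means)
  z_means <- (emp$means - exact$means) / se$se_means
  up <- upper.tri(se$se_pairs)
  z_pairs <- (emp$pair_products[up] - exact$pair_products[up]) /
    se$se_pairs[up]
  z <- c(z_means, z_pairs)
  list(z_means = z_means, z_pairs = z_pairs,
       frac_within = mean(abs(z) <= z_max), n_checks = length(z))
}
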