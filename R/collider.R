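check_effects <- function(e, coll) {
  e <- as.numeric(e)
  if (length(e) != coll$n_effects) {
    stop("effect configuration has length ", length(e), " but the model has ",
         coll$n_effects, " effects", call. = FALSE)
  }
  if (!all(e %in% c(0, 1))) {
    stop("effect values must be exactly 0 or 1", call. = FALSE)
  }
  e
}

#' Probability of each effect given the causes
#'
#' Each effect fires independently given the cause configuration, with
#' `p(e_r = 1 | x) = exp(0.5 * (l_r' x)^2 - log M_r)` where `l_r` is the
#' loading vector of effect `r`.  The stored bound `log M_r` guarantees the
#' value lies in `(0, 1]` for every configuration.
#'
#' @param x A +1/-1 configuration of length N.
#' @param coll A `collider_model`.
#' @param log If `TRUE` return log probabilities.
#' @return A numeric vector of length `n_effects` (empty for a rank-0
#'   model).
#' @export
effect_prob <- function(x, coll, log = FALSE) {
  stopifnot(inherits(coll, "collider_model"))
  x <- check_spin(x, coll$n_items)
  if (coll$n_effects == 0L) return(numeric(0))
  s <- drop(crossprod(coll$loadings, x))
  lp <- 0.5 * s^2 - coll$log_bounds
  if (log) lp else exp(lp)
}

#' Marginal distribution of the causes
#'
#' Without conditioning on the effects, the causes are independent:
#' `p(x) = prod_i exp(delta_i x_i) / (2 cosh delta_i)`.  All pairwise
#' correlations under this table are zero to machine precision; associations
#' only appear after selection on the effects.
#'
#' @param coll A `collider_model` with `n_items <= 20`.
#' @return A `pmf_table` in canonical configuration order.
#' @export
#' @examples
#' coll <- as_collider(curie_weiss(c(0, 0), log(2)))
#' marginal_cause_pmf(coll)$prob  # uniform 0.25
marginal_cause_pmf <- function(coll) {
  stopifnot(inherits(coll, "collider_model"))
  check_enum_cap(coll$n_items)
  configs <- spin_configs(coll$n_items)
  new_pmf_table(configs, drop(configs %*% coll$delta))
}

#' Distribution of the causes given all effects present
#'
#' Conditioning on `e = 1` multiplies the independent marginal by every
#' effect probability and renormalises.  All factors that do not depend on
#' `x` (the `2 cosh` normalisers and the bounds `M_r`) cancel, leaving
#' exactly the Ising distribution whose eigen representation generated the
#' collider: this is endogenous selection bias re-creating the network
#' model's associations.
#'
#' @param coll A `collider_model` with `n_items <= 20`.
#' @return A `pmf_table` equal (to numerical precision) to
#'   `pmf_table(from_collider(coll))`.
#' @export
#' @examples
#' coll <- as_collider(curie_weiss(c(0, 0), log(2)))
#' conditional_on_effects(coll)$prob  # 0.4 0.1 0.1 0.4
conditional_on_effects <- function(coll) {
  stopifnot(inherits(coll, "collider_model"))
  check_enum_cap(coll$n_items)
  configs <- spin_configs(coll$n_items)
  lw <- drop(configs %*% coll$delta)
  if (coll$n_effects > 0L) {
    s <- configs %*% coll$loadings  # 2^N x m
    lw <- lw + 0.5 * rowSums(s^2)
  }
  new_pmf_table(configs, lw)
}

#' Joint probability of causes and effects
#'
#' `p(x, e) = p(x) * prod_r p(e_r | x)^(e_r) * (1 - p(e_r | x))^(1 - e_r)`,
#' with `p(x)` the independent cause marginal.  Summing over all `(x, e)`
#' pairs gives 1; marginalising the effects recovers [marginal_cause_pmf()]
#' and conditioning on `e = 1` recovers [conditional_on_effects()].
#'
#' @param x A +1/-1 cause configuration of length N.
#' @param e A 0/1 effect configuration of length `n_effects`.
#' @param coll A `collider_model`.
#' @param log If `TRUE` return the log probability.
#' @return A probability (scalar).
#' @export
joint_pmf <- function(x, e, coll, log = FALSE) {
  stopifnot(inherits(coll, "collider_model"))
  x <- check_spin(x, coll$n_items)
  e <- check_effects(e, coll)
  lp_x <- sum(coll$delta * x - log2cosh(coll$delta))
  lp_e <- 0
  if (coll$n_effects > 0L) {
    lp1 <- effect_prob(x, coll, log = TRUE)
    # log(1 - exp(lp1)), safe as lp1 <= 0; a bound attained exactly gives -Inf
    lp0 <- ifelse(lp1 >= 0, -Inf, log1p(-exp(lp1)))
    lp_e <- sum(ifelse(e == 1, lp1, lp0))
  }
  out <- lp_x + lp_e
  if (log) out else exp(out)
}
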