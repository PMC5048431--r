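test_that("conditional pmf is the locally independent logistic product", {
  # no latent dimensions: the independence limit
  m0 <- as_mirt(ising_model(c(0.5, -1), matrix(0, 2, 2)))
  expect_equal(conditional_pmf(c(1, -1), numeric(0), m0),
               exp(0.5) / (2 * cosh(0.5)) * exp(1) / (2 * cosh(1)))

  # neutral items at the latent origin: uniform over configurations
  mi <- as_mirt(curie_weiss(rep(0, 4), 0.3))
  expect_equal(conditional_pmf(c(1, -1, 1, 1), 0, mi), 2^-4)

  # Rasch case: success probability increases with the latent trait
  probs <- sapply(seq(-2, 2, by = 0.5), function(th) {
    conditional_pmf(c(1, 1, 1, 1), th, mi)
  })
  expect_true(all(diff(probs) > 0))
})

test_that("conditional pmf given theta exhibits local independence", {
  mi <- as_mirt(random_low_rank_ising(4, 2, 0.5, seed = 12))
  theta <- c(0.7, -0.4)
  cfg <- spin_configs(4)
  p <- apply(cfg, 1L, conditional_pmf, theta = theta, mirt = mi)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # joint equals product of item margins => all correlations vanish
  mom <- moments(structure(list(configs = cfg, prob = p, log_prob = log(p),
                                log_partition = 0, n_items = 4L),
                           class = "pmf_table"))
  off <- mom$correlations[upper.tri(mom$correlations)]
  expect_lt(max(abs(off)), 1e-12)
})

test_that("latent density is even for zero main effects and normalises", {
  mi <- as_mirt(curie_weiss(rep(0, 5), 0.3))
  for (th in c(0.3, 1.1, 2.5)) {
    expect_equal(latent_density(th, mi), latent_density(-th, mi))
  }
  # normalised density integrates to 1 (fine trapezoid oracle, m = 1)
  grid <- seq(-9, 9, length.out = 4001)
  f <- vapply(grid, latent_density, 0, mirt = mi, normalised = TRUE)
  expect_equal(sum(f) * diff(grid[1:2]), 1, tolerance = 1e-8)
})

test_that("quadrature marginal reproduces the exact pmf", {
  # no latent dimensions: exact product table, no quadrature
  m0 <- ising_model(c(0.4, -0.2, 0.1), matrix(0, 3, 3))
  expect_tv(marginal_pmf_quadrature(as_mirt(m0)), pmf_table(m0), 1e-14)

  # two-item Curie-Weiss at order 40 recovers (0.4, 0.1, 0.1, 0.4)
  mi <- as_mirt(cw2())
  expect_lt(max(abs(marginal_pmf_quadrature(mi, 40)$prob -
                      c(0.4, 0.1, 0.1, 0.4))), 1e-8)

  # low-rank random model at order 30
  lr <- random_low_rank_ising(8, 3, 0.4, seed = 7)
  expect_tv(marginal_pmf_quadrature(as_mirt(lr), 30), pmf_table(lr), 1e-6)
})

test_that("quadrature error decreases as the order grows", {
  lr <- random_low_rank_ising(6, 2, 0.5, seed = 4)
  exact <- pmf_table(lr)
  mi <- as_mirt(lr)
  tv <- sapply(c(10, 20, 30, 40), function(o) {
    total_variation(marginal_pmf_quadrature(mi, o), exact)
  })
  expect_lt(tv[2], tv[1])
  # beyond the working-precision floor only non-increase is meaningful
  expect_true(tv[3] <= tv[2] + 1e-13)
  expect_true(tv[4] <= tv[3] + 1e-13)
  expect_lt(tv[4], 1e-10)
})

test_that("quadrature refuses high latent rank, pointing at the collider", {
  r <- random_ising(8, 1, 0.5, seed = 31)
  mi <- as_mirt(r)
  expect_gt(mi$latent_dim, 4L)
  expect_error(marginal_pmf_quadrature(mi), "collider")
})

test_that("the latent posterior is Normal(A'x, I)", {
  mi <- as_mirt(random_low_rank_ising(5, 2, 0.5, seed = 9))
  x <- c(1, -1, 1, 1, -1)
  post <- posterior_theta(x, mi)
  expect_equal(post$mean, drop(crossprod(mi$a_matrix, x)))
  expect_equal(post$covariance, diag(1, 2))
  # flipping the configuration negates the mean
  expect_equal(posterior_theta(-x, mi)$mean, -post$mean)
  # zero loadings: standard normal regardless of x
  m0 <- as_mirt(ising_model(c(0.2, -0.1), matrix(0, 2, 2)))
  expect_identical(length(posterior_theta(c(1, -1), m0)$mean), 0L)
})

test_that("Bayes consistency: f(theta) p(x|theta) / p(x) is the posterior", {
  mi <- as_mirt(curie_weiss(c(0.2, -0.1, 0.3), 0.4))
  exact <- pmf_table(from_mirt(mi))
  x <- c(1, 1, -1)
  row <- which(apply(exact$configs, 1L, function(r) all(r == x)))
  lpx <- exact$log_prob[row]
  post <- posterior_theta(x, mi)
  lconst <- latent_log_norm_const(mi, 60)
  for (th in seq(-2, 2, by = 0.5)) {
    lhs <- latent_density(th, mi, log = TRUE) - lconst +
      conditional_pmf(x, th, mi, log = TRUE) - lpx
    rhs <- dnorm(th, mean = post$mean, sd = 1, log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-7)
  }
})

test_that("posterior draws match the closed-form moments", {
  mi <- as_mirt(random_low_rank_ising(5, 2, 0.5, seed = 14))
  x <- c(1, 1, -1, 1, -1)
  th <- sample_posterior_theta(mi, x, n = 5e4, seed = 21)
  post <- posterior_theta(x, mi)
  se <- 1 / sqrt(nrow(th))
  expect_lt(max(abs(colMeans(th) - post$mean)), 4 * se)
  expect_lt(max(abs(diag(var(th)) - 1)), 4 * sqrt(2 / nrow(th)))
  expect_lt(abs(var(th)[1, 2]), 4 * se)
})
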