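test_that("log weight is the main-effect plus once-per-pair interaction sum", {
  empty <- ising_model(c(0, 0), matrix(0, 2, 2))
  expect_identical(log_weight(empty, c(1, 1)), 0)

  m <- cw2()
  expect_equal(log_weight(m, c(1, -1)), -log(2))
  expect_equal(log_weight(m, c(1, 1)), log(2))

  m3 <- ising_model(c(1, 0, -1), matrix(0, 3, 3))
  expect_equal(log_weight(m3, c(1, 1, 1)), 0)
  # direct two-term oracle on a random model
  set.seed(11)
  r <- random_ising(5, 1, 0.7, seed = 11)
  x <- sample(c(-1, 1), 5, replace = TRUE)
  manual <- sum(r$delta * x)
  for (i in 1:4) for (j in (i + 1):5) manual <- manual + r$sigma[i, j] * x[i] * x[j]
  expect_equal(log_weight(r, x), manual)
})

test_that("log weight rejects malformed configurations", {
  m <- cw2()
  expect_error(log_weight(m, c(1, -1, 1)), "length")
  expect_error(log_weight(m, c(1, 0)), "\\+1 or -1")
})

test_that("partition function matches enumeration oracles", {
  expect_equal(log_partition(ising_model(c(0, 0), matrix(0, 2, 2))), log(4))
  expect_equal(log_partition(cw2()), log(5))
  for (d in c(-2, 0.3, 5)) {
    expect_equal(log_partition(ising_model(d, matrix(0, 1, 1))),
                 log(2 * cosh(d)))
  }
})

test_that("partition function is stable for large exponents", {
  m <- ising_model(c(400, -400), matrix(0, 2, 2))
  expect_true(is.finite(log_partition(m)))
  # weights e^800, 1, 1, e^-800: log Z = 800 to double precision
  expect_equal(log_partition(m), 800, tolerance = 1e-12)
})

test_that("enumeration refuses above the cap, naming it", {
  big <- structure(list(delta = rep(0, 25), sigma = matrix(0, 25, 25),
                        n_items = 25L), class = "ising_model")
  expect_error(pmf_table(big), "20")
})

test_that("exact pmf matches hand-enumerated tables", {
  u <- pmf_table(ising_model(0, matrix(0, 1, 1)))
  expect_equal(u$prob, c(0.5, 0.5))

  p <- pmf_table(cw2())
  expect_equal(p$prob, c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-14)
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)
  # canonical order: item 1 slowest, -1 before +1
  expect_equal(p$configs[1, ], c(x_1 = -1L, x_2 = -1L))
  expect_equal(p$configs[4, ], c(x_1 = 1L, x_2 = 1L))
})

test_that("negating the main effects flips every configuration's probability", {
  r <- random_ising(5, 0.8, 0.6, seed = 3)
  flipped <- ising_model(-r$delta, r$sigma)
  p <- pmf_table(r)$prob
  q <- pmf_table(flipped)$prob
  # -x of row k sits at the mirrored row under the canonical order
  expect_equal(q, rev(p), tolerance = 1e-14)
})

test_that("the diagonal of the coupling matrix is irrelevant", {
  set.seed(42)
  for (k in 1:5) {
    r <- random_ising(5, 1, 0.5, seed = 40 + k)
    shift <- rnorm(1, sd = 3)
    shifted <- ising_model(r$delta, r$sigma + diag(shift, 5))
    expect_lt(max(abs(pmf_table(r)$prob - pmf_table(shifted)$prob)), 1e-12)
  }
})

test_that("zero couplings give an independent product distribution", {
  delta <- c(0.5, -1, 0.2)
  m <- ising_model(delta, matrix(0, 3, 3))
  p <- pmf_table(m)
  prod_p <- apply(p$configs, 1L, function(x) {
    prod(exp(delta * x) / (2 * cosh(delta)))
  })
  expect_equal(p$prob, prod_p, tolerance = 1e-12)
})

test_that("moments are exact expectations under the table", {
  ind <- pmf_table(ising_model(c(0, 0), matrix(0, 2, 2)))
  mom <- moments(ind)
  expect_equal(mom$means, c(0, 0))
  expect_equal(mom$correlations[1, 2], 0)

  mom2 <- moments(pmf_table(cw2()))
  expect_equal(mom2$pair_products[1, 2], 0.6, tolerance = 1e-14)
  expect_equal(diag(mom2$pair_products), c(1, 1))

  # positive coupling yields positive correlation, increasing with strength
  cors <- sapply(c(0.2, 0.6, 1.2), function(s) {
    moments(pmf_table(curie_weiss(c(0, 0), s)))$correlations[1, 2]
  })
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))
})

test_that("curie_weiss builds the equal-coupling model", {
  m <- curie_weiss(c(0.1, -0.2), 0.7)
  expect_equal(m$sigma, matrix(c(0, 0.7, 0.7, 0), 2))

  # with zero coupling the pmf factorises over items
  m0 <- curie_weiss(c(0.3, -0.5, 0.1), 0)
  p <- pmf_table(m0)
  marg <- moments(p)$means
  prod_p <- apply(p$configs, 1L, function(x) prod((1 + x * marg) / 2))
  expect_equal(p$prob, prod_p, tolerance = 1e-12)
})

test_that("equal-delta Curie-Weiss pmf depends only on the spin sum", {
  p <- pmf_table(curie_weiss(rep(0.2, 4), 0.5))
  sums <- rowSums(p$configs)
  for (s in unique(sums)) {
    expect_lt(diff(range(p$prob[sums == s])), 1e-15)
  }
  # and is invariant under item permutation (exhaustive at N = 4)
  pm <- sample(4)
  expect_equal(log_weight(curie_weiss(rep(0.2, 4), 0.5),
                          p$configs[7, ][pm]),
               log_weight(curie_weiss(rep(0.2, 4), 0.5), p$configs[7, ]))
})

test_that("random model generator is seeded and honours density", {
  a <- random_ising(6, 0.5, 0.4, seed = 99)
  b <- random_ising(6, 0.5, 0.4, seed = 99)
  expect_identical(a, b)

  z <- random_ising(6, 0, 0.4, seed = 1)
  expect_true(all(z$sigma == 0))

  f <- random_ising(6, 1, 0.4, seed = 1)
  expect_equal(sum(f$sigma[upper.tri(f$sigma)] != 0), 15L)

  lr <- random_low_rank_ising(7, 2, 0.4, seed = 5)
  e <- eigen_representation(lr)
  expect_identical(e$rank_m, 2L)
  expect_equal(e$shift_c, 0.4^2, tolerance = 1e-12)
})

test_that("constructor enforces symmetry and finiteness", {
  s <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ising_model(c(0, 0), s), "not symmetric")
  expect_error(ising_model(c(0, Inf), matrix(0, 2, 2)), "finite")
  expect_error(ising_model(c(0, 0), matrix(0, 3, 3)), "length")
})
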