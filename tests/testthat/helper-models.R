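# Shared fixtures, all built in code.

# two-item Curie-Weiss with coupling ln 2: exact pmf is (0.4, 0.1, 0.1, 0.4)
cw2 <- function() curie_weiss(c(0, 0), log(2))

# a mirt_model built directly from a loading matrix (for detector tests)
mirt_from_loadings <- function(delta, a) {
  structure(list(delta = delta, a_matrix = as.matrix(a),
                 latent_dim = ncol(as.matrix(a)), shift_c = NA_real_,
                 n_items = length(delta)),
            class = "mirt_model")
}

expect_tv <- function(m1, m2, tol) {
  expect_lte(total_variation(m1, m2), tol)
}
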