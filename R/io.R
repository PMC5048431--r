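#' Read a model from a JSON file
#'
#' Model files carry a `representation` tag (`"ising"`, `"mirt"` or
#' `"collider"`) that dispatches the type:
#' * ising: `delta` (length N), `sigma` (N x N, symmetric)
#' * mirt: `delta`, `a_matrix` (N x m)
#' * collider: `delta`, `loadings` (N x m), `log_bounds` (length m)
#'
#' Validation is field-level: asymmetric `sigma` is rejected naming the
#' offending pair, dimension mismatches name the fields, and NaN/Inf are
#' refused everywhere.
#'
#' @param path Path to a JSON model file.
#' @return An `ising_model`, `mirt_model` or `collider_model`.
#' @seealso [write_model()]
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rep_tag <- obj$representation
  if (is.null(rep_tag)) {
    stop("model file lacks a 'representation' tag", call. = FALSE)
  }
  delta <- as.numeric(obj$delta)
  if (length(delta) < 1L || anyNA(delta) || any(!is.finite(delta))) {
    stop("'delta' must be a finite numeric vector", call. = FALSE)
  }
  switch(rep_tag,
    ising = {
      sigma <- as.matrix(obj$sigma)
      storage.mode(sigma) <- "double"
      if (anyNA(sigma) || any(!is.finite(sigma))) {
        stop("'sigma' contains NaN/Inf", call. = FALSE)
      }
      ising_model(delta, sigma)
    },
    mirt = {
      a <- as.matrix(obj$a_matrix)
      storage.mode(a) <- "double"
      if (nrow(a) != length(delta)) {
        stop("'a_matrix' has ", nrow(a), " rows but 'delta' has length ",
             length(delta), call. = FALSE)
      }
      if (anyNA(a) || any(!is.finite(a))) {
        stop("'a_matrix' contains NaN/Inf", call. = FALSE)
      }
      structure(list(delta = delta, a_matrix = a,
                     latent_dim = ncol(a), shift_c = NA_real_,
                     n_items = length(delta)),
                class = "mirt_model")
    },
    collider = {
      l <- as.matrix(obj$loadings)
      storage.mode(l) <- "double"
      lb <- as.numeric(obj$log_bounds)
      if (nrow(l) != length(delta)) {
        stop("'loadings' has ", nrow(l), " rows but 'delta' has length ",
             length(delta), call. = FALSE)
      }
      if (length(lb) != ncol(l)) {
        stop("'log_bounds' has length ", length(lb), " but 'loadings' has ",
             ncol(l), " columns", call. = FALSE)
      }
      if (anyNA(l) || any(!is.finite(l)) || anyNA(lb) ||
            any(!is.finite(lb))) {
        stop("collider parameters contain NaN/Inf", call. = FALSE)
      }
      # the stored bound must make every effect probability valid;
      # max over sign patterns of (l_r' x)^2 is (sum_i |l_ir|)^2
      worst <- 0.5 * colSums(abs(l))^2
      if (any(worst > lb + 1e-9)) {
        stop("'log_bounds' too small for effect(s) ",
             paste(which(worst > lb + 1e-9), collapse = ", "),
             ": p(e=1|x) could exceed 1", call. = FALSE)
      }
      structure(list(delta = delta, loadings = l, log_bounds = lb,
                     n_effects = ncol(l), n_items = length(delta)),
                class = "collider_model")
    },
    stop("unknown representation tag: '", rep_tag, "'", call. = FALSE)
  )
}

#' Write a model to a JSON file
#'
#' Serialises at full double precision; write-then-read is an exact
#' round trip.
#'
#' @param model An `ising_model`, `mirt_model` or `collider_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "ising_model")) {
    list(representation = "ising", delta = model$delta, sigma = model$sigma)
  } else if (inherits(model, "mirt_model")) {
    list(representation = "mirt", delta = model$delta,
         a_matrix = model$a_matrix)
  } else if (inherits(model, "collider_model")) {
    list(representation = "collider", delta = model$delta,
         loadings = model$loadings, log_bounds = model$log_bounds)
  } else {
    stop("not a recognised model object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Export a probability table to CSV
#'
#' One row per configuration in canonical order, columns `x_1..x_N` and
#' `probability` (17 significant digits), preceded by a comment line with
#' the log partition function.  The fixed enumeration order makes exports
#' byte-stable.
#'
#' @param pmf A `pmf_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# log_partition = ",
                    formatC(pmf$log_partition, digits = 17, format = "g")),
             con)
  df <- as.data.frame(pmf$configs)
  df$probability <- formatC(pmf$prob, digits = 17, format = "g")
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
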