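#' Declare model parameters
#'
#' A parameter set holds the model coefficients: some deterministic (a single
#' number), some uniform random variables. Each random parameter is assigned
#' its own germ dimension, in declaration order, so mutually independent
#' parameters live on independent components of the Uniform`[-1,1]` germ
#' vector; deterministic parameters never consume a germ dimension.
#'
#' `uniform_param()` declares `Uniform(lower, upper)`. `uniform_about_param()`
#' follows the convention of centering a noninformative uniform on a point
#' estimate: given the estimate `theta`, it builds `Uniform(0, 2 * theta)`,
#' whose mean is `theta`. `fixed_param()` declares a deterministic value (a
#' zero-width uniform).
#'
#' @param ... For `param_set()`: parameter declarations created by
#'   `uniform_param()`, `uniform_about_param()`, or `fixed_param()`.
#' @param name Parameter name, e.g. `"beta"`.
#' @param lower,upper Distribution bounds, `upper >= lower`.
#' @param mean Point estimate `theta` for the `Uniform(0, 2 theta)` convention.
#' @param value Deterministic value.
#' @return `param_set()` returns a tibble of class `param_set` with columns
#'   `name`, `lower`, `upper`, `random`, and `germ_dim` (`NA` for
#'   deterministic parameters, otherwise 1-based germ dimension).
#' @examples
#' param_set(
#'   uniform_about_param("beta", 0.00085),
#'   fixed_param("mu", 0.000469)
#' )
#' @export
param_set <- function(...) {
  decls <- list(...)
  if (length(decls) == 1L && is.list(decls[[1]]) && !is.data.frame(decls[[1]]) &&
      is.null(decls[[1]]$name)) {
    decls <- decls[[1]]
  }
  tab <- purrr::map_dfr(decls, function(d) {
    stopifnot(is.list(d), !is.null(d$name))
    tibble::tibble(name = d$name, lower = d$lower, upper = d$upper)
  })
  if (anyDuplicated(tab$name)) {
    rlang::abort("Duplicate parameter names in `param_set()`.")
  }
  tab$random <- tab$upper > tab$lower
  tab$germ_dim <- NA_integer_
  tab$germ_dim[tab$random] <- seq_len(sum(tab$random))
  class(tab) <- c("param_set", class(tab))
  tab
}

#' @rdname param_set
#' @export
uniform_param <- function(name, lower, upper) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower), is.numeric(upper))
  if (upper < lower) rlang::abort("`upper` must be >= `lower`.")
  list(name = name, lower = as.numeric(lower), upper = as.numeric(upper))
}

#' @rdname param_set
#' @export
uniform_about_param <- function(name, mean) {
  stopifnot(is.numeric(mean), mean >= 0)
  uniform_param(name, 0, 2 * mean)
}

#' @rdname param_set
#' @export
fixed_param <- function(name, value) {
  uniform_param(name, value, value)
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %d parameters (%d random)\n",
              nrow(x), sum(x$random)))
  NextMethod()
}

#' Point values of a parameter set
#'
#' The mean of each parameter's distribution (the value itself for
#' deterministic parameters), as a named vector ready for
#' [solve_deterministic()] or [eval_rhs()].
#'
#' @param params A [param_set()].
#' @return Named numeric vector.
#' @export
param_means <- function(params) {
  stats::setNames((params$lower + params$upper) / 2, params$name)
}

n_random <- function(params) sum(params$random)

#' Legendre chaos coefficients of a uniform parameter
#'
#' A parameter `theta ~ Uniform(lower, upper)` expressed on germ dimension
#' `d` is the affine map `theta = m + h * xi_d` with `m = (lower + upper)/2`
#' and `h = (upper - lower)/2`, `xi_d ~ Uniform[-1, 1]`. Its Legendre chaos
#' expansion is therefore exact at order 1: the constant coefficient is `m`,
#' the degree-1 coefficient on dimension `d` is `h`, and every other
#' coefficient — including the degree-2 slot that the general second-order
#' expansion formally carries — is exactly 0.
#'
#' @param lower,upper Bounds, `upper >= lower`.
#' @param germ_dim Germ dimension (1-based) carrying the parameter; `NA` for
#'   a deterministic parameter.
#' @param basis A [pc_basis()].
#' @return Numeric vector of length `nrow(basis$indices)`.
#' @export
uniform_to_chaos <- function(lower, upper, germ_dim, basis) {
  stopifnot(inherits(basis, "pc_basis"))
  if (upper < lower) rlang::abort("`upper` must be >= `lower`.")
  coeffs <- numeric(nrow(basis$indices))
  coeffs[1] <- (lower + upper) / 2
  if (upper > lower) {
    if (is.na(germ_dim) || germ_dim < 1 || germ_dim > basis$n_dims) {
      rlang::abort("`germ_dim` must identify a germ dimension within the basis.")
    }
    deg1 <- which(basis$indices[, germ_dim] == 1L &
                    rowSums(basis$indices) == 1L)
    coeffs[deg1] <- (upper - lower) / 2
  }
  coeffs
}

# Chaos coefficient matrix for a whole parameter set: one row per parameter,
# one column per basis function.
param_chaos_matrix <- function(params, basis) {
  stopifnot(inherits(params, "param_set"))
  if (n_random(params) > basis$n_dims) {
    rlang::abort(sprintf(
      "Basis has %d germ dimensions but the parameter set needs %d.",
      basis$n_dims, n_random(params)
    ))
  }
  out <- t(vapply(
    seq_len(nrow(params)),
    function(i) uniform_to_chaos(params$lower[i], params$upper[i],
                                 params$germ_dim[i], basis),
    numeric(nrow(basis$indices))
  ))
  rownames(out) <- params$name
  out
}

#' Draw joint parameter samples
#'
#' Independent draws of every parameter: `Uniform(lower, upper)` columns for
#' random parameters, constant columns for deterministic ones. Reproducible
#' under a fixed seed without disturbing the caller's RNG state.
#'
#' @param params A [param_set()].
#' @param n_samples Number of joint draws, at least 1.
#' @param seed Integer seed.
#' @return A tibble with `n_samples` rows and one column per parameter.
#' @export
sample_params <- function(params, n_samples, seed) {
  stopifnot(inherits(params, "param_set"))
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(params)), function(i) {
      if (params$random[i]) {
        stats::runif(n_samples, params$lower[i], params$upper[i])
      } else {
        rep(params$lower[i], n_samples)
      }
    })
  })
  names(draws) <- params$name
  tibble::as_tibble(draws)
}

# Map germ points (matrix n x n_dims in [-1,1]) to parameter values via the
# affine transform; used to tie chaos expansions back to samples.
germ_to_params <- function(params, germ) {
  if (is.null(dim(germ))) germ <- matrix(germ, nrow = 1)
  out <- matrix(rep(param_means(params), each = nrow(germ)),
                nrow = nrow(germ),
                dimnames = list(NULL, params$name))
  for (i in which(params$random)) {
    h <- (params$upper[i] - params$lower[i]) / 2
    out[, params$name[i]] <- out[, params$name[i]] + h * germ[, params$germ_dim[i]]
  }
  out
}
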