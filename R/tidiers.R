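#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chaos basis
#'
#' @param x A [pc_basis()].
#' @param ... Unused.
#' @return A tibble with one row per basis function: `position` (1-based),
#'   `total_degree`, the per-dimension degrees `deg_1 ... deg_n`, and
#'   `norm_sq`.
#' @export
tidy.pc_basis <- function(x, ...) {
  degs <- tibble::as_tibble(x$indices, .name_repair = ~ paste0("deg_", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(position = seq_len(nrow(x$indices)),
                   total_degree = rowSums(x$indices)),
    degs,
    tibble::tibble(norm_sq = x$norms_sq)
  )
}

#' Tidy a chaos solution
#'
#' @param x A [integrate_chaos()] result.
#' @param ... Unused.
#' @return A tibble with columns `time`, `state`, `coefficient_index`
#'   (0-based; 0 is the mean trajectory) and `value`, one row per
#'   coefficient per state per time point.
#' @export
tidy.chaos_solution <- function(x, ...) {
  states <- dimnames(x$coefs)[[3]]
  purrr::map_dfr(states, function(s) {
    cf <- x$coefs[, , s, drop = FALSE]
    dim(cf) <- dim(x$coefs)[1:2]
    tibble::tibble(
      time = rep(x$time, times = ncol(cf)),
      state = s,
      coefficient_index = rep(seq_len(ncol(cf)) - 1L, each = length(x$time)),
      value = as.vector(cf)
    )
  })
}

#' @rdname tidy.chaos_solution
#' @return For `glance()`: a one-row tibble with the basis size, chaos
#'   order, germ dimension, state count and time span.
#' @export
glance.chaos_solution <- function(x, ...) {
  tibble::tibble(
    n_basis = dim(x$coefs)[2],
    order = x$basis$order,
    n_dims = x$basis$n_dims,
    n_states = dim(x$coefs)[3],
    n_random_params = sum(x$params$random),
    t_end = max(x$time),
    n_times = length(x$time)
  )
}

#' Tidy a Monte Carlo estimate
#'
#' @param x A [mc_propagate()] result.
#' @param ... Unused.
#' @return The per-time, per-state estimate tibble (`mean`, `variance`,
#'   `se`), tagged with a `method = "mc"` column.
#' @export
tidy.mc_estimate <- function(x, ...) {
  dplyr::mutate(x$estimates, method = "mc")
}

#' @rdname tidy.mc_estimate
#' @export
glance.mc_estimate <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, seed = x$seed,
                 n_times = length(unique(x$estimates$time)))
}
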