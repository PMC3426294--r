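#' Means, variances and standard-deviation bands of a chaos solution
#'
#' By orthogonality, the mean of each state process is its constant chaos
#' coefficient and the variance is
#' `Var(X(t)) = sum_{i >= 1} X_i(t)^2 <Psi_i, Psi_i>`. The reported band is
#' the mean plus/minus one standard deviation of the output process — not a
#' Gaussian-quantile confidence interval. Closure-state moments come from
#' its derived coefficients. Tiny negative variances from floating-point
#' cancellation (above `-1e-14`) are clamped to 0; anything more negative
#' raises a warning before clamping.
#'
#' @param solution A [integrate_chaos()] result.
#' @param states States to report; defaults to all (closure included).
#' @return A tibble of class `chaos_moments` with columns `time`, `state`,
#'   `mean`, `variance`, `sd`, `band_low`, `band_high`.
#' @examples
#' sys <- galerkin_system(obesity_model(), obesity_params(), pc_basis(4, 2))
#' chaos_moments(integrate_chaos(sys, 520, c(0, 520)))
#' @export
chaos_moments <- function(solution, states = NULL) {
  stopifnot(inherits(solution, "chaos_solution"))
  all_states <- dimnames(solution$coefs)[[3]]
  if (is.null(states)) states <- all_states
  stopifnot(all(states %in% all_states))
  nsq <- solution$basis$norms_sq
  out <- purrr::map_dfr(states, function(s) {
    cf <- solution$coefs[, , s, drop = FALSE]
    dim(cf) <- dim(solution$coefs)[1:2]
    variance <- drop(cf[, -1, drop = FALSE]^2 %*% nsq[-1])
    if (any(variance < -1e-14)) {
      rlang::warn(sprintf("Clamping negative variance (min %.3g) for state %s.",
                          min(variance), s))
    }
    variance <- pmax(variance, 0)
    tibble::tibble(
      time = solution$time, state = s, mean = cf[, 1],
      variance = variance, sd = sqrt(variance)
    )
  })
  out <- dplyr::mutate(out,
                       band_low = .data$mean - .data$sd,
                       band_high = .data$mean + .data$sd)
  class(out) <- c("chaos_moments", class(out))
  out
}

#' First-order Sobol indices from chaos coefficients
#'
#' The total variance of a state process decomposes over the chaos basis.
#' Gathering the squared coefficients of basis functions that depend only
#' on germ dimension `d` — for an order-2 basis, the degree-1 and pure
#' degree-2 functions in `xi_d` — and normalizing by the total variance
#' gives the first-order Sobol index of the parameter carried by `d`.
#' Basis functions involving two or more dimensions (the cross terms) form
#' the remaining interaction contribution, reported as the pseudo-parameter
#' `"interactions"` so the decomposition visibly sums to 1. Where the total
#' variance is 0 (e.g. at `t = 0` with deterministic initial conditions)
#' the indices are undefined and reported as `NA`.
#'
#' @param solution A [integrate_chaos()] result.
#' @param states States to report; defaults to all.
#' @return A tibble of class `chaos_sobol` with columns `time`, `state`,
#'   `parameter`, `index`.
#' @export
chaos_sobol <- function(solution, states = NULL) {
  stopifnot(inherits(solution, "chaos_solution"))
  all_states <- dimnames(solution$coefs)[[3]]
  if (is.null(states)) states <- all_states
  params <- solution$params
  rnd <- params[params$random, ]
  idx <- solution$basis$indices
  nsq <- solution$basis$norms_sq
  active <- idx > 0L
  groups <- c(
    stats::setNames(
      purrr::map(rnd$germ_dim,
                 function(d) which(active[, d] & rowSums(active) == 1L)),
      rnd$name
    ),
    list(interactions = which(rowSums(active) >= 2L))
  )
  out <- purrr::map_dfr(states, function(s) {
    cf <- solution$coefs[, , s, drop = FALSE]
    dim(cf) <- dim(solution$coefs)[1:2]
    contrib <- cf[, -1, drop = FALSE]^2 %*% diag(nsq[-1], nrow = ncol(cf) - 1)
    total <- rowSums(contrib)
    purrr::imap_dfr(groups, function(members, nm) {
      part <- rowSums(contrib[, members - 1L, drop = FALSE])
      tibble::tibble(
        time = solution$time, state = s, parameter = nm,
        index = ifelse(total > 0, part / total, NA_real_)
      )
    })
  })
  out$parameter <- factor(out$parameter, levels = names(groups))
  class(out) <- c("chaos_sobol", class(out))
  out
}
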