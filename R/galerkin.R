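#' Assemble the stochastic Galerkin auxiliary system
#'
#' Substitutes the chaos expansions of the states and of the random
#' parameters into the model equations and projects onto each basis
#' function `Psi_L` (Galerkin projection). For each modeled state `X` and
#' test index `L`, a term `theta * c` contributes `c * theta_L`; a term
#' `theta * c * Y` contributes
#' `c * sum_{i,j} theta_i Y_j <Psi_i Psi_j, Psi_L> / <Psi_L, Psi_L>`; and a
#' bilinear term `theta * c * Y * Z` contracts against the 4-way tensor in
#' the same way. The result is a closed deterministic ODE system for all
#' `n_states * n_basis` coefficient trajectories.
#'
#' The parameter chaos coefficients are folded into the inner-product
#' tensors once at assembly time, so each integration step only performs
#' matrix-vector products in the state coefficients.
#'
#' @param model An [ode_model()] with polynomial RHS of degree at most 2.
#' @param params A [param_set()] resolving every parameter the model terms
#'   reference.
#' @param basis A [pc_basis()] with at least as many germ dimensions as
#'   there are random parameters.
#' @param tensors Optional precomputed [inner_product_tensors()] for
#'   `basis`; built on the fly when omitted.
#' @return An object of class `galerkin_system` with the precontracted term
#'   operators and an `n_unknowns` field equal to
#'   `length(model$initial) * nrow(basis$indices)`.
#' @examples
#' sys <- galerkin_system(obesity_model(), obesity_params(), pc_basis(4, 2))
#' sys$n_unknowns # 2 states x 15 basis functions
#' @export
galerkin_system <- function(model, params, basis, tensors = NULL) {
  stopifnot(inherits(model, "ode_model"), inherits(params, "param_set"),
            inherits(basis, "pc_basis"))
  if (is.null(tensors)) tensors <- inner_product_tensors(basis)
  if (length(tensors$E2) != nrow(basis$indices)) {
    rlang::abort("`tensors` were built for a different basis.")
  }
  missing_pars <- setdiff(model_param_names(model), params$name)
  if (length(missing_pars)) {
    rlang::abort(sprintf("Parameter set does not resolve: %s.",
                         paste(missing_pars, collapse = ", ")))
  }
  if (any(purrr::map_int(model$terms$monomial, length) > 2L)) {
    rlang::abort("Galerkin assembly supports state monomials of degree <= 2.")
  }
  chaos <- param_chaos_matrix(params, basis)
  P <- nrow(basis$indices)
  states <- names(model$initial)
  inv_e2 <- 1 / tensors$E2

  ops <- purrr::map(seq_len(nrow(model$terms)), function(r) {
    tm <- model$terms[r, ]
    coef <- if (is.na(tm$param)) c(1, numeric(P - 1)) else chaos[tm$param, ]
    scale <- tm$sign * tm$const
    mono <- tm$monomial[[1]]
    if (length(mono) == 0L) {
      # <theta, Psi_L> / <Psi_L, Psi_L> = theta_L (orthogonality)
      list(kind = 0L, state = tm$state, const_vec = scale * coef)
    } else if (length(mono) == 1L) {
      # A[j, L] = sum_i theta_i E3[i, j, L] / E2[L]
      A <- matrix(0, P, P)
      for (i in which(coef != 0)) {
        A <- A + coef[i] * tensors$E3[i, , ]
      }
      A <- scale * sweep(A, 2, inv_e2, `*`)
      list(kind = 1L, state = tm$state, u = mono[1], A = A)
    } else {
      # B[(j,k), L] = sum_i theta_i E4[i, j, k, L] / E2[L]
      B <- array(0, dim = c(P, P, P))
      for (i in which(coef != 0)) {
        B <- B + coef[i] * tensors$E4[i, , , ]
      }
      Bm <- matrix(B, nrow = P * P, ncol = P)
      Bm <- scale * sweep(Bm, 2, inv_e2, `*`)
      list(kind = 2L, state = tm$state, u = mono[1], v = mono[2], Bm = Bm)
    }
  })

  structure(
    list(
      model = model, params = params, basis = basis,
      ops = ops, states = states, P = P,
      n_unknowns = length(states) * P
    ),
    class = "galerkin_system"
  )
}

#' @export
print.galerkin_system <- function(x, ...) {
  cat(sprintf(
    "<galerkin_system> %d unknowns (%d states x %d chaos coefficients)\n",
    x$n_unknowns, length(x$states), x$P
  ))
  invisible(x)
}

# RHS of the auxiliary system: y is the stacked coefficient vector
# (state-major: all P coefficients of state 1, then state 2, ...).
galerkin_rhs <- function(system, y) {
  P <- system$P
  states <- system$states
  coefs <- matrix(y, nrow = P, ncol = length(states),
                  dimnames = list(NULL, states))
  # closure-state coefficients: X_cl = (1,0,...) - sum of modeled states
  if (!is.null(system$model$closure)) {
    cl <- -rowSums(coefs)
    cl[1] <- cl[1] + 1
    coefs <- cbind(coefs, matrix(cl, ncol = 1,
                                 dimnames = list(NULL, names(system$model$closure))))
  }
  dy <- matrix(0, P, length(states), dimnames = list(NULL, states))
  for (op in system$ops) {
    contrib <- switch(op$kind + 1L,
      op$const_vec,
      drop(crossprod(op$A, coefs[, op$u])),
      drop(crossprod(op$Bm, as.vector(tcrossprod(coefs[, op$u], coefs[, op$v]))))
    )
    dy[, op$state] <- dy[, op$state] + contrib
  }
  as.vector(dy)
}

#' Integrate the chaos-coefficient system
#'
#' Solves the auxiliary deterministic ODE system assembled by
#' [galerkin_system()] with an adaptive explicit Runge-Kutta 4(5)
#' (Dormand-Prince) method. Initial conditions are deterministic: the
#' constant coefficient of each state starts at its initial value and all
#' higher coefficients start at 0. When the model declares a closure state
#' its derived coefficients (`cl_0 = 1 - sum of modeled constant
#' coefficients`, `cl_i = -sum` for `i >= 1`) are attached to the solution.
#'
#' @param system A [galerkin_system()].
#' @param t_end Final time (weeks), > 0.
#' @param output_times Increasing times in `[0, t_end]` at which to report
#'   coefficients; defaults to 201 evenly spaced points.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `chaos_solution`: `time` (vector), `coefs`
#'   (array `time x basis x state`, closure state included), plus the
#'   `basis` and `params` used. See [tidy.chaos_solution()].
#' @export
integrate_chaos <- function(system, t_end, output_times = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "galerkin_system"), t_end > 0)
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 201)
  if (any(output_times < 0 | output_times > t_end)) {
    rlang::abort("`output_times` must lie within [0, t_end].")
  }
  output_times <- sort(unique(c(0, output_times)))
  P <- system$P
  y0 <- as.vector(vapply(system$model$initial, function(v) c(v, numeric(P - 1)),
                         numeric(P)))
  sol <- deSolve::ode(
    y = y0, times = output_times,
    func = function(t, y, p) list(galerkin_rhs(system, y)),
    parms = NULL, method = "ode45", rtol = rtol, atol = atol
  )
  if (nrow(sol) < length(output_times)) {
    rlang::abort(sprintf("Chaos integration failed near t = %.3f.",
                         sol[nrow(sol), 1]))
  }
  states <- system$states
  coefs <- array(sol[, -1], dim = c(nrow(sol), P, length(states)),
                 dimnames = list(NULL, NULL, states))
  if (!is.null(system$model$closure)) {
    cl <- -apply(coefs, c(1, 2), sum)
    cl[, 1] <- cl[, 1] + 1
    full <- array(0, dim = dim(coefs) + c(0, 0, 1),
                  dimnames = list(NULL, NULL, c(states, names(system$model$closure))))
    full[, , states] <- coefs
    full[, , names(system$model$closure)] <- cl
    coefs <- full
  }
  structure(
    list(
      time = sol[, 1], coefs = coefs, basis = system$basis,
      params = system$params, modeled_states = states,
      closure = names(system$model$closure)
    ),
    class = "chaos_solution"
  )
}

#' @export
print.chaos_solution <- function(x, ...) {
  cat(sprintf(
    "<chaos_solution> %d time points, states %s, %d chaos coefficients each\n",
    length(x$time), paste(dimnames(x$coefs)[[3]], collapse = ", "),
    dim(x$coefs)[2]
  ))
  invisible(x)
}

#' Solve a model at fixed parameter values
#'
#' Plain deterministic integration of an [ode_model()] with every parameter
#' resolved to a number, using the same adaptive Runge-Kutta 4(5) settings
#' as the chaos solve. Closure states are reported alongside modeled ones.
#'
#' @param model An [ode_model()].
#' @param params Named numeric vector of parameter values, or a
#'   [param_set()] whose means are used.
#' @param output_times Increasing report times starting at or after 0.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with column `time` and one column per state.
#' @examples
#' solve_deterministic(obesity_model("full"), obesity_params(random = FALSE),
#'                     output_times = c(0, 520, 780))
#' @export
solve_deterministic <- function(model, params, output_times,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"))
  if (inherits(params, "param_set")) params <- param_means(params)
  output_times <- sort(unique(c(0, output_times)))
  sol <- deSolve::ode(
    y = model$initial, times = output_times,
    func = function(t, y, p) {
      list(eval_rhs(model, stats::setNames(y, names(model$initial)), params))
    },
    parms = NULL, method = "ode45", rtol = rtol, atol = atol
  )
  if (nrow(sol) < length(output_times)) {
    rlang::abort(sprintf("Deterministic integration failed near t = %.3f.",
                         sol[nrow(sol), 1]))
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  if (!is.null(model$closure)) {
    out[[names(model$closure)]] <-
      1 - rowSums(out[, names(model$initial), drop = FALSE])
  }
  out
}
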