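#' Polynomial-right-hand-side compartmental ODE models
#'
#' A model is a set of named states with initial values (proportions) and,
#' per state, a list of signed right-hand-side terms. Each term is
#' `sign * const * parameter * (product of up to two states)`, so any RHS
#' that is polynomial of total degree at most 2 in the states — constant
#' sources, linear flows, and bilinear (mass-action style) transmission
#' terms — can be declared. An optional `closure` names a state defined as
#' 1 minus the sum of the modeled states; closure states carry no equation
#' of their own.
#'
#' @param initial Named numeric vector of non-negative initial values for
#'   the modeled states.
#' @param terms A data frame of RHS terms with columns `state` (which
#'   equation the term belongs to), `sign` (+1/-1), `param` (parameter name,
#'   or `NA` for a purely literal coefficient), `const` (literal multiplier,
#'   default 1), and `monomial` (list column of 0-2 state names). Build rows
#'   with [rhs_term()].
#' @param closure Optional name of the eliminated state, with its initial
#'   value, e.g. `c(N = 0.522)`; modeled plus closure initial values must
#'   then sum to 1.
#' @return An object of class `ode_model`.
#' @examples
#' # logistic-style toy: dX/dt = r X - r X^2
#' m <- ode_model(
#'   initial = c(X = 0.1),
#'   terms = rbind(
#'     rhs_term("X", +1, param = "r", monomial = "X"),
#'     rhs_term("X", -1, param = "r", monomial = c("X", "X"))
#'   )
#' )
#' @export
ode_model <- function(initial, terms, closure = NULL) {
  stopifnot(is.numeric(initial), !is.null(names(initial)))
  if (any(initial < 0)) rlang::abort("Initial values must be non-negative.")
  terms <- tibble::as_tibble(terms)
  needed <- c("state", "sign", "param", "const", "monomial")
  if (!all(needed %in% names(terms))) {
    rlang::abort(sprintf("`terms` must have columns %s.",
                         paste(needed, collapse = ", ")))
  }
  if (!all(terms$sign %in% c(-1, 1))) rlang::abort("`sign` must be +1 or -1.")
  closure_name <- if (!is.null(closure)) names(closure) else character(0)
  all_states <- c(names(initial), closure_name)
  if (!all(terms$state %in% names(initial))) {
    rlang::abort("Every term must belong to a modeled state's equation.")
  }
  mono_ok <- purrr::map_lgl(terms$monomial, function(m) {
    length(m) <= 2 && all(m %in% all_states)
  })
  if (!all(mono_ok)) {
    rlang::abort("Monomials must contain 0-2 declared state names (degree <= 2).")
  }
  if (!is.null(closure)) {
    stopifnot(is.numeric(closure), length(closure) == 1L, !is.null(names(closure)))
    tot <- sum(initial) + closure
    if (abs(tot - 1) > 1e-10) {
      rlang::abort("With a closure state, initial values must sum to 1.")
    }
  }
  structure(
    list(initial = initial, terms = terms, closure = closure),
    class = "ode_model"
  )
}

#' @rdname ode_model
#' @param state Equation the term belongs to.
#' @param sign `+1` or `-1`.
#' @param param Parameter name or `NA` for a literal-only coefficient.
#' @param const Literal multiplier (e.g. the 2 in `2 beta S O`).
#' @param monomial Character vector of 0-2 state names.
#' @export
rhs_term <- function(state, sign, param = NA_character_, const = 1,
                     monomial = character(0)) {
  tibble::tibble(
    state = state, sign = sign, param = param, const = const,
    monomial = list(monomial)
  )
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model> states: %s", paste(names(x$initial), collapse = ", ")))
  if (!is.null(x$closure)) {
    cat(sprintf(" (+ closure state %s)", names(x$closure)))
  }
  cat(sprintf("; %d RHS terms\n", nrow(x$terms)))
  invisible(x)
}

model_param_names <- function(model) {
  unique(stats::na.omit(model$terms$param))
}

#' Evaluate the right-hand side of a model
#'
#' Exact polynomial evaluation of each state's term list at given state and
#' parameter values. Vectorized: `states` and `params` may be matrices (one
#' row per scenario), in which case a matrix of derivatives is returned.
#' When the model declares a closure state its value is derived as 1 minus
#' the sum of the modeled states before terms are evaluated.
#'
#' @param model An [ode_model()].
#' @param states Named numeric vector of modeled-state values, or a matrix
#'   with one named column per modeled state.
#' @param params Named numeric vector of parameter values, or a matrix with
#'   one named column per parameter (rows matching `states`).
#' @return Derivatives in the same shape as `states`.
#' @export
eval_rhs <- function(model, states, params) {
  stopifnot(inherits(model, "ode_model"))
  vec_in <- is.null(dim(states))
  if (vec_in) states <- matrix(states, nrow = 1, dimnames = list(NULL, names(states)))
  if (is.null(dim(params))) {
    params <- matrix(params, nrow = 1, dimnames = list(NULL, names(params)))
  }
  missing_states <- setdiff(names(model$initial), colnames(states))
  if (length(missing_states)) {
    rlang::abort(sprintf("Missing state values: %s.",
                         paste(missing_states, collapse = ", ")))
  }
  missing_pars <- setdiff(model_param_names(model), colnames(params))
  if (length(missing_pars)) {
    rlang::abort(sprintf("Unresolved parameters: %s.",
                         paste(missing_pars, collapse = ", ")))
  }
  if (nrow(params) == 1L && nrow(states) > 1L) {
    params <- params[rep(1L, nrow(states)), , drop = FALSE]
  }
  if (!is.null(model$closure)) {
    cl <- 1 - rowSums(states[, names(model$initial), drop = FALSE])
    states <- cbind(states, matrix(cl, ncol = 1,
                                   dimnames = list(NULL, names(model$closure))))
  }
  deriv <- matrix(0, nrow(states), length(model$initial),
                  dimnames = list(NULL, names(model$initial)))
  for (r in seq_len(nrow(model$terms))) {
    tm <- model$terms[r, ]
    val <- rep(tm$sign * tm$const, nrow(states))
    if (!is.na(tm$param)) val <- val * params[, tm$param]
    for (s in tm$monomial[[1]]) val <- val * states[, s]
    deriv[, tm$state] <- deriv[, tm$state] + val
  }
  if (vec_in) deriv[1, ] else deriv
}

#' The obesity population-dynamics model
#'
#' A three-compartment model of adult body-mass-index dynamics: normal
#' weight `N`, overweight `S`, and obese `O`, as proportions of the 24-65
#' year-old population (time in weeks). Individuals enter from the younger
#' age group in proportions `N0/S0/O0` at renewal rate `mu`, leave at the
#' same rate, move from normal weight to overweight through social
#' transmission at rate `beta * N * (S + O)`, progress from overweight to
#' obese at rate `gamma`, and recover (`O -> S` at rate `epsilon`,
#' `S -> N` at rate `rho`):
#' \deqn{N' = \mu N^0 - \mu N - \beta N (S + O) + \rho S}
#' \deqn{S' = \mu S^0 + \beta N (S + O) - (\mu + \gamma + \rho) S + \epsilon O}
#' \deqn{O' = \mu O^0 + \gamma S - (\mu + \epsilon) O}
#'
#' Because the proportions satisfy `N + S + O = 1` the `"reduced"` variant
#' eliminates `N`: it keeps the `S` and `O` equations, substitutes
#' `N = 1 - S - O` (expanding the transmission term into linear and
#' bilinear terms in `S`, `O`), and records `N` as a closure state. The
#' `"full"` variant transcribes all three equations.
#'
#' @param variant `"reduced"` (default; 2 modeled states + closure) or
#'   `"full"` (3 modeled states).
#' @param initial Named numeric vector with entries `N`, `S`, `O` summing
#'   to 1. Defaults to the 2000 Valencia survey proportions.
#' @return An [ode_model()] whose terms reference parameters
#'   `mu, beta, gamma, epsilon, rho` and constants `N0, S0, O0` (see
#'   [obesity_params()]).
#' @examples
#' m <- obesity_model("reduced")
#' eval_rhs(m, c(S = 0.362, O = 0.116), param_means(obesity_params()))
#' @export
obesity_model <- function(variant = c("reduced", "full"),
                          initial = c(N = 0.522, S = 0.362, O = 0.116)) {
  variant <- match.arg(variant)
  stopifnot(all(c("N", "S", "O") %in% names(initial)))
  if (abs(sum(initial[c("N", "S", "O")]) - 1) > 1e-10) {
    rlang::abort("Initial proportions N + S + O must sum to 1.")
  }
  src <- function(state, frac) rhs_term(state, +1, "mu", const = frac)
  s_common <- dplyr::bind_rows(
    rhs_term("S", -1, "mu", monomial = "S"),
    rhs_term("S", -1, "gamma", monomial = "S"),
    rhs_term("S", -1, "rho", monomial = "S"),
    rhs_term("S", +1, "epsilon", monomial = "O")
  )
  o_terms <- dplyr::bind_rows(
    src("O", obesity_entry_fractions()[["O0"]]),
    rhs_term("O", +1, "gamma", monomial = "S"),
    rhs_term("O", -1, "mu", monomial = "O"),
    rhs_term("O", -1, "epsilon", monomial = "O")
  )
  if (variant == "full") {
    terms <- dplyr::bind_rows(
      src("N", obesity_entry_fractions()[["N0"]]),
      rhs_term("N", -1, "mu", monomial = "N"),
      rhs_term("N", -1, "beta", monomial = c("N", "S")),
      rhs_term("N", -1, "beta", monomial = c("N", "O")),
      rhs_term("N", +1, "rho", monomial = "S"),
      src("S", obesity_entry_fractions()[["S0"]]),
      rhs_term("S", +1, "beta", monomial = c("N", "S")),
      rhs_term("S", +1, "beta", monomial = c("N", "O")),
      s_common,
      o_terms
    )
    ode_model(initial[c("N", "S", "O")], terms)
  } else {
    # beta * (1 - S - O) * (S + O) = beta(S + O) - beta(S + O)^2
    terms <- dplyr::bind_rows(
      src("S", obesity_entry_fractions()[["S0"]]),
      rhs_term("S", +1, "beta", monomial = "S"),
      rhs_term("S", +1, "beta", monomial = "O"),
      rhs_term("S", -1, "beta", monomial = c("S", "S")),
      rhs_term("S", -1, "beta", const = 2, monomial = c("S", "O")),
      rhs_term("S", -1, "beta", monomial = c("O", "O")),
      s_common,
      o_terms
    )
    ode_model(initial[c("S", "O")], terms, closure = initial["N"])
  }
}

obesity_entry_fractions <- function() {
  c(N0 = 0.704, S0 = 0.25, O0 = 0.046)
}

#' Parameter values and distributions for the obesity model
#'
#' Point estimates from the Valencia (Spain) health surveys: transmission
#' and transition rates per week, plus the entry proportions from the
#' 23-year-old age group. With `random = TRUE` the four transmission
#' parameters `beta, gamma, epsilon, rho` become independent
#' `Uniform(0, 2 theta)` random variables about their point estimates
#' `theta` — the noninformative choice whose mean is the estimate — while
#' the demographic turnover `mu` stays deterministic. The entry proportions
#' `N0/S0/O0` are treated as known constants baked into the model terms.
#'
#' @param random If `TRUE` (default) the four transmission parameters are
#'   uniform random variables on their own germ dimensions; if `FALSE` all
#'   parameters are deterministic point estimates.
#' @return A [param_set()] with parameters `beta, gamma, epsilon, rho, mu`.
#' @examples
#' obesity_params(random = FALSE)
#' @export
obesity_params <- function(random = TRUE) {
  est <- c(beta = 0.00085, gamma = 0.0003, epsilon = 0.000004, rho = 0.000035)
  decls <- if (random) {
    purrr::imap(est, function(v, nm) uniform_about_param(nm, v))
  } else {
    purrr::imap(est, function(v, nm) fixed_param(nm, v))
  }
  decls <- c(unname(decls), list(fixed_param("mu", 0.000469)))
  param_set(decls)
}
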