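# Shared fixtures: tiny models and an independent quadrature projector.

# dX/dt = -theta * X, one random parameter
toy_decay_model <- function(x0 = 1) {
  ode_model(c(X = x0), rhs_term("X", -1, "theta", monomial = "X"))
}

# dX/dt = a + b: additive in two parameters, X(t) = (a + b) t
toy_additive_model <- function() {
  ode_model(
    c(X = 0),
    dplyr::bind_rows(rhs_term("X", +1, "a"), rhs_term("X", +1, "b"))
  )
}

# Project a function of one germ variable onto a univariate Legendre chaos
# basis by high-resolution Gauss-Legendre quadrature (independent of the
# package's tensor machinery).
project_univariate <- function(f, basis, n_nodes = 400) {
  stopifnot(basis$n_dims == 1L)
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  vals <- f(gl$x)
  vapply(seq_len(nrow(basis$indices)), function(i) {
    sum(gl$w / 2 * vals * legendre_poly(basis$indices[i, 1], gl$x)) /
      basis$norms_sq[i]
  }, numeric(1))
}

# Independent high-resolution quadrature of E[prod of Legendre polys]
# under density 1/2 on [-1, 1].
uni_moment_quad <- function(degrees, n_nodes = 100) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  vals <- rep(1, n_nodes)
  for (d in degrees) vals <- vals * legendre_poly(d, gl$x)
  sum(gl$w / 2 * vals)
}

obesity_fixture <- function(order = 2) {
  params <- obesity_params()
  list(
    model = obesity_model("reduced"),
    params = params,
    basis = pc_basis(n_dims = sum(params$random), order = order)
  )
}
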