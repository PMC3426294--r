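test_that("assembled coefficient equations match a hand-derived linear projection", {
  # dX/dt = -theta X with theta = theta0 + theta1 * xi, one germ, order 2.
  # Hand Galerkin projection using E[P1 P1] = 1/3, E[P1 P1 P2] = 2/15,
  # E[P2 P2] = 1/5:
  #   X0' = -(theta0 X0 + theta1 X1 / 3)
  #   X1' = -(theta0 X1 + theta1 (X0 + 2 X2 / 5))
  #   X2' = -(theta0 X2 + 2 theta1 X1 / 3)
  theta0 <- 0.8; theta1 <- 0.3
  ps <- param_set(uniform_param("theta", theta0 - theta1, theta0 + theta1))
  sys <- galerkin_system(toy_decay_model(), ps, pc_basis(1, 2))
  M <- rbind(
    c(theta0, theta1 / 3, 0),
    c(theta1, theta0, 2 * theta1 / 5),
    c(0, 2 * theta1 / 3, theta0)
  )
  for (y in list(c(1, 0, 0), c(0.3, -0.2, 0.7), c(1, 1, 1))) {
    expect_equal(epichaos:::galerkin_rhs(sys, y), drop(-M %*% y),
                 tolerance = 1e-13)
  }
})

test_that("chaos coefficients converge to the quadrature projection of the exact solution", {
  # X(t; xi) = exp(-theta(xi) t), theta ~ U(0.5, 1.5); at order 8 the
  # Galerkin solution matches the exact projection to integrator accuracy
  basis <- pc_basis(1, 8)
  ps <- param_set(uniform_param("theta", 0.5, 1.5))
  sys <- galerkin_system(toy_decay_model(), ps, basis)
  sol <- integrate_chaos(sys, 2, output_times = c(0.5, 1, 2))
  for (k in seq_along(sol$time)) {
    tt <- sol$time[k]
    if (tt == 0) next
    exact <- project_univariate(function(xi) exp(-(1 + 0.5 * xi) * tt), basis)
    expect_equal(unname(sol$coefs[k, , "X"]), exact, tolerance = 1e-6)
  }
})

test_that("the reduced obesity Galerkin system has 30 unknowns", {
  fx <- obesity_fixture()
  sys <- galerkin_system(fx$model, fx$params, fx$basis)
  expect_equal(sys$n_unknowns, 30)
  expect_equal(nrow(fx$basis$indices), 15)
})

test_that("zero-width distributions reduce the chaos solve to the deterministic one", {
  fixed <- obesity_params(random = FALSE)
  times <- seq(0, 800, by = 40)
  sys <- galerkin_system(obesity_model("reduced"), fixed, pc_basis(4, 2))
  sol <- integrate_chaos(sys, 800, times)
  det <- solve_deterministic(obesity_model("reduced"), fixed, times)
  expect_equal(unname(sol$coefs[, 1, "S"]), det$S, tolerance = 1e-8)
  expect_equal(unname(sol$coefs[, 1, "O"]), det$O, tolerance = 1e-8)
  expect_lt(max(abs(sol$coefs[, -1, c("S", "O")])), 1e-10)
})

test_that("chaos initial conditions are deterministic", {
  fx <- obesity_fixture()
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         100, c(50, 100))
  expect_equal(unname(sol$coefs[1, 1, c("S", "O", "N")]),
               c(0.362, 0.116, 0.522))
  expect_equal(max(abs(sol$coefs[1, -1, ])), 0)
})

test_that("closure coefficients conserve total population in coefficient space", {
  fx <- obesity_fixture()
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         800, seq(0, 800, by = 40))
  tot <- sol$coefs[, , "N"] + sol$coefs[, , "S"] + sol$coefs[, , "O"]
  expect_lt(max(abs(tot[, 1] - 1)), 1e-12)
  expect_lt(max(abs(tot[, -1])), 1e-12)
})

test_that("full 3-state and reduced 2-state chaos solves agree", {
  params <- obesity_params()
  basis <- pc_basis(4, 2)
  times <- c(0, 260, 520, 780)
  red <- integrate_chaos(galerkin_system(obesity_model("reduced"), params, basis),
                         800, times)
  full <- integrate_chaos(galerkin_system(obesity_model("full"), params, basis),
                          800, times)
  for (s in c("N", "S", "O")) {
    expect_equal(red$coefs[, , s], full$coefs[, , s], tolerance = 1e-6)
  }
})

test_that("order-2 and order-3 chaos means agree to 0.1 percentage points", {
  f2 <- obesity_fixture(order = 2)
  f3 <- obesity_fixture(order = 3)
  s2 <- integrate_chaos(galerkin_system(f2$model, f2$params, f2$basis),
                        520, c(520))
  s3 <- integrate_chaos(galerkin_system(f3$model, f3$params, f3$basis),
                        520, c(520))
  for (s in c("S", "O")) {
    expect_lt(100 * abs(s2$coefs[2, 1, s] - s3$coefs[2, 1, s]), 0.1)
  }
})

test_that("deterministic solve hits the printed initial conditions at t = 0", {
  det <- solve_deterministic(obesity_model("full"), obesity_params(random = FALSE),
                             c(0, 1))
  expect_equal(det$N[1], 0.522)
  expect_equal(det$S[1], 0.362)
  expect_equal(det$O[1], 0.116)
})

test_that("assembly rejects mismatched inputs", {
  fx <- obesity_fixture()
  wrong <- inner_product_tensors(pc_basis(4, 1))
  expect_error(galerkin_system(fx$model, fx$params, fx$basis, wrong),
               "different basis")
  m3 <- ode_model(c(X = 1), rhs_term("X", +1, "a", monomial = c("X", "X")))
  expect_error(galerkin_system(m3, param_set(fixed_param("b", 1)),
                               pc_basis(1, 2)), "resolve")
  expect_error(integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                               -1))
})
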