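make_solution <- function(coefs, basis, params) {
  structure(
    list(time = seq_len(dim(coefs)[1]) - 1, coefs = coefs, basis = basis,
         params = params, modeled_states = dimnames(coefs)[[3]],
         closure = NULL),
    class = "chaos_solution"
  )
}

test_that("variance gathers squared coefficients against the basis norms", {
  basis <- pc_basis(2, 2)
  ps <- param_set(uniform_param("a", 0, 1), uniform_param("b", 0, 1))
  P <- nrow(basis$indices)
  cf <- array(0, dim = c(2, P, 1), dimnames = list(NULL, NULL, "X"))
  cf[, 1, 1] <- c(0.4, 0.5)
  cf[2, 2, 1] <- 0.3 # single degree-1 coefficient c: variance = c^2 / 3
  mom <- chaos_moments(make_solution(cf, basis, ps))
  expect_equal(mom$mean, c(0.4, 0.5))
  expect_equal(mom$variance, c(0, 0.3^2 / 3))
  expect_equal(mom$band_low, mom$mean - mom$sd)
  expect_equal(mom$band_high, mom$mean + mom$sd)
})

test_that("chaos variance equals the analytic variance of the truncated expansion", {
  # identity check via the tensor algebra: for the expansion with the
  # parameter's own coefficients, the gathered variance must equal the
  # closed-form uniform variance
  basis <- pc_basis(3, 2)
  ps <- param_set(uniform_param("a", 0.1, 0.9), fixed_param("c", 2),
                  uniform_param("b", -1, 3))
  cf <- array(0, dim = c(1, nrow(basis$indices), 1),
              dimnames = list(NULL, NULL, "X"))
  cf[1, , 1] <- uniform_to_chaos(-1, 3, 2, basis)
  mom <- chaos_moments(make_solution(cf, basis, ps))
  expect_equal(mom$variance, 16 / 12, tolerance = 1e-14)
})

test_that("obesity moments start deterministic and stay coherent", {
  fx <- obesity_fixture()
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         800, seq(0, 800, by = 80))
  mom <- chaos_moments(sol)
  expect_true(all(mom$variance >= 0))
  expect_true(all(mom$band_low <= mom$mean & mom$mean <= mom$band_high))
  at0 <- dplyr::filter(mom, time == 0)
  expect_equal(at0$variance, rep(0, 3))
  expect_equal(dplyr::filter(at0, state == "O")$mean, 0.116)
})

test_that("Sobol indices attribute everything to the only germ of a 1-parameter model", {
  ps <- param_set(uniform_param("theta", 0.5, 1.5))
  sys <- galerkin_system(toy_decay_model(), ps, pc_basis(1, 2))
  sol <- integrate_chaos(sys, 2, c(1, 2))
  sob <- chaos_sobol(sol)
  at_t <- dplyr::filter(sob, time > 0, parameter == "theta")
  expect_equal(at_t$index, rep(1, 2), tolerance = 1e-10)
  # t = 0 has zero variance: undefined indices flagged as NA
  expect_true(all(is.na(dplyr::filter(sob, time == 0)$index)))
})

test_that("a zero-width parameter gets a zero Sobol index", {
  ps <- param_set(uniform_param("a", 0.5, 1.5), uniform_param("b", 1, 1 + 1e-9))
  m <- ode_model(
    c(X = 1),
    dplyr::bind_rows(rhs_term("X", -1, "a", monomial = "X"),
                     rhs_term("X", -1, "b", monomial = "X"))
  )
  sys <- galerkin_system(m, ps, pc_basis(2, 2))
  sob <- chaos_sobol(integrate_chaos(sys, 1, c(1)))
  b_idx <- dplyr::filter(sob, time == 1, parameter == "b")$index
  expect_lt(b_idx, 1e-10)
})

test_that("the variance decomposition is complete and indices lie in [0, 1]", {
  fx <- obesity_fixture()
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         800, seq(40, 800, by = 40))
  sob <- chaos_sobol(sol)
  ok <- dplyr::filter(sob, !is.na(index))
  expect_true(all(ok$index >= 0 & ok$index <= 1))
  sums <- ok |>
    dplyr::summarise(s = sum(index), .by = c(time, state)) |>
    dplyr::pull(s)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("the order-2 two-term Sobol gather uses Var(P1) = 1/3 and Var(P2) = 1/5", {
  fx <- obesity_fixture()
  basis <- fx$basis
  # beta rides germ dimension 1: its group is positions 2 (xi_1) and 6 (xi_1^2)
  expect_equal(basis$norms_sq[2], 1 / 3)
  expect_equal(basis$norms_sq[6], 1 / 5)
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         520, c(520))
  o <- sol$coefs[2, , "O"]
  total <- sum(o[-1]^2 * basis$norms_sq[-1])
  manual <- (o[2]^2 * (1 / 3) + o[6]^2 * (1 / 5)) / total
  sob <- chaos_sobol(sol, states = "O")
  expect_equal(dplyr::filter(sob, time == 520, parameter == "beta")$index,
               manual, tolerance = 1e-12)
})

test_that("transit to obesity dominates the obese-state variance", {
  fx <- obesity_fixture()
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         800, seq(40, 800, by = 40))
  wide <- chaos_sobol(sol, states = "O") |>
    dplyr::filter(parameter != "interactions", time > 0) |>
    tidyr::pivot_wider(names_from = parameter, values_from = index)
  expect_true(all(wide$gamma > wide$beta))
  expect_true(all(wide$gamma > wide$epsilon))
  expect_true(all(wide$gamma > wide$rho))
})

test_that("moment and Sobol plots build", {
  fx <- obesity_fixture()
  sol <- integrate_chaos(galerkin_system(fx$model, fx$params, fx$basis),
                         520, seq(0, 520, by = 52))
  p1 <- ggplot2::autoplot(chaos_moments(sol))
  p2 <- ggplot2::autoplot(chaos_sobol(sol), states = "O")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
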