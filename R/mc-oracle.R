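# Solve the model for a matrix of parameter draws as one stacked ODE
# system (states vectorized over samples). Returns array
# [time, sample, state] including any closure state.
solve_param_samples <- function(model, draws, output_times,
                                rtol = 1e-8, atol = 1e-10) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  states <- names(model$initial)
  m <- length(states)
  output_times <- sort(unique(c(0, output_times)))
  y0 <- rep(model$initial, each = n)
  sol <- deSolve::ode(
    y = y0, times = output_times,
    func = function(t, y, p) {
      ymat <- matrix(y, nrow = n, dimnames = list(NULL, states))
      list(as.vector(eval_rhs(model, ymat, draws)))
    },
    parms = NULL, method = "ode45", rtol = rtol, atol = atol
  )
  if (nrow(sol) < length(output_times)) {
    bad <- which.max(abs(matrix(sol[nrow(sol), -1], nrow = n)[, 1]))
    rlang::abort(sprintf(
      "Monte Carlo integration failed near t = %.3f (worst draw row %d).",
      sol[nrow(sol), 1], bad
    ))
  }
  out <- array(sol[, -1], dim = c(nrow(sol), n, m),
               dimnames = list(NULL, NULL, states))
  if (!is.null(model$closure)) {
    cl <- 1 - apply(out, c(1, 2), sum)
    full <- array(0, dim = dim(out) + c(0, 0, 1),
                  dimnames = list(NULL, NULL, c(states, names(model$closure))))
    full[, , states] <- out
    full[, , names(model$closure)] <- cl
    out <- full
  }
  attr(out, "time") <- sol[, 1]
  out
}

#' Monte Carlo uncertainty propagation
#'
#' The brute-force reference method: draw joint parameter samples, solve
#' the deterministic model for each draw, and accumulate per-state means
#' and variances at the output times. Draws are processed in chunks, each
#' chunk solved as a single stacked ODE system, with single-pass
#' accumulation of sums and sums of squares across chunks, so memory stays
#' flat at large sample counts. Serves as the independent oracle for the
#' spectral (Galerkin) propagation.
#'
#' @param model An [ode_model()].
#' @param params A [param_set()].
#' @param output_times Report times.
#' @param n_samples Number of parameter draws, at least 2.
#' @param seed Integer seed.
#' @param chunk_size Draws per stacked solve.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `mc_estimate`; its `estimates` element is a
#'   tibble with columns `time`, `state`, `mean`, `variance`, `se`
#'   (standard error of the mean, `sqrt(variance / n_samples)`).
#' @examples
#' mc_propagate(obesity_model(), obesity_params(), c(260, 520),
#'              n_samples = 500, seed = 1)
#' @export
mc_propagate <- function(model, params, output_times, n_samples, seed,
                         chunk_size = 10000L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"), inherits(params, "param_set"))
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  draws <- sample_params(params, n_samples, seed)
  output_times <- sort(unique(c(0, output_times)))
  states <- c(names(model$initial), names(model$closure))
  # streaming pairwise (Chan et al.) mean / centered-sum-of-squares merge
  # across chunks: numerically stable even for zero-variance degenerate runs
  n_acc <- 0L
  mean_acc <- m2_acc <- matrix(0, length(output_times), length(states),
                               dimnames = list(NULL, states))
  starts <- seq(1L, n_samples, by = chunk_size)
  for (s0 in starts) {
    rows <- s0:min(s0 + chunk_size - 1L, n_samples)
    sims <- solve_param_samples(model, draws[rows, , drop = FALSE],
                                output_times, rtol = rtol, atol = atol)
    n_c <- length(rows)
    mean_c <- apply(sims, c(1, 3), mean)
    centered <- sims - aperm(array(mean_c, c(dim(mean_c), n_c)), c(1, 3, 2))
    m2_c <- apply(centered^2, c(1, 3), sum)
    delta <- mean_c - mean_acc
    n_new <- n_acc + n_c
    mean_acc <- mean_acc + delta * n_c / n_new
    m2_acc <- m2_acc + m2_c + delta^2 * n_acc * n_c / n_new
    n_acc <- n_new
  }
  est <- purrr::map_dfr(states, function(s) {
    var_s <- pmax(m2_acc[, s] / (n_samples - 1), 0)
    tibble::tibble(time = output_times, state = s, mean = mean_acc[, s],
                   variance = var_s, se = sqrt(var_s / n_samples))
  })
  structure(
    list(estimates = est, n_samples = n_samples, seed = seed),
    class = "mc_estimate"
  )
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("<mc_estimate> %d samples (seed %s)\n", x$n_samples,
              format(x$seed)))
  print(x$estimates)
  invisible(x)
}

#' Pick-and-freeze Monte Carlo Sobol indices
#'
#' First-order Sobol indices by the two-matrix pick-and-freeze scheme:
#' with independent draw matrices `A` and `B`, and `AB_d` equal to `A`
#' with parameter `d`'s column taken from `B`, the estimator is
#' `S_d = mean(y_B * (y_AB_d - y_A)) / Var(y)`. Bootstrap resampling of
#' the sample rows gives a standard error per index. This is the
#' independent oracle for the chaos-based index gather of [chaos_sobol()].
#'
#' @param model An [ode_model()].
#' @param params A [param_set()] with at least one random parameter.
#' @param output_times Report times.
#' @param n_samples Base sample size (total solves are
#'   `n_samples * (n_random + 2)`), at least 100.
#' @param seed Integer seed.
#' @param states States to report; defaults to all.
#' @param n_boot Bootstrap replicates for the standard error.
#' @param chunk_size,rtol,atol Passed to the stacked solver.
#' @return A tibble with columns `time`, `state`, `parameter`, `index`,
#'   `se`.
#' @export
mc_sobol <- function(model, params, output_times, n_samples, seed,
                     states = NULL, n_boot = 200L, chunk_size = 10000L,
                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"), inherits(params, "param_set"))
  n_samples <- check_count(n_samples, "n_samples", min = 100L)
  rnd <- params$name[params$random]
  if (!length(rnd)) rlang::abort("No random parameters to analyze.")
  output_times <- sort(unique(output_times))
  all_states <- c(names(model$initial), names(model$closure))
  if (is.null(states)) states <- all_states
  stopifnot(all(states %in% all_states))

  A <- sample_params(params, n_samples, seed)
  B <- sample_params(params, n_samples, seed + 1L)
  designs <- c(list(A = A, B = B),
               stats::setNames(purrr::map(rnd, function(p) {
                 AB <- A
                 AB[[p]] <- B[[p]]
                 AB
               }), rnd))

  run <- function(draws) {
    y <- array(NA_real_, dim = c(length(output_times), n_samples,
                                 length(states)),
               dimnames = list(NULL, NULL, states))
    starts <- seq(1L, n_samples, by = chunk_size)
    for (s0 in starts) {
      rows <- s0:min(s0 + chunk_size - 1L, n_samples)
      sims <- solve_param_samples(model, draws[rows, , drop = FALSE],
                                  output_times, rtol = rtol, atol = atol)
      tt <- match(output_times, attr(sims, "time"))
      y[, rows, ] <- sims[tt, , states, drop = FALSE]
    }
    y
  }
  ys <- purrr::map(designs, run)

  estimator <- function(rows, tix, s) {
    yA <- ys$A[tix, rows, s]
    yB <- ys$B[tix, rows, s]
    v <- stats::var(c(yA, yB))
    # centering yB leaves the expectation unchanged (E[y_AB - y_A] = 0)
    # but removes the mean-level noise from the product estimator
    yBc <- yB - mean(c(yA, yB))
    vapply(rnd, function(p) mean(yBc * (ys[[p]][tix, rows, s] - yA)) / v,
           numeric(1))
  }
  boot_rows <- withr::with_seed(seed + 2L, {
    purrr::map(seq_len(n_boot),
               function(b) sample.int(n_samples, replace = TRUE))
  })
  purrr::map_dfr(states, function(s) {
    purrr::map_dfr(seq_along(output_times), function(tix) {
      est <- estimator(seq_len(n_samples), tix, s)
      boots <- vapply(boot_rows, function(rows) estimator(rows, tix, s),
                      numeric(length(rnd)))
      if (length(rnd) == 1L) boots <- matrix(boots, nrow = 1)
      tibble::tibble(
        time = output_times[tix], state = s, parameter = rnd,
        index = unname(est), se = unname(apply(boots, 1, stats::sd))
      )
    })
  })
}
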