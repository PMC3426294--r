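#' Read and validate a run configuration
#'
#' A run configuration is a single YAML file declaring the model (the
#' bundled obesity model or a custom state/term list), the parameter
#' distributions, the chaos settings, the time grid, and which analyses to
#' run. See `system.file("extdata", "obesity.yaml", package = "epichaos")`
#' for the bundled example. Parameters are declared either as a bare number
#' (deterministic), as `{dist: uniform, lower, upper}`, or as
#' `{dist: uniform_about, mean}` (the `Uniform(0, 2 * mean)` convention).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such config file: %s", path))
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A raw configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(config) {
  fail <- function(field, msg) {
    rlang::abort(sprintf("Invalid configuration at `%s`: %s", field, msg))
  }
  if (!is.list(config)) fail("(root)", "must be a mapping")
  analyses <- config$analyses %||% "chaos"
  known <- c("deterministic", "chaos", "sobol", "mc")
  if (!all(analyses %in% known)) {
    fail("analyses", sprintf("must be a subset of {%s}",
                             paste(known, collapse = ", ")))
  }
  order <- config$chaos$order %||% 2
  if (any(c("chaos", "sobol") %in% analyses)) {
    if (!is.numeric(order) || length(order) != 1 || order < 1 ||
        order != as.integer(order)) {
      fail("chaos.order", "must be an integer >= 1 when chaos/sobol requested")
    }
  }
  if ("mc" %in% analyses) {
    if (is.null(config$mc$seed)) fail("mc.seed", "required when mc requested")
    if (is.null(config$mc$n_samples) || config$mc$n_samples < 2) {
      fail("mc.n_samples", "must be >= 2 when mc requested")
    }
  }
  tm <- config$time
  if (is.null(tm$t_end) || !is.numeric(tm$t_end) || tm$t_end <= 0) {
    fail("time.t_end", "must be a positive number")
  }
  if (is.null(tm$output_times) && is.null(tm$stride)) {
    fail("time", "needs `output_times` or `stride`")
  }
  if (is.null(config$model)) fail("model", "required")
  if (is.character(config$model) && !identical(config$model, "obesity")) {
    fail("model", "named models: \"obesity\"")
  }
  if (is.list(config$model)) {
    if (is.null(config$model$states)) fail("model.states", "required")
    if (is.null(config$model$terms)) fail("model.terms", "required")
  }
  if (!identical(config$model, "obesity") && is.null(config$parameters)) {
    fail("parameters", "required for custom models")
  }
  structure(config, class = "run_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

config_params <- function(config) {
  if (is.null(config$parameters)) return(obesity_params())
  decls <- purrr::imap(config$parameters, function(spec, nm) {
    if (is.numeric(spec)) return(fixed_param(nm, spec))
    if (!is.list(spec) || is.null(spec$dist)) {
      rlang::abort(sprintf(
        "Invalid configuration at `parameters.%s`: need a number or a dist spec",
        nm))
    }
    switch(spec$dist,
      uniform = uniform_param(nm, spec$lower, spec$upper),
      uniform_about = uniform_about_param(nm, spec$mean),
      rlang::abort(sprintf(
        "Invalid configuration at `parameters.%s.dist`: unknown \"%s\"",
        nm, spec$dist))
    )
  })
  param_set(unname(decls))
}

config_model <- function(config) {
  if (identical(config$model, "obesity")) {
    return(obesity_model(config$variant %||% "reduced"))
  }
  m <- config$model
  initial <- unlist(m$states)
  closure <- if (!is.null(m$closure)) {
    cl <- unlist(m$closure)
    initial <- initial[setdiff(names(initial), names(cl))]
    cl
  }
  terms <- purrr::map_dfr(m$terms, function(tm) {
    rhs_term(tm$state, tm$sign, param = tm$param %||% NA_character_,
             const = tm$const %||% 1,
             monomial = as.character(tm$monomial %||% character(0)))
  })
  ode_model(initial, terms, closure = closure)
}

config_times <- function(config) {
  tm <- config$time
  if (!is.null(tm$output_times)) sort(unique(c(0, unlist(tm$output_times))))
  else seq(0, tm$t_end, by = tm$stride)
}

#' Run the configured analyses and write tidy CSV outputs
#'
#' Executes each requested analysis (`deterministic`, `chaos`, `sobol`,
#' `mc`) and writes one tidy CSV per result — plus, for chaos runs, the
#' raw coefficient trajectories — and a JSON run manifest recording the
#' resolved configuration, package version, seeds and wall-clock time.
#' All value CSVs share the schema `time, state, quantity, method, value`.
#' On failure, partially written outputs are removed.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the paths of the files written.
#' @export
run_analyses <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    rlang::abort("Run failed; partial outputs removed.", parent = e)
  }
  tryCatch({
    model <- config_model(config)
    params <- config_params(config)
    times <- config_times(config)
    t_end <- config$time$t_end
    analyses <- config$analyses %||% "chaos"
    emit <- function(dat, file) {
      path <- file.path(out_dir, file)
      utils::write.csv(dat, path, row.names = FALSE)
      written <<- c(written, path)
      say("wrote %s", path)
    }
    long_schema <- function(dat, method) {
      dat |>
        tidyr::pivot_longer(-c("time", "state"), names_to = "quantity",
                            values_to = "value") |>
        dplyr::mutate(method = method, .before = "value")
    }
    sol <- NULL
    if (any(c("chaos", "sobol") %in% analyses)) {
      basis <- pc_basis(n_random(params), config$chaos$order %||% 2)
      say("assembling Galerkin system (%d unknowns)",
          length(model$initial) * nrow(basis$indices))
      sys <- galerkin_system(model, params, basis)
      sol <- integrate_chaos(sys, t_end, times)
    }
    if ("deterministic" %in% analyses) {
      det <- solve_deterministic(model, params, times) |>
        tidyr::pivot_longer(-"time", names_to = "state", values_to = "value") |>
        dplyr::mutate(quantity = "value", method = "deterministic",
                      .before = "value")
      emit(det, "deterministic.csv")
    }
    if ("chaos" %in% analyses) {
      emit(long_schema(chaos_moments(sol), "chaos"), "moments.csv")
      emit(dplyr::rename(tidy(sol), value = "value"), "coefficients.csv")
    }
    if ("sobol" %in% analyses) {
      sob <- chaos_sobol(sol) |>
        dplyr::transmute(.data$time, .data$state,
                         quantity = paste0("sobol_", .data$parameter),
                         method = "chaos", value = .data$index)
      emit(sob, "sobol.csv")
    }
    if ("mc" %in% analyses) {
      mc <- mc_propagate(model, params, times,
                         n_samples = config$mc$n_samples,
                         seed = config$mc$seed)
      emit(long_schema(dplyr::select(mc$estimates, -"se"), "mc"), "mc.csv")
    }
    manifest <- list(
      config = unclass(config),
      package = "epichaos",
      version = as.character(utils::packageVersion("epichaos")),
      r_version = R.version.string,
      wall_clock_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
      files = basename(written)
    )
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, path)
    invisible(written)
  }, error = on_fail)
}

#' Summary table of prevalence predictions
#'
#' Formats chaos (or deterministic) results the way prevalence projections
#' are tabulated: one row per calendar year, the mean prevalence in
#' percent, and — when variances are available — the one-standard-deviation
#' interval endpoints. Weeks map to calendar years as
#' `year = start_year + t / 52`. Percentages are rounded half-even to 2
#' decimals.
#'
#' @param moments A [chaos_moments()] tibble, or a [solve_deterministic()]
#'   tibble (means only).
#' @param times Week values to report (must be present in the input).
#' @param states States to include.
#' @param start_year Calendar year corresponding to `t = 0`.
#' @return A tibble with columns `year`, `time`, `state`, `mean_pct` and
#'   (for chaos input) `low_pct`, `high_pct`.
#' @export
prevalence_table <- function(moments, times = c(520, 572, 780),
                             states = c("S", "O"), start_year = 2000) {
  if (!nrow(moments)) rlang::abort("Empty moment input; nothing to report.")
  if (!"state" %in% names(moments)) {
    moments <- tidyr::pivot_longer(moments, -"time", names_to = "state",
                                   values_to = "mean")
  }
  dat <- dplyr::filter(moments, .data$state %in% states,
                       .data$time %in% times)
  missing_t <- setdiff(times, dat$time)
  if (length(missing_t)) {
    rlang::abort(sprintf("Times not present in the input: %s.",
                         paste(missing_t, collapse = ", ")))
  }
  out <- dat |>
    dplyr::mutate(year = start_year + .data$time / 52,
                  mean_pct = round(100 * .data$mean, 2))
  if ("band_low" %in% names(out)) {
    out <- dplyr::mutate(out,
                         low_pct = round(100 * .data$band_low, 2),
                         high_pct = round(100 * .data$band_high, 2))
  }
  cols <- intersect(c("year", "time", "state", "mean_pct", "low_pct", "high_pct"),
                    names(out))
  dplyr::arrange(dplyr::select(out, dplyr::all_of(cols)), .data$time,
                 .data$state)
}
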