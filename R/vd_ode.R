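#' Solver configuration
#'
#' @param n_steps number of integration timesteps `i` (default 40).
#' @param eta blending strength (default 1.0).
#' @param clamp_lo,clamp_hi clamp bounds applied to each scalar blending
#'   coefficient (defaults `1e-6` and `1 - 1e-6`).
#' @param seed integer seed recorded for stochastic fields.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_steps = 40L, eta = 1.0,
                          clamp_lo = 1e-6, clamp_hi = 1 - 1e-6,
                          seed = 1L) {
  if (n_steps < 1) stop_input("solver_config: n_steps must be >= 1")
  if (clamp_lo >= clamp_hi) stop_input("solver_config: clamp_lo must be < clamp_hi")
  if (eta <= 0) stop_input("solver_config: eta must be positive")
  structure(
    list(n_steps = as.integer(n_steps), eta = eta,
         clamp_lo = clamp_lo, clamp_hi = clamp_hi, seed = as.integer(seed)),
    class = "solver_config"
  )
}

clamp01 <- function(x, config) pmin(pmax(x, config$clamp_lo), config$clamp_hi)

#' One variance-diminishing ODE step
#'
#' With `t = n/i` and `s = (n+1)/i`, the update blends the current state
#' and the endpoint prediction with clamped scalar coefficients:
#' `x_{n+1} = clamp((1-s)/(1-t) * eta) * x_n +
#'            clamp((1 - (1-s)/(1-t)) * eta) * pred`.
#' The clamp acts on each scalar coefficient (not on coordinates),
#' bounding both into `[clamp_lo, clamp_hi]`. For `eta = 1` the unclamped
#' coefficients sum to 1 and the update is the Euler discretization of
#' the linear-path ODE; the clamp keeps the terminal step from fully
#' discarding the current state, which sharply interpolates toward the
#' prediction in late steps while damping early-step prediction variance.
#'
#' @param x_n current coordinates (n-th state).
#' @param endpoint_pred endpoint prediction `v(x_n, t)` of the same shape.
#' @param n current integer timestep, `0 <= n < n_steps`.
#' @param config a [solver_config()].
#' @return The next coordinate matrix.
#' @export
vd_ode_step <- function(x_n, endpoint_pred, n, config = solver_config()) {
  i <- config$n_steps
  if (n < 0 || n >= i) stop_input("vd_ode_step: step n = %d outside [0, %d)", n, i)
  t <- n / i
  s <- (n + 1) / i
  a <- clamp01((1 - s) / (1 - t) * config$eta, config)
  b <- clamp01((1 - (1 - s) / (1 - t)) * config$eta, config)
  a * x_n + b * endpoint_pred
}

#' Integrate an endpoint-predicting field with the VD-ODE solver
#'
#' Runs [vd_ode_step()] for `n = 0, ..., n_steps - 1` starting from a
#' prior sample. The field is called as `field(x, t)` and must return an
#' endpoint prediction of the same shape as `x`. Deterministic given the
#' prior sample and the field.
#'
#' @param prior_sample a [complex_structure()] (the t = 0 state) or a
#'   bare coordinate matrix.
#' @param field function `(coords, t) -> coords` predicting the endpoint.
#' @param config a [solver_config()].
#' @return An object of class `flow_trajectory`: list with `states`
#'   (length `n_steps + 1` list of coordinate matrices), `times` (the t
#'   grid `n/i`), and `template` (the input complex, if one was given).
#'   The final state is the holo prediction.
#' @export
vd_ode_integrate <- function(prior_sample, field, config = solver_config()) {
  integrate_impl(prior_sample, config, function(x, n) {
    t <- n / config$n_steps
    pred <- field(x, t)
    check_field_output(pred, x, n)
    vd_ode_step(x, pred, n, config)
  })
}

#' Integrate with a plain Euler baseline on the induced velocity
#'
#' Baseline solver for comparison with [vd_ode_integrate()]: the endpoint
#' prediction induces the velocity `(pred - x_t) / (1 - t)` of the CondOT
#' path, which is integrated with fixed-step Euler,
#' `x_{n+1} = x_n + (1/i) * v(x_n, t)`.
#'
#' @inheritParams vd_ode_integrate
#' @param field_as_velocity if `TRUE`, `field` is already a velocity
#'   field and is integrated as given; default `FALSE` treats `field` as
#'   an endpoint predictor and forms the induced velocity.
#' @return A `flow_trajectory` (see [vd_ode_integrate()]).
#' @export
euler_integrate <- function(prior_sample, field, config = solver_config(),
                            field_as_velocity = FALSE) {
  i <- config$n_steps
  integrate_impl(prior_sample, config, function(x, n) {
    t <- n / i
    out <- field(x, t)
    check_field_output(out, x, n)
    v <- if (field_as_velocity) out else (out - x) / (1 - t)
    x + v / i
  })
}

integrate_impl <- function(prior_sample, config, step_fn) {
  template <- NULL
  if (inherits(prior_sample, "complex_structure")) {
    template <- prior_sample
    x <- complex_coords(prior_sample)
  } else {
    x <- as_coord_matrix(prior_sample, "prior_sample")
  }
  i <- config$n_steps
  states <- vector("list", i + 1)
  states[[1]] <- x
  for (n in 0:(i - 1)) {
    x <- step_fn(x, n)
    if (!all(is.finite(x))) {
      stop_input("solver diverged: non-finite state after step %d", n)
    }
    states[[n + 2]] <- x
  }
  structure(
    list(states = states, times = (0:i) / i, template = template),
    class = "flow_trajectory"
  )
}

check_field_output <- function(pred, x, n) {
  if (!identical(dim(pred), dim(x))) {
    stop_input("field returned shape %s at step %d (expected %s)",
               paste(dim(pred), collapse = "x"), n,
               paste(dim(x), collapse = "x"))
  }
  if (!all(is.finite(pred))) {
    stop_input("field returned non-finite values at step %d", n)
  }
  invisible(TRUE)
}

#' Final state of a trajectory
#' @param trajectory a `flow_trajectory`.
#' @param as_complex if `TRUE` and the trajectory carries a complex
#'   template, return a [complex_structure()] at t = 1.
#' @return Coordinate matrix or `complex_structure`.
#' @export
trajectory_final <- function(trajectory, as_complex = !is.null(trajectory$template)) {
  x <- trajectory$states[[length(trajectory$states)]]
  if (as_complex && !is.null(trajectory$template)) {
    set_complex_coords(trajectory$template, x, t = 1)
  } else {
    x
  }
}

#' @export
print.flow_trajectory <- function(x, ...) {
  cat(sprintf("flow_trajectory: %d states over t in [0, 1]\n",
              length(x$states)))
  invisible(x)
}
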