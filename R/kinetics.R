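# Protein synthesis/degradation kinetics.
#
# The generative rationale for the power-law regression model: protein influx
# is proportional to the mRNA level and protein outflux proportional to the
# protein level, P'(t) = a E - b P, so at steady state P = (a/b) E. Allowing
# the effective a/b ratio to depend multiplicatively on miRNA expression gives
# the power-law model fitted elsewhere in the package.

#' Kinetic parameters of the protein balance equation
#'
#' Container for the first-order protein kinetics `P'(t) = a*E - b*P(t)` with
#' constant mRNA level `E`.
#'
#' @param a Translation rate (> 0, per unit time).
#' @param b Degradation rate (> 0, per unit time).
#' @param E Constant mRNA expression level (> 0).
#' @param P0 Initial protein level at time 0 (>= 0).
#' @return An object of class `kinetics_params`.
#' @examples
#' p <- kinetics_params(a = 2, b = 1, E = 3)
#' steady_state(p)  # (a/b) * E = 6
#' @export
kinetics_params <- function(a, b, E, P0 = 0) {
  assert_scalar_number(a, "a", lower = 0, strict_lower = TRUE)
  assert_scalar_number(b, "b", lower = 0, strict_lower = TRUE)
  assert_scalar_number(E, "E", lower = 0, strict_lower = TRUE)
  assert_scalar_number(P0, "P0", lower = 0)
  structure(list(a = a, b = b, E = E, P0 = P0), class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "Protein kinetics: a = %g, b = %g, E = %g, P0 = %g (steady state %g)\n",
    x$a, x$b, x$E, x$P0, steady_state(x)))
  invisible(x)
}

#' Steady-state protein level
#'
#' @param params A [kinetics_params()] object.
#' @return The fixed point `(a/b) * E`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "kinetics_params"))
  (params$a / params$b) * params$E
}

check_t_grid <- function(t_grid) {
  if (!is.numeric(t_grid) || length(t_grid) == 0L) {
    stop("`t_grid` must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(t_grid < 0)) stop("`t_grid` must be nonnegative", call. = FALSE)
  if (is.unsorted(t_grid)) stop("`t_grid` must be nondecreasing", call. = FALSE)
  t_grid
}

#' Closed-form protein trajectory
#'
#' Evaluates the exact solution `P(t) = (a/b)E + (P0 - (a/b)E) exp(-b t)` of
#' the protein balance equation on a time grid.
#'
#' @param params A [kinetics_params()] object.
#' @param t_grid Nonempty, nondecreasing vector of times (>= 0).
#' @return Numeric vector `P(t)` of the same length as `t_grid`.
#' @seealso [integrate_kinetics()] for the numerical cross-check.
#' @export
simulate_kinetics <- function(params, t_grid) {
  stopifnot(inherits(params, "kinetics_params"))
  check_t_grid(t_grid)
  ss <- steady_state(params)
  ss + (params$P0 - ss) * exp(-params$b * t_grid)
}

#' Numerical integration of the protein balance equation
#'
#' Fourth-order Runge-Kutta integration of `P' = a*E - b*P`, used as an
#' independent cross-check of [simulate_kinetics()]. The step size is chosen
#' so that `b * dt <= max_bdt`, which keeps the global error well below 1e-6
#' relative to the steady state.
#'
#' @inheritParams simulate_kinetics
#' @param max_bdt Dimensionless step-size cap on `b * dt` (default 0.02).
#' @return Numeric vector `P(t)` on `t_grid`.
#' @export
integrate_kinetics <- function(params, t_grid, max_bdt = 0.02) {
  stopifnot(inherits(params, "kinetics_params"))
  check_t_grid(t_grid)
  assert_scalar_number(max_bdt, "max_bdt", lower = 0, strict_lower = TRUE)
  a <- params$a; b <- params$b; E <- params$E
  deriv <- function(P) a * E - b * P
  rk4_span <- function(P, t0, t1) {
    span <- t1 - t0
    if (span <= 0) return(P)
    n_steps <- max(1L, ceiling(span * b / max_bdt))
    dt <- span / n_steps
    for (i in seq_len(n_steps)) {
      k1 <- deriv(P)
      k2 <- deriv(P + dt / 2 * k1)
      k3 <- deriv(P + dt / 2 * k2)
      k4 <- deriv(P + dt * k3)
      P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    P
  }
  out <- numeric(length(t_grid))
  P <- params$P0
  t_prev <- 0
  for (i in seq_along(t_grid)) {
    P <- rk4_span(P, t_prev, t_grid[i])
    t_prev <- t_grid[i]
    out[i] <- P
  }
  out
}
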