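#' Single steps of the explicit fixed-step schemes
#'
#' One step of the forward Euler, explicit midpoint, or two-step
#' Adams-Bashforth method for a first-order system `dy/dt = f(t, y)`.
#' These are the production integrators typically found in centre-based
#' model codes: forward Euler is first order; midpoint and Adams-Bashforth
#' are second order (the latter reuses the previous step's slope, so it
#' needs only one new right-hand-side evaluation per step but requires the
#' previous state on the same fixed grid).
#'
#' @param f Right-hand side, a function of `(t, y)` returning `dy/dt`.
#' @param t Current time.
#' @param y Current state (numeric vector).
#' @param dt Step size (hours), positive.
#' @return The state at `t + dt`.
#' @examples
#' f <- function(t, y) -y
#' euler_step(f, 0, 1, 0.1)     # 0.9
#' midpoint_step(f, 0, 1, 0.1)  # 0.905, closer to exp(-0.1)
#' @export
euler_step <- function(f, t, y, dt) {
  y + dt * f(t, y)
}

#' @rdname euler_step
#' @export
midpoint_step <- function(f, t, y, dt) {
  y + dt * f(t + dt / 2, y + (dt / 2) * f(t, y))
}

#' @rdname euler_step
#' @param t_prev,y_prev Time and state one step earlier on the same grid;
#'   `t - t_prev` must equal `dt` (checked to a small relative tolerance).
#' @export
ab2_step <- function(f, t_prev, y_prev, t, y, dt) {
  if (abs((t - t_prev) - dt) > 1e-9 * max(dt, 1)) {
    abort("ab2_step(): previous state is not one step of size `dt` earlier")
  }
  y + dt * (1.5 * f(t, y) - 0.5 * f(t_prev, y_prev))
}

#' Trajectory container
#'
#' A trajectory is a strictly increasing time grid plus one state vector per
#' time point (states stored row-wise). Positions of a cell population are
#' flattened cell-id-major, coordinate-minor: `(x_1, y_1, x_2, y_2, ...)`.
#' This layout contract makes space-time error norms reproducible.
#'
#' @param times Strictly increasing numeric vector.
#' @param states Numeric matrix, `length(times)` rows.
#' @param cell_ids Optional integer vector of cell ids (populations only).
#' @param dim Spatial dimension per cell (populations only).
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(times, states, cell_ids = NULL, dim = NULL) {
  states <- as.matrix(states)
  stopifnot(length(times) == nrow(states), all(diff(times) > 0))
  structure(
    list(times = times, states = states, cell_ids = cell_ids, dim = dim),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points on [",
    format(min(x$times)), ", ", format(max(x$times)), "], state dim ",
    ncol(x$states), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.trajectory <- function(x, ...) {
  if (!is.null(x$cell_ids) && !is.null(x$dim)) {
    d <- x$dim
    coords <- c("x", "y", "z")[seq_len(d)]
    out <- purrr::map(seq_along(x$cell_ids), function(i) {
      cols <- (i - 1) * d + seq_len(d)
      df <- tibble(time = x$times, cell_id = x$cell_ids[i])
      for (k in seq_len(d)) df[[coords[k]]] <- x$states[, cols[k]]
      df
    })
    bind_rows(out)
  } else {
    df <- tibble(time = x$times)
    nm <- colnames(x$states)
    if (is.null(nm)) nm <- paste0("y", seq_len(ncol(x$states)))
    for (k in seq_len(ncol(x$states))) df[[nm[k]]] <- x$states[, k]
    df
  }
}

#' Integrate with a fixed-step explicit scheme
#'
#' Runs forward Euler, midpoint or two-step Adams-Bashforth on a uniform
#' grid. If the span is not an integer multiple of `dt`, all interior steps
#' use `dt` and the final step is shortened to land exactly on the end time
#' (this keeps grids from different `dt` choices aligned at the endpoints,
#' which space-time error norms rely on). Adams-Bashforth bootstraps its
#' first step with one forward Euler step — the simplest consistent starter,
#' which does not degrade the asymptotic second-order global error.
#'
#' A non-finite state aborts with a diagnostic: with these explicit schemes
#' that almost always signals a step size beyond the stability bound.
#'
#' @inheritParams euler_step
#' @param y0 Initial state.
#' @param t_span Length-2 numeric `(t_start, t_end)`, `t_end > t_start`.
#' @param scheme One of `"euler"`, `"midpoint"`, `"ab2"`.
#' @return A [new_trajectory()] whose first state is `y0`.
#' @examples
#' tr <- solve_fixed(function(t, y) -y, 1, c(0, 1), dt = 0.1)
#' tail(tr$states, 1) # 0.9^10
#' @export
solve_fixed <- function(f, y0, t_span, dt,
                        scheme = c("euler", "midpoint", "ab2")) {
  scheme <- match.arg(scheme)
  stopifnot(length(t_span) == 2, dt > 0, t_span[2] > t_span[1])
  t0 <- t_span[1]
  t1 <- t_span[2]
  span <- t1 - t0
  n_full <- floor(span / dt + 1e-9)
  times <- t0 + dt * seq(0, n_full)
  short <- t1 - (t0 + dt * n_full)
  # interior steps use dt exactly (not grid differences, which carry
  # floating-point round-off); only a genuinely shortened final step differs
  if (short > 1e-9 * dt) {
    times <- c(times, t1)
    hs <- c(rep(dt, n_full), short)
  } else {
    times[length(times)] <- t1
    hs <- rep(dt, n_full)
  }
  n <- length(times)
  states <- matrix(NA_real_, nrow = n, ncol = length(y0))
  states[1, ] <- y0
  y <- y0
  for (k in seq_len(n - 1)) {
    h <- hs[k]
    y_new <- switch(scheme,
      euler = euler_step(f, times[k], y, h),
      midpoint = midpoint_step(f, times[k], y, h),
      ab2 = {
        if (k == 1) {
          euler_step(f, times[k], y, h)
        } else {
          ab2_step(f, times[k - 1], states[k - 1, ], times[k], y, h)
        }
      }
    )
    if (any(!is.finite(y_new))) {
      abort(paste0(
        "solve_fixed(): non-finite state at t = ", format(times[k + 1]),
        " (scheme ", scheme, ", dt = ", format(dt),
        ") - the step size likely exceeds the stability bound"
      ))
    }
    states[k + 1, ] <- y_new
    y <- y_new
  }
  new_trajectory(times, states)
}

#' High-accuracy adaptive reference solve
#'
#' Integrates with the adaptive embedded Dormand-Prince Runge-Kutta 5(4)
#' pair (via \pkg{deSolve}) at tight tolerances. Used as the gold standard
#' against which the fixed-step schemes are measured, and inside the
#' relaxation-time calibration objective.
#'
#' @inheritParams solve_fixed
#' @param dense_times Output times; defaults to 201 uniform points on
#'   `t_span`. The first must equal `t_span[1]`.
#' @param rtol,atol Relative / absolute tolerances (defaults `1e-9` /
#'   `1e-12`, tight enough that the reference error is negligible next to
#'   any fixed-step error of interest).
#' @return A [new_trajectory()] evaluated at `dense_times`.
#' @export
solve_reference <- function(f, y0, t_span, dense_times = NULL,
                            rtol = 1e-9, atol = 1e-12) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  if (is.null(dense_times)) {
    dense_times <- seq(t_span[1], t_span[2], length.out = 201)
  }
  stopifnot(abs(dense_times[1] - t_span[1]) < 1e-12, all(diff(dense_times) > 0))
  out <- deSolve::ode(
    y = y0, times = dense_times,
    func = function(t, y, parms) list(f(t, y)), parms = NULL,
    method = deSolve::rkMethod("rk45dp7"), rtol = rtol, atol = atol
  )
  if (attr(out, "istate")[1] < 0) {
    abort("solve_reference(): integration failed")
  }
  new_trajectory(out[, 1], out[, -1, drop = FALSE])
}
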