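#' Pairwise relaxation after division
#'
#' Simulates two overlapping daughter cells (initial separation `r0`)
#' relaxing towards the rest length, and returns the centre-centre
#' separation over time. This two-cell system is the fundamental unit used
#' for calibration and for the step-size robustness analysis.
#'
#' @param params A [force_params()] object.
#' @param scheme Solver scheme (see [simulate_population()]).
#' @param dt Step size for fixed-step schemes.
#' @param t_end End time in hours, default 1 (the calibrated relaxation
#'   time).
#' @param r0 Initial separation, default 0.3.
#' @param ... Passed to [simulate_population()].
#' @return A tibble with columns `time` and `separation`.
#' @examples
#' p <- force_params("cubic", mu = 5.7)
#' rel <- pairwise_relaxation(p, scheme = "reference")
#' tail(rel, 1) # separation ~ 0.99 at 1 h
#' @export
pairwise_relaxation <- function(params, scheme = "reference", dt = NULL,
                                t_end = 1, r0 = 0.3, ...) {
  sim <- simulate_population(two_cell_population(r0), params,
    t_end = t_end, scheme = scheme, dt = dt, ...
  )
  separation_series(sim)
}

#' Relaxation of adhering cells
#'
#' Two cells are placed at a separation at or beyond the rest length and
#' pulled together by the adhesive branch of the force law. At and beyond
#' the interaction cutoff the pair is stationary. Separations below the
#' rest length are rejected — that is the repulsive post-division scenario,
#' handled by [pairwise_relaxation()].
#'
#' @inheritParams pairwise_relaxation
#' @param r_init Initial separation, `>= ` rest length.
#' @param t_end End time, default 3 h (long enough for adhesive contact at
#'   the calibrated stiffnesses).
#' @return A tibble with columns `time` and `separation`.
#' @export
adhering_cells <- function(params, r_init, scheme = "reference", dt = NULL,
                           t_end = 3, ...) {
  if (r_init < params$s) {
    abort("adhering_cells() expects r_init >= rest length")
  }
  sim <- simulate_population(two_cell_population(r_init), params,
    t_end = t_end, scheme = scheme, dt = dt, ...
  )
  separation_series(sim)
}

separation_series <- function(sim) {
  stopifnot(inherits(sim, "cell_trajectory"), length(sim$segments) == 1)
  traj <- sim$segments[[1]]$traj
  d <- traj$dim
  stopifnot(ncol(traj$states) == 2 * d)
  diff2 <- (traj$states[, d + seq_len(d), drop = FALSE] -
    traj$states[, seq_len(d), drop = FALSE])^2
  tibble(time = traj$times, separation = sqrt(rowSums(diff2)))
}

#' Proliferating-monolayer relaxation experiment
#'
#' Builds a honeycomb of `n_init` cells at unit spacing, lets every cell
#' divide simultaneously at time zero (doubling the population), relaxes
#' the monolayer to `t_end`, and tracks the population radius. With several
#' seeds the division directions vary while everything else is fixed, so
#' the spread of the radius curves reflects division-geometry stochasticity
#' only.
#'
#' @param n_init Initial cell count; a centred hexagonal number (19 and 37
#'   are the standard sizes).
#' @param params A [force_params()] object.
#' @param t_end End time, default 10 h.
#' @param scheme,dt Solver choice (see [simulate_population()]).
#' @param seeds Integer vector of RNG seeds, one run per seed.
#' @param r0 Daughter separation at division.
#' @param ... Passed to [simulate_population()].
#' @return A `monolayer_result`: tibble of (`seed`, `time`, `radius`) rows
#'   with the final populations in `attr(, "final")`; [glance()] summarises
#'   per-seed endpoints, [autoplot()] shows mean and spread.
#' @export
monolayer_experiment <- function(n_init, params, t_end = 10,
                                 scheme = "reference", dt = NULL,
                                 seeds = 1, r0 = 0.3, ...) {
  pop0 <- honeycomb_population(n_init)
  events <- tibble(time = 0, cell_id = pop0$cell_id)
  runs <- purrr::map(seeds, function(sd) {
    sim <- simulate_population(pop0, params,
      t_end = t_end, scheme = scheme,
      dt = dt, events = events, r0 = r0, seed = sd, ...
    )
    list(radius = mutate(radius_series(sim), seed = sd, .before = 1),
         final = final_population(sim))
  })
  out <- bind_rows(purrr::map(runs, "radius"))
  structure(out,
    class = c("monolayer_result", class(out)),
    final = purrr::map(runs, "final"),
    n_init = n_init, law = params$law,
    initial_radius = population_radius(pop0)
  )
}

#' @export
glance.monolayer_result <- function(x, ...) {
  df <- as_tibble(x)
  df |>
    group_by(.data$seed) |>
    summarise(
      final_radius = .data$radius[which.max(.data$time)],
      min_radius = min(.data$radius),
      max_radius = max(.data$radius),
      .groups = "drop"
    ) |>
    mutate(
      n_init = attr(x, "n_init"),
      law = attr(x, "law"),
      initial_radius = attr(x, "initial_radius")
    )
}

#' Mean and spread of a monolayer radius ensemble
#'
#' @param x A `monolayer_result`.
#' @return A tibble of per-time `mean_radius` and `sd_radius` over seeds.
#' @export
summarise_radius <- function(x) {
  stopifnot(inherits(x, "monolayer_result"))
  as_tibble(x) |>
    group_by(.data$time) |>
    summarise(
      mean_radius = mean(.data$radius),
      sd_radius = sd(.data$radius),
      .groups = "drop"
    )
}

as_plain_trajectory <- function(x) {
  if (inherits(x, "cell_trajectory")) {
    if (length(x$segments) != 1) {
      abort("space-time error norms are defined for single-segment trajectories")
    }
    x$segments[[1]]$traj
  } else if (inherits(x, "trajectory")) {
    x
  } else {
    abort("expected a trajectory or single-segment cell_trajectory")
  }
}

#' Relative space-time error between two trajectories
#'
#' Linearly interpolates the coarser solution onto the reference time grid
#' (per state coordinate, over the common time span) and returns
#' `||y - y_ref||_2 / ||y_ref||_2` taken over the full space-time vector.
#' Both trajectories must describe the same state layout (same cell count
#' and flattening order).
#'
#' @param traj,ref Trajectories ([new_trajectory()] or single-segment
#'   results of [simulate_population()]); `ref` supplies the fine grid.
#' @return A non-negative scalar.
#' @export
relative_error <- function(traj, ref) {
  traj <- as_plain_trajectory(traj)
  ref <- as_plain_trajectory(ref)
  if (ncol(traj$states) != ncol(ref$states)) {
    abort("trajectories have different state dimensions")
  }
  lo <- max(min(traj$times), min(ref$times))
  hi <- min(max(traj$times), max(ref$times))
  if (hi <= lo) abort("trajectories have no overlapping time span")
  keep <- ref$times >= lo - 1e-12 & ref$times <= hi + 1e-12
  tt <- ref$times[keep]
  y_ref <- ref$states[keep, , drop = FALSE]
  y_int <- vapply(seq_len(ncol(traj$states)), function(k) {
    approx(traj$times, traj$states[, k], xout = tt, rule = 2)$y
  }, numeric(length(tt)))
  sqrt(sum((y_int - y_ref)^2)) / sqrt(sum(y_ref^2))
}

#' Empirical convergence study
#'
#' Measures the relative space-time error of a fixed-step scheme against a
#' fine-step run of the same scheme on one of the standard model problems,
#' over a list of step sizes, and fits the empirical convergence order as
#' the log-log slope over the asymptotic regime (the four smallest step
#' sizes with finite error; larger steps may be pre-asymptotic or
#' unstable). Runs that blow up are recorded as missing, not as failures.
#'
#' The model problems: `"pairwise_repulsive"` — post-division relaxation
#' from separation `r0` to `t_end = 1` h; `"pairwise_adhesive"` — adhering
#' pair from `r_init = 1.15` to 3 h; `"monolayer19"` / `"monolayer37"` —
#' honeycombs whose cells all divide at time zero, to 4 h, with one fixed
#' seed shared by every step size and the reference so the division
#' geometry is identical across runs.
#'
#' @param problem One of `"pairwise_repulsive"`, `"pairwise_adhesive"`,
#'   `"monolayer19"`, `"monolayer37"`.
#' @param params A [force_params()] object.
#' @param scheme `"euler"`, `"midpoint"` or `"ab2"`.
#' @param dt_list Step sizes to evaluate (should be well above `dt_ref`).
#' @param dt_ref Reference step size; defaults per problem to `1e-5`
#'   (repulsive), `1e-4` (adhesive) and `5e-4` (monolayers).
#' @param seed Seed fixing the monolayer division geometry.
#' @param t_end Optional override of the problem's default horizon.
#' @param r0,r_init Initial separations of the pairwise problems.
#' @return A `convergence_result` tibble (`dt`, `rel_error`) with the
#'   fitted order in `attr(, "fitted_order")`; see [glance()] and
#'   [autoplot()].
#' @export
convergence_study <- function(problem = c(
                                "pairwise_repulsive", "pairwise_adhesive",
                                "monolayer19", "monolayer37"
                              ),
                              params, scheme = c("euler", "midpoint", "ab2"),
                              dt_list, dt_ref = NULL, seed = 1,
                              t_end = NULL, r0 = 0.3, r_init = 1.15) {
  problem <- match.arg(problem)
  scheme <- match.arg(scheme)
  defaults <- list(
    pairwise_repulsive = c(t_end = 1, dt_ref = 1e-5),
    pairwise_adhesive = c(t_end = 3, dt_ref = 1e-4),
    monolayer19 = c(t_end = 4, dt_ref = 5e-4),
    monolayer37 = c(t_end = 4, dt_ref = 5e-4)
  )[[problem]]
  if (is.null(t_end)) t_end <- defaults[["t_end"]]
  if (is.null(dt_ref)) dt_ref <- defaults[["dt_ref"]]
  stopifnot(all(dt_list > dt_ref))

  run <- function(step) {
    switch(problem,
      pairwise_repulsive = simulate_population(
        two_cell_population(r0), params,
        t_end = t_end, scheme = scheme, dt = step
      ),
      pairwise_adhesive = simulate_population(
        two_cell_population(r_init), params,
        t_end = t_end, scheme = scheme, dt = step
      ),
      {
        n_init <- if (problem == "monolayer19") 19 else 37
        pop0 <- honeycomb_population(n_init)
        simulate_population(pop0, params,
          t_end = t_end, scheme = scheme,
          dt = step, events = tibble(time = 0, cell_id = pop0$cell_id),
          seed = seed
        )
      }
    )
  }

  ref <- run(dt_ref)
  errs <- purrr::map_dbl(dt_list, function(step) {
    tryCatch(relative_error(run(step), ref), error = function(e) NA_real_)
  })
  out <- tibble(dt = dt_list, rel_error = errs)
  structure(out,
    class = c("convergence_result", class(out)),
    fitted_order = fit_order(out),
    problem = problem, scheme = scheme, dt_ref = dt_ref
  )
}

fit_order <- function(df, n_points = 4) {
  ok <- is.finite(df$rel_error) & df$rel_error > 0
  df <- df[ok, ]
  df <- df[order(df$dt), ]
  df <- head(df, n_points)
  if (nrow(df) < 2) {
    return(NA_real_)
  }
  unname(coef(lm(log(rel_error) ~ log(dt), data = df))[2])
}

#' @export
glance.convergence_result <- function(x, ...) {
  tibble(
    problem = attr(x, "problem"),
    scheme = attr(x, "scheme"),
    dt_ref = attr(x, "dt_ref"),
    fitted_order = attr(x, "fitted_order"),
    n_stable = sum(is.finite(x$rel_error))
  )
}
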