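#' Cell population state
#'
#' A cell population is a tibble with one row per cell — columns `cell_id`,
#' the midpoint coordinates (`x`, `y` and, in 3D, `z`) and `radius` — carrying
#' the spatial dimension and the drag coefficient `eta` as attributes. In the
#' overdamped (inertialess) regime each cell's velocity equals the net
#' pairwise force on it divided by `eta`; since `eta` only rescales time it
#' defaults to 1.
#'
#' @param cells A data frame with columns `cell_id`, `x`, `y` (and `z` for
#'   `dim = 3`) and `radius`.
#' @param dim Spatial dimension, 2 (default) or 3.
#' @param eta Drag coefficient, positive.
#' @return A `cell_population` (a tibble subclass).
#' @examples
#' cell_population(data.frame(cell_id = 1:2, x = c(0, 0.3), y = 0, radius = 0.5))
#' @export
cell_population <- function(cells, dim = 2, eta = 1) {
  stopifnot(dim %in% c(2, 3), eta > 0)
  coords <- c("x", "y", "z")[seq_len(dim)]
  need <- c("cell_id", coords, "radius")
  if (!all(need %in% names(cells))) {
    abort(paste0(
      "population needs columns: ", paste(need, collapse = ", ")
    ))
  }
  cells <- as_tibble(cells)[, need]
  if (anyDuplicated(cells$cell_id)) abort("cell ids must be unique")
  if (any(cells$radius <= 0)) abort("cell radii must be positive")
  structure(cells,
    class = c("cell_population", class(tibble())),
    dimension = dim, eta = eta
  )
}

#' Two overlapping daughter cells on the x-axis
#'
#' The canonical pairwise fixture: two cells of radius `radius` placed
#' symmetrically about the origin at centre-centre separation `r0`, the state
#' of a mother cell immediately after instantaneous division.
#'
#' @param r0 Initial separation (cell diameters); the post-division default
#'   is 0.3.
#' @param radius Cell radius, default 0.5.
#' @param dim Spatial dimension.
#' @param eta Drag coefficient.
#' @return A [cell_population()] of two cells.
#' @export
two_cell_population <- function(r0 = 0.3, radius = 0.5, dim = 2, eta = 1) {
  stopifnot(r0 > 0)
  df <- data.frame(
    cell_id = 1:2, x = c(-r0 / 2, r0 / 2), y = 0, z = 0, radius = radius
  )
  cell_population(df[, c("cell_id", c("x", "y", "z")[seq_len(dim)], "radius")],
    dim = dim, eta = eta
  )
}

pop_dim <- function(pop) attr(pop, "dimension") %||% 2
pop_eta <- function(pop) attr(pop, "eta") %||% 1
`%||%` <- function(a, b) if (is.null(a)) b else a

pop_positions <- function(pop) {
  coords <- c("x", "y", "z")[seq_len(pop_dim(pop))]
  as.matrix(as.data.frame(pop)[, coords])
}

# net pairwise force on every cell; all-pairs scan with the r_A cutoff.
# Deliberately O(K^2): neighbourhood acceleration structures change per-step
# cost, not step counts, and are out of scope.
force_matrix_impl <- function(P, fn, cutoff) {
  K <- nrow(P)
  d <- ncol(P)
  out <- matrix(0, K, d)
  if (K < 2) {
    return(out)
  }
  D <- lapply(seq_len(d), function(k) {
    matrix(P[, k], K, K, byrow = TRUE) - matrix(P[, k], K, K)
  })
  dist2 <- D[[1]]^2
  for (k in seq_len(d)[-1]) dist2 <- dist2 + D[[k]]^2
  dist <- sqrt(dist2)
  diag(dist) <- Inf
  if (any(dist < 1e-9)) {
    idx <- which(dist < 1e-9, arr.ind = TRUE)[1, ]
    abort(paste0(
      "coincident cell midpoints (rows ", idx[1], " and ", idx[2], ")"
    ))
  }
  within <- which(dist < cutoff)
  if (!length(within)) {
    return(out)
  }
  scale <- matrix(0, K, K)
  scale[within] <- fn(dist[within]) / dist[within]
  for (k in seq_len(d)) {
    out[, k] <- rowSums(scale * D[[k]])
  }
  out
}

force_cutoff <- function(params) {
  if (params$law == "hertz") params$s else params$r_A
}

force_matrix <- function(P, params) {
  force_matrix_impl(P, force_fun(params), force_cutoff(params))
}

#' Net pairwise force on every cell
#'
#' Sums the pairwise interaction force over all cell pairs closer than the
#' maximum interaction distance (a plain all-pairs scan). By symmetry of the
#' pairwise law the per-axis force components sum to zero over the
#' population.
#'
#' @param pop A [cell_population()].
#' @param params A [force_params()] object.
#' @return A tibble with `cell_id` and force components `fx`, `fy` (and
#'   `fz` in 3D), in cell diameters per hour (with `eta = 1`).
#' @export
total_forces <- function(pop, params) {
  Fm <- force_matrix(pop_positions(pop), params)
  coords <- paste0("f", c("x", "y", "z")[seq_len(pop_dim(pop))])
  out <- tibble(cell_id = pop$cell_id)
  for (k in seq_along(coords)) out[[coords[k]]] <- Fm[, k]
  out
}

#' Overdamped equations of motion as a flat right-hand side
#'
#' Builds `f(t, y)` for the first-order system `dx_i/dt = (1/eta) * sum_j
#' F_ij`, with positions flattened cell-id-major, coordinate-minor
#' (`x_1, y_1, x_2, y_2, ...`). The cell count and layout are frozen at call
#' time; the event-driven loop rebuilds the right-hand side after each
#' division.
#'
#' @inheritParams total_forces
#' @return A function `(t, y) -> dy/dt` suitable for [solve_fixed()] and
#'   [solve_reference()].
#' @export
population_rhs <- function(pop, params) {
  d <- pop_dim(pop)
  K <- nrow(pop)
  eta <- pop_eta(pop)
  fn <- force_fun(params)
  cutoff <- force_cutoff(params)
  function(t, y) {
    P <- matrix(y, nrow = K, ncol = d, byrow = TRUE)
    as.vector(t(force_matrix_impl(P, fn, cutoff))) / eta
  }
}

flatten_positions <- function(pop) as.vector(t(pop_positions(pop)))

set_positions <- function(pop, y) {
  d <- pop_dim(pop)
  P <- matrix(y, ncol = d, byrow = TRUE)
  coords <- c("x", "y", "z")[seq_len(d)]
  for (k in seq_len(d)) pop[[coords[k]]] <- P[, k]
  pop
}

#' Instantaneous cell division
#'
#' Replaces the mother cell by two daughters of the same radius placed
#' symmetrically about the mother's midpoint at separation `r0`, along a
#' uniformly random direction (2D: a uniform angle; 3D: a uniform point on
#' the sphere). One draw is consumed from R's RNG per division, so runs are
#' reproducible given a seed and the event order. The daughter on the
#' negative side of the division axis keeps the mother's id (so trajectories
#' remain joinable across the event); the other daughter receives the
#' smallest unused id.
#'
#' @param pop A [cell_population()].
#' @param cell_id Id of the dividing cell.
#' @param r0 Initial daughter separation, `0 < r0 < ` rest length; the
#'   default 0.3 is the standard post-division overlap.
#' @return The updated population (one cell more).
#' @export
divide_cell <- function(pop, cell_id, r0 = 0.3) {
  i <- match(cell_id, pop$cell_id)
  if (is.na(i)) abort(paste0("no cell with id ", cell_id))
  stopifnot(r0 > 0)
  d <- pop_dim(pop)
  u <- if (d == 2) {
    th <- runif(1, 0, 2 * pi)
    c(cos(th), sin(th))
  } else {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  coords <- c("x", "y", "z")[seq_len(d)]
  centre <- as.numeric(pop[i, coords])
  new_id <- max(pop$cell_id) + 1L
  daughter <- pop[i, ]
  daughter$cell_id <- new_id
  pop[i, coords] <- as.list(centre - (r0 / 2) * u)
  daughter[, coords] <- as.list(centre + (r0 / 2) * u)
  out <- bind_rows(pop, daughter)
  cell_population(out, dim = d, eta = pop_eta(pop))
}

#' Population radius
#'
#' The single-cell radius plus the maximum distance of any cell midpoint
#' from the population centroid — the population-level summary used to
#' compare force laws on growing monolayers. Invariant under cell
#' relabelling.
#'
#' @param pop A [cell_population()].
#' @param R Single-cell radius added to the maximal centroid distance;
#'   defaults to the first cell's radius.
#' @return A scalar radius in cell diameters.
#' @export
population_radius <- function(pop, R = NULL) {
  if (nrow(pop) == 0) abort("population is empty")
  if (is.null(R)) R <- pop$radius[1]
  P <- pop_positions(pop)
  centroid <- colMeans(P)
  R + sqrt(max(rowSums(sweep(P, 2, centroid)^2)))
}

#' Event-driven simulation of a cell population
#'
#' Integrates the overdamped mechanics piecewise between scheduled division
#' events: the system is solved up to the next event time, all divisions
#' scheduled there are applied atomically (in ascending cell-id order, each
#' consuming one RNG draw for its direction), and integration continues with
#' the enlarged system. The trajectory is returned as per-epoch segments
#' since the state dimension changes at events; Adams-Bashforth re-bootstraps
#' after every event for the same reason.
#'
#' @param pop Initial [cell_population()].
#' @param params A [force_params()] object.
#' @param t_end End time (hours).
#' @param scheme `"euler"`, `"midpoint"`, `"ab2"` (fixed-step, require `dt`)
#'   or `"reference"` (adaptive high-accuracy solve).
#' @param dt Step size for the fixed-step schemes.
#' @param events Data frame of division events with columns `time` and
#'   `cell_id`; event times must lie in `[t_start, t_end]`. Events at
#'   `t_start` are applied before any integration (the standard
#'   all-divide-at-the-start setup).
#' @param r0 Daughter separation passed to [divide_cell()].
#' @param seed Optional integer seed fixing the division directions.
#' @param t_start Start time, default 0.
#' @param dense_n Output points per unit time for the reference scheme.
#' @param rtol,atol Reference-solver tolerances.
#' @return A `cell_trajectory`: per-epoch segments plus the final
#'   population; see [as_tibble()], [radius_series()], [final_population()].
#' @examples
#' pop <- two_cell_population(r0 = 0.3)
#' p <- force_params("cubic", mu = 5.7)
#' sim <- simulate_population(pop, p, t_end = 1, scheme = "reference")
#' population_radius(final_population(sim))
#' @export
simulate_population <- function(pop, params, t_end,
                                scheme = c("euler", "midpoint", "ab2", "reference"),
                                dt = NULL, events = NULL, r0 = 0.3,
                                seed = NULL, t_start = 0,
                                dense_n = 100, rtol = 1e-9, atol = 1e-12) {
  scheme <- match.arg(scheme)
  if (scheme != "reference" && is.null(dt)) {
    abort("fixed-step schemes require `dt`")
  }
  if (!is.null(seed)) set.seed(seed)
  stopifnot(t_end > t_start)
  if (!is.null(events)) {
    events <- as_tibble(events)
    stopifnot(all(c("time", "cell_id") %in% names(events)))
    if (any(events$time < t_start) || any(events$time > t_end)) {
      abort("event times must lie within [t_start, t_end]")
    }
    events <- arrange(events, .data$time, .data$cell_id)
  }
  event_times <- if (is.null(events)) numeric(0) else unique(events$time)

  apply_events_at <- function(pop, te) {
    ids <- sort(events$cell_id[events$time == te])
    for (id in ids) pop <- divide_cell(pop, id, r0 = r0)
    pop
  }

  segments <- list()
  t_now <- t_start
  if (length(event_times) && event_times[1] == t_start) {
    pop <- apply_events_at(pop, t_start)
    event_times <- event_times[-1]
  }
  for (te in sort(unique(c(event_times, t_end)))) {
    if (te > t_now) {
      f <- population_rhs(pop, params)
      y0 <- flatten_positions(pop)
      traj <- if (scheme == "reference") {
        n_out <- max(2, ceiling((te - t_now) * dense_n) + 1)
        solve_reference(f, y0, c(t_now, te),
          dense_times = seq(t_now, te, length.out = n_out),
          rtol = rtol, atol = atol
        )
      } else {
        solve_fixed(f, y0, c(t_now, te), dt = dt, scheme = scheme)
      }
      traj$cell_ids <- pop$cell_id
      traj$dim <- pop_dim(pop)
      segments[[length(segments) + 1]] <- list(
        traj = traj,
        cells = tibble(cell_id = pop$cell_id, radius = pop$radius)
      )
      pop <- set_positions(pop, traj$states[nrow(traj$states), ])
      t_now <- te
    }
    if (te %in% event_times) pop <- apply_events_at(pop, te)
  }
  structure(
    list(
      segments = segments, final = pop, params = params,
      scheme = scheme, dt = dt
    ),
    class = "cell_trajectory"
  )
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(
    "<cell_trajectory> ", length(x$segments), " segment(s), final population ",
    nrow(x$final), " cells, t in [",
    format(x$segments[[1]]$traj$times[1]), ", ",
    format(max(tail(x$segments, 1)[[1]]$traj$times)), "]\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.cell_trajectory <- function(x, ...) {
  bind_rows(purrr::map(seq_along(x$segments), function(i) {
    df <- as_tibble(x$segments[[i]]$traj)
    df$segment <- i
    df
  }))
}

#' Final population snapshot of a simulation
#'
#' @param sim A `cell_trajectory` from [simulate_population()].
#' @return The [cell_population()] at the end time.
#' @export
final_population <- function(sim) {
  stopifnot(inherits(sim, "cell_trajectory"))
  sim$final
}

#' Population radius over time
#'
#' Evaluates [population_radius()] at every stored time point of a
#' simulation, across division events.
#'
#' @param sim A `cell_trajectory` from [simulate_population()].
#' @return A tibble with columns `time` and `radius`.
#' @export
radius_series <- function(sim) {
  stopifnot(inherits(sim, "cell_trajectory"))
  bind_rows(purrr::map(sim$segments, function(seg) {
    traj <- seg$traj
    d <- traj$dim
    R <- seg$cells$radius[1]
    radius <- apply(traj$states, 1, function(y) {
      P <- matrix(y, ncol = d, byrow = TRUE)
      centroid <- colMeans(P)
      R + sqrt(max(rowSums(sweep(P, 2, centroid)^2)))
    })
    tibble(time = traj$times, radius = radius)
  }))
}

#' Population and event-list CSV I/O
#'
#' Snapshots are written as plain CSV (`cell_id`, coordinates, `radius`);
#' event lists as (`time`, `cell_id`); trajectories in long, deterministic
#' row order (time-major, cell-id-minor).
#'
#' @param pop,events,sim Objects to write.
#' @param path File path.
#' @param dim,eta Population attributes to attach on read.
#' @return Readers return the parsed object; writers return the first
#'   argument invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(pop)
}

#' @rdname write_population
#' @export
read_population <- function(path, dim = 2, eta = 1) {
  cell_population(utils::read.csv(path), dim = dim, eta = eta)
}

#' @rdname write_population
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("time", "cell_id")], path,
    row.names = FALSE
  )
  invisible(events)
}

#' @rdname write_population
#' @export
read_events <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' @rdname write_population
#' @export
write_trajectory <- function(sim, path) {
  df <- as_tibble(sim)
  df <- arrange(df, .data$segment, .data$time, .data$cell_id)
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(sim)
}
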