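#' Scalar ODE for a mechanically relaxing cell pair
#'
#' For two interacting cells the centre-centre separation obeys
#' `dr/dt = -2 F(r)` (with drag 1): each cell moves with velocity `F` along
#' the pair axis, in opposite directions. This reduction is what makes
#' pairwise calibration and the closed-form step bounds tractable.
#'
#' @param params A [force_params()] object.
#' @return A function `(t, r) -> dr/dt`, vectorised in `r`.
#' @export
pairwise_ode <- function(params) {
  force(params)
  function(t, r) -2 * force_eval(params, r)
}

#' Separation of a relaxing pair at a given time
#'
#' High-accuracy solve of the pairwise separation ODE from `r0`; used inside
#' the calibration objective and the forward checks.
#' @noRd
pairwise_r_at <- function(params, t, r0 = 0.3) {
  traj <- solve_reference(pairwise_ode(params), r0, c(0, t),
    dense_times = c(0, t)
  )
  unname(traj$states[nrow(traj$states), 1])
}

#' Maximum repulsive interaction distance of the piecewise quadratic law
#'
#' Requiring the piecewise quadratic force to vanish at the rest length
#' fixes the repulsive cutoff as
#' `r_R = s / (1 - sqrt(m) * (1 - s / r_A))`, where `m = mu_A / mu_R` is the
#' adhesive-to-repulsive stiffness ratio.
#'
#' @param s Rest length.
#' @param r_A Maximum (adhesive) interaction distance.
#' @param m Stiffness ratio in `[0, 1]`.
#' @return `r_R` in cell diameters.
#' @examples
#' r_R_from_ratio(1, 1.5, 0.21) # 1.18 to two decimals
#' @export
r_R_from_ratio <- function(s, r_A, m) {
  stopifnot(s > 0, r_A > s, m >= 0, m <= 1)
  den <- 1 - sqrt(m) * (1 - s / r_A)
  if (den <= 0) abort("invalid ratio: denominator of r_R is non-positive")
  s / den
}

#' Breadth of the gls exponential from a small-jump condition
#'
#' Choosing `alpha` so that the gls adhesive branch equals `eps` at the
#' cutoff bounds the force discontinuity there by `eps`:
#' `alpha = -log(eps / (mu * (r_A - s))) / (r_A - s)`. This is the
#' smoothness-preserving strategy for selecting `alpha` (as opposed to
#' shape-fitting the adhesive branch against another law, which can leave an
#' O(1e-2) jump and costs higher-order integrators their convergence order).
#'
#' @param mu Gls spring stiffness.
#' @param s Rest length.
#' @param r_A Maximum interaction distance.
#' @param eps Target force magnitude at the cutoff; default `1e-3`.
#' @return The decay parameter `alpha`.
#' @examples
#' alpha_small_jump(1.95, 1, 1.5) # 13.76 to two decimals
#' @export
alpha_small_jump <- function(mu, s, r_A, eps = 1e-3) {
  stopifnot(r_A > s, eps > 0)
  if (mu * (r_A - s) <= eps) {
    abort("need mu * (r_A - s) > eps for a positive alpha")
  }
  -log(eps / (mu * (r_A - s))) / (r_A - s)
}

round_tab <- function(x, digits) round(x, digits)

#' Calibrate a force law to a pairwise relaxation time
#'
#' Fits the free stiffness parameter(s) of a law so that two post-division
#' cells, starting at separation `r0`, reach `fraction` of the rest length
#' at the target relaxation time `t0`. The separation ODE is integrated with
#' the high-accuracy reference solver inside the objective.
#'
#' * cubic and gls: a bracketed 1-D root solve on
#'   the residual of the separation at `t0` against `fraction * s`
#'   (monotone in `mu`).
#'   For gls only the repulsive branch is active during relaxation, so
#'   `alpha` does not enter the fit; it is chosen afterwards by
#'   `alpha_strategy`.
#' * pwq: a Nelder-Mead minimisation of the absolute residual jointly over
#'   `(mu_R, m)` from the initial guess `(10, 0.2)`. The residual's zero set
#'   is a one-dimensional manifold, so the returned point depends on the
#'   starting guess; downstream checks should therefore be stated on the
#'   consequence (the relaxation time) rather than the raw parameters.
#'
#' Fitted stiffnesses are rounded to 2 decimals (the ratio `m` to 3) before
#' being used downstream; parameters derived from them (`mu_A`, `r_R`,
#' `alpha`) are computed from the rounded inputs but carried at full
#' precision.
#'
#' @param law `"cubic"`, `"gls"` or `"pwq"`.
#' @param t0 Target relaxation time (hours), default 1.
#' @param r0 Post-division separation, default 0.3 cell diameters.
#' @param fraction Fraction of the rest length defining "relaxed",
#'   default 0.99.
#' @param s,r_A Fixed geometry (rest length, interaction cutoff).
#' @param alpha_strategy For gls: `"small_jump"` (default; see
#'   [alpha_small_jump()], bound `eps_jump`) or `"shape_fit"` (fit the
#'   adhesive branch magnitude to `shape_target`, see [fit_force_shape()]).
#' @param eps_jump Jump bound for the small-jump strategy.
#' @param shape_target Target [force_params()] for the shape-fit strategy.
#' @param mu_bracket Search bracket for the 1-D root solve.
#' @return A `relaxation_fit` object: the calibrated `$params`
#'   ([force_params()]), the unrounded optimum, and the achieved residual.
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' \donttest{
#' fit <- fit_relaxation_time("cubic", t0 = 1)
#' tidy(fit)
#' }
#' @export
fit_relaxation_time <- function(law = c("cubic", "gls", "pwq"),
                                t0 = 1, r0 = 0.3, fraction = 0.99,
                                s = 1, r_A = s + 0.5,
                                alpha_strategy = c("small_jump", "shape_fit"),
                                eps_jump = 1e-3, shape_target = NULL,
                                mu_bracket = c(0.05, 100)) {
  law <- match.arg(law)
  alpha_strategy <- match.arg(alpha_strategy)
  stopifnot(t0 > 0, r0 > 0, r0 < s, fraction > 0, fraction < 1)
  target <- fraction * s

  make_params <- function(theta) {
    switch(law,
      cubic = force_params("cubic", mu = theta, s = s, r_A = r_A),
      # alpha is irrelevant during relaxation (r < s); any valid value works
      gls = force_params("gls", mu = theta, s = s, r_A = r_A, alpha = 10),
      pwq = force_params("pwq", mu_R = theta[1], m = theta[2], s = s, r_A = r_A)
    )
  }
  residual <- function(theta) {
    pairwise_r_at(make_params(theta), t0, r0) - target
  }

  if (law %in% c("cubic", "gls")) {
    root <- uniroot(residual, mu_bracket, tol = 1e-8)
    est_raw <- root$root
    est <- round_tab(est_raw, 2)
    resid <- residual(est_raw)
    estimates <- setNames(est, "mu")
    raw <- setNames(est_raw, "mu")
  } else {
    opt <- optim(c(10, 0.2), function(th) {
      if (th[1] <= 0 || th[2] <= 0 || th[2] >= 1) {
        return(1e6)
      }
      abs(residual(th))
    }, method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 500))
    if (opt$value > 1e-4) {
      abort(paste0(
        "pwq relaxation fit did not converge (residual ",
        format(opt$value), ")"
      ))
    }
    est_raw <- opt$par
    est <- c(round_tab(est_raw[1], 2), round_tab(est_raw[2], 3))
    resid <- opt$value
    estimates <- setNames(est, c("mu_R", "m"))
    raw <- setNames(est_raw, c("mu_R", "m"))
  }

  params <- switch(law,
    cubic = force_params("cubic", mu = estimates[["mu"]], s = s, r_A = r_A),
    gls = {
      mu <- estimates[["mu"]]
      alpha <- if (alpha_strategy == "small_jump") {
        alpha_small_jump(mu, s, r_A, eps = eps_jump)
      } else {
        if (is.null(shape_target)) {
          abort("alpha_strategy = 'shape_fit' needs a `shape_target` law")
        }
        sf <- fit_force_shape(shape_target,
          law = "gls", r_range = c(s, r_A),
          free = "alpha", fixed = list(mu = mu, s = s, r_A = r_A)
        )
        sf$params$alpha
      }
      force_params("gls", mu = mu, s = s, r_A = r_A, alpha = alpha)
    },
    pwq = force_params("pwq",
      mu_R = estimates[["mu_R"]], m = estimates[["m"]],
      s = s, r_A = r_A
    )
  )

  structure(
    list(
      params = params, law = law, estimates = estimates, raw = raw,
      residual = resid, t0 = t0, r0 = r0, fraction = fraction
    ),
    class = "relaxation_fit"
  )
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat("<relaxation_fit> law:", x$law, " t0 =", x$t0, "h\n")
  cat(
    "  ", paste0(names(x$estimates), " = ", x$estimates, collapse = ", "),
    " (residual ", format(x$residual, digits = 3), ")\n"
  )
  invisible(x)
}

#' @export
tidy.relaxation_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    unrounded = unname(x$raw)
  )
}

#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble(
    law = x$law, t0 = x$t0, r0 = x$r0, fraction = x$fraction,
    residual = x$residual
  )
}

#' Fit one force law's shape to another's
#'
#' Minimises the root-mean-square difference of force magnitudes between a
#' candidate law and a target law over a separation interval, on a grid of
#' 200 uniformly spaced points (the discretisation is a package choice; the
#' resulting parameters are only meaningful to within a few percent). Used
#' e.g. to pick the gls breadth `alpha` by matching the cubic law over the
#' adhesive range.
#'
#' @param target Target [force_params()] whose magnitude profile is matched.
#' @param law Candidate law (`"gls"` or `"pwq"`).
#' @param r_range Length-2 interval of separations to fit over.
#' @param free Character vector naming the free parameters: for `"gls"` a
#'   subset of `c("mu", "alpha")`; for `"pwq"` it is `c("mu_R", "m")`.
#' @param fixed Named list of the remaining parameters (defaults:
#'   `s = 1`, `r_A = 1.5`, plus any fixed stiffness).
#' @param init Optional named initial guess for the free parameters.
#' @return A `shape_fit` with `$params` (rounded per the 2/3-decimal
#'   convention), `$objective` (achieved RMS) and tidiers.
#' @export
fit_force_shape <- function(target, law = c("gls", "pwq"), r_range,
                            free, fixed = list(), init = NULL) {
  law <- match.arg(law)
  stopifnot(inherits(target, "force_params"), length(r_range) == 2)
  s <- fixed$s %||% target$s
  r_A <- fixed$r_A %||% target$r_A
  grid <- seq(r_range[1], r_range[2], length.out = 200)
  target_mag <- abs(force_eval(target, grid))

  defaults <- list(gls = c(mu = 2, alpha = 10), pwq = c(mu_R = 10, m = 0.2))
  theta0 <- defaults[[law]][free]
  if (!is.null(init)) theta0[names(init)] <- unlist(init)

  build <- function(theta) {
    th <- as.list(theta)
    names(th) <- free
    if (law == "gls") {
      mu <- th$mu %||% fixed$mu
      alpha <- th$alpha %||% fixed$alpha
      if (mu <= 0 || alpha <= 0) {
        return(NULL)
      }
      force_params("gls", mu = mu, s = s, r_A = r_A, alpha = alpha)
    } else {
      if (th$mu_R <= 0 || th$m <= 0 || th$m >= 1) {
        return(NULL)
      }
      force_params("pwq", mu_R = th$mu_R, m = th$m, s = s, r_A = r_A)
    }
  }
  objective <- function(theta) {
    p <- build(theta)
    if (is.null(p)) {
      return(1e6)
    }
    sqrt(mean((abs(force_eval(p, grid)) - target_mag)^2))
  }

  if (length(theta0) == 1) {
    opt <- optimize(function(v) objective(setNames(v, free)),
      interval = c(1e-3, 100)
    )
    est_raw <- setNames(opt$minimum, free)
    value <- opt$objective
  } else {
    opt <- optim(theta0, objective,
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000)
    )
    est_raw <- opt$par
    value <- opt$value
    if (opt$convergence != 0) {
      abort("fit_force_shape(): optimizer did not converge")
    }
  }

  est <- est_raw
  for (nm in names(est)) {
    est[nm] <- round_tab(est[nm], if (nm == "m") 3 else 2)
  }
  params <- build(est)
  structure(
    list(
      params = params, law = law, estimates = est, raw = est_raw,
      objective = value, r_range = r_range, target = target
    ),
    class = "shape_fit"
  )
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(
    "<shape_fit> law:", x$law, " over [", x$r_range[1], ",", x$r_range[2],
    "]\n  ", paste0(names(x$estimates), " = ", x$estimates, collapse = ", "),
    " (rms ", format(x$objective, digits = 3), ")\n"
  )
  invisible(x)
}

#' @export
tidy.shape_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    unrounded = unname(x$raw)
  )
}

#' @export
glance.shape_fit <- function(x, ...) {
  tibble(
    law = x$law, r_lo = x$r_range[1], r_hi = x$r_range[2],
    rms = x$objective
  )
}

#' Monotonicity and stability step-size bounds for forward Euler
#'
#' For two overlapping cells relaxing after division, the forward Euler
#' iteration on the separation is `r_{n+1} = r_n - 2 dt F(r_n)`. Requiring
#' the iterates never to overshoot the rest length gives the monotonicity
#' bound, and requiring the distance-to-rest to contract gives the stability
#' bound:
#' `dt_mono = (r0 - s) / (2 F(r0))` and `dt_stab = (r0 - s) / F(r0)`.
#' Both are positive in the compressed regime (`r0 < s`, where `F(r0) < 0`)
#' and the stability bound is exactly twice the monotonicity bound. Since
#' the force magnitude is largest at the initial overlap, the first step is
#' binding, which is why the bounds depend on `r0` only.
#'
#' Steps below `dt_mono` give monotone, physically sensible division
#' trajectories; between the bounds the pair overshoots into the adhesive
#' regime but still converges; above `dt_stab` the iteration diverges from
#' equilibrium (typically flinging the cells beyond the interaction cutoff).
#'
#' @param params A [force_params()] object.
#' @param r0 Initial separation, strictly below the rest length.
#' @return A `step_bounds` object with `dt_mono` and `dt_stab` (hours);
#'   has a [tidy()] method.
#' @examples
#' step_bounds(force_params("cubic", mu = 5.7), r0 = 0.3)
#' @export
step_bounds <- function(params, r0 = 0.3) {
  stopifnot(inherits(params, "force_params"))
  s <- params$s
  if (r0 <= 0 || r0 >= s) {
    abort("step bounds are defined for the compressed regime 0 < r0 < s")
  }
  F0 <- force_eval(params, r0)
  dt_mono <- (r0 - s) / (2 * F0)
  structure(
    list(law = params$law, r0 = r0, dt_mono = dt_mono, dt_stab = 2 * dt_mono),
    class = "step_bounds"
  )
}

#' @export
print.step_bounds <- function(x, ...) {
  cat(
    "<step_bounds> law:", x$law, " r0 =", x$r0,
    "\n  dt_mono =", format(x$dt_mono, digits = 6),
    " dt_stab =", format(x$dt_stab, digits = 6), "h\n"
  )
  invisible(x)
}

#' @export
tidy.step_bounds <- function(x, ...) {
  tibble(law = x$law, r0 = x$r0, dt_mono = x$dt_mono, dt_stab = x$dt_stab)
}
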