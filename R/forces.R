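#' Pairwise cell-cell interaction force laws
#'
#' Constructs a validated parameter set for one of the scalar pairwise force
#' laws used in centre-based (overlapping spheres) models. All laws share the
#' rest length `s` (the centre-centre distance at which a cell pair is in
#' mechanical equilibrium) and, except for Hertz, a maximum interaction
#' distance `r_A` beyond which the force is identically zero.
#'
#' Available laws, with negative values repulsive and positive adhesive:
#'
#' * `"cubic"`: `mu * (r - r_A)^2 * (r - s)` up to the cutoff — a linear spring
#'   times a quadratic term approximating the contact area (MecaGen's default).
#' * `"pwq"` (piecewise quadratic): sum of an adhesive polynomial
#'   `mu_A * (1 - r/r_A)^2` supported on `(0, r_A]` and a repulsive polynomial
#'   `-mu_R * (1 - r/r_R)^2` supported on `(0, r_R]` (PhysiCell's default
#'   form with quadratic exponents). Requiring the total force to vanish at
#'   the rest length fixes `r_R` as a function of the stiffness ratio
#'   `m = mu_A / mu_R` (see [r_R_from_ratio()]), so the free parameters are
#'   `mu_R` and `m`.
#' * `"gls"` (generalized linear spring): logarithmic repulsion
#'   `mu * log(1 + (r - s))` up to the rest length and exponentially damped
#'   linear adhesion `mu * (r - s) * exp(-alpha * (r - s))` out to `r_A`
#'   (Chaste's default). The adhesive branch is merely cut off at `r_A`,
#'   leaving a jump discontinuity there (see [gls_jump()]).
#' * `"linear"`: `mu * (r - s)` up to the cutoff (discontinuous at `r_A`).
#' * `"hertz"`: `-mu * (s - r)^(3/2)` below the rest length; repulsion only.
#'
#' Lengths are measured in cell diameters and time in hours; with the drag
#' coefficient fixed at 1 the force has units of cell diameters per hour.
#'
#' @param law Force law name; one of `"cubic"`, `"pwq"`, `"gls"`, `"linear"`,
#'   `"hertz"`.
#' @param mu Spring stiffness (cubic, gls, linear, hertz).
#' @param s Rest length in cell diameters. Default 1 (two touching cells of
#'   radius 0.5).
#' @param r_A Maximum interaction distance in cell diameters. Default
#'   `s + 0.5`, i.e. 1.5 for the default rest length, which lets a regular
#'   lattice relax to a honeycomb packing without next-to-nearest-neighbour
#'   interactions at rest.
#' @param mu_R,m Repulsive stiffness and stiffness ratio `mu_A / mu_R`
#'   (piecewise quadratic only). `mu_A = m * mu_R` and `r_R` are derived.
#' @param alpha Breadth of the adhesive exponential (gls only). If omitted it
#'   is chosen by [alpha_small_jump()] with `eps_jump` so that the cutoff
#'   discontinuity is at most `eps_jump`.
#' @param eps_jump Target bound on the gls cutoff jump used when `alpha` is
#'   not given. Default `1e-3`.
#'
#' @return An object of class `force_params`: a named list with `law` and the
#'   law's parameters (including derived `mu_A` and `r_R` for `"pwq"`).
#' @seealso [force_eval()], [force_vector()], [force_profile()], [gls_jump()]
#' @examples
#' cubic <- force_params("cubic", mu = 5.7)
#' force_eval(cubic, 0.3)     # strongly repulsive overlap
#' force_eval(cubic, 1)       # zero at the rest length
#'
#' pwq <- force_params("pwq", mu_R = 9.1, m = 0.21)
#' pwq$r_R                    # derived so that F(s) = 0
#' @export
force_params <- function(law = c("cubic", "pwq", "gls", "linear", "hertz"),
                         mu = NULL, s = 1, r_A = s + 0.5,
                         mu_R = NULL, m = NULL,
                         alpha = NULL, eps_jump = 1e-3) {
  law <- match.arg(law)
  stopifnot(is.numeric(s), length(s) == 1, s > 0)
  if (law != "hertz") {
    stopifnot(is.numeric(r_A), length(r_A) == 1, r_A > s)
  }

  p <- list(law = law, s = s, r_A = r_A)

  if (law == "pwq") {
    if (is.null(mu_R) || is.null(m)) {
      abort("piecewise quadratic law requires `mu_R` and `m`")
    }
    stopifnot(mu_R > 0, m > 0, m < 1)
    p$mu_R <- mu_R
    p$m <- m
    p$mu_A <- m * mu_R
    p$r_R <- r_R_from_ratio(s, r_A, m)
  } else {
    if (is.null(mu) || !is.numeric(mu) || mu <= 0) {
      abort(paste0("law '", law, "' requires a positive stiffness `mu`"))
    }
    p$mu <- mu
    if (law == "gls") {
      p$alpha <- if (is.null(alpha)) {
        alpha_small_jump(mu, s, r_A, eps = eps_jump)
      } else {
        stopifnot(alpha > 0)
        alpha
      }
    }
  }
  structure(p, class = "force_params")
}

#' @export
print.force_params <- function(x, ...) {
  vals <- x[setdiff(names(x), "law")]
  cat("<force_params> law:", x$law, "\n")
  cat(paste0("  ", names(vals), " = ", signif(unlist(vals), 6), collapse = "\n"),
      "\n")
  invisible(x)
}

# shared precondition for all laws
assert_separation <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    abort("separation `r` must be positive and finite")
  }
}

# compile a law into a bare vectorised closure; skips per-call validation so
# the O(K^2) force assembly inside solver steps stays cheap
force_fun <- function(params) {
  s <- params$s
  switch(params$law,
    linear = {
      mu <- params$mu
      r_A <- params$r_A
      function(r) {
        f <- mu * (r - s)
        f[r > r_A] <- 0
        f
      }
    },
    hertz = {
      mu <- params$mu
      function(r) {
        f <- numeric(length(r))
        i <- r <= s
        f[i] <- -mu * (s - r[i])^1.5
        f
      }
    },
    cubic = {
      mu <- params$mu
      r_A <- params$r_A
      function(r) {
        f <- mu * (r - r_A)^2 * (r - s)
        f[r > r_A] <- 0
        f
      }
    },
    pwq = {
      mu_A <- params$mu_A
      mu_R <- params$mu_R
      r_A <- params$r_A
      r_R <- params$r_R
      function(r) {
        f <- mu_A * (1 - r / r_A)^2
        f[r > r_A] <- 0
        i <- r <= r_R
        f[i] <- f[i] - mu_R * (1 - r[i] / r_R)^2
        f
      }
    },
    gls = {
      mu <- params$mu
      r_A <- params$r_A
      alpha <- params$alpha
      function(r) {
        if (any(r <= s - 1)) {
          abort("gls force undefined for r <= s - 1 (log argument non-positive)")
        }
        f <- numeric(length(r))
        i <- r <= s
        f[i] <- mu * log(1 + (r[i] - s))
        j <- r > s & r <= r_A
        f[j] <- mu * (r[j] - s) * exp(-alpha * (r[j] - s))
        f
      }
    }
  )
}

#' Evaluate a scalar pairwise force law
#'
#' Returns the signed scalar force `F(r)` for centre-centre separations `r`.
#' Negative values are repulsive (cells pushed apart when overlapping,
#' overlapping), positive values adhesive (between rest length and cutoff),
#' and the force is zero
#' at the rest length and beyond `r_A`. Vectorised over `r`.
#'
#' For the generalized linear spring the adhesive branch applies for
#' separations up to and including `r_A` (the cutoff value itself evaluates
#' the branch, which is
#' where the jump discontinuity sits); separations at or below `s - 1` would make
#' the logarithm's argument non-positive and raise an error, although this
#' cannot occur for positive `r` at the default rest length of 1.
#'
#' @param params A [force_params()] object.
#' @param r Numeric vector of positive separations (cell diameters).
#' @return Numeric vector of forces (cell diameters / hour).
#' @examples
#' p <- force_params("cubic", mu = 5.7)
#' force_eval(p, c(0.3, 1, 1.6))
#' @export
force_eval <- function(params, r) {
  stopifnot(inherits(params, "force_params"))
  assert_separation(r)
  force_fun(params)(r)
}

#' Pairwise force vector between two cell midpoints
#'
#' The scalar law is extended to 2D/3D by scaling the unit vector from cell
#' `i` towards cell `j`: the force on `i` is `F(||x_j - x_i||)` times that
#' unit vector, so the pair exchange is antisymmetric (Newton's third law).
#'
#' @param params A [force_params()] object.
#' @param x_i,x_j Midpoint coordinates of cells `i` and `j` (equal-length
#'   numeric vectors). Coincident midpoints are an error: the division
#'   operator always places daughters at a strictly positive separation, so
#'   coincidence signals a user error rather than a state to resolve with a
#'   random direction.
#' @return Numeric force vector acting on cell `i`.
#' @examples
#' p <- force_params("cubic", mu = 5.7)
#' force_vector(p, c(0, 0), c(0.3, 0))  # pushed away from the overlapping cell
#' @export
force_vector <- function(params, x_i, x_j) {
  stopifnot(length(x_i) == length(x_j))
  d <- x_j - x_i
  r <- sqrt(sum(d^2))
  if (r < 1e-12) {
    abort("coincident cell midpoints: pairwise direction undefined")
  }
  force_eval(params, r) * d / r
}

#' Size of the generalized linear spring's cutoff discontinuity
#'
#' The gls adhesive branch does not decay to zero at the cutoff; it is
#' truncated there, jumping from `mu * (r_A - s) * exp(-alpha * (r_A - s))`
#' to zero. This helper returns that jump size, which governs whether
#' higher-order time integrators retain their convergence order (a jump of
#' order the integrator's local error destroys second-order convergence).
#'
#' @param params A gls [force_params()] object.
#' @return The (positive) jump magnitude at `r_A`.
#' @examples
#' # alpha chosen via the small-jump rule makes the jump equal its target
#' p <- force_params("gls", mu = 1.95, eps_jump = 1e-3)
#' gls_jump(p)
#' @export
gls_jump <- function(params) {
  stopifnot(inherits(params, "force_params"))
  if (params$law != "gls") abort("gls_jump() is defined for the gls law only")
  dr <- params$r_A - params$s
  params$mu * dr * exp(-params$alpha * dr)
}

#' Tabulate a force law over a separation grid
#'
#' Convenience for plotting and fitting: evaluates the law on a grid and
#' returns a tibble, chainable into ggplot2.
#'
#' @param params A [force_params()] object.
#' @param r Separation grid; defaults to 400 points on `(0, r_A + 0.25]`.
#' @return A tibble with columns `r`, `force` and `law`.
#' @export
force_profile <- function(params, r = NULL) {
  stopifnot(inherits(params, "force_params"))
  if (is.null(r)) {
    upper <- if (params$law == "hertz") params$s + 0.5 else params$r_A + 0.25
    r <- seq(0.01, upper, length.out = 400)
  }
  tibble(r = r, force = force_eval(params, r), law = params$law)
}

#' Write / read force-law parameters as a flat JSON config
#'
#' Serialises a [force_params()] object to a flat JSON object (one key per
#' parameter) so runs can be reproduced from plain-text configs.
#'
#' @param params A [force_params()] object.
#' @param path File path.
#' @return `write_force_config()` returns `params` invisibly;
#'   `read_force_config()` returns a validated [force_params()] object.
#' @export
write_force_config <- function(params, path) {
  stopifnot(inherits(params, "force_params"))
  keep <- setdiff(names(params), c("mu_A", "r_R")) # derived; recomputed on read
  jsonlite::write_json(params[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(params)
}

#' @rdname write_force_config
#' @export
read_force_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(force_params, cfg)
}
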