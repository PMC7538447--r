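test_that("accurately solved post-division relaxation reaches 0.99 at one hour", {
  rel <- pairwise_relaxation(calib_cubic(), scheme = "reference")
  expect_equal(rel$separation[nrow(rel)], 0.99, tolerance = 0.005)
  expect_true(all(diff(rel$separation) > -1e-12)) # monotone relaxation
})

test_that("a step far above the stability bound flings the pair apart for good", {
  rel <- pairwise_relaxation(calib_cubic(),
    scheme = "euler", dt = 0.2, t_end = 3
  )
  expect_gt(rel$separation[nrow(rel)], 1.5) # beyond the cutoff: never adheres
  expect_gt(min(tail(rel$separation, 5)), 1.5)
})

test_that("euler converges to the reference trajectory as the step shrinks", {
  ref <- pairwise_relaxation(calib_cubic(), scheme = "reference")
  err_at_end <- function(dt) {
    rel <- pairwise_relaxation(calib_cubic(), scheme = "euler", dt = dt)
    abs(rel$separation[nrow(rel)] - ref$separation[nrow(ref)])
  }
  errs <- vapply(c(0.02, 0.01, 0.005), err_at_end, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("adhering pairs: stationary at the rest length and beyond the cutoff", {
  cub <- calib_cubic()
  at_rest <- adhering_cells(cub, 1.0, t_end = 1)
  expect_equal(at_rest$separation, rep(1, nrow(at_rest)), tolerance = 1e-9)
  beyond <- adhering_cells(cub, 1.6, t_end = 1)
  expect_equal(beyond$separation, rep(1.6, nrow(beyond)), tolerance = 1e-9)
  expect_error(adhering_cells(cub, 0.5), "rest length")
})

test_that("adhesion pulls a pair placed inside the cutoff back to the rest length", {
  a <- adhering_cells(calib_cubic(), 1.15, t_end = 3)
  expect_true(all(diff(a$separation) < 1e-12))
  expect_equal(a$separation[nrow(a)], 1, tolerance = 5e-3)
})

test_that("near the cutoff the two alpha strategies behave qualitatively differently", {
  # shape-fitted breadth: strong enough adhesion to reach contact within ~5 h
  a1 <- adhering_cells(calib_gls(1), 1.49, t_end = 5)
  expect_lt(a1$separation[nrow(a1)], 1.05)
  # small-jump breadth: force ~ 1e-3 near the cutoff, pair barely moves
  a2 <- adhering_cells(calib_gls(2), 1.49, t_end = 5)
  expect_gt(a2$separation[nrow(a2)], 1.4)
})

test_that("relative space-time errors: identity, homogeneity and order-one halving", {
  f <- pairwise_ode(calib_cubic())
  ref <- solve_fixed(f, 0.3, c(0, 1), dt = 1e-4, scheme = "euler")
  expect_equal(relative_error(ref, ref), 0)
  scaled <- new_trajectory(ref$times, ref$states * 1.01)
  expect_equal(relative_error(scaled, ref), 0.01, tolerance = 1e-6)

  e1 <- relative_error(solve_fixed(f, 0.3, c(0, 1), dt = 0.01, scheme = "euler"), ref)
  e2 <- relative_error(solve_fixed(f, 0.3, c(0, 1), dt = 0.005, scheme = "euler"), ref)
  expect_equal(e1 / e2, 2, tolerance = 0.15)

  bad <- new_trajectory(c(0, 1), matrix(0, 2, 3))
  expect_error(relative_error(bad, ref), "dimensions")
})

test_that("a small convergence study recovers first order for euler", {
  cv <- convergence_study("pairwise_repulsive", calib_cubic(), "euler",
    dt_list = c(0.02, 0.01, 0.005, 0.0025), dt_ref = 1e-4
  )
  expect_equal(attr(cv, "fitted_order"), 1, tolerance = 0.2)
  expect_true(all(is.finite(cv$rel_error)))
  g <- glance(cv)
  expect_equal(g$n_stable, 4)
})

test_that("monolayer runs double the population and report a tidy radius ensemble", {
  ml <- monolayer_experiment(19, calib_cubic(),
    t_end = 0.3, scheme = "midpoint", dt = 0.01, seeds = c(1, 2)
  )
  finals <- attr(ml, "final")
  expect_length(finals, 2)
  expect_equal(nrow(finals[[1]]), 38)
  g <- glance(ml)
  expect_equal(nrow(g), 2)
  expect_equal(unique(g$initial_radius), 2.5)
  sm <- summarise_radius(ml)
  expect_true(all(c("time", "mean_radius", "sd_radius") %in% names(sm)))
})

test_that("the radius series is invariant under relabelling the initial cells", {
  pop <- honeycomb_population(7)
  run <- function(p) {
    sim <- simulate_population(p, calib_cubic(),
      t_end = 0.2, scheme = "euler", dt = 0.02,
      events = data.frame(time = 0, cell_id = p$cell_id), seed = 9
    )
    radius_series(sim)$radius
  }
  shuffled <- cell_population(as.data.frame(pop)[c(3, 1, 7, 5, 2, 6, 4), ])
  expect_equal(run(pop), run(shuffled), tolerance = 1e-12)
})

test_that("adhesive-regime errors sit below repulsive-regime errors at matched steps", {
  cub <- calib_cubic()
  dts <- c(0.02, 0.01, 0.005)
  rep_err <- convergence_study("pairwise_repulsive", cub, "euler",
    dt_list = dts, dt_ref = 1e-4
  )$rel_error
  adh_err <- convergence_study("pairwise_adhesive", cub, "euler",
    dt_list = dts, dt_ref = 1e-4
  )$rel_error
  expect_true(all(adh_err < rep_err))
})

test_that("plot builders return ggplot objects without evaluation errors", {
  p <- plot_force_profiles(cubic = calib_cubic(), gls = calib_gls())
  expect_s3_class(p, "ggplot")
  sim <- simulate_population(two_cell_population(0.3), calib_cubic(),
    t_end = 0.2, scheme = "euler", dt = 0.02
  )
  expect_s3_class(autoplot(sim), "ggplot")
  cv <- convergence_study("pairwise_repulsive", calib_cubic(), "euler",
    dt_list = c(0.02, 0.01), dt_ref = 1e-3
  )
  expect_s3_class(autoplot(cv), "ggplot")
  ml <- monolayer_experiment(19, calib_cubic(),
    t_end = 0.1, scheme = "euler", dt = 0.01, seeds = 1
  )
  expect_s3_class(autoplot(ml), "ggplot")
})
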