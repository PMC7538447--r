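test_that("net forces: single cells, equilibrium pairs, and a collinear triple", {
  cub <- calib_cubic()
  one <- cell_population(data.frame(cell_id = 1, x = 0, y = 0, radius = 0.5))
  expect_equal(unlist(total_forces(one, cub)[, c("fx", "fy")]),
    c(fx = 0, fy = 0))

  pair <- two_cell_population(r0 = 1) # at the rest length
  expect_equal(sum(abs(total_forces(pair, cub)[, c("fx", "fy")])), 0)

  # three cells on a line at spacing 0.3: middle cancels, outers feel both
  trip <- cell_population(data.frame(
    cell_id = 1:3, x = c(0, 0.3, 0.6), y = 0, radius = 0.5
  ))
  Fm <- total_forces(trip, cub)
  f03 <- abs(force_eval(cub, 0.3)) # 5.7456
  f06 <- abs(force_eval(cub, 0.6)) # 5.7 * 0.81 * 0.4
  expect_equal(f06, 1.8468)
  expect_equal(Fm$fx, c(-(f03 + f06), 0, f03 + f06))
  expect_equal(Fm$fy, rep(0, 3))
})

test_that("the flattened rhs reproduces the pair force and conserves momentum", {
  cub <- calib_cubic()
  pair <- two_cell_population(r0 = 0.3)
  f <- population_rhs(pair, cub)
  dy <- f(0, cbmech:::flatten_positions(pair))
  expect_equal(dy, c(-5.7456, 0, 5.7456, 0)) # cells pushed apart
  # per-axis derivative components sum to zero for random populations
  set.seed(11)
  for (i in 1:5) {
    n <- 8
    pop <- cell_population(data.frame(
      cell_id = 1:n, x = runif(n, 0, 3), y = runif(n, 0, 3), radius = 0.5
    ))
    dy <- population_rhs(pop, cub)(0, cbmech:::flatten_positions(pop))
    P <- matrix(dy, ncol = 2, byrow = TRUE)
    expect_equal(colSums(P), c(0, 0), tolerance = 1e-12)
  }
})

test_that("populations with all pairs beyond the cutoff are stationary", {
  cub <- calib_cubic()
  pop <- cell_population(data.frame(
    cell_id = 1:3, x = c(0, 2, 4), y = 0, radius = 0.5
  ))
  dy <- population_rhs(pop, cub)(0, cbmech:::flatten_positions(pop))
  expect_equal(dy, rep(0, 6))
})

test_that("coincident midpoints raise an error naming the pair", {
  cub <- calib_cubic()
  pop <- cell_population(data.frame(
    cell_id = 1:2, x = c(1, 1), y = c(2, 2), radius = 0.5
  ))
  expect_error(total_forces(pop, cub), "coincident")
})

test_that("division geometry: separation, midpoint, ids and radius", {
  pop <- cell_population(data.frame(cell_id = 5L, x = 1, y = 2, radius = 0.4))
  set.seed(3)
  out <- divide_cell(pop, 5L, r0 = 0.3)
  expect_equal(nrow(out), 2)
  expect_setequal(out$cell_id, c(5L, 6L))
  P <- cbmech:::pop_positions(out)
  expect_equal(sqrt(sum((P[1, ] - P[2, ])^2)), 0.3) # daughter separation = r0
  expect_equal(unname(colMeans(P)), c(1, 2))        # midpoint preserved
  expect_equal(out$radius, c(0.4, 0.4))             # no growth at division
  expect_error(divide_cell(pop, 99L), "no cell")
  # one RNG draw per division: same seed, same geometry
  set.seed(3)
  again <- divide_cell(pop, 5L, r0 = 0.3)
  expect_equal(cbmech:::pop_positions(again), P)
})

test_that("simulation without events equals a plain fixed-step solve", {
  cub <- calib_cubic()
  pop <- two_cell_population(0.3)
  sim <- simulate_population(pop, cub, t_end = 0.5, scheme = "euler", dt = 0.02)
  expect_length(sim$segments, 1)
  direct <- solve_fixed(
    population_rhs(pop, cub), cbmech:::flatten_positions(pop),
    c(0, 0.5), dt = 0.02, scheme = "euler"
  )
  expect_identical(sim$segments[[1]]$traj$states, direct$states)
})

test_that("divisions at time zero double the population in a single epoch", {
  cub <- calib_cubic()
  pop <- honeycomb_population(19)
  sim <- simulate_population(pop, cub,
    t_end = 0.1, scheme = "euler", dt = 0.01,
    events = data.frame(time = 0, cell_id = pop$cell_id), seed = 1
  )
  expect_length(sim$segments, 1)
  expect_equal(nrow(final_population(sim)), 38)
  expect_equal(ncol(sim$segments[[1]]$traj$states), 76)
})

test_that("mid-run events split the trajectory and AB2 restarts cleanly", {
  cub <- calib_cubic()
  pop <- two_cell_population(1.0)
  sim <- simulate_population(pop, cub,
    t_end = 1, scheme = "ab2", dt = 0.05,
    events = data.frame(time = 0.5, cell_id = 1L), seed = 2
  )
  expect_length(sim$segments, 2)
  expect_equal(length(sim$segments[[1]]$traj$cell_ids), 2)
  expect_equal(length(sim$segments[[2]]$traj$cell_ids), 3)
  df <- tibble::as_tibble(sim)
  expect_true(all(c("time", "cell_id", "x", "y", "segment") %in% names(df)))
})

test_that("antisymmetric forces conserve the centroid within every epoch", {
  # a division shifts the equal-weight centroid towards the mother (cell
  # count changes), but between events the pairwise antisymmetry pins it
  cub <- calib_cubic()
  pop <- honeycomb_population(7)
  sim <- simulate_population(pop, cub,
    t_end = 1, scheme = "euler", dt = 0.01,
    events = data.frame(time = c(0, 0.5), cell_id = c(1L, 3L)), seed = 4
  )
  expect_length(sim$segments, 2)
  for (seg in sim$segments) {
    st <- seg$traj$states
    c_first <- colMeans(matrix(st[1, ], ncol = 2, byrow = TRUE))
    c_last <- colMeans(matrix(st[nrow(st), ], ncol = 2, byrow = TRUE))
    expect_equal(c_last, c_first, tolerance = 1e-10)
  }
  # and the division operator itself preserves the daughters' mean position
  set.seed(4)
  mother <- cbmech:::pop_positions(pop)[2, ]
  divided <- divide_cell(pop, 2L, r0 = 0.3)
  dpos <- cbmech:::pop_positions(divided)[divided$cell_id %in% c(2L, 8L), ]
  expect_equal(unname(colMeans(dpos)), unname(mother), tolerance = 1e-12)
})

test_that("population radius: singleton, pair, and the 19-cell honeycomb", {
  one <- cell_population(data.frame(cell_id = 1, x = 3, y = -1, radius = 0.5))
  expect_equal(population_radius(one), 0.5)
  pair <- two_cell_population(r0 = 1)
  expect_equal(population_radius(pair), 1.0)
  expect_equal(population_radius(honeycomb_population(19)), 2.5)
  expect_error(population_radius(honeycomb_population(19)[0, ]), "empty")
})

test_that("honeycomb lattices have the right counts, rings and spacings", {
  h7 <- honeycomb_population(7)
  d_centre <- sqrt(h7$x[-1]^2 + h7$y[-1]^2)
  expect_equal(d_centre, rep(1, 6))

  h19 <- honeycomb_population(19)
  expect_equal(max(sqrt(h19$x^2 + h19$y^2)), 2)

  h37 <- honeycomb_population(37)
  expect_equal(nrow(h37), 37)
  expect_equal(min(dist(cbmech:::pop_positions(h37))), 1)

  expect_error(honeycomb_population(10), "hexagonal")
})

test_that("population, event and trajectory files round-trip as plain CSV", {
  pop <- honeycomb_population(7)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, tmp)
  back <- read_population(tmp)
  expect_equal(as.data.frame(back), as.data.frame(pop))

  ev <- data.frame(time = c(0, 0.5), cell_id = c(1L, 2L))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, tmp2)
  expect_equal(as.data.frame(read_events(tmp2)), ev)

  sim <- simulate_population(two_cell_population(0.3), calib_cubic(),
    t_end = 0.1, scheme = "euler", dt = 0.05
  )
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(sim, tmp3)
  df <- utils::read.csv(tmp3)
  expect_equal(names(df), c("time", "cell_id", "x", "y", "segment"))
  expect_equal(nrow(df), 2 * 3)
})
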