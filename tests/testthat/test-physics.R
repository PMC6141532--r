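test_that("lattice construction places particles on the voxel grid", {
  # homogeneous robot: uniform 1 cm spacing, 4 x 4 x 3 extent, at rest
  st <- build_lattice(make_fixture("static"), devo_config(amplitude = 0))
  expect_equal(nrow(st$pos), 48)
  expect_equal(max(st$pos[, 1]) - min(st$pos[, 1]), 3)
  expect_equal(max(st$pos[, 2]) - min(st$pos[, 2]), 3)
  expect_equal(max(st$pos[, 3]) - min(st$pos[, 3]), 2)
  expect_equal(min(st$pos[, 3]), 0)
  expect_true(all(st$vel == 0))
  expect_equal(sort(unique(st$pos[, 1])), c(-1.5, -0.5, 0.5, 1.5))

  # 2 x 2 x 2 lattice: 8 particles, 12 edges
  g8 <- grid_spec(2, 2, 2)
  genome8 <- random_genome(g8, "evo", seed = 1)
  st8 <- build_lattice(genome8, devo_config(amplitude = 0))
  expect_equal(nrow(st8$pos), 8)
  expect_equal(nrow(st8$beams), 12)
  expect_equal(nrow(st8$triples), 0)

  # mirrored morphology with symmetric controller: x-coordinates mirror
  g <- grid_spec()
  genome <- random_genome(g, "evodevo", seed = 3)
  genome$phi_start <- rep(0, g$n_vox); genome$phi_final <- rep(0, g$n_vox)
  st <- build_lattice(genome)
  x <- st$pos[, 1]
  co_x <- (seq_len(g$n_vox) - 1) %% g$nx
  for (k in seq_len(g$n_vox)) {
    k_m <- k + (g$nx - 1 - 2 * co_x[k])
    expect_identical(x[k], -x[k_m])
  }
})

test_that("a single damped falling particle matches the closed form", {
  devo <- devo_config(amplitude = 0)
  m <- 1; cc <- 2; grav <- 981; tsim <- 0.5
  vterm <- m * grav / cc
  z_exact <- 50 - vterm * tsim + (m / cc) * vterm * (1 - exp(-cc * tsim / m))
  err <- sapply(c(1e-4, 5e-5), function(dt) {
    cf <- physics_config(dt = dt, damping_c = cc, ground_k = 0,
                         ground_c = 0, mu = 0)
    st <- make_lattice_state(matrix(c(0, 0, 50), 1, 3))
    s <- step_lattice(st, round(tsim / dt), devo, cf)
    abs(s$pos[1, 3] - z_exact) / abs(50 - z_exact)
  })
  expect_lt(err[1], 0.01)
  expect_lt(err[2], err[1])  # first-order Richardson improvement
})

test_that("a two-particle beam oscillates at sqrt(2k/m)/(2*pi)", {
  k <- 100
  cf <- physics_config(dt = 1e-4, spring_k = k, bend_k = 0, damping_c = 0,
                       gravity = 0, ground_k = 0, ground_c = 0, mu = 0)
  devo <- devo_config(amplitude = 0)
  st <- make_lattice_state(matrix(c(-0.55, 0, 5, 0.55, 0, 5), 2, 3,
                                  byrow = TRUE),
                           beams = matrix(c(0L, 1L), 1, 2))
  dists <- numeric(400)
  for (i in seq_len(400)) {
    st <- step_lattice(st, 100, devo, cf)
    dists[i] <- st$pos[2, 1] - st$pos[1, 1]
  }
  d <- dists - mean(dists)
  crossings <- which(d[-1] * d[-length(d)] < 0)
  f_meas <- 1 / (2 * mean(diff(crossings)) * 0.01)
  f_theory <- sqrt(2 * k / 1) / (2 * pi)
  expect_lt(abs(f_meas - f_theory) / f_theory, 0.02)
})

test_that("a force-free resting state is a fixed point", {
  cf <- physics_config(gravity = 0, ground_k = 0, ground_c = 0, mu = 0)
  st <- make_lattice_state(matrix(c(1, 2, 3), 1, 3))
  s <- step_lattice(st, 500, devo_config(amplitude = 0), cf)
  expect_equal(s$pos, st$pos)
  expect_equal(s$vel, st$vel)
})

test_that("passive robots dissipate energy monotonically", {
  traj <- simulate_robot(make_fixture("static"), tiny_devo(amplitude = 0),
                         tiny_phys(), record_interval = 0.02)
  expect_true(all(diff(traj$energy) <= 1e-9 * max(abs(traj$energy))))
  expect_lt(fitness_from_trajectory(traj), 0.01)
})

test_that("mirror-symmetric robots do not drift laterally", {
  traj <- simulate_robot(make_fixture("static"), tiny_devo(), tiny_phys())
  n <- nrow(traj)
  drift_bl <- abs(traj$com_x[n] - traj$com_x[1]) / 4
  expect_lt(drift_bl, 0.05)
  expect_lt(drift_bl, 1e-12)  # exact by construction of the integrator
})

test_that("no particle stays below the contact threshold", {
  cf <- tiny_phys()
  traj <- simulate_robot(make_fixture("shuffler", toy_grid()), tiny_devo(),
                         cf, record_interval = 0.02)
  below <- traj$min_z < -cf$contact_eps
  expect_true(all(!(below[-1] & below[-length(below)])))
})

test_that("simulation is deterministic and dt-convergent", {
  sh <- make_fixture("shuffler")
  t1 <- simulate_robot(sh, tiny_devo(), tiny_phys())
  t2 <- simulate_robot(sh, tiny_devo(), tiny_phys())
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  sh3 <- make_fixture("shuffler", toy_grid())
  f1 <- fitness_from_trajectory(simulate_robot(sh3, tiny_devo(), tiny_phys()))
  expect_gt(f1, 0)  # fore-aft-asymmetric actuation produces net motion
})

test_that("fitness is net COM displacement in body lengths", {
  g <- grid_spec()
  still <- tibble::tibble(time = 0:10, com_x = 0, com_y = 0)
  expect_equal(fitness_from_trajectory(still, g), 0)
  moved <- tibble::tibble(time = 0:1, com_x = c(0, 8), com_y = c(0, 0))
  expect_equal(fitness_from_trajectory(moved, g), 2)
  back <- tibble::tibble(time = 0:2, com_x = c(0, 5, 0), com_y = c(0, 1, 0))
  expect_equal(fitness_from_trajectory(back, g), 0)
  expect_gt(fitness_from_trajectory(back, g, path_length = TRUE), 0)
})

test_that("rollover detection returns the earliest touching sample", {
  base <- tibble::tibble(time = seq(0, 10, by = 0.5))
  up <- base; up$top_min_z <- rep(2, nrow(base))
  expect_true(is.na(detect_rollover(up, 0.05)))
  dip <- base
  dip$top_min_z <- c(rep(2, 16), 0.04, rep(2, nrow(base) - 17))
  expect_equal(detect_rollover(dip, 0.05), base$time[17])
  tie <- base
  tie$top_min_z <- c(rep(2, 16), 0.05, 0.01, rep(2, nrow(base) - 18))
  expect_equal(detect_rollover(tie, 0.05), base$time[17])  # <= comparison
})

test_that("divergent integrations raise an instability error", {
  st <- make_lattice_state(matrix(c(0, 0, 1), 1, 3),
                           vel = matrix(c(1e7, 0, 0), 1, 3))
  cf <- physics_config(ground_k = 0, ground_c = 0, mu = 0, damping_c = 0)
  expect_error(step_lattice(st, 1000, devo_config(amplitude = 0), cf),
               "diverged")
})
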