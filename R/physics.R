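#' Physics engine configuration
#'
#' Parameters of the mass-spring lattice simulator.  Units are cm, g, s
#' (forces in dyn, stiffness in dyn/cm).  The defaults place the lattice's
#' fundamental vibration period well below the 4 Hz actuation period
#' (quasi-static actuation) and satisfy the stability bound
#' `dt <= 0.1 * sqrt(mass / spring_k)`.
#'
#' @param dt Integration timestep, seconds.
#' @param spring_k Translational beam stiffness, dyn/cm.
#' @param bend_k Stiffness of the straightness springs spanning collinear
#'   beam pairs (the surrogate for beam rotational stiffness), dyn/cm.
#' @param damping_c Global viscous velocity damping, g/s.
#' @param gravity Gravitational acceleration, cm/s^2.
#' @param ground_k Ground contact penalty stiffness, dyn/cm.
#' @param ground_c Viscous damping of the normal contact force, g/s.
#' @param mu Coulomb friction coefficient.  The friction force is capped at
#'   the amount that brings a particle's tangential velocity to rest within
#'   one timestep, so slow contacts stick rather than chatter.
#' @param slip_eps Tangential speeds below this threshold (cm/s) are treated
#'   as at rest (no friction force).
#' @param particle_mass Mass per particle, g.
#' @param contact_eps Contact distance threshold, cm, used by
#'   [detect_rollover()]; defaults to 5% of a voxel.
#' @return An object of class `voxdev_physics_config`.
#' @export
physics_config <- function(dt = 1e-4, spring_k = 1e5, bend_k = 2.5e4,
                           damping_c = 30, gravity = 981,
                           ground_k = 4e5, ground_c = 800, mu = 1.0,
                           slip_eps = 1e-6, particle_mass = 1.0,
                           contact_eps = 0.05) {
  stopifnot(dt > 0, spring_k >= 0, bend_k >= 0, damping_c >= 0,
            ground_k >= 0, ground_c >= 0, mu >= 0, slip_eps > 0,
            particle_mass > 0, contact_eps >= 0)
  if (spring_k > 0 && dt > 0.1 * sqrt(particle_mass / spring_k))
    stop(sprintf("unstable configuration: dt=%g exceeds 0.1*sqrt(m/k)=%g",
                 dt, 0.1 * sqrt(particle_mass / spring_k)))
  structure(list(dt = dt, spring_k = spring_k, bend_k = bend_k,
                 damping_c = damping_c, gravity = gravity,
                 ground_k = ground_k, ground_c = ground_c, mu = mu,
                 slip_eps = slip_eps, particle_mass = particle_mass,
                 contact_eps = contact_eps),
            class = "voxdev_physics_config")
}

#' Softer, coarser physics for small test lattices
#'
#' A relaxed preset (softer springs, larger timestep) suited to reduced
#' grids such as 3 x 3 x 2; roughly 4x faster than the default while
#' keeping the same qualitative mechanics.
#'
#' @param ... Overrides passed to [physics_config()].
#' @return A `voxdev_physics_config`.
#' @export
toy_physics_config <- function(...) {
  defaults <- list(dt = 5e-4, spring_k = 3e4, bend_k = 7.5e3,
                   ground_k = 1.2e5, ground_c = 450)
  do.call(physics_config, modifyList(defaults, list(...)))
}

# Lattice topology as per-particle neighbor/span slot matrices in fixed
# direction order (x-, x+, y-, y+, z-, z+), 0-based with -1 for "none",
# plus flat beam/triple lists for inspection.  The fixed slot order is what
# makes force accumulation exactly mirror-symmetric in floating point: a
# reflection only swaps the two slots of one direction pair, and IEEE
# addition of two terms is commutative.
lattice_topology <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- grid$n_vox
  co <- voxel_coords(seq_len(n), grid)
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  inside <- function(x, y, z) x >= 0 & x < nx & y >= 0 & y < ny &
                              z >= 0 & z < nz
  nbr <- matrix(-1L, n, 6)
  span_other <- matrix(-1L, n, 6)
  span_mid <- matrix(-1L, n, 6)
  for (s in 1:6) {
    d <- dirs[s, ]
    x1 <- co[, "x"] + d[1]; y1 <- co[, "y"] + d[2]; z1 <- co[, "z"] + d[3]
    ok <- inside(x1, y1, z1)
    nbr[ok, s] <- voxel_index(x1[ok], y1[ok], z1[ok], grid) - 1L
    x2 <- co[, "x"] + 2 * d[1]; y2 <- co[, "y"] + 2 * d[2]
    z2 <- co[, "z"] + 2 * d[3]
    ok2 <- inside(x2, y2, z2)
    span_other[ok2, s] <- voxel_index(x2[ok2], y2[ok2], z2[ok2], grid) - 1L
    span_mid[ok2, s] <- voxel_index(x1[ok2], y1[ok2], z1[ok2], grid) - 1L
  }
  # flat lists (each undirected beam/span once)
  own <- matrix(rep(seq_len(n) - 1L, 6), n, 6)
  sel <- nbr >= 0 & nbr > own
  beams <- cbind(own[sel], nbr[sel])
  sel2 <- span_other >= 0 & span_other > own
  triples <- cbind(own[sel2], span_mid[sel2], span_other[sel2])
  list(nbr = nbr, span_other = span_other, span_mid = span_mid,
       beams = beams, triples = triples)
}

# Symmetric 1-d placement: positions built outward from the row center so
# that a palindromic rest-length sequence yields exactly sign-symmetric
# coordinates in floating point.
place_axis <- function(rests) {
  n <- length(rests) + 1L
  p <- numeric(n)
  if (n == 1L) return(p)
  if (n %% 2L == 1L) {
    ctr <- (n + 1L) %/% 2L
    for (k in seq(ctr + 1L, n)) p[k] <- p[k - 1L] + rests[k - 1L]
    for (k in seq(ctr - 1L, 1L)) p[k] <- p[k + 1L] - rests[k]
  } else {
    cl <- n %/% 2L
    p[cl] <- -rests[cl] / 2
    p[cl + 1L] <- rests[cl] / 2
    if (cl + 2L <= n) for (k in seq(cl + 2L, n)) p[k] <- p[k - 1L] + rests[k - 1L]
    if (cl - 1L >= 1L) for (k in seq(cl - 1L, 1L)) p[k] <- p[k + 1L] - rests[k]
  }
  p
}

# Expanded per-voxel development arrays (start/final resting length and
# phase) in particle order.
devo_arrays <- function(genome) {
  src <- mirror_source(genome$grid)
  list(ell0 = genome$ell_start[src], ell1 = genome$ell_final[src],
       phi0 = genome$phi_start, phi1 = genome$phi_final)
}

#' Build the particle lattice for a genome
#'
#' Places one particle per voxel on a cartesian grid whose spacing along
#' each axis is the mean of adjacent voxels' current lengths at birth
#' (`t = 0`), resting on the ground plane (minimum z = 0) with zero
#' velocities.  Each particle has at most six beam neighbors.
#'
#' @param genome A `voxdev_genome`.
#' @param devo_cfg A [devo_config()].
#' @param phys_cfg A [physics_config()].
#' @return An object of class `voxdev_lattice`: positions/velocities
#'   (`n_vox` x 3 matrices), beam and triple index matrices (0-based),
#'   expanded development arrays, top-layer particle indices, and `time`.
#' @export
build_lattice <- function(genome, devo_cfg = devo_config(),
                          phys_cfg = physics_config()) {
  validate_genome(genome)
  grid <- genome$grid
  da <- devo_arrays(genome)
  L0 <- current_length(genome, 0, devo_cfg)
  topo <- lattice_topology(grid)

  co <- voxel_coords(seq_len(grid$n_vox), grid)
  pos <- matrix(0, grid$n_vox, 3)
  # beam rest lengths along each axis within each row, placed outward from
  # the row center (exact mirror symmetry for symmetric robots)
  axis_pos <- function(axis_coord, other1, other2, get_idx, n_axis) {
    for (o1 in 0:(other1 - 1)) for (o2 in 0:(other2 - 1)) {
      ks <- vapply(0:(n_axis - 1), function(i) get_idx(i, o1, o2), numeric(1))
      rests <- if (n_axis > 1) 0.5 * (L0[ks[-n_axis]] + L0[ks[-1]])
               else numeric(0)
      pos[ks, axis_coord] <<- place_axis(rests)
    }
  }
  axis_pos(1, grid$ny, grid$nz,
           function(i, y, z) voxel_index(i, y, z, grid), grid$nx)
  axis_pos(2, grid$nx, grid$nz,
           function(j, x, z) voxel_index(x, j, z, grid), grid$ny)
  axis_pos(3, grid$nx, grid$ny,
           function(k, x, y) voxel_index(x, y, k, grid), grid$nz)
  pos[, 3] <- pos[, 3] - min(pos[, 3])

  structure(list(
    grid = grid,
    pos = pos, vel = matrix(0, grid$n_vox, 3),
    nbr = topo$nbr, span_other = topo$span_other, span_mid = topo$span_mid,
    beams = topo$beams, triples = topo$triples,
    ell0 = da$ell0, ell1 = da$ell1, phi0 = da$phi0, phi1 = da$phi1,
    top_particles = which(co[, "z"] == grid$nz - 1L) - 1L,
    time = 0
  ), class = "voxdev_lattice")
}

#' Construct a bare lattice state
#'
#' Low-level constructor for hand-built particle systems (single particles,
#' isolated beams) used to check the integrator against closed-form
#' mechanics.  Development is disabled: voxel lengths stay at `rest`.
#'
#' @param pos n x 3 position matrix, cm.
#' @param vel n x 3 velocity matrix, cm/s (default zero).
#' @param beams Beam matrix (m x 2, 0-based particle indices).
#' @param rest Per-particle voxel resting length, cm (recycled).
#' @return A `voxdev_lattice`.
#' @export
make_lattice_state <- function(pos, vel = NULL, beams = NULL, rest = 1.0) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(beams)) beams <- matrix(integer(), 0, 2)
  rest <- rep_len(rest, n)
  nbr <- matrix(-1L, n, 6)
  if (nrow(beams) > 0) {
    add_nbr <- function(i, j) {
      slot <- which(nbr[i + 1L, ] < 0)[1]
      if (is.na(slot)) stop("a particle may have at most 6 neighbors")
      nbr[i + 1L, slot] <<- as.integer(j)
    }
    for (b in seq_len(nrow(beams))) {
      add_nbr(beams[b, 1], beams[b, 2])
      add_nbr(beams[b, 2], beams[b, 1])
    }
  }
  structure(list(
    grid = NULL, pos = pos, vel = as.matrix(vel),
    nbr = nbr, span_other = matrix(-1L, n, 6), span_mid = matrix(-1L, n, 6),
    beams = beams, triples = matrix(integer(), 0, 3),
    ell0 = rest, ell1 = rest, phi0 = rep(0, n), phi1 = rep(0, n),
    top_particles = integer(0), time = 0
  ), class = "voxdev_lattice")
}

run_core <- function(state, devo_cfg, phys_cfg, n_steps, record_every,
                     amplitude = devo_cfg$amplitude) {
  run_lattice_cpp(
    state$pos, state$vel,
    state$nbr, state$span_other, state$span_mid,
    state$ell0, state$ell1, state$phi0, state$phi1,
    amplitude, devo_cfg$freq, devo_cfg$tau,
    state$time, as.integer(n_steps), phys_cfg$dt,
    phys_cfg$particle_mass, phys_cfg$spring_k, phys_cfg$bend_k,
    phys_cfg$damping_c, phys_cfg$gravity,
    phys_cfg$ground_k, phys_cfg$ground_c, phys_cfg$mu, phys_cfg$slip_eps,
    as.integer(state$top_particles), as.integer(record_every))
}

#' Advance a lattice state
#'
#' Integrates `n_steps` semi-implicit Euler steps from the state's current
#' time, refreshing per-beam resting lengths from the developing voxel
#' lengths each step.  Deterministic given state and configurations.
#'
#' @param state A `voxdev_lattice`.
#' @param n_steps Number of timesteps.
#' @param devo_cfg,phys_cfg Configurations.
#' @return The updated `voxdev_lattice`.
#' @export
step_lattice <- function(state, n_steps = 1L, devo_cfg = devo_config(),
                         phys_cfg = physics_config()) {
  out <- run_core(state, devo_cfg, phys_cfg, n_steps, record_every = 0L)
  state$pos <- out$pos
  state$vel <- out$vel
  state$time <- out$t_end
  state
}

#' Simulate a robot for its whole lifetime
#'
#' Builds the lattice at birth and integrates over `t` in `[0, tau]`,
#' recording center-of-mass position, the lowest height of any
#' initially-top-layer particle, the overall minimum particle height,
#' horizontal center-of-mass speed, and total mechanical energy at every
#' `record_interval`.
#'
#' @param genome A `voxdev_genome`.
#' @param devo_cfg,phys_cfg Configurations.
#' @param record_interval Sampling interval, seconds (snapped to a multiple
#'   of `dt`).
#' @return A `voxdev_trajectory`: a tibble with columns `time`, `com_x`,
#'   `com_y`, `com_z`, `top_min_z`, `min_z`, `speed`, `energy`, carrying
#'   the grid and configs as attributes.  An unstable integration raises an
#'   error naming the offending timestep/stiffness.
#' @export
simulate_robot <- function(genome, devo_cfg = devo_config(),
                           phys_cfg = physics_config(),
                           record_interval = 0.01) {
  state <- build_lattice(genome, devo_cfg, phys_cfg)
  n_steps <- round(devo_cfg$tau / phys_cfg$dt)
  record_every <- max(1L, round(record_interval / phys_cfg$dt))
  out <- run_core(state, devo_cfg, phys_cfg, n_steps, record_every)
  traj <- tibble::tibble(
    time = out$time, com_x = out$com_x, com_y = out$com_y,
    com_z = out$com_z, top_min_z = out$top_min_z, min_z = out$min_z,
    speed = out$speed, energy = out$energy)
  attr(traj, "grid") <- genome$grid
  attr(traj, "contact_eps") <- phys_cfg$contact_eps
  class(traj) <- c("voxdev_trajectory", class(traj))
  traj
}

#' Locomotion fitness of a trajectory
#'
#' Net horizontal displacement of the center of mass between birth and the
#' end of life, in undeformed body lengths (four voxels, 4 cm by default).
#' With `path_length = TRUE` the integrated horizontal path length is used
#' instead of net displacement.
#'
#' @param traj A `voxdev_trajectory`.
#' @param grid The robot's [grid_spec()]; defaults to the one recorded on
#'   the trajectory.
#' @param path_length Use cumulative path length rather than displacement.
#' @return Non-negative fitness in body lengths.
#' @export
fitness_from_trajectory <- function(traj, grid = attr(traj, "grid"),
                                    path_length = FALSE) {
  stopifnot(nrow(traj) >= 1)
  if (path_length) {
    d <- sum(sqrt(diff(traj$com_x)^2 + diff(traj$com_y)^2))
  } else {
    n <- nrow(traj)
    d <- sqrt((traj$com_x[n] - traj$com_x[1])^2 +
              (traj$com_y[n] - traj$com_y[1])^2)
  }
  d / grid$body_length
}

#' Detect the first rollover
#'
#' Rolling over is measured from the first sample at which any
#' initially-top-layer particle touches the ground (height at or below
#' `contact_eps`), not from a complete roll.
#'
#' @param traj A `voxdev_trajectory`.
#' @param contact_eps Contact threshold, cm; defaults to the simulating
#'   configuration's value (5% of a voxel).
#' @return The earliest such sample time in seconds, or `NA_real_` if the
#'   top never touches down.
#' @export
detect_rollover <- function(traj, contact_eps = attr(traj, "contact_eps")) {
  if (is.null(contact_eps)) contact_eps <- 0.05
  hit <- which(traj$top_min_z <= contact_eps)
  if (length(hit) == 0) NA_real_ else traj$time[hit[1]]
}

#' Export a trajectory as CSV
#'
#' @param traj A `voxdev_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
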