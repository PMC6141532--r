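# Shared miniature configurations: tiny grids and short lifetimes keep
# unit-test simulations around a millisecond while exercising the same
# code paths as the full-scale conditions.

tiny_grid <- function() grid_spec(2L, 2L, 1L)

toy_grid <- function() grid_spec(3L, 3L, 2L)

# 4 actuation cycles at 4 Hz: a one-second life
tiny_devo <- function(amplitude = 0.14) {
  devo_config(amplitude = amplitude, freq = 4, n_cycles = 4)
}

tiny_phys <- function(...) toy_physics_config(...)

tiny_evo_config <- function(treatment = "evodevo", pop_size = 3L,
                            generations = 2L, grid = tiny_grid()) {
  evo_config(grid = grid, treatment = treatment, pop_size = pop_size,
             generations = generations, devo_cfg = tiny_devo(),
             phys_cfg = tiny_phys(), record_interval = 0.05)
}

# random evaluated individuals for selection tests (no simulation)
random_pool <- function(n, max_age = 10) {
  lapply(seq_len(n), function(i)
    structure(list(uid = i, parent_uid = NA_integer_,
                   age = sample.int(max_age, 1),
                   fitness = round(runif(1), 3),
                   genome = NULL, unstable = FALSE),
              class = "voxdev_individual"))
}

# brute-force Pareto front on (fitness max, age min)
brute_force_nondominated <- function(pool) {
  dominated <- vapply(seq_along(pool), function(i)
    any(vapply(seq_along(pool), function(j)
      j != i && dominates(pool[[j]], pool[[i]]), logical(1))), logical(1))
  which(!dominated)
}
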