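#' Evolutionary run configuration
#'
#' Settings for one Age-Fitness-Pareto (AFPO) trial: a population of
#' `pop_size` robots (30 at full scale) evolved for `generations`
#' generations.  Every generation the population is doubled by mutated
#' copies, every individual's age is incremented, one random age-0
#' individual is injected (pool of `2 * pop_size + 1`), and Pareto
#' selection on maximized fitness / minimized age reduces the pool back to
#' `pop_size`.
#'
#' @param grid A [grid_spec()].
#' @param treatment `"evo"` or `"evodevo"`.
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations (>= 1).
#' @param mut A [mutation_params()]; set its `fixed_rate` to replicate the
#'   fixed-mutation-rate mode (self-adaptation is the default).
#' @param devo_cfg,phys_cfg Development and physics configurations.
#' @param record_interval Trajectory sampling interval, seconds.
#' @param archive_genomes Keep every logged individual's genome in memory
#'   (needed for lineage re-simulation; disable for very long runs).
#' @return An object of class `voxdev_evo_config`.
#' @export
evo_config <- function(grid = grid_spec(), treatment = c("evodevo", "evo"),
                       pop_size = 30L, generations = 100L,
                       mut = mutation_params(),
                       devo_cfg = devo_config(),
                       phys_cfg = physics_config(),
                       record_interval = 0.01,
                       archive_genomes = TRUE) {
  treatment <- match.arg(treatment)
  pop_size <- as.integer(pop_size); generations <- as.integer(generations)
  stopifnot(pop_size >= 2, generations >= 1)
  structure(list(grid = grid, treatment = treatment, pop_size = pop_size,
                 generations = generations, mut = mut, devo_cfg = devo_cfg,
                 phys_cfg = phys_cfg, record_interval = record_interval,
                 archive_genomes = archive_genomes),
            class = "voxdev_evo_config")
}

new_individual <- function(genome, uid, parent_uid = NA_integer_, age = 0L,
                           fitness = NA_real_) {
  structure(list(genome = genome, uid = as.integer(uid),
                 parent_uid = as.integer(parent_uid), age = as.integer(age),
                 fitness = fitness, unstable = FALSE),
            class = "voxdev_individual")
}

#' Pareto dominance on (fitness, age)
#'
#' Individual `i` dominates `j` iff `i` is at least as fit, at most as old,
#' and strictly better in at least one of the two.  The relation is
#' irreflexive, antisymmetric and transitive.
#'
#' @param i,j Evaluated `voxdev_individual`s (or lists with `fitness` and
#'   `age` fields).
#' @return Logical.
#' @export
dominates <- function(i, j) {
  if (is.na(i$fitness) || is.na(j$fitness))
    stop("cannot compare unevaluated individuals")
  (i$fitness >= j$fitness) && (i$age <= j$age) &&
    ((i$fitness > j$fitness) || (i$age < j$age))
}

# Index of the protected elite: maximum fitness, ties broken by minimum
# age then lowest uid.  The elite is exempt from stall-guard deletion so
# the best-ever design always survives selection.
elite_index <- function(pool) {
  fit <- vapply(pool, function(p) as.numeric(p$fitness), numeric(1))
  age <- vapply(pool, function(p) as.numeric(p$age), numeric(1))
  uid <- vapply(pool, function(p) as.numeric(p$uid), numeric(1))
  order(-fit, age, uid)[1]
}

#' AFPO selection: reduce a pool by Pareto-dominance tournaments
#'
#' Repeatedly draws two distinct random pool members and deletes the
#' dominated one (if either dominates).  If `pop_size^2` consecutive draws
#' find no dominance, the pool is scanned exhaustively: a dominated member
#' is deleted if any exists, otherwise (the pool is mutually non-dominated)
#' a random member of the oldest cohort is deleted, never the current
#' highest-fitness individual.
#'
#' @param pool List of evaluated `voxdev_individual`s.
#' @param pop_size Target size.
#' @return List with `survivors` (length `pop_size`) and `stall_deletions`
#'   (count of deletions made on the non-dominated path).
#' @export
afpo_select <- function(pool, pop_size) {
  stopifnot(length(pool) >= pop_size)
  stall_deletions <- 0L
  stall <- 0L
  max_stall <- max(16L, pop_size^2)
  while (length(pool) > pop_size) {
    ij <- sample.int(length(pool), 2L)
    a <- pool[[ij[1]]]; b <- pool[[ij[2]]]
    if (dominates(a, b)) {
      pool[[ij[2]]] <- NULL; stall <- 0L
    } else if (dominates(b, a)) {
      pool[[ij[1]]] <- NULL; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= max_stall) {
        deleted <- FALSE
        for (x in seq_along(pool)) {
          for (y in seq_along(pool)) {
            if (x != y && dominates(pool[[y]], pool[[x]])) {
              pool[[x]] <- NULL; deleted <- TRUE; break
            }
          }
          if (deleted) break
        }
        if (!deleted) {
          keep <- elite_index(pool)
          age <- vapply(pool, function(p) as.numeric(p$age), numeric(1))
          cand <- setdiff(which(age == max(age[-keep])), keep)
          if (length(cand) == 0) cand <- setdiff(seq_along(pool), keep)
          victim <- if (length(cand) == 1) cand else sample(cand, 1L)
          pool[[victim]] <- NULL
          stall_deletions <- stall_deletions + 1L
        }
        stall <- 0L
      }
    }
  }
  list(survivors = pool, stall_deletions = stall_deletions)
}

# Evaluate an individual's locomotion fitness, with caching keyed on the
# phenotype-determining genome values.  Unstable simulations score 0 and
# are flagged rather than aborting the trial.
evaluate_individual <- function(ind, cfg, cache = NULL) {
  if (!is.na(ind$fitness)) return(ind)
  key <- genome_hash(ind$genome)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    cached <- cache[[key]]
    ind$fitness <- cached$fitness
    ind$unstable <- cached$unstable
    return(ind)
  }
  res <- tryCatch({
    traj <- simulate_robot(ind$genome, cfg$devo_cfg, cfg$phys_cfg,
                           cfg$record_interval)
    list(fitness = fitness_from_trajectory(traj), unstable = FALSE)
  }, error = function(e) list(fitness = 0, unstable = TRUE))
  ind$fitness <- res$fitness
  ind$unstable <- res$unstable
  if (!is.null(cache)) cache[[key]] <- res
  ind
}

log_rows <- function(pop, generation, survived) {
  uids <- vapply(pop, `[[`, integer(1), "uid")
  tibble::tibble(
    generation = generation,
    uid = uids,
    parent_uid = vapply(pop, `[[`, integer(1), "parent_uid"),
    age = vapply(pop, `[[`, integer(1), "age"),
    fitness = vapply(pop, `[[`, numeric(1), "fitness"),
    W_L = vapply(pop, function(i) window_morph(i$genome), numeric(1)),
    W_Phi = vapply(pop, function(i) window_ctrl(i$genome), numeric(1)),
    unstable = vapply(pop, `[[`, logical(1), "unstable"),
    survived = uids %in% survived)
}

#' One AFPO generation
#'
#' Doubles the population with mutated copies (children inherit their
#' parent's age), increments every individual's age, injects one random
#' age-0 individual (pool size `2 * pop_size + 1`), evaluates the new
#' arrivals, and reduces the pool back to `pop_size` with [afpo_select()].
#'
#' @param pop List of `pop_size` evaluated individuals.
#' @param cfg A [evo_config()].
#' @param state Trial state environment (uid counter, evaluation cache,
#'   genome archive) as created by [run_trial()]; a fresh one is made if
#'   omitted.
#' @return List with `pop` (survivors), `log` (tibble of the full evaluated
#'   pool, with a `survived` flag) and `state`.
#' @export
afpo_generation <- function(pop, cfg, state = NULL) {
  if (is.null(state)) state <- new_trial_state()
  stopifnot(length(pop) == cfg$pop_size)

  children <- lapply(pop, function(parent) {
    state$uid <- state$uid + 1L
    new_individual(mutate_genome(parent$genome, cfg$mut),
                   uid = state$uid, parent_uid = parent$uid,
                   age = parent$age)
  })
  pool <- c(pop, children)
  pool <- lapply(pool, function(ind) { ind$age <- ind$age + 1L; ind })
  state$uid <- state$uid + 1L
  injected <- new_individual(random_genome(cfg$grid, cfg$treatment),
                             uid = state$uid, age = 0L)
  pool <- c(pool, list(injected))
  pool <- lapply(pool, evaluate_individual, cfg = cfg, cache = state$cache)

  if (cfg$archive_genomes)
    for (ind in pool) state$genomes[[as.character(ind$uid)]] <- ind$genome

  sel <- afpo_select(pool, cfg$pop_size)
  survivor_uids <- vapply(sel$survivors, `[[`, integer(1), "uid")
  list(pop = sel$survivors,
       log = log_rows(pool, generation = NA_integer_,
                      survived = survivor_uids),
       state = state)
}

new_trial_state <- function() {
  state <- new.env(parent = emptyenv())
  state$uid <- 0L
  state$cache <- new.env(parent = emptyenv())
  state$genomes <- new.env(parent = emptyenv())
  state
}

#' Run one evolutionary trial
#'
#' Initializes a random population, evolves it for `cfg$generations` AFPO
#' generations, and returns the complete history together with the run
#' champion: the highest-fitness individual at termination.  Deterministic
#' given `seed`.
#'
#' @param cfg A [evo_config()].
#' @param seed Integer seed for the trial.
#' @param quiet Suppress per-generation progress.
#' @return A list of class `voxdev_trial`: `history` (tibble; one row per
#'   evaluated individual per generation: uid, parent_uid, age, fitness,
#'   W_L, W_Phi, survived), `champion` (individual), `genomes` (environment
#'   keyed by uid, if archived), `cfg`, `seed`.
#' @export
run_trial <- function(cfg, seed = 1L, quiet = TRUE) {
  with_seed(seed, {
    state <- new_trial_state()
    pop <- lapply(seq_len(cfg$pop_size), function(i) {
      state$uid <- state$uid + 1L
      new_individual(random_genome(cfg$grid, cfg$treatment), uid = state$uid)
    })
    pop <- lapply(pop, evaluate_individual, cfg = cfg, cache = state$cache)
    if (cfg$archive_genomes)
      for (ind in pop) state$genomes[[as.character(ind$uid)]] <- ind$genome
    logs <- list(log_rows(pop, 0L, vapply(pop, `[[`, integer(1), "uid")))

    for (g in seq_len(cfg$generations)) {
      res <- afpo_generation(pop, cfg, state)
      pop <- res$pop
      res$log$generation <- g
      logs[[length(logs) + 1]] <- res$log
      if (!quiet && g %% 10 == 0)
        message(sprintf("gen %d: best fitness %.3f", g,
                        max(vapply(pop, `[[`, numeric(1), "fitness"))))
    }

    fit <- vapply(pop, `[[`, numeric(1), "fitness")
    champion <- pop[[which.max(fit)]]
    structure(list(history = do.call(rbind, logs), champion = champion,
                   genomes = state$genomes, cfg = cfg, seed = seed),
              class = "voxdev_trial")
  })
}

#' @export
print.voxdev_trial <- function(x, ...) {
  cat(sprintf("<voxdev_trial> %s, %d generations, pop %d, seed %d; champion uid %d fitness %.3f body lengths\n",
              x$cfg$treatment, x$cfg$generations, x$cfg$pop_size, x$seed,
              x$champion$uid, x$champion$fitness))
  invisible(x)
}

#' Expected fraction of parameters modified by one mutation
#'
#' Closed-form expectation under the two-stage mutation scheme: each
#' applicable parameter type is selected independently with probability
#' `type_prob`, each site of a selected type mutates with probability
#' `rate`, and draws changing nothing are resampled (i.e. the count is
#' conditioned on at least one modification).  With `m` types of sizes
#' `n_i`, the expected modified count is
#' `p * rate * sum(n_i) / (1 - prod((1 - p) + p * (1 - rate)^n_i))`,
#' and the returned value divides by the total parameter count.
#'
#' @param rate Per-site mutation probability in `(0, 1]`.
#' @param grid A [grid_spec()] (sets the site counts).
#' @param treatment `"evo"` (types: resting length, phase) or `"evodevo"`
#'   (start and final variants of both).
#' @param type_prob Per-type selection probability.
#' @return Expected fraction of the genome's free parameters modified.
#' @export
#' @examples
#' expected_mutation_impact(1 / 48)
expected_mutation_impact <- function(rate, grid = grid_spec(),
                                     treatment = c("evodevo", "evo"),
                                     type_prob = 0.5) {
  treatment <- match.arg(treatment)
  stopifnot(rate > 0, rate <= 1)
  n_sites <- if (treatment == "evo") c(grid$n_left, grid$n_vox)
             else c(grid$n_left, grid$n_left, grid$n_vox, grid$n_vox)
  p <- type_prob
  total <- sum(n_sites)
  e_uncond <- p * rate * total
  p_zero <- prod((1 - p) + p * (1 - rate)^n_sites)
  (e_uncond / (1 - p_zero)) / total
}
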