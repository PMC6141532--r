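#' Developmental window statistics
#'
#' The developmental window measures a genome's ballistic plasticity: the
#' total lifetime change summed across all voxels, normalized by the
#' maximum possible change, so 0 means no development and 1 maximal
#' development.  For morphology the per-voxel range is 1.5 cm (resting
#' lengths span 0.25-1.75 cm) and the sum runs over the full mirrored
#' grid:
#' `W_L = sum_k |ell*_k - ell_k| / (n_vox * 1.5)`.
#' For control the per-voxel range is pi (phase offsets span
#' `[-pi/2, pi/2]`):
#' `W_Phi = sum_k |phi*_k - phi_k| / (n_vox * pi)`.
#' Genomes of the `"evo"` treatment, and any genome passed through
#' [remove_development()], have both windows exactly 0.
#'
#' @param genome A `voxdev_genome`.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' window_morph(random_genome(grid_spec(), "evo", seed = 1))  # 0
window_morph <- function(genome) {
  grid <- genome$grid
  d <- abs(genome$ell_final - genome$ell_start)
  sum(d[mirror_source(grid)]) / (grid$n_vox * (ELL_MAX - ELL_MIN))
}

#' @rdname window_morph
#' @export
window_ctrl <- function(genome) {
  grid <- genome$grid
  sum(abs(genome$phi_final - genome$phi_start)) /
    (grid$n_vox * (PHI_MAX - PHI_MIN))
}

#' Trace the ancestor chain of a run champion
#'
#' Follows parent links back from the champion through the trial history to
#' the initial or injected ancestor that founded the lineage.
#'
#' @param trial A `voxdev_trial` from [run_trial()], or a history tibble.
#' @param champion_uid Champion uid; defaults to the trial's champion.
#' @return A tibble ordered from the most distant ancestor (evolutionary
#'   time `T = 0`) to the run champion, with columns `uid`, `generation`
#'   (first generation logged), `fitness`, `W_L`, `W_Phi`.
#' @export
trace_lineage <- function(trial, champion_uid = NULL) {
  history <- if (inherits(trial, "voxdev_trial")) trial$history else trial
  if (is.null(champion_uid)) {
    if (!inherits(trial, "voxdev_trial"))
      stop("champion_uid is required when passing a bare history")
    champion_uid <- trial$champion$uid
  }
  first <- history[!duplicated(history$uid), ]
  rows <- list()
  uid <- champion_uid
  seen <- integer(0)
  while (!is.na(uid)) {
    if (uid %in% seen) stop("cycle in parent links at uid ", uid)
    seen <- c(seen, uid)
    row <- first[first$uid == uid, ]
    if (nrow(row) != 1)
      stop("broken parent link: uid ", uid, " not found in history")
    rows[[length(rows) + 1]] <- row
    uid <- row$parent_uid
  }
  chain <- do.call(rbind, rev(rows))
  tibble::tibble(uid = chain$uid, generation = chain$generation,
                 fitness = chain$fitness, W_L = chain$W_L,
                 W_Phi = chain$W_Phi)
}

#' Mutation-robustness random walk
#'
#' Starting from a champion genome, applies a series of random mutations
#' restricted to one subsystem — `"control"` (phase offsets) or
#' `"morphology"` (resting lengths) — re-evaluating fitness after every
#' step.  Steps are cumulative (a Brownian trajectory in the chosen
#' subsystem's space); per-voxel mutation rates are frozen during walks so
#' that only subsystem sensitivity is probed.  The walk is repeated
#' `n_walks` times from the unmutated champion, each with its own derived
#' seed.
#'
#' @param genome Champion `voxdev_genome`.
#' @param kind `"control"` or `"morphology"`.
#' @param n_steps Mutations per walk (1000 at full scale).
#' @param n_walks Independent walks (10 at full scale).
#' @param mut A [mutation_params()].
#' @param devo_cfg,phys_cfg,record_interval Simulation settings.
#' @param seed Master seed; walk `w` uses `derive_seed(seed, "walk-w")`.
#' @return A list of class `voxdev_walk`: `kind`, `fitness` (an
#'   `n_walks x (n_steps + 1)` matrix whose first column is the unmutated
#'   champion's fitness), `seeds`.
#' @export
robustness_walk <- function(genome, kind = c("control", "morphology"),
                            n_steps = 1000L, n_walks = 10L,
                            mut = mutation_params(),
                            devo_cfg = devo_config(),
                            phys_cfg = physics_config(),
                            record_interval = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  types <- intersect(
    if (kind == "control") c("phi", "phi_final") else c("ell", "ell_final"),
    applicable_types(genome$treatment))
  eval_fit <- function(g) {
    tryCatch(fitness_from_trajectory(
      simulate_robot(g, devo_cfg, phys_cfg, record_interval)),
      error = function(e) 0)
  }
  base_fit <- eval_fit(genome)
  seeds <- vapply(seq_len(n_walks),
                  function(w) derive_seed(seed, paste0("walk-", w)),
                  integer(1))
  fit <- matrix(NA_real_, n_walks, n_steps + 1L)
  fit[, 1] <- base_fit
  for (w in seq_len(n_walks)) {
    with_seed(seeds[w], {
      g <- genome
      for (s in seq_len(n_steps)) {
        g <- mutate_genome(g, mut, types = types, adapt_rates = FALSE)
        fit[w, s + 1L] <- eval_fit(g)
      }
    })
  }
  structure(list(kind = kind, fitness = fit, seeds = seeds),
            class = "voxdev_walk")
}

#' Rollover onset along a lineage
#'
#' Re-simulates every ancestor in a lineage and measures the ontogenetic
#' time before rolling over ([detect_rollover()]): the heterochrony
#' analysis showing that descendants of the first roller tend to roll ever
#' earlier in life.
#'
#' @param lineage A lineage tibble from [trace_lineage()].
#' @param genomes Genome archive (environment keyed by uid) from the trial.
#' @param devo_cfg,phys_cfg,record_interval Simulation settings.
#' @param contact_eps Rollover contact threshold, cm.
#' @return The lineage tibble with an added `rollover_time` column
#'   (seconds; `NA` where the robot never rolls).
#' @export
rollover_onset_series <- function(lineage, genomes,
                                  devo_cfg = devo_config(),
                                  phys_cfg = physics_config(),
                                  record_interval = 0.01,
                                  contact_eps = phys_cfg$contact_eps) {
  lineage$rollover_time <- vapply(lineage$uid, function(uid) {
    g <- genomes[[as.character(uid)]]
    if (is.null(g)) return(NA_real_)
    traj <- tryCatch(simulate_robot(g, devo_cfg, phys_cfg, record_interval),
                     error = function(e) NULL)
    if (is.null(traj)) return(NA_real_)
    detect_rollover(traj, contact_eps)
  }, numeric(1))
  lineage
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  The U statistic is computed from midranks (so
#' ties contribute 1/2).  For small samples (both sizes <= 8) the p-value
#' is exact, from complete enumeration of the group assignments of the
#' pooled values; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   default chooses by sample size.
#' @return A list with `U` (for `a` versus `b`), `p_value`, `n1`, `n2`,
#'   `exact`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U  # 0
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- (n1 <= 8 && n2 <= 8)
  if (exact) {
    assignments <- combn(N, n1)
    stats <- apply(assignments, 2,
                   function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(stats <= U), mean(stats >= U)))
  } else {
    mu <- n1 * n2 / 2
    tie_counts <- table(pooled)
    tie_corr <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      if (U == mu) z <- 0
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = U, p_value = p, n1 = n1, n2 = n2, exact = exact)
}

#' Summarize canalization across lineages
#'
#' Tabulates, per lineage, the window statistics tested in the
#' canalization analysis: the starting, maximum and final morphological
#' and controller windows along evolutionary time, plus the champion's
#' fitness.  Rising-then-falling `W_L` with persistently drifting `W_Phi`
#' is the differential-canalization signature; the tabulated columns feed
#' directly into [mann_whitney_u()] (e.g. start vs max window, champion vs
#' most-distant-ancestor window).
#'
#' @param lineages A list of lineage tibbles from [trace_lineage()].
#' @return A tibble with one row per lineage.
#' @export
canalization_summary <- function(lineages) {
  stopifnot(length(lineages) >= 1)
  rows <- lapply(seq_along(lineages), function(i) {
    ln <- lineages[[i]]
    n <- nrow(ln)
    tibble::tibble(
      trial = i, chain_length = n,
      W_L_start = ln$W_L[1], W_L_max = max(ln$W_L), W_L_final = ln$W_L[n],
      W_Phi_start = ln$W_Phi[1], W_Phi_max = max(ln$W_Phi),
      W_Phi_final = ln$W_Phi[n],
      fitness_start = ln$fitness[1], fitness_final = ln$fitness[n])
  })
  do.call(rbind, rows)
}

#' Development-removal experiment
#'
#' Converts each trial's champion into a non-developing robot by
#' [remove_development()] (final values set equal to start values), then
#' re-simulates it.  The reduced robots have both developmental windows
#' exactly 0 and a birth phenotype identical to the original's, so any
#' fitness change isolates the behavioral (as opposed to search-time)
#' contribution of development.
#'
#' @param trials A list of `voxdev_trial` objects.
#' @return A tibble with one row per trial: original and reduced champion
#'   fitness, the retained fraction, and the original windows.
#' @export
remove_devo_experiment <- function(trials) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    champ <- tr$champion
    reduced <- remove_development(champ$genome)
    fit_removed <- tryCatch(fitness_from_trajectory(
      simulate_robot(reduced, tr$cfg$devo_cfg, tr$cfg$phys_cfg,
                     tr$cfg$record_interval)),
      error = function(e) 0)
    tibble::tibble(
      trial = i, seed = tr$seed, treatment = tr$cfg$treatment,
      fitness = champ$fitness, fitness_removed = fit_removed,
      retained = if (champ$fitness > 0) fit_removed / champ$fitness
                 else NA_real_,
      W_L = window_morph(champ$genome), W_Phi = window_ctrl(champ$genome))
  })
  do.call(rbind, rows)
}
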