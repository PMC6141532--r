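#' Experiment configuration
#'
#' Assembles and validates the full configuration of an experiment: grid,
#' development, physics, mutation and evolution settings plus the list of
#' trial seeds.  A run is reproducible from the configuration and seeds
#' alone.  The defaults are the reference conditions: a 4 x 4 x 3 grid of
#' 1 cm voxels, lifetime 10 s (40 cycles at 4 Hz), amplitude 0.14 cm,
#' population 30.
#'
#' The hard phenotypic bounds (resting lengths 0.25-1.75 cm, phase offsets
#' `[-pi/2, pi/2]`) are constants of the model, not knobs: a configuration
#' that states different bounds is rejected.
#'
#' @param grid,devo_cfg,phys_cfg,mut Component configurations.
#' @param treatment `"evo"` or `"evodevo"`.
#' @param pop_size,generations Evolution settings.
#' @param seeds Integer vector of trial seeds.
#' @param record_interval Trajectory sampling interval, seconds.
#' @return An object of class `voxdev_experiment_config`.
#' @export
experiment_config <- function(grid = grid_spec(),
                              devo_cfg = devo_config(),
                              phys_cfg = physics_config(),
                              mut = mutation_params(),
                              treatment = c("evodevo", "evo"),
                              pop_size = 30L, generations = 100L,
                              seeds = 1L, record_interval = 0.01) {
  treatment <- match.arg(treatment)
  structure(list(grid = grid, devo_cfg = devo_cfg, phys_cfg = phys_cfg,
                 mut = mut, treatment = treatment,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 seeds = as.integer(seeds),
                 record_interval = record_interval),
            class = "voxdev_experiment_config")
}

as_evo_config <- function(cfg) {
  evo_config(grid = cfg$grid, treatment = cfg$treatment,
             pop_size = cfg$pop_size, generations = cfg$generations,
             mut = cfg$mut, devo_cfg = cfg$devo_cfg,
             phys_cfg = cfg$phys_cfg, record_interval = cfg$record_interval)
}

config_schema <- list(
  grid = c("nx", "ny", "nz", "voxel_size"),
  devo = c("amplitude", "freq", "n_cycles"),
  physics = c("dt", "spring_k", "bend_k", "damping_c", "gravity",
              "ground_k", "ground_c", "mu", "slip_eps", "particle_mass",
              "contact_eps"),
  mutation = c("sigma_ell", "sigma_phi", "meta_step", "fixed_rate",
               "type_prob"),
  evolution = c("treatment", "pop_size", "generations"),
  bounds = c("ell", "phi"),
  top = c("grid", "devo", "physics", "mutation", "evolution", "bounds",
          "seeds", "record_interval")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")))
}

#' Save / load an experiment configuration as YAML
#'
#' Configurations serialize to a nested YAML document (`grid:`, `devo:`,
#' `physics:`, `mutation:`, `evolution:`, `seeds:`, `record_interval:`).
#' Loading fills every omitted key with the reference default, rejects
#' unknown keys, and validates values — in particular, any stated
#' phenotypic `bounds` must equal the model's hard bounds.  A minimal file
#' containing only `seeds:` therefore yields the full reference
#' configuration.
#'
#' @param cfg A [experiment_config()].
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the validated `voxdev_experiment_config`.
#' @export
save_config <- function(cfg, path) {
  obj <- list(
    grid = cfg$grid[c("nx", "ny", "nz", "voxel_size")],
    devo = cfg$devo_cfg[c("amplitude", "freq", "n_cycles")],
    physics = unclass(cfg$phys_cfg),
    mutation = Filter(Negate(is.null),
                      cfg$mut[c("sigma_ell", "sigma_phi", "meta_step",
                                "fixed_rate", "type_prob")]),
    evolution = list(treatment = cfg$treatment, pop_size = cfg$pop_size,
                     generations = cfg$generations),
    seeds = cfg$seeds,
    record_interval = cfg$record_interval)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  obj <- yaml::read_yaml(path)
  check_keys(obj, config_schema$top, "configuration")
  for (section in c("grid", "devo", "physics", "mutation", "evolution",
                    "bounds"))
    if (!is.null(obj[[section]]))
      check_keys(obj[[section]], config_schema[[section]], section)

  if (!is.null(obj$bounds)) {
    canonical <- voxdev_bounds()
    for (nm in names(obj$bounds)) {
      if (!isTRUE(all.equal(as.numeric(obj$bounds[[nm]]), canonical[[nm]])))
        stop(sprintf(
          "bounds.%s = [%s] conflicts with the model's hard bounds [%s]",
          nm, paste(obj$bounds[[nm]], collapse = ", "),
          paste(signif(canonical[[nm]], 6), collapse = ", ")))
    }
  }

  grid <- do.call(grid_spec, modifyList(
    list(nx = 4L, ny = 4L, nz = 3L, voxel_size = 1.0),
    as.list(obj$grid %||% list())))
  devo <- do.call(devo_config, as.list(obj$devo %||% list()))
  phys <- do.call(physics_config, as.list(obj$physics %||% list()))
  mut <- do.call(mutation_params, as.list(obj$mutation %||% list()))
  evo <- modifyList(list(treatment = "evodevo", pop_size = 30L,
                         generations = 100L),
                    as.list(obj$evolution %||% list()))
  experiment_config(grid = grid, devo_cfg = devo, phys_cfg = phys,
                    mut = mut, treatment = evo$treatment,
                    pop_size = evo$pop_size, generations = evo$generations,
                    seeds = obj$seeds %||% 1L,
                    record_interval = obj$record_interval %||% 0.01)
}

#' Deterministic test-fixture genomes
#'
#' A small suite of hand-constructed robots with known qualitative
#' behavior:
#' * `"static"` — uniform 1 cm voxels, zero phases, non-developing; with
#'   zero amplitude it stands still (fitness ~ 0) and both windows are 0.
#' * `"oscillator"` — a 2 x 1 x 1 two-particle body feeding the
#'   harmonic-oscillator closed-form check of the integrator.
#' * `"shuffler"` — uniform morphology with a phase ramp along the travel
#'   axis (mirror-symmetric in x), which breaks fore-aft symmetry and
#'   produces net displacement.
#' * `"devo-max"` — maximal morphological development: every voxel grows
#'   from 0.25 cm to 1.75 cm (`W_L = 1`).
#'
#' @param name Fixture name.
#' @param grid Optional [grid_spec()] override (the oscillator fixes its
#'   own 2 x 1 x 1 grid).
#' @return A `voxdev_genome`.
#' @export
make_fixture <- function(name = c("static", "oscillator", "shuffler",
                                  "devo-max"),
                         grid = NULL) {
  name <- match.arg(name)
  if (name == "oscillator") grid <- grid_spec(2L, 1L, 1L)
  if (is.null(grid)) grid <- grid_spec()
  ones <- rep(1.0, grid$n_left)
  zeros <- rep(0.0, grid$n_vox)
  rates <- rep(1 / grid$n_vox, grid$n_vox)
  switch(name,
    "static" = ,
    "oscillator" = new_genome(grid, "evo", ones, ones, zeros, zeros, rates),
    "shuffler" = {
      co <- voxel_coords(seq_len(grid$n_vox), grid)
      ramp <- if (grid$ny > 1) co[, "y"] / (grid$ny - 1) else rep(0.5, grid$n_vox)
      phi <- PHI_MIN + ramp * (PHI_MAX - PHI_MIN)
      new_genome(grid, "evo", ones, ones, phi, phi, rates)
    },
    "devo-max" = new_genome(grid, "evodevo",
                            rep(ELL_MIN, grid$n_left),
                            rep(ELL_MAX, grid$n_left),
                            zeros, zeros, rates))
}

history_schema <- "voxdevo-history-1"

#' Write / read a trial history CSV
#'
#' The first line carries the column-schema version (`#voxdevo-history-1`)
#' so the analysis stage can validate files before parsing.
#'
#' @param history History tibble from [run_trial()].
#' @param path File path.
#' @return `write_history` returns `path` invisibly; `read_history` the
#'   tibble.
#' @export
write_history <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", history_schema), con)
  write.csv(as.data.frame(history), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("#", history_schema)))
    stop("unrecognized history schema in ", path, ": ", first)
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}

#' Run a full experiment
#'
#' Runs one evolutionary trial per seed in the configuration, writing per
#' seed a history CSV and a champion genome JSON, and finally a manifest
#' listing every output file with its MD5 content hash.  Existing per-seed
#' outputs are reused (resume); a directory with a complete manifest is
#' not overwritten unless `overwrite = TRUE`.
#'
#' @param cfg A [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Re-run and replace existing outputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of `voxdev_trial` objects (`NULL` for seeds
#'   resumed from disk without re-running).
#' @export
run_experiment <- function(cfg, out_dir, overwrite = FALSE, quiet = TRUE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("output directory already contains a completed experiment ",
         "(manifest.json); use overwrite = TRUE to replace it")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path)

  trials <- list()
  files <- "config.yaml"
  for (seed in cfg$seeds) {
    hist_file <- sprintf("history_seed%d.csv", seed)
    champ_file <- sprintf("champion_seed%d.json", seed)
    files <- c(files, hist_file, champ_file)
    hist_path <- file.path(out_dir, hist_file)
    champ_path <- file.path(out_dir, champ_file)
    if (!overwrite && file.exists(hist_path) && file.exists(champ_path)) {
      if (!quiet) message("seed ", seed, ": reusing existing outputs")
      trials[as.character(seed)] <- list(NULL)
      next
    }
    if (!quiet) message("seed ", seed, ": running trial")
    trial <- run_trial(as_evo_config(cfg), seed = seed, quiet = quiet)
    write_history(trial$history, hist_path)
    write_genome(trial$champion$genome, champ_path,
                 seed_info = list(seed = seed,
                                  champion_uid = trial$champion$uid,
                                  fitness = trial$champion$fitness))
    trials[[as.character(seed)]] <- trial
  }

  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  jsonlite::write_json(
    list(format = "voxdevo-manifest-1",
         package_version = as.character(utils::packageVersion("voxdevo")),
         r_version = R.version.string,
         seeds = cfg$seeds, files = hashes),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(trials)
}
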