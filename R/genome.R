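#' Mutation operator settings
#'
#' Mutations perturb selected parameters with Gaussian noise
#' (`sigma_ell = 0.75` cm for resting lengths, `sigma_phi = pi/2` rad for
#' phase offsets) and are applied in two stages: first the parameter *types*
#' to mutate are selected (each applicable type independently with
#' probability `type_prob`), then for each selected type the voxels to
#' mutate are chosen by per-voxel Bernoulli draws with the genome's evolved
#' rates.  Per-voxel rates are themselves slightly modified (log-normal
#' multiplicative steps of size `meta_step`) every time a genotype is
#' copied, unless a `fixed_rate` overrides self-adaptation.
#'
#' @param sigma_ell Perturbation s.d. for resting lengths, cm.
#' @param sigma_phi Perturbation s.d. for phase offsets, radians.
#' @param meta_step S.d. of the log-normal multiplicative rate step.
#' @param fixed_rate Optional fixed per-voxel mutation probability in
#'   `(0, 1]`; when set, self-adaptation is disabled.
#' @param type_prob Probability that each applicable parameter type is
#'   selected for mutation.
#' @return An object of class `voxdev_mutation_params`.
#' @export
mutation_params <- function(sigma_ell = 0.75, sigma_phi = pi / 2,
                            meta_step = 0.1, fixed_rate = NULL,
                            type_prob = 0.5) {
  stopifnot(sigma_ell > 0, sigma_phi > 0, meta_step >= 0,
            type_prob > 0, type_prob <= 1)
  if (!is.null(fixed_rate))
    stopifnot(fixed_rate > 0, fixed_rate <= 1)
  structure(list(sigma_ell = sigma_ell, sigma_phi = sigma_phi,
                 meta_step = meta_step, fixed_rate = fixed_rate,
                 type_prob = type_prob),
            class = "voxdev_mutation_params")
}

new_genome <- function(grid, treatment, ell_start, ell_final,
                       phi_start, phi_final, rates) {
  g <- structure(list(
    grid = grid, treatment = treatment,
    ell_start = ell_start, ell_final = ell_final,
    phi_start = phi_start, phi_final = phi_final,
    rates = rates
  ), class = "voxdev_genome")
  validate_genome(g)
  g
}

#' Validate a genome's invariants
#'
#' Checks vector lengths, hard phenotypic bounds, rate bounds, and (for the
#' non-developmental treatment) that final values equal start values.
#'
#' @param genome A `voxdev_genome`.
#' @return The genome, invisibly; errors describe the violated invariant.
#' @export
validate_genome <- function(genome) {
  grid <- genome$grid
  stopifnot(inherits(grid, "voxdev_grid"))
  if (!genome$treatment %in% c("evo", "evodevo"))
    stop("treatment must be 'evo' or 'evodevo'")
  if (length(genome$ell_start) != grid$n_left ||
      length(genome$ell_final) != grid$n_left)
    stop("resting-length vectors must have one entry per lefthand site")
  if (length(genome$phi_start) != grid$n_vox ||
      length(genome$phi_final) != grid$n_vox)
    stop("phase-offset vectors must have one entry per voxel")
  if (length(genome$rates) != grid$n_vox)
    stop("one mutation rate per voxel is required")
  ell <- c(genome$ell_start, genome$ell_final)
  phi <- c(genome$phi_start, genome$phi_final)
  if (any(ell < ELL_MIN) || any(ell > ELL_MAX))
    stop(sprintf("resting lengths must lie in [%.2f, %.2f] cm", ELL_MIN, ELL_MAX))
  if (any(phi < PHI_MIN) || any(phi > PHI_MAX))
    stop("phase offsets must lie in [-pi/2, pi/2]")
  if (any(genome$rates <= 0) || any(genome$rates > 1))
    stop("mutation rates must lie in (0, 1]")
  if (genome$treatment == "evo" &&
      (!identical(genome$ell_final, genome$ell_start) ||
       !identical(genome$phi_final, genome$phi_start)))
    stop("evo genomes must have final values identical to start values")
  invisible(genome)
}

#' Draw a random genome
#'
#' Every parameter is drawn uniformly over its legal interval (resting
#' lengths over `[0.25, 1.75]` cm, phase offsets over `[-pi/2, pi/2]`).
#' Under the `"evo"` treatment final values are set equal to start values,
#' so the genome encodes a static phenotype.  Per-voxel mutation rates are
#' initialized to `1/n_vox` so that a single voxel is mutated on average.
#'
#' @param grid A [grid_spec()].
#' @param treatment `"evo"` (static phenotype) or `"evodevo"` (ballistic
#'   development from start to final values).
#' @param seed Optional integer seed for a reproducible draw.
#' @return A `voxdev_genome`.
#' @export
#' @examples
#' g <- random_genome(grid_spec(), "evodevo", seed = 1)
#' range(g$ell_start)
random_genome <- function(grid, treatment = c("evodevo", "evo"), seed = NULL) {
  treatment <- match.arg(treatment)
  with_seed(seed, {
    ell_start <- runif(grid$n_left, ELL_MIN, ELL_MAX)
    phi_start <- runif(grid$n_vox, PHI_MIN, PHI_MAX)
    if (treatment == "evodevo") {
      ell_final <- runif(grid$n_left, ELL_MIN, ELL_MAX)
      phi_final <- runif(grid$n_vox, PHI_MIN, PHI_MAX)
    } else {
      ell_final <- ell_start
      phi_final <- phi_start
    }
    new_genome(grid, treatment, ell_start, ell_final, phi_start, phi_final,
               rates = rep(1 / grid$n_vox, grid$n_vox))
  })
}

# Parameter types that mutation may touch, per treatment.  Under "evo" the
# final vectors are slaved to the start vectors and are not independent
# targets.
applicable_types <- function(treatment) {
  if (treatment == "evo") c("ell", "phi")
  else c("ell", "ell_final", "phi", "phi_final")
}

type_field <- c(ell = "ell_start", ell_final = "ell_final",
                phi = "phi_start", phi_final = "phi_final")

# Per-site selection rates and Gaussian sigma/bounds for one type.
type_info <- function(type, genome, params) {
  grid <- genome$grid
  if (startsWith(type, "ell")) {
    list(rates = genome$rates[left_indices(grid)],
         sigma = params$sigma_ell, lo = ELL_MIN, hi = ELL_MAX)
  } else {
    list(rates = genome$rates,
         sigma = params$sigma_phi, lo = PHI_MIN, hi = PHI_MAX)
  }
}

#' Mutate a genome
#'
#' Produces a mutated copy.  Per-voxel mutation rates are perturbed first
#' (self-adaptation on copy), then parameter types are selected, then voxels
#' within each selected type; selected sites receive Gaussian perturbations
#' clipped to the hard bounds.  Whole draws that change nothing are
#' resampled so the child always differs from the parent in at least one
#' parameter.  Morphology mutations act on the independent lefthand sites
#' only (the righthand side remains the mirror image); under the `"evo"`
#' treatment final vectors are kept identical to start vectors.
#'
#' @param genome Parent `voxdev_genome`.
#' @param params A [mutation_params()].
#' @param seed Optional integer seed.
#' @param types Optional subset of parameter types to restrict mutation to
#'   (`"ell"`, `"ell_final"`, `"phi"`, `"phi_final"`); used e.g. by
#'   [robustness_walk()] to confine mutations to one subsystem.
#' @param adapt_rates Perturb the per-voxel rates on copy (default `TRUE`;
#'   robustness walks freeze them).
#' @param max_retries Zero-effect draws are resampled at most this many
#'   times before one random site is forced to change.
#' @return The child `voxdev_genome`.
#' @export
mutate_genome <- function(genome, params = mutation_params(), seed = NULL,
                          types = NULL, adapt_rates = TRUE,
                          max_retries = 100L) {
  validate_genome(genome)
  pool <- applicable_types(genome$treatment)
  if (!is.null(types)) {
    bad <- setdiff(types, pool)
    if (length(bad))
      stop("types not applicable to this treatment: ",
           paste(bad, collapse = ", "))
    pool <- types
  }
  with_seed(seed, {
    child <- genome
    n_vox <- genome$grid$n_vox
    if (!is.null(params$fixed_rate)) {
      child$rates <- rep(params$fixed_rate, n_vox)
    } else if (adapt_rates) {
      child$rates <- pmin(1, pmax(1 / (10 * n_vox),
        genome$rates * exp(rnorm(n_vox) * params$meta_step)))
    }

    try_draw <- function() {
      sel <- runif(length(pool)) < params$type_prob
      if (!any(sel)) return(NULL)
      prop <- child
      changed <- FALSE
      for (type in pool[sel]) {
        info <- type_info(type, child, params)
        field <- type_field[[type]]
        mask <- runif(length(info$rates)) < info$rates
        if (!any(mask)) next
        v <- prop[[field]]
        v[mask] <- pmin(info$hi, pmax(info$lo,
          v[mask] + rnorm(sum(mask)) * info$sigma))
        if (any(v != prop[[field]])) changed <- TRUE
        prop[[field]] <- v
      }
      if (changed) prop else NULL
    }

    out <- NULL
    for (i in seq_len(max_retries)) {
      out <- try_draw()
      if (!is.null(out)) break
    }
    if (is.null(out)) {
      # Degenerate rates/bounds: force exactly one random site to change.
      out <- child
      type <- sample(pool, 1L)
      info <- type_info(type, child, params)
      field <- type_field[[type]]
      site <- sample.int(length(info$rates), 1L)
      v <- out[[field]]
      repeat {
        cand <- min(info$hi, max(info$lo, v[site] + rnorm(1L) * info$sigma))
        if (cand != v[site]) break
      }
      v[site] <- cand
      out[[field]] <- v
    }

    if (out$treatment == "evo") {
      out$ell_final <- out$ell_start
      out$phi_final <- out$phi_start
    }
    validate_genome(out)
    out
  })
}

#' Remove development from a genome
#'
#' Sets every final value equal to its start value, freezing the phenotype
#' at its birth (`t = 0`) configuration.  The operation is idempotent and
#' leaves both developmental windows ([window_morph()], [window_ctrl()])
#' exactly zero; genomes of the `"evo"` treatment are fixed points.  The
#' treatment tag is preserved so reduced robots remain distinguishable in
#' logs.
#'
#' @param genome A `voxdev_genome`.
#' @return The reduced genome.
#' @export
remove_development <- function(genome) {
  genome$ell_final <- genome$ell_start
  genome$phi_final <- genome$phi_start
  genome
}

#' Count a genome's free parameters
#'
#' Degrees-of-freedom accounting: an `"evo"` genome on the default grid has
#' 24 morphological + 48 control parameters; an `"evodevo"` genome doubles
#' both (48 + 96) because start and final values evolve independently.
#' Per-voxel mutation rates are strategy parameters and are not counted.
#'
#' @param genome A `voxdev_genome`.
#' @return A list with `morphology`, `control` and `total` counts.
#' @export
n_free_parameters <- function(genome) {
  grid <- genome$grid
  mult <- if (genome$treatment == "evodevo") 2L else 1L
  list(morphology = mult * grid$n_left,
       control = mult * grid$n_vox,
       total = mult * (grid$n_left + grid$n_vox))
}

# Hash of the phenotype-determining parameters (rates excluded): the
# evaluation cache key.
genome_hash <- function(genome) {
  rlang::hash(list(genome$treatment,
                   genome$grid$nx, genome$grid$ny, genome$grid$nz,
                   genome$grid$voxel_size,
                   genome$ell_start, genome$ell_final,
                   genome$phi_start, genome$phi_final))
}

#' @export
print.voxdev_genome <- function(x, ...) {
  p <- n_free_parameters(x)
  cat(sprintf("<voxdev_genome> %s, %dx%dx%d grid, %d free parameters (W_L=%.3f, W_Phi=%.3f)\n",
              x$treatment, x$grid$nx, x$grid$ny, x$grid$nz, p$total,
              window_morph(x), window_ctrl(x)))
  invisible(x)
}

#' Write / read a genome as JSON
#'
#' Genomes serialize to JSON with explicit field names, grid shape and
#' treatment tag; numeric values round-trip bit-exactly.
#'
#' @param genome A `voxdev_genome`.
#' @param path File path.
#' @param seed_info Optional provenance (e.g. the seed that produced the
#'   genome) stored alongside the values.
#' @return `write_genome` returns `path` invisibly; `read_genome` returns
#'   the genome.
#' @export
write_genome <- function(genome, path, seed_info = NULL) {
  validate_genome(genome)
  num <- function(v) sprintf("%.17g", v)
  obj <- list(
    format = "voxdevo-genome-1",
    grid = list(nx = genome$grid$nx, ny = genome$grid$ny, nz = genome$grid$nz,
                voxel_size = num(genome$grid$voxel_size)),
    treatment = genome$treatment,
    ell_start = num(genome$ell_start),
    ell_final = num(genome$ell_final),
    phi_start = num(genome$phi_start),
    phi_final = num(genome$phi_final),
    rates = num(genome$rates)
  )
  if (!is.null(seed_info)) obj$seed_info <- seed_info
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "voxdevo-genome-1"))
    stop("not a voxdevo genome file: ", path)
  grid <- grid_spec(obj$grid$nx, obj$grid$ny, obj$grid$nz,
                    as.numeric(obj$grid$voxel_size))
  new_genome(grid, obj$treatment,
             as.numeric(obj$ell_start), as.numeric(obj$ell_final),
             as.numeric(obj$phi_start), as.numeric(obj$phi_final),
             as.numeric(obj$rates))
}
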