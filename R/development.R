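#' Development / actuation configuration
#'
#' The lifetime is `n_cycles` actuation cycles at frequency `freq`:
#' 40 cycles at 4 Hz give the default 10-second lifetime `tau`.  A global
#' sinusoidal signal of amplitude `amplitude` (0.14 cm) actuates every
#' voxel, each with its own (possibly developing) phase offset.
#'
#' @param amplitude Actuation amplitude `A`, cm.
#' @param freq Actuation frequency `f`, Hz.
#' @param n_cycles Actuation cycles per lifetime.
#' @return An object of class `voxdev_devo_config` with fields `tau`
#'   (seconds), `amplitude`, `freq`, `n_cycles`.
#' @export
#' @examples
#' devo_config()$tau  # 10
devo_config <- function(amplitude = 0.14, freq = 4, n_cycles = 40) {
  stopifnot(amplitude >= 0, freq > 0, n_cycles > 0)
  structure(list(tau = n_cycles / freq, amplitude = amplitude,
                 freq = freq, n_cycles = n_cycles),
            class = "voxdev_devo_config")
}

#' Ballistic (linear) development
#'
#' A developing parameter moves linearly from its start value `a` at birth
#' to its final value `b` at the end of life `tau`:
#' `a + t * (b - a) / tau`.  Development is open-loop, monotone and
#' irreversible; with `a == b` it degenerates to the constant `a` (the
#' static, non-developmental phenotype).
#'
#' @param a Start value(s).
#' @param b Final value(s), same length as `a` (or either scalar).
#' @param t Ontogenetic time, seconds, in `[0, tau]`.
#' @param tau Lifetime, seconds.
#' @return The interpolated value(s).
#' @export
#' @examples
#' ballistic(0.25, 1.75, t = 5, tau = 10)  # 1.0
ballistic <- function(a, b, t, tau) {
  stopifnot(tau > 0)
  if (any(t < 0) || any(t > tau))
    stop(sprintf("ontogenetic time must lie in [0, %g] s", tau))
  a + t * (b - a) / tau
}

#' Actuation damping factor
#'
#' Small voxels are actuated less to keep the simulation stable: amplitude
#' is scaled by `min(1, (4 x - 1) / 3)` where `x` is the (developing)
#' resting length in cm.  The factor is 1 for `x >= 1` cm and falls
#' linearly to 0 at the lower bound `x = 0.25` cm (no actuation).
#'
#' @param x Resting length(s), cm, in `[0.25, 1.75]`.
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @export
#' @examples
#' damping_factor(c(0.25, 0.625, 1, 1.75))  # 0, 0.5, 1, 1
damping_factor <- function(x) {
  pmin(1, (4 * x - 1) / 3)
}

#' Voxel actuation displacement
#'
#' The displacement of voxel `k` at time `t`:
#' `psi_k(t) = A * sin(2 pi f t + B(phi_k, phi*_k)) * xi(B(ell_k, ell*_k))`
#' where `B` is the ballistic interpolant of the developing phase offset /
#' resting length and `xi` the [damping_factor()].  `|psi| <= A` always.
#'
#' @param genome A `voxdev_genome`.
#' @param t Time, seconds, in `[0, tau]` (scalar).
#' @param cfg A [devo_config()].
#' @param k Voxel indices (1-based, full grid); default all voxels.
#' @return Displacements in cm, one per requested voxel.
#' @export
actuation <- function(genome, t, cfg = devo_config(), k = NULL) {
  grid <- genome$grid
  if (is.null(k)) k <- seq_len(grid$n_vox)
  src <- mirror_source(grid)[k]
  phi_t <- ballistic(genome$phi_start[k], genome$phi_final[k], t, cfg$tau)
  ell_t <- ballistic(genome$ell_start[src], genome$ell_final[src], t, cfg$tau)
  cfg$amplitude * sin(2 * pi * cfg$freq * t + phi_t) * damping_factor(ell_t)
}

#' Current (instantaneous) voxel length
#'
#' The resting length of voxel `k` at time `t` is its developing resting
#' length plus the damped actuation signal:
#' `L_k(t) = B(ell_k, ell*_k, t) + psi_k(t)`.  For an `"evo"` genome the
#' resting-length term is constant, so the expression collapses to
#' `ell_k + psi_k(t)`.
#'
#' @inheritParams actuation
#' @return Current lengths in cm, one per requested voxel.
#' @export
current_length <- function(genome, t, cfg = devo_config(), k = NULL) {
  grid <- genome$grid
  if (is.null(k)) k <- seq_len(grid$n_vox)
  src <- mirror_source(grid)[k]
  ell_t <- ballistic(genome$ell_start[src], genome$ell_final[src], t, cfg$tau)
  ell_t + actuation(genome, t, cfg, k)
}
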