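#' Voxel grid specification
#'
#' Defines the cartesian voxel lattice the robot is built from.  The default
#' is the 4 x 4 x 3 grid of 1 cm voxels used throughout: `nx` spans the
#' left-right axis (split by the midsagittal mirror plane), `ny` the travel
#' axis, and `nz` the vertical axis.  One body length equals four undeformed
#' voxels (4 cm) and is the fitness unit.
#'
#' @param nx,ny,nz Voxel counts along the left-right, travel and vertical
#'   axes.  All must be >= 1.
#' @param voxel_size Undeformed voxel edge length in cm.
#' @return An object of class `voxdev_grid` with fields `nx`, `ny`, `nz`,
#'   `voxel_size`, `n_vox`, `n_left` (independent morphology sites on or left
#'   of the mirror plane) and `body_length` (4 voxels, cm).
#' @export
#' @examples
#' g <- grid_spec()
#' g$n_vox    # 48
#' g$n_left   # 24
grid_spec <- function(nx = 4L, ny = 4L, nz = 3L, voxel_size = 1.0) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  stopifnot(nx >= 1, ny >= 1, nz >= 1, voxel_size > 0)
  structure(list(
    nx = nx, ny = ny, nz = nz,
    voxel_size = voxel_size,
    n_vox = nx * ny * nz,
    n_left = ((nx + 1L) %/% 2L) * ny * nz,
    body_length = 4 * voxel_size
  ), class = "voxdev_grid")
}

#' @export
print.voxdev_grid <- function(x, ...) {
  cat(sprintf("<voxdev_grid> %d x %d x %d (%d voxels, %d mirror-independent sites), voxel %.3g cm\n",
              x$nx, x$ny, x$nz, x$n_vox, x$n_left, x$voxel_size))
  invisible(x)
}

# 1-based linear voxel index for 0-based lattice coordinates; x varies
# fastest, then y, then z.
voxel_index <- function(x, y, z, grid) {
  1L + x + grid$nx * (y + grid$ny * z)
}

# 0-based (x, y, z) coordinates for 1-based linear indices.
voxel_coords <- function(k, grid) {
  k0 <- k - 1L
  cbind(x = k0 %% grid$nx,
        y = (k0 %/% grid$nx) %% grid$ny,
        z = k0 %/% (grid$nx * grid$ny))
}

# Linear indices (into the full grid) of the independent lefthand sites:
# columns x < ceiling(nx/2).  For odd nx the middle column sits on the
# mirror plane and is its own image.
left_indices <- function(grid) {
  co <- voxel_coords(seq_len(grid$n_vox), grid)
  which(co[, "x"] < (grid$nx + 1L) %/% 2L)
}

# For each full-grid voxel, the index (into the lefthand vector) of the
# independent site it mirrors: (x, y, z) |-> (min(x, nx-1-x), y, z).
mirror_source <- function(grid) {
  co <- voxel_coords(seq_len(grid$n_vox), grid)
  xl <- pmin(co[, "x"], grid$nx - 1L - co[, "x"])
  half_nx <- (grid$nx + 1L) %/% 2L
  1L + xl + half_nx * (co[, "y"] + grid$ny * co[, "z"])
}

#' Mirror a half-grid morphology across the midsagittal plane
#'
#' Morphology is bilaterally symmetric: only the lefthand sites (voxel
#' columns on or left of the mirror plane) are free parameters; the
#' righthand side is their reflection.  For the default grid this expands
#' 2 x 4 x 3 = 24 values to the full 48.
#'
#' @param left_values Numeric vector of length `grid$n_left` in lefthand
#'   site order (x fastest, then y, then z).
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `grid$n_vox`; the value at voxel
#'   `(x, y, z)` equals the value at `(nx - 1 - x, y, z)`.
#' @seealso [extract_left()] for the inverse.
#' @export
#' @examples
#' g <- grid_spec()
#' full <- expand_symmetry(runif(g$n_left, 0.25, 1.75), g)
#' length(full)  # 48
expand_symmetry <- function(left_values, grid) {
  if (length(left_values) != grid$n_left)
    stop(sprintf("expected %d lefthand values, got %d",
                 grid$n_left, length(left_values)))
  left_values[mirror_source(grid)]
}

#' Extract the independent lefthand half of a full-grid morphology
#'
#' @param full_values Numeric vector of length `grid$n_vox`.
#' @param grid A [grid_spec()].
#' @return The `grid$n_left` lefthand values; inverse of [expand_symmetry()]
#'   on mirror-symmetric input.
#' @export
extract_left <- function(full_values, grid) {
  if (length(full_values) != grid$n_vox)
    stop(sprintf("expected %d values, got %d", grid$n_vox, length(full_values)))
  full_values[left_indices(grid)]
}
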