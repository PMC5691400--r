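#' Padded axis-aligned bounding box of a molecule
#'
#' The box is the componentwise min/max of the atomic centres, padded by
#' twice the maximum atomic radius on every side. The padding guarantees
#' both Gaussian surfaces (the outer one uses radii inflated by the 1.4
#' Angstrom water probe) fall strictly inside the grid domain.
#'
#' @param mol A `molecule`.
#' @return An object of class `bounding_box`: list with 3-vectors `p`
#'   (minimum corner) and `q` (maximum corner), Angstrom.
#' @export
compute_domain <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  xyz <- atom_centers(mol)
  R <- max(mol$atoms$radius)
  p <- apply(xyz, 2, min) - 2 * R
  q <- apply(xyz, 2, max) + 2 * R
  structure(list(p = unname(p), q = unname(q)), class = "bounding_box")
}

#' Build a cubic voxel grid over a bounding box
#'
#' The box is partitioned into cubic voxels of edge `spacing`. Node counts
#' use a ceiling rule, so a box whose extent is not an integer multiple of
#' the spacing is covered, never truncated; the slack the ceiling introduces
#' is split equally between the two sides of each axis, so the voxelization
#' commutes with axis mirroring and the detector is not biased toward one
#' corner of the domain. Node `(i, j, k)` (1-based) sits
#' at `origin + (i-1, j-1, k-1) * spacing`; voxel `(i, j, k)` is the cube
#' whose 0-th corner is that node, for `i` up to `node_counts[1] - 1` (and
#' likewise per axis). Corner `k` of a voxel (bit `k` of its flag, `k` in
#' 0..7) is offset by `(k & 1, (k >> 1) & 1, (k >> 2) & 1)` voxel edges from
#' the 0-th corner.
#'
#' @param box A `bounding_box`.
#' @param spacing Voxel edge length (Angstrom), default 1.0.
#' @return An object of class `voxel_grid`: list with `origin` (3-vector),
#'   `spacing`, `node_counts` and `voxel_counts` (integer 3-vectors).
#' @export
build_grid <- function(box, spacing = 1.0) {
  stopifnot(inherits(box, "bounding_box"))
  if (!is.finite(spacing) || spacing <= 0) stop("grid spacing must be > 0")
  extent <- box$q - box$p
  nvox <- pmax(1L, as.integer(ceiling(extent / spacing - 1e-9)))
  # guard against floating-point shortfall of the ceiling
  short <- nvox * spacing < extent
  nvox[short] <- nvox[short] + 1L
  slack <- nvox * spacing - extent
  structure(list(
    origin = box$p - slack / 2, spacing = spacing,
    node_counts = nvox + 1L, voxel_counts = nvox
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "Voxel grid: %d x %d x %d nodes, spacing %.3g Angstrom\n  origin (%.3f, %.3f, %.3f)\n",
    x$node_counts[1], x$node_counts[2], x$node_counts[3], x$spacing,
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Node coordinate axes of a grid
#' @param grid A `voxel_grid`.
#' @return List of numeric vectors `x`, `y`, `z` with node coordinates.
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  list(
    x = grid$origin[1] + (seq_len(grid$node_counts[1]) - 1) * grid$spacing,
    y = grid$origin[2] + (seq_len(grid$node_counts[2]) - 1) * grid$spacing,
    z = grid$origin[3] + (seq_len(grid$node_counts[3]) - 1) * grid$spacing
  )
}

#' Cartesian position of grid nodes
#' @param grid A `voxel_grid`.
#' @param ijk Integer matrix (or 3-vector) of 1-based node index triples.
#' @return Numeric matrix of node coordinates (one row per triple).
#' @export
node_position <- function(grid, ijk) {
  stopifnot(inherits(grid, "voxel_grid"))
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep((ijk - 1) * grid$spacing, 2, grid$origin, "+")
}

#' Cartesian centres of voxels
#'
#' The centre of voxel `(i, j, k)` is its 0-th corner node plus half a voxel
#' edge along each axis.
#'
#' @param grid A `voxel_grid`.
#' @param ijk Integer matrix (or 3-vector) of 1-based voxel index triples.
#' @return Numeric matrix of voxel-centre coordinates.
#' @export
voxel_center <- function(grid, ijk) {
  node_position(grid, ijk) + grid$spacing / 2
}
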