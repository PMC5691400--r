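#' Gaussian kernel of a single atom
#'
#' The per-atom kernel is
#' \deqn{f(x) = \exp\{-\beta(\|x - x_i\|^2 / \rho^2 - 1)\}}
#' so it equals \eqn{e^{\beta}} at the atomic centre, exactly 1 on the
#' sphere of radius \eqn{\rho}, and decays smoothly outside. The molecular
#' field is the sum of one kernel per atom, and the molecular surface is its
#' level set at the isovalue `c`.
#'
#' @param x Query point(s): numeric 3-vector or matrix with 3 columns.
#' @param center Atomic centre, 3-vector (Angstrom).
#' @param radius Kernel radius \eqn{\rho > 0} (Angstrom).
#' @param beta Gaussian decay (dimensionless), default 2.3.
#' @return Numeric vector of kernel values, one per query point.
#' @export
kernel_value <- function(x, center, radius, beta = 2.3) {
  if (!is.finite(radius) || radius <= 0) stop("kernel radius must be > 0")
  x <- matrix(as.numeric(x), ncol = 3)
  d2 <- (x[, 1] - center[1])^2 + (x[, 2] - center[2])^2 + (x[, 3] - center[3])^2
  exp(-beta * (d2 / radius^2 - 1))
}

# direct pointwise field sum; rho = per-atom kernel radii
field_at_points <- function(pts, centers, rho, beta) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  centers <- unname(as.matrix(centers))
  vals <- numeric(nrow(pts))
  for (i in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
      (pts[, 3] - centers[i, 3])^2
    vals <- vals + exp(-beta * (d2 / rho[i]^2 - 1))
  }
  vals
}

surface_radii <- function(mol, surface, probe) {
  if (surface == "inner") mol$atoms$radius else mol$atoms$radius + probe
}

#' Evaluate a summed Gaussian field on every grid node
#'
#' Computes \eqn{F(x) = \sum_i \exp\{-\beta(\|x - x_i\|^2/\rho_i^2 - 1)\}} at
#' every node of the grid, with \eqn{\rho_i = r_i} for the inner (van der
#' Waals) surface or \eqn{\rho_i = r_i + w} for the outer surface inflated by
#' the water-probe radius `w`. Summation is exact over all atoms by default;
#' the squared distance separates along the grid axes, so each atom's
#' contribution is a rank-1 product of per-axis exponentials and the total is
#' accumulated with dense matrix products. The optional cutoff mode skips an
#' atom's contribution where it falls below `cutoff_tol` (beyond distance
#' \eqn{\rho_i\sqrt{1 + \ln(1/tol)/\beta}}), bounding the absolute error at
#' any node by `n * cutoff_tol`.
#'
#' @param mol A `molecule`.
#' @param grid A `voxel_grid` covering [compute_domain()] of the molecule.
#' @param surface `"inner"` or `"outer"`.
#' @param beta Gaussian decay, default 2.3.
#' @param probe Water-probe radius added to every atomic radius for the
#'   outer surface (Angstrom), default 1.4.
#' @param cutoff Use the truncated per-atom evaluation? Default `FALSE`.
#' @param cutoff_tol Per-atom truncation threshold, default 1e-12.
#' @return An object of class `scalar_field`: list with the `grid` and a
#'   3-d numeric array `values` of node field values.
#' @export
evaluate_field <- function(mol, grid, surface = c("inner", "outer"),
                           beta = 2.3, probe = 1.4,
                           cutoff = FALSE, cutoff_tol = 1e-12) {
  stopifnot(inherits(mol, "molecule"), inherits(grid, "voxel_grid"))
  surface <- match.arg(surface)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.finite(probe) || probe < 0) stop("probe radius must be >= 0")
  ax <- grid_axes(grid)
  nn <- grid$node_counts
  centers <- atom_centers(mol)
  rho <- surface_radii(mol, surface, probe)
  vals <- if (cutoff) {
    field_nodes_cutoff(ax, nn, centers, rho, beta, cutoff_tol)
  } else {
    field_nodes_exact(ax, nn, centers, rho, beta)
  }
  structure(list(grid = grid, values = vals, surface = surface,
                 beta = beta, probe = probe),
            class = "scalar_field")
}

# exact summation via separable exponentials and a BLAS product:
# F[x, (y,z)] = sum_i EX[x,i] * (EY[,i] o EZ[,i])[(y,z)]
field_nodes_exact <- function(ax, nn, centers, rho, beta, block = 256L) {
  n <- nrow(centers)
  fmat <- matrix(0, nn[1], nn[2] * nn[3])
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    b <- length(idx)
    ex <- exp(beta / 3 - beta * outer(ax$x, centers[idx, 1], "-")^2 /
                rep(rho[idx]^2, each = nn[1]))
    ey <- exp(beta / 3 - beta * outer(ax$y, centers[idx, 2], "-")^2 /
                rep(rho[idx]^2, each = nn[2]))
    ez <- exp(beta / 3 - beta * outer(ax$z, centers[idx, 3], "-")^2 /
                rep(rho[idx]^2, each = nn[3]))
    w <- matrix(0, b, nn[2] * nn[3])
    for (i in seq_len(b)) w[i, ] <- tcrossprod(ey[, i], ez[, i])
    fmat <- fmat + ex %*% w
  }
  array(fmat, dim = nn)
}

field_nodes_cutoff <- function(ax, nn, centers, rho, beta, tol) {
  vals <- array(0, dim = nn)
  dmax <- rho * sqrt(1 + log(1 / tol) / beta)
  for (i in seq_len(nrow(centers))) {
    ix <- which(abs(ax$x - centers[i, 1]) <= dmax[i])
    iy <- which(abs(ax$y - centers[i, 2]) <= dmax[i])
    iz <- which(abs(ax$z - centers[i, 3]) <= dmax[i])
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- exp(beta / 3 - beta * (ax$x[ix] - centers[i, 1])^2 / rho[i]^2)
    ey <- exp(beta / 3 - beta * (ax$y[iy] - centers[i, 2])^2 / rho[i]^2)
    ez <- exp(beta / 3 - beta * (ax$z[iz] - centers[i, 3])^2 / rho[i]^2)
    vals[ix, iy, iz] <- vals[ix, iy, iz] +
      outer(outer(ex, ey), ez)
  }
  vals
}

#' Is a point inside a Gaussian molecular surface?
#'
#' A point is inside the level set when the summed field is at least the
#' isovalue; points exactly on the surface count as inside, matching the
#' voxel-flag rule that marks a corner "outside" only where the field is
#' strictly below the isovalue.
#'
#' @param mol A `molecule`.
#' @param x Query point(s): 3-vector or matrix with 3 columns.
#' @param surface `"inner"` or `"outer"`.
#' @param isovalue Level-set isovalue `c`, default 1.0.
#' @param beta Gaussian decay, default 2.3.
#' @param probe Water-probe radius for the outer surface, default 1.4.
#' @return Logical vector, one per query point.
#' @export
inside_surface <- function(mol, x, surface = c("inner", "outer"),
                           isovalue = 1.0, beta = 2.3, probe = 1.4) {
  stopifnot(inherits(mol, "molecule"))
  surface <- match.arg(surface)
  rho <- surface_radii(mol, surface, probe)
  field_at_points(x, atom_centers(mol), rho, beta) >= isovalue
}

#' Export a scalar field in OpenDX grid format
#'
#' Writes the node values as an OpenDX "regularpositions / regularconnections"
#' scalar dataset, readable by PyMOL/VMD for debugging the fields.
#'
#' @param field A `scalar_field`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_opendx <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  nn <- g$node_counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", nn[1], nn[2], nn[3]),
    sprintf("origin %g %g %g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %g 0 0", g$spacing),
    sprintf("delta 0 %g 0", g$spacing),
    sprintf("delta 0 0 %g", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", nn[1], nn[2], nn[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(nn))
  ), con)
  # OpenDX expects z fastest
  v <- aperm(field$values, c(3, 2, 1))
  vals <- as.vector(v)
  pad <- (-length(vals)) %% 3
  if (pad) vals <- c(vals, rep(NA, pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(format(r[!is.na(r)], digits = 8),
                                         collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
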