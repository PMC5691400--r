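#' Per-voxel corner flags of a scalar field
#'
#' Each voxel carries an 8-bit flag, one bit per corner: bit `k` (k = 0..7,
#' corner offset `(k & 1, (k >> 1) & 1, (k >> 2) & 1)`) is 1 exactly where
#' the node field value is strictly below the isovalue. Flag 255 means the
#' voxel lies entirely outside the surface, flag 0 entirely inside; the 254
#' mixed configurations straddle it.
#'
#' @param field A `scalar_field`.
#' @param isovalue Level-set isovalue `c`, default 1.0.
#' @return An object of class `flag_field`: list with the `grid` and a 3-d
#'   integer array `flags` over voxels.
#' @export
voxel_flags <- function(field, isovalue = 1.0) {
  stopifnot(inherits(field, "scalar_field"))
  below <- field$values < isovalue
  nn <- field$grid$node_counts
  i0 <- seq_len(nn[1] - 1L); j0 <- seq_len(nn[2] - 1L); k0 <- seq_len(nn[3] - 1L)
  flags <- array(0L, dim = nn - 1L)
  for (k in 0:7) {
    off <- c(bitwAnd(k, 1L), bitwAnd(bitwShiftR(k, 1L), 1L),
             bitwAnd(bitwShiftR(k, 2L), 1L))
    flags <- flags + bitwShiftL(1L, k) *
      below[i0 + off[1], j0 + off[2], k0 + off[3], drop = FALSE]
  }
  structure(list(grid = field$grid, flags = flags), class = "flag_field")
}

new_voxel_mask <- function(grid, mask, role) {
  structure(list(grid = grid, mask = mask, role = role), class = "voxel_mask")
}

#' Voxels between the inner and outer surfaces
#'
#' A voxel is "intermediate" when it lies entirely outside the inner (van
#' der Waals) surface and entirely inside the outer (probe-inflated)
#' surface: inner flag 255 and outer flag 0.
#'
#' @param flag_in Inner-surface `flag_field`.
#' @param flag_out Outer-surface `flag_field` on the same grid.
#' @return A `voxel_mask` with role `"intermediate"`.
#' @export
intermediate_mask <- function(flag_in, flag_out) {
  stopifnot(inherits(flag_in, "flag_field"), inherits(flag_out, "flag_field"))
  if (!identical(flag_in$grid, flag_out$grid)) {
    stop("flag fields live on different grids")
  }
  new_voxel_mask(flag_in$grid, flag_in$flags == 255L & flag_out$flags == 0L,
                 "intermediate")
}

#' Cavity voxels among the intermediate voxels
#'
#' An intermediate voxel is a cavity voxel when its full 3x3x3 voxel
#' neighbourhood (itself plus all 26 index neighbours) exists and is
#' intermediate, which guarantees a water molecule fits. Voxels on the grid
#' index boundary never qualify.
#'
#' @param intermediate A `voxel_mask` with role `"intermediate"`.
#' @return A `voxel_mask` with role `"cavity"` (a subset of the input).
#' @export
cavity_mask <- function(intermediate) {
  stopifnot(inherits(intermediate, "voxel_mask"))
  if (!identical(intermediate$role, "intermediate")) {
    stop("cavity_mask expects an intermediate-voxel mask")
  }
  m <- intermediate$mask
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- m
  s <- array(0L, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    s <- s + pad[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3]),
                 drop = FALSE]
  }
  new_voxel_mask(intermediate$grid, s == 27L, "cavity")
}

#' DBSCAN clustering of points
#'
#' Density-based clustering with the standard semantics: a core point has at
#' least `min_pts` neighbours within `eps` (counting itself); clusters are
#' maximal density-connected sets grown from core points; points assigned to
#' no cluster are noise. Points are visited in input order and neighbour
#' lists are expanded in ascending index order, so the labelling is
#' deterministic for a fixed input ordering. Neighbour queries use a uniform
#' cell index of width `eps`; a distance equal to `eps` counts as a
#' neighbour, within a relative tolerance of 1e-9 so that points exactly at
#' the radius (e.g. voxel centres across a cube diagonal at
#' `eps = sqrt(3) * spacing`) are not lost to floating-point rounding.
#'
#' @param points Numeric matrix with 3 columns (one point per row).
#' @param eps Neighbourhood radius (> 0).
#' @param min_pts Core-point threshold (>= 1), self-inclusive.
#' @return List with `clusters` (list of integer index vectors, each sorted,
#'   ordered by smallest member index) and `noise` (sorted integer vector).
#' @export
dbscan_cluster <- function(points, eps, min_pts = 1L) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  min_pts <- as.integer(min_pts)
  if (min_pts < 1L) stop("min_pts must be >= 1")
  n <- nrow(points)
  if (n == 0L) return(list(clusters = list(), noise = integer(0)))

  cell <- floor(sweep(points, 2, apply(points, 2, min)) / eps)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  neighbor_cells <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  query <- function(p) {
    cand <- integer(0)
    for (r in seq_len(27L)) {
      k <- paste(cell[p, 1] + neighbor_cells$dx[r],
                 cell[p, 2] + neighbor_cells$dy[r],
                 cell[p, 3] + neighbor_cells$dz[r], sep = ",")
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (points[cand, 1] - points[p, 1])^2 +
      (points[cand, 2] - points[p, 2])^2 +
      (points[cand, 3] - points[p, 3])^2
    sort(cand[d2 <= eps^2 * (1 + 1e-9)])
  }

  labels <- integer(n)          # 0 = unvisited, -1 = noise, >0 cluster id
  ncl <- 0L
  for (p in seq_len(n)) {
    if (labels[p] != 0L) next
    nb <- query(p)
    if (length(nb) < min_pts) {
      labels[p] <- -1L
      next
    }
    ncl <- ncl + 1L
    labels[p] <- ncl
    seeds <- setdiff(nb, p)
    while (length(seeds)) {
      q <- seeds[1L]
      seeds <- seeds[-1L]
      if (labels[q] == -1L) labels[q] <- ncl   # border point, was noise
      if (labels[q] != 0L) next
      labels[q] <- ncl
      nbq <- query(q)
      if (length(nbq) >= min_pts) seeds <- c(seeds, nbq[labels[nbq] == 0L])
    }
  }
  clusters <- unname(split(seq_len(n), labels)[as.character(seq_len(ncl))])
  clusters <- lapply(clusters, sort)
  ord <- order(vapply(clusters, min, 1L))
  list(clusters = clusters[ord], noise = sort(which(labels == -1L)))
}

#' Detect protein cavities between two Gaussian surfaces
#'
#' Runs the full pipeline: padded bounding box, cubic voxel grid, inner and
#' outer Gaussian field evaluation, per-voxel corner flags, the intermediate
#' condition (outside the van der Waals surface, inside the probe-inflated
#' surface), the 3x3x3 cavity-voxel condition, and DBSCAN clustering of
#' cavity-voxel centres. Clusters of at least `min_cluster_size` voxels
#' become accepted cavities; smaller clusters and noise points are kept as
#' rejected clusters (the "negative cavities" consumed by
#' [score_detection()]). Each cavity's centre is the unweighted mean of its
#' member voxel centres, and its volume is the voxel count times
#' `spacing^3`.
#'
#' With the defaults (`eps = sqrt(3) * spacing`, `min_pts = 1`,
#' `min_cluster_size = 1`) clustering reduces to 26-connected component
#' labelling of the cavity voxels and nothing is rejected.
#'
#' @param mol A `molecule` (see [read_pdb()] or [molecule()]).
#' @param spacing Voxel edge length, Angstrom (default 1.0).
#' @param isovalue Level-set isovalue `c` (default 1.0).
#' @param beta Gaussian decay (default 2.3).
#' @param probe Water-probe radius, Angstrom (default 1.4).
#' @param eps DBSCAN neighbourhood radius; default `sqrt(3) * spacing`.
#' @param min_pts DBSCAN core threshold (default 1).
#' @param min_cluster_size Minimum voxel count of an accepted cavity
#'   (default 1).
#' @param cutoff,cutoff_tol Passed to [evaluate_field()].
#' @param keep_masks Keep the intermediate/cavity masks in the result
#'   (default `TRUE`; set `FALSE` to save memory on large grids).
#' @return An object of class `cavity_detection`; see Details. Its
#'   `cavities` and `rejected` components are data frames with columns
#'   `id`, `n_voxels`, `volume`, `x`, `y`, `z`.
#' @examples
#' cage <- make_open_cage()
#' det <- detect_cavities(cage$molecule)
#' det
#' @export
detect_cavities <- function(mol, spacing = 1.0, isovalue = 1.0, beta = 2.3,
                            probe = 1.4, eps = sqrt(3) * spacing,
                            min_pts = 1L, min_cluster_size = 1L,
                            cutoff = FALSE, cutoff_tol = 1e-12,
                            keep_masks = TRUE) {
  stopifnot(inherits(mol, "molecule"))
  if (!is.finite(isovalue) || isovalue <= 0) stop("isovalue must be > 0")
  grid <- build_grid(compute_domain(mol), spacing)
  f_in <- evaluate_field(mol, grid, "inner", beta = beta, probe = probe,
                         cutoff = cutoff, cutoff_tol = cutoff_tol)
  f_out <- evaluate_field(mol, grid, "outer", beta = beta, probe = probe,
                          cutoff = cutoff, cutoff_tol = cutoff_tol)
  inter <- intermediate_mask(voxel_flags(f_in, isovalue),
                             voxel_flags(f_out, isovalue))
  cav <- cavity_mask(inter)

  idx <- which(cav$mask, arr.ind = TRUE)   # lexicographic in (i, j, k)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  centers <- voxel_center(grid, idx)
  cl <- dbscan_cluster(centers, eps = eps, min_pts = min_pts)

  members <- c(cl$clusters, as.list(cl$noise))
  sizes <- lengths(members)
  accepted <- sizes >= min_cluster_size & seq_along(members) <= length(cl$clusters)
  summarize <- function(which_members) {
    if (!length(which_members)) {
      return(data.frame(id = integer(0), n_voxels = integer(0),
                        volume = numeric(0), x = numeric(0), y = numeric(0),
                        z = numeric(0)))
    }
    do.call(rbind, lapply(seq_along(which_members), function(i) {
      m <- which_members[[i]]
      ctr <- colMeans(centers[m, , drop = FALSE])
      data.frame(id = i, n_voxels = length(m),
                 volume = length(m) * spacing^3,
                 x = ctr[1], y = ctr[2], z = ctr[3], row.names = NULL)
    }))
  }
  res <- structure(list(
    label = mol$label,
    params = list(spacing = spacing, isovalue = isovalue, beta = beta,
                  probe = probe, eps = eps, min_pts = min_pts,
                  min_cluster_size = min_cluster_size, cutoff = cutoff),
    grid = grid,
    n_intermediate = sum(inter$mask),
    n_cavity_voxels = nrow(idx),
    cavities = summarize(members[accepted]),
    rejected = summarize(members[!accepted]),
    cluster_voxels = lapply(members[accepted], function(m) idx[m, , drop = FALSE]),
    rejected_voxels = lapply(members[!accepted], function(m) idx[m, , drop = FALSE])
  ), class = "cavity_detection")
  if (keep_masks) {
    res$intermediate <- inter
    res$cavity <- cav
  }
  res
}

#' Predicted cavity centres of a detection
#' @param det A `cavity_detection`.
#' @param which `"accepted"` (default) or `"rejected"`.
#' @return Numeric matrix of centres (possibly 0 rows).
#' @export
cavity_centers <- function(det, which = c("accepted", "rejected")) {
  stopifnot(inherits(det, "cavity_detection"))
  which <- match.arg(which)
  tab <- if (which == "accepted") det$cavities else det$rejected
  as.matrix(tab[, c("x", "y", "z"), drop = FALSE])
}

#' @export
print.cavity_detection <- function(x, ...) {
  cat("Gaussian-surface cavity detection:", sQuote(x$label), "\n")
  p <- x$params
  cat(sprintf("  spacing %.2f A, isovalue %.2f, beta %.2f, probe %.2f A\n",
              p$spacing, p$isovalue, p$beta, p$probe))
  cat(sprintf("  grid %d x %d x %d nodes; %d intermediate, %d cavity voxels\n",
              x$grid$node_counts[1], x$grid$node_counts[2],
              x$grid$node_counts[3], x$n_intermediate, x$n_cavity_voxels))
  cat(sprintf("  %d cavity(ies) accepted, %d cluster(s) rejected\n",
              nrow(x$cavities), nrow(x$rejected)))
  if (nrow(x$cavities)) {
    print(format(x$cavities, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cavity_detection <- function(object, ...) {
  cat("Cavity detection summary for", sQuote(object$label), "\n")
  print(object)
  if (nrow(object$cavities)) {
    cat(sprintf("  total cavity volume: %.1f A^3 (largest %.1f A^3)\n",
                sum(object$cavities$volume), max(object$cavities$volume)))
  }
  invisible(object)
}

#' @export
as.data.frame.cavity_detection <- function(x, ...) {
  out <- x$cavities
  if (nrow(out)) out$label <- x$label
  out
}

#' Plot a cavity detection
#'
#' Draws an orthographic projection of the atomic centres (grey) and the
#' cavity voxel centres coloured by cavity id, with cavity centres marked.
#'
#' @param x A `cavity_detection`.
#' @param mol Optional `molecule` to overlay atom positions.
#' @param plane Projection plane: `"xy"`, `"xz"` or `"yz"`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.cavity_detection <- function(x, mol = NULL, plane = c("xy", "xz", "yz"),
                                  ...) {
  plane <- match.arg(plane)
  cols <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  labs <- strsplit(plane, "")[[1]]
  pts <- do.call(rbind, lapply(x$cluster_voxels, function(v) {
    voxel_center(x$grid, v)
  }))
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
  xr <- range(c(pts[, cols[1]], if (!is.null(mol)) mol$atoms[[labs[1]]]))
  yr <- range(c(pts[, cols[2]], if (!is.null(mol)) mol$atoms[[labs[2]]]))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = paste(labs[1], "(A)"),
                 ylab = paste(labs[2], "(A)"), asp = 1,
                 main = paste("Cavity voxels:", x$label), ...)
  if (!is.null(mol)) {
    graphics::points(mol$atoms[[labs[1]]], mol$atoms[[labs[2]]],
                     pch = 16, col = "grey70", cex = 0.8)
  }
  ids <- rep(seq_along(x$cluster_voxels), vapply(x$cluster_voxels, nrow, 1L))
  if (nrow(pts)) {
    graphics::points(pts[, cols[1]], pts[, cols[2]], pch = 15,
                     col = ids %% 8 + 1, cex = 0.6)
  }
  ctr <- cavity_centers(x)
  if (nrow(ctr)) {
    graphics::points(ctr[, cols[1]], ctr[, cols[2]], pch = 3, cex = 1.4,
                     lwd = 2)
  }
  invisible(x)
}
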