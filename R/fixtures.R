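# Synthetic molecules with known geometry, plus an independent brute-force
# oracle, so every pipeline stage is testable without external structures.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Single-atom test molecule
#'
#' One atom at the origin: the sphere case where every surface, field and
#' mask has a closed form. Its inner isosurface at isovalue 1 is exactly the
#' sphere of the atomic radius, and detection finds no cavity (the shell
#' between the surfaces is too thin for the 3x3x3 condition).
#'
#' @param radius Atomic radius, Angstrom (default 1.7).
#' @return A `molecule`.
#' @export
make_single_atom <- function(radius = 1.7) {
  molecule(0, 0, 0, radius = radius, element = "C", label = "single-atom")
}

#' Two-atom test molecule
#'
#' A pair of atoms on the x axis, used for additivity and dominance checks.
#'
#' @param separation Centre-to-centre distance, Angstrom (default 4.0).
#' @param radius Atomic radius of both atoms (default 1.7).
#' @return A `molecule`.
#' @export
make_atom_pair <- function(separation = 4.0, radius = 1.7) {
  molecule(c(0, separation), c(0, 0), c(0, 0), radius = radius,
           element = "C", label = "atom-pair")
}

#' Open-cage pocket fixture
#'
#' Pseudo-carbon atoms on five faces of a cubic lattice (one face left
#' open), forming a box-shaped pocket whose interior lies outside the van
#' der Waals surface of the walls but inside their probe-inflated outer
#' surface, so it fills with cavity voxels. The designed ground truth is a
#' single cavity centred at the origin. The default geometry (half-width
#' 4.5 Angstrom, 2 Angstrom requested lattice spacing) makes the pocket
#' interior span about 5 Angstrom across — comfortably above the
#' 3x3x3-voxel minimum at 1 Angstrom spacing — while keeping it narrow
#' enough that the probe-inflated outer surfaces of opposing walls close
#' over the whole interior. A wider cage leaves the pocket middle outside
#' the outer surface and the cavity evaporates, which thinner-shell
#' parameter choices can be used to probe.
#'
#' @param half_width Half edge length of the cage, Angstrom (default 4.5).
#' @param spacing Requested lattice spacing of wall atoms, Angstrom
#'   (default 2.0); the realised spacing is shrunk so the lattice spans the
#'   face symmetrically.
#' @param atom_radius Radius of the wall atoms (default 1.7).
#' @param open_face Which face to leave open: one of `"+z"`, `"-z"`,
#'   `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @return List with `molecule` and `truth` (1 x 3 matrix, the pocket
#'   centre at the origin).
#' @export
make_open_cage <- function(half_width = 4.5, spacing = 2.0,
                           atom_radius = 1.7, open_face = "+z") {
  if (half_width < 2 * spacing) stop("half_width must be at least 2 * spacing")
  open_face <- match.arg(open_face, c("+z", "-z", "+x", "-x", "+y", "-y"))
  # symmetric lattice: endpoints included, actual spacing <= requested
  g <- seq(-half_width, half_width,
           length.out = ceiling(2 * half_width / spacing) + 1L)
  faces <- list(
    "+x" = cbind(half_width, rep(g, each = length(g)), rep(g, length(g))),
    "-x" = cbind(-half_width, rep(g, each = length(g)), rep(g, length(g))),
    "+y" = cbind(rep(g, each = length(g)), half_width, rep(g, length(g))),
    "-y" = cbind(rep(g, each = length(g)), -half_width, rep(g, length(g))),
    "+z" = cbind(rep(g, each = length(g)), rep(g, length(g)), half_width),
    "-z" = cbind(rep(g, each = length(g)), rep(g, length(g)), -half_width)
  )
  pts <- do.call(rbind, faces[setdiff(names(faces), open_face)])
  pts <- unique(round(pts, 9))
  mol <- molecule(pts[, 1], pts[, 2], pts[, 3], radius = atom_radius,
                  element = "C", label = "open-cage")
  list(molecule = mol, truth = matrix(0, 1, 3,
                                      dimnames = list(NULL, c("x", "y", "z"))))
}

#' Random test molecule
#'
#' `n` atoms uniform in `[0, box]^3` with radii uniform in [1.2, 2.0]
#' Angstrom (the common van der Waals range), deterministic for a fixed
#' seed. The caller's RNG state is left untouched.
#'
#' @param n Number of atoms.
#' @param box Edge length of the sampling cube, Angstrom.
#' @param seed Integer seed.
#' @return A `molecule`.
#' @export
make_random_molecule <- function(n, box = 10, seed = 1) {
  if (n < 1L) stop("n must be >= 1")
  with_seed(seed, {
    molecule(stats::runif(n, 0, box), stats::runif(n, 0, box),
             stats::runif(n, 0, box),
             radius = stats::runif(n, 1.2, 2.0), element = "C",
             label = sprintf("random-n%d-seed%d", n, seed))
  })
}

#' Brute-force cavity-voxel oracle
#'
#' Recomputes the intermediate and cavity voxel masks from first principles,
#' sharing no code with the pipeline: the two fields are summed atom by atom
#' at each node with [kernel_value()], voxel classification checks all eight
#' corners explicitly, and the 3x3x3 condition is a naive triple loop.
#' Intended as an independent cross-check on small grids only.
#'
#' @param mol A `molecule`.
#' @param spacing,isovalue,beta,probe Detection parameters as in
#'   [detect_cavities()].
#' @param max_voxels Refuse grids larger than this many voxels
#'   (default `64^3`).
#' @return List with logical 3-d arrays `intermediate` and `cavity` over
#'   voxels, and the `grid`.
#' @export
brute_force_cavity_voxels <- function(mol, spacing = 1.0, isovalue = 1.0,
                                      beta = 2.3, probe = 1.4,
                                      max_voxels = 64^3) {
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms
  # independent grid arithmetic (same ceiling contract as build_grid)
  p <- c(min(a$x), min(a$y), min(a$z)) - 2 * max(a$radius)
  q <- c(max(a$x), max(a$y), max(a$z)) + 2 * max(a$radius)
  nvox <- pmax(1L, as.integer(ceiling((q - p) / spacing - 1e-9)))
  nvox[nvox * spacing < (q - p)] <- nvox[nvox * spacing < (q - p)] + 1L
  p <- p - (nvox * spacing - (q - p)) / 2   # centre the covering slack
  if (prod(nvox) > max_voxels) {
    stop("grid too large for the brute-force oracle (",
         paste(nvox, collapse = " x "), " voxels)")
  }
  nn <- nvox + 1L

  f_in <- array(0, nn)
  f_out <- array(0, nn)
  for (i in seq_len(nn[1])) for (j in seq_len(nn[2])) for (k in seq_len(nn[3])) {
    node <- p + (c(i, j, k) - 1) * spacing
    d2 <- (node[1] - a$x)^2 + (node[2] - a$y)^2 + (node[3] - a$z)^2
    f_in[i, j, k] <- sum(exp(-beta * (d2 / a$radius^2 - 1)))
    f_out[i, j, k] <- sum(exp(-beta * (d2 / (a$radius + probe)^2 - 1)))
  }

  inter <- array(FALSE, nvox)
  for (i in seq_len(nvox[1])) for (j in seq_len(nvox[2])) for (k in seq_len(nvox[3])) {
    all_out <- TRUE; all_in <- TRUE
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      if (!(f_in[i + dx, j + dy, k + dz] < isovalue)) all_out <- FALSE
      if (f_out[i + dx, j + dy, k + dz] < isovalue) all_in <- FALSE
    }
    inter[i, j, k] <- all_out && all_in
  }

  cav <- array(FALSE, nvox)
  for (i in seq_len(nvox[1])) for (j in seq_len(nvox[2])) for (k in seq_len(nvox[3])) {
    if (!inter[i, j, k]) next
    if (i == 1L || j == 1L || k == 1L ||
        i == nvox[1] || j == nvox[2] || k == nvox[3]) next
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (!inter[i + dx, j + dy, k + dz]) ok <- FALSE
    }
    cav[i, j, k] <- ok
  }

  grid <- structure(list(origin = p, spacing = spacing,
                         node_counts = nn, voxel_counts = nvox),
                    class = "voxel_grid")
  list(intermediate = inter, cavity = cav, grid = grid)
}
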