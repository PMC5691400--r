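# Independent oracles used across the test files. These deliberately share
# no code with the package internals they check.

atom_centers2 <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

# direct double-loop field sum at a single point
oracle_field <- function(mol, x, beta = 2.3, probe = 0) {
  a <- mol$atoms
  total <- 0
  for (i in seq_len(nrow(a))) {
    d2 <- sum((x - c(a$x[i], a$y[i], a$z[i]))^2)
    total <- total + exp(-beta * (d2 / (a$radius[i] + probe)^2 - 1))
  }
  total
}

# 26-connected component labelling of a set of voxel index triples (matrix,
# one row per voxel) by breadth-first search over a key lookup
oracle_components <- function(idx) {
  n <- nrow(idx)
  if (n == 0L) return(list())
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  seen <- logical(n)
  comps <- list()
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      comp <- c(comp, cur)
      for (r in seq_len(nrow(offs))) {
        k <- paste(idx[cur, 1] + offs[r, 1], idx[cur, 2] + offs[r, 2],
                   idx[cur, 3] + offs[r, 3], sep = ",")
        j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, 1L))]
}

# exhaustive optimal one-to-one assignment: maximise the number of matched
# pairs within d_max, break ties by minimum total distance; returns the
# optimum match count and that minimum total distance
oracle_assignment <- function(pred, truth, d_max = 4.0) {
  np <- nrow(pred)
  nt <- nrow(truth)
  if (np == 0L || nt == 0L) return(list(n = 0L, total = 0))
  d <- as.matrix(stats::dist(rbind(pred, truth)))[seq_len(np),
                                                  np + seq_len(nt),
                                                  drop = FALSE]
  best_n <- 0L
  best_total <- Inf
  # enumerate injections from the smaller side into the larger side
  if (np <= nt) {
    perms <- utils::combn(nt, np, simplify = FALSE)
    for (subset in perms) {
      for (p in all_perms(subset)) {
        ok <- d[cbind(seq_len(np), p)] <= d_max
        n <- sum(ok)
        tot <- sum(d[cbind(seq_len(np), p)][ok])
        if (n > best_n || (n == best_n && tot < best_total)) {
          best_n <- n
          best_total <- tot
        }
      }
    }
  } else {
    res <- oracle_assignment(truth, pred, d_max)
    return(res)
  }
  list(n = best_n, total = best_total)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# random voxel mask over a small grid, returned as a voxel_mask object
random_mask <- function(dims = c(8, 8, 8), p = 0.3) {
  grid <- build_grid(
    structure(list(p = c(0, 0, 0), q = dims), class = "bounding_box"),
    spacing = 1
  )
  m <- array(stats::runif(prod(dims)) < p, dim = dims)
  structure(list(grid = grid, mask = m, role = "cavity"), class = "voxel_mask")
}

# translate every atom of a molecule by t
translate_molecule <- function(mol, t) {
  mol$atoms$x <- mol$atoms$x + t[1]
  mol$atoms$y <- mol$atoms$y + t[2]
  mol$atoms$z <- mol$atoms$z + t[3]
  mol
}

# apply a signed axis permutation (perm of 1:3 with signs) to all atoms
transform_molecule <- function(mol, perm, signs) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz[, perm, drop = FALSE], 2, signs, "*")
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

# two-record PDB snippet used by the IO tests
pdb_lines_basic <- c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  O   ALA A   1       2.000   0.000   0.000  1.00  0.00           O",
  "HETATM    3  O   HOH A   2       5.000   0.000   0.000  1.00  0.00           O",
  "END"
)
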