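make_field <- function(values, spacing = 1) {
  nn <- dim(values)
  box <- structure(list(p = c(0, 0, 0), q = (nn - 1) * spacing),
                   class = "bounding_box")
  grid <- build_grid(box, spacing)
  structure(list(grid = grid, values = values), class = "scalar_field")
}

test_that("voxel flags encode corner classifications bit by bit", {
  v <- array(2, dim = c(3, 3, 3))       # all nodes >= c: flag 0
  expect_true(all(voxel_flags(make_field(v))$flags == 0L))
  v[] <- 0.5                            # all nodes < c: flag 255
  expect_true(all(voxel_flags(make_field(v))$flags == 255L))
  # exactly corner 0 of voxel (1,1,1) below c: flag 1
  v[] <- 2
  v[1, 1, 1] <- 0.5
  fl <- voxel_flags(make_field(v))$flags
  expect_equal(fl[1, 1, 1], 1L)
  expect_equal(sum(fl), 1L)
  # corner at node offset (1,0,0) of voxel (1,1,1) is bit 1 -> flag 2
  v[] <- 2
  v[2, 1, 1] <- 0.5
  fl <- voxel_flags(make_field(v))$flags
  expect_equal(fl[1, 1, 1], 2L)
  # a node exactly at the isovalue is not below it (strict comparison)
  v[] <- 1
  expect_true(all(voxel_flags(make_field(v))$flags == 0L))
})

test_that("the intermediate condition is flag_in 255 and flag_out 0", {
  vin <- array(0.5, dim = c(3, 3, 3))    # everywhere outside inner
  vout <- array(2, dim = c(3, 3, 3))     # everywhere inside outer
  fi <- voxel_flags(make_field(vin))
  fo <- voxel_flags(make_field(vout))
  m <- intermediate_mask(fi, fo)
  expect_true(all(m$mask))
  # (255, 255) fails the second conjunct
  m2 <- intermediate_mask(fi, fi)
  expect_true(!any(m2$mask))
  # grid mismatch errors
  fo_small <- voxel_flags(make_field(array(2, dim = c(4, 3, 3))))
  expect_error(intermediate_mask(fi, fo_small), "grids")
})

test_that("single-atom intermediate voxels match the corner-distance rule", {
  mol <- make_single_atom(1.7)
  det <- detect_cavities(mol)
  g <- det$grid
  inter <- det$intermediate$mask
  # oracle: all 8 corners at distance in (1.7, 3.1] from the centre
  for (i in seq_len(g$voxel_counts[1])) {
    for (j in seq_len(g$voxel_counts[2])) {
      for (k in seq_len(g$voxel_counts[3])) {
        corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) +
          rep(c(i, j, k), each = 8)
        d <- sqrt(rowSums(node_position(g, corners)^2))
        expect_equal(inter[i, j, k], all(d > 1.7) && all(d <= 3.1))
      }
    }
  }
})

test_that("only the centre of a full 3x3x3 intermediate block is a cavity voxel", {
  m <- array(FALSE, dim = c(7, 7, 7))
  m[3:5, 3:5, 3:5] <- TRUE
  grid <- build_grid(structure(list(p = c(0, 0, 0), q = c(7, 7, 7)),
                               class = "bounding_box"), 1)
  mask <- structure(list(grid = grid, mask = m, role = "intermediate"),
                    class = "voxel_mask")
  cav <- cavity_mask(mask)
  expect_equal(sum(cav$mask), 1L)
  expect_true(cav$mask[4, 4, 4])
})

test_that("grid-boundary voxels are never cavity voxels", {
  m <- array(TRUE, dim = c(5, 5, 5))
  grid <- build_grid(structure(list(p = c(0, 0, 0), q = c(5, 5, 5)),
                               class = "bounding_box"), 1)
  mask <- structure(list(grid = grid, mask = m, role = "intermediate"),
                    class = "voxel_mask")
  cav <- cavity_mask(mask)
  expect_true(all(cav$mask[2:4, 2:4, 2:4]))
  border <- cav$mask
  border[2:4, 2:4, 2:4] <- NA
  expect_true(all(!border, na.rm = TRUE))
})

test_that("a small single atom yields an empty cavity mask and no cavities", {
  for (r in c(1.2, 1.7, 2.0)) {
    det <- detect_cavities(make_single_atom(r))
    expect_equal(det$n_cavity_voxels, 0L)
    expect_equal(nrow(det$cavities), 0L)
  }
})

test_that("DBSCAN separates distant blocks and min_pts=1 leaves no noise", {
  block <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  pts <- rbind(block, sweep(block, 2, c(10, 0, 0), "+"))
  res <- dbscan_cluster(pts, eps = sqrt(3), min_pts = 1)
  expect_length(res$clusters, 2L)
  expect_length(res$noise, 0L)
  expect_equal(res$clusters[[1]], 1:8)
  expect_equal(res$clusters[[2]], 9:16)
  expect_error(dbscan_cluster(pts, eps = 0), "eps")
})

test_that("DBSCAN with min_pts above the local density marks noise", {
  pts <- rbind(as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0)),
               c(50, 50, 0))
  res <- dbscan_cluster(pts, eps = 1.5, min_pts = 4)
  expect_length(res$clusters, 1L)
  expect_equal(res$noise, 10L)
})

test_that("DBSCAN at eps=sqrt(3), min_pts=1 equals 26-connected components", {
  set.seed(11)
  for (rep in 1:10) {
    mask <- random_mask(dims = c(8, 8, 8), p = runif(1, 0.15, 0.5))
    idx <- which(mask$mask, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
    if (!nrow(idx)) next
    pts <- voxel_center(mask$grid, idx)
    res <- dbscan_cluster(pts, eps = sqrt(3) * 1.000001, min_pts = 1)
    comp <- oracle_components(idx)
    expect_equal(lapply(res$clusters, function(i) idx[i, , drop = FALSE]),
                 lapply(comp, function(i) idx[i, , drop = FALSE]))
  }
})

test_that("detection satisfies the containment chain and volume conservation", {
  cage <- make_open_cage()
  det <- detect_cavities(cage$molecule)
  expect_true(all(det$intermediate$mask[det$cavity$mask]))
  expect_equal(sum(det$cavities$volume) + sum(det$rejected$volume),
               det$n_cavity_voxels * det$params$spacing^3)
  # inner flag 0 implies outer flag 0 (pointwise dominance at the corners)
  grid <- det$grid
  fi <- voxel_flags(evaluate_field(cage$molecule, grid, "inner"))
  fo <- voxel_flags(evaluate_field(cage$molecule, grid, "outer"))
  expect_true(all(fo$flags[fi$flags == 0L] == 0L))
})

test_that("accepted and rejected clusters partition the cavity voxels", {
  cage <- make_open_cage()
  det <- detect_cavities(cage$molecule, min_cluster_size = 30)
  expect_equal(nrow(det$cavities), 0L)
  expect_gte(nrow(det$rejected), 1L)
  expect_equal(sum(det$rejected$n_voxels), det$n_cavity_voxels)
})

test_that("translation shifts cavity centres and preserves all counts", {
  cage <- make_open_cage()
  t <- c(3.21, -1.57, 0.73)
  d1 <- detect_cavities(cage$molecule)
  d2 <- detect_cavities(translate_molecule(cage$molecule, t))
  expect_equal(d2$n_intermediate, d1$n_intermediate)
  expect_equal(d2$n_cavity_voxels, d1$n_cavity_voxels)
  expect_equal(d2$cavities$n_voxels, d1$cavities$n_voxels)
  expect_equal(cavity_centers(d2), sweep(cavity_centers(d1), 2, t, "+"),
               tolerance = 1e-6)
})

test_that("signed axis permutations preserve cavity statistics", {
  cage <- make_open_cage()
  d0 <- detect_cavities(cage$molecule)
  perms <- list(c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  signs <- list(c(1, -1, 1), c(-1, -1, -1), c(1, 1, -1))
  for (i in seq_along(perms)) {
    dt <- detect_cavities(transform_molecule(cage$molecule,
                                             perms[[i]], signs[[i]]))
    expect_equal(dt$n_cavity_voxels, d0$n_cavity_voxels)
    expect_equal(sort(dt$cavities$n_voxels), sort(d0$cavities$n_voxels))
    expect_equal(dt$n_intermediate, d0$n_intermediate)
  }
})

test_that("intermediate voxel count grows with the probe radius", {
  for (fix in list(make_single_atom(1.9), make_open_cage()$molecule)) {
    counts <- vapply(c(1.0, 1.4, 1.8), function(w) {
      detect_cavities(fix, probe = w)$n_intermediate
    }, 1L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("a zero probe radius produces no intermediate voxels", {
  det <- detect_cavities(make_single_atom(1.7), probe = 0)
  expect_equal(det$n_intermediate, 0L)
})
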