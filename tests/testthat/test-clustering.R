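rotation_z <- function(th) {
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

test_that("superposition recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  moved <- sweep(ref %*% rotation_z(pi / 2), 2, c(4, -2, 7), "+")
  fit <- superpose(moved, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(moved, fit), ref, tolerance = 1e-9)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposed RMSD is symmetric and rotation-invariant", {
  set.seed(2)
  a <- matrix(rnorm(24), ncol = 3)
  b <- a + matrix(rnorm(24, 0, 0.4), ncol = 3)
  r_ab <- superpose(a, b)$rmsd
  r_ba <- superpose(b, a)$rmsd
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  a_rot <- sweep(a %*% rotation_z(1.1), 2, c(-3, 5, 2), "+")
  expect_equal(superpose(a_rot, b)$rmsd, r_ab, tolerance = 1e-9)
})

test_that("Kabsch RMSD agrees with a rotation-grid search on 4-point toys", {
  set.seed(3)
  for (case in 1:3) {
    ref <- matrix(rnorm(12), ncol = 3)
    mob <- ref
    mob[1, ] <- mob[1, ] + c(1, 0, 0) # one atom displaced by 1 A
    got <- superpose(mob, ref)$rmsd
    want <- oracle_grid_rmsd(mob, ref)
    expect_equal(got, want, tolerance = 1e-3)
    expect_lte(got, want + 1e-9) # Kabsch is the true minimum
  }
})

test_that("neighbour-count clustering recovers constructed separations", {
  topo <- build_peptide_topology("ADKEG")
  set.seed(4)
  base1 <- matrix(rnorm(75), ncol = 3)
  base2 <- matrix(rnorm(75, sd = 2), ncol = 3) # different internal shape
  jitter <- function(m, s) m + matrix(rnorm(length(m), 0, s), ncol = 3)
  frames <- c(
    lapply(1:6, function(i) jitter(base1, 0.02)),
    lapply(1:4, function(i) jitter(base2, 0.02))
  )
  tr <- new_trajectory(topo, frames)
  cl <- gromos_cluster(tr, indices = 1:25, cutoff = 2.0)
  expect_equal(length(cl$centers), 2)
  expect_equal(cl$populations, c(0.6, 0.4))
  expect_true(cl$centers[1] %in% 1:6)
  expect_true(cl$centers[2] %in% 7:10)
  expect_true(all(diff(cl$populations) <= 0))
  # all frames identical -> single cluster with population 1
  tr1 <- new_trajectory(topo, lapply(1:5, function(i) base1))
  cl1 <- gromos_cluster(tr1, indices = 1:25)
  expect_equal(cl1$populations, 1)
  expect_equal(cl1$labels, rep(1L, 5))
})

test_that("clustering agrees with a naive reference and breaks ties low", {
  # symmetric distance matrix with tied neighbour counts: centre must be
  # the lowest frame index
  d <- matrix(10, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 1
  topo <- build_peptide_topology("AAA")
  dummy <- new_trajectory(topo, lapply(1:4, function(i) matrix(rnorm(45), ncol = 3)))
  cl <- gromos_cluster(dummy, rmsd_matrix = d, cutoff = 2)
  expect_equal(cl$centers[1], 1)
  expect_equal(cl$labels, c(1L, 1L, 2L, 2L))
  # random instances vs the reference implementation
  set.seed(5)
  for (case in 1:4) {
    n <- 60
    pts <- matrix(rnorm(n * 2, sd = 3), ncol = 2)
    dm <- as.matrix(dist(pts))
    dummy2 <- new_trajectory(
      topo, lapply(seq_len(n), function(i) matrix(rnorm(45), ncol = 3))
    )
    got <- gromos_cluster(dummy2, rmsd_matrix = dm, cutoff = 2.5)
    want <- oracle_gromos(dm, 2.5)
    expect_identical(got$labels, want$labels)
    expect_identical(got$centers, want$centers)
  }
})

test_that("pose points are invariant under global rigid motion", {
  ens <- generate_ensemble(synth_config(n_frames = 6, seed = 61))
  tr <- ens$trajectory
  rec_bb <- select_atoms(tr$topology, "backbone", chain = "R")
  lig <- select_atoms(tr$topology, "all", chain = "A")
  pp <- pose_points(tr, rec_bb, lig, reference_frame = ens$reference)
  # move every frame rigidly: pose points must not change
  moved <- lapply(seq_len(n_frames(tr)), function(f) {
    sweep(frame_coords(tr, f) %*% rotation_z(0.8), 2, c(12, -7, 3), "+")
  })
  tr2 <- new_trajectory(tr$topology, moved)
  pp2 <- pose_points(tr2, rec_bb, lig, reference_frame = ens$reference)
  expect_equal(as.matrix(pp2[, 2:4]), as.matrix(pp[, 2:4]), tolerance = 1e-6)
})

test_that("pose points recover planted site centres", {
  cfg <- synth_config(
    n_frames = 150, unbound_probability = 0,
    pose_sites = tibble::tibble(x = -16, y = -12, z = 6, weight = 1, sigma = 1),
    saltbridge_spec = tibble::tibble(
      ligand_residue = integer(0), receptor_residue = integer(0),
      probability = numeric(0)
    ),
    seed = 71
  )
  ens <- generate_ensemble(cfg)
  tr <- ens$trajectory
  rec_bb <- select_atoms(tr$topology, "backbone", chain = "R")
  lig <- select_atoms(tr$topology, "all", chain = "A")
  pp <- pose_points(tr, rec_bb, lig, reference_frame = ens$reference)
  centre <- colMeans(as.matrix(pp[, 2:4]))
  expect_true(all(abs(centre - c(-16, -12, 6)) < 3 * 1 / sqrt(150) + 0.1))
})

test_that("density clustering matches brute-force reachability", {
  set.seed(6)
  blob1 <- matrix(rnorm(100, sd = 0.8), ncol = 2)
  blob2 <- matrix(rnorm(100, sd = 0.8), ncol = 2) + 100
  pts <- rbind(blob1, blob2)
  cl <- dbscan_cluster(pts, eps = 3, min_samples = 5)
  expect_equal(nrow(cl$centroids), 2)
  expect_equal(cl$n_noise, 0)
  want <- oracle_dbscan_partition(pts, 3, 5)
  core <- sapply(seq_len(nrow(pts)), function(i) {
    sum(sqrt(rowSums(sweep(pts, 2, pts[i, ])^2)) <= 3) >= 5
  })
  expect_true(same_partition(cl$labels[core], want[core]))
  expect_identical(cl$labels == -1, want == 0)
  # one tight blob is a single cluster, an isolated point is noise
  tight <- matrix(rnorm(60, sd = 0.2), ncol = 3)
  cl_t <- dbscan_cluster(tight, eps = 3, min_samples = 5)
  expect_equal(unique(cl_t$labels), 1L)
  cl_i <- dbscan_cluster(matrix(c(0, 0, 0), 1, 3), eps = 3, min_samples = 2)
  expect_equal(cl_i$labels, -1L)
})

test_that("density clusters are stable under input permutation", {
  set.seed(7)
  pts <- rbind(
    matrix(rnorm(80, sd = 0.7), ncol = 2),
    matrix(rnorm(80, sd = 0.7), ncol = 2) + 50
  )
  cl <- dbscan_cluster(pts, eps = 3, min_samples = 4)
  perm <- sample(nrow(pts))
  cl_p <- dbscan_cluster(pts[perm, ], eps = 3, min_samples = 4)
  back <- integer(nrow(pts))
  back[perm] <- cl_p$labels
  noise_a <- cl$labels == -1
  noise_b <- back == -1
  expect_identical(noise_a, noise_b)
  expect_true(same_partition(cl$labels[!noise_a], back[!noise_a]))
})
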