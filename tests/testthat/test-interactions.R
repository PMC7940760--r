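two_chain_frame <- function(dist_x) {
  # two single-residue chains separated along x by dist_x (CA atoms)
  topo <- new_topology(
    tibble::tibble(
      atom_name = rep(c("N", "CA", "C", "O", "SC"), 2),
      element = rep(c("N", "C", "C", "O", "C"), 2),
      residue_index = rep(0L, 10),
      residue_name = "ALA",
      chain_id = rep(c("A", "B"), each = 5)
    ),
    chain_roles = c(A = "ligand", B = "receptor")
  )
  base <- rbind(
    c(-1.2, 0.3, 0), c(0, 0, 0), c(1.2, 0.3, 0), c(1.2, 1.5, 0), c(0, -1.8, 0)
  )
  frame <- rbind(base, sweep(base, 2, c(dist_x, 30, 0), "+"))
  # closest heavy pair: C of A (x = 1.2) vs N of B (x = dist_x - 1.2)... use
  # y-offset 30 so only deliberate proximity counts; shift B back down
  frame[6:10, 2] <- frame[6:10, 2] - 30
  list(topology = topo, frame = frame)
}

test_that("contacts follow the heavy-atom minimum-distance boundary", {
  # closest heavy atoms at 5.3 A -> contact; at 5.5 -> none
  tc <- two_chain_frame(5.3 + 2.4) # C(A) at 1.2, N(B) at dist_x - 1.2
  expect_true(residue_contact(tc$frame, tc$topology, "A", "B")[1, 1])
  tc2 <- two_chain_frame(5.5 + 2.4)
  expect_false(residue_contact(tc2$frame, tc2$topology, "A", "B")[1, 1])
})

test_that("residue contacts equal a brute-force double loop on random frames", {
  ens <- generate_ensemble(synth_config(n_frames = 2, seed = 33))
  tr <- ens$trajectory
  topo <- tr$topology
  frame <- frame_coords(tr, 1)
  got <- residue_contact(frame, topo, "A", "R", cutoff = 5.4)
  at <- topo$atoms
  res_a <- topo$residues$residue_index[topo$residues$chain_id == "A"]
  res_b <- topo$residues$residue_index[topo$residues$chain_id == "R"]
  for (ia in seq(1, length(res_a), by = 7)) {
    for (ib in seq(1, length(res_b), by = 5)) {
      ra <- which(at$chain_id == "A" & at$residue_index == res_a[ia] & at$is_heavy)
      rb <- which(at$chain_id == "R" & at$residue_index == res_b[ib] & at$is_heavy)
      dmin <- Inf
      for (i in ra) for (j in rb) {
        dmin <- min(dmin, sqrt(sum((frame[i, ] - frame[j, ])^2)))
      }
      expect_identical(got[ia, ib], dmin <= 5.4)
    }
  }
})

test_that("contact maps are symmetric probabilities with unit diagonal", {
  ens <- generate_ensemble(synth_config(n_frames = 30, seed = 34))
  cm <- contact_map(ens$trajectory, "A")
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_true(all(diag(cm) == 1))
  # single-frame map is 0/1
  ens1 <- generate_ensemble(synth_config(n_frames = 1, seed = 35))
  cm1 <- contact_map(ens1$trajectory, "A")
  expect_true(all(cm1 %in% c(0, 1)))
  # persistent hairpin: paired strand residues in contact in every
  # hairpin frame
  cfgh <- synth_config(
    n_frames = 25,
    beta_spec = tibble::tibble(a_start = 17, a_end = 23, b_start = 30,
                               b_end = 36, probability = 1),
    seed = 36
  )
  ensh <- generate_ensemble(cfgh)
  cmh <- contact_map(ensh$trajectory, "A")
  pair_probs <- cmh[cbind(17:23, 36:30)]
  expect_true(all(pair_probs == 1))
})

test_that("binding propensities count frames with any partner contact", {
  cfg <- synth_config(
    n_frames = 200, unbound_probability = 0.1,
    saltbridge_spec = tibble::tibble(
      ligand_residue = 28, receptor_residue = 1, probability = 1
    ),
    seed = 37
  )
  ens <- generate_ensemble(cfg)
  bp <- binding_propensity(ens$trajectory, "A", "R")
  bound_frac <- mean(!is.na(ens$truth$pose_site))
  k28 <- bp$propensity[bp$role == "ligand" & bp$residue == 28]
  # K28 forced into contact in every bound frame
  expect_gte(k28, bound_frac)
  p <- 0.9 # configured bound fraction
  expect_lt(abs(k28 - p), 3 * sqrt(p * (1 - p) / 200) + 0.05)
  # propensity of any residue never exceeds the bound-frame fraction
  nf <- n_frames(ens$trajectory)
  any_contact <- sapply(seq_len(nf), function(f) {
    any(residue_contact(frame_coords(ens$trajectory, f),
                        ens$trajectory$topology, "A", "R"))
  })
  expect_true(all(bp$propensity <= mean(any_contact) + 1e-12))
  # exact agreement with the ground-truth contact table
  truth_prop <- ens$truth$contacts |>
    dplyr::distinct(frame, ligand_residue) |>
    dplyr::count(ligand_residue) |>
    dplyr::mutate(propensity = n / nf)
  lig <- dplyr::filter(bp, role == "ligand")
  for (k in seq_len(nrow(truth_prop))) {
    expect_equal(
      lig$propensity[lig$residue == truth_prop$ligand_residue[k]],
      truth_prop$propensity[k]
    )
  }
})

test_that("salt bridges obey the oxygen-nitrogen distance rule", {
  topo <- build_peptide_topology("DKAS")
  xyz <- matrix(0, 20, 3)
  xyz[, 1] <- rep(seq(0, 30, by = 10), each = 5) + rep(0:4, 4) * 0.5
  # place the D side-chain O and K side-chain N 3.2 A apart
  xyz[5, ] <- c(0, 0, 0)      # SC of D1 (oxygen)
  xyz[10, ] <- c(3.2, 0, 0)   # SC of K2 (nitrogen)
  sb <- salt_bridges(xyz, topo)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$acidic_residue, 1L)
  expect_equal(sb$basic_residue, 2L)
  expect_equal(sb$distance, 3.2)
  # same pair at 4.5 A: absent
  xyz[10, ] <- c(4.5, 0, 0)
  expect_equal(nrow(salt_bridges(xyz, topo)), 0)
  # no acidic or no basic residues: empty
  topo2 <- build_peptide_topology("KKAA")
  expect_equal(nrow(salt_bridges(matrix(rnorm(60), ncol = 3), topo2)), 0)
  # histidine is neutral and never participates
  topo3 <- build_peptide_topology("DH")
  xyz3 <- matrix(seq(0, 2.7, length.out = 30), ncol = 3)
  expect_equal(nrow(salt_bridges(xyz3, topo3)), 0)
})

test_that("salt bridges are a subset of contacts at the wider cutoff", {
  ens <- generate_ensemble(synth_config(n_frames = 10, seed = 38))
  tr <- ens$trajectory
  for (f in c(1, 5, 10)) {
    frame <- frame_coords(tr, f)
    sb <- salt_bridges(frame, tr$topology)
    sb_inter <- dplyr::filter(sb, acidic_chain != basic_chain)
    if (nrow(sb_inter) == 0) next
    cm <- residue_contact(frame, tr$topology, "A", "R", cutoff = 5.4)
    for (k in seq_len(nrow(sb_inter))) {
      lig <- ifelse(sb_inter$acidic_chain[k] == "A",
                    sb_inter$acidic_residue[k], sb_inter$basic_residue[k])
      rec <- ifelse(sb_inter$acidic_chain[k] == "R",
                    sb_inter$acidic_residue[k], sb_inter$basic_residue[k])
      expect_true(cm[lig, rec])
    }
  }
})

test_that("hydrogen bonds require both distance and angle", {
  # ideal planted-hairpin cross-strand bonds are counted
  topo <- build_peptide_topology(ab42_sequence)
  xyz <- plant_hairpin(42, 17:23, 30:36)
  hb <- hydrogen_bonds(xyz, topo, "A", "A")
  cross <- dplyr::filter(
    hb, donor_residue %in% 17:23, acceptor_residue %in% 30:36
  )
  expect_gte(nrow(cross), 3)
  # far-apart donor/acceptor and a bad angle are both rejected
  topo1 <- build_peptide_topology("AA")
  bb <- rbind(
    c(-1.458, 0, 0), c(0, 0, 0), c(0.6, 1.4, 0), c(0.2, 2.5, 0), c(0, -1.8, 0),
    c(5, 0, 0), c(6.5, 0, 0), c(7.1, 1.4, 0), c(6.7, 2.5, 0), c(6.5, -1.8, 0)
  )
  hb1 <- hydrogen_bonds(bb, topo1, "A", "A")
  expect_equal(nrow(dplyr::filter(hb1, distance > 3.5)), 0)
  expect_true(all(hb1$angle <= 30))
})

test_that("beta-region grouping applies the cluster-count and gap rules", {
  # residues 2-6 in 3 of 6 clusters qualify; 2 clusters do not
  flags <- matrix(FALSE, 6, 12)
  flags[1:3, 2:6] <- TRUE
  flags[1:2, 9:10] <- TRUE
  r <- beta_regions(flags)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(2, 6))
  # single-residue gap backed by >= 1 cluster is bridged
  flags2 <- matrix(FALSE, 6, 12)
  flags2[1:3, 3:5] <- TRUE
  flags2[1:3, 7:9] <- TRUE
  flags2[1, 6] <- TRUE
  r2 <- beta_regions(flags2)
  expect_equal(c(r2$start, r2$end), c(3, 9))
  # a gap residue never seen in a strand splits the region
  flags2[1, 6] <- FALSE
  r3 <- beta_regions(flags2)
  expect_equal(r3$start, c(3, 7))
  expect_equal(r3$end, c(5, 9))
  # raising the threshold never enlarges a region
  for (thr in 3:5) {
    ra <- beta_regions(flags2, min_clusters = thr)
    rb <- beta_regions(flags2, min_clusters = thr + 1)
    span <- function(r) sum(r$end - r$start + 1)
    expect_lte(span(rb), span(ra))
  }
  # no qualifying residues: empty result, not an error
  expect_equal(nrow(beta_regions(matrix(FALSE, 3, 8))), 0)
})

test_that("the grouping rule reproduces the five conserved regions", {
  fx <- strand_fixture_flags()
  r <- beta_regions(list(fx$free, fx$bound), sequence = ab42_sequence)
  expect_equal(nrow(r), 5)
  expect_equal(r$label,
               c("A2-H6", "Y10-H13", "Q15-V24", "N27-V36", "G38-I41"))
})

test_that("sheet associations need two cross-strand hydrogen bonds", {
  topo <- build_peptide_topology(ab42_sequence)
  xyz <- plant_hairpin(42, 17:23, 30:36)
  labs <- assign_ss(xyz, topo, "A")
  regions <- tibble::tibble(
    region = c("b3", "b4"), start = c(15, 27), end = c(24, 36)
  )
  assoc <- sheet_associations(xyz, topo, labs, regions)
  expect_true(any(assoc$region_a == "b3" & assoc$region_b == "b4"))
  # all-coil frame: no association
  set.seed(40)
  coil <- rest2tools:::peptide_conformation(42, list())
  labs_c <- assign_ss(coil, topo, "A")
  expect_equal(nrow(sheet_associations(coil, topo, labs_c, regions)), 0)
})

test_that("RMSF vanishes for static or rigidly moving structures", {
  ens <- generate_ensemble(synth_config(n_frames = 1, seed = 45))
  base <- frame_coords(ens$trajectory, 1)
  topo <- ens$trajectory$topology
  static <- new_trajectory(topo, lapply(1:5, function(i) base))
  r0 <- rmsf(static, chain = "R")
  expect_true(all(r0$rmsf < 1e-9))
  # rigid-body motion only: still zero after superposition
  moved <- lapply(1:5, function(i) {
    th <- i / 3
    rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    sweep(base %*% rot, 2, c(i, -i, 2 * i), "+")
  })
  r1 <- rmsf(new_trajectory(topo, moved), chain = "R")
  expect_true(all(r1$rmsf < 1e-6))
})

test_that("RMSF of an isotropically jittered residue matches sqrt(3) sigma", {
  ens <- generate_ensemble(synth_config(n_frames = 1, seed = 46))
  base <- frame_coords(ens$trajectory, 1)
  topo <- ens$trajectory$topology
  rec_rows <- which(topo$atoms$chain_id == "R")
  ca5 <- rec_rows[topo$atoms$atom_name[rec_rows] == "CA"][5]
  set.seed(8)
  sigma <- 0.5
  frames <- lapply(1:1000, function(i) {
    fr <- base
    fr[ca5, ] <- fr[ca5, ] + rnorm(3, 0, sigma)
    fr
  })
  r <- rmsf(new_trajectory(topo, frames), chain = "R")
  expect_lt(abs(r$rmsf[5] - sqrt(3) * sigma) / (sqrt(3) * sigma), 0.05)
  expect_true(all(r$rmsf[-5] < 0.05))
})
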