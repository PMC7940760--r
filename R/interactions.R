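#' Analysis cutoffs
#'
#' Defaults: heavy-atom contacts within 5.4 angstrom; salt bridges when an
#' acidic-residue oxygen lies within 4 angstrom of a basic-residue
#' nitrogen; hydrogen bonds at 3.5 angstrom donor-acceptor and 30 degrees
#' H-donor-acceptor; a residue belongs to a conserved beta-region when it
#' forms beta-strands in at least `region_min_clusters` clusters.
#'
#' @param contact_cutoff,saltbridge_cutoff,hbond_distance Angstrom.
#' @param hbond_angle Degrees.
#' @param region_min_clusters Integer cluster count threshold.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(contact_cutoff = 5.4, saltbridge_cutoff = 4.0,
                            hbond_distance = 3.5, hbond_angle = 30,
                            region_min_clusters = 3) {
  cfg <- list(
    contact_cutoff = contact_cutoff, saltbridge_cutoff = saltbridge_cutoff,
    hbond_distance = hbond_distance, hbond_angle = hbond_angle,
    region_min_clusters = as.integer(region_min_clusters)
  )
  if (any(unlist(cfg) <= 0)) abort("analysis cutoffs must be positive")
  structure(cfg, class = "analysis_config")
}

# heavy atoms of the requested residues, with residue-membership columns
heavy_group <- function(frame, topology, chain, res) {
  at <- topology$atoms
  rows <- which(at$is_heavy & at$chain_id == chain &
                  at$residue_index %in% res)
  member <- outer(at$residue_index[rows], res, "==") * 1
  if (any(colSums(member) == 0)) abort("residue with no heavy atoms")
  list(xyz = frame[rows, , drop = FALSE], member = member)
}

# squared distances between two coordinate sets
cross_dist2 <- function(a, b) {
  pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0)
}

# minimum heavy-atom distance between every residue of A and every residue
# of B; returns a length(res_a) x length(res_b) matrix
min_heavy_distance <- function(frame, topology, chain_a, res_a,
                               chain_b, res_b) {
  ga <- heavy_group(frame, topology, chain_a, res_a)
  gb <- heavy_group(frame, topology, chain_b, res_b)
  d2 <- cross_dist2(ga$xyz, gb$xyz)
  m <- matrix(Inf, length(res_a), length(res_b))
  for (ia in seq_along(res_a)) {
    ra <- ga$member[, ia] == 1
    sub <- d2[ra, , drop = FALSE]
    for (ib in seq_along(res_b)) {
      m[ia, ib] <- sqrt(min(sub[, gb$member[, ib] == 1]))
    }
  }
  m
}

#' Residue-residue contacts in one frame
#'
#' Two residues are in contact when their closest heavy atoms lie within
#' the cutoff.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching `rest2_topology`.
#' @param chain_a,chain_b Chain ids of the two residue groups.
#' @param res_a,res_b 0-based residue index vectors (default: all residues
#'   of the chain).
#' @param cutoff Heavy-atom distance cutoff, angstrom (default 5.4).
#' @return Logical length(res_a) x length(res_b) matrix.
#' @export
residue_contact <- function(frame, topology, chain_a, chain_b,
                            res_a = NULL, res_b = NULL, cutoff = 5.4) {
  res <- topology$residues
  if (is.null(res_a)) res_a <- res$residue_index[res$chain_id == chain_a]
  if (is.null(res_b)) res_b <- res$residue_index[res$chain_id == chain_b]
  ga <- heavy_group(frame, topology, chain_a, res_a)
  gb <- heavy_group(frame, topology, chain_b, res_b)
  hit <- cross_dist2(ga$xyz, gb$xyz) <= cutoff^2
  (t(ga$member) %*% hit %*% gb$member) > 0
}

#' Intrachain residue contact-probability map
#'
#' Per-pair fraction of frames in which the two residues' closest heavy
#' atoms lie within the cutoff. The diagonal is reported as 1 by
#' convention; sequence neighbours are included (mask them downstream if
#' needed).
#'
#' @param trajectory A `rest2_trajectory`.
#' @param chain Chain id (default: first chain).
#' @param cutoff Angstrom (default 5.4).
#' @return A `contact_map`: symmetric probability matrix with residue
#'   labels as dimnames.
#' @export
contact_map <- function(trajectory, chain = NULL, cutoff = 5.4) {
  topo <- trajectory$topology
  if (is.null(chain)) chain <- topo$chains$chain_id[1]
  res <- topo$residues$residue_index[topo$residues$chain_id == chain]
  acc <- matrix(0, length(res), length(res))
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    acc <- acc + residue_contact(
      frame_coords(trajectory, f), topo, chain, chain,
      res, res, cutoff
    )
  }
  m <- acc / nf
  diag(m) <- 1
  labs <- residue_labels(topo, chain)
  dimnames(m) <- list(labs, labs)
  structure(m, class = c("contact_map", class(m)), chain = chain)
}

#' Per-residue binding propensity
#'
#' For each residue of one molecule, the fraction of frames in which it
#' has at least one heavy-atom contact with the partner molecule;
#' reported for both directions, with the molecule-wide mean alongside.
#'
#' @param trajectory A `rest2_trajectory` containing both chains.
#' @param ligand_chain,receptor_chain Chain ids.
#' @param cutoff Angstrom (default 5.4).
#' @return Tibble with `chain`, `role`, `residue` (1-based),
#'   `residue_label`, `propensity` and the per-role `mean_propensity`.
#' @export
binding_propensity <- function(trajectory, ligand_chain, receptor_chain,
                               cutoff = 5.4) {
  topo <- trajectory$topology
  res_l <- topo$residues$residue_index[topo$residues$chain_id == ligand_chain]
  res_r <- topo$residues$residue_index[topo$residues$chain_id == receptor_chain]
  nf <- n_frames(trajectory)
  hits_l <- numeric(length(res_l))
  hits_r <- numeric(length(res_r))
  for (f in seq_len(nf)) {
    cm <- residue_contact(
      frame_coords(trajectory, f), topo,
      ligand_chain, receptor_chain, res_l, res_r, cutoff
    )
    hits_l <- hits_l + (rowSums(cm) > 0)
    hits_r <- hits_r + (colSums(cm) > 0)
  }
  bind_rows(
    tibble(
      chain = ligand_chain, role = "ligand",
      residue = res_l + 1L,
      residue_label = residue_labels(topo, ligand_chain),
      propensity = hits_l / nf, mean_propensity = mean(hits_l / nf)
    ),
    tibble(
      chain = receptor_chain, role = "receptor",
      residue = res_r + 1L,
      residue_label = residue_labels(topo, receptor_chain),
      propensity = hits_r / nf, mean_propensity = mean(hits_r / nf)
    )
  )
}

#' Salt bridges in one frame
#'
#' A salt bridge pairs an acidic residue (D/E) with a basic residue (K/R)
#' whose side-chain oxygen/nitrogen atoms come within the cutoff.
#' Histidine is treated as neutral and never participates. Backbone
#' carbonyl oxygens and amide nitrogens are excluded; termini can be
#' admitted with `include_termini` (off by default).
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching `rest2_topology`.
#' @param config An [analysis_config()].
#' @param include_termini Also allow the chain-terminal backbone N/O as
#'   charged groups (default FALSE).
#' @return Tibble with `acidic_chain`, `acidic_residue` (1-based),
#'   `basic_chain`, `basic_residue`, `distance` (angstrom), sorted by
#'   distance. Zero rows when no bridge is present.
#' @export
salt_bridges <- function(frame, topology, config = analysis_config(),
                         include_termini = FALSE) {
  at <- topology$atoms
  res <- topology$residues
  cls <- res$class[match(
    paste(at$chain_id, at$residue_index),
    paste(res$chain_id, res$residue_index)
  )]
  acid_o <- which(cls == "acidic" & at$element == "O" & !at$is_backbone)
  base_n <- which(cls == "basic" & at$element == "N" & !at$is_backbone)
  if (include_termini) {
    for (ch in topology$chains$chain_id) {
      r <- res$residue_index[res$chain_id == ch]
      first_n <- which(at$chain_id == ch & at$residue_index == min(r) &
                         at$atom_name == "N")
      last_o <- which(at$chain_id == ch & at$residue_index == max(r) &
                        at$element == "O")
      base_n <- union(base_n, first_n)
      acid_o <- union(acid_o, last_o)
    }
  }
  empty <- tibble(
    acidic_chain = character(0), acidic_residue = integer(0),
    basic_chain = character(0), basic_residue = integer(0),
    distance = numeric(0)
  )
  if (length(acid_o) == 0 || length(base_n) == 0) return(empty)
  xa <- frame[acid_o, , drop = FALSE]
  xb <- frame[base_n, , drop = FALSE]
  d <- sqrt(pmax(
    outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb), 0
  ))
  pairs <- tibble(
    acidic_chain = rep(at$chain_id[acid_o], times = length(base_n)),
    acidic_residue = rep(at$residue_index[acid_o], times = length(base_n)) + 1L,
    basic_chain = rep(at$chain_id[base_n], each = length(acid_o)),
    basic_residue = rep(at$residue_index[base_n], each = length(acid_o)) + 1L,
    distance = as.numeric(d)
  ) |>
    group_by(.data$acidic_chain, .data$acidic_residue,
             .data$basic_chain, .data$basic_residue) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    filter(.data$distance <= config$saltbridge_cutoff) |>
    arrange(.data$distance)
  pairs
}

#' Salt-bridge occupancy over a trajectory
#'
#' @inheritParams salt_bridges
#' @param trajectory A `rest2_trajectory`.
#' @return Tibble of residue pairs with `occupancy` (fraction of frames).
#' @export
salt_bridge_occupancy <- function(trajectory, config = analysis_config(),
                                  include_termini = FALSE) {
  nf <- n_frames(trajectory)
  all <- lapply(seq_len(nf), function(f) {
    salt_bridges(frame_coords(trajectory, f), trajectory$topology,
                 config, include_termini)
  })
  bind_rows(all) |>
    count(.data$acidic_chain, .data$acidic_residue,
          .data$basic_chain, .data$basic_residue, name = "n_frames") |>
    mutate(occupancy = .data$n_frames / nf) |>
    arrange(desc(.data$occupancy))
}

#' Hydrogen bonds between two selections in one frame
#'
#' Donors are nitrogens/oxygens carrying a hydrogen; on reduced topologies
#' the backbone amide H is reconstructed geometrically
#' ([reconstruct_amide_h()]) and side-chain tips (no H) are skipped. A
#' bond requires donor-acceptor distance <= `hbond_distance` and
#' H-donor-acceptor angle <= `hbond_angle`.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching `rest2_topology`.
#' @param chain_a,chain_b Chain ids of donor-or-acceptor groups (bonds are
#'   counted in both directions between the chains; use the same chain for
#'   intrachain bonds).
#' @param config An [analysis_config()].
#' @return Tibble with donor/acceptor chain, residue (1-based), distance
#'   and angle; `nrow()` is the bond count.
#' @export
hydrogen_bonds <- function(frame, topology, chain_a, chain_b,
                           config = analysis_config()) {
  donors_of <- function(chain) {
    bb <- backbone_matrices(frame, topology, chain)
    n <- nrow(bb$N)
    if (n < 2) {
      return(tibble(residue = integer(0)))
    }
    idx <- 2:n
    ok <- !is.na(bb$N[idx, 1]) & !is.na(bb$C[idx - 1, 1]) &
      !is.na(bb$O[idx - 1, 1])
    idx <- idx[ok]
    h <- reconstruct_amide_h(
      bb$N[idx, , drop = FALSE],
      bb$C[idx - 1, , drop = FALSE], bb$O[idx - 1, , drop = FALSE]
    )
    tibble(
      chain = chain, residue = bb$residue_index[idx] + 1L,
      dx = bb$N[idx, 1], dy = bb$N[idx, 2], dz = bb$N[idx, 3],
      hx = h[, 1], hy = h[, 2], hz = h[, 3]
    )
  }
  acceptors_of <- function(chain) {
    at <- topology$atoms
    rows <- which(at$chain_id == chain & at$element %in% c("N", "O"))
    tibble(
      chain = chain, residue = at$residue_index[rows] + 1L,
      ax = frame[rows, 1], ay = frame[rows, 2], az = frame[rows, 3]
    )
  }
  bonds_between <- function(don, acc) {
    if (nrow(don) == 0 || nrow(acc) == 0) {
      return(tibble(
        donor_chain = character(0), donor_residue = integer(0),
        acceptor_chain = character(0), acceptor_residue = integer(0),
        distance = numeric(0), angle = numeric(0)
      ))
    }
    dmat <- as.matrix(don[, c("dx", "dy", "dz")])
    hmat <- as.matrix(don[, c("hx", "hy", "hz")])
    amat <- as.matrix(acc[, c("ax", "ay", "az")])
    d2 <- outer(rowSums(dmat^2), rowSums(amat^2), "+") -
      2 * tcrossprod(dmat, amat)
    hits <- which(d2 <= config$hbond_distance^2 & d2 > 1e-12, arr.ind = TRUE)
    if (nrow(hits) == 0) return(bonds_between(don[0, ], acc))
    i <- hits[, 1]; j <- hits[, 2]
    dh <- hmat[i, , drop = FALSE] - dmat[i, , drop = FALSE]
    da <- amat[j, , drop = FALSE] - dmat[i, , drop = FALSE]
    cosang <- rowSums(dh * da) /
      sqrt(rowSums(dh^2) * rowSums(da^2))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    keep <- ang <= config$hbond_angle &
      !(don$chain[i] == acc$chain[j] & don$residue[i] == acc$residue[j])
    tibble(
      donor_chain = don$chain[i], donor_residue = don$residue[i],
      acceptor_chain = acc$chain[j], acceptor_residue = acc$residue[j],
      distance = sqrt(d2[hits]), angle = ang
    )[keep, ] |>
      group_by(.data$donor_chain, .data$donor_residue,
               .data$acceptor_chain, .data$acceptor_residue) |>
      slice_min(.data$distance, n = 1, with_ties = FALSE) |>
      ungroup()
  }
  if (identical(chain_a, chain_b)) {
    bonds_between(donors_of(chain_a), acceptors_of(chain_a))
  } else {
    bind_rows(
      bonds_between(donors_of(chain_a), acceptors_of(chain_b)),
      bonds_between(donors_of(chain_b), acceptors_of(chain_a))
    )
  }
}

#' Conserved beta-regions from per-cluster strand profiles
#'
#' A residue qualifies when it forms a beta-strand in at least
#' `min_clusters` clusters of any provided group (pass one flag matrix,
#' or a list of matrices to pool several systems). Maximal runs of
#' qualifying residues become regions, labelled b1, b2, ... from the
#' N-terminus. A single-residue gap inside a run is bridged only when the
#' gap residue itself is a strand residue in at least one cluster; a
#' residue that never forms a strand always splits regions.
#'
#' @param flags Logical clusters x residues matrix (TRUE = residue is in
#'   a beta-strand in that cluster's representative structure), or a list
#'   of such matrices.
#' @param min_clusters Threshold (default 3, i.e. "more than 2 clusters").
#' @param sequence Optional 1-letter sequence for residue labels.
#' @return Tibble with `region`, `start`, `end` (1-based, inclusive) and,
#'   when `sequence` is given, a `label` like "A2-H6".
#' @export
beta_regions <- function(flags, min_clusters = 3, sequence = NULL) {
  if (!is.list(flags)) flags <- list(flags)
  n_res <- ncol(flags[[1]])
  qualify <- rep(FALSE, n_res)
  ever <- rep(FALSE, n_res)
  for (m in flags) {
    qualify <- qualify | colSums(m) >= min_clusters
    ever <- ever | colSums(m) > 0
  }
  # close single-residue gaps backed by at least one cluster
  merged <- qualify
  for (i in seq_len(n_res)) {
    if (!qualify[i] && ever[i] &&
          i > 1 && i < n_res && qualify[i - 1] && qualify[i + 1]) {
      merged[i] <- TRUE
    }
  }
  r <- rle(merged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- tibble(
    region = paste0("b", seq_along(keep)),
    start = starts[keep], end = ends[keep]
  )
  if (!is.null(sequence) && nrow(out) > 0) {
    aa <- strsplit(sequence, "")[[1]]
    out$label <- paste0(
      aa[out$start], out$start, "-", aa[out$end], out$end
    )
  }
  out
}

#' Beta-sheet associations between regions in one frame
#'
#' Two regions are associated when at least `min_hbonds` backbone
#' hydrogen bonds (Kabsch-Sander) connect E-labelled residues of one to
#' E-labelled residues of the other.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching `rest2_topology`.
#' @param ss_labels Per-residue labels for the chain (from [assign_ss()]).
#' @param regions Tibble from [beta_regions()].
#' @param chain Chain id (default first chain).
#' @param min_hbonds Bonds required to call an association (default 2).
#' @return Tibble with `region_a`, `region_b` (region_a < region_b, plus
#'   self-pairs for intra-region sheets) and `n_hbonds`.
#' @export
sheet_associations <- function(frame, topology, ss_labels, regions,
                               chain = NULL, min_hbonds = 2) {
  if (is.null(chain)) chain <- topology$chains$chain_id[1]
  bb <- backbone_matrices(frame, topology, chain)
  hb <- ks_hbond_matrix(bb)
  e_res <- which(ss_labels == "E")
  reg_of <- rep(NA_character_, length(ss_labels))
  for (k in seq_len(nrow(regions))) {
    reg_of[regions$start[k]:regions$end[k]] <- regions$region[k]
  }
  idx <- which(hb, arr.ind = TRUE)
  out <- tibble(region_a = character(0), region_b = character(0),
                n_hbonds = integer(0))
  if (nrow(idx) == 0) return(out)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- i %in% e_res & j %in% e_res &
    !is.na(reg_of[i]) & !is.na(reg_of[j])
  if (!any(keep)) return(out)
  tibble(
    region_a = pmin(reg_of[i[keep]], reg_of[j[keep]]),
    region_b = pmax(reg_of[i[keep]], reg_of[j[keep]])
  ) |>
    count(.data$region_a, .data$region_b, name = "n_hbonds") |>
    filter(.data$n_hbonds >= min_hbonds |
             (.data$region_a != .data$region_b & .data$n_hbonds >= min_hbonds))
}

#' Association frequencies over a trajectory
#'
#' @inheritParams sheet_associations
#' @param trajectory A `rest2_trajectory`.
#' @param ss An `ss_matrix` for the chain (from [assign_ss_trajectory()]).
#' @return Tibble with `region_a`, `region_b`, `n_frames`, `frequency`.
#' @export
association_frequencies <- function(trajectory, ss, regions, chain = NULL,
                                    min_hbonds = 2) {
  topo <- trajectory$topology
  nf <- n_frames(trajectory)
  per_frame <- lapply(seq_len(nf), function(f) {
    sheet_associations(
      frame_coords(trajectory, f), topo, ss[f, ], regions, chain, min_hbonds
    )
  })
  bind_rows(per_frame) |>
    count(.data$region_a, .data$region_b, name = "n_frames") |>
    mutate(frequency = .data$n_frames / nf) |>
    arrange(desc(.data$frequency))
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is superposed onto the reference on the fit selection; the
#' RMSF of every residue's C-alpha about its mean position is reported.
#'
#' @param trajectory A `rest2_trajectory`.
#' @param fit_indices Atom indices for the superposition (default:
#'   backbone of `chain`).
#' @param chain Chain whose residues are reported (default first chain).
#' @param reference_frame Frame number (default 1).
#' @return Tibble with `residue` (1-based), `residue_label`, `rmsf`
#'   (angstrom).
#' @export
rmsf <- function(trajectory, fit_indices = NULL, chain = NULL,
                 reference_frame = 1) {
  topo <- trajectory$topology
  if (is.null(chain)) chain <- topo$chains$chain_id[1]
  if (is.null(fit_indices)) {
    fit_indices <- select_atoms(topo, "backbone", chain = chain)
  }
  ca <- which(topo$atoms$chain_id == chain & topo$atoms$atom_name == "CA")
  ref <- frame_coords(trajectory, reference_frame)
  nf <- n_frames(trajectory)
  stack <- array(0, dim = c(length(ca), 3, nf))
  for (f in seq_len(nf)) {
    fr <- frame_coords(trajectory, f)
    fit <- superpose(fr, ref, fit_indices)
    stack[, , f] <- apply_transform(fr, fit)[ca, , drop = FALSE]
  }
  mean_pos <- apply(stack, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(f) {
    rowSums((stack[, , f] - mean_pos)^2)
  }, numeric(length(ca)))
  dev2 <- matrix(dev2, nrow = length(ca))
  tibble(
    residue = topo$atoms$residue_index[ca] + 1L,
    residue_label = residue_labels(topo, chain),
    rmsf = sqrt(rowMeans(dev2))
  )
}
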