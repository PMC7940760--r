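#' The 42-residue amyloid-beta peptide sequence
#' @export
ab42_sequence <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

.sc_element <- function(code) {
  cls <- residue_class(code)
  dplyr::case_when(
    cls == "acidic" ~ "O",
    cls == "basic" ~ "N",
    cls == "polar" & code != "G" ~ "O",
    TRUE ~ "C"
  )
}

#' Build a reduced peptide topology from a 1-letter sequence
#'
#' Five atoms per residue: backbone N, CA, C, O plus a side-chain tip SC
#' whose element follows the residue class (oxygen for acidic, nitrogen
#' for basic, oxygen for polar side chains, carbon otherwise).
#'
#' @param sequence 1-letter amino-acid string.
#' @param chain_id Chain id (default "A").
#' @return A `rest2_topology`.
#' @export
build_peptide_topology <- function(sequence, chain_id = "A") {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% names(.aa1to3))) {
    abort(paste0(
      "unknown residue code(s): ",
      paste(unique(aa[!aa %in% names(.aa1to3)]), collapse = ", ")
    ))
  }
  n <- length(aa)
  new_topology(tibble(
    atom_name = rep(c("N", "CA", "C", "O", "SC"), n),
    element = as.vector(vapply(
      aa, function(a) c("N", "C", "C", "O", .sc_element(a)), character(5)
    )),
    residue_index = rep(seq_len(n) - 1L, each = 5L),
    residue_name = rep(unname(.aa1to3[aa]), each = 5L),
    chain_id = chain_id
  ))
}

# --- internal geometry builders -------------------------------------------

# place atom d given a-b-c, bond length |cd|, angle b-c-d, dihedral a-b-c-d
nerf_place <- function(a, b, c, length, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  ang <- pi - angle # supplement: angle is the b-c-d bond angle
  d2 <- c(
    length * cos(ang),
    length * sin(ang) * cos(dihedral),
    length * sin(ang) * sin(dihedral)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.deg <- pi / 180

# backbone of n residues from phi/psi via chain extension; returns a list
# of per-residue 5 x 3 blocks (N, CA, C, O, SC)
coil_backbone <- function(phi, psi) {
  n <- length(phi)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_cnca <- 121.7 * .deg; a_ncac <- 111.2 * .deg; a_cacn <- 116.2 * .deg
  N <- matrix(0, n, 3); CA <- N; C <- N; O <- N; SC <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], b_cac, a_ncac, psi[1] * .deg + pi)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           b_cn, a_cacn, psi[i - 1] * .deg)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            b_nca, a_cnca, pi) # omega = 180
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           b_cac, a_ncac, phi[i] * .deg)
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         1.231, 120.8 * .deg, (psi[i] - 180) * .deg)
    u <- (CA[i, ] - N[i, ]) + (CA[i, ] - C[i, ])
    u <- u / sqrt(sum(u^2))
    SC[i, ] <- CA[i, ] + 1.8 * u
  }
  list(N = N, CA = CA, C = C, O = O, SC = SC)
}

# random coil dihedrals kept out of the beta-sheet basin
coil_dihedrals <- function(n) {
  phi <- stats::runif(n, -160, -55)
  psi <- ifelse(stats::runif(n) < 0.5,
                stats::runif(n, -60, -15),
                stats::runif(n, 90, 170))
  list(phi = phi, psi = psi)
}

# per-residue atom block matrix in canonical order for a chain of n
# residues; `parts` is a list of per-atom n x 3 matrices
interleave_blocks <- function(parts) {
  n <- nrow(parts$N)
  out <- matrix(0, 5 * n, 3)
  out[seq(1, 5 * n, 5), ] <- parts$N
  out[seq(2, 5 * n, 5), ] <- parts$CA
  out[seq(3, 5 * n, 5), ] <- parts$C
  out[seq(4, 5 * n, 5), ] <- parts$O
  out[seq(5, 5 * n, 5), ] <- parts$SC
  out
}

# ideal antiparallel two-strand block. Residues of strand A (low indices)
# run +x; strand B runs -x at lateral separation `sep`, registered so the
# cross-strand amide/carbonyl pairs meet at 2.8-3.0 angstrom O...N.
# Returns per-strand atom lists plus carbonyl orientation requirements for
# the residues immediately preceding each strand.
strand_pair_geometry <- function(len, spacing = 3.4, sep = 4.75,
                                 offset = c(0, 0, 0)) {
  k <- seq_len(len) - 1
  eA <- ifelse(k %% 2 == 0, 1, -1)
  x <- spacing * k
  A <- list(
    N = cbind(x - 1.2, 0.3 * eA, 0),
    CA = cbind(x, 0, 0),
    C = cbind(x + 1.2, 0.3 * eA, 0),
    SC = cbind(x, -0.6, 1.8 * eA)
  )
  A$O <- A$C + cbind(0, 1.23 * eA, 0)
  fB <- eA # same parity pattern
  B_rev <- list( # indexed by k (pair partner order)
    N = cbind(x + 1.2, sep - 0.3 * fB, 0),
    CA = cbind(x, sep, 0),
    C = cbind(x - 1.2, sep - 0.3 * fB, 0),
    SC = cbind(x, sep + 0.6, -1.8 * fB)
  )
  B_rev$O <- B_rev$C + cbind(0, -1.23 * fB, 0)
  # strand B in chain order (first residue of B pairs the last of A)
  B <- lapply(B_rev, function(m) m[rev(seq_len(len)), , drop = FALSE])
  shift <- function(part) lapply(part, function(m) sweep(m, 2, offset, "+"))
  list(
    A = shift(A), B = shift(B),
    # carbonyl direction required on the residue before each strand so the
    # reconstructed amide H of the strand's first residue points across
    pre_A_o_dir = c(0, -eA[1], 0),
    pre_B_o_dir = c(0, fB[len], 0)
  )
}

# circular-arc waypoints between two anchors with ~3.4 A spacing; the arc
# bulges along u_bulge and lengthens as needed to fit n residues
arc_points <- function(from, to, n, u_bulge) {
  chord <- sqrt(sum((to - from)^2))
  want <- 3.4 * (n + 1)
  t <- seq_len(n) / (n + 1)
  if (want <= chord) {
    return(outer(1 - t, from) + outer(t, to))
  }
  # solve sin(phi/2)/(phi/2) = chord/want for the arc span phi
  f <- function(phi) sin(phi / 2) / (phi / 2) - chord / want
  phi <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root
  r <- want / phi
  e1 <- (to - from) / max(chord, 1e-9)
  u <- u_bulge - sum(u_bulge * e1) * e1
  u <- u / sqrt(sum(u^2))
  mid <- (from + to) / 2
  center <- mid - r * cos(phi / 2) * u
  alpha <- -phi / 2 + phi * t
  outer(cos(alpha), r * u) + outer(sin(alpha), r * e1) +
    matrix(center, n, 3, byrow = TRUE)
}

# residues laid along a line or arc between two anchor points, carbonyls
# pointing +z so no backbone H-bond ladder can form; the last residue's O
# direction can be overridden to satisfy a following strand
line_segment_geometry <- function(from, to, n, u_bulge = NULL,
                                  end_o_dir = NULL) {
  if (is.null(u_bulge)) {
    t <- seq_len(n) / (n + 1)
    CA <- outer(1 - t, from) + outer(t, to)
  } else {
    CA <- arc_points(from, to, n, u_bulge)
  }
  tau <- rbind(CA[min(2, n), ] - CA[1, ], diff(CA))
  if (n == 1) tau <- rbind(to - from)
  tau <- tau / sqrt(rowSums(tau^2))
  N <- CA - 1.2 * tau
  C <- CA + 1.2 * tau
  O <- C + matrix(rep(c(0, 0, 1.23), each = n), ncol = 3)
  if (!is.null(end_o_dir)) O[n, ] <- C[n, ] + 1.23 * end_o_dir
  zhat <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  SC <- CA - 1.8 * zhat
  list(N = N, CA = CA, C = C, O = O, SC = SC)
}

#' Plant an antiparallel beta-hairpin in a peptide conformation
#'
#' Builds a full-length peptide conformation in which residues
#' `range_a` and `range_b` (equal-length, disjoint, 1-based inclusive
#' ranges) form two ideally paired antiparallel strands whose cross-strand
#' O...N distances fall in the 2.8-3.0 angstrom hydrogen-bond window;
#' connecting residues form a loop and the remaining residues are placed
#' as non-beta segments.
#'
#' @param n_res Total residue count.
#' @param range_a,range_b Integer vectors (the strand residues, 1-based).
#' @return 5*n_res x 3 coordinate matrix in canonical atom order
#'   (N, CA, C, O, SC per residue).
#' @export
plant_hairpin <- function(n_res, range_a, range_b) {
  peptide_conformation(n_res, hairpins = list(list(a = range_a, b = range_b)))
}

# build one peptide conformation; hairpins is a list of list(a=, b=)
# (1-based residue ranges); residues outside strands go to loop/tail
# segments (deterministic) unless the frame has no hairpin at all, in
# which case the whole chain is a random coil from NeRF dihedrals
peptide_conformation <- function(n_res, hairpins = list()) {
  if (length(hairpins) == 0) {
    d <- coil_dihedrals(n_res)
    return(interleave_blocks(coil_backbone(d$phi, d$psi)))
  }
  for (h in hairpins) {
    if (length(h$a) != length(h$b)) abort("strand ranges must have equal length")
    if (length(intersect(h$a, h$b)) > 0) abort("strand ranges overlap")
  }
  hairpins <- hairpins[order(vapply(hairpins, function(h) min(h$a), numeric(1)))]
  parts <- list(
    N = matrix(NA_real_, n_res, 3), CA = matrix(NA_real_, n_res, 3),
    C = matrix(NA_real_, n_res, 3), O = matrix(NA_real_, n_res, 3),
    SC = matrix(NA_real_, n_res, 3)
  )
  o_override <- list() # residue -> carbonyl direction
  for (hi in seq_along(hairpins)) {
    h <- hairpins[[hi]]
    len <- length(h$a)
    off <- c(0, 35 * (hi - 1), 45 * (hi - 1))
    g <- strand_pair_geometry(len, offset = off)
    for (nm in names(parts)) {
      parts[[nm]][h$a, ] <- g$A[[nm]]
      parts[[nm]][h$b, ] <- g$B[[nm]]
    }
    if (min(h$a) > 1) o_override[[as.character(min(h$a) - 1)]] <- g$pre_A_o_dir
    if (min(h$b) > 1) o_override[[as.character(min(h$b) - 1)]] <- g$pre_B_o_dir
  }
  # fill every unplaced maximal run with a line/arc segment
  placed <- !is.na(parts$CA[, 1])
  r <- rle(placed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (s in which(!r$values)) {
    i0 <- starts[s]; i1 <- ends[s]
    n_seg <- i1 - i0 + 1L
    from <- if (i0 > 1) parts$CA[i0 - 1, ] else NULL
    to <- if (i1 < n_res) parts$CA[i1 + 1, ] else NULL
    if (is.null(from) && is.null(to)) abort("no anchored segment")
    if (is.null(from)) { # N-terminal tail: extend away from the sheet
      d <- c(-1, -0.6, 0.25); d <- d / sqrt(sum(d^2))
      from <- to + d * 3.6 * (n_seg + 1)
      seg <- line_segment_geometry(
        from, to, n_seg,
        end_o_dir = o_override[[as.character(i1)]]
      )
    } else if (is.null(to)) { # C-terminal tail
      d <- c(-1, 0.8, -0.35); d <- d / sqrt(sum(d^2))
      to <- from + d * 3.6 * (n_seg + 1)
      seg <- line_segment_geometry(from, to, n_seg)
    } else { # loop / connector between anchored segments
      seg <- line_segment_geometry(
        from, to, n_seg, u_bulge = c(1, 0, 0.8),
        end_o_dir = o_override[[as.character(i1)]]
      )
    }
    for (nm in names(parts)) parts[[nm]][i0:i1, ] <- seg[[nm]]
  }
  interleave_blocks(parts)
}

# --- receptor --------------------------------------------------------------

# evenly distributed unit directions (deterministic golden-spiral points)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build the rigid three-lobe receptor
#'
#' A deterministic stand-in for a multi-domain globular receptor: three
#' spherical lobes of surface residues (radius `lobe_radius`), each
#' residue a reduced N/CA/C/O/SC block with its side-chain tip pointing
#' outward. The per-lobe sequence starts with a glutamate so acidic
#' side-chain tips are available as salt-bridge partners (receptor
#' residues 1, 1 + n_per_lobe, ... are E).
#'
#' @param n_per_lobe Residues per lobe (default 15).
#' @param lobe_radius Angstrom (default 7).
#' @param chain_id Chain id (default "R").
#' @return List with `topology` and `coords` (atoms x 3).
#' @export
build_receptor <- function(n_per_lobe = 15, lobe_radius = 7, chain_id = "R") {
  lobe_seq <- "EKDLSVAGTFRNIYM"
  seq1 <- paste(rep(substr(
    paste(rep(lobe_seq, 10), collapse = ""), 1, n_per_lobe
  ), 1), collapse = "")
  centers <- rbind(c(0, 0, 0), c(24, 0, 0), c(12, 20, 0))
  full_seq <- paste(rep(seq1, 3), collapse = "")
  topo <- build_peptide_topology(full_seq, chain_id = chain_id)
  coords <- matrix(0, 5 * 3 * n_per_lobe, 3)
  dirs <- sphere_points(n_per_lobe)
  row <- 0L
  for (lobe in 1:3) {
    for (j in seq_len(n_per_lobe)) {
      u <- dirs[j, ]
      ca <- centers[lobe, ] + lobe_radius * u
      t1 <- c(-u[2], u[1], 0)
      if (sqrt(sum(t1^2)) < 1e-6) t1 <- c(1, 0, 0)
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(
        u[2] * t1[3] - u[3] * t1[2],
        u[3] * t1[1] - u[1] * t1[3],
        u[1] * t1[2] - u[2] * t1[1]
      )
      block <- rbind(
        ca + 1.46 * t1,        # N
        ca,                    # CA
        ca - 1.52 * t1,        # C
        ca - 1.52 * t1 + 1.23 * t2, # O
        ca + 2.0 * u           # SC outward
      )
      coords[row + 1:5, ] <- block
      row <- row + 5L
    }
  }
  list(topology = topo, coords = coords)
}

# --- ensemble generator ----------------------------------------------------

#' Synthetic-ensemble configuration
#'
#' Defines the planted features of a synthetic peptide-receptor
#' trajectory: antiparallel hairpins over given residue ranges with given
#' per-frame probabilities, discrete binding-pose sites, forced salt
#' bridges, an unbound fraction, and coordinate noise.
#'
#' @param sequence Peptide 1-letter sequence (default the 42-mer).
#' @param n_frames Number of frames.
#' @param beta_spec Data frame with columns `a_start`, `a_end`, `b_start`,
#'   `b_end` (1-based inclusive strand ranges, equal lengths) and
#'   `probability`.
#' @param pose_sites Data frame with columns `x`, `y`, `z` (site centre,
#'   angstrom, in the receptor frame), `weight` (summing to 1) and `sigma`
#'   (positional spread, angstrom).
#' @param saltbridge_spec Data frame with columns `ligand_residue`,
#'   `receptor_residue` (1-based) and `probability` (applied in bound
#'   frames).
#' @param unbound_probability Fraction of frames with the peptide placed
#'   at least 20 angstrom from every receptor atom.
#' @param coordinate_noise_sigma Isotropic Gaussian noise on every peptide
#'   atom, angstrom (default 0.05).
#' @param seed Integer seed; generation is bitwise reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(sequence = ab42_sequence,
                         n_frames = 100,
                         beta_spec = tibble(
                           a_start = 17, a_end = 23,
                           b_start = 30, b_end = 36, probability = 0.5
                         ),
                         pose_sites = tibble(
                           x = c(-16, 40, 14), y = c(-12, -10, 34),
                           z = c(6, 8, 10),
                           weight = c(0.4, 0.35, 0.25), sigma = 1
                         ),
                         saltbridge_spec = tibble(
                           ligand_residue = 28, receptor_residue = 1,
                           probability = 0.8
                         ),
                         unbound_probability = 0.1,
                         coordinate_noise_sigma = 0.05,
                         seed = 1) {
  beta_spec <- as_tibble(beta_spec)
  pose_sites <- as_tibble(pose_sites)
  saltbridge_spec <- as_tibble(saltbridge_spec)
  if (nrow(beta_spec) > 0) {
    la <- beta_spec$a_end - beta_spec$a_start
    lb <- beta_spec$b_end - beta_spec$b_start
    if (any(la != lb)) abort("strand ranges must have equal lengths")
    if (any(beta_spec$probability < 0 | beta_spec$probability > 1)) {
      abort("probabilities must lie in [0, 1]")
    }
  }
  if (nrow(pose_sites) > 0 &&
        abs(sum(pose_sites$weight) - 1) > 1e-9) {
    abort("pose-site weights must sum to 1")
  }
  structure(
    list(
      sequence = sequence, n_frames = as.integer(n_frames),
      beta_spec = beta_spec, pose_sites = pose_sites,
      saltbridge_spec = saltbridge_spec,
      unbound_probability = unbound_probability,
      coordinate_noise_sigma = coordinate_noise_sigma,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

random_rotation <- function() {
  # uniform rotation from a normalised quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a synthetic peptide-receptor ensemble with ground truth
#'
#' Per frame, independently: hairpin presence is drawn per `beta_spec`
#' row; the peptide is placed at a pose site (Gaussian positional noise,
#' random orientation) or unbound (>= 20 angstrom from every receptor
#' atom); listed salt bridges are forced by moving the ligand side-chain
#' tip within 3.2 angstrom of the receptor tip; the whole complex gets a
#' random rigid-body motion. Every planted label is audited against the
#' emitted coordinates (secondary structure by Kabsch-Sander assignment,
#' bridges and poses by distance) and generation fails loudly if any
#' audit fails.
#'
#' @param config A [synth_config()].
#' @return List with `trajectory` (a `rest2_trajectory`, ligand chain "A",
#'   receptor chain "R") and `truth` (a `ground_truth`: `beta` frames x
#'   residues logical matrix, `pose_site` integer vector with NA for
#'   unbound, `salt_bridges` and `contacts` tibbles, `config` echo).
#' @export
generate_ensemble <- function(config) {
  set.seed(config$seed)
  n_res <- nchar(config$sequence)
  pep_topo <- build_peptide_topology(config$sequence, chain_id = "A")
  rec <- build_receptor()
  rec_com <- colMeans(rec$coords)
  rec_radius <- sqrt(max(rowSums(sweep(rec$coords, 2, rec_com)^2)))

  combined <- new_topology(
    bind_rows(pep_topo$atoms[1:5], rec$topology$atoms[1:5]),
    chain_roles = c(A = "ligand", R = "receptor")
  )
  n_pep_atoms <- 5L * n_res
  # heavy-atom membership matrices for the independent contact audit
  lig_block <- outer(
    rep(seq_len(n_res), each = 5), seq_len(n_res), "=="
  ) * 1
  n_rec_res <- nrow(rec$topology$residues)
  rec_block <- outer(
    rep(seq_len(n_rec_res), each = 5), seq_len(n_rec_res), "=="
  ) * 1

  nf <- config$n_frames
  frames <- vector("list", nf)
  beta_truth <- matrix(FALSE, nf, n_res)
  pose_truth <- rep(NA_integer_, nf)
  sb_rows <- list()
  contact_rows <- list()
  n_sites <- nrow(config$pose_sites)

  for (f in seq_len(nf)) {
    # --- conformation with audited secondary structure ---
    present <- if (nrow(config$beta_spec) > 0) {
      stats::runif(nrow(config$beta_spec)) < config$beta_spec$probability
    } else logical(0)
    hairpins <- lapply(which(present), function(k) {
      list(
        a = config$beta_spec$a_start[k]:config$beta_spec$a_end[k],
        b = config$beta_spec$b_start[k]:config$beta_spec$b_end[k]
      )
    })
    strand_res <- sort(unique(unlist(lapply(hairpins, function(h) c(h$a, h$b)))))
    pep <- NULL
    for (try in 1:25) {
      cand <- peptide_conformation(n_res, hairpins)
      cand <- cand + matrix(
        stats::rnorm(length(cand), 0, config$coordinate_noise_sigma),
        ncol = 3
      )
      labs <- assign_ss(cand, pep_topo, "A")
      ok <- all(labs[strand_res] == "E") &&
        !any(labs[setdiff(seq_len(n_res), strand_res)] == "E")
      if (ok) { pep <- cand; break }
    }
    if (is.null(pep)) {
      abort(paste0("frame ", f, ": could not realise planted secondary structure"))
    }
    beta_truth[f, strand_res] <- TRUE

    # --- placement ---
    pep <- sweep(pep, 2, center_of_mass(pep, pep_topo))
    pep <- pep %*% random_rotation()
    unbound <- stats::runif(1) < config$unbound_probability
    if (unbound || n_sites == 0) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pep_radius <- sqrt(max(rowSums(pep^2)))
      dist <- rec_radius + pep_radius + 21 + abs(stats::rnorm(1, 0, 3))
      pep <- sweep(pep, 2, rec_com + dist * u, "+")
    } else {
      site <- sample.int(n_sites, 1, prob = config$pose_sites$weight)
      pose_truth[f] <- site
      target <- c(
        config$pose_sites$x[site], config$pose_sites$y[site],
        config$pose_sites$z[site]
      ) + stats::rnorm(3, 0, config$pose_sites$sigma[site])
      pep <- sweep(pep, 2, target, "+")
      # --- forced salt bridges: move the ligand side-chain tip ---
      if (nrow(config$saltbridge_spec) > 0) {
        for (k in seq_len(nrow(config$saltbridge_spec))) {
          if (stats::runif(1) >= config$saltbridge_spec$probability[k]) next
          lr <- config$saltbridge_spec$ligand_residue[k]
          rr <- config$saltbridge_spec$receptor_residue[k]
          rec_sc <- rec$coords[5 * (rr - 1) + 5, ]
          toward <- target - rec_sc
          toward <- toward / sqrt(sum(toward^2))
          pep[5 * (lr - 1) + 5, ] <- rec_sc + 3.2 * toward
          sb_rows[[length(sb_rows) + 1]] <- tibble(
            frame = f, ligand_residue = lr, receptor_residue = rr,
            distance = 3.2
          )
        }
      }
    }

    frame <- rbind(pep, rec$coords)
    # --- global rigid motion of the whole complex ---
    rot <- random_rotation()
    com <- colMeans(frame)
    frame <- sweep(sweep(frame, 2, com) %*% rot, 2,
                   com + stats::runif(3, -8, 8), "+")
    frames[[f]] <- frame

    # --- geometric audits + contact ground truth (independent route:
    #     0/1 block-matrix products over the atom contact matrix) ---
    lig_xyz <- frame[seq_len(n_pep_atoms), , drop = FALSE]
    rec_xyz <- frame[-seq_len(n_pep_atoms), , drop = FALSE]
    d2 <- outer(rowSums(lig_xyz^2), rowSums(rec_xyz^2), "+") -
      2 * tcrossprod(lig_xyz, rec_xyz)
    amap <- (d2 <= 5.4^2) * 1
    rmap <- (t(lig_block) %*% amap %*% rec_block) > 0
    hits <- which(rmap, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      contact_rows[[length(contact_rows) + 1]] <- tibble(
        frame = f, ligand_residue = as.integer(hits[, 1]),
        receptor_residue = as.integer(hits[, 2])
      )
    }
    if (unbound && n_sites > 0) {
      if (min(d2) < 20^2) {
        abort(paste0("frame ", f, ": unbound placement violates 20 A clearance"))
      }
    }
  }

  sb <- if (length(sb_rows) > 0) bind_rows(sb_rows) else {
    tibble(frame = integer(0), ligand_residue = integer(0),
           receptor_residue = integer(0), distance = numeric(0))
  }
  contacts <- if (length(contact_rows) > 0) bind_rows(contact_rows) else {
    tibble(frame = integer(0), ligand_residue = integer(0),
           receptor_residue = integer(0))
  }
  # audit: every planted salt bridge satisfied in the final coordinates
  if (nrow(sb) > 0) {
    for (k in seq_len(nrow(sb))) {
      fr <- frames[[sb$frame[k]]]
      a <- fr[5 * (sb$ligand_residue[k] - 1) + 5, ]
      b <- fr[n_pep_atoms + 5 * (sb$receptor_residue[k] - 1) + 5, ]
      if (sqrt(sum((a - b)^2)) > 4.0) {
        abort(paste0("frame ", sb$frame[k], ": planted salt bridge broken"))
      }
    }
  }

  traj <- new_trajectory(combined, frames)
  truth <- structure(
    list(
      beta = beta_truth, pose_site = pose_truth,
      salt_bridges = sb, contacts = contacts, config = config
    ),
    class = "ground_truth"
  )
  # reference structure in the receptor's own frame (peptide rows are
  # placeholders; pose analyses fit on the receptor selection only)
  reference <- rbind(matrix(0, n_pep_atoms, 3), rec$coords)
  list(trajectory = traj, truth = truth, reference = reference)
}

#' Write an ensemble to disk (multi-model PDB + ground-truth JSON)
#'
#' @param ensemble Result of [generate_ensemble()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "ensemble.pdb")
  write_multimodel_pdb(ensemble$trajectory, pdb)
  truth <- ensemble$truth
  json <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(
      beta = truth$beta, pose_site = truth$pose_site,
      salt_bridges = truth$salt_bridges, contacts = truth$contacts,
      config = truth$config[c(
        "sequence", "n_frames", "unbound_probability",
        "coordinate_noise_sigma", "seed"
      )]
    ),
    json, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(c(pdb = pdb, truth = json))
}
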