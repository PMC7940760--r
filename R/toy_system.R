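#' Toy-system configuration
#'
#' A decomposable model system: a bead-chain solute (harmonic bonds between
#' consecutive beads, truncated Lennard-Jones between non-bonded pairs) in
#' a Lennard-Jones solvent bath, in a cubic periodic box with the
#' minimum-image convention. All quantities are in reduced units (kB = 1,
#' lengths in sigma, energies in epsilon).
#'
#' @param n_solute,n_solvent Bead counts.
#' @param box_length Cubic box edge (sigma).
#' @param bond_k Harmonic bond constant (epsilon/sigma^2).
#' @param bond_r0 Equilibrium bond length (sigma).
#' @param lj_epsilon,lj_sigma,lj_cutoff Lennard-Jones parameters; the
#'   potential is truncated (unshifted) at the cutoff.
#' @param move_size Maximum single-bead displacement per move (sigma).
#' @param temperature Bath temperature (reduced units).
#' @param dim Dimensionality of the moves (3 default; 1 gives the
#'   one-dimensional chain used for analytic equipartition checks).
#' @param periodic Apply periodic boundaries (default TRUE).
#' @param kB Boltzmann constant (1 in reduced units).
#' @return A `toy_system_config` list.
#' @export
toy_system_config <- function(n_solute = 10, n_solvent = 100,
                              box_length = 10, bond_k = 100, bond_r0 = 1,
                              lj_epsilon = 1, lj_sigma = 1, lj_cutoff = 2.5,
                              move_size = 0.1, temperature = 1,
                              dim = 3, periodic = TRUE, kB = 1) {
  cfg <- list(
    n_solute = n_solute, n_solvent = n_solvent, box_length = box_length,
    bond_k = bond_k, bond_r0 = bond_r0, lj_epsilon = lj_epsilon,
    lj_sigma = lj_sigma, lj_cutoff = lj_cutoff, move_size = move_size,
    temperature = temperature, dim = as.integer(dim),
    periodic = isTRUE(periodic), kB = kB
  )
  num <- c("n_solute", "box_length", "bond_k", "bond_r0", "lj_epsilon",
           "lj_sigma", "lj_cutoff", "temperature")
  if (any(unlist(cfg[num]) <= 0)) abort("toy-system parameters must be positive")
  if (cfg$periodic && cfg$lj_cutoff >= cfg$box_length / 2) {
    abort("lj_cutoff must be below half the box length")
  }
  structure(cfg, class = "toy_system_config")
}

#' Build an initial toy configuration
#'
#' Solute beads start as a straight chain at the bond rest length; solvent
#' beads go on a cubic lattice with small random jitter, skipping sites too
#' close to the solute. Deterministic given the RNG state.
#'
#' @param config A [toy_system_config()].
#' @return A `toy_configuration` with a cached energy decomposition.
#' @export
toy_configuration <- function(config) {
  ns <- config$n_solute
  solute <- cbind(
    (seq_len(ns) - (ns + 1) / 2) * config$bond_r0,
    rep(0, ns), rep(0, ns)
  )
  if (config$periodic) {
    solute <- solute + config$box_length / 2
  }
  nw <- config$n_solvent
  solvent <- matrix(0, nrow = 0, ncol = 3)
  if (nw > 0) {
    per_side <- ceiling((2 * nw)^(1 / 3))
    spacing <- config$box_length / per_side
    g <- (seq_len(per_side) - 0.5) * spacing
    lattice <- as.matrix(expand.grid(x = g, y = g, z = g))
    # keep lattice sites away from the solute chain
    d2min <- apply(lattice, 1, function(p) {
      min(colSums((t(solute) - p)^2))
    })
    lattice <- lattice[order(-d2min), , drop = FALSE]
    if (nrow(lattice) < nw) abort("box too small for requested solvent count")
    solvent <- lattice[seq_len(nw), , drop = FALSE] +
      matrix(stats::runif(3 * nw, -0.05, 0.05) * spacing, ncol = 3)
  }
  cfg_new <- structure(
    list(
      solute = solute, solvent = solvent, config = config,
      decomp = NULL
    ),
    class = "toy_configuration"
  )
  cfg_new$decomp <- energy_decomposition_of(cfg_new)
  cfg_new
}

#' Full energy decomposition of a toy configuration
#'
#' Recomputes epp/epw/eww from scratch with a pairwise double loop;
#' the cached decomposition carried by the configuration stays within
#' 1e-9 of this after any number of accepted moves.
#'
#' @param config A `toy_configuration`.
#' @return An [energy_decomposition()].
#' @export
energy_decomposition_of <- function(config) {
  v <- cpp_toy_energy(config$solute, config$solvent, config$config)
  if (!all(is.finite(v))) abort("overlapping beads: non-finite LJ energy")
  energy_decomposition(v[["epp"]], v[["epw"]], v[["eww"]])
}

#' Metropolis Monte-Carlo sweeps under the deformed potential
#'
#' One sweep attempts one displacement per bead. Solute moves are accepted
#' on lambda-scaled epp and epw terms; solvent moves on scaled epw plus
#' unscaled eww. Randomness comes from R's RNG stream (use `set.seed()`).
#'
#' @param config A `toy_configuration`.
#' @param lambda Scaling factor in (0, 1].
#' @param n_sweeps Number of sweeps.
#' @param pw_exponent See [scaled_energy()].
#' @return `list(config = <updated>, acceptance = <fraction>)`.
#' @export
mc_sweep <- function(config, lambda, n_sweeps = 1, pw_exponent = 1) {
  if (lambda <= 0 || lambda > 1) abort("lambda must be in (0, 1]")
  p <- config$config
  beta <- 1 / (p$kB * p$temperature)
  out <- cpp_toy_sweep(
    config$solute, config$solvent, unclass(config$decomp), p,
    lambda, beta, as.integer(n_sweeps), pw_exponent
  )
  config$solute <- out$solute
  config$solvent <- out$solvent
  config$decomp <- energy_decomposition(
    out$decomp[["epp"]], out$decomp[["epw"]], out$decomp[["eww"]]
  )
  list(config = config, acceptance = out$acceptance)
}

# --- system contract for the replica-exchange driver ----------------------

#' Toy system honouring the replica-exchange contract
#'
#' @param config A [toy_system_config()].
#' @param pw_exponent See [scaled_energy()].
#' @return A `toy_system` usable as a `system_factory` product in
#'   [run_replica_exchange()].
#' @export
toy_system <- function(config, pw_exponent = 1) {
  structure(
    list(state = toy_configuration(config), pw_exponent = pw_exponent),
    class = "toy_system"
  )
}

#' @export
sys_energy.toy_system <- function(system, ...) system$state$decomp

#' @export
sys_propagate.toy_system <- function(system, lambda, n_sweeps, ...) {
  out <- mc_sweep(system$state, lambda, n_sweeps, system$pw_exponent)
  system$state <- out$config
  list(system = system, acceptance = out$acceptance)
}

#' Export toy solute coordinates as a single-chain trajectory
#'
#' Solute beads become CA pseudo-atoms of consecutive glycine residues so
#' the analysis pipeline (and the PDB writer) can consume toy runs.
#'
#' @param frames List of n_solute x 3 coordinate matrices.
#' @return A `rest2_trajectory`.
#' @export
toy_solute_trajectory <- function(frames) {
  n <- nrow(frames[[1]])
  topo <- new_topology(tibble(
    atom_name = rep("CA", n),
    element = rep("C", n),
    residue_index = seq_len(n) - 1L,
    residue_name = rep("GLY", n),
    chain_id = rep("A", n)
  ))
  new_trajectory(topo, frames)
}
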