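#' Boltzmann constant in kJ/mol/K
#'
#' Physical-unit systems use this value; reduced-unit systems (the toy
#' Hamiltonians) set `kB = 1`.
#' @export
kB_kJ_mol_K <- 0.0083144621

#' Geometric effective-temperature ladder
#'
#' Solute-tempering replicas are spaced exponentially in effective
#' temperature: T_i = T0 * (Tmax/T0)^(i/(n-1)), i = 0..n-1. Endpoints are
#' exact and the ladder is strictly increasing.
#'
#' @param t0 Base (solvent) temperature, K.
#' @param tmax Top effective temperature, K.
#' @param n_replicas Number of rungs (>= 2).
#' @return Numeric vector of effective temperatures, K.
#' @export
make_ladder <- function(t0, tmax, n_replicas) {
  if (n_replicas < 2) abort("a ladder needs at least 2 replicas")
  if (!(t0 > 0 && t0 < tmax)) abort("need 0 < t0 < tmax")
  i <- seq_len(n_replicas) - 1
  t0 * (tmax / t0)^(i / (n_replicas - 1))
}

#' Scaling factor for a rung
#'
#' A replica at effective temperature T_eff runs with its solute terms
#' scaled by lambda = T0/T_eff, which is what "heating the solute" means
#' in solute tempering.
#'
#' @param t_eff Effective temperature, K (>= t0).
#' @param t0 Base temperature, K.
#' @return lambda in (0, 1].
#' @export
lambda_for <- function(t_eff, t0) {
  if (any(t0 <= 0)) abort("t0 must be positive")
  if (any(t_eff < t0)) abort("t_eff < t0 would imply lambda > 1")
  t0 / t_eff
}

#' Energy decomposition of a configuration
#'
#' The potential is decomposed into solute-solute (`epp`), solute-solvent
#' (`epw`) and solvent-solvent (`eww`) components; the deformed replica
#' potential scales the first two.
#'
#' @param epp,epw,eww Finite energies (any consistent unit).
#' @return Named numeric vector of class `energy_decomposition`.
#' @export
energy_decomposition <- function(epp, epw, eww) {
  v <- c(epp = epp, epw = epw, eww = eww)
  if (!all(is.finite(v))) abort("non-finite energy component")
  structure(v, class = "energy_decomposition")
}

#' Deformed (scaled) potential of a replica
#'
#' E(lambda) = lambda * Epp + lambda^pw_exponent * Epw + Eww. The default
#' `pw_exponent = 1` scales solute-solvent interactions linearly in
#' lambda; `pw_exponent = 0.5` gives the sqrt(lambda) coupling of the
#' canonical solute-tempering formulation. Both are exposed because the
#' two conventions coexist in the literature.
#'
#' @param lambda Scaling factor in (0, 1].
#' @param decomp An [energy_decomposition()] (or named vector with
#'   epp/epw/eww).
#' @param pw_exponent Exponent on lambda for the solute-solvent term.
#' @return Scalar energy.
#' @export
scaled_energy <- function(lambda, decomp, pw_exponent = 1) {
  if (any(lambda <= 0) || any(lambda > 1)) abort("lambda must be in (0, 1]")
  lambda * decomp[["epp"]] + lambda^pw_exponent * decomp[["epw"]] +
    decomp[["eww"]]
}

#' Metropolis acceptance probability for a replica exchange
#'
#' For configurations x_i, x_j held at scaling factors lambda_i, lambda_j,
#' the swap is accepted with p = min(1, exp(-beta0 * Delta)) where
#' Delta = [E_i(x_j) + E_j(x_i)] - [E_i(x_i) + E_j(x_j)] and E_k is the
#' deformed potential at lambda_k. The solvent-solvent terms cancel
#' algebraically, so p depends only on the solute components.
#'
#' @param decomp_i,decomp_j Energy decompositions of the two current
#'   configurations.
#' @param lambda_i,lambda_j Scaling factors of the two rungs.
#' @param t0 Base temperature (K, or reduced units).
#' @param kB Boltzmann constant matching the energy/temperature units
#'   (default reduced units, kB = 1).
#' @param pw_exponent See [scaled_energy()].
#' @return Acceptance probability in [0, 1].
#' @export
exchange_accept_prob <- function(decomp_i, decomp_j, lambda_i, lambda_j,
                                 t0, kB = 1, pw_exponent = 1) {
  vi <- unclass(decomp_i)
  vj <- unclass(decomp_j)
  if (!all(is.finite(c(vi, vj)))) abort("non-finite energies")
  e <- function(lambda, v) {
    lambda * v[["epp"]] + lambda^pw_exponent * v[["epw"]]
  }
  delta <- (e(lambda_i, vj) + e(lambda_j, vi)) -
    (e(lambda_i, vi) + e(lambda_j, vj))
  min(1, exp(-delta / (kB * t0)))
}

# ---------------------------------------------------------------------------
# replica-exchange driver
#
# A "system" is any object with sys_energy() and sys_propagate() methods;
# the toy Hamiltonians implement the contract, and tests plug in frozen or
# discrete systems.

#' Energy decomposition of a system state
#' @param system A system object implementing the decomposition contract.
#' @param ... Method arguments.
#' @export
sys_energy <- function(system, ...) UseMethod("sys_energy")

#' Propagate a system at a given scaling factor
#'
#' @param system A system object.
#' @param lambda Scaling factor of the rung the system currently occupies.
#' @param n_sweeps Number of propagation sweeps.
#' @param ... Method arguments.
#' @return `list(system = <updated>, acceptance = <fraction>)`.
#' @export
sys_propagate <- function(system, lambda, n_sweeps, ...) UseMethod("sys_propagate")

#' Run replica exchange with solute tempering
#'
#' Replicas all run at the base temperature `t0`; rung i deforms the
#' potential by lambda_i = t0 / T_eff_i over a geometric effective-
#' temperature ladder. Propagation (delegated to the system objects) and
#' neighbour-exchange attempts alternate; attempts sweep even pairs
#' (0-1, 2-3, ...) and odd pairs (1-2, 3-4, ...) on successive rounds.
#' An accepted exchange swaps the rung assignment (the lambda), not the
#' coordinates.
#'
#' @param system_factory Function `(replica_id)` returning a fresh system
#'   object honouring the [sys_energy()]/[sys_propagate()] contract.
#' @param t0,tmax,n_replicas Ladder specification, see [make_ladder()].
#' @param n_steps Total propagation steps (each step is one
#'   `sys_propagate()` call per replica with `sweeps_per_step` sweeps).
#' @param exchange_interval Attempt exchanges every this many steps.
#' @param seed Integer seed fixing all randomness.
#' @param kB Boltzmann constant in the system's units (default reduced).
#' @param pw_exponent See [scaled_energy()].
#' @param sweeps_per_step Propagation sweeps per step (default 1).
#' @param snapshot Optional function `(system)` returning the solute
#'   coordinates to record at each exchange step; `NULL` records nothing.
#' @return A `rest2_run` object: `history` (attempt records and per-step
#'   occupancy), `diagnostics` (acceptance rate, dwell fractions,
#'   round-trip count), `ladder`, `snapshots` (per rung).
#' @export
run_replica_exchange <- function(system_factory, t0, tmax, n_replicas,
                                 n_steps, exchange_interval = 1, seed = 1,
                                 kB = 1, pw_exponent = 1,
                                 sweeps_per_step = 1, snapshot = NULL) {
  n_replicas <- as.integer(n_replicas)
  ladder <- make_ladder(t0, tmax, n_replicas)
  lambdas <- lambda_for(ladder, t0)
  set.seed(seed)
  systems <- lapply(seq_len(n_replicas), system_factory)
  replica_rung <- seq_len(n_replicas) # rung (1-based) of each replica

  n_attempt_rounds <- floor(n_steps / exchange_interval)
  attempts <- vector("list", n_attempt_rounds)
  occupancy <- matrix(0L, nrow = n_steps, ncol = n_replicas)
  snapshots <- if (is.null(snapshot)) NULL else {
    lapply(seq_len(n_replicas), function(i) vector("list", n_attempt_rounds))
  }
  # round-trip bookkeeping: a replica completes a trip when it has visited
  # both end rungs and returns to rung 1
  seen_top <- rep(FALSE, n_replicas)
  round_trips <- 0L
  round <- 0L
  prop_acc <- 0
  prop_n <- 0L

  for (step in seq_len(n_steps)) {
    for (r in seq_len(n_replicas)) {
      lam <- lambdas[replica_rung[r]]
      out <- sys_propagate(systems[[r]], lam, sweeps_per_step)
      systems[[r]] <- out$system
      prop_acc <- prop_acc + out$acceptance
      prop_n <- prop_n + 1L
    }
    occupancy[step, ] <- replica_rung
    if (step %% exchange_interval == 0) {
      round <- round + 1L
      first <- if (round %% 2L == 1L) 1L else 2L
      pairs <- if (first > n_replicas - 1L) integer(0) else {
        seq(first, n_replicas - 1L, by = 2L)
      }
      rec <- matrix(NA_real_, nrow = length(pairs), ncol = 5)
      rung_replica <- order(replica_rung) # replica at each rung
      for (k in seq_along(pairs)) {
        ri <- pairs[k]
        rj <- ri + 1L
        a <- rung_replica[ri]
        b <- rung_replica[rj]
        p <- exchange_accept_prob(
          sys_energy(systems[[a]]), sys_energy(systems[[b]]),
          lambdas[ri], lambdas[rj], t0, kB, pw_exponent
        )
        acc <- stats::runif(1) < p
        if (acc) {
          replica_rung[a] <- rj
          replica_rung[b] <- ri
          rung_replica[ri] <- b
          rung_replica[rj] <- a
        }
        rec[k, ] <- c(step, ri, rj, p, as.numeric(acc))
      }
      attempts[[round]] <- rec
      if (!is.null(snapshot)) {
        for (r in seq_len(n_replicas)) {
          snapshots[[replica_rung[r]]][[round]] <- snapshot(systems[[r]])
        }
      }
      seen_top <- seen_top | replica_rung == n_replicas
      done <- seen_top & replica_rung == 1L
      round_trips <- round_trips + sum(done)
      seen_top[done] <- FALSE
    }
  }

  attempts <- do.call(rbind, attempts)
  attempts <- tibble(
    step = as.integer(attempts[, 1]),
    rung_i = as.integer(attempts[, 2]),
    rung_j = as.integer(attempts[, 3]),
    prob = attempts[, 4],
    accepted = attempts[, 5] == 1
  )
  history <- structure(
    list(attempts = attempts, occupancy = occupancy, n_replicas = n_replicas),
    class = "exchange_history"
  )
  dwell <- dwell_fractions(history)
  diagnostics <- list(
    mean_acceptance = mean(attempts$accepted),
    propagation_acceptance = prop_acc / max(prop_n, 1L),
    dwell_fractions = dwell,
    round_trips = round_trips
  )
  structure(
    list(
      history = history, diagnostics = diagnostics, ladder = ladder,
      lambdas = lambdas, snapshots = snapshots, systems = systems,
      seed = seed
    ),
    class = "rest2_run"
  )
}

#' @export
print.rest2_run <- function(x, ...) {
  cat(
    "<rest2_run> ", length(x$ladder), " replicas, ",
    nrow(x$history$occupancy), " steps, mean exchange acceptance ",
    sprintf("%.3f", x$diagnostics$mean_acceptance), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-replica dwell-time fractions over the rung ladder
#'
#' Rows are replicas, columns rungs; each row sums to 1 and, because rung
#' occupancy is a permutation of replicas at every step, every column mean
#' over replicas is exactly 1/n_replicas (the 6.25% line for 16 replicas).
#'
#' @param history An `exchange_history` (from [run_replica_exchange()]).
#' @return n_replicas x n_replicas matrix of time fractions.
#' @export
dwell_fractions <- function(history) {
  occ <- history$occupancy
  if (is.null(occ) || nrow(occ) == 0) abort("empty exchange history")
  n <- history$n_replicas
  d <- matrix(0, nrow = n, ncol = n,
              dimnames = list(replica = NULL, rung = NULL))
  for (r in seq_len(n)) {
    d[r, ] <- tabulate(occ[, r], nbins = n) / nrow(occ)
  }
  d
}
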