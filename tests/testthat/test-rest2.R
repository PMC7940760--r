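test_that("the effective-temperature ladder is geometric and endpoint-exact", {
  expect_equal(make_ladder(300, 600, 2), c(300, 600))
  l <- make_ladder(300, 600, 16)
  expect_equal(l[1], 300)
  expect_equal(l[16], 600)
  expect_true(all(diff(l) > 0))
  # geometric spacing: constant ratio
  expect_equal(sd(diff(log(l))), 0, tolerance = 1e-12)
  # property over many specs
  for (spec in list(c(250, 500, 5), c(300, 450, 3), c(100, 1000, 24))) {
    li <- make_ladder(spec[1], spec[2], spec[3])
    expect_equal(li[1], spec[1])
    expect_equal(li[length(li)], spec[2])
    expect_true(all(diff(li) > 0))
  }
  expect_error(make_ladder(300, 600, 1), "at least 2")
  expect_error(make_ladder(600, 300, 4), "t0 < tmax")
})

test_that("lambda is the base-to-effective temperature ratio", {
  expect_equal(lambda_for(300, 300), 1)
  expect_equal(lambda_for(600, 300), 0.5)
  expect_equal(lambda_for(434.2, 300), 300 / 434.2)
  expect_error(lambda_for(200, 300), "lambda > 1")
})

test_that("the deformed potential scales solute terms only", {
  d <- energy_decomposition(10, 4, 7)
  expect_equal(scaled_energy(1, d), 21)
  expect_equal(scaled_energy(0.5, d), 14)
  expect_equal(scaled_energy(0.25, energy_decomposition(8, 4, 1),
                             pw_exponent = 0.5), 5)
  expect_error(scaled_energy(0, d), "lambda")
  expect_error(energy_decomposition(Inf, 0, 0), "finite")
})

test_that("exchange acceptance depends only on solute terms (Eww cancels)", {
  set.seed(31)
  t0 <- 300
  kb <- kB_kJ_mol_K
  for (case in 1:200) {
    di <- energy_decomposition(rnorm(1, 0, 50), rnorm(1, 0, 50), rnorm(1, 0, 500))
    dj <- energy_decomposition(rnorm(1, 0, 50), rnorm(1, 0, 50), rnorm(1, 0, 500))
    li <- runif(1, 0.3, 1)
    lj <- runif(1, 0.3, 1)
    p <- exchange_accept_prob(di, dj, li, lj, t0, kB = kb)
    # independent route through the full deformed potentials incl. Eww
    delta_full <- (scaled_energy(li, dj) + scaled_energy(lj, di)) -
      (scaled_energy(li, di) + scaled_energy(lj, dj))
    expect_equal(p, min(1, exp(-delta_full / (kb * t0))), tolerance = 1e-12)
  }
  # equal lambdas always accept
  d1 <- energy_decomposition(3, -2, 9)
  d2 <- energy_decomposition(-8, 5, -1)
  expect_equal(exchange_accept_prob(d1, d2, 0.7, 0.7, 300, kB = kb), 1)
  expect_error(
    exchange_accept_prob(d1, energy_decomposition(1, 2, 3) * NA, 1, 0.5, 300),
    "finite"
  )
})

test_that("rung occupancy stays a permutation and degenerate ladders always swap", {
  run <- run_replica_exchange(
    function(i) frozen_system(rnorm(1), rnorm(1)),
    t0 = 1, tmax = 1 + 1e-12, n_replicas = 4,
    n_steps = 60, exchange_interval = 2, seed = 5
  )
  # all lambdas (numerically) equal -> acceptance 1 at every attempt
  expect_equal(run$diagnostics$mean_acceptance, 1)
  occ <- run$history$occupancy
  for (s in seq_len(nrow(occ))) {
    expect_identical(sort(occ[s, ]), 1:4)
  }
})

test_that("empirical exchange frequency matches the closed-form probability", {
  # two frozen replicas: every attempt has the same acceptance probability
  di <- energy_decomposition(2.0, 1.0, 5)
  dj <- energy_decomposition(0.5, -0.3, -2)
  t0 <- 1
  run <- run_replica_exchange(
    function(i) if (i == 1) frozen_system(2.0, 1.0, 5) else frozen_system(0.5, -0.3, -2),
    t0 = t0, tmax = 2, n_replicas = 2,
    n_steps = 10000, exchange_interval = 1, seed = 12
  )
  att <- tidy(run)
  lam <- run$lambdas
  # frozen configurations: after an accepted swap the configurations carry
  # their energies with them, so the acceptance probability alternates
  # between p(forward) and p(backward); both equal by symmetry of delta
  p_expected <- exchange_accept_prob(di, dj, lam[1], lam[2], t0)
  expect_equal(mean(att$prob %in%
                      c(p_expected,
                        exchange_accept_prob(dj, di, lam[1], lam[2], t0))), 1)
  n <- nrow(att)
  phat <- mean(att$accepted)
  p_mean <- mean(att$prob)
  expect_lt(abs(phat - p_mean), 3 * sqrt(p_mean * (1 - p_mean) / n))
})

test_that("dwell fractions conserve rung occupancy", {
  run <- run_replica_exchange(
    function(i) frozen_system(rnorm(1, 0, 2), rnorm(1)),
    t0 = 1, tmax = 3, n_replicas = 16,
    n_steps = 400, exchange_interval = 1, seed = 3
  )
  d <- dwell_fractions(run$history)
  expect_equal(rowSums(d), rep(1, 16))
  expect_equal(colMeans(d), rep(1 / 16, 16), tolerance = 1e-12)
  # no accepted exchange -> identity occupancy
  run2 <- run_replica_exchange(
    function(i) frozen_system(i * 1e6, 0), # huge energy gaps: never swap
    t0 = 1e-6, tmax = 2, n_replicas = 3,
    n_steps = 20, exchange_interval = 1, seed = 1
  )
  expect_equal(diag(dwell_fractions(run2$history)), rep(1, 3))
  # perfect alternating swaps of 2 replicas -> 0.5 / 0.5
  run3 <- run_replica_exchange(
    function(i) frozen_system(0, 0),
    t0 = 1, tmax = 2, n_replicas = 2,
    n_steps = 400, exchange_interval = 1, seed = 2
  )
  expect_equal(as.vector(dwell_fractions(run3$history)),
               rep(0.5, 4), tolerance = 0.01)
})

test_that("rung-conditional state frequencies obey detailed balance", {
  # discrete two-state solute (energies 0 and e1), two rungs; long-run
  # conditional frequencies must match the Boltzmann weights of the
  # deformed potentials
  e1 <- 1.2
  t0 <- 1
  run <- run_replica_exchange(
    function(i) two_state_system(e1 = e1, t0 = t0),
    t0 = t0, tmax = 2.5, n_replicas = 2,
    n_steps = 6000, exchange_interval = 1, seed = 21,
    sweeps_per_step = 4,
    snapshot = function(sys) sys$state
  )
  for (rung in 1:2) {
    lam <- run$lambdas[rung]
    states <- unlist(run$snapshots[[rung]])
    p1_expected <- exp(-lam * e1 / t0) / (1 + exp(-lam * e1 / t0))
    n <- length(states)
    se <- sqrt(p1_expected * (1 - p1_expected) / n)
    expect_lt(abs(mean(states) - p1_expected), 4 * se)
  }
})

test_that("tidiers summarise runs faithfully", {
  run <- run_replica_exchange(
    function(i) frozen_system(rnorm(1), 0),
    t0 = 1, tmax = 2, n_replicas = 3,
    n_steps = 30, exchange_interval = 3, seed = 7
  )
  g <- glance(run)
  expect_equal(g$n_replicas, 3)
  expect_equal(g$n_steps, 30)
  att <- tidy(run)
  expect_equal(nrow(att), 10) # one neighbour pair per round for n = 3
  expect_true(all(att$prob >= 0 & att$prob <= 1))
})
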