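# Independent reference implementations used as oracles. These stay
# deliberately naive (double loops, grid searches) and never share code
# with the package paths they check.

# --- frozen system: configurations that never move --------------------------
frozen_system <- function(epp, epw, eww = 0) {
  structure(list(d = energy_decomposition(epp, epw, eww)),
            class = "frozen_system")
}
registerS3method("sys_energy", "frozen_system",
                 function(system, ...) system$d,
                 envir = asNamespace("rest2tools"))
registerS3method("sys_propagate", "frozen_system",
                 function(system, lambda, n_sweeps, ...) {
                   list(system = system, acceptance = 1)
                 },
                 envir = asNamespace("rest2tools"))

# --- discrete two-state solute: epp in {0, e1}, Metropolis flips ------------
two_state_system <- function(e1 = 1, t0 = 1) {
  structure(list(state = 0L, e1 = e1, t0 = t0), class = "two_state_system")
}
registerS3method("sys_energy", "two_state_system",
                 function(system, ...) {
                   energy_decomposition(system$state * system$e1, 0, 0)
                 },
                 envir = asNamespace("rest2tools"))
registerS3method("sys_propagate", "two_state_system",
                 function(system, lambda, n_sweeps, ...) {
                   for (k in seq_len(n_sweeps)) {
                     prop <- 1L - system$state
                     de <- lambda * (prop - system$state) * system$e1
                     if (de <= 0 || runif(1) < exp(-de / system$t0)) {
                       system$state <- prop
                     }
                   }
                   list(system = system, acceptance = 1)
                 },
                 envir = asNamespace("rest2tools"))

# --- brute-force toy-system energy (double loop, minimum image) -------------
oracle_toy_energy <- function(solute, solvent, cfg) {
  mi <- function(d) {
    if (cfg$periodic) d - cfg$box_length * round(d / cfg$box_length) else d
  }
  r2 <- function(a, b) sum(mi(a - b)^2)
  lj <- function(rr) {
    if (rr >= cfg$lj_cutoff^2) return(0)
    sr6 <- (cfg$lj_sigma^2 / rr)^3
    4 * cfg$lj_epsilon * (sr6^2 - sr6)
  }
  epp <- 0
  ns <- nrow(solute)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j <= i) next
      rr <- r2(solute[i, ], solute[j, ])
      epp <- epp + if (j == i + 1) {
        0.5 * cfg$bond_k * (sqrt(rr) - cfg$bond_r0)^2
      } else {
        lj(rr)
      }
    }
  }
  epw <- 0
  for (i in seq_len(ns)) {
    for (j in seq_len(nrow(solvent))) {
      epw <- epw + lj(r2(solute[i, ], solvent[j, ]))
    }
  }
  eww <- 0
  for (i in seq_len(nrow(solvent))) {
    for (j in seq_len(nrow(solvent))) {
      if (j > i) eww <- eww + lj(r2(solvent[i, ], solvent[j, ]))
    }
  }
  c(epp = epp, epw = epw, eww = eww)
}

# --- gromos clustering, naive reference on a distance matrix ----------------
oracle_gromos <- function(d, cutoff) {
  n <- nrow(d)
  remaining <- seq_len(n)
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  k <- 0L
  while (length(remaining) > 0) {
    best <- remaining[1]
    best_count <- -1L
    for (f in remaining) {
      cnt <- sum(d[f, remaining] <= cutoff)
      if (cnt > best_count) {
        best <- f
        best_count <- cnt
      }
    }
    members <- remaining[d[best, remaining] <= cutoff]
    k <- k + 1L
    labels[members] <- k
    centers[k] <- best
    remaining <- setdiff(remaining, members)
  }
  list(labels = labels, centers = centers)
}

# --- DBSCAN, naive reachability reference -----------------------------------
oracle_dbscan_partition <- function(points, eps, min_samples) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  core <- sapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_samples)
  # connected components of core points under eps-adjacency
  comp <- rep(0L, n)
  k <- 0L
  for (i in which(core)) {
    if (comp[i] > 0) next
    k <- k + 1L
    stack <- i
    comp[i] <- k
    while (length(stack) > 0) {
      p <- stack[[1]]
      stack <- stack[-1]
      nb <- which(core & d[p, ] <= eps & comp == 0L)
      comp[nb] <- k
      stack <- c(stack, nb)
    }
  }
  # border points join some reachable core component; noise stays 0
  for (i in which(!core)) {
    near_core <- which(core & d[i, ] <= eps)
    if (length(near_core) > 0) comp[i] <- comp[near_core[1]]
  }
  comp
}

# same-partition check up to label permutation (border-point ownership may
# legitimately differ between implementations; callers pass core+noise only)
same_partition <- function(a, b) {
  ok <- TRUE
  for (x in unique(a)) {
    members <- which(a == x)
    ok <- ok && length(unique(b[members])) == 1
  }
  for (x in unique(b)) {
    members <- which(b == x)
    ok <- ok && length(unique(a[members])) == 1
  }
  ok
}

# --- rigid-fit RMSD by brute-force search over rotations --------------------
oracle_grid_rmsd <- function(mobile, reference, n_angle = 40) {
  a0 <- sweep(mobile, 2, colMeans(mobile))
  b0 <- sweep(reference, 2, colMeans(reference))
  ang <- seq(0, 2 * pi, length.out = n_angle + 1)[-(n_angle + 1)]
  rot <- function(ax, ay, az) {
    rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
    ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
    rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
    rz %*% ry %*% rx
  }
  val <- function(a) {
    r <- rot(a[1], a[2], a[3])
    sqrt(mean(rowSums((a0 %*% t(r) - b0)^2)))
  }
  best <- Inf
  best_a <- c(0, 0, 0)
  for (ax in ang) for (ay in ang) for (az in ang) {
    v <- val(c(ax, ay, az))
    if (v < best) {
      best <- v
      best_a <- c(ax, ay, az)
    }
  }
  # successive local grid refinement around the best coarse rotation
  width <- 2 * pi / n_angle
  for (lvl in 1:4) {
    g <- seq(-width, width, length.out = 9)
    for (ax in best_a[1] + g) for (ay in best_a[2] + g) for (az in best_a[3] + g) {
      v <- val(c(ax, ay, az))
      if (v < best) {
        best <- v
        best_a <- c(ax, ay, az)
      }
    }
    width <- width / 4
  }
  best
}

# --- Fig-style per-cluster strand fixture (synthetic, built in code) --------
strand_fixture_flags <- function() {
  mk <- function(sys) {
    t(vapply(sys, function(cl) 1:42 %in% unlist(cl), logical(42)))
  }
  free_state <- list(
    c1 = list(2:6, 15:24, 27:36),
    c2 = list(16:23, 38:41),
    c3 = list(10:13, 15:24, 27:36, 38:41),
    c4 = list(2:6, 10:13, 15:20, 27:36, 38:41),
    c5 = list(17:21, 30:36, 39:41),
    c6 = list(2:6, 10:13, 15:24, 27:36, 38:41)
  )
  bound_state <- list(
    c1 = list(2:6, 16:19, 26:31, 34:36),
    c2 = list(16:19, 27:33, 38:41),
    c3 = list(10:13, 28:33, 38:41),
    c4 = list(2:6, 17:21, 27:31, 39:41),
    c5 = list(10:13, 16:19, 28:33),
    c6 = list(2:6, 15:18, 20:24, 27:33, 38:41)
  )
  list(free = mk(free_state), bound = mk(bound_state))
}
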