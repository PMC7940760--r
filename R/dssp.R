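# Kabsch-Sander secondary-structure assignment on backbone geometry.
# The H-bond model is the electrostatic one behind DSSP:
#   E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol
# with a bond when E < -0.5 kcal/mol.

.ks_q <- 0.084 * 332 # kcal/mol * angstrom

#' Reconstruct the backbone amide hydrogen
#'
#' The N-H vector is taken antiparallel to the previous residue's C=O
#' bond: H = N + unit(C_prev - O_prev), bond length 1.0 angstrom. The
#' first residue of a chain has no amide H (it is never a donor).
#'
#' @param n Donor nitrogen position(s), 3-vector or n x 3 matrix.
#' @param c_prev,o_prev Carbonyl C and O of the preceding residue.
#' @return Position(s) of H, same shape as `n`.
#' @export
reconstruct_amide_h <- function(n, c_prev, o_prev) {
  v <- rbind(c_prev) - rbind(o_prev)
  v <- v / sqrt(rowSums(v^2))
  h <- rbind(n) + v
  if (is.matrix(n)) h else drop(h)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' @param donor_n,donor_h Donor backbone N and amide H positions
#'   (3-vectors or n x 3 matrices; see [reconstruct_amide_h()]).
#' @param acceptor_c,acceptor_o Acceptor carbonyl C and O positions.
#' @return Energy in kcal/mol; a hydrogen bond is present when the value
#'   is below -0.5.
#' @export
hbond_energy <- function(donor_n, donor_h, acceptor_c, acceptor_o) {
  dn <- rbind(donor_n); dh <- rbind(donor_h)
  ac <- rbind(acceptor_c); ao <- rbind(acceptor_o)
  d <- function(a, b) sqrt(rowSums((a - b)^2))
  r_on <- d(ao, dn); r_ch <- d(ac, dh)
  r_oh <- d(ao, dh); r_cn <- d(ac, dn)
  if (any(c(r_on, r_ch, r_oh, r_cn) < 0.5)) {
    abort("atoms closer than 0.5 angstrom: clashing geometry")
  }
  e <- .ks_q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  if (length(e) == 1) e[[1]] else e
}

# per-residue backbone coordinate matrices for one chain; rows with any
# missing atom are NA
backbone_matrices <- function(frame, topology, chain) {
  at <- topology$atoms
  sel <- at$chain_id == chain
  res_idx <- sort(unique(at$residue_index[sel]))
  n_res <- length(res_idx)
  out <- list()
  for (nm in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, nrow = n_res, ncol = 3)
    rows <- which(sel & at$atom_name == nm)
    m[match(at$residue_index[rows], res_idx), ] <- frame[rows, , drop = FALSE]
    out[[nm]] <- m
  }
  out$residue_index <- res_idx
  out
}

# full Kabsch-Sander H-bond matrix for one chain: hb[i, j] is TRUE when
# the amide of residue i donates to the carbonyl of residue j
ks_hbond_matrix <- function(bb) {
  n <- nrow(bb$N)
  h <- matrix(NA_real_, n, 3)
  if (n >= 2) {
    ok <- !is.na(bb$N[-1, 1]) & !is.na(bb$C[-n, 1]) & !is.na(bb$O[-n, 1])
    idx <- which(ok) + 1L
    if (length(idx) > 0) {
      h[idx, ] <- reconstruct_amide_h(
        bb$N[idx, , drop = FALSE],
        bb$C[idx - 1L, , drop = FALSE], bb$O[idx - 1L, , drop = FALSE]
      )
    }
  }
  pd <- function(a, b) {
    # pairwise distances between rows of a and rows of b
    an <- rowSums(a^2); bn <- rowSums(b^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  }
  zero_na <- function(m) { m[is.na(m)] <- 0; m }
  r_on <- pd(zero_na(bb$N), zero_na(bb$O))
  r_cn <- pd(zero_na(bb$N), zero_na(bb$C))
  r_oh <- pd(zero_na(h), zero_na(bb$O))
  r_ch <- pd(zero_na(h), zero_na(bb$C))
  eps <- 1e-9
  e <- .ks_q * (1 / pmax(r_on, eps) + 1 / pmax(r_ch, eps) -
                  1 / pmax(r_oh, eps) - 1 / pmax(r_cn, eps))
  # invalidate undefined donors/acceptors and clashing pairs
  bad_donor <- is.na(h[, 1]) | is.na(bb$N[, 1])
  bad_acceptor <- is.na(bb$C[, 1]) | is.na(bb$O[, 1])
  e[bad_donor, ] <- 0
  e[, bad_acceptor] <- 0
  clash <- r_on < 0.5 | r_cn < 0.5 | r_oh < 0.5 | r_ch < 0.5
  e[clash] <- 0
  sep <- abs(outer(seq_len(nrow(e)), seq_len(nrow(e)), "-"))
  hb <- e < -0.5 & sep >= 2
  diag(hb) <- FALSE
  hb
}

#' Assign secondary structure to one frame
#'
#' Implements the ladder logic of the Kabsch-Sander algorithm on the
#' chain's backbone: antiparallel/parallel bridges between residues at
#' least 3 apart, adjacent bridges of one type forming ladders (E),
#' isolated bridges (B), four-turn helix runs (H), isolated 3/4/5-turns
#' (T) and C-alpha bends over 70 degrees (S); everything else is coil (C).
#' Labels obey the priority E > B > H > T > S > C, and residues with
#' incomplete backbone geometry are coil.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching `rest2_topology`.
#' @param chain Chain id (defaults to the first chain).
#' @return Character vector of labels in `{E, B, H, T, S, C}`, one per
#'   residue of the chain.
#' @export
assign_ss <- function(frame, topology, chain = NULL) {
  if (is.null(chain)) chain <- topology$chains$chain_id[1]
  bb <- backbone_matrices(frame, topology, chain)
  n <- nrow(bb$N)
  hb <- ks_hbond_matrix(bb)
  # shifted view: S(M, a, b)[i, j] = M[i + a, j + b], FALSE outside
  S <- function(m, a, b) {
    out <- matrix(FALSE, n, n)
    ri <- seq_len(n) + a
    cj <- seq_len(n) + b
    ok_i <- ri >= 1 & ri <= n
    ok_j <- cj >= 1 & cj <= n
    out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j], drop = FALSE]
    out
  }
  th <- t(hb)
  sep_ok <- abs(outer(seq_len(n), seq_len(n), "-")) >= 3
  anti <- ((hb & th) | (S(hb, -1, 1) & S(th, 1, -1))) & sep_ok
  para <- ((S(hb, 0, -1) & S(th, 0, 1)) | (S(hb, -1, 0) & S(th, 1, 0))) &
    sep_ok
  anti <- anti | t(anti)
  para <- para | t(para)

  anti_ladder <- anti & (S(anti, 1, -1) | S(anti, -1, 1))
  para_ladder <- para & (S(para, 1, 1) | S(para, -1, -1))
  in_bridge <- rowSums(anti | para) > 0
  in_ladder <- rowSums(anti_ladder | para_ladder) > 0

  # n-turns: the amide of residue i+k donates to the carbonyl of i
  turn_of <- function(k) {
    t <- rep(FALSE, n)
    if (n > k) {
      i <- seq_len(n - k)
      t[i] <- hb[cbind(i + k, i)]
    }
    t
  }
  t3 <- turn_of(3); t4 <- turn_of(4); t5 <- turn_of(5)

  is_h <- rep(FALSE, n)
  for (i in seq_len(max(n - 4, 0))) {
    if (i >= 2 && t4[i - 1] && t4[i]) is_h[i:(i + 3)] <- TRUE
  }
  is_t <- rep(FALSE, n)
  for (k in c(3, 4, 5)) {
    tk <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
    for (i in which(tk)) is_t[(i + 1):(i + k - 1)] <- TRUE
  }

  is_s <- rep(FALSE, n)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      a <- bb$CA[i, ] - bb$CA[i - 2, ]
      b <- bb$CA[i + 2, ] - bb$CA[i, ]
      if (anyNA(a) || anyNA(b)) next
      cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      kappa <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      is_s[i] <- kappa > 70
    }
  }

  labels <- rep("C", n)
  labels[is_s] <- "S"
  labels[is_t] <- "T"
  labels[is_h] <- "H"
  labels[in_bridge & !in_ladder] <- "B"
  labels[in_ladder] <- "E"
  # residues lacking backbone geometry are always coil
  incomplete <- is.na(bb$N[, 1]) | is.na(bb$CA[, 1]) |
    is.na(bb$C[, 1]) | is.na(bb$O[, 1])
  labels[incomplete] <- "C"
  labels
}

#' Assign secondary structure over a whole trajectory
#'
#' @param trajectory A `rest2_trajectory`.
#' @param chain Chain id (defaults to the first chain).
#' @return An `ss_matrix`: frames x residues character matrix of labels.
#' @export
assign_ss_trajectory <- function(trajectory, chain = NULL) {
  topo <- trajectory$topology
  if (is.null(chain)) chain <- topo$chains$chain_id[1]
  nf <- n_frames(trajectory)
  rows <- lapply(seq_len(nf), function(f) {
    assign_ss(frame_coords(trajectory, f), topo, chain)
  })
  m <- do.call(rbind, rows)
  structure(m, class = c("ss_matrix", class(m)), chain = chain)
}

.ss_class_names <- c(
  C = "coil", E = "beta_sheet", B = "beta_bridge",
  H = "helix", T = "turn", S = "bend"
)

#' Average secondary-structure content
#'
#' Fractions of each class over all frames x residues; they sum to 1.
#'
#' @param ss An `ss_matrix` (frames x residues labels).
#' @return Tibble with `label`, `class` and `probability`.
#' @export
ss_content <- function(ss) {
  labs <- names(.ss_class_names)
  counts <- vapply(labs, function(l) sum(ss == l), numeric(1))
  tibble(
    label = labs,
    class = unname(.ss_class_names[labs]),
    probability = unname(counts) / length(ss)
  )
}

#' Residue-specific beta-sheet probability
#'
#' Per-residue fraction of frames labelled E (extended sheet). Bridges (B)
#' are excluded by default, matching the sheet-vs-bridge distinction of
#' the assignment; set `include_bridge = TRUE` to count both.
#'
#' @param ss An `ss_matrix`.
#' @param include_bridge Count B labels as beta too (default FALSE).
#' @return A `beta_profile` tibble with `residue` (1-based),
#'   `beta_probability`, and the ensemble mean as attribute
#'   `mean_beta` (also repeated in column `mean_beta`).
#' @export
residue_beta_profile <- function(ss, include_bridge = FALSE) {
  hits <- ss == "E"
  if (include_bridge) hits <- hits | ss == "B"
  p <- colMeans(hits)
  out <- tibble(
    residue = seq_along(p),
    beta_probability = as.numeric(p),
    mean_beta = mean(p)
  )
  attr(out, "mean_beta") <- mean(p)
  class(out) <- c("beta_profile", class(out))
  out
}

#' Histogram of beta-strand lengths
#'
#' Counts maximal runs of E per frame and normalises over all runs.
#'
#' @param ss An `ss_matrix`.
#' @param include_bridge Count B labels as beta too (default FALSE).
#' @return Tibble with `length`, `count` and `probability` (empty when no
#'   strand was ever formed).
#' @export
beta_length_histogram <- function(ss, include_bridge = FALSE) {
  lengths_all <- integer(0)
  for (f in seq_len(nrow(ss))) {
    hits <- ss[f, ] == "E"
    if (include_bridge) hits <- hits | ss[f, ] == "B"
    r <- rle(hits)
    lengths_all <- c(lengths_all, r$lengths[r$values])
  }
  if (length(lengths_all) == 0) {
    return(tibble(length = integer(0), count = integer(0),
                  probability = numeric(0)))
  }
  tb <- table(lengths_all)
  tibble(
    length = as.integer(names(tb)),
    count = as.integer(tb),
    probability = as.integer(tb) / sum(tb)
  )
}
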