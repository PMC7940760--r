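#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# element -> mass (Da); deliberately small: unknown elements must error,
# never default to 0
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971
)

# one-letter -> three-letter residue codes
.aa1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.aa3to1 <- stats::setNames(names(.aa1to3), .aa1to3)

#' Chemical class of a residue
#'
#' D and E are acidic; K and R basic; H, S, T, N, Q, Y and G polar
#' (histidine is treated as neutral-polar at pH 7, so it never enters
#' salt-bridge analysis); everything else hydrophobic.
#'
#' @param code One-letter residue codes (vectorised).
#' @return Character vector in `c("acidic", "basic", "polar", "hydrophobic")`.
#' @export
residue_class <- function(code) {
  code <- toupper(code)
  dplyr::case_when(
    code %in% c("D", "E") ~ "acidic",
    code %in% c("K", "R") ~ "basic",
    code %in% c("H", "S", "T", "N", "Q", "Y", "G") ~ "polar",
    TRUE ~ "hydrophobic"
  )
}

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    abort(paste0(
      "unknown element(s): ",
      paste(unique(element[is.na(m)]), collapse = ", ")
    ))
  }
  unname(m)
}

#' Build a topology from an atom table
#'
#' The native representation is a reduced backbone (N, CA, C, O and an
#' optional side-chain tip atom per residue), but any atom set is accepted;
#' extra heavy atoms simply take part in heavy-atom analyses.
#'
#' @param atoms Data frame with columns `atom_name`, `element`,
#'   `residue_index` (0-based, contiguous per chain), `residue_name`
#'   (3-letter code) and `chain_id`.
#' @param chain_roles Named character vector mapping chain id to
#'   `"ligand"`/`"receptor"` (optional; used by inter-chain analyses).
#' @return A `rest2_topology` object.
#' @export
new_topology <- function(atoms, chain_roles = NULL) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_name", "element", "residue_index", "residue_name", "chain_id")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  atoms <- atoms |>
    mutate(
      atom_name = toupper(.data$atom_name),
      element = toupper(.data$element),
      mass = element_mass(.data$element),
      is_backbone = .data$atom_name %in% c("N", "CA", "C", "O"),
      is_heavy = .data$element != "H"
    )
  residues <- atoms |>
    distinct(.data$chain_id, .data$residue_index, .data$residue_name) |>
    arrange(.data$chain_id, .data$residue_index) |>
    mutate(
      code1 = unname(.aa3to1[.data$residue_name]),
      class = residue_class(ifelse(is.na(.data$code1), "X", .data$code1))
    )
  chains <- tibble(chain_id = unique(atoms$chain_id))
  chains$role <- if (is.null(chain_roles)) {
    NA_character_
  } else {
    unname(chain_roles[chains$chain_id])
  }
  structure(
    list(atoms = atoms, residues = residues, chains = chains),
    class = "rest2_topology"
  )
}

#' @export
print.rest2_topology <- function(x, ...) {
  cat(
    "<rest2_topology> ", nrow(x$atoms), " atoms, ",
    nrow(x$residues), " residues, ",
    nrow(x$chains), " chain(s)\n",
    sep = ""
  )
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Human-readable residue labels (1-based, e.g. "D1", "A42")
#'
#' @param topology A `rest2_topology`.
#' @param chain Chain id; defaults to the first chain.
#' @return Character vector, one label per residue of the chain.
#' @export
residue_labels <- function(topology, chain = NULL) {
  res <- topology$residues
  if (is.null(chain)) chain <- res$chain_id[1]
  res <- res[res$chain_id == chain, ]
  code <- ifelse(is.na(res$code1), "X", res$code1)
  paste0(code, res$residue_index + 1L)
}

#' Select atoms from a topology
#'
#' @param topology A `rest2_topology`.
#' @param what One of `"backbone"` (N, CA, C, O), `"heavy"` or `"all"`.
#' @param chain Optional chain id restriction.
#' @param residues Optional 0-based residue index vector or inclusive
#'   range restriction (applies within `chain` if given).
#' @return Strictly increasing integer vector of atom indices (1-based,
#'   valid for every frame of a trajectory over this topology).
#' @export
select_atoms <- function(topology, what = c("backbone", "heavy", "all"),
                         chain = NULL, residues = NULL) {
  what <- match.arg(what)
  at <- topology$atoms
  keep <- switch(what,
    backbone = at$is_backbone,
    heavy = at$is_heavy,
    all = rep(TRUE, nrow(at))
  )
  if (!is.null(chain)) keep <- keep & at$chain_id %in% chain
  if (!is.null(residues)) keep <- keep & at$residue_index %in% residues
  idx <- which(keep)
  if (length(idx) == 0) {
    abort("empty atom selection; refusing to run analytics on nothing")
  }
  idx
}

#' Construct a trajectory
#'
#' @param topology A `rest2_topology`.
#' @param coords A list of n_atoms x 3 coordinate matrices (one per frame,
#'   in angstrom) or a 3-d array `[atom, xyz, frame]`.
#' @return A `rest2_trajectory`.
#' @export
new_trajectory <- function(topology, coords) {
  if (is.list(coords)) {
    if (length(coords) == 0) abort("a trajectory needs at least one frame")
    coords <- array(
      unlist(coords, use.names = FALSE),
      dim = c(nrow(coords[[1]]), 3, length(coords))
    )
  }
  if (dim(coords)[1] != n_atoms(topology)) {
    abort("coordinate count does not match topology atom count")
  }
  if (!all(is.finite(coords))) abort("non-finite coordinates")
  structure(
    list(topology = topology, coords = coords),
    class = "rest2_trajectory"
  )
}

#' @export
print.rest2_trajectory <- function(x, ...) {
  cat(
    "<rest2_trajectory> ", n_frames(x), " frame(s) x ",
    dim(x$coords)[1], " atoms\n",
    sep = ""
  )
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `rest2_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Coordinates of one frame
#' @param trajectory A `rest2_trajectory`.
#' @param i Frame number (1-based).
#' @return n_atoms x 3 matrix (angstrom).
#' @export
frame_coords <- function(trajectory, i) {
  trajectory$coords[, , i, drop = FALSE][, , 1]
}

#' Mass-weighted (or geometric) centre of mass
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching `rest2_topology` (for masses).
#' @param indices Atom indices to include.
#' @param weighted Mass-weighted (default) or plain geometric mean.
#' @return Length-3 numeric vector (angstrom).
#' @export
center_of_mass <- function(frame, topology, indices = seq_len(nrow(frame)),
                           weighted = TRUE) {
  if (length(indices) == 0) abort("empty selection in center_of_mass()")
  xyz <- frame[indices, , drop = FALSE]
  w <- if (weighted) topology$atoms$mass[indices] else rep(1, length(indices))
  colSums(xyz * w) / sum(w)
}

#' Radius of gyration of a selection
#'
#' Mass-weighted spread about the selection centre of mass:
#' sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i)).
#'
#' @inheritParams center_of_mass
#' @return Non-negative scalar (angstrom).
#' @export
radius_of_gyration <- function(frame, topology, indices = seq_len(nrow(frame)),
                               weighted = TRUE) {
  if (length(indices) == 0) abort("empty selection in radius_of_gyration()")
  com <- center_of_mass(frame, topology, indices, weighted)
  xyz <- sweep(frame[indices, , drop = FALSE], 2, com)
  w <- if (weighted) topology$atoms$mass[indices] else rep(1, length(indices))
  sqrt(sum(w * rowSums(xyz^2)) / sum(w))
}
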