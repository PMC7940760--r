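#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL records delimit frames; a file without MODEL records yields
#' a single-frame trajectory. Only ATOM records are parsed (fixed columns).
#' Residue indices are re-based to contiguous 0-based indices per chain in
#' order of appearance.
#'
#' @param path Path to a PDB file.
#' @param chain_roles Optional named vector of chain roles, see
#'   [new_topology()].
#' @return A `rest2_trajectory`.
#' @export
read_multimodel_pdb <- function(path, chain_roles = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  atom_line <- rec == "ATOM  "
  model_open <- which(rec == "MODEL ")
  if (length(model_open) == 0) {
    frames_at <- list(which(atom_line))
  } else {
    model_close <- which(rec == "ENDMDL")
    if (length(model_close) != length(model_open)) {
      abort("unbalanced MODEL/ENDMDL records")
    }
    frames_at <- Map(
      function(a, b) intersect(which(atom_line), seq(a, b)),
      model_open, model_close
    )
  }
  if (length(frames_at[[1]]) == 0) abort("no ATOM records found")

  parse_block <- function(idx) {
    ll <- lines[idx]
    x <- suppressWarnings(as.numeric(substr(ll, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ll, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ll, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad) > 0) {
      abort(paste0("unparseable ATOM record at line ", idx[bad[1]]))
    }
    list(
      atom_name = trimws(substr(ll, 13, 16)),
      residue_name = trimws(substr(ll, 18, 20)),
      chain_id = substr(ll, 22, 22),
      res_seq = trimws(substr(ll, 23, 26)),
      element = trimws(substr(ll, 77, 78)),
      xyz = cbind(x, y, z)
    )
  }

  first <- parse_block(frames_at[[1]])
  n_at <- length(first$atom_name)
  # element column may be absent in minimal files; fall back on the first
  # character of the atom name
  element <- first$element
  blank <- element == ""
  element[blank] <- substr(gsub("[0-9]", "", first$atom_name[blank]), 1, 1)
  # 0-based contiguous residue indices per chain, order of appearance
  res_key <- paste(first$chain_id, first$res_seq, sep = "|")
  residue_index <- as.integer(factor(res_key, levels = unique(res_key)))
  residue_index <- stats::ave(
    residue_index, first$chain_id,
    FUN = function(v) match(v, sort(unique(v))) - 1L
  )
  topo <- new_topology(
    tibble(
      atom_name = first$atom_name,
      element = element,
      residue_index = as.integer(residue_index),
      residue_name = first$residue_name,
      chain_id = first$chain_id
    ),
    chain_roles = chain_roles
  )

  coords <- lapply(seq_along(frames_at), function(k) {
    idx <- frames_at[[k]]
    if (length(idx) != n_at) {
      abort(paste0(
        "model ", k, " has ", length(idx),
        " atoms; expected ", n_at
      ))
    }
    parse_block(idx)$xyz
  })
  new_trajectory(topo, coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the format's native 0.001 angstrom precision,
#' one MODEL/ENDMDL block per frame.
#'
#' @param trajectory A `rest2_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  at <- trajectory$topology$atoms
  res_seq <- at$residue_index + 1L
  name_field <- ifelse(
    nchar(at$atom_name) >= 4,
    substr(at$atom_name, 1, 4),
    sprintf(" %-3s", at$atom_name)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_coords(trajectory, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)) %% 100000L, name_field, at$residue_name,
      at$chain_id, res_seq %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
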