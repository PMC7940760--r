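#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over the rows
#' given by `indices`; the proper rotation is enforced by the determinant
#' correction of the SVD solution. The returned transform maps mobile
#' coordinates as `x %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param indices Rows used for the fit (default: all); at least 3
#'   non-collinear points.
#' @return List with `rotation` (3 x 3), `translation` (length 3), and
#'   `rmsd` (the minimised RMSD over the fitted rows, angstrom).
#' @export
superpose <- function(mobile, reference, indices = seq_len(nrow(mobile))) {
  if (length(indices) < 3) abort("superposition needs at least 3 atoms")
  a <- mobile[indices, , drop = FALSE]
  b <- reference[indices, , drop = FALSE]
  if (nrow(a) != nrow(b)) abort("selection size differs between structures")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (min(svd(a0)$d) < 1e-8 * max(svd(a0)$d, 1e-30)) {
    abort("degenerate (collinear or coincident) selection")
  }
  s <- svd(crossprod(a0, b0)) # 3x3
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- a0 %*% r
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rotation = r, translation = cb - drop(ca %*% r), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param fit Result of [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

#' Pairwise superposed RMSD matrix
#'
#' @param trajectory A `rest2_trajectory`.
#' @param indices Atom indices used both for the fit and the RMSD.
#' @return Symmetric n_frames x n_frames matrix (angstrom).
#' @export
pairwise_rmsd <- function(trajectory, indices) {
  nf <- n_frames(trajectory)
  sel <- lapply(seq_len(nf), function(f) {
    frame_coords(trajectory, f)[indices, , drop = FALSE]
  })
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      m[i, j] <- m[j, i] <- superpose(sel[[i]], sel[[j]])$rmsd
    }
  }
  m
}

#' Conformational clustering by iterative neighbour counting
#'
#' The gromos algorithm: the frame with the most neighbours within
#' `cutoff` (superposed RMSD) becomes a cluster centre; it and its
#' neighbours are removed and the procedure repeats until no frame is
#' left. Ties in neighbour count go to the lowest frame index, making the
#' result deterministic. Singleton clusters are allowed.
#'
#' @param trajectory A `rest2_trajectory`.
#' @param indices Atom indices for fit + RMSD (e.g. the backbone); default
#'   backbone of the first chain.
#' @param cutoff RMSD cutoff in angstrom (default 2.0, i.e. 0.2 nm).
#' @param rmsd_matrix Optional precomputed pairwise RMSD matrix.
#' @return A `cluster_result`: `labels` (per-frame cluster id, 1-based in
#'   discovery order), `centers` (representative frame index per cluster),
#'   `populations` (fractions, non-increasing).
#' @export
gromos_cluster <- function(trajectory, indices = NULL, cutoff = 2.0,
                           rmsd_matrix = NULL) {
  nf <- n_frames(trajectory)
  if (is.null(rmsd_matrix)) {
    if (is.null(indices)) {
      indices <- select_atoms(trajectory$topology, "backbone",
                              chain = trajectory$topology$chains$chain_id[1])
    }
    rmsd_matrix <- pairwise_rmsd(trajectory, indices)
  }
  neighbour <- rmsd_matrix <= cutoff
  diag(neighbour) <- TRUE
  labels <- rep(NA_integer_, nf)
  centers <- integer(0)
  remaining <- rep(TRUE, nf)
  k <- 0L
  while (any(remaining)) {
    counts <- colSums(neighbour[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts) # ties -> lowest index
    members <- which(remaining & neighbour[center, ])
    k <- k + 1L
    labels[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  structure(
    list(
      labels = labels, centers = centers,
      populations = as.numeric(tabulate(labels, k) / nf),
      n_frames = nf, cutoff = cutoff
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(
    "<cluster_result> ", length(x$centers), " cluster(s) over ",
    x$n_frames, " frames; top populations: ",
    paste(sprintf("%.3f", utils::head(x$populations, 5)), collapse = ", "),
    "\n", sep = ""
  )
  invisible(x)
}

#' Binding-pose points: ligand centre of mass in the receptor frame
#'
#' Every frame is superposed onto the reference frame using the receptor
#' backbone selection, the transform is applied to the whole frame, and
#' the ligand centre of mass is recorded. Pose points are therefore
#' invariant under global rigid motion of the complex.
#'
#' @param trajectory A `rest2_trajectory`.
#' @param receptor_indices Atom indices used for the superposition
#'   (typically the receptor backbone).
#' @param ligand_indices Atom indices whose centre of mass is reported.
#' @param reference_frame Frame number defining the receptor frame
#'   (default 1, the starting structure), or an n_atoms x 3 coordinate
#'   matrix of a reference structure (only the `receptor_indices` rows
#'   are used for the fit).
#' @param weighted Mass-weighted COM (default) or geometric.
#' @return Tibble with `frame`, `x`, `y`, `z` (angstrom).
#' @export
pose_points <- function(trajectory, receptor_indices, ligand_indices,
                        reference_frame = 1, weighted = TRUE) {
  topo <- trajectory$topology
  ref <- if (is.matrix(reference_frame)) {
    reference_frame
  } else {
    frame_coords(trajectory, reference_frame)
  }
  out <- matrix(0, n_frames(trajectory), 3)
  for (f in seq_len(n_frames(trajectory))) {
    fr <- frame_coords(trajectory, f)
    fit <- superpose(fr, ref, receptor_indices)
    moved <- apply_transform(fr, fit)
    out[f, ] <- center_of_mass(moved, topo, ligand_indices, weighted)
  }
  tibble(
    frame = seq_len(n_frames(trajectory)),
    x = out[, 1], y = out[, 2], z = out[, 3]
  )
}

#' Density-based clustering (DBSCAN)
#'
#' Core points have at least `min_samples` points (self included) within
#' `eps`; clusters are the connected components of core points, plus
#' border points claimed by the first cluster whose core reaches them in
#' scan order (a deterministic resolution of the algorithm's border
#' ambiguity). Points reachable from no core are noise, labelled -1.
#'
#' @param points n x d numeric matrix, or a data frame whose numeric
#'   columns (e.g. the x/y/z of [pose_points()]) are used.
#' @param eps Neighbourhood radius (same units as the points; default 3).
#' @param min_samples Core threshold (default 20).
#' @return A `pose_clusters` object: `labels` (1-based ids, -1 noise),
#'   `centroids` (cluster mean points), `populations` (fractions of all
#'   points; noise excluded, so they sum to <= 1).
#' @export
dbscan_cluster <- function(points, eps = 3, min_samples = 20) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[vapply(points, is.numeric, logical(1))])
    if ("frame" %in% colnames(points)) {
      points <- points[, colnames(points) != "frame", drop = FALSE]
    }
  }
  if (eps <= 0 || min_samples < 1) abort("need eps > 0 and min_samples >= 1")
  n <- nrow(points)
  d2 <- as.matrix(stats::dist(points))^2
  nbr <- d2 <= eps^2
  core <- rowSums(nbr) >= min_samples
  labels <- rep(0L, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    k <- k + 1L
    queue <- i
    labels[i] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      reach <- which(nbr[p, ] & labels == 0L)
      if (length(reach) > 0) {
        labels[reach] <- k
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  labels[labels == 0L] <- -1L
  ids <- sort(unique(labels[labels > 0]))
  centroids <- t(vapply(
    ids,
    function(id) colMeans(points[labels == id, , drop = FALSE]),
    numeric(ncol(points))
  ))
  structure(
    list(
      labels = labels,
      centroids = centroids,
      populations = vapply(ids, function(id) mean(labels == id), numeric(1)),
      n_noise = sum(labels == -1L), eps = eps, min_samples = min_samples
    ),
    class = "pose_clusters"
  )
}

#' @export
print.pose_clusters <- function(x, ...) {
  cat(
    "<pose_clusters> ", nrow(x$centroids), " cluster(s), ",
    x$n_noise, " noise point(s)\n", sep = ""
  )
  invisible(x)
}
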