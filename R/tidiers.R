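#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the exchange attempts of a replica-exchange run
#'
#' @param x A `rest2_run`.
#' @param ... Unused.
#' @return Tibble with one row per exchange attempt (`step`, `rung_i`,
#'   `rung_j`, `prob`, `accepted`).
#' @export
tidy.rest2_run <- function(x, ...) x$history$attempts

#' One-row summary of a replica-exchange run
#'
#' @param x A `rest2_run`.
#' @param ... Unused.
#' @return Tibble with `n_replicas`, `n_steps`, `mean_acceptance`,
#'   `propagation_acceptance`, `round_trips`, `t0`, `tmax`.
#' @export
glance.rest2_run <- function(x, ...) {
  tibble(
    n_replicas = length(x$ladder),
    n_steps = nrow(x$history$occupancy),
    mean_acceptance = x$diagnostics$mean_acceptance,
    propagation_acceptance = x$diagnostics$propagation_acceptance,
    round_trips = x$diagnostics$round_trips,
    t0 = x$ladder[1], tmax = x$ladder[length(x$ladder)]
  )
}

#' Tidy a conformational clustering result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble with `frame` and `cluster`.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(frame = seq_len(x$n_frames), cluster = x$labels)
}

#' One-row summary of a conformational clustering result
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(
    n_clusters = length(x$centers),
    n_frames = x$n_frames,
    top_population = max(x$populations),
    cutoff = x$cutoff
  )
}

#' Tidy a pose-clustering result
#'
#' @param x A `pose_clusters`.
#' @param ... Unused.
#' @return Tibble with `point` and `cluster` (-1 = noise).
#' @export
tidy.pose_clusters <- function(x, ...) {
  tibble(point = seq_along(x$labels), cluster = x$labels)
}

#' Tidy a secondary-structure matrix into long form
#'
#' @param x An `ss_matrix`.
#' @param ... Unused.
#' @return Tibble with `frame`, `residue` (1-based) and `label`.
#' @export
tidy.ss_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    frame = rep(seq_len(nrow(m)), times = ncol(m)),
    residue = rep(seq_len(ncol(m)), each = nrow(m)),
    label = as.vector(m)
  )
}

#' Tidy a contact map into long form
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return Tibble with `residue_i`, `residue_j` (1-based) and
#'   `probability`.
#' @export
tidy.contact_map <- function(x, ...) {
  m <- unclass(x)
  tibble(
    residue_i = rep(seq_len(nrow(m)), times = ncol(m)),
    residue_j = rep(seq_len(ncol(m)), each = nrow(m)),
    probability = as.vector(m)
  )
}
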