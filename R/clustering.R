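#' Greedy RMSD-cutoff (Daura) conformational clustering
#'
#' The neighbor count of every frame is the number of other frames within
#' `cutoff` (least-squares-fitted RMSD over the selection). Iteratively, the
#' frame with the most neighbors is taken as a cluster centroid, it and its
#' neighbors are removed as one cluster, and the counts are recomputed over
#' the remaining frames until none are left. Ties on the neighbor count are
#' broken deterministically toward the lowest frame index. Clusters are
#' numbered 1, 2, ... in decreasing size order (ties again by centroid index).
#'
#' @param traj a `trajectory`.
#' @param selection atom ids used in the pairwise RMSD.
#' @param cutoff neighbor cutoff in Angstrom (> 0).
#' @return a `daura_clusters` object: list with `assignments` (integer per
#'   frame), `centroids` (frame index per cluster), `sizes`, `cutoff`.
#' @export
daura_cluster <- function(traj, selection = NULL, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  ids <- if (is.null(selection)) top$atom_id else as_selection_ids(selection, top)
  d <- pairwise_rmsd(traj, ids, fit = TRUE)
  nf <- nrow(d)
  adj <- d <= cutoff
  diag(adj) <- FALSE
  remaining <- rep(TRUE, nf)
  assignments <- integer(nf)
  centroids <- integer(0)
  k <- 0L
  while (any(remaining)) {
    counts <- rowSums(adj[, remaining, drop = FALSE])
    counts[!remaining] <- -1L
    centre <- which.max(counts)          # which.max returns the lowest index on ties
    members <- which(remaining & (adj[centre, ] | seq_len(nf) == centre))
    k <- k + 1L
    assignments[members] <- k
    centroids[k] <- centre
    remaining[members] <- FALSE
  }
  sizes <- tabulate(assignments, nbins = k)
  ord <- order(-sizes, centroids)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(assignments = relabel[assignments],
                 centroids = centroids[ord],
                 sizes = sizes[ord], cutoff = cutoff),
            class = "daura_clusters")
}

#' @export
print.daura_clusters <- function(x, ...) {
  cat("<daura_clusters> ", length(x$sizes), " cluster(s) over ",
      length(x$assignments), " frames (cutoff ", x$cutoff, " A)\n", sep = "")
  cat(" sizes:", paste(utils::head(x$sizes, 10), collapse = " "),
      if (length(x$sizes) > 10) "...", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.daura_clusters <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$assignments), cluster = x$assignments,
                 is_centroid = seq_along(x$assignments) %in% x$centroids)
}

#' @export
glance.daura_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$sizes),
                 n_frames = length(x$assignments),
                 largest_cluster = x$sizes[1],
                 largest_fraction = x$sizes[1] / length(x$assignments),
                 cutoff = x$cutoff)
}

#' Write cluster centroids as a multi-MODEL PDB
#'
#' @param clusters a `daura_clusters`.
#' @param traj the clustered `trajectory`.
#' @param path output PDB path.
#' @export
write_centroids <- function(clusters, traj, path) {
  sub <- traj$coords[clusters$centroids, , , drop = FALSE]
  write_trajectory(new_trajectory(traj$topology, sub), path,
                   format = "pdb_multimodel")
}
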