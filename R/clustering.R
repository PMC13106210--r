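#' GROMOS (Daura) conformational clustering
#'
#' Frames are clustered on their pairwise superposed RMSD: repeatedly take
#' the frame with the most neighbours within the cutoff as a cluster
#' centre, assign it and its neighbours to one cluster, remove them, and
#' continue until no frames remain. A stable trajectory visits few
#' clusters, has a large first cluster and low average pairwise RMSD.
#'
#' @name clustering
NULL

#' All-pairs superposed RMSD between frames
#'
#' @param traj `md_trajectory`, at least 2 frames.
#' @param selection atom selection (default `"calpha"`).
#' @return Symmetric n_frames x n_frames matrix in nm (zero diagonal);
#'   entry (i, j) is the minimum RMSD after Kabsch superposition of frame i
#'   onto frame j.
#' @export
pairwise_rmsd_matrix <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  cube <- aperm(traj$coords[, idx, , drop = FALSE], c(2, 3, 1))
  cpp_pairwise_rmsd(cube) / 10  # Angstrom -> nm
}

#' GROMOS clustering of an RMSD matrix
#'
#' Neighbourhood is strict (`rmsd < cutoff`); ties in neighbour count are
#' broken towards the lowest frame index. Clusters are returned ordered by
#' decreasing size (ties again by centre index).
#'
#' @param m symmetric pairwise RMSD matrix, nm.
#' @param cutoff RMSD cutoff, nm (default 0.2).
#' @return List of class `cluster_result`: `clusters` (list of
#'   `list(center, members)`, members including the centre), `cutoff`,
#'   `n_clusters`, `first_cluster_size`, `mean_pairwise_rmsd` (mean of the
#'   upper triangle of `m`, nm).
#' @export
gromos_cluster <- function(m, cutoff = 0.2) {
  m <- as.matrix(m)
  n <- nrow(m)
  stopifnot(n == ncol(m), n >= 1L)
  mean_rmsd <- if (n > 1L) mean(m[upper.tri(m)]) else 0
  neigh <- m < cutoff
  diag(neigh) <- TRUE
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    counts <- rowSums(neigh[, alive, drop = FALSE]) * alive
    center <- which.max(counts)  # ties -> lowest index
    members <- which(alive & neigh[center, ])
    clusters[[length(clusters) + 1L]] <- list(center = center, members = members)
    alive[members] <- FALSE
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  ord <- order(-sizes, vapply(clusters, function(cl) cl$center, integer(1)))
  clusters <- clusters[ord]
  structure(list(clusters = clusters, cutoff = cutoff,
                 n_clusters = length(clusters),
                 first_cluster_size = length(clusters[[1]]$members),
                 mean_pairwise_rmsd = mean_rmsd),
            class = "cluster_result")
}

#' Cluster a trajectory
#'
#' Convenience wrapper: [pairwise_rmsd_matrix()] then [gromos_cluster()].
#'
#' @inheritParams pairwise_rmsd_matrix
#' @param cutoff RMSD cutoff, nm.
#' @return `cluster_result`.
#' @export
cluster_trajectory <- function(traj, selection = "calpha", cutoff = 0.2) {
  if (n_frames(traj) == 1L) {
    return(structure(list(clusters = list(list(center = 1L, members = 1L)),
                          cutoff = cutoff, n_clusters = 1L,
                          first_cluster_size = 1L, mean_pairwise_rmsd = 0),
                     class = "cluster_result"))
  }
  gromos_cluster(pairwise_rmsd_matrix(traj, selection), cutoff = cutoff)
}

#' The three reported clustering scalars
#'
#' @param result `cluster_result`.
#' @return Named numeric vector: `n_clusters`, `first_cluster_size`,
#'   `mean_pairwise_rmsd` (nm).
#' @export
cluster_summary <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  c(n_clusters = result$n_clusters,
    first_cluster_size = result$first_cluster_size,
    mean_pairwise_rmsd = result$mean_pairwise_rmsd)
}

#' Write cluster-centre frames as a multi-model PDB
#'
#' @param traj the clustered `md_trajectory`.
#' @param result `cluster_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_centers <- function(traj, result, path) {
  centers <- vapply(result$clusters, function(cl) cl$center, integer(1))
  sub <- traj$coords[centers, , , drop = FALSE]
  write_trajectory(md_trajectory(traj$topology, sub, traj$timestep), path)
}
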