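## Clustering and ranking of recorded encounter complexes.
## Poses are compared by fixed-frame RMSD (both poses expressed in the
## nucleosome frame, no re-superposition), computed in closed form from
## the pose parameters and the second moments of the mobile solute's
## C-alpha (bead) coordinates.

#' Pairwise pose RMSD matrix of a recorded set
#'
#' @param rs a `recorded_set` with at least 2 records.
#' @param lh optional `lh_model`; defaults to the RMSD bookkeeping stored
#'   in the archive.
#' @return symmetric matrix of RMSDs, Angstrom, zero diagonal; rows in
#'   energy order (matching [as.data.frame.recorded_set()]).
#' @export
pose_rmsd_matrix <- function(rs, lh = NULL) {
  if (rs$n < 2) stop("need at least 2 records")
  meta <- if (is.null(lh)) rs$meta else .rmsd_meta(lh)
  ord <- order(rs$E)
  pose_rmsd_mat_cpp(rs$Q[ord, , drop = FALSE], rs$T[ord, , drop = FALSE],
                    meta$M, meta$ybar, as.integer(meta$n_atoms))
}

#' Cluster the recorded set into ranked groups
#'
#' Average-linkage hierarchical clustering on the pose RMSD matrix, cut to
#' `k` groups. Clusters are ranked by occurrence-weighted size (the sum of
#' the members' counts), ties broken by lower representative energy; the
#' representative of each cluster is its lowest-energy member.
#'
#' @param rs a `recorded_set`.
#' @param k number of clusters (default 10).
#' @param lh optional `lh_model` overriding the stored RMSD bookkeeping.
#' @return list of clusters, each a list with `rank`, `members` (row
#'   indices into `as.data.frame(rs)`), `weighted_size`,
#'   `population_fraction`, `representative` (row index), and
#'   `representative_pose`.
#' @export
cluster_recorded_set <- function(rs, k = 10, lh = NULL) {
  if (rs$n == 0) return(list())
  df <- as.data.frame(rs)
  if (rs$n < k) {
    warning(sprintf("only %d records for k = %d: returning singletons", rs$n, k))
    assignment <- seq_len(rs$n)
  } else if (rs$n == 1) {
    assignment <- 1L
  } else {
    rmat <- pose_rmsd_matrix(rs, lh)
    hc <- stats::hclust(stats::as.dist(rmat), method = "average")
    assignment <- stats::cutree(hc, k = k)
  }
  total <- sum(df$count)
  clusters <- lapply(sort(unique(assignment)), function(g) {
    members <- which(assignment == g)
    rep_i <- members[which.min(df$energy[members])]
    list(members = members, weighted_size = sum(df$count[members]),
         representative = rep_i,
         representative_pose = pose(as.numeric(df[rep_i, c("qw", "qx", "qy", "qz")]),
                                    as.numeric(df[rep_i, c("tx", "ty", "tz")])),
         representative_energy = df$energy[rep_i],
         population_fraction = sum(df$count[members]) / total)
  })
  ## rank: weighted size descending, ties by lower representative energy
  ord <- order(-vapply(clusters, `[[`, numeric(1), "weighted_size"),
               vapply(clusters, `[[`, numeric(1), "representative_energy"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$rank <- i
  clusters
}

#' First n clusters by rank
#'
#' @param clusters a [cluster_recorded_set()] result.
#' @param n how many (default 2, the two largest encounter-complex
#'   clusters used for configuration analysis).
#' @return list of the first `n` clusters (all of them when `n` exceeds
#'   the cluster count).
#' @export
top_clusters <- function(clusters, n = 2) {
  clusters[seq_len(min(n, length(clusters)))]
}

#' Serialize clusters to a JSON-ready list
#'
#' @param clusters a [cluster_recorded_set()] result.
#' @return list of plain lists (members, weighted sizes, fractions,
#'   representative pose as quaternion + translation).
#' @export
clusters_to_list <- function(clusters) {
  lapply(clusters, function(cl) {
    list(rank = cl$rank, members = cl$members,
         weighted_size = cl$weighted_size,
         population_fraction = cl$population_fraction,
         representative = cl$representative,
         representative_energy = cl$representative_energy,
         representative_pose = list(q = cl$representative_pose$q,
                                    t = cl$representative_pose$t))
  })
}
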