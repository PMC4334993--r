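# Greedy clustering of top poses by ligand C-alpha RMSD in the fixed
# receptor frame (no re-superposition), the refinement-stage convention:
# repeatedly pick the unassigned pose with the most unassigned neighbors
# within the radius as a cluster center and absorb that neighborhood.

#' Ligand C-alpha RMSD between two poses
#'
#' Both poses are applied to the same ligand C-alpha coordinates in the
#' receptor frame; no re-superposition is performed.
#'
#' @param pose_a,pose_b lists with `rotation` and `translation`.
#' @param ligand_ca_coords n x 3 matrix of ligand C-alpha coordinates.
#' @param centroid rotation origin (default: ligand centroid of the CA set;
#'   pass the all-atom centroid when poses come from [dock_rigid()]).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose_a, pose_b, ligand_ca_coords, centroid = NULL) {
  x <- as.matrix(ligand_ca_coords)
  if (ncol(x) != 3) stop("coordinate shape error", call. = FALSE)
  a <- pose_transform(x, pose_a, centroid)
  b <- pose_transform(x, pose_b, centroid)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Greedy RMSD clustering of top-scored poses
#'
#' @param poses a `pose_list` from [dock_rigid()].
#' @param ligand atom table or bundle the poses refer to (C-alpha atoms are
#'   extracted; used for pose-pose RMSD).
#' @param radius cluster radius, Angstrom (default 9).
#' @param M pose pool size: the top-M poses are clustered (default 1000).
#' @return list of class `pose_clustering`: `clusters` (each with `center`,
#'   `members` — pose ranks — and `size`, in creation order) and `rmsd_radius`.
#'   Ties in neighbor count go to the higher-scoring (lower-rank) pose.
#' @export
greedy_cluster <- function(poses, ligand, radius = 9, M = 1000) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  if (inherits(ligand, "structure_bundle")) ligand <- model_atoms(ligand, 1L)
  df <- poses$poses
  if (nrow(df) == 0L) stop("empty pose list", call. = FALSE)
  m <- min(M, nrow(df))
  df <- df[seq_len(m), , drop = FALSE]
  ca <- atom_coords(ligand[ligand$name == "CA", , drop = FALSE])
  if (nrow(ca) == 0L) stop("ligand has no C-alpha atoms", call. = FALSE)
  ctr <- colMeans(atom_coords(ligand))
  # no re-superposition => RMSD(a, b) = |flat_a - flat_b| / sqrt(n_ca)
  flat <- t(vapply(seq_len(m), function(i) {
    p <- list(rotation = poses$rotations[[df$rotation_index[i]]],
              translation = c(df$tx[i], df$ty[i], df$tz[i]))
    as.vector(pose_transform(ca, p, ctr))
  }, double(3 * nrow(ca))))
  d <- as.matrix(stats::dist(flat)) / sqrt(nrow(ca))
  dimnames(d) <- NULL
  nbr <- d <= radius            # includes self
  unassigned <- rep(TRUE, m)
  clusters <- list()
  while (any(unassigned)) {
    counts <- colSums(nbr[unassigned, , drop = FALSE])
    counts[!unassigned] <- -1L
    best <- which(counts == max(counts))[1]   # ranks ordered by score
    members <- which(nbr[best, ] & unassigned)
    unassigned[members] <- FALSE
    clusters[[length(clusters) + 1L]] <-
      list(center = best, members = members, size = length(members))
  }
  structure(list(clusters = clusters, rmsd_radius = radius, M = m),
            class = "pose_clustering")
}

#' @export
print.pose_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, `[[`, 0L, "size")
  cat(sprintf("<pose_clustering: %d clusters from %d poses (radius %.1f A); sizes %s>\n",
              length(x$clusters), x$M, x$rmsd_radius,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Cluster table as a data.frame (TSV-ready)
#' @param clustering a [greedy_cluster()] result.
#' @export
cluster_table <- function(clustering) {
  do.call(rbind, lapply(seq_along(clustering$clusters), function(i) {
    cl <- clustering$clusters[[i]]
    data.frame(cluster = i, size = cl$size, center_rank = cl$center,
               member_ranks = paste(cl$members, collapse = ","))
  }))
}
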