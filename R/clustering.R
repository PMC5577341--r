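#' Pairwise superposed RMSD matrix
#'
#' Entry (i, j) is the Kabsch-superposed RMSD between frames i and j over
#' the selected atoms (typically the 42-mer Calpha trace). Symmetric, zero
#' diagonal.
#'
#' @param x An `ensemble` with at least 2 frames.
#' @param selection Atom indices (>= 3).
#' @return `n_frames x n_frames` matrix in nm.
#' @export
pairwise_rmsd_matrix <- function(x, selection = NULL) {
  nf <- n_frames(x)
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(selection)) {
    selection <- atom_select(x$topology, name = "CA", chain = x$topology$chains[1])
  }
  if (length(selection) < 3) stop("selection must contain at least 3 atoms")
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    fi <- frame_coords(x, i)
    for (j in (i + 1):nf) {
      m[i, j] <- m[j, i] <- kabsch_rmsd(fi, frame_coords(x, j), selection)
    }
  }
  m
}

#' Gromos-style greedy RMSD clustering
#'
#' Repeatedly picks the unassigned frame with the most unassigned neighbors
#' (pairwise distance strictly below `cutoff`); that frame becomes the
#' cluster center and it and its neighbors form the cluster. Ties are broken
#' by the lowest frame index, making the result deterministic. Clusters are
#' returned in non-increasing size order.
#'
#' @param matrix Square symmetric distance matrix (nm).
#' @param cutoff Neighbor cutoff in nm (> 0); the production analyses use a
#'   0.3 nm pairwise Calpha-RMSD cutoff.
#' @return Object of class `cluster_result`: list with `clusters` (list of
#'   member index vectors), `centers`, `sizes`, `cutoff`, `n_frames`.
#' @export
gromos_cluster <- function(matrix, cutoff) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix), cutoff > 0)
  if (max(abs(matrix - t(matrix))) > 1e-9) stop("distance matrix is not symmetric")
  n <- nrow(matrix)
  unassigned <- rep(TRUE, n)
  clusters <- list(); centers <- integer(0)
  adj <- matrix < cutoff
  diag(adj) <- FALSE
  while (any(unassigned)) {
    idx <- which(unassigned)
    nb_counts <- vapply(idx, function(i) sum(adj[i, idx]), integer(1))
    center <- idx[which.max(nb_counts)] # which.max takes the first maximum
    members <- sort(c(center, idx[adj[center, idx]]))
    clusters[[length(clusters) + 1]] <- members
    centers <- c(centers, center)
    unassigned[members] <- FALSE
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, integer(1)))
  structure(
    list(clusters = clusters[ord], centers = centers[ord], sizes = sizes[ord],
         cutoff = cutoff, n_frames = n),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d frames (cutoff %.2f nm); largest %d (%.1f%%)\n",
              length(x$clusters), x$n_frames, x$cutoff, x$sizes[1],
              100 * x$sizes[1] / x$n_frames))
  invisible(x)
}

#' Cumulative population of the k largest clusters
#'
#' @param result A [gromos_cluster()] result.
#' @param k Number of top clusters (>= 1); values beyond the cluster count
#'   return 1.
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_population <- function(result, k) {
  stopifnot(inherits(result, "cluster_result"), k >= 1)
  if (length(result$clusters) == 0) stop("empty cluster result")
  k <- min(k, length(result$sizes))
  sum(result$sizes[seq_len(k)]) / result$n_frames
}

#' Tidy cluster summary
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble: cluster, size, population_pct, center.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x$sizes), size = x$sizes,
    population_pct = 100 * x$sizes / x$n_frames, center = x$centers
  )
}

#' One-line cluster summary
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$sizes), n_frames = x$n_frames, cutoff = x$cutoff,
    top1_pct = 100 * x$sizes[1] / x$n_frames,
    top50_pct = 100 * cumulative_population(x, 50)
  )
}

#' Export cluster centers as a multi-model PDB
#'
#' @param x The clustered `ensemble`.
#' @param result The matching `cluster_result`.
#' @param path Output PDB path.
#' @param k Number of top-cluster centers to write.
#' @export
write_cluster_centers <- function(x, result, path, k = length(result$centers)) {
  k <- min(k, length(result$centers))
  write_ensemble(subset_frames(x, result$centers[seq_len(k)]), path, "pdb")
}
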