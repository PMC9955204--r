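## Associating MSM macrostates with whole-structure conformations:
## Jarvis-Patrick clustering on full-scaffold pairwise RMSD, iteratively
## aligned average structures, and minimum-RMSD matching of macrostate
## representatives to cluster averages.

#' Pairwise RMSD matrix over trajectory frames
#'
#' Backbone (or other subset) RMSD after optimal superposition for every
#' frame pair.
#'
#' @param traj a \code{\link{TrajectoryEnsemble}}.
#' @param subset atom indices used both for fitting and for the RMSD
#'   (default: backbone atoms).
#' @return symmetric n x n matrix, zero diagonal (Angstrom).
#' @export
pairwiseRMSD <- function(traj, subset = NULL) {
  if (is.null(subset)) subset <- selectAtoms(topology(traj), "backbone")
  fr <- lapply(frames(traj), function(f) f[subset, , drop = FALSE])
  n <- length(fr)
  M <- matrix(0, n, n)
  sub <- seq_along(subset)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- kabschSuperpose(fr[[i]], fr[[j]], sub)$rmsd
    }
  }
  M
}

#' Jarvis-Patrick clustering on a pairwise distance matrix
#'
#' Two frames join iff each lists the other among its K nearest neighbors
#' and their neighbor lists share at least \code{kmin} common frames;
#' clusters are the connected components of the join graph. Weights are
#' component sizes as a percentage of all frames. The result is invariant
#' under frame reordering up to cluster relabeling; ids are assigned in
#' order of first frame occurrence.
#'
#' @param D symmetric distance matrix with zero diagonal (e.g. from
#'   \code{\link{pairwiseRMSD}}).
#' @param nNeighbors K, neighbor-list length (default 10; K < n required).
#' @param minShared kmin, required shared neighbors (default 3).
#' @return list with \code{cluster} (id per frame) and \code{weights}
#'   (percent per cluster).
#' @export
jarvisPatrick <- function(D, nNeighbors = 10, minShared = 3) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (nNeighbors >= n) stop("nNeighbors must be smaller than the frame count")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  # K nearest neighbors per frame, excluding self and tie-inclusive: every
  # frame at or below the K-th smallest distance is a neighbor. Index
  # tie-breaking would make the result depend on frame order; including
  # ties keeps the clustering invariant under reordering.
  nbr <- lapply(seq_len(n), function(i) {
    d <- D[i, -i]
    thr <- sort(d, partial = nNeighbors)[nNeighbors]
    which(D[i, ] <= thr + 1e-12 & seq_len(n) != i)
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j %in% nbr[[i]] && i %in% nbr[[j]] &&
          length(intersect(nbr[[i]], nbr[[j]])) >= minShared) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel by first occurrence for reorder-invariance up to labels
  ids <- as.integer(factor(comp, levels = unique(comp)))
  w <- 100 * tabulate(ids) / n
  list(cluster = ids, weights = w)
}

#' Iteratively aligned average structure
#'
#' Aligns every frame onto the running mean by Kabsch superposition and
#' re-averages until the mean moves by less than \code{tol} (RMSD).
#'
#' @param frameList list of n x 3 coordinate matrices (>= 1).
#' @param subset atom indices used for the alignment fit (default all).
#' @param tol convergence tolerance in Angstrom (default 1e-6).
#' @return n x 3 average coordinates.
#' @export
averageStructure <- function(frameList, subset = NULL, tol = 1e-6,
                             maxIter = 50) {
  if (!length(frameList)) stop("at least one frame required")
  if (length(frameList) == 1) return(frameList[[1]])
  if (is.null(subset)) subset <- seq_len(nrow(frameList[[1]]))
  ref <- frameList[[1]]
  for (it in seq_len(maxIter)) {
    aligned <- lapply(frameList, function(f)
      kabschSuperpose(f, ref, subset)$coords)
    newMean <- Reduce(`+`, aligned) / length(aligned)
    delta <- rawRMSD(newMean, ref)
    ref <- newMean
    if (delta < tol) break
  }
  ref
}

#' Build a structure clustering from a trajectory
#'
#' Convenience wrapper: pairwise backbone RMSD, Jarvis-Patrick clustering,
#' and per-cluster average structures.
#'
#' @inheritParams pairwiseRMSD
#' @inheritParams jarvisPatrick
#' @return a \code{\link{StructureClustering}}.
#' @export
clusterStructures <- function(traj, subset = NULL, nNeighbors = 10,
                              minShared = 3) {
  if (is.null(subset)) subset <- selectAtoms(topology(traj), "backbone")
  D <- pairwiseRMSD(traj, subset)
  jp <- jarvisPatrick(D, nNeighbors, minShared)
  ncl <- max(jp$cluster)
  averages <- lapply(seq_len(ncl), function(cl)
    averageStructure(frames(traj)[jp$cluster == cl], subset = subset))
  new("StructureClustering", cluster = jp$cluster,
      weights = setNames(jp$weights, seq_len(ncl)), averages = averages)
}

#' Associate macrostates with structure clusters by minimum backbone RMSD
#'
#' Each macrostate representative is matched to the cluster average with
#' the lowest RMSD after superposition. Ties are broken by larger cluster
#' weight, then by lower cluster id. An optional maximum acceptance RMSD
#' (off by default) marks macrostates with no sufficiently close cluster
#' as unmatched.
#'
#' @param representatives named list of n x 3 coordinate matrices, one per
#'   macrostate (e.g. the frame of highest membership).
#' @param clustering a \code{\link{StructureClustering}}.
#' @param subset atom indices (backbone) used for the RMSD; default all.
#' @param sourceLabel label of the trajectory the clustering came from.
#' @param maxRMSD optional acceptance cutoff in Angstrom (default Inf).
#' @return data.frame: macrostate, cluster, source_label, weight_pct,
#'   rmsd_A; cluster is NA for unmatched macrostates.
#' @export
associateMacrostates <- function(representatives, clustering, subset = NULL,
                                 sourceLabel = "trajectory", maxRMSD = Inf) {
  avgs <- clustering@averages
  w <- clustering@weights
  rows <- list()
  for (s in seq_along(representatives)) {
    rep <- representatives[[s]]
    if (is.null(subset)) subset <- seq_len(nrow(rep))
    if (any(vapply(avgs, nrow, 1L) != nrow(rep)))
      stop("atom count mismatch between representatives and cluster averages")
    r <- vapply(avgs, function(avg)
      kabschSuperpose(rep, avg, subset)$rmsd, numeric(1))
    ord <- order(r, -w, seq_along(r))
    best <- ord[1]
    matched <- r[best] <= maxRMSD
    rows[[s]] <- data.frame(
      macrostate = if (!is.null(names(representatives)))
        names(representatives)[s] else as.character(s),
      cluster = if (matched) best else NA_integer_,
      source_label = sourceLabel,
      weight_pct = if (matched) w[best] else NA_real_,
      rmsd_A = if (matched) r[best] else NA_real_,
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Representative frames per macrostate
#'
#' Picks, for each macrostate, the frame whose microstate has the highest
#' PCCA++ membership in that macrostate (first such frame).
#'
#' @param traj a \code{\link{TrajectoryEnsemble}}.
#' @param assignments per-frame microstate (1-based, concatenated order).
#' @param model the \code{\link{MarkovModel}} (for the active set mapping).
#' @param grouping a \code{\link{CoarseGraining}}.
#' @return named list of coordinate matrices, one per macrostate.
#' @export
macrostateRepresentatives <- function(traj, assignments, model, grouping) {
  a <- unlist(assignments)
  chi <- memberships(grouping)
  out <- list()
  for (ms in seq_len(grouping@m)) {
    ord <- order(chi[, ms], decreasing = TRUE)
    frame <- NA_integer_
    for (micro in ord) {
      orig <- model@activeSet[micro]
      hit <- which(a == orig)
      if (length(hit)) { frame <- hit[1]; break }
    }
    if (is.na(frame)) stop("no frame found for macrostate ", ms)
    out[[paste0("S", ms)]] <- frames(traj)[[frame]]
  }
  out
}
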