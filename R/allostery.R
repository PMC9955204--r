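## Residue-coupling allosteric network: normalized Calpha displacement
## cross-correlations after global superposition, a distance-gated graph
## with -ln|C| edge weights, and shortest communication pathways.

#' Residue displacement coupling matrix
#'
#' Every frame is rigid-body aligned onto the mean structure (Kabsch, over
#' the selected Calpha atoms); displacements from the mean are correlated
#' by the scalar dot product,
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>).
#' Residues with zero displacement variance are flagged undefined and are
#' excluded from graph construction.
#'
#' @param traj a \code{\link{TrajectoryEnsemble}} (>= 2 frames).
#' @param residues residue numbers to include (default: all with a CA atom).
#' @param align superpose frames onto the mean first (default TRUE; disable
#'   for pre-aligned or synthetic input).
#' @return a \code{\link{CouplingMatrix}}.
#' @export
couplingMatrix <- function(traj, residues = NULL, align = TRUE) {
  if (nFrames(traj) < 2) stop("at least 2 frames required")
  a <- atoms(topology(traj))
  if (is.null(residues)) residues <- sort(unique(a$resid[a$name == "CA"]))
  caIdx <- .atomIndexByResidue(a, residues, "CA")
  if (anyNA(caIdx))
    stop("missing CA atom for residue(s) ",
         paste(residues[is.na(caIdx)], collapse = ", "))
  fr <- lapply(frames(traj), function(f) f[caIdx, , drop = FALSE])
  if (align) {
    mean0 <- averageStructure(fr)
    fr <- lapply(fr, function(f) kabschSuperpose(f, mean0)$coords)
  }
  nR <- length(residues); nF <- length(fr)
  arr <- array(unlist(fr), c(nR, 3, nF))
  mu <- apply(arr, c(1, 2), mean)
  d <- sweep(arr, c(1, 2), mu)
  # inner products <dr_i . dr_j>: sum over xyz of the per-component covs
  G <- matrix(0, nR, nR)
  for (c3 in 1:3) {
    Dc <- matrix(d[, c3, ], nR, nF)
    G <- G + Dc %*% t(Dc)
  }
  G <- G / nF
  v <- diag(G)
  undef <- v <= 1e-12
  C <- matrix(NA_real_, nR, nR)
  ok <- which(!undef)
  C[ok, ok] <- G[ok, ok] / sqrt(outer(v[ok], v[ok]))
  C[ok, ok] <- pmin(pmax(C[ok, ok], -1), 1)
  diag(C)[ok] <- 1
  C <- (C + t(C)) / 2
  if (any(undef))
    message("couplingMatrix: ", sum(undef),
            " immobile residue(s) flagged undefined")
  new("CouplingMatrix", residues = as.integer(residues),
      correlations = C, undefined = undef)
}

#' Alternating-residue node coarse-graining
#'
#' Splits the residue list into the two alternating-parity subsets
#' (offsets 0 and 1) so downstream analyses can run per subset and be
#' merged by union, halving the node count per run.
#'
#' @param residues ordered residue numbers (>= 2).
#' @return list with \code{subsets} (list of two residue vectors) and
#'   \code{merge} (function combining two per-run edge tables by union,
#'   tagging each row with its run).
#' @export
coarseGrainNodes <- function(residues) {
  if (length(residues) < 2) stop("at least 2 residues required")
  idx <- seq_along(residues)
  subsets <- list(offset0 = residues[idx %% 2 == 1],
                  offset1 = residues[idx %% 2 == 0])
  merge <- function(tab0, tab1) {
    tab0$run <- "offset0"; tab1$run <- "offset1"
    rbind(tab0, tab1)
  }
  list(subsets = subsets, merge = merge)
}

#' Mean Calpha-Calpha distance matrix
#'
#' @param traj a \code{\link{TrajectoryEnsemble}}.
#' @param residues residue numbers (default: all with CA).
#' @return symmetric matrix of mean distances, Angstrom.
#' @export
meanDistanceMatrix <- function(traj, residues = NULL) {
  a <- atoms(topology(traj))
  if (is.null(residues)) residues <- sort(unique(a$resid[a$name == "CA"]))
  caIdx <- .atomIndexByResidue(a, residues, "CA")
  n <- length(residues)
  M <- matrix(0, n, n)
  for (f in frames(traj)) {
    x <- f[caIdx, , drop = FALSE]
    M <- M + as.matrix(dist(x))
  }
  M / nFrames(traj)
}

#' Build the distance-gated allosteric graph
#'
#' An edge joins residues i and j iff their mean Calpha-Calpha distance is
#' within the cutoff and |C_ij| exceeds \code{minAbsCoupling}; the weight
#' is -ln|C_ij| so perfect coupling has zero length. The 1.2 nm cutoff of
#' the published network is expressed as 12 Angstrom at this boundary.
#'
#' @param coupling a \code{\link{CouplingMatrix}}.
#' @param meanDistances conformant distance matrix (Angstrom).
#' @param cutoff distance gate in Angstrom (default 12).
#' @param minAbsCoupling minimum |C| for an edge (default 0, exclusive).
#' @param reportThreshold display threshold stored with the graph
#'   (default 0.6).
#' @return an \code{\link{AllosteryGraph}}.
#' @export
buildGraph <- function(coupling, meanDistances, cutoff = 12,
                       minAbsCoupling = 0, reportThreshold = 0.6) {
  C <- couplings(coupling)
  res <- coupling@residues
  D <- as.matrix(meanDistances)
  if (!all(dim(D) == dim(C))) stop("distance matrix must conform to C")
  n <- length(res)
  rows <- list()
  for (i in seq_len(n - 1)) {
    if (coupling@undefined[i]) next
    for (j in (i + 1):n) {
      if (coupling@undefined[j]) next
      cij <- C[i, j]
      if (D[i, j] <= cutoff && abs(cij) > minAbsCoupling && abs(cij) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          resI = res[i], resJ = res[j], distance = D[i, j],
          coupling = cij, weight = -log(min(abs(cij), 1)))
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows)
           else data.frame(resI = integer(), resJ = integer(),
                           distance = numeric(), coupling = numeric(),
                           weight = numeric())
  new("AllosteryGraph", nodes = as.integer(res[!coupling@undefined]),
      edges = edges, cutoff = cutoff, reportThreshold = reportThreshold)
}

#' Shortest allosteric communication pathway (Dijkstra)
#'
#' Minimal-total-weight path between two residues; deterministic
#' tie-breaking by lexicographic (ascending residue number) predecessor
#' order. A disconnected pair yields an explicit no-path result, not an
#' error.
#'
#' @param graph an \code{\link{AllosteryGraph}}.
#' @param source,target residue numbers present as nodes.
#' @return list with \code{found}, \code{path} (ordered residue numbers),
#'   \code{totalWeight} and \code{edgeWeights} (per-edge contributions).
#' @export
shortestPath <- function(graph, source = 768, target = 976) {
  nodes <- sort(graph@nodes)
  if (!(source %in% nodes) || !(target %in% nodes))
    stop("source and target must both be graph nodes")
  n <- length(nodes)
  id <- function(r) match(r, nodes)
  adj <- vector("list", n)
  e <- graph@edges
  for (r in seq_len(nrow(e))) {
    i <- id(e$resI[r]); j <- id(e$resJ[r]); w <- e$weight[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  distV <- rep(Inf, n); prev <- rep(NA_integer_, n); done <- rep(FALSE, n)
  s <- id(source); t <- id(target)
  distV[s] <- 0
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(distV))
    if (!length(cand)) break
    u <- cand[which.min(distV[cand])]  # ties: lowest index = lowest residue
    done[u] <- TRUE
    if (u == t) break
    if (is.null(adj[[u]])) next
    for (r in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
      alt <- distV[u] + w
      better <- alt < distV[v] - 1e-15
      tie <- abs(alt - distV[v]) <= 1e-15 &&
        (is.na(prev[v]) || nodes[u] < nodes[prev[v]])
      if (better || tie) { distV[v] <- alt; prev[v] <- u }
    }
  }
  if (!is.finite(distV[t]))
    return(list(found = FALSE, path = integer(), totalWeight = Inf,
                edgeWeights = numeric()))
  path <- t
  while (path[1] != s) path <- c(prev[path[1]], path)
  resPath <- nodes[path]
  ew <- numeric(length(path) - 1)
  for (i in seq_along(ew)) {
    sel <- (e$resI == resPath[i] & e$resJ == resPath[i + 1]) |
           (e$resJ == resPath[i] & e$resI == resPath[i + 1])
    ew[i] <- e$weight[which(sel)[1]]
  }
  list(found = TRUE, path = resPath, totalWeight = distV[t],
       edgeWeights = ew)
}
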