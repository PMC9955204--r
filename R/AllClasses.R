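#' @import methods
#' @importFrom stats cov kmeans rnorm runif rgamma quantile sd var dnorm
#'   setNames dist
#' @importFrom graphics hist
#' @importFrom utils head tail write.table read.table
NULL

## Central containers are S4 with validity checks; light per-row records
## (marker definitions, pucker tables, association reports) are data.frames.

#' Molecular structure
#'
#' Holds the atom records of a single structure: atom name, 1-based author
#' residue numbering, residue name, chain identifier and Cartesian
#' coordinates in Angstrom.
#'
#' @slot atoms data.frame with columns \code{name}, \code{resid},
#'   \code{resname}, \code{chain}, \code{x}, \code{y}, \code{z}.
#' @exportClass Structure
setClass("Structure", representation(atoms = "data.frame"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("name", "resid", "resname", "chain", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(a) > 0) {
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      return("coordinates must be finite")
    if (any(a$resid < 1)) return("residue indices must be positive")
  }
  TRUE
})

#' Trajectory ensemble
#'
#' A topology plus an ordered list of coordinate frames (Angstrom) and the
#' physical time per frame in nanoseconds.
#'
#' @slot topology a \code{Structure}.
#' @slot frames list of natoms x 3 numeric matrices.
#' @slot frameStride time between stored frames, ns (> 0).
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
         representation(topology = "Structure", frames = "list",
                        frameStride = "numeric"))

setValidity("TrajectoryEnsemble", function(object) {
  na <- nrow(object@topology@atoms)
  if (length(object@frameStride) != 1 || !is.finite(object@frameStride) ||
      object@frameStride <= 0)
    return("frameStride must be a single positive number")
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3)
      return(sprintf("frame %d does not match topology atom count (%d)", i, na))
  }
  TRUE
})

#' Domain map
#'
#' Maps domain labels to inclusive 1-based residue ranges. Ranges must be
#' well formed and may not overlap across labels.
#'
#' @slot ranges data.frame with columns \code{label}, \code{start}, \code{end}.
#' @exportClass DomainMap
setClass("DomainMap", representation(ranges = "data.frame"))

setValidity("DomainMap", function(object) {
  r <- object@ranges
  if (!all(c("label", "start", "end") %in% names(r)))
    return("ranges must have columns label, start, end")
  if (nrow(r) == 0) return(TRUE)
  if (any(r$start > r$end)) return("malformed range: start > end")
  if (any(r$start < 1)) return("residue ranges are 1-based")
  covered <- unlist(Map(seq.int, r$start, r$end))
  if (anyDuplicated(covered)) return("residue ranges overlap")
  TRUE
})

#' Feature matrix
#'
#' Frames x features matrix of sin/cos-expanded torsions with per-column
#' provenance (residue index, torsion name, sin or cos part).
#'
#' @slot values numeric matrix, frames x features.
#' @slot labels data.frame with columns \code{resid}, \code{torsion},
#'   \code{part} ("sin" or "cos").
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
         representation(values = "matrix", labels = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  if (!all(c("resid", "torsion", "part") %in% names(object@labels)))
    return("labels must have columns resid, torsion, part")
  if (nrow(object@labels) != ncol(object@values))
    return("labels length must equal feature count")
  if (length(object@values) && !all(is.finite(object@values)))
    return("feature values must be finite")
  TRUE
})

#' tICA model
#'
#' Result of time-lagged independent component analysis: feature means,
#' instantaneous and symmetrized time-lagged covariances, and the
#' generalized eigenpairs (kinetic modes).
#'
#' @slot mean per-feature mean.
#' @slot C0 instantaneous covariance (symmetric PSD, after regularization).
#' @slot Ctau symmetrized time-lagged covariance.
#' @slot lag lag in frames.
#' @slot eigenvalues sorted descending.
#' @slot components feature x component loading matrix (C0-orthonormal).
#' @slot nDims number of components kept.
#' @slot labels feature label data.frame (as in \code{FeatureMatrix}).
#' @slot reg ridge added to the diagonal of C0.
#' @exportClass TICAModel
setClass("TICAModel",
         representation(mean = "numeric", C0 = "matrix", Ctau = "matrix",
                        lag = "integer", eigenvalues = "numeric",
                        components = "matrix", nDims = "integer",
                        labels = "data.frame", reg = "numeric"))

setValidity("TICAModel", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be sorted descending")
  if (any(abs(object@eigenvalues) > 1 + 1e-6))
    return("|eigenvalues| must not exceed 1 + 1e-6")
  if (max(abs(object@C0 - t(object@C0))) > 1e-8)
    return("C0 must be symmetric")
  TRUE
})

#' Discretization of projected coordinates
#'
#' k-means cluster centers in tICA space and the per-frame microstate
#' assignment (1-based), one assignment vector per trajectory.
#'
#' @slot centers k x d matrix.
#' @slot assignments list of integer vectors, one per trajectory.
#' @slot k number of centers.
#' @slot seed RNG seed used.
#' @exportClass Discretization
setClass("Discretization",
         representation(centers = "matrix", assignments = "list",
                        k = "integer", seed = "integer"))

setValidity("Discretization", function(object) {
  for (a in object@assignments) {
    if (any(a < 1L | a > object@k)) return("assignments out of range")
    if (anyNA(a)) return("every frame must be assigned")
  }
  TRUE
})

#' Transition count matrix
#'
#' Sliding-window transition counts at a fixed lag.
#'
#' @slot counts k x k non-negative matrix.
#' @slot lag lag in frames.
#' @exportClass CountMatrix
setClass("CountMatrix", representation(counts = "matrix", lag = "integer"))

setValidity("CountMatrix", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (nrow(object@counts) != ncol(object@counts)) return("counts must be square")
  TRUE
})

#' Markov state model
#'
#' Row-stochastic transition matrix estimated at a fixed lag, together with
#' its stationary distribution, eigenvalues and the active (connected)
#' microstate set. Implied timescales are derived via
#' \code{\link{timescales}} using the frame stride.
#'
#' @slot transitionMatrix row-stochastic matrix over the active set.
#' @slot lag lag in frames.
#' @slot stride physical time per frame, ns.
#' @slot stationary stationary distribution.
#' @slot eigenvalues eigenvalues sorted by decreasing modulus (lambda1 = 1).
#' @slot activeSet original microstate indices retained (largest connected set).
#' @slot reversible logical; TRUE for the detailed-balance MLE.
#' @exportClass MarkovModel
setClass("MarkovModel",
         representation(transitionMatrix = "matrix", lag = "integer",
                        stride = "numeric", stationary = "numeric",
                        eigenvalues = "numeric", activeSet = "integer",
                        reversible = "logical"))

setValidity("MarkovModel", function(object) {
  T <- object@transitionMatrix
  if (any(abs(rowSums(T) - 1) > 1e-10)) return("rows of T must sum to 1")
  if (any(T < -1e-12)) return("T entries must be non-negative")
  p <- object@stationary
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    return("stationary distribution must be a probability vector")
  if (max(abs(p %*% T - p)) > 1e-8) return("pi T = pi violated")
  if (object@reversible) {
    db <- p * T - t(p * T)
    if (max(abs(db)) > 1e-8) return("detailed balance violated")
  }
  TRUE
})

#' Bayesian transition-matrix ensemble
#'
#' Posterior samples of the transition matrix (per-row Dirichlet conjugate
#' with uniform prior) used for confidence intervals on timescales and
#' Chapman-Kolmogorov curves.
#'
#' @slot samples list of row-stochastic matrices.
#' @slot lag lag in frames.
#' @slot stride ns per frame.
#' @slot seed RNG seed.
#' @exportClass BayesianEnsemble
setClass("BayesianEnsemble",
         representation(samples = "list", lag = "integer", stride = "numeric",
                        seed = "integer"))

setValidity("BayesianEnsemble", function(object) {
  for (S in object@samples)
    if (any(abs(rowSums(S) - 1) > 1e-8)) return("sample rows must sum to 1")
  TRUE
})

#' PCCA++ coarse-graining
#'
#' Fuzzy memberships of microstates in metastable macrostates and the crisp
#' (argmax) assignment.
#'
#' @slot memberships k x m row-stochastic matrix, entries in [0, 1].
#' @slot assignment integer macrostate per microstate.
#' @slot m number of macrostates.
#' @exportClass CoarseGraining
setClass("CoarseGraining",
         representation(memberships = "matrix", assignment = "integer",
                        m = "integer"))

setValidity("CoarseGraining", function(object) {
  chi <- object@memberships
  if (any(chi < -1e-12 | chi > 1 + 1e-12)) return("memberships must lie in [0,1]")
  if (any(abs(rowSums(chi) - 1) > 1e-10)) return("membership rows must sum to 1")
  if (ncol(chi) != object@m) return("membership columns must equal m")
  TRUE
})

#' Free-energy surface grid
#'
#' Two-dimensional binned free energies in kT over the leading tICA
#' components; unpopulated bins are NA (flagged, not zero), and the minimum
#' of the populated bins is shifted to zero.
#'
#' @slot xEdges,yEdges bin edges.
#' @slot F free energy per bin in kT (matrix, NA where empty).
#' @exportClass FESGrid
setClass("FESGrid",
         representation(xEdges = "numeric", yEdges = "numeric", F = "matrix"))

setValidity("FESGrid", function(object) {
  if (nrow(object@F) != length(object@xEdges) - 1 ||
      ncol(object@F) != length(object@yEdges) - 1)
    return("F dimensions must match bin edges")
  v <- object@F[!is.na(object@F)]
  if (length(v) && (!all(is.finite(v)) || abs(min(v)) > 1e-9))
    return("populated bins must be finite with minimum 0")
  TRUE
})

#' Structure clustering
#'
#' Jarvis-Patrick clustering of trajectory frames on pairwise RMSD:
#' per-frame cluster ids, cluster weights as percentage of frames, and the
#' iteratively aligned average structure per cluster.
#'
#' @slot cluster integer cluster id per frame.
#' @slot weights named numeric, percent of frames per cluster (sums to 100).
#' @slot averages list of natoms x 3 average coordinate matrices per cluster.
#' @exportClass StructureClustering
setClass("StructureClustering",
         representation(cluster = "integer", weights = "numeric",
                        averages = "list"))

setValidity("StructureClustering", function(object) {
  if (length(object@weights) && abs(sum(object@weights) - 100) > 0.1)
    return("cluster weights must sum to 100 within 0.1")
  if (anyNA(object@cluster)) return("every frame must be assigned")
  TRUE
})

#' Residue coupling matrix
#'
#' Normalized cross-correlations of Calpha displacement vectors after
#' global superposition; diagonal 1, symmetric, entries in [-1, 1].
#' Residues with zero displacement variance are flagged undefined and
#' excluded from graph construction.
#'
#' @slot residues ordered residue indices.
#' @slot correlations correlation matrix.
#' @slot undefined logical per residue.
#' @exportClass CouplingMatrix
setClass("CouplingMatrix",
         representation(residues = "integer", correlations = "matrix",
                        undefined = "logical"))

setValidity("CouplingMatrix", function(object) {
  C <- object@correlations
  ok <- !object@undefined
  if (length(object@residues) != nrow(C)) return("residues must match C")
  if (max(abs(C - t(C)), na.rm = TRUE) > 1e-10) return("C must be symmetric")
  if (any(abs(C[ok, ok]) > 1 + 1e-10)) return("|C| must not exceed 1")
  if (any(abs(diag(C)[ok] - 1) > 1e-10)) return("diagonal must be 1")
  TRUE
})

#' Allosteric communication graph
#'
#' Residue nodes with edges between residue pairs whose mean Calpha-Calpha
#' distance is within the cutoff; edge weight is -ln|C_ij| so strong
#' coupling means short graph distance.
#'
#' @slot nodes residue indices.
#' @slot edges data.frame: \code{resI}, \code{resJ}, \code{distance},
#'   \code{coupling}, \code{weight}.
#' @slot cutoff distance gate, Angstrom.
#' @slot reportThreshold |coupling| threshold used for display only.
#' @exportClass AllosteryGraph
setClass("AllosteryGraph",
         representation(nodes = "integer", edges = "data.frame",
                        cutoff = "numeric", reportThreshold = "numeric"))

setValidity("AllosteryGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$weight < -1e-12)) return("edge weights must be non-negative")
    if (any(e$resI == e$resJ)) return("no self-edges")
    if (any(abs(e$coupling) <= 0)) return("edges require |coupling| > 0")
  }
  TRUE
})
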