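#' Accessor generics
#'
#' Accessors for the central S4 containers: use these rather than reaching
#' into slots.
#'
#' @param object an object from this package.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("topology", function(object) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("frameStride", function(object) standardGeneric("frameStride"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("stationaryDistribution",
           function(object) standardGeneric("stationaryDistribution"))
#' @rdname accessors
#' @export
setGeneric("modelEigenvalues", function(object) standardGeneric("modelEigenvalues"))
#' @rdname accessors
#' @export
setGeneric("timescales", function(object, ...) standardGeneric("timescales"))
#' @rdname accessors
#' @export
setGeneric("lagTime", function(object) standardGeneric("lagTime"))
#' @rdname accessors
#' @export
setGeneric("activeSet", function(object) standardGeneric("activeSet"))
#' @rdname accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("crispAssignment", function(object) standardGeneric("crispAssignment"))
#' @rdname accessors
#' @export
setGeneric("clusterWeights", function(object) standardGeneric("clusterWeights"))
#' @rdname accessors
#' @export
setGeneric("couplings", function(object) standardGeneric("couplings"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setMethod("atoms", "Structure", function(object) object@atoms)
#' @rdname accessors
#' @export
setMethod("frames", "TrajectoryEnsemble", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(object) length(object@frames))
#' @rdname accessors
#' @export
setMethod("topology", "TrajectoryEnsemble", function(object) object@topology)
#' @rdname accessors
#' @export
setMethod("frameStride", "TrajectoryEnsemble", function(object) object@frameStride)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("featureLabels", "FeatureMatrix", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("nFrames", "FeatureMatrix", function(object) nrow(object@values))
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "MarkovModel",
          function(object) object@transitionMatrix)
#' @rdname accessors
#' @export
setMethod("stationaryDistribution", "MarkovModel",
          function(object) object@stationary)
#' @rdname accessors
#' @export
setMethod("modelEigenvalues", "MarkovModel", function(object) object@eigenvalues)
#' @rdname accessors
#' @export
setMethod("modelEigenvalues", "TICAModel", function(object) object@eigenvalues)
#' @rdname accessors
#' @export
setMethod("lagTime", "MarkovModel", function(object) object@lag)
#' @rdname accessors
#' @export
setMethod("lagTime", "TICAModel", function(object) object@lag)
#' @rdname accessors
#' @export
setMethod("activeSet", "MarkovModel", function(object) object@activeSet)
#' @rdname accessors
#' @export
setMethod("memberships", "CoarseGraining", function(object) object@memberships)
#' @rdname accessors
#' @export
setMethod("crispAssignment", "CoarseGraining", function(object) object@assignment)
#' @rdname accessors
#' @export
setMethod("crispAssignment", "Discretization",
          function(object) object@assignments)
#' @rdname accessors
#' @export
setMethod("clusterWeights", "StructureClustering", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("couplings", "CouplingMatrix", function(object) object@correlations)
#' @rdname accessors
#' @export
setMethod("graphEdges", "AllosteryGraph", function(object) object@edges)

#' Implied relaxation timescales of a Markov model
#'
#' Computes t_i = -tau * stride / ln|lambda_(i+1)| in ns. Eigenvalues that
#' are non-positive give NA (undefined, not fabricated); unit eigenvalues
#' beyond the stationary one give +Inf.
#'
#' @param object a \code{MarkovModel}.
#' @param nIts number of timescales (default 3).
#' @return numeric vector of length \code{nIts}, ns.
#' @export
setMethod("timescales", "MarkovModel", function(object, nIts = 3) {
  ev <- object@eigenvalues
  out <- rep(NA_real_, nIts)
  tau <- as.numeric(object@lag) * object@stride
  for (i in seq_len(nIts)) {
    l <- if (i + 1 <= length(ev)) ev[i + 1] else NA_real_
    if (is.na(l) || l <= 0) next
    out[i] <- if (l >= 1) Inf else -tau / log(l)
  }
  out
})

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resid))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble:", length(object@frames), "frames x",
      nrow(object@topology@atoms), "atoms, stride",
      object@frameStride, "ns\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "frames x",
      ncol(object@values), "features (",
      length(unique(object@labels$resid)), "residues )\n")
})

setMethod("show", "TICAModel", function(object) {
  cat("TICAModel: lag", object@lag, "frames,", object@nDims,
      "components kept\n  leading eigenvalues:",
      paste(signif(head(object@eigenvalues, 4), 4), collapse = ", "), "\n")
})

setMethod("show", "MarkovModel", function(object) {
  cat("MarkovModel:", nrow(object@transitionMatrix), "states, lag",
      object@lag, "frames (", object@lag * object@stride, "ns ),",
      if (object@reversible) "reversible" else "non-reversible", "\n")
  ts <- timescales(object, nIts = 3)
  cat("  implied timescales (ns):", paste(signif(ts, 4), collapse = ", "), "\n")
})

setMethod("show", "CoarseGraining", function(object) {
  cat("CoarseGraining:", nrow(object@memberships), "microstates ->",
      object@m, "macrostates; sizes:",
      paste(tabulate(object@assignment, object@m), collapse = ", "), "\n")
})

setMethod("show", "AllosteryGraph", function(object) {
  cat("AllosteryGraph:", length(object@nodes), "residue nodes,",
      nrow(object@edges), "edges (cutoff", object@cutoff, "A)\n")
})

setMethod("show", "CouplingMatrix", function(object) {
  cat("CouplingMatrix:", length(object@residues), "residues,",
      sum(object@undefined), "undefined\n")
})
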