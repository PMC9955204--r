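## Time-lagged independent component analysis. The slow collective modes
## of a feature time series are the solutions of the symmetrized
## generalized eigenproblem  Ctau v = lambda C0 v  after mean removal;
## eigenvalues are lag-autocorrelations of the corresponding modes.

# Symmetrized covariance pair from a list of feature matrices at a lag.
.ticaCovariances <- function(xlist, lag) {
  p <- ncol(xlist[[1]])
  sw <- matrix(0, p, p); sl <- matrix(0, p, p)
  s1 <- numeric(p); n <- 0
  for (x in xlist) {
    if (nrow(x) <= lag) next
    X0 <- x[1:(nrow(x) - lag), , drop = FALSE]
    Xt <- x[(lag + 1):nrow(x), , drop = FALSE]
    s1 <- s1 + colSums(X0) + colSums(Xt)
    sw <- sw + t(X0) %*% X0 + t(Xt) %*% Xt
    sl <- sl + t(X0) %*% Xt
    n <- n + nrow(X0)
  }
  if (n == 0) stop("no trajectory longer than the lag")
  mu <- s1 / (2 * n)
  C0 <- sw / (2 * n) - tcrossprod(mu)
  Ct <- (sl + t(sl)) / (2 * n) - tcrossprod(mu)
  list(mean = mu, C0 = (C0 + t(C0)) / 2, Ctau = (Ct + t(Ct)) / 2, n = n)
}

.asFeatureList <- function(features) {
  if (is(features, "FeatureMatrix"))
    list(values = list(featureValues(features)), labels = featureLabels(features))
  else if (is.list(features) && all(vapply(features, is, TRUE, "FeatureMatrix")))
    list(values = lapply(features, featureValues),
         labels = featureLabels(features[[1]]))
  else list(values = list(as.matrix(features)),
            labels = data.frame(resid = seq_len(ncol(as.matrix(features))),
                                torsion = "feature", part = "cos"))
}

#' Estimate a tICA model
#'
#' Mean-removes the features, forms the instantaneous covariance C0 and the
#' symmetrized time-lagged covariance Ctau, and solves
#' \code{Ctau v = lambda C0 v} by whitening. Components are C0-orthonormal,
#' so each projected coordinate has unit instantaneous variance and its
#' lag-autocorrelation equals the eigenvalue.
#'
#' @param features a \code{\link{FeatureMatrix}}, a plain matrix, or a list
#'   of \code{FeatureMatrix} objects (multiple trajectories).
#' @param lag lag in frames (frames > lag required).
#' @param nDims number of components to keep.
#' @param reg ridge added to the diagonal of C0 (default 1e-8). A
#'   rank-deficient C0 with \code{reg = 0} raises an error suggesting
#'   regularization.
#' @return a \code{\link{TICAModel}}.
#' @export
estimateTICA <- function(features, lag, nDims = 4, reg = 1e-8) {
  fl <- .asFeatureList(features)
  p <- ncol(fl$values[[1]])
  if (nDims > p) stop("nDims must not exceed the feature count")
  cv <- .ticaCovariances(fl$values, lag)
  C0 <- cv$C0 + diag(reg, p)
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- 1e-10 * max(e0$values, 1)
  if (min(e0$values) < tol)
    stop("singular instantaneous covariance; set reg > 0 to regularize")
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), p) %*% t(e0$vectors)
  M <- W %*% cv$Ctau %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lambda <- pmin(pmax(em$values, -1 - 1e-6), 1 + 1e-6)
  comps <- W %*% em$vectors
  new("TICAModel", mean = cv$mean, C0 = C0, Ctau = cv$Ctau,
      lag = as.integer(lag), eigenvalues = lambda, components = comps,
      nDims = as.integer(nDims), labels = fl$labels, reg = reg)
}

#' Project features onto the kept tICA components
#'
#' Mean-free linear projection onto the leading \code{nDims} components of
#' the model.
#'
#' @param model a \code{\link{TICAModel}}.
#' @param features a \code{FeatureMatrix} or matrix; when a
#'   \code{FeatureMatrix}, its labels must match the model's (an error
#'   lists offending columns).
#' @return frames x nDims coordinate matrix.
#' @export
projectTICA <- function(model, features) {
  if (is(features, "FeatureMatrix")) {
    lab <- featureLabels(features)
    mlab <- model@labels
    same <- nrow(lab) == nrow(mlab) &&
      all(lab$resid == mlab$resid & lab$torsion == mlab$torsion &
          lab$part == mlab$part)
    if (!same) {
      bad <- which(paste(lab$resid, lab$torsion, lab$part) !=
                   paste(mlab$resid, mlab$torsion, mlab$part))
      stop("feature labels do not match the model; offending columns: ",
           paste(head(bad, 10), collapse = ", "))
    }
    x <- featureValues(features)
  } else x <- as.matrix(features)
  sweep(x, 2, model@mean) %*% model@components[, seq_len(model@nDims),
                                               drop = FALSE]
}

#' Per-feature contributions to the slow modes and residue selection
#'
#' Each kept component's loading vector is scaled to unit maximum absolute
#' loading; a feature's contribution is the maximum of its scaled absolute
#' loadings over the kept components, and sin/cos partners are merged to
#' one residue-level score (maximum). Residues with any score at or above
#' the threshold are selected.
#'
#' @param model a fitted \code{\link{TICAModel}}.
#' @param threshold contribution threshold (default 0.195).
#' @return list with \code{featureScores} (per feature),
#'   \code{residueScores} (named by residue) and \code{selectedResidues}.
#' @export
featureContributions <- function(model, threshold = 0.195) {
  V <- model@components[, seq_len(model@nDims), drop = FALSE]
  Vn <- apply(V, 2, function(v) abs(v) / max(abs(v)))
  featureScores <- apply(Vn, 1, max)
  resid <- model@labels$resid
  residueScores <- tapply(featureScores, resid, max)
  sel <- as.integer(names(residueScores)[residueScores >= threshold])
  list(featureScores = featureScores,
       residueScores = residueScores,
       selectedResidues = sort(sel))
}

#' VAMP2 score of a feature set at a lag
#'
#' Kinetic variance captured by the top \code{nDims} singular functions of
#' the half-weighted propagator \code{C00^-1/2 C0t Ctt^-1/2}, including the
#' constant mode (which always contributes 1). Larger is better; pure white
#' noise scores 1 in the large-sample limit.
#'
#' @inheritParams estimateTICA
#' @return scalar score >= 1.
#' @export
vamp2Score <- function(features, lag, nDims = 4, reg = 1e-8) {
  fl <- .asFeatureList(features)
  p <- ncol(fl$values[[1]])
  sw0 <- matrix(0, p, p); swt <- matrix(0, p, p); s0t <- matrix(0, p, p)
  m0 <- numeric(p); mt <- numeric(p); n <- 0
  for (x in fl$values) {
    if (nrow(x) <= lag) next
    X0 <- x[1:(nrow(x) - lag), , drop = FALSE]
    Xt <- x[(lag + 1):nrow(x), , drop = FALSE]
    m0 <- m0 + colSums(X0); mt <- mt + colSums(Xt)
    sw0 <- sw0 + t(X0) %*% X0; swt <- swt + t(Xt) %*% Xt
    s0t <- s0t + t(X0) %*% Xt
    n <- n + nrow(X0)
  }
  if (n == 0) stop("no trajectory longer than the lag")
  m0 <- m0 / n; mt <- mt / n
  C00 <- sw0 / n - tcrossprod(m0) + diag(reg, p)
  Ctt <- swt / n - tcrossprod(mt) + diag(reg, p)
  C0t <- s0t / n - tcrossprod(m0, mt)
  isqrt <- function(C) {
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    vals <- pmax(e$values, max(e$values) * 1e-12)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  K <- isqrt(C00) %*% C0t %*% isqrt(Ctt)
  s <- svd(K, nu = 0, nv = 0)$d
  s <- pmin(s, 1)
  1 + sum(s[seq_len(min(nDims - 1, length(s)))]^2)
}
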