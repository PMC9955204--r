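## Markov state model construction and validation: k-means discretization
## of the projected coordinates, sliding-window transition counting,
## reversible maximum-likelihood estimation on the largest connected set,
## Bayesian (Dirichlet) uncertainty, implied timescales, the
## Chapman-Kolmogorov test, PCCA++ coarse-graining, mean first-passage
## times between macrostates, and the reweighted free-energy surface.

#' k-means discretization of projected coordinates
#'
#' k-means++ seeding followed by Lloyd iterations (via \code{stats::kmeans}
#' with explicit starting centers), deterministic for a given seed.
#'
#' @param points n x d matrix, or a list of such matrices (one per
#'   trajectory).
#' @param k number of cluster centers (default 100; must not exceed n).
#' @param seed integer RNG seed.
#' @param maxIter maximum Lloyd iterations.
#' @return a \code{\link{Discretization}}; assignments are 1-based.
#' @export
kmeansDiscretize <- function(points, k = 100, seed = 1L, maxIter = 100) {
  plist <- if (is.list(points) && !is.data.frame(points)) points else list(points)
  plist <- lapply(plist, function(p) {
    p <- as.matrix(p); if (ncol(p) == 1 || !is.null(dim(p))) p else matrix(p)
  })
  X <- do.call(rbind, plist)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of points")
  set.seed(seed)
  # k-means++ seeding
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      prob <- d2 / sum(d2)
      centers[j, ] <- X[sample.int(n, 1, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = maxIter,
                                       algorithm = "Lloyd"))
  splitIdx <- rep(seq_along(plist), vapply(plist, nrow, 1L))
  assignments <- split(as.integer(km$cluster), splitIdx)
  names(assignments) <- NULL
  new("Discretization", centers = km$centers, assignments = assignments,
      k = as.integer(k), seed = as.integer(seed))
}

#' Sliding-window transition count matrix
#'
#' counts[i, j] = number of times state i is followed by state j exactly
#' \code{lag} frames later, summed over trajectories (sliding window).
#' A lag at or beyond every trajectory length yields an all-zero matrix
#' with a warning.
#'
#' @param assignments integer state sequence (1-based), or list of them.
#' @param lag lag in frames (>= 1).
#' @param nStates number of states (default: maximum observed).
#' @return a \code{\link{CountMatrix}}.
#' @export
countMatrix <- function(assignments, lag, nStates = NULL) {
  if (lag < 1) stop("lag must be >= 1")
  alist <- if (is.list(assignments)) assignments else list(assignments)
  if (is.null(nStates)) nStates <- max(unlist(alist))
  C <- matrix(0, nStates, nStates)
  any <- FALSE
  for (a in alist) {
    n <- length(a)
    if (lag >= n) next
    any <- TRUE
    from <- a[1:(n - lag)]; to <- a[(lag + 1):n]
    tab <- table(factor(from, levels = 1:nStates),
                 factor(to, levels = 1:nStates))
    C <- C + unclass(tab)
  }
  if (!any) warning("lag >= trajectory length: all-zero count matrix")
  dimnames(C) <- NULL
  new("CountMatrix", counts = C, lag = as.integer(lag))
}

# Largest strongly connected component of the count graph.
.largestConnectedSet <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  members <- which(comp$membership == which.max(comp$csize))
  sort(as.integer(members))
}

# Reversible MLE by the standard self-consistent iteration on the
# unnormalized flow matrix x_ij, converging in log-likelihood.
.reversibleMLE <- function(C, tol = 1e-10, maxIter = 10000) {
  Csym <- C + t(C)
  x <- Csym
  ci <- rowSums(C)
  loglik <- function(T) {
    ok <- C > 0 & T > 0
    sum(C[ok] * log(T[ok]))
  }
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    xNew <- Csym / denom
    x <- xNew
    T <- x / rowSums(x)
    llNew <- loglik(T)
    if (is.finite(ll) && abs(llNew - ll) < tol * max(1, abs(llNew))) break
    ll <- llNew
  }
  pi <- rowSums(x) / sum(x)
  list(T = T, pi = pi)
}

#' Estimate a Markov state model from transition counts
#'
#' Restricts to the largest strongly connected state set (dropped states
#' are logged), then estimates the transition matrix: reversible
#' maximum likelihood by the standard detailed-balance fixed-point
#' iteration (default), or the row-normalized non-reversible MLE.
#' Eigenvalues of the reversible estimate are real.
#'
#' @param counts a \code{\link{CountMatrix}}.
#' @param reversible enforce detailed balance (default TRUE).
#' @param stride physical time per frame in ns (default 1).
#' @return a \code{\link{MarkovModel}} over the active set.
#' @export
estimateMSM <- function(counts, reversible = TRUE, stride = 1) {
  C <- counts@counts
  active <- .largestConnectedSet(C)
  if (!length(active) || sum(C[active, active, drop = FALSE]) == 0)
    stop("empty connected set: no transitions observed")
  if (length(active) < nrow(C))
    message("estimateMSM: dropping ", nrow(C) - length(active),
            " disconnected state(s); active set has ", length(active))
  Ca <- C[active, active, drop = FALSE]
  if (reversible) {
    fit <- .reversibleMLE(Ca)
    T <- fit$T; pi <- fit$pi
    # real spectrum via the symmetrized similarity transform
    s <- sqrt(pi)
    S <- (T * outer(s, 1 / s)) |> (\(M) (M + t(M)) / 2)()
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  } else {
    T <- Ca / rowSums(Ca)
    e <- eigen(t(T))
    iMax <- which.max(Re(e$values))
    pi <- Re(e$vectors[, iMax]); pi <- pi / sum(pi)
    ev <- eigen(T, only.values = TRUE)$values
    ev <- Re(ev[order(-Mod(ev))])
  }
  ev <- sort(pmin(ev, 1), decreasing = TRUE)
  # clean tiny numerical asymmetries so validity invariants hold exactly
  T <- pmax(T, 0); T <- T / rowSums(T)
  new("MarkovModel", transitionMatrix = T, lag = counts@lag,
      stride = stride, stationary = pi, eigenvalues = ev,
      activeSet = active, reversible = reversible)
}

#' Implied timescales across lag times, with Bayesian confidence intervals
#'
#' For each lag, estimates the model and reports the slowest \code{nIts}
#' implied timescales t_i = -tau * stride / ln|lambda_(i+1)| together with
#' 95\% posterior intervals from \code{\link{bayesianSample}}. Non-positive
#' eigenvalues give NA (undefined, not fabricated).
#'
#' @param assignments state sequence or list of sequences (1-based).
#' @param lags integer vector of lags (frames).
#' @param nIts number of timescales (default 3).
#' @param stride ns per frame.
#' @param nSamples Bayesian samples per lag (default 50).
#' @param seed RNG seed.
#' @return data.frame: lag, its index, timescale ns, lower, upper.
#' @export
impliedTimescales <- function(assignments, lags, nIts = 3, stride = 1,
                              nSamples = 50, seed = 1L) {
  out <- list()
  for (tau in lags) {
    cm <- countMatrix(assignments, tau)
    model <- estimateMSM(cm, stride = stride)
    ts <- timescales(model, nIts = nIts)
    ens <- bayesianSample(cm, nSamples = nSamples,
                          seed = childSeed(seed, paste0("its", tau)),
                          stride = stride)
    tsSamples <- vapply(ens@samples, function(S) {
      ev <- sort(Re(eigen(S, only.values = TRUE)$values), decreasing = TRUE)
      vapply(seq_len(nIts), function(i) {
        l <- if (i + 1 <= length(ev)) ev[i + 1] else NA_real_
        if (is.na(l) || l <= 0) NA_real_
        else if (l >= 1) Inf else -tau * stride / log(l)
      }, numeric(1))
    }, numeric(nIts))
    tsSamples <- matrix(tsSamples, nrow = nIts)
    for (i in seq_len(nIts)) {
      qs <- quantile(tsSamples[i, ], c(0.025, 0.975), na.rm = TRUE,
                     names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        lag = tau, its = i, timescale = ts[i], lower = qs[1], upper = qs[2])
    }
  }
  do.call(rbind, out)
}

#' Sample the Bayesian transition-matrix posterior
#'
#' Per-row conjugate Dirichlet posterior with a uniform prior (alpha =
#' counts + 1), sampled on the active connected set. The sampler is
#' non-reversible; samples are row-stochastic by construction.
#'
#' @param counts a \code{\link{CountMatrix}}.
#' @param nSamples number of posterior samples (default 100).
#' @param seed integer RNG seed.
#' @param stride ns per frame.
#' @return a \code{\link{BayesianEnsemble}}.
#' @export
bayesianSample <- function(counts, nSamples = 100, seed = 1L, stride = 1) {
  C <- counts@counts
  active <- .largestConnectedSet(C)
  Ca <- C[active, active, drop = FALSE]
  k <- nrow(Ca)
  set.seed(seed)
  samples <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    G <- matrix(rgamma(k * k, shape = as.numeric(Ca) + 1), k, k)
    samples[[s]] <- G / rowSums(G)
  }
  new("BayesianEnsemble", samples = samples, lag = counts@lag,
      stride = stride, seed = as.integer(seed))
}

#' Chapman-Kolmogorov test
#'
#' For each macrostate set A, compares the model prediction
#' p_pred(k) = w' T(tau)^k 1_A (w = stationary distribution restricted to
#' A) with p_est(k) from a model re-estimated at lag k*tau. The 95\% band
#' comes from propagating the Bayesian ensemble of the lag-tau model. The
#' test passes when the estimated points lie inside the band for at least
#' 95\% of the evaluated points.
#'
#' @param model a \code{\link{MarkovModel}} at lag tau.
#' @param ensemble matching \code{\link{BayesianEnsemble}}.
#' @param assignments the discrete trajectories used for re-estimation.
#' @param factors integer multipliers k (default 2:5); factors with
#'   insufficient data are skipped with a message.
#' @param sets a \code{\link{CoarseGraining}} over the model's states, or
#'   NULL to test each microstate as its own set (small models only).
#' @return list with \code{table} (set, factor, predicted, estimated,
#'   lower, upper, inside) and \code{pass}.
#' @export
ckTest <- function(model, ensemble, assignments, factors = 2:5, sets = NULL) {
  T1 <- model@transitionMatrix
  k <- nrow(T1)
  groups <- if (is.null(sets)) as.list(seq_len(k))
            else split(seq_len(k), crispAssignment(sets))
  alist <- if (is.list(assignments)) assignments else list(assignments)
  maxLen <- max(vapply(alist, length, 1L))
  rows <- list()
  for (f in sort(unique(as.integer(factors)))) {
    lagF <- model@lag * f
    if (lagF >= maxLen) {
      message("ckTest: factor ", f, " needs lag ", lagF,
              " >= trajectory length; skipped")
      next
    }
    cmF <- countMatrix(alist, lagF, nStates = max(unlist(alist)))
    mF <- tryCatch(estimateMSM(cmF, stride = model@stride),
                   error = function(e) NULL)
    if (is.null(mF)) {
      message("ckTest: insufficient data at factor ", f, "; skipped")
      next
    }
    # matrix powers at this factor
    Tk <- .matPow(T1, f)
    ensK <- lapply(ensemble@samples, .matPow, p = f)
    # map microstates of mF back to model states
    for (gi in seq_along(groups)) {
      gModel <- groups[[gi]]
      w <- model@stationary[gModel]
      w <- w / sum(w)
      pred <- sum(w * rowSums(Tk[gModel, gModel, drop = FALSE]))
      # estimated: same quantity from the re-estimated model where states map
      gOrig <- model@activeSet[gModel]
      gF <- match(gOrig, mF@activeSet)
      gF <- gF[!is.na(gF)]
      if (!length(gF)) next
      wF <- mF@stationary[gF]; wF <- wF / sum(wF)
      est <- sum(wF * rowSums(mF@transitionMatrix[gF, gF, drop = FALSE]))
      bandVals <- vapply(ensK, function(S) {
        sum(w * rowSums(S[gModel, gModel, drop = FALSE]))
      }, numeric(1))
      qs <- quantile(bandVals, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        set = gi, factor = f, predicted = pred, estimated = est,
        lower = qs[1], upper = qs[2],
        inside = est >= qs[1] - 1e-12 & est <= qs[2] + 1e-12)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, pass = mean(tab$inside) >= 0.95)
}

.matPow <- function(M, p) {
  R <- diag(nrow(M))
  B <- M
  while (p > 0) {
    if (p %% 2 == 1) R <- R %*% B
    B <- B %*% B
    p <- p %/% 2
  }
  R
}

#' PCCA++ coarse-graining into metastable macrostates
#'
#' Spectral coarse-graining on the top-m right eigenvectors of a
#' reversible transition matrix: the simplex vertex search picks the m
#' most spread microstates as membership vertices, the eigenvector rows
#' are expressed in that vertex basis, and the resulting fuzzy memberships
#' are clipped to [0, 1] and row-normalized. Crisp assignment is the
#' argmax membership.
#'
#' @param model a reversible \code{\link{MarkovModel}} (a non-reversible
#'   model has a complex spectrum and is rejected).
#' @param m number of macrostates (default 4; m <= number of states).
#' @return a \code{\link{CoarseGraining}}.
#' @export
pcca <- function(model, m = 4) {
  if (!model@reversible)
    stop("PCCA++ requires a real spectrum: estimate the model with ",
         "reversible = TRUE")
  T <- model@transitionMatrix
  k <- nrow(T)
  if (m > k) stop("m must not exceed the number of states")
  if (m == 1)
    return(new("CoarseGraining", memberships = matrix(1, k, 1),
               assignment = rep(1L, k), m = 1L))
  pi <- model@stationary
  s <- sqrt(pi)
  S <- (T * outer(s, 1 / s)); S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)[seq_len(m)]
  Psi <- es$vectors[, ord, drop = FALSE] / s  # right eigenvectors of T
  Psi[, 1] <- 1  # constant eigenvector, exact
  # simplex vertex search
  vert <- integer(m)
  d <- rowSums(Psi^2)
  vert[1] <- which.max(d)
  Y <- sweep(Psi, 2, Psi[vert[1], ])
  for (j in 2:m) {
    nrm <- sqrt(rowSums(Y^2))
    vert[j] <- which.max(nrm)
    v <- Y[vert[j], ] / nrm[vert[j]]
    Y <- Y - outer(as.numeric(Y %*% v), v)
  }
  A <- solve(Psi[vert, , drop = FALSE])
  chi <- Psi %*% A
  chi[chi < 0] <- 0
  chi[chi > 1] <- 1
  chi <- chi / rowSums(chi)
  assignment <- max.col(chi, ties.method = "first")
  new("CoarseGraining", memberships = chi,
      assignment = as.integer(assignment), m = as.integer(m))
}

#' Mean first-passage times and net rates between macrostates
#'
#' MFPTs between macrostate sets by first-step analysis: for target set A,
#' the vector of expected hitting times m satisfies
#' (I - T_BB) m_B = tau_ns on the complement B, m_A = 0; the reported
#' MFPT(i -> j) is the stationary-weighted average of m over the source
#' set. Unreachable targets give +Inf. Rates are reciprocal MFPTs.
#'
#' @param model a \code{\link{MarkovModel}}.
#' @param grouping a \code{\link{CoarseGraining}} with crisp assignments.
#' @return list with \code{mfpt} (m x m matrix, ns; diagonal 0) and
#'   \code{rates} (1/ns).
#' @export
macrostateTransitionTimes <- function(model, grouping) {
  T <- model@transitionMatrix
  tauNs <- as.numeric(model@lag) * model@stride
  asg <- crispAssignment(grouping)
  m <- grouping@m
  k <- nrow(T)
  mfpt <- matrix(0, m, m)
  for (j in seq_len(m)) {
    A <- which(asg == j)
    B <- setdiff(seq_len(k), A)
    h <- numeric(k)  # hitting time of A from each state
    if (length(B)) {
      TBB <- T[B, B, drop = FALSE]
      rhs <- rep(tauNs, length(B))
      sol <- tryCatch(solve(diag(length(B)) - TBB, rhs),
                      error = function(e) rep(Inf, length(B)))
      sol[sol < 0 | !is.finite(sol)] <- Inf
      h[B] <- sol
    }
    for (i in seq_len(m)) {
      if (i == j) next
      src <- which(asg == i)
      w <- model@stationary[src]; w <- w / sum(w)
      mfpt[i, j] <- sum(w * h[src])
    }
  }
  rates <- ifelse(mfpt > 0, 1 / mfpt, 0)
  diag(rates) <- 0
  list(mfpt = mfpt, rates = rates)
}

#' Reweighted two-dimensional free-energy surface
#'
#' Bins the projected coordinates on a regular grid; each frame carries the
#' stationary weight of its microstate divided by the number of frames in
#' that microstate, so the histogram estimates the equilibrium density
#' even when the raw trajectory does not. F(bin) = -kT ln(sum of weights),
#' shifted so the populated minimum is 0; empty bins are NA.
#'
#' @param projection frames x 2 matrix (leading tICA components).
#' @param weights per-frame weights (>= 0, summing to 1), e.g. from
#'   \code{\link{stationaryFrameWeights}}.
#' @param nbins bins per axis (default 50) or a list of two edge vectors.
#' @param temperatureKT kT units per unit free energy (default 1).
#' @return a \code{\link{FESGrid}}.
#' @export
freeEnergySurface <- function(projection, weights = NULL, nbins = 50,
                              temperatureKT = 1) {
  P <- as.matrix(projection)
  if (nrow(P) == 0) stop("empty projection")
  if (ncol(P) < 2) stop("projection must have two columns")
  if (is.null(weights)) weights <- rep(1 / nrow(P), nrow(P))
  if (any(weights < 0)) stop("weights must be >= 0")
  weights <- weights / sum(weights)
  if (is.list(nbins)) {
    xe <- nbins[[1]]; ye <- nbins[[2]]
  } else {
    pad <- function(r) r + c(-1, 1) * max(1e-9, diff(r) * 1e-9)
    xe <- seq(pad(range(P[, 1]))[1], pad(range(P[, 1]))[2],
              length.out = nbins + 1)
    ye <- seq(pad(range(P[, 2]))[1], pad(range(P[, 2]))[2],
              length.out = nbins + 1)
  }
  ix <- findInterval(P[, 1], xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(P[, 2], ye, rightmost.closed = TRUE, all.inside = TRUE)
  W <- matrix(0, length(xe) - 1, length(ye) - 1)
  for (f in seq_len(nrow(P))) W[ix[f], iy[f]] <- W[ix[f], iy[f]] + weights[f]
  F <- matrix(NA_real_, nrow(W), ncol(W))
  pop <- W > 0
  F[pop] <- -temperatureKT * log(W[pop])
  F <- F - min(F, na.rm = TRUE)
  new("FESGrid", xEdges = xe, yEdges = ye, F = F)
}

#' Stationary frame weights for free-energy reweighting
#'
#' weight(frame) = pi(microstate of frame) / (number of frames assigned to
#' that microstate); frames in microstates outside the model's active set
#' get weight 0.
#'
#' @param model a \code{\link{MarkovModel}}.
#' @param assignments 1-based microstate sequence (or list).
#' @return numeric weights summing to 1, in frame order.
#' @export
stationaryFrameWeights <- function(model, assignments) {
  a <- unlist(assignments)
  w <- numeric(length(a))
  cnt <- tabulate(a, nbins = max(a))
  for (s in seq_along(model@activeSet)) {
    orig <- model@activeSet[s]
    sel <- a == orig
    if (any(sel)) w[sel] <- model@stationary[s] / cnt[orig]
  }
  w / sum(w)
}
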