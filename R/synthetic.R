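## Synthetic-data generators. Every pipeline stage assumes a particular
## statistical structure in its input; these generators produce inputs with
## that structure and a known ground truth, so each stage can be validated
## without any simulation data. All generators are pure functions of their
## parameters and seed.

#' Simulate a discrete Markov chain
#'
#' Draws a state sequence from a row-stochastic transition matrix. Serves
#' as ground truth for the Markov-model estimators: empirical lag-1
#' transition frequencies converge to the generating matrix.
#'
#' @param transitionMatrix square row-stochastic matrix (rows sum to 1
#'   within 1e-12, entries >= 0).
#' @param length number of states to draw (>= 1).
#' @param initialState 1-based starting state.
#' @param seed integer RNG seed.
#' @return integer vector of 1-based state indices, length \code{length}.
#' @examples
#' T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
#' s <- simulateMarkovChain(T, 1000, initialState = 1, seed = 7)
#' table(s) / length(s)  # approaches the stationary distribution (2/3, 1/3)
#' @export
simulateMarkovChain <- function(transitionMatrix, length, initialState = 1L,
                                seed = 1L) {
  P <- as.matrix(transitionMatrix)
  n <- nrow(P)
  if (ncol(P) != n) stop("transition matrix must be square")
  if (any(P < 0)) stop("transition matrix entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1 (within 1e-12)")
  if (length < 1) stop("length must be >= 1")
  if (initialState < 1 || initialState > n) stop("initialState out of range")
  set.seed(seed)
  s <- integer(length)
  s[1] <- as.integer(initialState)
  if (length > 1) {
    u <- runif(length - 1)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:length) {
      # findInterval on the cumulative row: first state whose cumsum >= u
      s[t] <- min(as.integer(findInterval(u[t - 1], cum[s[t - 1], ],
                                          left.open = TRUE) + 1L), n)
    }
  }
  s
}

#' Simulate overdamped Langevin dynamics on a multi-well potential
#'
#' Euler-Maruyama discretization of dx = -U'(x) dt + noise * sqrt(2 dt) dW
#' on a polynomial potential with wells at \code{wellCenters} and barrier
#' height \code{barrierHeight} (kT) between adjacent wells. With
#' \code{noiseScale = 1} the stationary density is Boltzmann at unit kT (in
#' the small-timestep limit); with \code{noiseScale = 0} the dynamics is
#' plain gradient descent into the nearest well. Stands in for a metastable
#' torsion coordinate.
#'
#' @param wellCenters numeric positions of the potential minima (>= 1).
#' @param barrierHeight barrier height in kT (>= 0).
#' @param noiseScale dimensionless thermal noise multiplier.
#' @param timestep integration step (> 0, dimensionless).
#' @param nSteps number of steps (>= 1).
#' @param x0 starting position (default: first well center).
#' @param seed integer RNG seed.
#' @return numeric trajectory of length \code{nSteps}.
#' @export
simulateDoubleWell <- function(wellCenters, barrierHeight = 4, noiseScale = 1,
                               timestep = 1e-3, nSteps, x0 = wellCenters[1],
                               seed = 1L) {
  if (length(wellCenters) < 1) stop("at least one well center required")
  if (barrierHeight < 0) stop("barrierHeight must be >= 0")
  if (timestep <= 0) stop("timestep must be > 0")
  if (nSteps < 1) stop("nSteps must be >= 1")
  centers <- sort(wellCenters)
  # For >= 2 wells: piecewise quartic between adjacent centers, harmonic
  # outside; U(center) = 0, U(midpoint) = barrierHeight.
  gradU <- function(x) {
    if (length(centers) == 1) return(2 * (x - centers))
    if (x <= centers[1]) return(2 * barrierHeight * (x - centers[1]))
    if (x >= centers[length(centers)])
      return(2 * barrierHeight * (x - centers[length(centers)]))
    i <- findInterval(x, centers)
    a <- centers[i]; b <- centers[i + 1]
    m <- (a + b) / 2; d <- (b - a) / 2
    # U = h * ((x-m)^2 - d^2)^2 / d^4  (wells at a,b; barrier h at m)
    4 * barrierHeight * ((x - m)^2 - d^2) * (x - m) / d^4
  }
  set.seed(seed)
  x <- numeric(nSteps)
  xi <- rnorm(nSteps)
  cur <- x0
  amp <- noiseScale * sqrt(2 * timestep)
  for (t in seq_len(nSteps)) {
    g <- gradU(cur)
    drift <- -g * timestep
    # stabilized step for stiff gradients: the overdamped drift may never
    # overshoot the nearest well centre
    near <- centers[which.min(abs(centers - cur))]
    toNear <- near - cur
    if (sign(drift) == sign(toNear) && abs(drift) > abs(toNear))
      drift <- toNear
    cur <- cur + drift + amp * xi[t]
    x[t] <- cur
  }
  x
}

#' Generate a toy Calpha chain trajectory with prescribed displacement
#' covariance
#'
#' Frames are \code{baseCoordinates} plus zero-mean Gaussian displacements
#' whose per-residue covariance (applied independently to x, y and z) is
#' \code{displacementCovariance}. Ground truth for the residue-coupling
#' estimator: the sample displacement correlation converges to the
#' normalized covariance.
#'
#' @param nResidues number of residues.
#' @param displacementCovariance symmetric PSD nResidues x nResidues matrix.
#' @param nFrames number of frames.
#' @param baseCoordinates optional nResidues x 3 matrix (Angstrom); default
#'   an extended chain at 3.8 A Calpha spacing.
#' @param frameStride ns per frame (default 1).
#' @param seed integer RNG seed.
#' @return a \code{\link{TrajectoryEnsemble}} of Calpha pseudo-atoms.
#' @export
generateChainTrajectory <- function(nResidues, displacementCovariance, nFrames,
                                    baseCoordinates = NULL, frameStride = 1,
                                    seed = 1L) {
  S <- as.matrix(displacementCovariance)
  if (nrow(S) != nResidues || ncol(S) != nResidues)
    stop("displacementCovariance must be nResidues x nResidues")
  if (!isPSD(S)) stop("displacementCovariance must be symmetric PSD")
  if (is.null(baseCoordinates))
    baseCoordinates <- cbind(3.8 * (seq_len(nResidues) - 1), 0, 0)
  base <- as.matrix(baseCoordinates)
  if (nResidues > 1) {
    dmin <- min(dist(base))
    if (dmin < 1) stop("base geometry has residues closer than 1 A")
  }
  set.seed(seed)
  # one displacement draw per frame and Cartesian component
  dx <- rmvnormPSD(nFrames, S)
  dy <- rmvnormPSD(nFrames, S)
  dz <- rmvnormPSD(nFrames, S)
  frames <- lapply(seq_len(nFrames), function(f)
    base + cbind(dx[f, ], dy[f, ], dz[f, ]))
  topo <- new("Structure", atoms = data.frame(
    name = "CA", resid = seq_len(nResidues), resname = "ALA",
    chain = "A", x = base[, 1], y = base[, 2], z = base[, 3],
    stringsAsFactors = FALSE))
  new("TrajectoryEnsemble", topology = topo, frames = frames,
      frameStride = frameStride)
}

#' Generate the five endocyclic sugar-ring torsions from pseudorotation
#' parameters
#'
#' Standard pseudorotation parameterization of a five-membered (furanose)
#' ring: nu_j = tau_m * cos(P + 144 * (j - 2)) degrees, j = 0..4. Inverse
#' of \code{\link{pseudorotation}}.
#'
#' @param phaseP pseudorotation phase angle P, degrees in [0, 360).
#' @param amplitude puckering amplitude tau_m, degrees (>= 0).
#' @return named numeric vector nu0..nu4 (degrees).
#' @examples
#' generateSugarRing(18, 35)   # C3'-endo (A-form-like) pucker
#' @export
generateSugarRing <- function(phaseP, amplitude) {
  if (phaseP < 0 || phaseP >= 360) stop("phaseP must lie in [0, 360)")
  if (amplitude < 0) stop("amplitude must be >= 0")
  j <- 0:4
  nu <- amplitude * cos((phaseP + 144 * (j - 2)) * pi / 180)
  names(nu) <- paste0("nu", j)
  nu
}

#' Sample a Gaussian-mixture distance series
#'
#' I.i.d. samples from a mixture of normal components; fixture for the
#' marker histogram/fit machinery. Uses a single seeded generator stream.
#'
#' @param componentMeans,componentSds,weights equal-length vectors; weights
#'   sum to 1, sds > 0.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return numeric vector of length n (Angstrom).
#' @export
generateDistanceSeries <- function(componentMeans, componentSds, weights, n,
                                   seed = 1L) {
  k <- length(componentMeans)
  if (length(componentSds) != k || length(weights) != k)
    stop("componentMeans, componentSds and weights must have equal length")
  if (any(componentSds <= 0)) stop("sds must be > 0")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  set.seed(seed)
  comp <- findInterval(runif(n), cumsum(weights), left.open = TRUE) + 1L
  comp[comp > k] <- k
  rnorm(n, mean = componentMeans[comp], sd = componentSds[comp])
}

# Ideal backbone internal coordinates (Angstrom / degrees).
.bbGeom <- list(
  b.N.CA = 1.458, b.CA.C = 1.525, b.C.N = 1.329, b.C.O = 1.231,
  a.N.CA.C = 111.0, a.CA.C.N = 116.2, a.C.N.CA = 121.7, a.CA.C.O = 120.5,
  omega = 180)

# Build one backbone frame (atoms N, CA, C, O per residue) from phi/psi
# vectors via sequential internal-coordinate placement.
buildBackboneFrame <- function(phi, psi) {
  n <- length(phi)
  g <- .bbGeom
  coords <- matrix(NA_real_, 4 * n, 3)
  # residue 1: N at origin, CA on x, C in xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b.N.CA, 0, 0)
  ang <- g$a.N.CA.C * pi / 180
  C1 <- CA1 + g$b.CA.C * c(-cos(ang), sin(ang), 0)
  coords[1, ] <- N1; coords[2, ] <- CA1; coords[3, ] <- C1
  prevN <- N1; prevCA <- CA1; prevC <- C1
  for (r in seq_len(n)) {
    i0 <- 4 * (r - 1)
    if (r > 1) {
      N <- placeAtom(prevN, prevCA, prevC, g$b.C.N, g$a.CA.C.N, psi[r - 1])
      CA <- placeAtom(prevCA, prevC, N, g$b.N.CA, g$a.C.N.CA, g$omega)
      C <- placeAtom(prevC, N, CA, g$b.CA.C, g$a.N.CA.C, phi[r])
      coords[i0 + 1, ] <- N; coords[i0 + 2, ] <- CA; coords[i0 + 3, ] <- C
      prevN <- N; prevCA <- CA; prevC <- C
    }
    # carbonyl O: torsion psi + 180 about CA-C viewed from N
    coords[i0 + 4, ] <- placeAtom(prevN, prevCA, prevC, g$b.C.O, g$a.CA.C.O,
                                  psi[r] + 180)
  }
  coords
}

#' Generate a backbone trajectory with prescribed per-frame phi/psi torsions
#'
#' Rebuilds N/CA/C/O backbone coordinates frame by frame from ideal bond
#' lengths and angles and the supplied torsions, so the torsion featurizer
#' can be validated against known ground truth and metastable torsion
#' dynamics (e.g. driven by \code{\link{simulateMarkovChain}}) can be
#' turned into a full trajectory.
#'
#' @param phi,psi nFrames x nResidues matrices of torsions in degrees.
#'   phi of residue 1 and psi of the last residue are still needed to place
#'   atoms but are not recoverable as dihedrals from the chain itself.
#' @param frameStride ns per frame.
#' @param resids optional residue numbering (default 1..nResidues).
#' @return a \code{\link{TrajectoryEnsemble}} of poly-alanine backbone.
#' @export
generateBackboneTrajectory <- function(phi, psi, frameStride = 1,
                                       resids = NULL) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  if (!all(dim(phi) == dim(psi))) stop("phi and psi must have equal dims")
  nRes <- ncol(phi)
  if (is.null(resids)) resids <- seq_len(nRes)
  frames <- lapply(seq_len(nrow(phi)), function(f)
    buildBackboneFrame(phi[f, ], psi[f, ]))
  topo <- new("Structure", atoms = data.frame(
    name = rep(c("N", "CA", "C", "O"), nRes),
    resid = rep(resids, each = 4),
    resname = "ALA", chain = "A",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    stringsAsFactors = FALSE))
  new("TrajectoryEnsemble", topology = topo, frames = frames,
      frameStride = frameStride)
}
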