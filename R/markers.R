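## Conformational marker distances and their histogram/Gaussian-fit
## machinery. Distances refer to Calpha atoms of protein residues and P
## atoms of nucleic residues unless a marker states otherwise; nucleic
## sites named as base steps are realized as the midpoint of the named P
## atoms.

.sel <- function(resids, atom, kind = c("single", "midpoint")) {
  list(resids = resids, atom = atom, kind = match.arg(kind))
}

#' Built-in conformational markers
#'
#' The six marker groups monitored for HNH/RuvC activation state:
#' (a) catalytic His840 to the target-strand cleavage site (DA17/DC18);
#' (b) the FRET-motivated Ser355-Ser867, Ser867-Asn1054 and Asp839-Lys866
#' distances; (c) His983 to the non-target-strand scissile phosphate
#' (DG13/DT14); (d) the Arg976 terminal side-chain carbon to the same
#' scissile phosphate; (e) Gln768 to the PAM-distal target-DNA end
#' (DA24/DT25); (f) Arg1333 and Arg1335 of the PAM-interacting domain to
#' the PAM (DT21/DG22/DG23). Protein anchors are Calpha except the stated
#' Arg976 side-chain exception; nucleic anchors are midpoints of the named
#' P atoms.
#'
#' @return data.frame-backed list of marker definitions with fields
#'   \code{label}, \code{group}, \code{selA}, \code{selB}, \code{notes}.
#' @export
builtinMarkers <- function() {
  mk <- function(label, group, selA, selB, notes = "") {
    list(label = label, group = group, selA = selA, selB = selB,
         notes = notes)
  }
  list(
    mk("His840-tsDNA_cleavage", "a", .sel(840, "CA"),
       .sel(c(17, 18), "P", "midpoint"),
       "HNH active/inactive discriminator"),
    mk("Ser355-Ser867", "b", .sel(355, "CA"), .sel(867, "CA"),
       "FRET pair for the HNH transition"),
    mk("Ser867-Asn1054", "b", .sel(867, "CA"), .sel(1054, "CA"),
       "FRET pair for the HNH transition"),
    mk("Asp839-Lys866", "b", .sel(839, "CA"), .sel(866, "CA"),
       "FRET pair for the HNH transition"),
    mk("His983-ntDNA_scissile_P", "c", .sel(983, "CA"),
       .sel(c(13, 14), "P", "midpoint"), "RuvC active site"),
    mk("Arg976_sidechain-ntDNA_scissile_P", "d", .sel(976, "CZ"),
       .sel(c(13, 14), "P", "midpoint"),
       "terminal side-chain carbon, stated exception"),
    mk("Gln768-PAM_distal_tDNA", "e", .sel(768, "CA"),
       .sel(c(24, 25), "P", "midpoint"), "PAM-distal duplex end"),
    mk("Arg1333-PAM", "f", .sel(1333, "CA"),
       .sel(c(21, 22, 23), "P", "midpoint"), "PAM-interacting domain"),
    mk("Arg1335-PAM", "f", .sel(1335, "CA"),
       .sel(c(21, 22, 23), "P", "midpoint"), "PAM-interacting domain"))
}

# Resolve a selector to one anchor point per frame (midpoint of the named
# atoms when kind = "midpoint"). Returns NULL when unresolvable.
.resolveAnchor <- function(a, sel, frame) {
  idx <- .atomIndexByResidue(a, sel$resids, sel$atom)
  if (anyNA(idx)) return(NULL)
  pts <- frame[idx, , drop = FALSE]
  colMeans(pts)
}

#' Marker distance series over a trajectory
#'
#' One distance per frame. An unresolvable selector (e.g. a mutant
#' topology lacking the residue) skips the marker with a message and
#' returns NULL rather than failing.
#'
#' @param traj a \code{\link{TrajectoryEnsemble}}.
#' @param marker one element of \code{\link{builtinMarkers}} (or a
#'   compatible list).
#' @return numeric vector of distances (Angstrom), or NULL when skipped.
#' @export
markerSeries <- function(traj, marker) {
  a <- atoms(topology(traj))
  test <- .resolveAnchor(a, marker$selA, frames(traj)[[1]])
  test2 <- .resolveAnchor(a, marker$selB, frames(traj)[[1]])
  if (is.null(test) || is.null(test2)) {
    message("markerSeries: selector unresolvable for marker ",
            marker$label, "; skipped")
    return(NULL)
  }
  vapply(frames(traj), function(f) {
    atomDistance(.resolveAnchor(a, marker$selA, f),
                 .resolveAnchor(a, marker$selB, f))
  }, numeric(1))
}

#' Fit Gaussian components to a distance sample
#'
#' One component: closed-form sample moments. Two or more: expectation-
#' maximization with seeded quantile-based restarts, keeping the best of
#' \code{nRestarts} by log-likelihood. The log-likelihood is non-decreasing
#' across EM iterations by construction.
#'
#' @param samples numeric vector (>= 10 values, positive variance).
#' @param nComponents number of Gaussian components (default 1).
#' @param nRestarts EM restarts (default 5).
#' @param seed integer RNG seed for the restarts.
#' @param maxIter,tol EM iteration control.
#' @return data.frame: component, mean, sd, amplitude (mixture weight);
#'   with attribute \code{logLik}.
#' @export
fitGaussians <- function(samples, nComponents = 1, nRestarts = 5, seed = 1L,
                         maxIter = 500, tol = 1e-8) {
  x <- as.numeric(samples)
  if (length(x) < 10) stop("at least 10 samples required")
  if (var(x) <= 0) stop("degenerate fit: zero sample variance")
  if (nComponents == 1) {
    out <- data.frame(component = 1L, mean = mean(x), sd = sd(x),
                      amplitude = 1)
    attr(out, "logLik") <- sum(dnorm(x, mean(x), sd(x), log = TRUE))
    return(out)
  }
  set.seed(seed)
  best <- NULL; bestLL <- -Inf
  n <- length(x); k <- nComponents
  for (r in seq_len(nRestarts)) {
    # quantile-spread means, jittered per restart
    mu <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE) +
      rnorm(k, 0, sd(x) / (4 * k) * (r > 1))
    sg <- rep(sd(x) / k, k)
    w <- rep(1 / k, k)
    ll <- -Inf
    for (it in seq_len(maxIter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * dnorm(x, mu[j], max(sg[j], 1e-8)), numeric(n))
      rowS <- rowSums(dens)
      rowS[rowS < 1e-300] <- 1e-300
      resp <- dens / rowS
      llNew <- sum(log(rowS))
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sg <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
      sg <- pmax(sg, 1e-6)
      if (is.finite(ll) && llNew - ll < tol * (1 + abs(llNew))) { ll <- llNew; break }
      ll <- llNew
    }
    if (ll > bestLL) {
      bestLL <- ll
      ord <- order(mu)
      best <- data.frame(component = seq_len(k), mean = mu[ord],
                         sd = sg[ord], amplitude = w[ord])
    }
  }
  attr(best, "logLik") <- bestLL
  best
}

#' Histogram and Gaussian fit of a marker distance series
#'
#' Normalized density histogram (Freedman-Diaconis bins unless given) plus
#' a \code{\link{fitGaussians}} fit; the density integrates to 1.
#'
#' @param samples distance series (Angstrom).
#' @param label marker label carried through.
#' @param nComponents Gaussian components for the fit (default 1).
#' @param breaks passed to \code{hist} (default "FD").
#' @param seed seed for the EM restarts.
#' @return list with \code{label}, \code{samples}, \code{histogram}
#'   (edges, density) and \code{fit}.
#' @export
distanceProfile <- function(samples, label = "marker", nComponents = 1,
                            breaks = "FD", seed = 1L) {
  h <- hist(samples, breaks = breaks, plot = FALSE)
  fit <- fitGaussians(samples, nComponents = nComponents, seed = seed)
  list(label = label, samples = samples,
       histogram = list(edges = h$breaks, density = h$density),
       fit = fit)
}
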