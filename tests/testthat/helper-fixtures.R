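# Fixtures are built in code at test time; nothing binary is stored.

# A 3-residue poly-alanine backbone structure with fixed torsions.
makeTriPeptide <- function(phi = -60, psi = -45) {
  generateBackboneTrajectory(matrix(rep(phi, 3), 1),
                             matrix(rep(psi, 3), 1))
}

# Random proper rotation matrix (uniform via QR of Gaussian).
randomRotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Coordinate-level furanose fixture. The ring is a regular pentagon with an
# out-of-plane displacement mode z_j = q cos(2 theta_j + phi0); empirically
# the resulting pseudorotation phase is phi0 + 270 (mod 360) within ~1.2
# degrees, and q = 0.38 A gives an amplitude near 54 degrees. Exocyclic
# C5' and O3' are placed so the delta torsion (C5'-C4'-C3'-O3') equals
# `delta`.
sugarRingCoords <- function(targetPhase, q = 0.38, delta = 80) {
  phi0 <- (targetPhase - 270) %% 360
  th <- 2 * pi * (0:4) / 5
  R <- 1.31
  ring <- cbind(R * cos(th), R * sin(th), q * cos(2 * th + phi0 * pi / 180))
  rownames(ring) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  C2p <- ring["C2'", ]; C3p <- ring["C3'", ]; C4p <- ring["C4'", ]
  C5p <- Cas9Dynamics:::placeAtom(C2p, C3p, C4p, 1.51, 112, 140)
  O3p <- Cas9Dynamics:::placeAtom(C5p, C4p, C3p, 1.42, 110, delta)
  rbind(ring, "C5'" = C5p, "O3'" = O3p)
}

# Structure with one synthetic nucleotide per requested phase.
makeSugarStructure <- function(phases, deltas = rep(80, length(phases)),
                               resnames = rep("DA", length(phases))) {
  rows <- list()
  for (i in seq_along(phases)) {
    m <- sugarRingCoords(phases[i], delta = deltas[i])
    m[, 1] <- m[, 1] + 20 * (i - 1)  # separate the residues in space
    rows[[i]] <- data.frame(name = rownames(m), resid = i,
                            resname = resnames[i], chain = "B",
                            x = m[, 1], y = m[, 2], z = m[, 3],
                            stringsAsFactors = FALSE)
  }
  new("Structure", atoms = do.call(rbind, rows))
}

# Minimal CHARMM-style DCD writer (little-endian, Fortran record markers);
# just enough of the format for bio3d's reader, used to exercise the
# binary-trajectory adapter without storing binary fixtures.
writeMiniDCD <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload) {
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    writeBin(payload, con, endian = "little")
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  }
  hdr <- raw(84)
  hdr[1:4] <- charToRaw("CORD")
  icntrl <- integer(20)
  icntrl[1] <- length(frames)   # NSET
  icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- length(frames)
  hdr[5:84] <- writeBin(as.integer(icntrl), raw(), size = 4,
                        endian = "little")
  rec(hdr)
  title <- c(writeBin(1L, raw(), size = 4, endian = "little"),
             charToRaw(formatC("synthetic test dcd", width = 80)))
  rec(title)
  rec(writeBin(as.integer(nrow(frames[[1]])), raw(), size = 4,
               endian = "little"))
  for (f in frames) {
    for (d in 1:3)
      rec(writeBin(as.numeric(f[, d]), raw(), size = 4, endian = "little"))
  }
  invisible(path)
}

# Exhaustive shortest-path oracle: enumerate all simple paths.
bruteForcePath <- function(edges, source, target) {
  best <- list(weight = Inf, path = integer())
  nbrs <- function(v) {
    sel <- edges$resI == v | edges$resJ == v
    data.frame(to = ifelse(edges$resI[sel] == v, edges$resJ[sel],
                           edges$resI[sel]),
               w = edges$weight[sel])
  }
  recurse <- function(v, visited, w, path) {
    if (w >= best$weight) return()
    if (v == target) { best <<- list(weight = w, path = path); return() }
    nb <- nbrs(v)
    for (r in seq_len(nrow(nb))) {
      if (nb$to[r] %in% visited) next
      recurse(nb$to[r], c(visited, nb$to[r]), w + nb$w[r], c(path, nb$to[r]))
    }
  }
  recurse(source, source, 0, source)
  best
}

# Value-iteration (dynamic-programming) MFPT oracle for small chains:
# h <- tau + T h on the complement of the target set, iterated to a fixed
# point, then stationary-weighted over the source set.
mfptOracle <- function(T, pi, sourceSet, targetSet, tauNs = 1) {
  k <- nrow(T)
  h <- rep(0, k)
  for (it in 1:200000) {
    hNew <- tauNs + as.numeric(T %*% h)
    hNew[targetSet] <- 0
    if (max(abs(hNew - h)) < 1e-12) { h <- hNew; break }
    h <- hNew
  }
  w <- pi[sourceSet] / sum(pi[sourceSet])
  sum(w * h[sourceSet])
}
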