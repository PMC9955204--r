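## Geometric kernels: distances, dihedrals, superposition, torsion
## featurization, and the nucleic-acid delta/pseudorotation analysis.

#' Euclidean distance between two points
#'
#' @param a,b numeric length-3 coordinates (Angstrom).
#' @return distance in Angstrom.
#' @export
atomDistance <- function(a, b) sqrt(sum((a - b)^2))

#' Signed dihedral angle
#'
#' Standard two-argument arctangent convention with IUPAC sign: cis = 0,
#' trans = 180, angles in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  n1 <- crossProd3(p2 - p1, b2)
  n2 <- crossProd3(b2, p4 - p3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: collinear points give no defined dihedral")
  dihedralRows(matrix(p1, 1), matrix(p2, 1), matrix(p3, 1), matrix(p4, 1))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid transform of \code{mobile} onto \code{reference}
#' over the atom \code{subset}, with the determinant correction that
#' guarantees a proper rotation (no reflection).
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param subset indices used for the fit (default all; >= 3 required).
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd} (Angstrom, over the subset after transform) and
#'   \code{coords} (all mobile coordinates transformed). The transform maps
#'   x to \code{x \%*\% rotation + translation}.
#' @export
kabschSuperpose <- function(mobile, reference, subset = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  if (length(subset) < 3) stop("subset must contain at least 3 points")
  P <- mobile[subset, , drop = FALSE]
  Q <- reference[subset, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  trans <- cq - as.numeric(cp %*% R)
  fit <- P %*% R
  fit <- sweep(fit, 2, as.numeric(cp %*% R) - cq, "-")
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  all <- sweep(mobile %*% R, 2, trans, "+")
  list(rotation = R, translation = trans, rmsd = rmsd, coords = all)
}

#' Root-mean-square deviation without superposition
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rawRMSD <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

# indices of one named atom per residue; NA when absent
.atomIndexByResidue <- function(a, resids, name) {
  key <- paste(a$resid, a$name)
  match(paste(resids, name), key)
}

#' Featurize a trajectory by backbone torsions
#'
#' Computes per-residue backbone phi and psi (and optionally chi1) for the
#' requested residue range and expands each angle into (sin, cos) columns.
#' Terminal residues lacking an angle, and residues with missing backbone
#' atoms, are skipped with their provenance recorded in the returned
#' labels; missing atoms are logged, not fatal.
#'
#' @param traj a \code{\link{TrajectoryEnsemble}}.
#' @param residRange inclusive residue range \code{c(start, end)}.
#' @param includeChi1 include the chi1 side-chain torsion where the gamma
#'   atom exists (default FALSE).
#' @return a \code{\link{FeatureMatrix}}.
#' @export
featurizeTorsions <- function(traj, residRange = NULL, includeChi1 = FALSE) {
  a <- atoms(topology(traj))
  resids <- sort(unique(a$resid))
  if (!is.null(residRange))
    resids <- resids[resids >= residRange[1] & resids <= residRange[2]]
  idx <- list(N = .atomIndexByResidue(a, resids, "N"),
              CA = .atomIndexByResidue(a, resids, "CA"),
              C = .atomIndexByResidue(a, resids, "C"),
              CB = .atomIndexByResidue(a, resids, "CB"))
  gammaNames <- c("CG", "CG1", "OG", "OG1", "SG")
  defs <- list()  # each: resid, torsion, 4 atom indices
  for (i in seq_along(resids)) {
    r <- resids[i]
    # phi: C(i-1) - N(i) - CA(i) - C(i); requires the preceding residue
    if (i > 1 && resids[i - 1] == r - 1 &&
        !anyNA(c(idx$C[i - 1], idx$N[i], idx$CA[i], idx$C[i])))
      defs[[length(defs) + 1]] <- list(resid = r, torsion = "phi",
        atoms = c(idx$C[i - 1], idx$N[i], idx$CA[i], idx$C[i]))
    # psi: N(i) - CA(i) - C(i) - N(i+1)
    if (i < length(resids) && resids[i + 1] == r + 1 &&
        !anyNA(c(idx$N[i], idx$CA[i], idx$C[i], idx$N[i + 1])))
      defs[[length(defs) + 1]] <- list(resid = r, torsion = "psi",
        atoms = c(idx$N[i], idx$CA[i], idx$C[i], idx$N[i + 1]))
    if (includeChi1 && !is.na(idx$CB[i])) {
      sel <- which(a$resid == r & a$name %in% gammaNames)
      if (length(sel) && !anyNA(c(idx$N[i], idx$CA[i], idx$CB[i])))
        defs[[length(defs) + 1]] <- list(resid = r, torsion = "chi1",
          atoms = c(idx$N[i], idx$CA[i], idx$CB[i], sel[1]))
    }
  }
  if (!length(defs)) stop("no torsions defined for the requested range")
  nf <- nFrames(traj)
  X <- array(NA_real_, c(nf, nrow(a), 3))
  for (f in seq_len(nf)) X[f, , ] <- frames(traj)[[f]]
  cols <- vector("list", 2 * length(defs))
  labs <- vector("list", 2 * length(defs))
  for (d in seq_along(defs)) {
    ai <- defs[[d]]$atoms
    ang <- dihedralRows(X[, ai[1], , drop = TRUE] |> matrix(ncol = 3),
                        X[, ai[2], , drop = TRUE] |> matrix(ncol = 3),
                        X[, ai[3], , drop = TRUE] |> matrix(ncol = 3),
                        X[, ai[4], , drop = TRUE] |> matrix(ncol = 3))
    rad <- ang * pi / 180
    cols[[2 * d - 1]] <- sin(rad)
    cols[[2 * d]] <- cos(rad)
    labs[[2 * d - 1]] <- data.frame(resid = defs[[d]]$resid,
                                    torsion = defs[[d]]$torsion, part = "sin")
    labs[[2 * d]] <- data.frame(resid = defs[[d]]$resid,
                                torsion = defs[[d]]$torsion, part = "cos")
  }
  new("FeatureMatrix", values = do.call(cbind, cols),
      labels = do.call(rbind, labs))
}

#' Pseudorotation phase and amplitude of a furanose ring
#'
#' Inverts the standard parameterization nu_j = tau_m cos(P + 144 (j - 2)):
#' tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)), with the
#' quadrant resolved by the two-argument arctangent (sign of nu2), and the
#' amplitude recovered robustly as the hypotenuse of (tau_m sin P,
#' tau_m cos P) — algebraically equal to nu2 / cos P away from P = 90/270.
#'
#' @param nu numeric length-5 vector nu0..nu4 (degrees).
#' @return named vector \code{c(phaseP =, amplitude =)}, P in [0, 360).
#' @export
pseudorotation <- function(nu) {
  if (length(nu) != 5 || !all(is.finite(nu))) stop("need 5 finite torsions")
  denomC <- 2 * (sin(36 * pi / 180) + sin(72 * pi / 180))
  Y <- (nu[5] + nu[2]) - (nu[4] + nu[1])  # (nu4 + nu1) - (nu3 + nu0)
  X <- nu[3] * denomC
  if (abs(X) < 1e-12 && abs(Y) < 1e-12)
    stop("undefined pucker: flat ring (nu2 = 0 and zero numerator)")
  P <- atan2(Y, X) * 180 / pi
  if (P < 0) P <- P + 360
  tauM <- sqrt((Y / denomC)^2 + nu[3]^2)
  c(phaseP = unname(P), amplitude = unname(tauM))
}

#' Delta backbone torsion of a nucleotide
#'
#' The C5'-C4'-C3'-O3' torsion, reported in [0, 360) for plotting parity
#' with pseudorotation-phase scatter plots.
#'
#' @param structure a \code{\link{Structure}} (or its atoms data.frame).
#' @param resid residue number of the nucleotide.
#' @param coords optional replacement coordinates (n x 3) for the
#'   structure's atoms (e.g. one trajectory frame).
#' @return angle in degrees in [0, 360), or NA (with a message) when an
#'   atom is missing.
#' @export
deltaTorsion <- function(structure, resid, coords = NULL) {
  a <- if (is(structure, "Structure")) atoms(structure) else structure
  need <- c("C5'", "C4'", "C3'", "O3'")
  idx <- vapply(need, function(nm) {
    w <- which(a$resid == resid & a$name == nm)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    message("deltaTorsion: residue ", resid, " missing atom(s) ",
            paste(need[is.na(idx)], collapse = ", "), "; skipped")
    return(NA_real_)
  }
  m <- if (is.null(coords)) as.matrix(a[, c("x", "y", "z")]) else as.matrix(coords)
  ang <- dihedralAngle(m[idx[1], ], m[idx[2], ], m[idx[3], ], m[idx[4], ])
  ang <- ang %% 360
  if (ang >= 360) ang <- 0  # guard the rounding boundary
  ang
}

#' Classify a sugar pucker regime from the pseudorotation phase
#'
#' Phase regimes: R-loop-associated above 270 degrees, B-form at or above
#' 100 degrees, A-form below 100 degrees. The R-loop window is a subset of
#' the B-form half-plane, so precedence is R-loop > B-form > A-form.
#'
#' @param phaseP phase in degrees, [0, 360) (vectorized).
#' @return character vector: "A-form", "B-form" or "R-loop".
#' @export
classifyPucker <- function(phaseP) {
  if (any(phaseP < 0 | phaseP >= 360)) stop("phase must lie in [0, 360)")
  ifelse(phaseP > 270, "R-loop", ifelse(phaseP >= 100, "B-form", "A-form"))
}

# Endocyclic ring torsions nu0..nu4 for one nucleotide from coordinates.
# Ring atom cycle: O4'-C1'-C2'-C3'-C4'; nu_j is the torsion about the bond
# C(j)-C(j+1) in the conventional numbering:
#   nu0: C4'-O4'-C1'-C2', nu1: O4'-C1'-C2'-C3', nu2: C1'-C2'-C3'-C4',
#   nu3: C2'-C3'-C4'-O4', nu4: C3'-C4'-O4'-C1'
sugarTorsions <- function(a, resid, m) {
  ring <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  idx <- vapply(ring, function(nm) {
    w <- which(a$resid == resid & a$name == nm)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx)) return(NULL)
  ord <- c("C4'", "O4'", "C1'", "C2'", "C3'", "C4'", "O4'", "C1'")
  pos <- setNames(idx, ring)
  vapply(0:4, function(j) {
    q <- ord[(j + 1):(j + 4)]
    dihedralAngle(m[pos[q[1]], ], m[pos[q[2]], ], m[pos[q[3]], ], m[pos[q[4]], ])
  }, numeric(1))
}

.nucleicResnames <- c("DA", "DT", "DG", "DC", "A", "U", "G", "C",
                      "RA", "RU", "RG", "RC")

#' Per-residue pucker table over a structure or trajectory
#'
#' One record per nucleic residue per frame: delta torsion, pseudorotation
#' phase and amplitude, and the pucker regime. Residues with undefined
#' (flat) puckers or missing sugar atoms are omitted with a log message.
#'
#' @param x a \code{\link{Structure}} or \code{\link{TrajectoryEnsemble}}.
#' @param resids nucleic residue numbers to analyze; default: all residues
#'   with a recognized nucleic resname.
#' @param strandLabels optional named character vector resid -> strand
#'   label (e.g. "tDNA", "ntDNA"); default "other".
#' @return data.frame: resid, strand, frame, delta_deg, phase_deg,
#'   amplitude_deg, regime. Empty (with a warning) when no nucleic
#'   residues are found.
#' @export
puckerTable <- function(x, resids = NULL, strandLabels = NULL) {
  if (is(x, "TrajectoryEnsemble")) {
    a <- atoms(topology(x)); frameList <- frames(x)
  } else {
    a <- atoms(x); frameList <- list(as.matrix(a[, c("x", "y", "z")]))
  }
  if (is.null(resids))
    resids <- sort(unique(a$resid[a$resname %in% .nucleicResnames]))
  if (!length(resids)) {
    warning("no nucleic residues found")
    return(data.frame(resid = integer(), strand = character(),
                      frame = integer(), delta_deg = numeric(),
                      phase_deg = numeric(), amplitude_deg = numeric(),
                      regime = character()))
  }
  rows <- list()
  for (f in seq_along(frameList)) {
    m <- frameList[[f]]
    for (r in resids) {
      nu <- sugarTorsions(a, r, m)
      if (is.null(nu)) {
        message("puckerTable: residue ", r, " lacks sugar ring atoms; skipped")
        next
      }
      pr <- tryCatch(pseudorotation(nu), error = function(e) NULL)
      if (is.null(pr)) {
        message("puckerTable: residue ", r, " frame ", f,
                " has undefined (flat) pucker; omitted")
        next
      }
      delta <- suppressMessages(deltaTorsion(a, r, coords = m))
      strand <- if (!is.null(strandLabels) && as.character(r) %in%
                    names(strandLabels)) strandLabels[[as.character(r)]]
                else "other"
      rows[[length(rows) + 1]] <- data.frame(
        resid = r, strand = strand, frame = f, delta_deg = delta,
        phase_deg = pr["phaseP"], amplitude_deg = pr["amplitude"],
        regime = classifyPucker(pr["phaseP"]), row.names = NULL)
    }
  }
  if (!length(rows))
    return(data.frame(resid = integer(), strand = character(),
                      frame = integer(), delta_deg = numeric(),
                      phase_deg = numeric(), amplitude_deg = numeric(),
                      regime = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
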