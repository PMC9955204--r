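# Geometric kernels: distances, dihedrals, superposition, torsion
# featurization, pseudorotation.

test_that("distances are Euclidean and symmetric", {
  expect_equal(atomDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(atomDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(atomDistance(a, b), atomDistance(b, a))
  }
})

test_that("dihedrals follow the IUPAC atan2 convention", {
  expect_equal(as.numeric(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                        c(2, 1, 0))), 0)
  expect_equal(as.numeric(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                        c(2, -1, 0))), 180)
  # construct a +60 degree torsion by explicit rotation about the p2-p3 axis
  th <- 60 * pi / 180
  p4 <- c(2, cos(th), sin(th))
  expect_equal(as.numeric(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                        p4)), 60, tolerance = 1e-6)
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "degenerate|collinear")
})

test_that("dihedrals are invariant under rigid motion", {
  set.seed(7)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), 4)
    ang0 <- tryCatch(dihedralAngle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                     error = function(e) NULL)
    if (is.null(ang0)) next
    R <- randomRotation(); tr <- rnorm(3, sd = 10)
    q <- sweep(pts %*% R, 2, tr, "+")
    ang1 <- dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ])
    d <- abs(ang1 - ang0) %% 360
    expect_lt(min(d, 360 - d), 1e-9)
  }
})

test_that("Kabsch superposition removes rigid motions and is optimal", {
  set.seed(2)
  A <- matrix(rnorm(15), 5)
  expect_equal(kabschSuperpose(A, A)$rmsd, 0, tolerance = 1e-12)
  R <- randomRotation()
  B <- sweep(A %*% R, 2, c(4, -2, 7), "+")
  k <- kabschSuperpose(B, A)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_error(kabschSuperpose(A[1:2, ], A[1:2, ]), "3 points")
})

test_that("Kabsch matches a brute-force rotation grid on a perturbed cloud", {
  set.seed(3)
  A <- matrix(rnorm(12), 4)
  B <- A + matrix(rnorm(12, sd = 0.3), 4)
  got <- kabschSuperpose(B, A)$rmsd
  # oracle: center both, scan Euler angles with local refinement
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rotZ <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                            c(0, 0, 1))
  rotY <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                            c(-sin(t), 0, cos(t)))
  evalR <- function(a, b, c) {
    R <- rotZ(a) %*% rotY(b) %*% rotZ(c)
    sqrt(mean(rowSums((Bc %*% R - Ac)^2)))
  }
  best <- c(0, 0, 0); bestV <- Inf
  step <- 2 * pi / 24
  grid <- seq(0, 2 * pi - step, by = step)
  for (a in grid) for (b in seq(0, pi, by = step)) for (c in grid) {
    v <- evalR(a, b, c)
    if (v < bestV) { bestV <- v; best <- c(a, b, c) }
  }
  for (ref in 1:4) {
    step <- step / 6
    g <- function(x) seq(x - 3 * step, x + 3 * step, by = step)
    for (a in g(best[1])) for (b in g(best[2])) for (c in g(best[3])) {
      v <- evalR(a, b, c)
      if (v < bestV) { bestV <- v; best <- c(a, b, c) }
    }
  }
  expect_equal(got, bestV, tolerance = 1e-3)
  expect_lte(got, bestV + 1e-9)  # never worse than any searched rotation
})

test_that("superposed RMSD never exceeds raw RMSD", {
  set.seed(4)
  for (i in 1:15) {
    A <- matrix(rnorm(18), 6)
    B <- A + matrix(rnorm(18, sd = runif(1, 0.01, 2)), 6)
    expect_lte(kabschSuperpose(B, A)$rmsd, rawRMSD(B, A) + 1e-12)
  }
})

test_that("torsion featurization yields the defined angles and identities", {
  # static trajectory: constant columns
  tr <- generateBackboneTrajectory(matrix(-60, 3, 3), matrix(-45, 3, 3))
  fm <- featurizeTorsions(tr)
  expect_true(all(apply(featureValues(fm), 2, var) < 1e-20))
  # 3-residue chain: middle residue has phi+psi, termini one each
  lab <- featureLabels(fm)
  ang <- unique(lab[, c("resid", "torsion")])
  expect_equal(nrow(ang), 4)
  expect_setequal(paste(ang$resid, ang$torsion),
                  c("1 psi", "2 phi", "2 psi", "3 phi"))
  expect_equal(ncol(featureValues(fm)), 8)  # sin+cos per angle
  # sin^2 + cos^2 = 1 per angle pair per frame
  v <- featureValues(fm)
  s2 <- v[, lab$part == "sin", drop = FALSE]^2 +
        v[, lab$part == "cos", drop = FALSE]^2
  expect_lt(max(abs(s2 - 1)), 1e-12)
})

test_that("pseudorotation inverts the sugar-ring generator", {
  expect_equal(unname(pseudorotation(generateSugarRing(144, 38))),
               c(144, 38), tolerance = 1e-9)
  expect_equal(unname(pseudorotation(generateSugarRing(18, 35))[1]), 18,
               tolerance = 1e-9)
  expect_error(pseudorotation(rep(0, 5)), "flat ring")
  # property: identity over random phases/amplitudes
  set.seed(9)
  for (i in 1:200) {
    P <- runif(1, 0, 360 - 1e-9); tau <- runif(1, 5, 60)
    out <- pseudorotation(generateSugarRing(P, tau))
    dP <- abs(out["phaseP"] - P) %% 360
    expect_lt(min(dP, 360 - dP), 1e-9)
    expect_equal(unname(out["amplitude"]), tau, tolerance = 1e-9)
  }
})

test_that("delta torsion is the C5'-C4'-C3'-O3' dihedral in [0, 360)", {
  for (target in c(0, 180, 85, 275.5)) {
    s <- makeSugarStructure(18, deltas = target)
    d <- deltaTorsion(s, 1)
    dd <- abs(d - target) %% 360
    expect_lt(min(dd, 360 - dd), 1e-6)
    expect_gte(d, 0); expect_lt(d, 360)
  }
  # missing atom: skip with message, NA result
  s <- makeSugarStructure(18)
  a <- atoms(s); a <- a[a$name != "O3'", ]
  expect_message(res <- deltaTorsion(new("Structure", atoms = a), 1),
                 "missing")
  expect_true(is.na(res))
})

test_that("pucker classification partitions the phase circle", {
  expect_equal(classifyPucker(50), "A-form")
  expect_equal(classifyPucker(162), "B-form")
  expect_equal(classifyPucker(300), "R-loop")
  grid <- seq(0, 359.9, by = 0.1)
  reg <- classifyPucker(grid)
  expect_true(all(reg %in% c("A-form", "B-form", "R-loop")))
  expect_equal(sum(reg == "A-form"), sum(grid < 100))
  expect_equal(sum(reg == "R-loop"), sum(grid > 270))
})

test_that("pucker tables classify synthetic duplexes per residue", {
  # all-C3'-endo (A-form) synthetic strand
  sA <- makeSugarStructure(c(18, 25, 40))
  tab <- puckerTable(sA)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$regime == "A-form"))
  expect_true(all(abs(tab$phase_deg - c(18, 25, 40)) < 2.5))
  # empty residue list
  expect_equal(nrow(suppressWarnings(puckerTable(sA, resids = integer()))), 0)
  # exactly one R-loop residue in a mixed fixture
  sMix <- makeSugarStructure(c(18, 350, 162))
  tabM <- puckerTable(sMix)
  expect_equal(sum(tabM$regime == "R-loop"), 1)
  expect_equal(tabM$resid[tabM$regime == "R-loop"], 2)
  # a structure with no nucleic residues warns and returns empty
  tr <- makeTriPeptide()
  expect_warning(empty <- puckerTable(topology(tr)), "no nucleic")
  expect_equal(nrow(empty), 0)
})
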