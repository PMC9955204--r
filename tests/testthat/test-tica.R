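# tICA: slow-mode recovery, projection contracts, contribution
# thresholding, VAMP2 scoring.

makeAR1 <- function(n, rho, seed) {
  set.seed(seed)
  x <- numeric(n)
  innov <- rnorm(n)
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t]
  x
}

test_that("white-noise features carry no kinetic variance", {
  set.seed(1)
  F <- matrix(rnorm(1e4 * 4), ncol = 4)
  m <- estimateTICA(F, lag = 5, nDims = 2)
  expect_lt(max(abs(m@eigenvalues)), 0.1)
  expect_equal(vamp2Score(F, lag = 5, nDims = 2), 1, tolerance = 0.1)
})

test_that("a planted AR(1) mode is recovered with lambda1 = rho^lag", {
  n <- 1e4; rho <- 0.99; L <- 10
  x <- makeAR1(n, rho, seed = 5)
  set.seed(6)
  F <- cbind(x, matrix(rnorm(n * 5), n))
  m <- estimateTICA(F, lag = L, nDims = 2)
  expect_equal(m@eigenvalues[1], rho^L, tolerance = 0.02)
  # the leading component loads on the planted column
  lead <- abs(m@components[, 1])
  expect_equal(which.max(lead), 1L)
})

test_that("duplicated features leave the projected series unchanged under ridge", {
  n <- 5000
  x <- makeAR1(n, 0.95, seed = 8)
  set.seed(9)
  F <- cbind(x, matrix(rnorm(n * 2), n))
  Fdup <- cbind(F, F[, 1])
  m1 <- estimateTICA(F, lag = 5, nDims = 1, reg = 1e-6)
  m2 <- estimateTICA(Fdup, lag = 5, nDims = 1, reg = 1e-6)
  p1 <- projectTICA(m1, F)
  p2 <- projectTICA(m2, Fdup)
  # components are sign-arbitrary
  err <- min(max(abs(p1 - p2)), max(abs(p1 + p2)))
  expect_lt(err, 1e-2)
  # rank-deficient C0 without regularization errors helpfully
  expect_error(estimateTICA(Fdup, lag = 5, nDims = 1, reg = 0),
               "reg > 0")
})

test_that("projection is mean-free, reproducible and label-checked", {
  tr <- generateBackboneTrajectory(
    matrix(rnorm(60 * 4, -70, 15), 60), matrix(rnorm(60 * 4, -40, 15), 60))
  fm <- featurizeTorsions(tr)
  m <- estimateTICA(fm, lag = 2, nDims = 2)
  p1 <- projectTICA(m, fm)
  expect_identical(p1, projectTICA(m, fm))
  # mean-free with respect to the model mean (exact), hence near-zero
  # column means over the training frames
  expect_lt(max(abs(projectTICA(m, matrix(m@mean, 1)))), 1e-10)
  expect_equal(colMeans(p1), c(0, 0), tolerance = 0.05)
  # unit instantaneous variance under C0-orthonormal components
  expect_equal(apply(p1, 2, function(v) mean(v^2)), c(1, 1),
               tolerance = 0.05)
  # an all-constant feature set projects to zero (mean removal)
  constVals <- matrix(1.5, 500, 3)
  mc <- estimateTICA(constVals, lag = 2, nDims = 2, reg = 1e-6)
  expect_lt(max(abs(projectTICA(mc, constVals))), 1e-8)
  # label mismatch is reported with offending columns
  badLab <- featureLabels(fm)
  badLab$resid <- rev(badLab$resid)
  fbad <- new("FeatureMatrix", values = featureValues(fm), labels = badLab)
  expect_error(projectTICA(m, fbad), "offending")
})

test_that("feature contributions select the residues that drive slow modes", {
  # planted: two residues carry the two slow modes, others are noise
  n <- 8000
  slow <- makeAR1(n, 0.98, seed = 12)
  slow2 <- makeAR1(n, 0.9, seed = 14)
  set.seed(13)
  vals <- cbind(sin(slow), cos(slow),
                sin(slow2), cos(slow2),
                matrix(rnorm(n * 4, sd = 1), n))
  labels <- data.frame(resid = rep(c(768, 976, 10, 11), each = 2),
                       torsion = "phi",
                       part = rep(c("sin", "cos"), 4))
  fm <- new("FeatureMatrix", values = vals, labels = labels)
  m <- estimateTICA(fm, lag = 5, nDims = 2)
  sel <- featureContributions(m, threshold = 0.195)
  expect_setequal(sel$selectedResidues, c(768, 976))
  # threshold 0 selects everything
  expect_setequal(featureContributions(m, threshold = 0)$selectedResidues,
                  c(10, 11, 768, 976))
  # a one-hot loading selects only its residue at any threshold <= 1
  m1 <- m
  oneHot <- matrix(0, ncol(vals), m@nDims)
  oneHot[3, 1] <- 2; oneHot[4, 2] <- 1
  m1@components <- cbind(oneHot, m@components[, -(1:2)])[, 1:ncol(m@components)]
  expect_equal(featureContributions(m1, threshold = 1)$selectedResidues, 976)
})

test_that("VAMP2 matches the spectral identity for a two-state chain", {
  T <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  s <- simulateMarkovChain(T, 2e4, seed = 20)
  F <- cbind(as.numeric(s == 1), as.numeric(s == 2))
  lambda2 <- 0.9
  v <- vamp2Score(F, lag = 1, nDims = 2, reg = 1e-10)
  expect_equal(v, 1 + lambda2^2, tolerance = 0.03)
  # non-decreasing in nDims
  set.seed(21)
  F2 <- cbind(F, matrix(rnorm(2e4 * 2), ncol = 2))
  scores <- vapply(1:4, function(d) vamp2Score(F2, lag = 1, nDims = d),
                   numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("tICA eigenvalues are invariant under invertible reparameterization", {
  n <- 4000
  x <- makeAR1(n, 0.9, seed = 30)
  set.seed(31)
  F <- cbind(x, makeAR1(n, 0.5, seed = 32), rnorm(n))
  A <- matrix(c(2, 0.5, 0, -1, 1, 0.3, 0.2, 0, 1), 3)  # invertible
  m1 <- estimateTICA(F, lag = 4, nDims = 3, reg = 0)
  m2 <- estimateTICA(F %*% A, lag = 4, nDims = 3, reg = 0)
  expect_equal(m1@eigenvalues, m2@eigenvalues, tolerance = 1e-6)
})

test_that("one-hot featurized Markov chains give chain eigenvalues^lag", {
  T <- rbind(c(0.9, 0.08, 0.02), c(0.08, 0.9, 0.02), c(0.02, 0.02, 0.96))
  s <- simulateMarkovChain(T, 5e4, seed = 40)
  F <- vapply(1:3, function(k) as.numeric(s == k), numeric(5e4))
  evTrue <- sort(eigen(T, only.values = TRUE)$values, decreasing = TRUE)
  for (L in c(1, 3)) {
    m <- estimateTICA(F, lag = L, nDims = 2, reg = 1e-8)
    expect_equal(m@eigenvalues[1:2], evTrue[2:3]^L, tolerance = 0.05)
  }
})
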