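# Markov state model estimation and validation.

blockChainT <- function(pIn = 0.1, pOut = 1e-3) {
  T <- matrix(0, 4, 4)
  T[1, 2] <- T[2, 1] <- pIn; T[3, 4] <- T[4, 3] <- pIn
  T[1, 3] <- T[3, 1] <- pOut; T[2, 4] <- T[4, 2] <- pOut
  diag(T) <- 1 - rowSums(T)
  T
}

test_that("k-means discretization honours its contracts", {
  set.seed(1)
  X <- matrix(rnorm(200), ncol = 2)
  d1 <- kmeansDiscretize(X, k = 1, seed = 2)
  expect_equal(as.numeric(d1@centers), colMeans(X))
  # points equal to k distinct locations: zero inertia, centers = points
  P <- matrix(c(0, 0, 5, 5, -5, 5), 3, byrow = TRUE)
  dk <- kmeansDiscretize(P, k = 3, seed = 3)
  expect_equal(sort(unname(dk@centers[, 1])), sort(P[, 1]))
  expect_error(kmeansDiscretize(P, k = 4), "exceed")
  # two well-separated clouds
  set.seed(4)
  cloud <- rbind(matrix(rnorm(600, 0, 0.5), ncol = 2),
                 matrix(rnorm(600, 10, 0.5), ncol = 2))
  d2 <- kmeansDiscretize(cloud, k = 2, seed = 5)
  mu <- d2@centers[order(d2@centers[, 1]), ]
  expect_lt(max(abs(mu[1, ] - c(0, 0))), 3 * 0.5 / sqrt(300))
  expect_lt(max(abs(mu[2, ] - c(10, 10))), 3 * 0.5 / sqrt(300))
  # determinism
  expect_identical(crispAssignment(kmeansDiscretize(cloud, 2, seed = 5)),
                   crispAssignment(d2))
})

test_that("transition counting is the sliding-window hand count", {
  cm <- countMatrix(c(1, 1, 2), lag = 1)
  expect_equal(cm@counts, rbind(c(1, 1), c(0, 0)))
  cm2 <- countMatrix(rep(1, 10), lag = 1)
  expect_equal(cm2@counts, matrix(9))
  expect_warning(z <- countMatrix(c(1, 2, 1), lag = 3), "all-zero")
  expect_equal(sum(z@counts), 0)
  # multiple trajectories never count across the boundary
  cm3 <- countMatrix(list(c(1, 2), c(2, 1)), lag = 1)
  expect_equal(cm3@counts, rbind(c(0, 1), c(1, 0)))
})

test_that("MSM estimation recovers exact and simulated chains", {
  mm <- estimateMSM(new("CountMatrix", counts = rbind(c(8, 2), c(2, 8)),
                        lag = 1L))
  expect_equal(mm@transitionMatrix, rbind(c(0.8, 0.2), c(0.2, 0.8)),
               tolerance = 1e-9)
  expect_equal(mm@stationary, c(0.5, 0.5), tolerance = 1e-9)
  # diagonal counts: identity T, infinite timescales
  mdiag <- estimateMSM(new("CountMatrix", counts = diag(c(5, 0)) + diag(2) * 4,
                           lag = 1L))
  expect_equal(mdiag@transitionMatrix, matrix(1))  # connected set is 1 state
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  s <- simulateMarkovChain(T, 1e5, seed = 7)
  fit <- estimateMSM(countMatrix(s, 1))
  se <- 3 * sqrt(T * (1 - T) / rowSums(countMatrix(s, 1)@counts))
  expect_true(all(abs(fit@transitionMatrix - T) <= se + 0.002))
  # detailed balance and stationarity invariants
  P <- fit@transitionMatrix; pi <- fit@stationary
  expect_lt(max(abs(pi %*% P - pi)), 1e-8)
  expect_lt(max(abs(pi * P - t(pi * P))), 1e-8)
})

test_that("a truly diagonal count matrix yields identity T and +Inf timescales", {
  cm <- new("CountMatrix", counts = diag(c(6, 6)), lag = 1L)
  # two disconnected absorbing states: largest component is a single state
  m <- estimateMSM(cm)
  expect_equal(m@transitionMatrix, matrix(1))
  expect_true(all(!is.finite(timescales(m, 2)) | is.na(timescales(m, 2))))
})

test_that("implied timescales match closed forms and stay flat for Markov data", {
  # exact 2-state chain with lambda2 = 0.7: t = -1/ln(0.7)
  mm <- new("MarkovModel",
            transitionMatrix = rbind(c(0.85, 0.15), c(0.15, 0.85)),
            lag = 1L, stride = 1, stationary = c(0.5, 0.5),
            eigenvalues = c(1, 0.7), activeSet = 1:2, reversible = TRUE)
  expect_equal(timescales(mm, 1), -1 / log(0.7), tolerance = 1e-9)
  expect_equal(timescales(mm, 1), 2.804, tolerance = 1e-3)
  # Markovian chain: timescales flat in lag within the 95% CIs
  T <- blockChainT(0.08, 0.01)
  s <- simulateMarkovChain(T, 8e4, seed = 9)
  its <- impliedTimescales(s, lags = c(1, 2, 5, 10), nIts = 1, seed = 10)
  tTrue <- -1 / log(sort(eigen(T, only.values = TRUE)$values,
                         decreasing = TRUE)[2])
  expect_true(all(its$lower <= tTrue * 1.05 & its$upper >= tTrue * 0.95))
  spread <- diff(range(its$timescale))
  expect_lt(spread, tTrue * 0.5)
})

test_that("Bayesian posterior sampling concentrates and covers", {
  C <- rbind(c(80, 20), c(30, 70))
  ens1 <- bayesianSample(new("CountMatrix", counts = C, lag = 1L),
                         nSamples = 200, seed = 1)
  ens2 <- bayesianSample(new("CountMatrix", counts = C * 1000, lag = 1L),
                         nSamples = 200, seed = 1)
  width <- function(e) {
    v <- vapply(e@samples, function(S) S[1, 2], numeric(1))
    diff(quantile(v, c(0.025, 0.975)))
  }
  ratio <- width(ens1) / width(ens2)
  expect_gt(ratio, sqrt(1000) * 0.5)
  expect_lt(ratio, sqrt(1000) * 2)
  # one-state chain: degenerate ensemble
  e1 <- bayesianSample(new("CountMatrix", counts = matrix(9), lag = 1L),
                       nSamples = 5, seed = 2)
  expect_true(all(vapply(e1@samples, identical, TRUE, matrix(1))))
  # coverage: 95% CI for lambda2 covers the truth in most seeded reps
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  l2 <- sort(eigen(T, only.values = TRUE)$values, decreasing = TRUE)[2]
  hits <- 0
  for (r in 1:20) {
    s <- simulateMarkovChain(T, 3000, seed = 100 + r)
    ens <- bayesianSample(countMatrix(s, 1), nSamples = 100, seed = 200 + r)
    l2s <- vapply(ens@samples, function(S)
      sort(Re(eigen(S, only.values = TRUE)$values), decreasing = TRUE)[2],
      numeric(1))
    ci <- quantile(l2s, c(0.025, 0.975))
    if (l2 >= ci[1] && l2 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 16)  # ~95% nominal; allow binomial fluctuation
})

test_that("the Chapman-Kolmogorov test discriminates Markovian data", {
  T <- blockChainT(0.1, 5e-3)
  s <- simulateMarkovChain(T, 1e5, seed = 21)
  cm <- countMatrix(s, 1)
  model <- estimateMSM(cm)
  ens <- bayesianSample(cm, nSamples = 100, seed = 22)
  sets <- pcca(model, 2)
  ck <- ckTest(model, ens, s, factors = 2:5, sets = sets)
  expect_true(ck$pass)
  # exact self-consistency: the generating T predicts itself
  expect_true(all(abs(ck$table$predicted - ck$table$estimated) < 0.05))

  # non-Markovian observable: 3 hidden states lumped into 2
  Th <- rbind(c(0.98, 0.02, 0), c(0.02, 0.0, 0.98), c(0.01, 0.0, 0.99))
  Th[2, ] <- c(0.3, 0.0, 0.7)
  sh <- simulateMarkovChain(Th, 1e5, seed = 23)
  obs <- ifelse(sh == 1, 1L, 2L)
  cmO <- countMatrix(obs, 1)
  mO <- estimateMSM(cmO)
  ensO <- bayesianSample(cmO, nSamples = 100, seed = 24)
  ckO <- ckTest(mO, ensO, obs, factors = 2:5, sets = NULL)
  expect_false(ckO$pass)
})

test_that("PCCA++ recovers planted metastable blocks", {
  T <- blockChainT(0.1, 1e-3)
  s <- simulateMarkovChain(T, 5e4, seed = 31)
  model <- estimateMSM(countMatrix(s, 1))
  cg <- pcca(model, 2)
  asg <- crispAssignment(cg)
  expect_equal(asg[1], asg[2])
  expect_equal(asg[3], asg[4])
  expect_true(asg[1] != asg[3])
  expect_lt(max(abs(rowSums(memberships(cg)) - 1)), 1e-10)
  # m = 1: single macrostate
  cg1 <- pcca(model, 1)
  expect_equal(memberships(cg1), matrix(1, 4, 1))
  # block permutation gives the same partition up to relabeling
  perm <- c(3, 4, 1, 2)
  sPerm <- perm[s]
  mPerm <- estimateMSM(countMatrix(sPerm, 1))
  asgP <- crispAssignment(pcca(mPerm, 2))
  expect_equal(asgP[1], asgP[2]); expect_equal(asgP[3], asgP[4])
  expect_true(asgP[1] != asgP[3])
  # non-reversible models are rejected
  mNR <- estimateMSM(countMatrix(s, 1), reversible = FALSE)
  expect_error(pcca(mNR, 2), "reversible")
})

test_that("macrostate MFPTs solve the first-step equations", {
  mm <- new("MarkovModel",
            transitionMatrix = rbind(c(0.9, 0.1), c(0.2, 0.8)),
            lag = 1L, stride = 1, stationary = c(2 / 3, 1 / 3),
            eigenvalues = c(1, 0.7), activeSet = 1:2, reversible = TRUE)
  g <- new("CoarseGraining", memberships = diag(2), assignment = 1:2, m = 2L)
  tt <- macrostateTransitionTimes(mm, g)
  expect_equal(tt$mfpt[1, 2], 10, tolerance = 1e-9)
  expect_equal(tt$mfpt[2, 1], 5, tolerance = 1e-9)
  expect_equal(tt$rates[1, 2], 0.1, tolerance = 1e-9)
  expect_equal(diag(tt$mfpt), c(0, 0))  # source inside target set
})

test_that("MFPT linear solve equals value-iteration on small random chains", {
  set.seed(41)
  for (rep in 1:6) {
    k <- sample(3:6, 1)
    C <- matrix(rpois(k * k, 5) + 1, k)
    model <- estimateMSM(new("CountMatrix", counts = C, lag = 1L))
    m <- 2
    asg <- as.integer(c(rep(1, ceiling(k / 2)), rep(2, floor(k / 2))))
    chi <- matrix(0, k, m); chi[cbind(seq_len(k), asg)] <- 1
    g <- new("CoarseGraining", memberships = chi, assignment = asg, m = 2L)
    tt <- macrostateTransitionTimes(model, g)
    T <- model@transitionMatrix; pi <- model@stationary
    for (i in 1:2) for (j in 1:2) {
      if (i == j) next
      oracle <- mfptOracle(T, pi, which(asg == i), which(asg == j))
      expect_equal(tt$mfpt[i, j], oracle, tolerance = 1e-8)
    }
  }
})

test_that("free-energy surfaces follow -ln(weight) with min zero", {
  # two occupied bins at 0.73 / 0.27: dF = ln(0.73/0.27)
  proj <- rbind(c(0.5, 0.5), c(1.5, 0.5))
  fes <- freeEnergySurface(proj, weights = c(0.73, 0.27),
                           nbins = list(c(0, 1, 2), c(0, 1)))
  vals <- fes@F[!is.na(fes@F)]
  expect_equal(max(vals) - min(vals), log(0.73 / 0.27), tolerance = 1e-9)
  expect_equal(max(vals) - min(vals), 0.994, tolerance = 1e-3)
  expect_equal(min(vals), 0)
  # equal weights: dF = 0; single occupied bin: F = 0 there
  fes2 <- freeEnergySurface(proj, weights = c(0.5, 0.5),
                            nbins = list(c(0, 1, 2), c(0, 1)))
  v2 <- fes2@F[!is.na(fes2@F)]
  expect_equal(v2, c(0, 0))
  fes3 <- freeEnergySurface(rbind(c(0.5, 0.5)), weights = 1,
                            nbins = list(c(0, 1), c(0, 1)))
  expect_equal(fes3@F[1, 1], 0)
  expect_error(freeEnergySurface(matrix(0, 0, 2)), "empty")
})

test_that("stationary frame weights reweight to the model equilibrium", {
  T <- rbind(c(0.99, 0.01), c(0.04, 0.96))  # pi = (0.8, 0.2)
  s <- simulateMarkovChain(T, 2e4, seed = 55)
  model <- estimateMSM(countMatrix(s, 1))
  w <- stationaryFrameWeights(model, s)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w[s == 1]), model@stationary[1], tolerance = 1e-9)
})

test_that("end-to-end recovery: chain -> one-hot -> kmeans -> MSM -> PCCA", {
  T <- blockChainT(0.1, 2e-3)
  s <- simulateMarkovChain(T, 4e4, seed = 61)
  onehot <- vapply(1:4, function(k) as.numeric(s == k), numeric(length(s)))
  # jitter breaks ties so kmeans can separate the four corners
  set.seed(62)
  pts <- onehot + matrix(rnorm(length(onehot), sd = 0.01), nrow(onehot))
  disc <- kmeansDiscretize(pts, k = 4, seed = 63)
  asg <- crispAssignment(disc)[[1]]
  model <- estimateMSM(countMatrix(asg, 1))
  evTrue <- sort(eigen(T, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(sort(model@eigenvalues, decreasing = TRUE), evTrue,
               tolerance = 0.02)
  cg <- pcca(model, 2)
  # recover which kmeans microstate holds which chain state
  stateOfMicro <- vapply(1:4, function(m2)
    as.integer(names(which.max(table(s[asg == m2])))), integer(1))
  macro <- crispAssignment(cg)
  expect_equal(macro[stateOfMicro[1]], macro[stateOfMicro[2]])
  expect_equal(macro[stateOfMicro[3]], macro[stateOfMicro[4]])
  expect_true(macro[stateOfMicro[1]] != macro[stateOfMicro[3]])
})
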