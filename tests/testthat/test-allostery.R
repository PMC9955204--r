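# Residue coupling, graph construction, shortest pathways.

test_that("coupling matrix reproduces designed displacement correlations", {
  # identical translation every frame, alignment disabled: C = 1
  base <- cbind(3.8 * (0:2), 0, 0)
  frames <- lapply(seq_len(50), function(f) sweep(base, 2, c(0, rnorm(1), 0), "+"))
  topo <- new("Structure", atoms = data.frame(
    name = "CA", resid = 1:3, resname = "ALA", chain = "A",
    x = base[, 1], y = base[, 2], z = base[, 3], stringsAsFactors = FALSE))
  tr <- new("TrajectoryEnsemble", topology = topo, frames = frames,
            frameStride = 1)
  C <- couplingMatrix(tr, align = FALSE)
  expect_equal(unname(couplings(C)[1, 2]), 1, tolerance = 1e-12)
  # exactly opposite displacements: C = -1
  fr2 <- lapply(seq_len(50), function(f) {
    d <- rnorm(1); m <- base; m[1, 2] <- d; m[2, 2] <- -d; m
  })
  tr2 <- new("TrajectoryEnsemble", topology = topo, frames = fr2,
             frameStride = 1)
  C2 <- couplingMatrix(tr2, align = FALSE)
  expect_equal(unname(couplings(C2)[1, 2]), -1, tolerance = 1e-12)
  # immobile residue flagged undefined
  expect_true(C2@undefined[3])
  # symmetric, unit diagonal on generic input
  S <- diag(4); S[1, 2] <- S[2, 1] <- 0.6
  tr3 <- generateChainTrajectory(4, S, nFrames = 400, seed = 1)
  C3 <- couplings(couplingMatrix(tr3))
  expect_equal(C3, t(C3))
  expect_equal(unname(diag(C3)), rep(1, 4))
})

test_that("block-covariance chains yield the prescribed correlations", {
  n <- 4000
  S <- diag(6)
  S[1, 2] <- S[2, 1] <- 0.8
  S[5, 6] <- S[6, 5] <- -0.5
  tr <- generateChainTrajectory(6, S, nFrames = n, seed = 2)
  C <- couplings(couplingMatrix(tr, align = FALSE))
  expect_equal(unname(C[1, 2]), 0.8, tolerance = 3 / sqrt(n) * 3)
  expect_equal(unname(C[5, 6]), -0.5, tolerance = 3 / sqrt(n) * 3)
  expect_lt(abs(C[1, 5]), 3 / sqrt(n))
})

test_that("alternating node coarse-graining partitions the 767-984 region", {
  cg <- coarseGrainNodes(767:984)
  expect_length(cg$subsets$offset0, 109)
  expect_length(cg$subsets$offset1, 109)
  expect_setequal(c(cg$subsets$offset0, cg$subsets$offset1), 767:984)
  expect_length(intersect(cg$subsets$offset0, cg$subsets$offset1), 0)
  cg2 <- coarseGrainNodes(c(5, 9))
  expect_equal(cg2$subsets$offset0, 5)
  expect_equal(cg2$subsets$offset1, 9)
})

test_that("graph edges respect the distance gate and -ln|C| weights", {
  res <- 1:4
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 1
  C[1, 3] <- C[3, 1] <- 0.5
  C[2, 3] <- C[3, 2] <- -0.25
  C[1, 4] <- C[4, 1] <- 0.9
  cm <- new("CouplingMatrix", residues = as.integer(res),
            correlations = C, undefined = rep(FALSE, 4))
  D <- matrix(5, 4, 4); diag(D) <- 0
  D[1, 4] <- D[4, 1] <- 50  # beyond cutoff
  g <- buildGraph(cm, D, cutoff = 12)
  e <- graphEdges(g)
  expect_false(any(e$resI == 1 & e$resJ == 4))
  expect_equal(e$weight[e$resI == 1 & e$resJ == 2], 0)
  expect_equal(e$weight[e$resI == 2 & e$resJ == 3], -log(0.25))
  expect_equal(e$weight, -log(abs(e$coupling)), tolerance = 1e-12)
  # all distances beyond the cutoff: empty edge set
  gEmpty <- buildGraph(cm, D + 100, cutoff = 12)
  expect_equal(nrow(graphEdges(gEmpty)), 0)
})

test_that("Dijkstra equals exhaustive enumeration on small random graphs", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    C <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.6) C[i, j] <- C[j, i] <- runif(1, 0.05, 0.999)
    }
    cm <- new("CouplingMatrix", residues = as.integer(1:n),
              correlations = C, undefined = rep(FALSE, n))
    D <- matrix(5, n, n); diag(D) <- 0
    g <- buildGraph(cm, D, cutoff = 12, minAbsCoupling = 0.01)
    e <- graphEdges(g)
    got <- shortestPath(g, 1, n)
    oracle <- bruteForcePath(e, 1, n)
    if (!got$found) {
      expect_equal(oracle$weight, Inf)
    } else {
      expect_equal(got$totalWeight, oracle$weight, tolerance = 1e-12)
      expect_equal(sum(got$edgeWeights), got$totalWeight, tolerance = 1e-12)
      # removing an on-path edge strictly increases (or disconnects)
      kill <- which((e$resI == got$path[1] & e$resJ == got$path[2]) |
                    (e$resJ == got$path[1] & e$resI == got$path[2]))
      g2 <- g; g2@edges <- e[-kill, , drop = FALSE]
      got2 <- shortestPath(g2, 1, n)
      expect_true(!got2$found || got2$totalWeight >= got$totalWeight - 1e-12)
    }
  }
})

test_that("zero-weight direct edges and disconnected pairs behave", {
  C <- diag(2); C[1, 2] <- C[2, 1] <- 1
  cm <- new("CouplingMatrix", residues = c(10L, 20L),
            correlations = C, undefined = c(FALSE, FALSE))
  D <- matrix(c(0, 5, 5, 0), 2)
  g <- buildGraph(cm, D)
  p <- shortestPath(g, 10, 20)
  expect_equal(p$path, c(10, 20))
  expect_equal(p$totalWeight, 0)
  gE <- buildGraph(cm, D + 100)
  pE <- shortestPath(gE, 10, 20)
  expect_false(pE$found)
  expect_equal(pE$totalWeight, Inf)
  expect_error(shortestPath(g, 10, 99), "nodes")
})

test_that("intra-block pathways avoid the weakly coupled block", {
  n <- 3000
  S <- diag(6)
  # block {1,2,3} strongly coupled; block {4,5,6} strongly coupled;
  # inter-block couplings weak
  for (i in 1:2) for (j in (i + 1):3) S[i, j] <- S[j, i] <- 0.7
  for (i in 4:5) for (j in (i + 1):6) S[i, j] <- S[j, i] <- 0.7
  S <- S + diag(0.5, 6)
  tr <- generateChainTrajectory(6, S, nFrames = n, seed = 9,
                                baseCoordinates = cbind(2 * (0:5), 0, 0))
  C <- couplingMatrix(tr, align = FALSE)
  D <- meanDistanceMatrix(tr)
  g <- buildGraph(C, D, cutoff = 50, minAbsCoupling = 0.01)
  p <- shortestPath(g, 1, 3)
  expect_true(all(p$path %in% 1:3))
})
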