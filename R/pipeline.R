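## End-to-end orchestration from a YAML config: featurize -> tICA ->
## discretize -> MSM (+ implied timescales, CK test, Bayesian ensemble) ->
## PCCA++ -> macrostate association -> allostery -> markers -> pucker
## table. Stage failures are recorded and later independent stages still
## run; all stochastic stages consume named seeds so two runs with the
## same config are numerically identical.

#' Read a pipeline configuration
#'
#' @param path YAML file.
#' @return named list (unvalidated); see \code{\link{validateConfig}}.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

.cfgDefaults <- list(
  frame_stride_ns = 1,
  tica = list(lag_frames = 50, n_dims = 4, threshold = 0.195),
  msm = list(lag_frames = 50, n_clusters = 100, n_macrostates = 4,
             n_bayes_samples = 100, seed = 42),
  allostery = list(cutoff_A = 12, report_threshold = 0.6,
                   source = 768, target = 976),
  markers = list(enabled = TRUE),
  pucker = list(enabled = TRUE))

.mergeCfg <- function(defaults, cfg) {
  for (k in names(cfg)) {
    defaults[[k]] <- if (is.list(cfg[[k]]) && is.list(defaults[[k]]))
      .mergeCfg(defaults[[k]], cfg[[k]]) else cfg[[k]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Fills defaults, checks cross-field constraints (positive counts,
#' existing input files, lag versus trajectory length where known) and
#' derives the replica bookkeeping: cumulative enhanced-sampling time in
#' microseconds is n_conditions * n_replicas * ns_per_replica / 1000.
#'
#' @param config named list (e.g. from \code{\link{readConfig}}).
#' @return the validated config with a \code{derived} element.
#' @export
validateConfig <- function(config) {
  cfg <- .mergeCfg(.cfgDefaults, config)
  chk <- function(ok, key, why)
    if (!ok) stop("config key '", key, "': ", why)
  chk(cfg$frame_stride_ns > 0, "frame_stride_ns", "must be positive")
  chk(cfg$tica$lag_frames >= 1, "tica.lag_frames", "must be >= 1")
  chk(cfg$tica$n_dims >= 1, "tica.n_dims", "must be >= 1")
  chk(cfg$msm$lag_frames >= 1, "msm.lag_frames", "must be >= 1")
  chk(cfg$msm$n_clusters >= 2, "msm.n_clusters", "must be >= 2")
  chk(cfg$msm$n_macrostates >= 1, "msm.n_macrostates", "must be >= 1")
  chk(cfg$allostery$cutoff_A > 0, "allostery.cutoff_A", "must be positive")
  for (key in c("topology", "trajectories")) {
    if (!is.null(cfg[[key]])) {
      for (p in cfg[[key]])
        chk(file.exists(p), key, paste("file not found:", p))
    }
  }
  derived <- list()
  rb <- cfg$replica_bookkeeping
  if (!is.null(rb)) {
    for (key in c("n_conditions", "n_replicas", "ns_per_replica"))
      chk(!is.null(rb[[key]]) && rb[[key]] > 0,
          paste0("replica_bookkeeping.", key), "must be positive")
    derived$cumulative_time_us <-
      rb$n_conditions * rb$n_replicas * rb$ns_per_replica / 1000
  }
  if (!is.null(cfg$equilibrium_trajectories_ns))
    derived$cumulative_equilibrium_us <-
      sum(cfg$equilibrium_trajectories_ns) / 1000
  cfg$derived <- derived
  cfg
}

.stage <- function(report, name, expr) {
  res <- tryCatch(list(status = "ok", value = expr),
                  error = function(e) list(status = "failed",
                                           value = conditionMessage(e)))
  report$stages[[name]] <- res$status
  if (res$status == "failed")
    message("stage ", name, " failed: ", res$value)
  report$results[[name]] <- res$value
  report
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on the configured inputs and writes TSV
#' outputs under \code{outDir}. Any stage failure is recorded in the
#' report and later independent stages are still attempted. Fully
#' deterministic given the config's seeds.
#'
#' @param config validated config list, or a YAML path.
#' @param outDir output directory (created).
#' @return a run-report list: per-stage status, output paths and headline
#'   numbers (timescales, macrostate count, MFPT table, pathway, domain
#'   composition of selected residues).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), results = list(), outputs = character(),
                 config = cfg)
  outPaths <- character()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeTSV(df, p)
    outPaths <<- c(outPaths, p)
  }

  topo <- readStructure(cfg$topology)
  traj <- readTrajectory(cfg$trajectories, topo,
                         frameStride = cfg$frame_stride_ns)
  stride <- cfg$frame_stride_ns
  seed <- as.integer(cfg$msm$seed)

  report <- .stage(report, "featurize", {
    featurizeTorsions(traj, residRange = cfg$tica$resid_range)
  })
  feats <- report$results$featurize

  report <- .stage(report, "tica", {
    m <- estimateTICA(feats, lag = cfg$tica$lag_frames,
                      nDims = cfg$tica$n_dims)
    contrib <- featureContributions(m, threshold = cfg$tica$threshold)
    emit(data.frame(resid = names(contrib$residueScores),
                    score = as.numeric(contrib$residueScores)),
         "tica_residue_scores.tsv")
    list(model = m, contributions = contrib,
         projection = projectTICA(m, feats))
  })
  proj <- report$results$tica$projection

  report <- .stage(report, "discretize", {
    kmeansDiscretize(proj, k = cfg$msm$n_clusters,
                     seed = childSeed(seed, "kmeans"))
  })
  disc <- report$results$discretize

  report <- .stage(report, "msm", {
    asg <- crispAssignment(disc)
    cm <- countMatrix(asg, cfg$msm$lag_frames, nStates = disc@k)
    model <- estimateMSM(cm, stride = stride)
    ens <- bayesianSample(cm, nSamples = cfg$msm$n_bayes_samples,
                          seed = childSeed(seed, "bayes"), stride = stride)
    lags <- unique(pmax(1, round(cfg$msm$lag_frames * c(0.2, 0.5, 1, 2))))
    its <- impliedTimescales(asg, lags, stride = stride,
                             seed = childSeed(seed, "its"))
    emit(its, "implied_timescales.tsv")
    ck <- ckTest(model, ens, asg, factors = 2:3,
                 sets = pcca(model, m = cfg$msm$n_macrostates))
    emit(ck$table, "ck_test.tsv")
    list(counts = cm, model = model, ensemble = ens, its = its, ck = ck)
  })
  model <- report$results$msm$model

  report <- .stage(report, "pcca", {
    grouping <- pcca(model, m = cfg$msm$n_macrostates)
    mfpt <- macrostateTransitionTimes(model, grouping)
    mf <- as.data.frame(mfpt$mfpt)
    names(mf) <- paste0("to_S", seq_len(ncol(mf)))
    mf <- cbind(from = paste0("S", seq_len(nrow(mf))), mf)
    emit(mf, "macrostate_mfpt_ns.tsv")
    w <- stationaryFrameWeights(model, crispAssignment(disc))
    fes <- freeEnergySurface(proj[, 1:2, drop = FALSE], weights = w,
                             nbins = 25)
    grid <- expand.grid(ix = seq_len(nrow(fes@F)), iy = seq_len(ncol(fes@F)))
    emit(data.frame(
      bin_x = (fes@xEdges[grid$ix] + fes@xEdges[grid$ix + 1]) / 2,
      bin_y = (fes@yEdges[grid$iy] + fes@yEdges[grid$iy + 1]) / 2,
      F_kT = fes@F[cbind(grid$ix, grid$iy)]), "fes_kT.tsv")
    list(grouping = grouping, mfpt = mfpt, fes = fes)
  })

  report <- .stage(report, "associate", {
    grouping <- report$results$pcca$grouping
    # cluster a strided frame subset: full-scaffold pairwise RMSD is
    # quadratic in frames
    nSub <- min(60, nFrames(traj))
    subIdx <- unique(round(seq(1, nFrames(traj), length.out = nSub)))
    subTraj <- new("TrajectoryEnsemble", topology = topology(traj),
                   frames = frames(traj)[subIdx],
                   frameStride = frameStride(traj))
    clustering <- clusterStructures(
      subTraj, nNeighbors = min(10, nFrames(subTraj) - 1), minShared = 3)
    reps <- macrostateRepresentatives(traj, crispAssignment(disc),
                                      model, grouping)
    assoc <- associateMacrostates(
      reps, clustering,
      subset = selectAtoms(topology(traj), "backbone"),
      sourceLabel = if (!is.null(cfg$label)) cfg$label else "trajectory")
    emit(assoc, "macrostate_association.tsv")
    assoc
  })

  report <- .stage(report, "allostery", {
    resRange <- cfg$allostery$resid_range
    a <- atoms(topo)
    res <- sort(unique(a$resid[a$name == "CA"]))
    if (!is.null(resRange))
      res <- res[res >= resRange[1] & res <= resRange[2]]
    nSub <- min(500, nFrames(traj))
    subIdx <- unique(round(seq(1, nFrames(traj), length.out = nSub)))
    subTraj <- new("TrajectoryEnsemble", topology = topology(traj),
                   frames = frames(traj)[subIdx],
                   frameStride = frameStride(traj))
    C <- couplingMatrix(subTraj, residues = res)
    D <- meanDistanceMatrix(subTraj, residues = res)
    g <- buildGraph(C, D, cutoff = cfg$allostery$cutoff_A,
                    reportThreshold = cfg$allostery$report_threshold)
    emit(graphEdges(g), "allostery_edges.tsv")
    src <- cfg$allostery$source; tgt <- cfg$allostery$target
    path <- if (src %in% g@nodes && tgt %in% g@nodes)
      shortestPath(g, src, tgt)
    else list(found = FALSE, path = integer(), totalWeight = Inf)
    if (path$found)
      emit(data.frame(step = seq_along(path$path), resid = path$path),
           "allosteric_pathway.tsv")
    list(graph = g, path = path)
  })

  if (isTRUE(cfg$markers$enabled)) {
    report <- .stage(report, "markers", {
      out <- list()
      for (mk in builtinMarkers()) {
        s <- markerSeries(traj, mk)
        if (is.null(s)) next
        out[[mk$label]] <- s
      }
      if (length(out)) {
        df <- do.call(rbind, lapply(names(out), function(l)
          data.frame(marker = l, frame = seq_along(out[[l]]),
                     distance_A = out[[l]])))
        emit(df, "marker_distances.tsv")
      }
      out
    })
  }

  if (isTRUE(cfg$pucker$enabled)) {
    report <- .stage(report, "pucker", {
      tab <- puckerTable(traj)
      if (nrow(tab)) emit(tab, "pucker_table.tsv")
      tab
    })
  }

  report$headline <- list(
    timescales_ns = tryCatch(timescales(model), error = function(e) NULL),
    n_macrostates = tryCatch(report$results$pcca$grouping@m,
                             error = function(e) NULL),
    mfpt_ns = tryCatch(report$results$pcca$mfpt$mfpt,
                       error = function(e) NULL),
    pathway = tryCatch(report$results$allostery$path$path,
                       error = function(e) NULL),
    selected_residues =
      tryCatch(report$results$tica$contributions$selectedResidues,
               error = function(e) NULL))
  report$outputs <- outPaths
  report
}

#' Write the shipped synthetic demonstration inputs
#'
#' Generates the end-to-end demo: a hidden four-state Markov chain (two
#' weakly coupled two-state blocks) drives the phi/psi torsions of a small
#' backbone peptide between four basins; the trajectory is written as
#' multi-model PDB together with a matching YAML config, so the full
#' pipeline can be exercised with known ground truth (four macrostates,
#' block structure).
#'
#' @param dir directory to create the inputs in.
#' @param nFrames trajectory length (default 3000).
#' @param seed integer RNG seed.
#' @return the config path, invisibly.
#' @export
makeDemoInputs <- function(dir, nFrames = 3000, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nRes <- 6
  # two weakly coupled blocks {1,2} and {3,4}
  pIn <- 0.02; pOut <- 0.005
  T <- matrix(0, 4, 4)
  T[1, 2] <- T[2, 1] <- pIn; T[3, 4] <- T[4, 3] <- pIn
  T[1, 3] <- T[3, 1] <- pOut; T[2, 4] <- T[4, 2] <- pOut
  diag(T) <- 1 - rowSums(T)
  states <- simulateMarkovChain(T, nFrames, initialState = 1L,
                                seed = childSeed(seed, "demo-chain"))
  # four well-separated (phi, psi) basins for the two central residues
  basins <- rbind(c(-140, 150), c(-70, -40), c(60, 60), c(-150, -60))
  set.seed(childSeed(seed, "demo-noise"))
  phi <- matrix(rnorm(nFrames * nRes, -100, 6), nFrames, nRes)
  psi <- matrix(rnorm(nFrames * nRes, 130, 6), nFrames, nRes)
  for (rr in 3:4) {
    phi[, rr] <- basins[states, 1] + rnorm(nFrames, 0, 8)
    psi[, rr] <- basins[states, 2] + rnorm(nFrames, 0, 8)
  }
  traj <- generateBackboneTrajectory(phi, psi, frameStride = 1)
  trajPath <- file.path(dir, "demo_trajectory.pdb")
  writePDB(traj, trajPath)
  topoPath <- file.path(dir, "demo_topology.pdb")
  writePDB(topology(traj), topoPath)
  cfg <- list(
    label = "synthetic-demo",
    topology = topoPath,
    trajectories = list(trajPath),
    frame_stride_ns = 1,
    tica = list(lag_frames = 5, n_dims = 3, threshold = 0.195,
                resid_range = c(1, nRes)),
    msm = list(lag_frames = 5, n_clusters = 12, n_macrostates = 4,
               n_bayes_samples = 30, seed = seed),
    allostery = list(cutoff_A = 12, report_threshold = 0.6,
                     source = 2, target = 5),
    markers = list(enabled = FALSE),
    pucker = list(enabled = FALSE),
    replica_bookkeeping = list(n_conditions = 2, n_replicas = 16,
                               ns_per_replica = 100))
  cfgPath <- file.path(dir, "demo_config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  invisible(cfgPath)
}
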