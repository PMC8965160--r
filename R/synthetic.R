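## synthetic_data module: ground-truth chains, trajectory emission, adaptive
## sampling, and dihedral ensembles with a planted coupling chain.

#' Build a ground-truth hidden-state chain
#'
#' Constructs a [GroundTruthSystem-class]: a row-stochastic chain over hidden
#' metastable states with a diagonal-covariance Gaussian emission model per
#' state. Presets:
#'
#' * `"two_state"`: symmetric two-state chain with escape probability 0.1 per
#'   frame and one emitted coordinate.
#' * `"double_well_1d"`: two basins on a 1-D reaction coordinate with a
#'   configured basin free-energy gap (`basinGap`, kcal/mol, default 1.0 at
#'   300 K) encoded exactly in the stationary distribution via detailed
#'   balance.
#' * `"binding_landscape"`: six states of a ligand-binding landscape --
#'   unbound, entry, two antagonist-like poses, and two agonist-like poses
#'   distinguished by the sign of the ligand alkyl-chain dihedral -- emitting
#'   four features: binding distance (A), chain dihedral (deg), toggle-switch
#'   chi2-like angle (deg) and a TM3-TM6-like distance (A). The topology
#'   forces passage unbound -> entry -> antagonist poses -> agonist poses.
#' * `"bottleneck_chain"`: a six-state linear chain with forward probability
#'   0.02 and backward 0.15 per frame, emitting one coordinate; used to study
#'   adaptive sampling on landscapes biased against forward progress.
#' * `"custom"`: supply `Ttrue`, `emissionMeans`, `emissionSds`,
#'   `featureNames`, and optionally `macrostates` and `frameDt` explicitly.
#'
#' The stationary distribution is always computed from the transition matrix;
#' presets promise ergodicity and reducible chains are rejected.
#'
#' @param scenario preset name or "custom".
#' @param seed integer seed recorded with the system (presets are
#'   deterministic given the seed).
#' @param basinGap free-energy gap (kcal/mol) between the wells of
#'   "double_well_1d".
#' @param Ttrue,emissionMeans,emissionSds,featureNames,macrostates,frameDt
#'   explicit specification for "custom".
#' @return a validated [GroundTruthSystem-class].
#' @export
buildGroundTruthChain <- function(scenario, seed = 1L, basinGap = 1.0,
                                  Ttrue = NULL, emissionMeans = NULL,
                                  emissionSds = NULL, featureNames = NULL,
                                  macrostates = list(), frameDt = 1.0) {
  if (scenario == "two_state") {
    T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
    mu <- matrix(c(-1, 1), 2, 1)
    sdm <- matrix(0.25, 2, 1)
    fn <- "x"
    macro <- list(A = 1L, B = 2L)
    params <- list(escape = 0.1)
  } else if (scenario == "double_well_1d") {
    temperature <- 300
    ratio <- exp(-basinGap / (.kB * temperature))  # pi2 / pi1
    p1 <- 1 / (1 + ratio); p2 <- ratio / (1 + ratio)
    cte <- 0.05                                     # base exchange rate per frame
    T <- matrix(c(1 - cte * p2, cte * p2,
                  cte * p1, 1 - cte * p1), 2, 2, byrow = TRUE)
    mu <- matrix(c(-1, 1), 2, 1)
    sdm <- matrix(0.18, 2, 1)
    fn <- "reaction_coordinate"
    macro <- list(left = 1L, right = 2L)
    params <- list(basinGap = basinGap, temperature = temperature)
  } else if (scenario == "binding_landscape") {
    T <- matrix(0, 6, 6)
    T[1, 2] <- 0.03
    T[2, 1] <- 0.05; T[2, 3] <- 0.05
    T[3, 2] <- 0.02; T[3, 4] <- 0.04
    T[4, 3] <- 0.03; T[4, 5] <- 0.02; T[4, 6] <- 0.01
    T[5, 4] <- 0.01; T[5, 6] <- 0.05
    T[6, 4] <- 0.01; T[6, 5] <- 0.04
    diag(T) <- 1 - rowSums(T)
    ## binding distance (A), chain dihedral (deg), toggle chi2 (deg),
    ## TM3-TM6 distance (A); loosely: unbound far/inactive, agonist poses
    ## close with rotated toggle and larger TM3-TM6 separation.
    mu <- rbind(
      c(25,    0, 90,  8.0),   # unbound
      c(21,    0, 90,  8.0),   # entry
      c(19, -120, 90,  8.0),   # antagonist-like pose 1 (chain toward Na+ site)
      c(15,  -40, 90,  8.0),   # antagonist-like pose 2 (chain toward agonist site)
      c(10,   90,  0, 10.5),   # agonist-like, dihedral +
      c(10,  -90,  0, 10.5)    # agonist-like, dihedral -
    )
    sdm <- matrix(rep(c(0.5, 15, 15, 0.4), each = 6), 6, 4)
    fn <- c("binding_distance", "chain_dihedral", "toggle_chi2", "tm3_tm6_distance")
    macro <- list(unbound = 1L, antagonist = c(3L, 4L), agonist = c(5L, 6L))
    params <- list()
  } else if (scenario == "bottleneck_chain") {
    n <- 6
    T <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (i < n) T[i, i + 1] <- 0.02
      if (i > 1) T[i, i - 1] <- 0.15
    }
    diag(T) <- 1 - rowSums(T)
    mu <- matrix(3 * (seq_len(n) - 1), n, 1)
    sdm <- matrix(0.4, n, 1)
    fn <- "position"
    macro <- list(unbound = 1L)
    params <- list(forward = 0.02, backward = 0.15)
  } else if (scenario == "custom") {
    if (is.null(Ttrue) || is.null(emissionMeans) || is.null(emissionSds))
      stop("custom scenario requires Ttrue, emissionMeans and emissionSds")
    T <- Ttrue
    mu <- as.matrix(emissionMeans)
    sdm <- as.matrix(emissionSds)
    fn <- if (is.null(featureNames)) paste0("f", seq_len(ncol(mu))) else featureNames
    macro <- macrostates
    params <- list()
  } else {
    stop("unknown scenario: ", scenario)
  }
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-12))
    stop("transition matrix must be row-stochastic")
  if (scenario != "custom" && length(largestSCC(matrix(as.numeric(T > 0), nrow(T)))) != nrow(T))
    stop("preset chain must be irreducible")
  pi <- statDist(T)
  new("GroundTruthSystem",
      nStates = nrow(T), Ttrue = T, piTrue = pi,
      emissionMeans = mu, emissionSds = sdm, featureNames = fn,
      macrostateLabels = lapply(macro, as.integer),
      frameDt = frameDt, scenario = scenario,
      params = c(params, list(seed = as.integer(seed))))
}

#' Random metastable ergodic chain
#'
#' Generates a random ergodic chain with two long-lived basin states (the
#' first and last index) connected through fast, low-population transit
#' states; the regime Markov state models are built for. Used as a test bed
#' for transition-path-theory kinetics against brute-force simulation.
#'
#' @param nStates total states (>= 3).
#' @param seed integer seed.
#' @param basinSelf self-transition probability of the two basin states.
#' @param transitSelf self-transition probability of transit states.
#' @param basinPull probability mass a transit state sends directly into the
#'   two basins (split at random); the rest is spread over other transit
#'   states. High values give fast-relaxing barrier states, the regime where
#'   transit states carry negligible stationary population.
#' @return a [GroundTruthSystem-class] with macrostates `A` (first state) and
#'   `B` (last state) and a single emitted coordinate.
#' @export
randomErgodicChain <- function(nStates, seed = 1L, basinSelf = 0.99,
                               transitSelf = 0.05, basinPull = 0.8) {
  stopifnot(nStates >= 3)
  withSeed(deriveSeed(seed, 11L), {
    n <- nStates
    T <- matrix(0, n, n)
    transit <- 2:(n - 1)
    for (b in c(1L, n)) {
      w <- runif(length(transit)) + 0.2
      T[b, transit] <- (1 - basinSelf) * w / sum(w)
      T[b, b] <- basinSelf
    }
    for (i in transit) {
      wB <- runif(2) + 0.2
      T[i, c(1L, n)] <- basinPull * wB / sum(wB)
      otherTransit <- setdiff(transit, i)
      if (length(otherTransit)) {
        w <- runif(length(otherTransit)) + 0.2
        T[i, otherTransit] <- (1 - transitSelf - basinPull) * w / sum(w)
      } else {
        T[i, c(1L, n)] <- (basinPull + (1 - transitSelf - basinPull)) * wB / sum(wB)
      }
      T[i, i] <- transitSelf
    }
    buildGroundTruthChain("custom", seed = seed, Ttrue = T,
                          emissionMeans = matrix(seq_len(n), n, 1),
                          emissionSds = matrix(0.1, n, 1),
                          featureNames = "coordinate",
                          macrostates = list(A = 1L, B = as.integer(n)))
  })
}

#' Sample a feature trajectory from a ground-truth system
#'
#' Draws a hidden state path from the system's transition matrix and emits
#' each frame's features from that state's Gaussian emission model.
#' Bit-reproducible given the seed.
#'
#' @param system a [GroundTruthSystem-class].
#' @param nSteps number of frames (>= 2).
#' @param startState starting hidden state.
#' @param seed integer seed.
#' @param trajectoryId identifier (default derived from the seed).
#' @return a [FeatureTrajectory-class] carrying the hidden state path.
#' @export
sampleChainTrajectory <- function(system, nSteps, startState = 1L, seed = 1L,
                                  trajectoryId = sprintf("traj_seed%d", seed)) {
  stopifnot(nSteps >= 2)
  if (startState < 1 || startState > system@nStates)
    stop("invalid start state: ", startState)
  withSeed(deriveSeed(seed, 0L), {
    s <- sampleStatePath(system@Ttrue, nSteps, startState)
    Fn <- length(system@featureNames)
    noise <- matrix(rnorm(nSteps * Fn), nSteps, Fn)
    X <- system@emissionMeans[s, , drop = FALSE] +
      noise * system@emissionSds[s, , drop = FALSE]
    colnames(X) <- system@featureNames
    new("FeatureTrajectory", trajectoryId = trajectoryId,
        frameDt = system@frameDt, X = X,
        featureNames = system@featureNames, hiddenStates = as.integer(s))
  })
}

## Assign each of nRestarts to a cluster, favouring the least-populated
## clusters; ties in counts are broken uniformly at random under the caller's
## RNG state. Returns cluster indices of length nRestarts.
leastCountRestarts <- function(counts, nRestarts) {
  K <- length(counts)
  ord <- order(counts, runif(K))   # ascending counts, random tie-break
  ord[((seq_len(nRestarts) - 1L) %% K) + 1L]
}

#' Least-counts adaptive sampling
#'
#' Emulates adaptive restarting of short simulations: round 1 starts every
#' trajectory from the system's unbound state; each later round pools all
#' frames sampled so far, clusters them with k-means on the emitted features,
#' counts frames per cluster, and restarts the next batch of trajectories
#' from randomly chosen frames of the least-populated clusters (ties broken
#' uniformly at random under the run seed).
#'
#' @param system a [GroundTruthSystem-class]; its `unbound` macrostate (or
#'   state 1) seeds round 1.
#' @param nRounds,trajsPerRound,stepsPerTraj sampling budget (all positive).
#' @param nClusters k-means cluster count for the restart policy.
#' @param seed integer seed.
#' @return list of [FeatureTrajectory-class] with round/trajectory annotations
#'   in their ids.
#' @export
runAdaptiveSampling <- function(system, nRounds, trajsPerRound, stepsPerTraj,
                                nClusters, seed = 1L) {
  stopifnot(nRounds >= 1, trajsPerRound >= 1, stepsPerTraj >= 2, nClusters >= 1)
  unbound <- if (!is.null(system@macrostateLabels$unbound))
    system@macrostateLabels$unbound[1] else 1L
  trajs <- list()
  Xall <- NULL
  hiddenAll <- integer()
  counter <- 0L
  for (round in seq_len(nRounds)) {
    if (round == 1L) {
      starts <- rep(unbound, trajsPerRound)
    } else {
      if (nClusters > nrow(Xall))
        stop("nClusters (", nClusters, ") exceeds accumulated frames (", nrow(Xall), ")")
      starts <- withSeed(deriveSeed(seed, 1000L + round), {
        km <- suppressWarnings(
          kmeans(Xall, centers = nClusters, iter.max = 30, nstart = 2))
        counts <- tabulate(km$cluster, nClusters)
        chosen <- leastCountRestarts(counts, trajsPerRound)
        vapply(chosen, function(cl) {
          pool <- which(km$cluster == cl)
          hiddenAll[pool[sample.int(length(pool), 1L)]]
        }, integer(1))
      })
    }
    for (j in seq_len(trajsPerRound)) {
      counter <- counter + 1L
      tr <- sampleChainTrajectory(
        system, stepsPerTraj, startState = starts[j],
        seed = deriveSeed(seed, counter),
        trajectoryId = sprintf("round%02d_traj%02d", round, j))
      trajs[[counter]] <- tr
      Xall <- rbind(Xall, tr@X)
      hiddenAll <- c(hiddenAll, tr@hiddenStates)
    }
  }
  trajs
}

#' Generate paired dihedral ensembles with a planted coupling chain
#'
#' Builds two [DihedralEnsemble-class]s ("agonist_like" and
#' "partial_agonist_like") over the same residues. Residues along `pathSpec`
#' form a dependency chain: each angle is a wrapped-normal perturbation of its
#' predecessor with noise standard deviation `90 * (1 - couplingStrength)`
#' degrees, so coupling 1 gives exact copies. Off-path residues are
#' independent. The contact map places consecutive path residues 4.5 A apart
#' (< 6 A), adds decoy short contacts (4.0 A) between uncoupled residue
#' pairs, and keeps every other pair at 8-15 A. The two ensembles differ in
#' the angle distributions of `differingResidues` (mean shifted in the second
#' ensemble), the ground truth for divergence-ranking tests.
#'
#' @param nResidues residue count.
#' @param pathSpec ordered residue indices of the coupling chain (distinct,
#'   in range).
#' @param couplingStrength value in (0, 1].
#' @param nFrames frames per ensemble.
#' @param seed integer seed.
#' @param differingResidues residues whose distribution differs between the
#'   two ensembles; default up to 3 off-path residues chosen under the seed.
#' @param shiftDeg mean shift (degrees) applied to differing residues in the
#'   second ensemble.
#' @param nDecoys number of decoy short contacts.
#' @return list with `ensembleA`, `ensembleB`, `differingResidues`,
#'   `plantedPath`.
#' @export
generateDihedralEnsembles <- function(nResidues, pathSpec, couplingStrength,
                                      nFrames, seed = 1L,
                                      differingResidues = NULL,
                                      shiftDeg = 70, nDecoys = 2L) {
  pathSpec <- as.integer(pathSpec)
  if (anyDuplicated(pathSpec) || any(pathSpec < 1) || any(pathSpec > nResidues))
    stop("pathSpec residues must be distinct and within range")
  if (couplingStrength <= 0 || couplingStrength > 1)
    stop("couplingStrength must lie in (0, 1]")
  offPath <- setdiff(seq_len(nResidues), pathSpec)

  setupSeed <- deriveSeed(seed, 7L)
  setup <- withSeed(setupSeed, {
    mu <- wrapAngle(runif(nResidues, -120, 120))
    if (is.null(differingResidues)) {
      nd <- min(3L, length(offPath))
      differingResidues <- if (nd > 0) sort(sample(offPath, nd)) else integer(0)
    }
    ## contact map: background 8-15 A, consecutive path pairs 4.5 A,
    ## decoy short contacts 4.0 A between pairs with zero coupling
    cd <- matrix(runif(nResidues^2, 8, 15), nResidues, nResidues)
    cd[lower.tri(cd)] <- t(cd)[lower.tri(cd)]
    diag(cd) <- 0
    if (length(pathSpec) > 1) {
      for (k in seq_len(length(pathSpec) - 1L)) {
        i <- pathSpec[k]; j <- pathSpec[k + 1L]
        cd[i, j] <- cd[j, i] <- 4.5
      }
    }
    consec <- if (length(pathSpec) > 1)
      cbind(pathSpec[-length(pathSpec)], pathSpec[-1]) else matrix(0, 0, 2)
    placed <- 0L; guard <- 0L
    while (placed < nDecoys && guard < 200L) {
      guard <- guard + 1L
      pr <- sample.int(nResidues, 2L)
      onChain <- any(consec[, 1] == min(pr) & consec[, 2] == max(pr)) ||
        any(consec[, 1] == max(pr) & consec[, 2] == min(pr))
      bothOnPath <- all(pr %in% pathSpec)
      if (!onChain && !bothOnPath) {
        cd[pr[1], pr[2]] <- cd[pr[2], pr[1]] <- 4.0
        placed <- placed + 1L
      }
    }
    list(mu = mu, differing = as.integer(differingResidues), cd = cd)
  })

  makeEnsemble <- function(label, stream, shifted) {
    withSeed(deriveSeed(seed, stream), {
      D <- matrix(0, nFrames, nResidues)
      for (r in offPath) {
        m <- setup$mu[r] + if (shifted && r %in% setup$differing) shiftDeg else 0
        D[, r] <- wrapAngle(m + rnorm(nFrames, 0, 35))
      }
      if (length(pathSpec)) {
        D[, pathSpec[1]] <- wrapAngle(rnorm(nFrames, 0, 80))
        noiseSd <- 90 * (1 - couplingStrength)
        if (length(pathSpec) > 1) {
          for (k in 2:length(pathSpec)) {
            prev <- D[, pathSpec[k - 1L]]
            D[, pathSpec[k]] <- if (noiseSd == 0) prev else
              wrapAngle(prev + rnorm(nFrames, 0, noiseSd))
          }
        }
      }
      ## path residues in differing set also shift (applies when caller puts
      ## them there explicitly); handled above only for off-path residues
      new("DihedralEnsemble", label = label, nResidues = as.integer(nResidues),
          D = D, contactDistances = setup$cd, plantedPath = pathSpec)
    })
  }

  list(ensembleA = makeEnsemble("agonist_like", 100L, shifted = FALSE),
       ensembleB = makeEnsemble("partial_agonist_like", 200L, shifted = TRUE),
       differingResidues = setup$differing,
       plantedPath = pathSpec)
}
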