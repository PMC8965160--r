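test_that("preset systems have valid stationary distributions and free energies", {
  for (sc in c("two_state", "double_well_1d", "binding_landscape", "bottleneck_chain")) {
    sys <- buildGroundTruthChain(sc)
    T <- transitionMatrix(sys)
    pi <- stationaryDistribution(sys)
    expect_equal(rowSums(T), rep(1, nStates(sys)), tolerance = 1e-12)
    expect_lt(max(abs(drop(pi %*% T) - pi)), 1e-10)
  }
  ## two_state symmetry
  sys2 <- buildGroundTruthChain("two_state")
  expect_equal(stationaryDistribution(sys2), c(0.5, 0.5))
  ## double-well basin gap encoded exactly in pi (construction identity)
  dw <- buildGroundTruthChain("double_well_1d", basinGap = 1.3)
  pi <- stationaryDistribution(dw)
  expect_equal(-0.0019872 * 300 * log(pi[2] / pi[1]), 1.3, tolerance = 1e-10)
})

test_that("explicit transition matrices give the analytic stationary distribution", {
  ## left eigenvector of [[0.9, 0.1], [0.3, 0.7]] is (0.75, 0.25)
  sys <- buildGroundTruthChain("custom",
    Ttrue = matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE),
    emissionMeans = matrix(c(-1, 1), 2, 1),
    emissionSds = matrix(0.2, 2, 1))
  expect_equal(stationaryDistribution(sys), c(0.75, 0.25), tolerance = 1e-10)
  ## non-stochastic matrices rejected
  expect_error(buildGroundTruthChain("custom",
    Ttrue = matrix(c(0.9, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE),
    emissionMeans = matrix(c(-1, 1), 2, 1),
    emissionSds = matrix(0.2, 2, 1)), "stochastic")
})

test_that("chain sampling is reproducible and matches the generator law", {
  sys <- buildGroundTruthChain("two_state")
  a <- sampleChainTrajectory(sys, 500, startState = 1, seed = 42)
  b <- sampleChainTrajectory(sys, 500, startState = 1, seed = 42)
  expect_identical(trajectoryMatrix(a), trajectoryMatrix(b))
  expect_identical(hiddenStates(a), hiddenStates(b))
  expect_error(sampleChainTrajectory(sys, 100, startState = 7), "start state")

  ## occupancy converges to pi (law of large numbers)
  tr <- sampleChainTrajectory(sys, 200000, startState = 1, seed = 3)
  occ <- tabulate(hiddenStates(tr), 2) / 200000
  expect_lt(sum(abs(occ - stationaryDistribution(sys))), 0.02)

  ## per-state feature means within 3 standard errors of the emission model
  sysb <- buildGroundTruthChain("binding_landscape")
  trb <- sampleChainTrajectory(sysb, 50000, startState = 1, seed = 5)
  hid <- hiddenStates(trb)
  X <- trajectoryMatrix(trb)
  for (s in unique(hid)) {
    n <- sum(hid == s)
    mu <- colMeans(X[hid == s, , drop = FALSE])
    se <- sysb@emissionSds[s, ] / sqrt(n)
    expect_true(all(abs(mu - sysb@emissionMeans[s, ]) < 3.5 * se))
  }

  ## empirical transition counts converge to the true matrix
  Te <- transitionMatrix(estimateMSM(countTransitions(list(hiddenStates(tr)), 1)))
  expect_lt(max(abs(Te - transitionMatrix(sys))), 0.02)
})

test_that("least-counts restart policy favours the smallest clusters", {
  picks <- ligandMSM:::withSeed(1, ligandMSM:::leastCountRestarts(c(A = 10, B = 3, C = 7), 1))
  expect_identical(unname(picks), 2L)   # cluster B
  ## cycling: 3 restarts cover the clusters in ascending-count order
  picks3 <- ligandMSM:::withSeed(1, ligandMSM:::leastCountRestarts(c(10, 3, 7), 3))
  expect_identical(unname(picks3), c(2L, 3L, 1L))
  ## all counts equal: chosen cluster is uniform under the seed
  picks1 <- replicate(200, ligandMSM:::leastCountRestarts(c(5, 5, 5), 1))
  expect_true(all(sort(unique(picks1)) == 1:3))
  expect_gt(min(tabulate(picks1, 3)), 30)
})

test_that("adaptive sampling annotates rounds and validates its budget", {
  sys <- buildGroundTruthChain("bottleneck_chain")
  trajs <- runAdaptiveSampling(sys, nRounds = 3, trajsPerRound = 2,
                               stepsPerTraj = 50, nClusters = 4, seed = 1)
  expect_length(trajs, 6)
  expect_identical(trajs[[1]]@trajectoryId, "round01_traj01")
  expect_identical(trajs[[6]]@trajectoryId, "round03_traj02")
  ## round 1 starts from the unbound state
  expect_true(all(vapply(trajs[1:2], function(t) hiddenStates(t)[1], 1L) == 1L))
  expect_error(runAdaptiveSampling(sys, 2, 1, 10, nClusters = 100, seed = 1),
               "exceeds accumulated frames")
})

test_that("dihedral ensembles plant the coupling chain and the contact gates", {
  ens <- generateDihedralEnsembles(10, pathSpec = c(2, 5, 8),
                                   couplingStrength = 1, nFrames = 500, seed = 4)
  A <- ens$ensembleA
  expect_identical(A@plantedPath, c(2L, 5L, 8L))
  ## coupling 1: exact copies along the chain
  expect_equal(A@D[, 5], A@D[, 2])
  expect_equal(A@D[, 8], A@D[, 5])
  ## consecutive path residues in contact, non-consecutive path pairs not
  expect_lt(A@contactDistances[2, 5], 6)
  expect_lt(A@contactDistances[5, 8], 6)
  expect_gt(A@contactDistances[2, 8], 6)
  expect_equal(A@contactDistances, t(A@contactDistances))
  expect_error(generateDihedralEnsembles(10, c(2, 5), 1.5, 100, 1), "couplingStrength")
  expect_error(generateDihedralEnsembles(10, c(2, 2), 0.5, 100, 1), "distinct")

  ## off-path pairs are statistically independent: actual MI within the
  ## shuffled null band
  ens2 <- generateDihedralEnsembles(8, pathSpec = c(1, 2), couplingStrength = 0.8,
                                    nFrames = 4000, seed = 6,
                                    differingResidues = integer(0))
  D <- ens2$ensembleA@D
  actual <- dihedralMutualInformation(D[, 4], D[, 6])
  null <- ligandMSM:::withSeed(9, vapply(1:100, function(i)
    dihedralMutualInformation(D[, 4], D[sample.int(nrow(D)), 6]), numeric(1)))
  expect_lt(actual, quantile(null, 0.99))
})
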