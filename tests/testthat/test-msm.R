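test_that("transition counting enumerates lagged pairs per mode", {
  C1 <- countTransitions(list(c(1L, 1L, 2L, 2L)), lag = 1)@counts
  expect_equal(C1, rbind(c(1, 1), c(0, 1)))
  C2 <- countTransitions(list(c(1L, 1L, 2L, 2L)), lag = 2)@counts
  expect_equal(C2, rbind(c(0, 2), c(0, 0)))
  ## strided counting uses t = 0, lag, 2 lag, ...
  Cs <- countTransitions(list(c(1L, 1L, 2L, 2L, 1L)), lag = 2, mode = "strided")@counts
  expect_equal(Cs, rbind(c(0, 1), c(1, 0)))
  ## two copies double the counts; trajectories never concatenate
  s <- c(1L, 2L, 1L, 2L)
  expect_equal(countTransitions(list(s, s), 1)@counts,
               2 * countTransitions(list(s), 1)@counts)
  expect_error(countTransitions(list(1:2), lag = 5), "longer than the lag")
})

test_that("MSM estimation row-normalizes and restricts to the largest SCC", {
  m <- msmFromCounts(rbind(c(8, 2), c(2, 8)))
  expect_equal(transitionMatrix(m), rbind(c(0.8, 0.2), c(0.2, 0.8)))
  expect_equal(stationaryDistribution(m), c(0.5, 0.5))
  ## analytic left eigenvector
  m2 <- msmFromCounts(rbind(c(9, 1), c(3, 7)))
  expect_equal(stationaryDistribution(m2), c(0.75, 0.25), tolerance = 1e-12)
  ## isolated absorbing pair {4, 5} unreachable from {1, 2, 3}: only the
  ## largest strongly connected component survives
  C <- matrix(0, 5, 5)
  C[1, 2] <- C[2, 3] <- C[3, 1] <- 5; diag(C)[1:3] <- 5
  C[4, 5] <- C[5, 4] <- 100
  m3 <- msmFromCounts(C)
  expect_identical(activeSet(m3), c(1L, 2L, 3L))
  ## constructor-level invariants
  expect_equal(rowSums(transitionMatrix(m3)), rep(1, 3), tolerance = 1e-12)
  p <- stationaryDistribution(m3)
  expect_lt(max(abs(drop(p %*% transitionMatrix(m3)) - p)), 1e-10)
})

test_that("implied timescales follow the closed form and stay flat in lag", {
  ## eigenvalues {1, 0.6} at tau = 10 frames
  T <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(timescalesFromTransitionMatrix(T, lag = 10)[1], -10 / log(0.6))
  ## eigenvalue at 1 reports +Inf; non-positive reports NA
  Trep <- rbind(c(1, 0), c(0, 1))
  expect_identical(timescalesFromTransitionMatrix(Trep, 1)[1], Inf)
  Tneg <- rbind(c(0.1, 0.9), c(0.9, 0.1))  # lambda2 = -0.8
  expect_true(is.na(timescalesFromTransitionMatrix(Tneg, 1)[1]))

  ## Markovian generator: timescale estimates flat (within 15%) across lags
  sys <- buildGroundTruthChain("binding_landscape")
  dtrajs <- lapply(presetTrajectories(sys, 10, 25000, seed = 9), hiddenStates)
  its <- impliedTimescales(dtrajs, lags = c(1, 2, 5, 10), nTimescales = 1)
  ts <- its$timescaleNs
  expect_true(all(abs(ts / mean(ts) - 1) < 0.15))
})

test_that("state free energies follow G = -kB T ln pi", {
  expect_equal(diff(freeEnergyOfStates(c(0.5, 0.5))), 0)
  expect_equal(diff(freeEnergyOfStates(c(0.8, 0.2), temperature = 300)),
               0.0019872 * 300 * log(4))
  ## monotonicity: the most populated state is the minimum
  set.seed(8)
  for (i in 1:5) {
    p <- runif(6); p <- p / sum(p)
    expect_identical(which.min(freeEnergyOfStates(p)), which.max(p))
  }
  ## zero populations are masked, not -Inf
  G <- freeEnergyOfStates(c(0.7, 0.3, 0))
  expect_true(is.na(G[3]) && all(is.finite(G[1:2])))
})

test_that("weighted landscapes reduce to histograms for one state and conserve weight", {
  set.seed(4)
  x <- rnorm(2000)
  tr <- new("FeatureTrajectory", trajectoryId = "t", frameDt = 1,
            X = cbind(x = x), featureNames = "x", hiddenStates = integer(0))
  msm1 <- msmFromCounts(matrix(2000, 1, 1))
  surf <- weightedLandscape(msm1, list(rep(1L, 2000)), list(tr), "x", bins = 20)
  ## single-state MSM: equal frame weights, so G equals the plain histogram
  ## converted to free energy
  h <- tabulate(cut(x, surf@xEdges, include.lowest = TRUE), 20)
  Gref <- -0.0019872 * 300 * log(h / max(h))
  expect_equal(surf@G[!surf@mask], Gref[h > 0], tolerance = 1e-10)
  expect_equal(min(surf@G, na.rm = TRUE), 0)

  ## total MSM frame weight is 1 before the log transform
  sys <- buildGroundTruthChain("two_state")
  trs <- presetTrajectories(sys, 4, 2000, seed = 2)
  dts <- lapply(trs, hiddenStates)
  msm <- estimateMSM(countTransitions(dts, 1))
  w <- ligandMSM:::frameWeights(msm, dts)
  expect_equal(sum(unlist(w)), 1, tolerance = 1e-12)

  ## duplicating all trajectories leaves state free energies unchanged
  msmDup <- estimateMSM(countTransitions(c(dts, dts), 1))
  expect_equal(freeEnergyOfStates(stationaryDistribution(msmDup)),
               freeEnergyOfStates(stationaryDistribution(msm)), tolerance = 1e-12)
})

test_that("conditional probabilities are weight ratios with the right bounds", {
  ## state weights pi = (0.4, 0.2, 0.3, 0.1): P(state 2 | states {1, 2}) = 1/3
  C <- matrix(rep(c(4000, 2000, 3000, 1000), 4), 4, 4, byrow = TRUE)
  msm <- msmFromCounts(C)
  expect_equal(stationaryDistribution(msm), c(0.4, 0.2, 0.3, 0.1), tolerance = 1e-12)
  st <- rep(1:4, each = 25)
  trajs <- list(matrix(st, ncol = 1, dimnames = list(NULL, "s")))
  cp <- conditionalProbability(msm, list(st), trajs,
                               condition = function(X) X[, "s"] %in% c(1, 2),
                               outcome = function(X) X[, "s"] == 2)
  expect_equal(cp, 0.2 / 0.6, tolerance = 1e-12)
  ## outcome containing the condition gives exactly 1
  cp1 <- conditionalProbability(msm, list(st), trajs,
                                condition = function(X) X[, "s"] == 3,
                                outcome = function(X) X[, "s"] %in% c(1, 3))
  expect_equal(cp1, 1)
  expect_error(conditionalProbability(msm, list(st), trajs,
                                      condition = function(X) X[, "s"] > 10,
                                      outcome = function(X) X[, "s"] == 1),
               "zero")
})
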