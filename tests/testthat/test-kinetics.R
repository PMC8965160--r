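test_that("macrostate definition keeps the top states by raw count", {
  ## 6 active states with controlled frame counts; region selects all
  counts <- c(50, 40, 30, 20, 10, 5)
  dtraj <- rep(1:6, counts)
  msm <- estimateMSM(countTransitions(list(c(dtraj, 1L)), 1, nStates = 6))
  disc <- new("Discretization", centers = matrix(1:6, 6, 1),
              assignments = list(rep(1:6, counts)), K = 6L, seed = 1L,
              inertia = 0)
  ms <- defineMacrostate(msm, disc, region = function(center) TRUE, nTop = 5)
  expect_identical(ms@states, 1:5)
  ## fewer qualifying states than requested: all taken, with a warning
  expect_warning(
    ms3 <- defineMacrostate(msm, disc, region = function(c) c[1] <= 3, nTop = 5),
    "3 states")
  expect_identical(ms3@states, 1:3)
  expect_error(defineMacrostate(msm, disc, region = function(c) FALSE), "no active state")
  ## count ties break toward the lower state index
  disc2 <- new("Discretization", centers = matrix(1:6, 6, 1),
               assignments = list(rep(1:6, c(10, 10, 10, 10, 10, 10))),
               K = 6L, seed = 1L, inertia = 0)
  ms2 <- defineMacrostate(msm, disc2, region = function(c) TRUE, nTop = 2)
  expect_identical(ms2@states, 1:2)
})

test_that("committors satisfy boundary conditions, symmetry, and simulation", {
  T2 <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(committor(T2, 1, 2), c(0, 1))
  ## symmetric 3-state chain: middle state commits 50:50
  T3 <- rbind(c(0.8, 0.2, 0), c(0.3, 0.4, 0.3), c(0, 0.2, 0.8))
  expect_equal(committor(T3, 1, 3)[2], 0.5)
  ## unreachable sink is an explicit error naming the offending state
  Tur <- rbind(c(0.8, 0.2, 0.0, 0.0),
               c(1.0, 0.0, 0.0, 0.0),   # state 2 can never reach state 4
               c(0.0, 0.0, 0.5, 0.5),
               c(0.0, 0.0, 0.5, 0.5))
  expect_error(committor(Tur, 1, 4), "unreachable from state\\(s\\): 2")
  ## reversible birth-death chain: q+ and q- partition unity state-wise
  Tbd <- rbind(c(0.9, 0.1, 0, 0), c(0.2, 0.5, 0.3, 0),
               c(0, 0.3, 0.5, 0.2), c(0, 0, 0.1, 0.9))
  pibd <- ligandMSM:::statDist(Tbd)
  qp <- committor(Tbd, 1, 4)
  qm <- backwardCommittor(Tbd, pibd, 1, 4)
  expect_equal(qp + qm, rep(1, 4), tolerance = 1e-10)
  ## 6-state random ergodic chain against the Monte-Carlo hit fractions
  rc <- randomErgodicChain(6, seed = 3)
  Tr <- transitionMatrix(rc)
  q <- committor(Tr, 1, 6)
  qmc <- committorMonteCarlo(Tr, 1, 6, nRuns = 4000, seed = 3)
  expect_lt(max(abs(q[as.integer(names(qmc))] - qmc)), 0.03)
  qb <- backwardCommittor(Tr, stationaryDistribution(rc), 1, 6)
  expect_true(all(qb >= 0 & qb <= 1))
  expect_equal(qb[1], 1); expect_equal(qb[6], 0)
})

test_that("reactive flux and MFPT follow the closed forms", {
  m <- twoStateMsm(p01 = 0.1, p10 = 0.1)
  expect_equal(reactiveFlux(m, 1, 2), 0.5 * 0.1, tolerance = 1e-12)
  res <- mfpt(m, 1, 2)
  expect_equal(res$frames, 10, tolerance = 1e-12)   # 1 / T_AB
  ## flux invariant under state relabeling
  C <- rbind(c(800, 100, 100), c(50, 900, 50), c(20, 30, 950))
  mA <- msmFromCounts(C)
  perm <- c(3L, 1L, 2L)
  mB <- msmFromCounts(C[perm, perm])
  expect_equal(reactiveFlux(mA, 1, 3), reactiveFlux(mB, which(perm == 1), which(perm == 3)),
               tolerance = 1e-12)
  ## MFPT scales linearly with the lag for fixed T
  m5 <- twoStateMsm(p01 = 0.1, p10 = 0.1, lag = 5L)
  expect_equal(mfpt(m5, 1, 2)$frames, 50, tolerance = 1e-12)
  ## 4-state metastable chain against brute-force first passage
  rc <- randomErgodicChain(4, seed = 11)
  mr <- estimateMSM(round(transitionMatrix(rc) * 1e6), lag = 1)
  sim <- firstPassageMonteCarlo(transitionMatrix(mr), stationaryDistribution(mr),
                                1, 4, nRuns = 10000, seed = 2)
  expect_lt(abs(mfpt(mr, 1, 4)$frames - sim) / sim, 0.05)
})

test_that("kMC follows the cumulative-probability jump rule", {
  m <- twoStateMsm(0.1, 0.1)
  ## same seed, identical trajectory
  k1 <- kmcRun(m, 1, 1000, seed = 5)
  k2 <- kmcRun(m, 1, 1000, seed = 5)
  expect_identical(k1@states, k2@states)
  expect_identical(length(k1@states), 1000L)
  expect_true(all(k1@states %in% 1:2))
  expect_error(kmcRun(m, 9, 10), "start state")
  ## absorbing state: constant trajectory
  Cabs <- rbind(c(10, 10), c(0, 1e6))
  mAbs <- estimateMSM(Cabs, lag = 1)     # SCC keeps only state 2 (absorbing-like)
  expect_identical(activeSet(mAbs), 2L)
  kAbs <- kmcRun(mAbs, 1, 50, seed = 1)
  expect_true(all(kAbs@states == 1L))
  ## occupancy matches pi by the ergodic theorem
  k <- kmcRun(m, 1, 200000, seed = 9)
  occ <- tabulate(k@states, 2) / 200000
  expect_lt(sum(abs(occ - stationaryDistribution(m))), 0.02)
})

test_that("frame stitching draws frames from the visited state pools", {
  sys <- buildGroundTruthChain("two_state")
  trs <- presetTrajectories(sys, 3, 500, seed = 2)
  dts <- lapply(trs, hiddenStates)
  msm <- estimateMSM(countTransitions(dts, 1))
  k <- kmcRun(msm, 1, 200, seed = 4)
  st <- stitchFrames(k, msm, dts, seed = 4)
  ## stitched frame labels equal the kMC state sequence
  labels <- vapply(seq_len(nrow(st@frames)), function(i)
    dts[[st@frames$trajectory[i]]][st@frames$frame[i]], 1L)
  expect_identical(labels, k@states)
  ## determinism
  st2 <- stitchFrames(k, msm, dts, seed = 4)
  expect_identical(st@frames, st2@frames)

  ## a state with a single frame always yields that frame
  single <- list(c(rep(1L, 50), 2L, rep(1L, 50)))
  msmS <- estimateMSM(countTransitions(single, 1))
  kS <- kmcRun(msmS, 1, 100, seed = 2)
  stS <- stitchFrames(kS, msmS, single, seed = 2)
  visits2 <- stS@frames[stS@frames$state == 2L, ]
  if (nrow(visits2)) expect_true(all(visits2$frame == 51L))
})
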