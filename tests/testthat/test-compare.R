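makeEnsemblePair <- function(nFrames = 400, shift = 8, seed = 1) {
  set.seed(seed)
  P <- 5
  base <- matrix(rnorm(nFrames * P), nFrames, P)
  fn <- paste0("d", 1:P)
  fr <- setNames(lapply(1:P, function(i) c(i, i + 1L)), fn)
  A <- ensembleMatrix(base, fn, fr, "A")
  Xb <- matrix(rnorm(nFrames * P), nFrames, P)
  Xb[, 3] <- Xb[, 3] + shift      # planted mean shift on feature d3
  B <- ensembleMatrix(Xb, fn, fr, "B")
  list(A = A, B = B)
}

test_that("pooled PCA separates a planted mean shift onto PC1", {
  pr <- makeEnsemblePair()
  fit <- pcaCompare(pr$A, pr$B, nComponents = 3)
  ## the shifted feature dominates the first component
  expect_identical(rownames(fit$loadings)[which.max(abs(fit$loadings[, 1]))], "d3")
  expect_identical(topWeightFeatures(fit$loadings, 1, 1)$feature, "d3")
  ## explained variances are non-increasing and sum to at most 1
  expect_true(all(diff(fit$explainedVariance) <= 1e-12))
  expect_lte(sum(fit$explainedVariance), 1 + 1e-12)
  ## identical ensembles project onto statistically indistinguishable clouds
  fit0 <- pcaCompare(pr$A, pr$A, 2)
  expect_equal(fit0$projA, fit0$projB)
  ## feature mismatch is rejected
  C <- ensembleMatrix(pr$A@X, paste0("x", 1:5),
                      setNames(lapply(1:5, identity), paste0("x", 1:5)))
  expect_error(pcaCompare(pr$A, C, 2), "identical feature set")
})

test_that("top-weight ranking is complete and order-equivariant", {
  pr <- makeEnsemblePair()
  fit <- pcaCompare(pr$A, pr$B, 2)
  all5 <- topWeightFeatures(fit$loadings, 1, 5)
  expect_identical(sort(all5$feature), sort(rownames(fit$loadings)))
  expect_error(topWeightFeatures(fit$loadings, 1, 9), "exceeds")
  expect_error(topWeightFeatures(fit$loadings, 5, 2), "does not exist")
  ## permuting feature order leaves the ranking invariant
  perm <- c(4, 2, 5, 1, 3)
  fitP <- pcaCompare(
    ensembleMatrix(pr$A@X[, perm], colnames(pr$A@X)[perm], pr$A@featureResidues),
    ensembleMatrix(pr$B@X[, perm], colnames(pr$B@X)[perm], pr$B@featureResidues), 2)
  expect_identical(topWeightFeatures(fitP$loadings, 1, 1)$feature, "d3")
})

test_that("symmetrized KL matches the Gaussian closed form and is symmetric", {
  set.seed(5)
  a <- rnorm(100000); b <- rnorm(100000, mean = 1)
  ## sum of both directions for unit-variance unit-shift Gaussians = 1 nat
  kl <- symmetrizedKL(a, b)
  expect_equal(kl, 1.0, tolerance = 0.1)
  expect_equal(symmetrizedKL(b, a), kl)
  expect_identical(symmetrizedKL(a, a), 0)
  expect_identical(symmetrizedKL(rep(2, 50), rep(2, 70)), 0)  # degenerate range
  expect_gte(symmetrizedKL(rnorm(500), rnorm(500)), 0)
})

test_that("per-residue aggregation averages divergences over involved features", {
  fr <- list(f1 = c(1L, 2L), f2 = c(2L, 3L))
  ## all-zero divergences give all-zero residues
  z <- perResidueDivergence(c(f1 = 0, f2 = 0), fr)
  expect_true(all(z == 0))
  ## a single feature credits both its residues
  d <- perResidueDivergence(c(f1 = 0.8), list(f1 = c(1L, 2L)))
  expect_equal(unname(d), c(0.8, 0.8))
  ## residue 2 averages over f1 and f2
  m <- perResidueDivergence(c(f1 = 1, f2 = 3), fr)
  expect_equal(unname(m[c("1", "2", "3")]), c(1, 2, 3))
  expect_error(perResidueDivergence(c(zz = 1), fr), "unmapped")
})

test_that("planted distribution differences localize to the right residues", {
  ens <- generateDihedralEnsembles(12, pathSpec = c(2, 5, 8, 11),
                                   couplingStrength = 0.8, nFrames = 8000,
                                   seed = 3)
  kl <- vapply(1:12, function(r)
    symmetrizedKL(ens$ensembleA@D[, r], ens$ensembleB@D[, r]), numeric(1))
  prd <- perResidueDivergence(setNames(kl, as.character(1:12)),
                              setNames(lapply(1:12, identity), as.character(1:12)))
  k <- length(ens$differingResidues)
  top <- as.integer(names(sort(prd, decreasing = TRUE)))[seq_len(k)]
  expect_gte(mean(top %in% ens$differingResidues), 0.8)
})

test_that("normalized mutual information has the right conventions", {
  set.seed(7)
  a <- runif(5000, -180, 180)
  ## a series against itself normalizes to 1
  expect_equal(dihedralMutualInformation(a, a), 1)
  ## constant series have normalized MI 0 by convention
  expect_identical(dihedralMutualInformation(rep(10, 100), runif(100, -180, 180)), 0)
  ## independent angles stay below the shuffled null band
  b <- runif(5000, -180, 180)
  actual <- dihedralMutualInformation(a, b)
  null <- ligandMSM:::withSeed(2, vapply(1:200, function(i)
    dihedralMutualInformation(a, b[sample.int(5000)]), numeric(1)))
  expect_lt(actual, quantile(null, 0.975) + 0.01)
  ## stronger coupling gives strictly larger MI
  strong <- generateDihedralEnsembles(4, c(1, 2), 0.9, 5000, seed = 8)$ensembleA
  weak <- generateDihedralEnsembles(4, c(1, 2), 0.1, 5000, seed = 8)$ensembleA
  expect_gt(dihedralMutualInformation(strong@D[, 1], strong@D[, 2]),
            dihedralMutualInformation(weak@D[, 1], weak@D[, 2]))
  ## estimator bias shrinks with sample size (null MI at 20k vs 500 frames)
  nullAt <- function(n, seed) {
    ligandMSM:::withSeed(seed, {
      median(vapply(1:20, function(i)
        dihedralMutualInformation(runif(n, -180, 180), runif(n, -180, 180)),
        numeric(1)))
    })
  }
  expect_lt(nullAt(20000, 4), nullAt(500, 4))
})

test_that("MI graph applies both gates and Dijkstra recovers the planted chain", {
  mi <- matrix(0.05, 4, 4); diag(mi) <- 1
  mi[1, 2] <- mi[2, 1] <- 0.9
  mi[3, 4] <- mi[4, 3] <- 0.9
  cd <- matrix(10, 4, 4); diag(cd) <- 0
  cd[1, 2] <- cd[2, 1] <- 7    # strong MI but out of contact: no edge
  cd[3, 4] <- cd[4, 3] <- 3    # contact and strong MI: edge
  cd[1, 3] <- cd[3, 1] <- 3    # contact but weak MI: no edge
  net <- buildMiGraph(mi, cd, distanceCutoff = 6, miThreshold = 0.2)
  expect_identical(nrow(net@edges), 1L)
  expect_identical(c(net@edges$i, net@edges$j), c(3L, 4L))
  ## single-edge graph: the path is that edge; disconnected pairs are explicit
  sp <- shortestAllostericPath(net, 3, 4)
  expect_identical(sp$path, c(3L, 4L))
  expect_false(shortestAllostericPath(net, 1, 4)$reachable)

  ## planted chain with decoy contacts: exact recovery, verified exhaustively
  ens <- generateDihedralEnsembles(10, pathSpec = c(1, 4, 7, 10),
                                   couplingStrength = 0.8, nFrames = 6000,
                                   seed = 5)
  A <- ens$ensembleA
  miA <- mutualInformationMatrix(A)
  thr <- miPermutationThreshold(A, seed = 6)
  netA <- buildMiGraph(miA, A@contactDistances, 6.0, thr)
  spA <- shortestAllostericPath(netA, 1, 10)
  expect_identical(spA$path, c(1L, 4L, 7L, 10L))
  paths <- enumerateSimplePaths(netA, 1, 10)
  expect_equal(paths[[1]]$cost, spA$cost, tolerance = 1e-12)
  expect_identical(paths[[1]]$path, spA$path)
  ## the Dijkstra cost is minimal over every enumerated simple path
  expect_true(all(vapply(paths, `[[`, numeric(1), "cost") >= spA$cost - 1e-12))
})
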