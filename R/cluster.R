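## featurize_cluster module, part 2: seeded k-means discretization.

## k-means++ seeding (Arthur & Vassilvitskii). For very large inputs the
## seeding scan runs on a random subsample (cap below); Lloyd then runs on
## the full data.
kmeansPlusPlusInit <- function(X, K, subsampleCap = 100000L) {
  n <- nrow(X)
  if (n > subsampleCap) X <- X[sample.int(n, subsampleCap), , drop = FALSE]
  n <- nrow(X)
  tX <- t(X)
  centers <- matrix(0, K, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- colSums((tX - centers[1, ])^2)
  if (K > 1) for (k in 2:K) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2 / tot)
    centers[k, ] <- X[i, ]
    d2 <- pmin(d2, colSums((tX - centers[k, ])^2))
  }
  centers
}

#' Discretize trajectories with seeded k-means
#'
#' Pools all frames, runs Lloyd iterations from k-means++ initializations
#' (`nRestarts` seeded restarts, best inertia kept), and assigns every frame
#' to its nearest center in Euclidean distance. Deterministic given the seed.
#'
#' @param trajs list of [FeatureTrajectory-class] or numeric matrices
#'   (typically TICA-transformed).
#' @param K number of clusters (<= total frames).
#' @param seed integer seed.
#' @param maxIter Lloyd iteration cap per restart.
#' @param nRestarts number of seeded k-means++ restarts.
#' @param fitCap Lloyd iterations run on a seeded random subsample of at most
#'   this many frames when the data are larger (centers are fitted on the
#'   subsample, then every frame is assigned to its nearest center); keeps
#'   discretization of multi-million-frame datasets tractable.
#' @return a [Discretization-class].
#' @export
kmeansDiscretize <- function(trajs, K, seed = 1L, maxIter = 100L,
                             nRestarts = 10L, fitCap = 200000L) {
  if (!is.list(trajs)) trajs <- list(trajs)
  if (!length(trajs)) stop("empty input")
  Xs <- lapply(trajs, asTrajMatrix)
  lens <- vapply(Xs, nrow, 1L)
  X <- do.call(rbind, Xs)
  n <- nrow(X)
  K <- as.integer(K)
  if (K > n) stop("K (", K, ") exceeds total frames (", n, ")")

  Xfit <- if (n > fitCap) {
    withSeed(deriveSeed(seed, 0L), X[sample.int(n, fitCap), , drop = FALSE])
  } else X
  nDistinct <- nrow(unique(Xfit))
  if (K > nDistinct) stop("K (", K, ") exceeds distinct points (", nDistinct, ")")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(deriveSeed(seed, r), {
      init <- kmeansPlusPlusInit(Xfit, K)
      init <- init[!duplicated(init), , drop = FALSE]
      if (nrow(init) < K) {
        extra <- unique(Xfit)[sample.int(nDistinct, K - nrow(init)), , drop = FALSE]
        init <- rbind(init, extra)
        init <- init[!duplicated(init), , drop = FALSE]
      }
      suppressWarnings(kmeans(Xfit, centers = init, iter.max = maxIter,
                              algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }

  centers <- unname(best$centers)
  assign <- nearestCenter(X, centers)   # guarantee the nearest-center invariant
  splitIdx <- rep(seq_along(lens), lens)
  new("Discretization",
      centers = centers,
      assignments = unname(split(assign, splitIdx)),
      K = K, seed = as.integer(seed),
      inertia = sum((X - centers[assign, , drop = FALSE])^2))
}
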