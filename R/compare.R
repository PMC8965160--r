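## ensemble_compare module: PCA over pooled ensembles, symmetrized K-L
## divergence with per-residue aggregation, and the mutual-information
## allosteric network.

#' Construct an ensemble feature matrix
#'
#' @param X frames x P numeric matrix.
#' @param featureNames P labels (default from column names).
#' @param featureResidues named list mapping each feature to the residue
#'   index (length 1) or residue pair (length 2) it involves.
#' @param label condition label.
#' @return an [EnsembleMatrix-class].
#' @export
ensembleMatrix <- function(X, featureNames = colnames(X), featureResidues,
                           label = "ensemble") {
  X <- as.matrix(X)
  colnames(X) <- featureNames
  new("EnsembleMatrix", label = label, X = X,
      featureNames = featureNames, featureResidues = featureResidues)
}

#' PCA comparison of two ensembles
#'
#' Fits PCA on the pooled, mean-centered frames of both ensembles and
#' projects each ensemble onto the components, so the two conditions are
#' embedded in a common low-dimensional space.
#'
#' @param ensA,ensB [EnsembleMatrix-class]s with identical feature sets.
#' @param nComponents components retained.
#' @return list with `projA`, `projB` (scores), `loadings` (P x k),
#'   `explainedVariance` (fractions), `center`.
#' @export
pcaCompare <- function(ensA, ensB, nComponents = 2L) {
  if (!identical(ensA@featureNames, ensB@featureNames))
    stop("ensembles must share an identical feature set")
  pooled <- rbind(ensA@X, ensB@X)
  fit <- prcomp(pooled, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(fit$rotation))
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  evar <- fit$sdev^2 / sum(fit$sdev^2)
  nA <- nrow(ensA@X)
  list(projA = fit$x[seq_len(nA), seq_len(k), drop = FALSE],
       projB = fit$x[(nA + 1):nrow(pooled), seq_len(k), drop = FALSE],
       loadings = loadings,
       explainedVariance = evar[seq_len(k)],
       center = fit$center)
}

#' Top-weight features of a principal component
#'
#' @param loadings P x k loading matrix (rownames = feature names).
#' @param component component index.
#' @param n number of features returned.
#' @return data.frame (feature, loading) sorted by |loading| descending.
#' @export
topWeightFeatures <- function(loadings, component = 1L, n = 10L) {
  if (component > ncol(loadings)) stop("component ", component, " does not exist")
  if (n > nrow(loadings)) stop("n exceeds the number of features")
  l <- loadings[, component]
  ord <- order(-abs(l), rownames(loadings))
  data.frame(feature = rownames(loadings)[ord][seq_len(n)],
             loading = unname(l[ord][seq_len(n)]))
}

#' Symmetrized Kullback-Leibler divergence of two samples
#'
#' Histograms both samples on shared bins spanning their common range, adds a
#' pseudocount to every bin, normalizes, and returns the sum of the two
#' directed divergences KL(P||Q) + KL(Q||P), in nats. Identical samples give
#' exactly 0; a degenerate common range (all values equal) is defined as 0.
#'
#' @param samplesA,samplesB numeric vectors (non-empty).
#' @param nBins shared bin count (default 30).
#' @param pseudocount added to every bin before normalization.
#' @return divergence in nats (>= 0).
#' @export
symmetrizedKL <- function(samplesA, samplesB, nBins = 30L, pseudocount = 1e-10) {
  stopifnot(length(samplesA) > 0, length(samplesB) > 0)
  r <- range(c(samplesA, samplesB))
  if (r[1] == r[2]) return(0)
  edges <- seq(r[1], r[2], length.out = nBins + 1L)
  binOf <- function(v) pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nBins)
  p <- tabulate(binOf(samplesA), nBins) + pseudocount
  q <- tabulate(binOf(samplesB), nBins) + pseudocount
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

#' Per-residue aggregation of feature divergences
#'
#' Each residue's score is the mean divergence over all features that involve
#' it; residues with no mapped feature are absent from the output.
#'
#' @param featureDivergences named numeric vector of per-feature divergences.
#' @param featureResidues named list mapping feature -> residue indices.
#' @return named numeric vector (names = residue indices), sorted by residue.
#' @export
perResidueDivergence <- function(featureDivergences, featureResidues) {
  miss <- setdiff(names(featureDivergences), names(featureResidues))
  if (length(miss)) stop("unmapped feature(s): ", paste(miss, collapse = ", "))
  acc <- list()
  for (f in names(featureDivergences)) {
    for (r in featureResidues[[f]]) {
      key <- as.character(r)
      acc[[key]] <- c(acc[[key]], featureDivergences[[f]])
    }
  }
  res <- vapply(acc, mean, numeric(1))
  res[order(as.integer(names(res)))]
}

#' Normalized mutual information of two dihedral series
#'
#' Histograms the joint distribution over \[-180, 180) with `nBins` per axis,
#' computes the mutual information in nats from the empirical joint and
#' marginals, and normalizes by the smaller of the two marginal entropies,
#' clipping to \[0, 1\]. A constant series has zero entropy and its
#' normalized MI is defined as 0; a series against itself gives 1.
#'
#' @param anglesA,anglesB equal-length angle vectors in degrees.
#' @param nBins angular bins per axis (default 24).
#' @return normalized mutual information in \[0, 1\].
#' @export
dihedralMutualInformation <- function(anglesA, anglesB, nBins = 24L) {
  stopifnot(length(anglesA) == length(anglesB))
  a <- wrapAngle(anglesA); b <- wrapAngle(anglesB)
  bin <- function(x) pmin(floor((x + 180) / (360 / nBins)) + 1L, nBins)
  ba <- bin(a); bb <- bin(b)
  n <- length(a)
  joint <- tabulate(ba + (bb - 1L) * nBins, nBins * nBins) / n
  pa <- tabulate(ba, nBins) / n
  pb <- tabulate(bb, nBins) / n
  Ha <- entropyNats(pa); Hb <- entropyNats(pb)
  if (Ha == 0 || Hb == 0) return(0)
  nz <- joint > 0
  Pab <- joint[nz]
  idx <- which(nz)
  ia <- ((idx - 1L) %% nBins) + 1L
  ib <- ((idx - 1L) %/% nBins) + 1L
  mi <- sum(Pab * log(Pab / (pa[ia] * pb[ib])))
  min(max(mi / min(Ha, Hb), 0), 1)
}

#' Pairwise normalized MI matrix of a dihedral ensemble
#'
#' @param ens a [DihedralEnsemble-class] (or frames x residues angle matrix).
#' @param nBins angular bins per axis.
#' @return symmetric matrix of normalized MI (diagonal set to 1).
#' @export
mutualInformationMatrix <- function(ens, nBins = 24L) {
  D <- if (is(ens, "DihedralEnsemble")) ens@D else as.matrix(ens)
  R <- ncol(D)
  M <- diag(1, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      M[i, j] <- M[j, i] <- dihedralMutualInformation(D[, i], D[, j], nBins)
    }
  }
  M
}

#' Permutation-null MI threshold per residue pair
#'
#' Finite samples never give exactly zero mutual information, so the
#' "nonzero MI" gate is made operational as a per-pair significance
#' threshold: for each pair, one series is randomly permuted `nShuffles`
#' times and the chosen quantile of the null normalized MI is returned.
#'
#' @param ens a [DihedralEnsemble-class] or angle matrix.
#' @param nBins angular bins.
#' @param nShuffles permutations per pair (default 20).
#' @param probability null quantile (default 0.975).
#' @param seed integer seed.
#' @return symmetric matrix of per-pair thresholds.
#' @export
miPermutationThreshold <- function(ens, nBins = 24L, nShuffles = 20L,
                                   probability = 0.975, seed = 1L) {
  D <- if (is(ens, "DihedralEnsemble")) ens@D else as.matrix(ens)
  R <- ncol(D); n <- nrow(D)
  thr <- matrix(0, R, R)
  withSeed(deriveSeed(seed, 17L), {
    for (i in seq_len(R - 1)) {
      for (j in (i + 1):R) {
        null <- vapply(seq_len(nShuffles), function(k)
          dihedralMutualInformation(D[, i], D[sample.int(n), j], nBins),
          numeric(1))
        thr[i, j] <- thr[j, i] <- quantile(null, probability, names = FALSE)
      }
    }
  })
  thr
}

#' Build the mutual-information allosteric network
#'
#' Creates an undirected residue graph with an edge (i, j) wherever the
#' residues are in spatial contact (distance < cutoff) AND statistically
#' coupled (normalized MI above the threshold). Edge path-cost is
#' -ln(normalized MI), clipped at `costCeiling`, so the shortest path is the
#' route of highest information flow.
#'
#' @param mi symmetric normalized MI matrix.
#' @param contactDistances symmetric distance matrix (A).
#' @param distanceCutoff contact gate in Angstrom (default 6.0).
#' @param miThreshold scalar or per-pair matrix MI gate (e.g. from
#'   [miPermutationThreshold()]).
#' @param costCeiling cap on edge costs.
#' @return a [MutualInfoNetwork-class].
#' @export
buildMiGraph <- function(mi, contactDistances, distanceCutoff = 6.0,
                         miThreshold = 0, costCeiling = 20) {
  stopifnot(nrow(mi) == nrow(contactDistances),
            isTRUE(all.equal(mi, t(mi), tolerance = 1e-8)),
            isTRUE(all.equal(contactDistances, t(contactDistances), tolerance = 1e-8)))
  R <- nrow(mi)
  thr <- if (is.matrix(miThreshold)) miThreshold else matrix(miThreshold, R, R)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      if (contactDistances[i, j] < distanceCutoff && mi[i, j] > thr[i, j]) {
        ii <- c(ii, i); jj <- c(jj, j)
      }
    }
  }
  cost <- pmin(-log(pmax(mi[cbind(ii, jj)], exp(-costCeiling))), costCeiling)
  edges <- data.frame(i = ii, j = jj,
                      distance = contactDistances[cbind(ii, jj)],
                      nmi = mi[cbind(ii, jj)], cost = cost)
  g <- igraph::make_empty_graph(n = R, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(R))
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$i, edges$j), cost = edges$cost)
  new("MutualInfoNetwork", nResidues = as.integer(R), mi = mi,
      contactDistances = contactDistances, edges = edges, graph = g,
      distanceCutoff = distanceCutoff, miThreshold = miThreshold)
}

#' Shortest allosteric path between two residues
#'
#' Minimum total path-cost route through the gated residue graph (Dijkstra,
#' via igraph). Returns an explicit no-path result when the residues are
#' disconnected.
#'
#' @param net a [MutualInfoNetwork-class].
#' @param source,target residue indices.
#' @return list with `path` (residue indices, empty when unreachable),
#'   `cost` (Inf when unreachable), `reachable`.
#' @export
shortestAllostericPath <- function(net, source, target) {
  R <- net@nResidues
  if (source < 1 || source > R || target < 1 || target > R)
    stop("source/target residue out of range")
  d <- suppressWarnings(
    igraph::distances(net@graph, v = source, to = target,
                      weights = igraph::E(net@graph)$cost))
  if (!is.finite(d[1, 1]))
    return(list(path = integer(0), cost = Inf, reachable = FALSE))
  sp <- suppressWarnings(
    igraph::shortest_paths(net@graph, from = source, to = target,
                           weights = igraph::E(net@graph)$cost,
                           output = "vpath"))
  path <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  list(path = path, cost = d[1, 1], reachable = TRUE)
}

#' Enumerate all simple paths and their costs (brute-force oracle)
#'
#' Exhaustive check for small graphs: enumerates every simple path between
#' two residues and returns them with total costs, cheapest first.
#'
#' @param net a [MutualInfoNetwork-class] (intended for <= 12 residues).
#' @param source,target residue indices.
#' @return list of lists with `path` and `cost`, sorted by cost.
#' @export
enumerateSimplePaths <- function(net, source, target) {
  ps <- igraph::all_simple_paths(net@graph, from = source, to = target)
  costOf <- function(p) {
    v <- as.integer(igraph::as_ids(p))
    sum(vapply(seq_len(length(v) - 1L), function(k) {
      e <- igraph::get_edge_ids(net@graph, c(v[k], v[k + 1L]))
      igraph::E(net@graph)$cost[e]
    }, numeric(1)))
  }
  out <- lapply(ps, function(p)
    list(path = as.integer(igraph::as_ids(p)), cost = costOf(p)))
  out[order(vapply(out, `[[`, numeric(1), "cost"))]
}
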