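## Internal numerical helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one integer seed through this
#' splitting scheme: child = (seed * 48271 + stream * 9973) mod (2^31 - 1),
#' a Lehmer-style mix keeping every derived seed a valid 32-bit integer.
#' Distinct stream indices give independent, reproducible substreams.
#'
#' @param seed master integer seed.
#' @param stream non-negative integer stream index.
#' @return derived integer seed.
#' @export
deriveSeed <- function(seed, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(stream) * 9973) %% m)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Wrap angles to the half-open interval \[-180, 180)
#'
#' @param a numeric angles in degrees.
#' @return wrapped angles.
#' @export
wrapAngle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w >= 180] <- -180
  w
}

## Leading left eigenvector of a row-stochastic matrix, normalized to sum 1.
statDist <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (min(v) < -1e-8) stop("stationary distribution has negative entries; chain not ergodic?")
  v <- pmax(v, 0)
  v / sum(v)
}

## Sample an n-step state sequence from row-stochastic T (includes the start).
## Uses the cumulative-row rule: with R ~ U[0,1), move to the smallest j with
## R < sum_{k<=j} T[i,k].
sampleStatePath <- function(T, nSteps, start) {
  cum <- t(apply(T, 1, cumsum))
  cum[, ncol(cum)] <- 1 + 1e-12
  s <- integer(nSteps)
  s[1] <- as.integer(start)
  if (nSteps >= 2) {
    u <- runif(nSteps - 1L)
    for (t in 2:nSteps) {
      r <- u[t - 1L]
      row <- cum[s[t - 1L], ]
      j <- 1L
      while (r >= row[j]) j <- j + 1L
      s[t] <- j
    }
  }
  s
}

## Step many walkers of a Markov chain at once; states is an integer vector.
stepWalkers <- function(T, states) {
  K <- nrow(T)
  out <- states
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(K, length(idx), replace = TRUE, prob = T[s, ])
  }
  out
}

## Nearest Euclidean center index for each row of X.
nearestCenter <- function(X, centers) {
  n <- nrow(X)
  cs2 <- rowSums(centers^2)
  ## process in blocks to bound memory for large n
  out <- integer(n)
  block <- 200000L
  for (from in seq(1L, n, by = block)) {
    to <- min(from + block - 1L, n)
    G <- X[from:to, , drop = FALSE] %*% t(centers)
    D <- sweep(-2 * G, 2, cs2, "+")
    out[from:to] <- max.col(-D, ties.method = "first")
  }
  out
}

## Symmetric inverse square root of a positive-definite matrix.
symInvSqrt <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, tol * max(e$values))
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

## Indices of the largest strongly connected component of the directed graph
## with an edge i -> j wherever C[i, j] > 0. Largest by member count; ties
## broken by total counts, then by lowest index.
largestSCC <- function(C) {
  K <- nrow(C)
  A <- (C > 0) * 1
  diag(A) <- pmax(diag(A), 1)  # self-loops never disconnect a state from itself
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    mass <- vapply(cand, function(cc) {
      idx <- which(comp$membership == cc)
      sum(C[idx, idx])
    }, numeric(1))
    cand <- cand[which.max(mass)]
  } else {
    cand <- cand[1]
  }
  sort(which(comp$membership == cand))
}

## Shannon entropy (nats) of a probability vector; zero cells contribute 0.
entropyNats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
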