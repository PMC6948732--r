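# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: straightforward loops and closed forms only.

# Direct running-sum enrichment score over the full ranking (O(N) walk).
oracleES <- function(statSorted, memberLogical, exponent = 1) {
  N <- length(statSorted)
  m <- sum(memberLogical)
  w <- abs(statSorted)^exponent
  NR <- sum(w[memberLogical])
  run <- 0
  maxP <- 0
  minP <- 0
  for (i in seq_len(N)) {
    run <- run + if (memberLogical[i]) w[i] / NR else -1 / (N - m)
    maxP <- max(maxP, run)
    minP <- min(minP, run)
  }
  if (abs(maxP + minP) < 1e-12) 0 else if (maxP > -minP) maxP else minP
}

# All simple paths from `from`, by plain recursion over an adjacency list.
oracleSimplePaths <- function(adj, from) {
  out <- list()
  walk <- function(path) {
    out[[length(out) + 1]] <<- path
    for (nxt in adj[[path[length(path)]]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  walk(from)
  out
}

# Upper-tail hypergeometric P(X >= k) by explicit combinatorial sum.
oracleHyperTail <- function(k, nSuccess, nUniverse, nDraw) {
  js <- k:min(nDraw, nSuccess)
  sum(choose(nSuccess, js) * choose(nUniverse - nSuccess, nDraw - js)) /
    choose(nUniverse, nDraw)
}

# Upper-tail binomial P(X >= k) at p = 1/2 by explicit sum.
oracleBinomTail <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# Reaction adjacency by literal rule application: edge r1 -> r2 iff some
# non-ubiquitous product of r1 is a substrate of r2 and r1 != r2.
oracleReactionEdges <- function(reactions, ubiquitous) {
  edges <- character()
  for (r1 in reactions) for (r2 in reactions) {
    if (r1$id == r2$id) next
    shared <- setdiff(intersect(r1$products, r2$substrates), ubiquitous)
    if (length(shared)) edges <- c(edges, paste(r1$id, r2$id))
  }
  sort(edges)
}

# Small random FeatureMatrix for property tests.
randomFeatureMatrix <- function(nFeat, nPerGroup, seed, missingRate = 0,
                                scale = "log2") {
  set.seed(seed)
  n <- 2 * nPerGroup
  v <- matrix(rnorm(nFeat * n, 10), nFeat, n)
  if (scale == "raw") v <- 2^(v / 2)
  if (missingRate > 0) v[runif(length(v)) < missingRate] <- NA
  dimnames(v) <- list(sprintf("f%03d", seq_len(nFeat)),
                      sprintf("s%02d", seq_len(n)))
  FeatureMatrix(v, groups = rep(c("A", "B"), each = nPerGroup),
                scale = scale)
}
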