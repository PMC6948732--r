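makeChainNetwork <- function(nRxn) {
  mets <- sprintf("m%02d", seq_len(nRxn + 1))
  rxn <- lapply(seq_len(nRxn), function(i)
    list(id = sprintf("R%02d", i), substrates = mets[i],
         products = mets[i + 1], genes = sprintf("g%02d", i)))
  MetabolicNetwork(rxn, data.frame(id = mets, ubiquitous = FALSE))
}

test_that("reaction-graph edges follow the shared-metabolite rule and drop ubiquitous compounds", {
  rxn <- list(
    list(id = "r1", substrates = "a", products = c("b", "w"), genes = "g1"),
    list(id = "r2", substrates = c("b", "w"), products = "c", genes = "g2"),
    list(id = "r3", substrates = "w", products = "d", genes = "g3"))
  net <- MetabolicNetwork(rxn, data.frame(id = c("a", "b", "c", "d", "w"),
                                          ubiquitous = c(F, F, F, F, T)))
  g <- buildReactionGraph(net)@graph
  el <- igraph::as_edgelist(g)
  # only r1 -> r2 via b; the ubiquitous w creates no edge (r1->r3 absent)
  expect_equal(nrow(el), 1)
  expect_equal(unname(el[1, ]), c("r1", "r2"))
  # flagging b too removes the last edge
  g2 <- buildReactionGraph(net, extraUbiquitous = "b")@graph
  expect_equal(igraph::ecount(g2), 0)
})

test_that("reaction-graph adjacency matches brute-force enumeration on random toy networks", {
  for (seed in 1:5) {
    set.seed(seed)
    mets <- sprintf("m%02d", 1:10)
    ubiq <- sample(mets, 2)
    rxn <- lapply(1:12, function(i)
      list(id = sprintf("r%02d", i),
           substrates = sample(mets, sample(1:2, 1)),
           products = sample(mets, sample(1:2, 1)),
           genes = sprintf("g%02d", i)))
    net <- MetabolicNetwork(rxn, data.frame(id = mets,
                                            ubiquitous = mets %in% ubiq))
    g <- buildReactionGraph(net)@graph
    el <- igraph::as_edgelist(g)
    got <- sort(paste(el[, 1], el[, 2]))
    expect_identical(got, oracleReactionEdges(rxn, ubiq))
  }
})

test_that("edge weights hit 1 for duplicated expression and need 3 samples per group", {
  net <- makeChainNetwork(3)
  rg <- buildReactionGraph(net)
  set.seed(71)
  base <- rnorm(8)
  v <- rbind(g01 = base, g02 = base, g03 = rnorm(8))
  colnames(v) <- sprintf("s%d", 1:8)
  expr <- FeatureMatrix(v, groups = rep(c("A", "B"), each = 4),
                        scale = "log2")
  w <- weightEdges(rg, expr, groups = "A")
  el <- igraph::as_edgelist(w@graph)
  wA <- igraph::edge_attr(w@graph, "weight_A")
  expect_equal(wA[el[, 1] == "R01" & el[, 2] == "R02"], 1.0)

  tiny <- FeatureMatrix(v[, 1:4], groups = c("A", "A", "B", "B"),
                        scale = "log2")
  expect_error(weightEdges(rg, tiny, groups = "A"), "< 3 samples")
})

test_that("unmeasured reactions get the group median weight and a flag", {
  net <- makeChainNetwork(4)
  rg <- buildReactionGraph(net)
  set.seed(72)
  v <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(c("g01", "g02", "g03"), sprintf("s%d", 1:6)))
  expr <- FeatureMatrix(v, groups = rep("A", 6), scale = "log2")
  w <- weightEdges(rg, expr, groups = "A")
  flags <- igraph::edge_attr(w@graph, "unmeasured_A")
  wA <- igraph::edge_attr(w@graph, "weight_A")
  el <- igraph::as_edgelist(w@graph)
  unm <- el[, 2] == "R04"  # g04 is not in the expression matrix
  expect_true(all(flags[unm]))
  expect_equal(wA[unm], rep(median(wA[!unm]), sum(unm)))
})

test_that("null expression keeps most edge weights small", {
  net <- generateToyNetwork(20, 36, 40, 0, seed = 4)
  rg <- buildReactionGraph(net)
  set.seed(73)
  genes <- sort(unique(unlist(lapply(net@reactions, `[[`, "genes"))))
  v <- matrix(rnorm(length(genes) * 60), length(genes), 60,
              dimnames = list(genes, sprintf("s%02d", 1:60)))
  expr <- FeatureMatrix(v, groups = rep("A", 60), scale = "log2")
  w <- weightEdges(rg, expr, groups = "A")
  wA <- igraph::edge_attr(w@graph, "weight_A")
  expect_gte(mean(abs(wA) < 0.5), 0.95)
})

test_that("path extraction boundary: a 7-reaction chain qualifies, a 6-reaction chain does not", {
  rg7 <- buildReactionGraph(makeChainNetwork(7))
  v <- matrix(rnorm(7 * 6), 7, 6,
              dimnames = list(sprintf("g%02d", 1:7), sprintf("s%d", 1:6)))
  expr <- FeatureMatrix(v, groups = rep("A", 6), scale = "log2")
  w7 <- weightEdges(rg7, expr, groups = "A")
  ps <- extractTopPaths(w7, "A", k = 50, minLength = 6)
  expect_equal(length(ps), 1)
  expect_identical(ps@paths[[1]], sprintf("R%02d", 1:7))
  expect_equal(ps@length, 6L)

  rg6 <- buildReactionGraph(makeChainNetwork(6))
  w6 <- weightEdges(rg6, expr[1:6, ], groups = "A")
  expect_warning(ps6 <- extractTopPaths(w6, "A", k = 50, minLength = 6),
                 "no path")
  expect_equal(length(ps6), 0)
})

test_that("top-k paths match exhaustive enumeration on small random graphs", {
  for (seed in 1:10) {
    net <- generateToyNetwork(12, 28, 24, 0, seed = seed)
    rg <- buildReactionGraph(net)
    set.seed(seed + 500)
    genes <- sort(unique(unlist(lapply(net@reactions, `[[`, "genes"))))
    v <- matrix(rnorm(length(genes) * 8), length(genes), 8,
                dimnames = list(genes, sprintf("s%d", 1:8)))
    expr <- FeatureMatrix(v, groups = rep("A", 8), scale = "log2")
    w <- weightEdges(rg, expr, groups = "A")
    got <- extractTopPaths(w, "A", k = 5, minLength = 3)

    # oracle: recursive DFS from every vertex, keep source->sink simple
    # paths with >= 3 edges, score by mean edge weight
    g <- w@graph
    el <- igraph::as_edgelist(g)
    wts <- igraph::edge_attr(g, "weight_A")
    adj <- lapply(setNames(igraph::V(g)$name, igraph::V(g)$name),
                  function(nd) el[el[, 1] == nd, 2])
    sources <- igraph::V(g)$name[igraph::degree(g, mode = "in") == 0]
    sinks <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
    cand <- list()
    for (s in sources) cand <- c(cand, oracleSimplePaths(adj, s))
    cand <- cand[vapply(cand, function(p)
      length(p) >= 4 && p[length(p)] %in% sinks, logical(1))]
    scores <- vapply(cand, function(p) {
      mean(vapply(seq_len(length(p) - 1), function(i)
        wts[which(el[, 1] == p[i] & el[, 2] == p[i + 1])], numeric(1)))
    }, numeric(1))
    ord <- order(-scores, vapply(cand, paste, character(1),
                                 collapse = "\r"))
    top <- ord[seq_len(min(5, length(ord)))]
    expect_equal(length(got), length(top))
    for (i in seq_along(top)) {
      expect_identical(got@paths[[i]], cand[[top[i]]])
      expect_equal(got@score[i], scores[top[i]], tolerance = 1e-12)
    }
  }
})

test_that("EM training is deterministic and its objective never decreases", {
  net <- generateToyNetwork(30, 46, 60, 0.1, seed = 2)
  lay <- attr(net, "layout")
  rg <- buildReactionGraph(net)
  d <- cohortDesign(30)
  ex <- generateExpressionForPaths(
    net, d, list(RRMM = list(lay$chain_a), NDMM = list(lay$chain_b)),
    correlation = 0.9, seed = 12)
  w <- weightEdges(rg, ex$matrix, c("RRMM", "NDMM"))
  both <- combinePathSets(extractTopPaths(w, "RRMM", k = 10, minLength = 6),
                          extractTopPaths(w, "NDMM", k = 10, minLength = 6))
  m1 <- trainPathClassifier(both, seed = 9)
  m2 <- trainPathClassifier(both, seed = 9)
  expect_identical(m1@components, m2@components)
  expect_identical(m1@mixtureWeights, m2@mixtureWeights)
  expect_true(all(diff(m1@objective) > -1e-8))
  expect_true(all(diff(m1@logLik) > -1e-6))
  expect_true(validObject(m1))
  # single condition refused
  onlyA <- extractTopPaths(w, "RRMM", k = 10, minLength = 6)
  expect_error(trainPathClassifier(onlyA), "two conditions")
})

test_that("paths from one distribution give near-chance posteriors, disjoint alphabets separate perfectly", {
  # same-distribution null: structureless uniform simple paths on a common
  # alphabet, arbitrary labels -> held-out posteriors near 0.5
  set.seed(81)
  alpha <- sprintf("N%02d", 1:15)
  rw <- function() sample(alpha, 7)
  mkSet <- function(n, cond) methods::new(
    "MetabolicPathSet",
    paths = replicate(n, rw(), simplify = FALSE),
    score = rep(0.5, n), length = rep(6L, n),
    condition = rep(cond, n))
  train <- combinePathSets(mkSet(25, "A"), mkSet(25, "B"))
  test <- combinePathSets(mkSet(20, "A"), mkSet(20, "B"))
  m <- trainPathClassifier(train, seed = 3)
  cl <- classifyPaths(m, test)
  expect_lt(abs(mean(cl$posterior) - 0.5), 0.1)

  # disjoint alphabets: training-set classification is perfect
  a1 <- sprintf("X%02d", 1:7)
  a2 <- sprintf("Y%02d", 1:7)
  disj <- combinePathSets(
    methods::new("MetabolicPathSet",
                 paths = replicate(8, sample(a1), simplify = FALSE),
                 score = rep(1, 8), length = rep(6L, 8),
                 condition = rep("A", 8)),
    methods::new("MetabolicPathSet",
                 paths = replicate(8, sample(a2), simplify = FALSE),
                 score = rep(1, 8), length = rep(6L, 8),
                 condition = rep("B", 8)))
  md <- trainPathClassifier(disj, seed = 5)
  cld <- classifyPaths(md, disj)
  expect_equal(cld$auc, 1.0)
  aucs <- sort(vapply(cld$components, `[[`, numeric(1), "auc"))
  expect_equal(aucs, c(0, 1))
})

test_that("AUC agrees with the pROC reference and label shuffles give chance AUC", {
  set.seed(91)
  score <- rnorm(60)
  labels <- score + rnorm(60) > 0
  r <- mmomics:::.roc(score, labels)
  ref <- pROC::auc(pROC::roc(response = as.integer(labels),
                             predictor = score, levels = c(0, 1),
                             direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)

  shuffled <- replicate(20, mmomics:::.roc(score, sample(labels))$auc)
  expect_lt(abs(mean(shuffled) - 0.5), 0.1)
})

test_that("subnetwork labels partition the edge union by exclusivity", {
  mkPaths <- function(paths, cond) methods::new(
    "MetabolicPathSet", paths = paths,
    score = rep(1, length(paths)),
    length = vapply(paths, length, integer(1)) - 1L,
    condition = rep(cond, length(paths)))
  # A edges {e1: r1->r2, e2: r2->r3, e3: r3->r4}; B edges {e3, e4: r4->r5}
  pa <- mkPaths(list(c("r1", "r2", "r3", "r4")), "A")
  pb <- mkPaths(list(c("r3", "r4", "r5")), "B")
  sn <- extractSubnetwork(pa, pb)
  st <- igraph::edge_attr(sn$graph, "status")
  el <- igraph::as_edgelist(sn$graph)
  key <- paste(el[, 1], el[, 2])
  expect_setequal(key[st == "exclusive_A"], c("r1 r2", "r2 r3"))
  expect_setequal(key[st == "exclusive_B"], c("r4 r5"))
  expect_setequal(key[st == "shared"], c("r3 r4"))
  expect_equal(sn$counts$edges,
               sn$counts$exclusive_A + sn$counts$exclusive_B +
                 sn$counts$shared)
  # disjoint and identical path sets
  expect_equal(extractSubnetwork(pa, pa)$counts$shared, 3)
  pc <- mkPaths(list(c("x1", "x2", "x3")), "B")
  expect_equal(extractSubnetwork(pa, pc)$counts$shared, 0)
})

test_that("differential projection labels nodes and reports coverage", {
  mkPaths <- function(paths, cond) methods::new(
    "MetabolicPathSet", paths = paths,
    score = rep(1, length(paths)),
    length = vapply(paths, length, integer(1)) - 1L,
    condition = rep(cond, length(paths)))
  sn <- extractSubnetwork(mkPaths(list(c("r1", "r2", "r3")), "A"),
                          mkPaths(list(c("r2", "r3", "r4")), "B"))
  diff <- data.frame(feature_id = c("p1", "p2"),
                     logFC = c(2, -1),
                     significant_raw = c(TRUE, FALSE))
  geneMap <- data.frame(gene = c("gA", "gB"), feature_id = c("p1", "p2"))
  reactionGenes <- list(r1 = "gA", r2 = "gB", r3 = "gZ")
  proj <- projectDifferential(sn, diff, geneMap, reactionGenes)
  expect_identical(unname(proj$regulation["r1"]), "up")
  expect_identical(unname(proj$regulation["r2"]), "undetected") # not significant
  expect_identical(unname(proj$regulation["r3"]), "undetected") # unmapped gene
  expect_identical(unname(proj$regulation["r4"]), "undetected") # no genes
  expect_equal(proj$coverage, 2 / 4)

  empty <- projectDifferential(sn, diff,
                               data.frame(gene = character(),
                                          feature_id = character()),
                               reactionGenes)
  expect_true(all(empty$regulation == "undetected"))
})

test_that("network JSON and graph exports round-trip", {
  net <- generateToyNetwork(10, 24, 20, 0.2, seed = 6)
  f <- tempfile(fileext = ".json")
  writeMetabolicNetwork(net, f)
  back <- readMetabolicNetwork(f)
  expect_identical(names(back@reactions), names(net@reactions))
  expect_identical(back@metabolites$ubiquitous, net@metabolites$ubiquitous)
  expect_identical(back@reactions[[3]]$substrates,
                   net@reactions[[3]]$substrates)

  rg <- buildReactionGraph(net)
  sif <- tempfile(fileext = ".sif")
  writeSif(rg@graph, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(rg@graph))
  expect_true(all(grepl("\t", lines)))
  gml <- tempfile(fileext = ".graphml")
  writeGraphml(rg@graph, gml)
  expect_true(file.exists(gml))
})
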