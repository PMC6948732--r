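test_that("generators are bit-identical under a fixed seed", {
  d <- cohortDesign(4)
  nm <- noiseModel(seed = 13)
  a <- generateLipidomicsCohort(d, list(plantedEffect("PC", -2, "RRMM")), nm)
  b <- generateLipidomicsCohort(d, list(plantedEffect("PC", -2, "RRMM")), nm)
  expect_identical(intensities(a$matrix), intensities(b$matrix))
  expect_identical(a$truth, b$truth)

  pa <- generateProteomicsCohort(d, noise = nm, nProteins = 40)
  pb <- generateProteomicsCohort(d, noise = nm, nProteins = 40)
  expect_identical(intensities(pa$table), intensities(pb$table))
  expect_identical(SummarizedExperiment::rowData(pa$table),
                   SummarizedExperiment::rowData(pb$table))

  na <- generateToyNetwork(12, 28, 24, 0.1, seed = 2)
  nb <- generateToyNetwork(12, 28, 24, 0.1, seed = 2)
  expect_identical(na@reactions, nb@reactions)

  ea <- generateExpressionForPaths(na, d, list(RRMM = list(
    attr(na, "layout")$chain_a)), 0.5, seed = 3)
  eb <- generateExpressionForPaths(nb, d, list(RRMM = list(
    attr(nb, "layout")$chain_a)), 0.5, seed = 3)
  expect_identical(intensities(ea$matrix), intensities(eb$matrix))
})

test_that("no-effect, no-noise limit leaves only dilution differences", {
  d <- cohortDesign(3)
  nm <- noiseModel(featureSd = 0, mnarThresholdQuantile = 0, marRate = 0,
                   seed = 4)
  lc <- generateLipidomicsCohort(d, effects = list(), noise = nm)
  v <- intensities(lc$matrix)
  undiluted <- sweep(log2(v), 2, lc$truth$dilution_log2, "-")
  expect_lt(max(apply(undiluted, 1, function(r) diff(range(r)))), 1e-10)
})

test_that("planted class effects are recovered by group-mean differences", {
  d <- cohortDesign(20)
  lfc <- -2
  lc <- generateLipidomicsCohort(
    d, list(plantedEffect("PC", lfc, "RRMM")),
    noiseModel(mnarThresholdQuantile = 0, marRate = 0, seed = 19))
  v <- log2(intensities(lc$matrix))
  v <- sweep(v, 2, lc$truth$dilution_log2, "-")
  grp <- groupLabels(lc$matrix)
  planted <- unique(lc$truth$effects$feature)
  expect_gt(length(planted), 0)
  dif <- rowMeans(v[planted, grp == "RRMM", drop = FALSE]) -
    rowMeans(v[planted, grp == "NDMM", drop = FALSE])
  se <- noiseModel()$featureSd * sqrt(1 / 20 + 1 / 20)
  expect_true(all(abs(dif - lfc) <= 3 * se))
  # unknown selector errors with its name
  expect_error(generateLipidomicsCohort(
    d, list(plantedEffect("NOPE", 1, "RRMM")), noiseModel(seed = 1)),
    "NOPE")
})

test_that("degenerate missingness rates give a complete proteomics table", {
  d <- cohortDesign(4)
  pc <- generateProteomicsCohort(
    d, noise = noiseModel(mnarThresholdQuantile = 0, marRate = 0,
                          seed = 23), nProteins = 30)
  expect_false(anyNA(intensities(pc$table)))
  expect_error(generateProteomicsCohort(cohortDesign(2), nProteins = 5),
               "nProteins")
})

test_that("censored missingness concentrates in low-abundance proteins", {
  d <- cohortDesign(10)
  pc <- generateProteomicsCohort(
    d, noise = noiseModel(mnarThresholdQuantile = 0.15, marRate = 0,
                          seed = 29), nProteins = 120)
  nMiss <- rowSums(is.na(intensities(pc$table)))
  rho <- cor(pc$truth$baseline, nMiss, method = "spearman")
  expect_lt(rho, -0.5)
  # masks partition the missing cells exactly
  expect_true(all(xor(pc$truth$mar_mask, pc$truth$mnar_mask) ==
                    (pc$truth$mar_mask | pc$truth$mnar_mask)))
  expect_identical(unname(pc$truth$mar_mask | pc$truth$mnar_mask),
                   unname(is.na(intensities(pc$table))))
})

test_that("toy networks honour the ubiquitous fraction and admit a long path", {
  net0 <- generateToyNetwork(12, 28, 24, 0, seed = 5)
  expect_equal(sum(net0@metabolites$ubiquitous), 0)
  expect_true(validObject(net0))

  net <- generateToyNetwork(30, 46, 60, 0.15, seed = 5)
  expect_gt(sum(net@metabolites$ubiquitous), 0)
  # exhaustive search certifies a simple reaction path of >= 6 edges
  g <- buildReactionGraph(net)@graph
  el <- igraph::as_edgelist(g)
  adj <- lapply(setNames(igraph::V(g)$name, igraph::V(g)$name),
                function(nd) el[el[, 1] == nd, 2])
  srcs <- igraph::V(g)$name[igraph::degree(g, mode = "in") == 0]
  best <- 0
  for (s in srcs) {
    lens <- vapply(oracleSimplePaths(adj, s), length, integer(1))
    best <- max(best, max(lens) - 1)
  }
  expect_gte(best, 6)
  expect_error(generateToyNetwork(5, 20, 20, 0, seed = 1), "nReactions")
})

test_that("expression generation plants group-specific on-path correlation", {
  net <- generateToyNetwork(30, 46, 60, 0.1, seed = 7)
  lay <- attr(net, "layout")
  d <- cohortDesign(60)
  ex <- generateExpressionForPaths(
    net, d, list(RRMM = list(lay$chain_a)), correlation = 0.9, seed = 31)
  v <- intensities(ex$matrix)
  grp <- groupLabels(ex$matrix)
  genesOf <- lapply(net@reactions, `[[`, "genes")
  adjPairs <- do.call(rbind, lapply(seq_len(7), function(i)
    expand.grid(g1 = genesOf[[lay$chain_a[i]]],
                g2 = genesOf[[lay$chain_a[i + 1]]],
                stringsAsFactors = FALSE)))
  corIn <- mapply(function(a, b)
    cor(v[a, grp == "RRMM"], v[b, grp == "RRMM"]),
    adjPairs$g1, adjPairs$g2)
  corOut <- mapply(function(a, b)
    cor(v[a, grp == "NDMM"], v[b, grp == "NDMM"]),
    adjPairs$g1, adjPairs$g2)
  expect_lt(abs(mean(corIn) - 0.9), 0.1)
  expect_lt(mean(abs(corOut)), 0.2)

  # off-path genes stay uncorrelated
  off <- setdiff(rownames(v), ex$truth$active_genes$RRMM)
  set.seed(1)
  pick <- sample(off, 12)
  cc <- cor(t(v[pick, grp == "RRMM"]))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.2)

  # zero correlation: adjacent-pair correlations centre at 0
  ex0 <- generateExpressionForPaths(
    net, d, list(RRMM = list(lay$chain_a)), correlation = 0, seed = 32)
  v0 <- intensities(ex0$matrix)
  cor0 <- mapply(function(a, b)
    cor(v0[a, grp == "RRMM"], v0[b, grp == "RRMM"]),
    adjPairs$g1, adjPairs$g2)
  expect_lt(abs(mean(cor0)), 0.15)

  expect_error(generateExpressionForPaths(
    net, d, list(RRMM = list(lay$chain_a)), correlation = 1), "correlation")
  expect_error(generateExpressionForPaths(
    net, d, list(RRMM = list(c("R001", "missing"))), 0.5), "unknown")
})

test_that("lipid truth tables record the exact missingness partition", {
  d <- cohortDesign(6)
  lc <- generateLipidomicsCohort(
    d, list(), noiseModel(mnarThresholdQuantile = 0.1, marRate = 0.05,
                          seed = 37))
  tr <- lc$truth
  expect_false(any(tr$mar_mask & tr$mnar_mask))
  expect_identical(unname(tr$mar_mask | tr$mnar_mask),
                   unname(missingMask(lc$matrix)))
})
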