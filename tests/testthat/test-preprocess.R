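test_that("presence filter keeps a feature iff one group reaches the threshold", {
  v <- matrix(NA_real_, 2, 7,
              dimnames = list(c("kept", "dropped"),
                              sprintf("s%d", 1:7)))
  # kept: 3 of 4 in A (= 0.75, inclusive), 0 of 3 in B
  v["kept", 1:3] <- 5
  # dropped: 2/4 in A and 2/3 in B, both below 0.75
  v["dropped", c(1, 2, 5, 6)] <- 5
  fm <- FeatureMatrix(v, groups = c(rep("A", 4), rep("B", 3)))
  out <- filterByPresence(fm, 0.75)
  expect_identical(rownames(out), "kept")
})

test_that("presence filter matches brute-force rule application and is idempotent", {
  set.seed(11)
  fm <- randomFeatureMatrix(10, 4, seed = 11, missingRate = 0.4)
  out <- filterByPresence(fm, 0.75)
  v <- intensities(fm)
  grp <- groupLabels(fm)
  expected <- rownames(v)[vapply(seq_len(nrow(v)), function(i) {
    any(vapply(unique(grp), function(g)
      mean(!is.na(v[i, grp == g])) >= 0.75, logical(1)))
  }, logical(1))]
  expect_identical(rownames(out), expected)
  expect_identical(intensities(filterByPresence(out, 0.75)),
                   intensities(out))
})

test_that("quantile normalization maps samples onto the mean quantile profile", {
  fm <- FeatureMatrix(matrix(c(1, 3, 5, 7), 2,
                             dimnames = list(c("f1", "f2"), c("a", "b"))),
                      groups = c("A", "A"), scale = "log2")
  out <- intensities(quantileNormalize(fm))
  expect_equal(unname(out[, "a"]), c(3, 5))
  expect_equal(unname(out[, "b"]), c(3, 5))

  # identical columns are a fixed point
  v <- matrix(rep(c(2, 4, 9), 3), 3)
  fm2 <- FeatureMatrix(v, groups = c("A", "A", "B"), scale = "log2")
  expect_equal(intensities(quantileNormalize(fm2)), intensities(fm2),
               ignore_attr = TRUE)
})

test_that("complete columns share sorted values after quantile normalization", {
  fm <- randomFeatureMatrix(60, 5, seed = 3)
  v <- intensities(fm)
  # missing cells only in columns 3+, so columns 1-2 stay complete
  naIdx <- cbind(sample(nrow(v), 40, replace = TRUE),
                 sample(3:ncol(v), 40, replace = TRUE))
  v[naIdx] <- NA
  fm <- FeatureMatrix(v, groups = groupLabels(fm), scale = "log2")
  out <- intensities(quantileNormalize(fm))
  complete <- which(colSums(is.na(out)) == 0)
  expect_gte(length(complete), 2)
  ref <- sort(out[, complete[1]])
  for (j in complete[-1])
    expect_lt(max(abs(sort(out[, j]) - ref)), 1e-12)

  vAllNA <- v; vAllNA[, 3] <- NA
  expect_error(quantileNormalize(
    FeatureMatrix(vAllNA, groups = groupLabels(fm), scale = "log2")),
    "all-missing")
})

test_that("PQN removes a pure dilution and fixes identical samples", {
  ref <- c(4, 8, 2, 6, 10)
  # median spectrum of (ref, ref, 2*ref) is ref, so the doubled sample maps
  # back onto the reference exactly
  v <- cbind(a = ref, b = ref, doubled = ref * 2)
  fm <- FeatureMatrix(v, groups = c("A", "A", "B"), scale = "raw")
  out <- intensities(pqnNormalize(fm))
  expect_equal(unname(out[, "doubled"]), ref)
  expect_equal(unname(out[, "a"]), ref)

  v2 <- cbind(ref, ref, ref)
  fm2 <- FeatureMatrix(v2, groups = c("A", "A", "B"), scale = "raw")
  expect_equal(unname(intensities(pqnNormalize(fm2))), unname(v2))
})

test_that("PQN recovers planted dilution factors within 2%", {
  # injection-variation setting: a targeted-panel-sized catalog with
  # near-proportional spectra (small residual noise), dilution the
  # dominant difference
  panel <- unlist(lapply(
    c("PC", "PE", "PI", "PG", "PS", "SM", "Cer", "HexCer", "LPC", "LPE"),
    function(cl) sprintf("%s %d:%d", cl, 28:58, (28:58) %% 7)))
  d <- cohortDesign(10)
  lc <- generateLipidomicsCohort(
    d, effects = list(),
    noise = noiseModel(featureSd = 0.1, sampleDilutionSd = 0.8,
                       mnarThresholdQuantile = 0, marRate = 0, seed = 5),
    lipidCatalog = panel)
  out <- pqnNormalize(lc$matrix)
  est <- S4Vectors::metadata(out)$pqn_factors
  truth <- 2^lc$truth$dilution_log2
  # factors are identified up to a common scale; compare after geometric-mean
  # normalization
  est <- est / exp(mean(log(est)))
  truth <- truth / exp(mean(log(truth)))
  expect_lt(max(abs(est / truth - 1)), 0.02)
})

test_that("log2 transform is exact, keeps missing cells and refuses zeros", {
  v <- matrix(c(8, 1, NA, 4), 2,
              dimnames = list(c("f1", "f2"), c("a", "b")))
  fm <- FeatureMatrix(v, groups = c("A", "A"))
  out <- log2Transform(fm)
  expect_equal(unname(intensities(out)[, "a"]), c(3, 0))
  expect_true(is.na(intensities(out)["f1", "b"]))
  expect_identical(scaleFlag(out), "log2")

  vz <- v; vz[2, 2] <- 0
  expect_error(log2Transform(FeatureMatrix(vz, groups = c("A", "A"))),
               "zero or negative")
})

test_that("minimum imputation fills exactly the missing cells with the matrix minimum", {
  v <- matrix(c(5, 9, NA, 7, NA, 12), 2)
  fm <- FeatureMatrix(v, groups = c("A", "A", "B"), scale = "log2")
  out <- imputeMinimum(fm)
  expect_equal(sum(intensities(out) == 5), 3)  # min itself + two imputed
  expect_identical(S4Vectors::metadata(out)$imputed_cells, 2L)
  expect_false(anyNA(intensities(out)))
  # observed cells untouched; no-missing input is identity
  expect_equal(intensities(out)[!is.na(v)], v[!is.na(v)],
               ignore_attr = TRUE)
  expect_equal(intensities(imputeMinimum(out)), intensities(out))
})

test_that("protein filter applies >=2 peptides, >5 score, then presence", {
  v <- matrix(10, 4, 4, dimnames = list(sprintf("p%d", 1:4),
                                        sprintf("s%d", 1:4)))
  pt <- ProteinTable(v, groups = c("A", "A", "B", "B"),
                     unique_peptides = c(2, 2, 1, 3),
                     score = c(5.0, 5.1, 9, 8))
  out <- filterProteins(pt)
  # p1 dropped (score not > 5), p3 dropped (1 peptide)
  expect_identical(rownames(out), c("p2", "p4"))
})

test_that("protein filter count matches hand enumeration on a synthetic table", {
  d <- cohortDesign(6)
  pc <- generateProteomicsCohort(d, noise = noiseModel(seed = 9),
                                 nProteins = 80)
  out <- filterProteins(pc$table)
  rd <- SummarizedExperiment::rowData(pc$table)
  v <- intensities(pc$table)
  grp <- groupLabels(pc$table)
  byHand <- rownames(v)[vapply(seq_len(nrow(v)), function(i) {
    rd$unique_peptides[i] >= 2 && rd$score[i] > 5 &&
      any(vapply(unique(grp), function(g)
        mean(!is.na(v[i, grp == g])) >= 0.75, logical(1)))
  }, logical(1))]
  expect_identical(rownames(out), byHand)
})

test_that("proteomics imputation: LLS beats minimum-value imputation under MAR masking", {
  set.seed(21)
  # correlated proteins via shared latent factors, n = 20 samples
  n <- 20; nProt <- 60
  fac <- matrix(rnorm(3 * n), 3, n)
  load <- matrix(rnorm(nProt * 3), nProt, 3)
  truth <- 14 + load %*% fac + matrix(rnorm(nProt * n, 0, 0.3), nProt, n)
  dimnames(truth) <- list(sprintf("p%02d", 1:nProt), sprintf("s%02d", 1:n))
  masked <- truth
  # mask 10% of the cells of 15 target proteins (stays below the MAR cutoff)
  targets <- 1:15
  idx <- cbind(rep(targets, each = 2),
               as.vector(replicate(length(targets), sample(n, 2))))
  masked[idx] <- NA
  fm <- FeatureMatrix(masked, groups = rep(c("A", "B"), each = n / 2),
                      scale = "log2")
  out <- imputeProteomics(fm, seed = 1)
  meta <- S4Vectors::metadata(out)$imputation
  expect_identical(meta$mar_method, "lls")
  expect_setequal(meta$mar_proteins, rownames(truth)[targets])
  rmseLLS <- sqrt(mean((intensities(out)[idx] - truth[idx])^2))
  rmseMin <- sqrt(mean((min(masked, na.rm = TRUE) - truth[idx])^2))
  expect_lt(rmseLLS, rmseMin)
  # observed cells are never altered
  obs <- !is.na(masked)
  expect_equal(intensities(out)[obs], masked[obs])
})

test_that("proteomics imputation: censored draws centre at the matrix minimum", {
  set.seed(8)
  v <- matrix(rnorm(40 * 12, 20, 2), 40, 12,
              dimnames = list(sprintf("p%02d", 1:40), sprintf("s%02d", 1:12)))
  v[1:5, 1:6] <- NA  # 50% missing -> censored branch
  fm <- FeatureMatrix(v, groups = rep(c("A", "B"), each = 6),
                      scale = "log2")
  out <- imputeProteomics(fm, mnarSdFactor = 0.3, seed = 4)
  meta <- S4Vectors::metadata(out)$imputation
  expect_setequal(meta$mnar_proteins, sprintf("p%02d", 1:5))
  imput <- intensities(out)[1:5, 1:6]
  s <- 0.3 * sd(v, na.rm = TRUE)
  se <- s / sqrt(length(imput))
  expect_lt(abs(mean(imput) - min(v, na.rm = TRUE)), 3 * se)
  # same seed reproduces the draws
  out2 <- imputeProteomics(fm, mnarSdFactor = 0.3, seed = 4)
  expect_identical(intensities(out), intensities(out2))
})
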