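#' Two-group cohort design
#'
#' @param nPerGroup integer(2) (or integer(1), recycled): samples per group.
#' @param groups character(2) distinct group labels, default
#'   `c("RRMM", "NDMM")`.
#' @return list with `sample_ids`, `group_of`, `n_per_group`.
#' @export
cohortDesign <- function(nPerGroup, groups = c("RRMM", "NDMM")) {
  if (length(groups) != 2 || anyDuplicated(groups))
    stop("exactly two distinct group labels required")
  nPerGroup <- rep(as.integer(nPerGroup), length.out = 2)
  if (any(nPerGroup < 2)) stop("need >= 2 samples per group")
  ids <- unlist(lapply(1:2, function(i)
    sprintf("%s_%02d", groups[i], seq_len(nPerGroup[i]))))
  structure(list(sample_ids = ids,
                 group_of = setNames(rep(groups, nPerGroup), ids),
                 n_per_group = setNames(nPerGroup, groups)),
            class = "cohortDesign")
}

#' Noise model for synthetic cohorts
#'
#' Log-normal intensity model on the log2 scale: per-feature baselines
#' spread around `baseLog2Mean`, additive feature-level residual noise,
#' multiplicative per-sample dilution (log-normal), left-censoring (MNAR)
#' below a global intensity quantile plus uniform random (MAR) missingness.
#'
#' @param baseLog2Mean grand mean of log2 intensities, default 20.
#' @param featureSd residual sd on the log2 scale, default 0.5.
#' @param featureMeanSd sd of per-feature baselines, default 2.
#' @param sampleDilutionSd sd of per-sample log2 dilution factors,
#'   default 0.5.
#' @param mnarThresholdQuantile global intensity quantile below which values
#'   are censored, default 0.05.
#' @param marRate uniform missingness rate, default 0.02.
#' @param seed integer seed.
#' @return list of class `noiseModel`.
#' @export
noiseModel <- function(baseLog2Mean = 20, featureSd = 0.5,
                       featureMeanSd = 2, sampleDilutionSd = 0.5,
                       mnarThresholdQuantile = 0.05, marRate = 0.02,
                       seed = 1L) {
  if (mnarThresholdQuantile < 0 || mnarThresholdQuantile > 1)
    stop("mnarThresholdQuantile must be in [0, 1]")
  if (marRate < 0 || marRate > 1) stop("marRate must be in [0, 1]")
  if (featureSd < 0 || sampleDilutionSd < 0 || featureMeanSd < 0)
    stop("sds must be non-negative")
  structure(list(baseLog2Mean = baseLog2Mean, featureSd = featureSd,
                 featureMeanSd = featureMeanSd,
                 sampleDilutionSd = sampleDilutionSd,
                 mnarThresholdQuantile = mnarThresholdQuantile,
                 marRate = marRate, seed = as.integer(seed)),
            class = "noiseModel")
}

#' A planted differential effect
#'
#' @param targetSelector a lipid class name (matched against the parsed
#'   catalog), a character vector of feature ids (`kind = "features"`), or a
#'   path id (`kind = "path"`).
#' @param log2FoldChange effect added to the affected group's log2 means.
#' @param affectedGroup group label receiving the effect.
#' @param kind `"class"`, `"features"` or `"path"`.
#' @return list of class `plantedEffect`.
#' @export
plantedEffect <- function(targetSelector, log2FoldChange, affectedGroup,
                          kind = c("class", "features", "path")) {
  structure(list(targetSelector = targetSelector,
                 log2FoldChange = log2FoldChange,
                 affectedGroup = affectedGroup,
                 kind = match.arg(kind)),
            class = "plantedEffect")
}

# default targeted-panel-like catalog: the classes of a typical three-method
# targeted acquisition (Cer/PC/SM; PC-O/PC-P/HexCer/LPE/LPC; PE/PE-O/PE-P/PI/PG)
defaultLipidCatalog <- function() {
  classes <- c("Cer", "PC", "SM", "PC-O", "PC-P", "HexCer", "LPE", "LPC",
               "PE", "PE-O", "PE-P", "PI", "PG")
  unlist(lapply(classes, function(cl) {
    carbons <- seq(30, 40, by = 2)
    if (cl %in% c("LPE", "LPC")) carbons <- seq(16, 22, by = 2)
    if (cl %in% c("Cer", "SM", "HexCer")) carbons <- seq(32, 42, by = 2)
    vapply(carbons, function(cb)
      sprintf("%s %d:%d", cl, cb, (cb %% 6)), character(1))
  }))
}

.resolveSelector <- function(effect, catalog) {
  if (effect$kind == "features") {
    hit <- intersect(effect$targetSelector, catalog$raw_name)
  } else if (effect$kind == "class") {
    hit <- catalog$raw_name[catalog$lipid_class %in% effect$targetSelector]
  } else {
    stop("path effects apply to expression generation, not lipid cohorts")
  }
  if (!length(hit))
    stop("planted-effect selector matched no catalog entry: ",
         paste(effect$targetSelector, collapse = ", "))
  hit
}

#' Generate a synthetic lipidomics cohort with planted class effects
#'
#' Draws log2 intensities from the noise model, adds each planted effect to
#' the affected group's features, applies per-sample multiplicative dilution
#' factors, exponentiates to the raw scale, then censors below the global
#' MNAR quantile and adds uniform MAR missingness. The truth table records
#' baselines, planted effects, dilution factors and the exact MAR/MNAR
#' missingness partition.
#'
#' @param design a [cohortDesign()].
#' @param effects list of [plantedEffect()]s (class or feature selectors).
#' @param noise a [noiseModel()].
#' @param lipidCatalog character vector of parseable lipid names; default a
#'   targeted-panel-like catalog across 13 classes.
#' @return list with `matrix` (raw-scale [FeatureMatrix-class]) and `truth`
#'   (list: `catalog`, `effects` data.frame, `baseline`, `dilution_log2`,
#'   `mar_mask`, `mnar_mask`, `complete_log2`).
#' @export
generateLipidomicsCohort <- function(design, effects = list(),
                                     noise = noiseModel(),
                                     lipidCatalog = defaultLipidCatalog()) {
  stopifnot(inherits(design, "cohortDesign"), inherits(noise, "noiseModel"))
  catalog <- parseLipidCatalog(lipidCatalog)
  set.seed(noise$seed)
  nF <- nrow(catalog)
  ids <- design$sample_ids
  grp <- design$group_of
  nS <- length(ids)

  baseline <- rnorm(nF, noise$baseLog2Mean, noise$featureMeanSd)
  log2m <- matrix(baseline, nF, nS) +
    matrix(rnorm(nF * nS, 0, noise$featureSd), nF, nS)
  dimnames(log2m) <- list(catalog$raw_name, ids)

  effTab <- data.frame(feature = character(), group = character(),
                       log2_fold_change = numeric(),
                       stringsAsFactors = FALSE)
  for (ef in effects) {
    feats <- .resolveSelector(ef, catalog)
    cols <- which(grp == ef$affectedGroup)
    if (!length(cols))
      stop("affected group not in design: ", ef$affectedGroup)
    log2m[feats, cols] <- log2m[feats, cols] + ef$log2FoldChange
    effTab <- rbind(effTab, data.frame(
      feature = feats, group = ef$affectedGroup,
      log2_fold_change = ef$log2FoldChange, stringsAsFactors = FALSE))
  }

  dilution <- rnorm(nS, 0, noise$sampleDilutionSd)
  raw <- 2^sweep(log2m, 2, dilution, "+")

  mnarMask <- matrix(FALSE, nF, nS, dimnames = dimnames(raw))
  if (noise$mnarThresholdQuantile > 0) {
    thr <- quantile(raw, noise$mnarThresholdQuantile)
    mnarMask <- raw < thr
  }
  marMask <- matrix(runif(nF * nS) < noise$marRate, nF, nS,
                    dimnames = dimnames(raw)) & !mnarMask
  obs <- raw
  obs[mnarMask | marMask] <- NA_real_

  fm <- FeatureMatrix(obs, groups = grp[ids], scale = "raw")
  list(matrix = fm,
       truth = list(catalog = catalog, effects = effTab,
                    baseline = setNames(baseline, catalog$raw_name),
                    dilution_log2 = setNames(dilution, ids),
                    mar_mask = marMask, mnar_mask = mnarMask,
                    complete_log2 = log2m))
}

#' Generate a synthetic proteomics cohort
#'
#' Like [generateLipidomicsCohort()] but for generic protein features, with
#' per-protein unique-peptide counts and identification scores (a fraction
#' deliberately below the usual >= 2 peptides / > 5 score thresholds so the
#' filters have something to remove), and the MAR/MNAR missingness split
#' recorded in the truth table.
#'
#' @param design a [cohortDesign()].
#' @param effects list of [plantedEffect()]s with `kind = "features"`
#'   selectors over `protein_1 ... protein_n`.
#' @param noise a [noiseModel()].
#' @param nProteins number of proteins, >= 10.
#' @param lowQualityFraction fraction of proteins given sub-threshold
#'   peptide counts or scores, default 0.15.
#' @return list with `table` (raw-scale [ProteinTable-class]) and `truth`.
#' @export
generateProteomicsCohort <- function(design, effects = list(),
                                     noise = noiseModel(),
                                     nProteins = 100,
                                     lowQualityFraction = 0.15) {
  stopifnot(inherits(design, "cohortDesign"), inherits(noise, "noiseModel"))
  if (nProteins < 10) stop("nProteins must be >= 10")
  if (any(design$n_per_group < 2)) stop("need >= 2 samples per group")
  set.seed(noise$seed)
  ids <- design$sample_ids
  grp <- design$group_of
  nS <- length(ids)
  prot <- sprintf("protein_%03d", seq_len(nProteins))

  baseline <- rnorm(nProteins, noise$baseLog2Mean, noise$featureMeanSd)
  log2m <- matrix(baseline, nProteins, nS) +
    matrix(rnorm(nProteins * nS, 0, noise$featureSd), nProteins, nS)
  dimnames(log2m) <- list(prot, ids)

  effTab <- data.frame(feature = character(), group = character(),
                       log2_fold_change = numeric(),
                       stringsAsFactors = FALSE)
  for (ef in effects) {
    if (ef$kind != "features")
      stop("proteomics effects must use feature-id selectors")
    feats <- intersect(ef$targetSelector, prot)
    if (!length(feats))
      stop("planted-effect selector matched no protein: ",
           paste(ef$targetSelector, collapse = ", "))
    cols <- which(grp == ef$affectedGroup)
    log2m[feats, cols] <- log2m[feats, cols] + ef$log2FoldChange
    effTab <- rbind(effTab, data.frame(
      feature = feats, group = ef$affectedGroup,
      log2_fold_change = ef$log2FoldChange, stringsAsFactors = FALSE))
  }

  dilution <- rnorm(nS, 0, noise$sampleDilutionSd)
  raw <- 2^sweep(log2m, 2, dilution, "+")

  nLow <- round(lowQualityFraction * nProteins)
  lowIdx <- sample.int(nProteins, nLow)
  uniquePeptides <- 2L + rpois(nProteins, 4)
  score <- 6 + rexp(nProteins, 1 / 40)
  if (nLow) {
    half <- seq_len(ceiling(nLow / 2))
    uniquePeptides[lowIdx[half]] <- sample(0:1, length(half), replace = TRUE)
    score[lowIdx[-half]] <- runif(nLow - length(half), 0, 5)
  }

  mnarMask <- matrix(FALSE, nProteins, nS, dimnames = dimnames(raw))
  if (noise$mnarThresholdQuantile > 0) {
    thr <- quantile(raw, noise$mnarThresholdQuantile)
    mnarMask <- raw < thr
  }
  marMask <- matrix(runif(nProteins * nS) < noise$marRate, nProteins, nS,
                    dimnames = dimnames(raw)) & !mnarMask
  obs <- raw
  obs[mnarMask | marMask] <- NA_real_

  pt <- ProteinTable(obs, groups = grp[ids],
                     unique_peptides = uniquePeptides, score = score,
                     scale = "raw")
  list(table = pt,
       truth = list(effects = effTab,
                    baseline = setNames(baseline, prot),
                    dilution_log2 = setNames(dilution, ids),
                    mar_mask = marMask, mnar_mask = mnarMask,
                    low_quality = prot[lowIdx],
                    complete_log2 = log2m))
}

#' Generate a toy metabolic network
#'
#' Builds a bipartite reaction/metabolite structure with substrate/product
#' roles, gene annotations and a flagged ubiquitous-compound subset,
#' arranged as a directed acyclic network with a rich simple-path space:
#' one linear backbone chain of reactions (two parallel chains sharing
#' start and end metabolites when `nReactions >= 20`), plus "bypass"
#' reactions that jump forward between chain positions, so the number of
#' source-to-sink simple paths grows combinatorially with the bypass
#' count. The backbone guarantees at least one simple reaction path of 6
#' or more edges. Each reaction receives dedicated genes from the pool
#' (chains never share genes, so path-correlated expression stays
#' path-specific); ubiquitous metabolites join many reactions the way
#' water and co-factors would, and are flagged for removal.
#'
#' The chain/bypass layout is returned in the `layout` attribute:
#' `chain_a` and `chain_b` (reaction id vectors; `chain_b` empty for a
#' single-chain network).
#'
#' @param nReactions total reactions (at least 7 so a 6-edge chain fits).
#' @param nMetabolites total metabolites (enough to cover the chains).
#' @param nGenes size of the gene pool (at least `nReactions`).
#' @param ubiquitousFraction fraction of metabolites flagged ubiquitous.
#' @param seed integer seed.
#' @return a [MetabolicNetwork-class]
#' @export
generateToyNetwork <- function(nReactions = 30, nMetabolites = 44,
                               nGenes = 60, ubiquitousFraction = 0.1,
                               seed = 1L) {
  if (nReactions <= 0 || nMetabolites <= 0 || nGenes <= 0)
    stop("counts must be positive")
  if (nReactions < 7)
    stop("no length-6 reaction path possible; increase nReactions to >= 7")
  if (nGenes < nReactions)
    stop("need nGenes >= nReactions for dedicated gene annotations")
  set.seed(as.integer(seed))

  twoChains <- nReactions >= 20
  lenA <- if (twoChains) 8L else min(nReactions, 10L)
  lenB <- if (twoChains) 8L else 0L
  # chain A uses mets a0..a<lenA>; chain B shares a0 and a<lenA> as its
  # endpoints; positions in (0,1) order the DAG
  metsA <- sprintf("A%02d", 0:lenA)
  metsB <- if (twoChains) sprintf("B%02d", seq_len(lenB - 1)) else character()
  core <- c(metsA, metsB)
  nUb <- round(ubiquitousFraction * nMetabolites)
  nOther <- nMetabolites - length(core)
  if (nOther < nUb)
    stop("nMetabolites too small for the chains plus ubiquitous pool")
  other <- if (nOther > 0) sprintf("X%03d", seq_len(nOther)) else character()
  ubiq <- if (nUb > 0) other[seq_len(nUb)] else character()
  mets <- c(core, other)

  pos <- c(setNames((0:lenA) / lenA, metsA),
           if (twoChains) setNames(seq_len(lenB - 1) / lenB, metsB))
  chainPath <- function(ms) lapply(seq_len(length(ms) - 1), function(i)
    c(ms[i], ms[i + 1]))
  steps <- chainPath(metsA)
  if (twoChains)
    steps <- c(steps, chainPath(c(metsA[1], metsB, metsA[lenA + 1])))
  nChain <- length(steps)

  reactions <- list()
  for (i in seq_len(nReactions)) {
    id <- sprintf("R%03d", i)
    if (i <= nChain) {
      subs <- steps[[i]][1]
      prods <- steps[[i]][2]
    } else {
      # forward bypass within one chain: consume a DAG-positioned
      # metabolite, produce a slightly later one on the same chain (short
      # jumps keep alternative routes long enough to qualify as paths, so
      # each chain's path space grows combinatorially)
      sideB <- twoChains && (i %% 2 == 0)
      sideMets <- if (sideB) c(metsA[1], metsB, metsA[lenA + 1]) else metsA
      repeat {
        pick <- sample(sideMets, 2)
        d <- pos[pick[2]] - pos[pick[1]]
        if (d < 0) { pick <- rev(pick); d <- -d }
        if (d > 0 && d <= 0.27) break
      }
      subs <- pick[1]
      prods <- pick[2]
    }
    if (length(ubiq) && runif(1) < 0.5) {
      subs <- c(subs, sample(ubiq, 1))
      prods <- c(prods, sample(ubiq, 1))
    }
    reactions[[id]] <- list(id = id, substrates = subs, products = prods,
                            genes = character())
  }
  # dedicated genes: partition a shuffled pool across reactions
  pool <- sample(sprintf("G%03d", seq_len(nGenes)))
  per <- max(1L, nGenes %/% nReactions)
  for (i in seq_len(nReactions)) {
    take <- pool[seq((i - 1) * per + 1, min(i * per, length(pool)))]
    reactions[[i]]$genes <- take[!is.na(take)]
  }
  net <- MetabolicNetwork(reactions,
                          data.frame(id = mets, ubiquitous = mets %in% ubiq))
  attr(net, "layout") <- list(
    chain_a = sprintf("R%03d", seq_len(lenA)),
    chain_b = if (twoChains) sprintf("R%03d", lenA + seq_len(lenB))
              else character())
  # the backbone guarantees a >= 6-edge simple path; verify the contract
  rg <- buildReactionGraph(net)
  ch <- sprintf("R%03d", seq_len(lenA))
  eid <- igraph::get_edge_ids(rg@graph, rbind(ch[-lenA], ch[-1]))
  if (any(eid == 0))
    stop("generated network has no path of >= 6 edges; increase nReactions")
  net
}

#' Generate expression with group-specific correlation along network paths
#'
#' Genes annotated along a group's active paths are drawn with exchangeable
#' pairwise correlation `correlation` within that group's samples and
#' independently in the other group; background genes are independent
#' everywhere. The returned matrix follows the public-expression convention:
#' log2-scale values, median-centered per gene.
#'
#' @param network a [MetabolicNetwork-class].
#' @param design a [cohortDesign()].
#' @param activePaths named list: for each group label, a list of reaction-id
#'   vectors (the paths whose genes should co-express in that group).
#' @param correlation target pairwise correlation in `[0, 1)`.
#' @param seed integer seed.
#' @param sdLog2 marginal sd of log2 expression, default 1.
#' @return list with `matrix` (log2-scale [FeatureMatrix-class], rows = all
#'   network genes) and `truth` (`active_genes` per group, `path_genes` per
#'   path, `correlation`).
#' @export
generateExpressionForPaths <- function(network, design, activePaths,
                                       correlation, seed = 1L, sdLog2 = 1) {
  stopifnot(is(network, "MetabolicNetwork"),
            inherits(design, "cohortDesign"))
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)")
  rids <- names(network@reactions)
  for (grpPaths in activePaths) for (p in grpPaths) {
    bad <- setdiff(p, rids)
    if (length(bad))
      stop("path references unknown reactions: ", paste(bad, collapse = ", "))
  }
  genesOf <- lapply(network@reactions, function(r) r$genes)
  allGenes <- sort(unique(unlist(genesOf)))
  ids <- design$sample_ids
  grp <- design$group_of
  nS <- length(ids)
  set.seed(as.integer(seed))
  expr <- matrix(rnorm(length(allGenes) * nS, 0, sdLog2),
                 length(allGenes), nS,
                 dimnames = list(allGenes, ids))

  activeGenes <- list()
  pathGenes <- list()
  for (g in names(activePaths)) {
    cols <- which(grp == g)
    for (p in activePaths[[g]]) {
      pg <- unique(unlist(genesOf[p]))
      pathGenes[[paste(g, paste(p, collapse = ">"), sep = ":")]] <- pg
      k <- length(pg)
      if (k < 2) next
      # exchangeable correlation: shared factor + idiosyncratic noise
      shared <- rnorm(length(cols))
      z <- sqrt(correlation) * matrix(shared, k, length(cols),
                                      byrow = TRUE) +
        sqrt(1 - correlation) * matrix(rnorm(k * length(cols)), k)
      expr[pg, cols] <- z * sdLog2
      activeGenes[[g]] <- union(activeGenes[[g]], pg)
    }
  }
  expr <- expr - apply(expr, 1, median)
  fm <- FeatureMatrix(expr, groups = grp[ids], scale = "log2")
  list(matrix = fm,
       truth = list(active_genes = activeGenes, path_genes = pathGenes,
                    correlation = correlation))
}
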