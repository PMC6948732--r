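# Config schema: known keys, defaults, and simple validators. Unknown keys
# are rejected (typo safety); every defaulted parameter is echoed in the
# returned provenance.
.configSchema <- function() {
  list(
    seed = list(default = 1L, check = function(x) is.numeric(x)),
    output_dir = list(default = "mmomics_output",
                      check = function(x) is.character(x)),
    groups = list(default = c("RRMM", "NDMM"),
                  check = function(x) length(x) == 2 && !anyDuplicated(x)),
    n_per_group = list(default = c(10L, 10L),
                       check = function(x) all(x >= 2)),
    lipid_log2fc = list(default = -2,
                        check = function(x) is.numeric(x)),
    lipid_target_class = list(default = "PC",
                              check = function(x) is.character(x)),
    presence_threshold = list(default = 0.75,
                              check = function(x) x > 0 && x <= 1),
    min_unique_peptides = list(default = 2, check = function(x) x >= 0),
    min_score = list(default = 5, check = function(x) is.numeric(x)),
    mar_cutoff = list(default = 0.25,
                      check = function(x) x > 0 && x <= 1),
    lls_neighbors = list(default = 10, check = function(x) x >= 1),
    mnar_sd_factor = list(default = 0.3, check = function(x) x > 0),
    p_threshold = list(default = 0.05, check = function(x) x > 0 && x < 1),
    lfc_threshold = list(default = 1.5, check = function(x) x > 0),
    n_perm = list(default = 2000, check = function(x) x >= 100),
    n_proteins = list(default = 120, check = function(x) x >= 10),
    n_reactions = list(default = 30, check = function(x) x >= 7),
    n_expression_per_group = list(default = 60,
                                  check = function(x) all(x >= 3)),
    path_correlation = list(default = 0.9,
                            check = function(x) x >= 0 && x < 1),
    top_k_paths = list(default = 15, check = function(x) x >= 1),
    min_path_length = list(default = 6, check = function(x) x >= 1))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, applies schema defaults, rejects
#' unknown keys, and records which parameters were defaulted.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @return normalized config list of class `pipelineConfig`; defaulted keys
#'   listed in `attr(x, "defaulted")`.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  schema <- .configSchema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  errors <- character()
  out <- list()
  defaulted <- character()
  for (key in names(schema)) {
    if (is.null(config[[key]])) {
      out[[key]] <- schema[[key]]$default
      defaulted <- c(defaulted, key)
    } else {
      val <- config[[key]]
      if (!isTRUE(schema[[key]]$check(val)))
        errors <- c(errors, sprintf("invalid value for '%s'", key))
      out[[key]] <- val
    }
  }
  if (length(out$groups) != 2)
    errors <- c(errors, "comparison must name exactly two groups")
  if (length(errors)) stop(paste(errors, collapse = "; "))
  out$n_per_group <- rep(as.integer(out$n_per_group), length.out = 2)
  out$seed <- as.integer(out$seed)
  structure(out, defaulted = defaulted, class = "pipelineConfig")
}

.table1Counts <- function(detected, filtered, results) {
  s <- attr(results, "summary")
  list(detected = detected, filtered = filtered,
       sig_raw = s$sig_raw, sig_adj = s$sig_adj,
       up = s$up, down = s$down)
}

#' Run the full synthetic multi-omics pipeline
#'
#' Generates a synthetic cohort from the configuration, then executes every
#' stage in dependency order: targeted-lipidomics preprocessing (PQN, log2)
#' and differential analysis with lipid-set enrichment; proteomics filtering,
#' quantile normalization, log2, two-mechanism imputation, differential
#' analysis and pathway enrichment; transcriptomics generation along planted
#' network paths with differential analysis and pathway enrichment;
#' gene- and pathway-level cross-omics concordance; and reaction-graph path
#' mining with classification. All randomness derives from `config$seed`.
#' Stage outputs are written as TSV/JSON files under `config$output_dir`
#' so any stage can be re-examined independently; the run report (JSON and
#' markdown, no timestamps) summarizes counts per stage.
#'
#' @param config a `pipelineConfig` from [validateConfig()] (or anything it
#'   accepts).
#' @return the run report, invisibly also written to
#'   `<output_dir>/report.json` and `report.md`.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig")) config <- validateConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outDir <- config$output_dir
  seed <- config$seed
  grpLabels <- config$groups
  design <- cohortDesign(config$n_per_group, grpLabels)
  contrast <- grpLabels

  ## --- lipidomics (targeted chain: PQN -> log2 -> limma-style -> LSEA)
  lip <- generateLipidomicsCohort(
    design,
    effects = list(plantedEffect(config$lipid_target_class,
                                 config$lipid_log2fc, grpLabels[1],
                                 kind = "class")),
    noise = noiseModel(seed = seed))
  lipDetected <- nrow(lip$matrix)
  lipFiltered <- filterByPresence(lip$matrix, config$presence_threshold)
  lipNorm <- log2Transform(pqnNormalize(lipFiltered))
  lipRes <- runDifferential(imputeMinimum(lipNorm), contrast,
                            config$p_threshold, config$lfc_threshold)
  writeDifferentialTsv(lipRes, file.path(outDir, "lipidomics_diff.tsv"))
  lipSets <- buildLipidSets(lipRes$feature_id)
  lipRanking <- setNames(lipRes$logFC, lipRes$feature_id)
  lipRanking <- lipRanking[!is.na(lipRanking)]
  lipEnr <- prerankedEnrichment(lipRanking, lipSets, nPerm = config$n_perm,
                                seed = seed + 101L)
  utils::write.table(lipEnr, file.path(outDir, "lipidomics_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- network + transcriptomics (path-correlated expression)
  net <- generateToyNetwork(nReactions = config$n_reactions,
                            nMetabolites = config$n_reactions + 16,
                            nGenes = 3 * config$n_reactions,
                            ubiquitousFraction = 0.1, seed = seed + 201L)
  writeMetabolicNetwork(net, file.path(outDir, "network.json"))
  rg0 <- buildReactionGraph(net)
  layout <- attr(net, "layout")
  if (!length(layout$chain_b))
    stop("stage network: need n_reactions >= 20 for two plantable chains")
  pathA <- layout$chain_a
  pathB <- layout$chain_b
  exprDesign <- cohortDesign(config$n_expression_per_group, grpLabels)
  expr <- generateExpressionForPaths(
    net, exprDesign,
    activePaths = setNames(list(list(pathA), list(pathB)), grpLabels),
    correlation = config$path_correlation, seed = seed + 301L)
  writeGct(expr$matrix, file.path(outDir, "expression.gct"))

  ## --- proteomics: planted effects on a block of proteins that the
  ## gene<->protein mapping below ties to the first pathway sets
  prot <- generateProteomicsCohort(
    design,
    effects = list(plantedEffect(
      sprintf("protein_%03d", seq_len(min(20, config$n_proteins))),
      2, grpLabels[1], kind = "features")),
    noise = noiseModel(seed = seed + 401L, marRate = 0.05),
    nProteins = config$n_proteins)
  protDetected <- nrow(prot$table)
  protFiltered <- filterProteins(prot$table, config$min_unique_peptides,
                                 config$min_score,
                                 config$presence_threshold)
  protImp <- imputeProteomics(log2Transform(quantileNormalize(protFiltered)),
                              marCutoff = config$mar_cutoff,
                              llsNeighbors = config$lls_neighbors,
                              mnarSdFactor = config$mnar_sd_factor,
                              seed = seed + 402L)
  protRes <- runDifferential(protImp, contrast, config$p_threshold,
                             config$lfc_threshold)
  writeDifferentialTsv(protRes, file.path(outDir, "proteomics_diff.tsv"))

  ## --- transcriptomics differential + enrichment over gene pathways
  txRes <- runDifferential(expr$matrix, contrast, config$p_threshold,
                           config$lfc_threshold)
  writeDifferentialTsv(txRes, file.path(outDir, "transcriptomics_diff.tsv"))
  geneSets <- lapply(net@reactions, function(r) r$genes)
  geneSets <- geneSets[vapply(geneSets, length, integer(1)) >= 1]
  # reaction-level gene sets are tiny; pool consecutive reactions into
  # pathway-sized sets
  rids <- names(geneSets)
  pool <- split(rids, (seq_along(rids) - 1) %/% 4)
  txSets <- lapply(pool, function(rr) unique(unlist(geneSets[rr])))
  names(txSets) <- sprintf("gene_pathway_%02d", seq_along(txSets))
  writeGmt(txSets, file.path(outDir, "gene_pathways.gmt"))
  txRanking <- setNames(txRes$logFC, txRes$feature_id)
  txRanking <- txRanking[!is.na(txRanking)]
  txEnr <- prerankedEnrichment(txRanking, txSets, nPerm = config$n_perm,
                               seed = seed + 501L)
  utils::write.table(txEnr, file.path(outDir,
                                      "transcriptomics_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## gene <-> protein id mapping; proteomics pathway sets mirror the gene
  ## pathways through it, so pathway ids are shared across the two layers
  allGenes <- rownames(intensities(expr$matrix))
  nMap <- min(length(allGenes), nrow(protRes))
  mapping <- data.frame(source_id = allGenes[seq_len(nMap)],
                        target_id = protRes$feature_id[seq_len(nMap)],
                        stringsAsFactors = FALSE)
  gene2prot <- setNames(mapping$target_id, mapping$source_id)
  protSets <- lapply(txSets, function(gs)
    unname(na.omit(gene2prot[intersect(gs, names(gene2prot))])))
  protSets <- protSets[vapply(protSets, length, integer(1)) >= 3]
  protRanking <- setNames(protRes$logFC, protRes$feature_id)
  protRanking <- protRanking[!is.na(protRanking)]
  protEnr <- prerankedEnrichment(protRanking, protSets,
                                 nPerm = config$n_perm, seed = seed + 403L)
  utils::write.table(protEnr, file.path(outDir, "proteomics_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- cross-omics concordance at the gene and pathway levels
  txMapped <- txRes[match(mapping$source_id, txRes$feature_id), ]
  txMapped$feature_id <- mapping$target_id
  geneUniverse <- intersect(txMapped$feature_id, protRes$feature_id)
  geneConc <- concordance(
    protRes[protRes$significant_raw, c("feature_id", "logFC")],
    txMapped[txMapped$significant_raw %in% TRUE, c("feature_id", "logFC")],
    geneUniverse)
  pathUniverse <- intersect(protEnr$set_id, txEnr$set_id)
  pathConc <- concordance(
    data.frame(feature_id = protEnr$set_id[protEnr$p_value < 0.05],
               logFC = protEnr$ES[protEnr$p_value < 0.05]),
    data.frame(feature_id = txEnr$set_id[txEnr$p_value < 0.05],
               logFC = txEnr$ES[txEnr$p_value < 0.05]),
    pathUniverse)

  ## --- network stage: weight, paths, classify, subnetwork, projection
  rgW <- weightEdges(rg0, expr$matrix, groups = grpLabels)
  topA <- extractTopPaths(rgW, grpLabels[1], k = config$top_k_paths,
                          minLength = config$min_path_length)
  topB <- extractTopPaths(rgW, grpLabels[2], k = config$top_k_paths,
                          minLength = config$min_path_length)
  writePathsTsv(combinePathSets(topA, topB),
                file.path(outDir, "top_paths.tsv"))
  netSummary <- list(reactions = igraph::vcount(rgW@graph),
                     edges = igraph::ecount(rgW@graph),
                     paths_A = length(topA), paths_B = length(topB))
  classification <- NULL
  if (length(topA) >= 5 && length(topB) >= 5) {
    model <- trainPathClassifier(combinePathSets(topA, topB),
                                 seed = seed + 601L)
    classification <- classifyPaths(model, combinePathSets(topA, topB))
    writeRocCsv(classification, file.path(outDir, "roc_points.csv"))
    netSummary$auc <- classification$auc
  }
  subnet <- extractSubnetwork(topA, topB)
  writeSif(subnet$graph, file.path(outDir, "subnetwork.sif"))
  netSummary$subnetwork <- subnet$counts
  geneMap <- data.frame(gene = mapping$source_id,
                        feature_id = mapping$target_id,
                        stringsAsFactors = FALSE)
  proj <- projectDifferential(subnet, protRes, geneMap,
                              lapply(net@reactions, function(r) r$genes))
  netSummary$proteomics_coverage <- proj$coverage

  ## --- report
  report <- list(
    parameters = unclass(config),
    defaulted_parameters = attr(config, "defaulted"),
    comparison = paste(contrast, collapse = "."),
    counts = list(
      lipidomics = .table1Counts(lipDetected, nrow(lipFiltered), lipRes),
      proteomics = .table1Counts(protDetected, nrow(protFiltered), protRes),
      transcriptomics = .table1Counts(nrow(expr$matrix), nrow(expr$matrix),
                                      txRes)),
    enrichment = list(
      lipid_sets_significant =
        sum(lipEnr$adj_p_value < config$p_threshold),
      proteomics_pathways_significant =
        sum(protEnr$adj_p_value < config$p_threshold),
      transcriptomics_pathways_significant =
        sum(txEnr$adj_p_value < config$p_threshold)),
    concordance = list(gene_level = unclass(geneConc),
                       pathway_level = unclass(pathConc)),
    network = netSummary)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Pipeline run report",
          sprintf("- comparison: %s", report$comparison),
          sprintf("- seed: %d", config$seed), "",
          "## Feature counts (detected / filtered / raw-sig / adj-sig)",
          vapply(names(report$counts), function(nm) {
            ct <- report$counts[[nm]]
            sprintf("- %s: %d / %d / %d / %d", nm, ct$detected,
                    ct$filtered, ct$sig_raw, ct$sig_adj)
          }, character(1)), "",
          sprintf("- gene-level overlap: %d (p = %.3g)",
                  report$concordance$gene_level$n_overlap,
                  report$concordance$gene_level$p_overlap),
          if (!is.null(netSummary$auc))
            sprintf("- path classifier AUC: %.3f", netSummary$auc))
  writeLines(md, file.path(outDir, "report.md"))
  report
}
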