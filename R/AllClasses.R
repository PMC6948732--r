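#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx cor lm median na.omit p.adjust pbinom phyper pnorm
#'   predict pt quantile rbinom rexp rnorm rpois runif sd setNames var
#' @importFrom utils combn head write.csv read.csv
NULL

setOldClass("igraph")

#' FeatureMatrix: an intensity matrix with group labels and a scale flag
#'
#' The central container of the package: a features x samples matrix of
#' non-negative intensities (raw scale) or log2 intensities, with a two-group
#' (or more) sample annotation and a declared scale. Missing values are `NA`.
#' Built on [SummarizedExperiment::SummarizedExperiment] so the usual
#' `dim`, `rownames`, `colnames`, `[` and `assay` machinery applies.
#'
#' @slot .. see SummarizedExperiment; the single assay is named `"intensity"`,
#'   `colData$group` holds sample group labels and
#'   `metadata(x)$scale` is `"raw"` or `"log2"`.
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  sc <- S4Vectors::metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "log2"))
    msg <- c(msg, "metadata 'scale' must be 'raw' or 'log2'")
  if (length(msg)) return(msg)
  v <- SummarizedExperiment::assay(object, "intensity")
  if (identical(sc, "raw") && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "raw-scale intensities must be non-negative")
  grp <- SummarizedExperiment::colData(object)$group
  if (anyNA(grp)) msg <- c(msg, "every sample needs a group label")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, features x samples; `NA` marks missing.
#' @param groups character/factor of length `ncol(values)`: group per sample.
#' @param scale `"raw"` (linear intensities) or `"log2"`.
#' @param rowData optional `DataFrame`/data.frame of per-feature annotation.
#' @return A [FeatureMatrix-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 10), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' fm <- FeatureMatrix(m, groups = c("A", "A", "B", "B"))
#' groupLabels(fm)
#' @export
FeatureMatrix <- function(values, groups, scale = c("raw", "log2"),
                          rowData = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (length(groups) != ncol(values))
    stop("length(groups) must equal ncol(values)")
  cd <- S4Vectors::DataFrame(group = as.character(groups),
                             row.names = colnames(values))
  args <- list(assays = list(intensity = values), colData = cd,
               metadata = list(scale = scale))
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  methods::new("FeatureMatrix", se)
}

#' ProteinTable: a FeatureMatrix with protein-level identification metadata
#'
#' Adds MaxQuant-style per-protein annotation (`unique_peptides`, `score`)
#' as rowData columns, used by the identification-quality filters.
#'
#' @export
setClass("ProteinTable", contains = "FeatureMatrix")

setValidity("ProteinTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  need <- c("unique_peptides", "score")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (any(rd$unique_peptides < 0)) return("unique_peptides must be >= 0")
  if (anyDuplicated(rownames(object))) return("protein ids must be unique")
  TRUE
})

#' Construct a ProteinTable
#'
#' @inheritParams FeatureMatrix
#' @param unique_peptides integer vector, unique peptide count per protein.
#' @param score numeric vector, identification score per protein.
#' @return A [ProteinTable-class] object.
#' @export
ProteinTable <- function(values, groups, unique_peptides, score,
                         scale = c("raw", "log2")) {
  fm <- FeatureMatrix(values, groups, scale,
                      rowData = S4Vectors::DataFrame(
                        unique_peptides = as.integer(unique_peptides),
                        score = as.numeric(score)))
  methods::new("ProteinTable", fm)
}

#' MetabolicNetwork: reactions, metabolites and gene annotations
#'
#' A bipartite description of a metabolic pathway: each reaction lists its
#' substrate and product metabolite ids and the gene ids annotated to it;
#' each metabolite carries a `ubiquitous` flag (water-like, co-factor-like
#' compounds that would over-connect a reaction graph).
#'
#' @slot reactions named list; each element has `id`, `substrates`,
#'   `products`, `genes` (character vectors).
#' @slot metabolites data.frame with columns `id`, `ubiquitous`.
#' @export
setClass("MetabolicNetwork",
         representation(reactions = "list", metabolites = "data.frame"))

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  met <- object@metabolites
  if (!all(c("id", "ubiquitous") %in% colnames(met)))
    return("metabolites needs columns 'id' and 'ubiquitous'")
  ids <- vapply(object@reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "reaction ids must be unique")
  used <- unique(unlist(lapply(object@reactions,
                               function(r) c(r$substrates, r$products))))
  unknown <- setdiff(used, met$id)
  if (length(unknown))
    msg <- c(msg, paste("metabolites not declared:",
                        paste(head(unknown, 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MetabolicNetwork
#'
#' @param reactions list of lists with fields `id`, `substrates`, `products`,
#'   `genes`.
#' @param metabolites data.frame with columns `id` (character) and
#'   `ubiquitous` (logical).
#' @return A [MetabolicNetwork-class] object.
#' @export
MetabolicNetwork <- function(reactions, metabolites) {
  reactions <- lapply(reactions, function(r) {
    list(id = as.character(r$id),
         substrates = as.character(r$substrates %||% character()),
         products = as.character(r$products %||% character()),
         genes = as.character(r$genes %||% character()))
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  metabolites <- data.frame(id = as.character(metabolites$id),
                            ubiquitous = as.logical(metabolites$ubiquitous),
                            stringsAsFactors = FALSE)
  methods::new("MetabolicNetwork", reactions = reactions,
               metabolites = metabolites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ReactionGraph: a directed reaction-adjacency graph with group edge weights
#'
#' Nodes are reactions (with gene annotations); a directed edge r1 -> r2
#' exists when a non-ubiquitous product of r1 is a substrate of r2. After
#' [weightEdges()] each edge carries one correlation weight per sample group
#' (edge attributes `weight_<group>`) plus an `unmeasured_<group>` flag.
#'
#' @slot graph the underlying [igraph::igraph] object.
#' @slot groups character: groups for which edge weights are present.
#' @export
setClass("ReactionGraph",
         representation(graph = "igraph", groups = "character"))

#' MetabolicPathSet: ranked simple paths through a reaction graph
#'
#' @slot paths list of character vectors (ordered reaction ids).
#' @slot score numeric: mean edge weight of each path.
#' @slot length integer: edge count of each path.
#' @slot condition character: the sample group each path was extracted for.
#' @export
setClass("MetabolicPathSet",
         representation(paths = "list", score = "numeric",
                        length = "integer", condition = "character"))

setValidity("MetabolicPathSet", function(object) {
  n <- length(object@paths)
  if (length(object@score) != n || length(object@length) != n ||
      length(object@condition) != n)
    return("paths, score, length and condition must have equal length")
  if (any(vapply(object@paths, anyDuplicated, integer(1)) > 0))
    return("paths must be simple (no repeated reactions)")
  TRUE
})

#' PathClassifierModel: a two-component mixture of first-order Markov chains
#'
#' Fitted by EM over reaction-node sequences; each component holds
#' Laplace-smoothed initial and transition probabilities over the common
#' reaction alphabet. Components are associated with the condition whose
#' training paths they best explain.
#'
#' @slot components list of two lists, each with `initial` (named numeric)
#'   and `transition` (matrix, rows sum to 1).
#' @slot mixtureWeights numeric(2), sums to 1.
#' @slot conditionOf character(2): condition label assigned to each component.
#' @slot logLik numeric: per-iteration observed-data log-likelihood.
#' @slot objective numeric: per-iteration penalized (MAP) objective.
#' @slot alphabet character: reaction-node alphabet.
#' @export
setClass("PathClassifierModel",
         representation(components = "list", mixtureWeights = "numeric",
                        conditionOf = "character", logLik = "numeric",
                        objective = "numeric", alphabet = "character"))

setValidity("PathClassifierModel", function(object) {
  msg <- character()
  if (abs(sum(object@mixtureWeights) - 1) > 1e-9)
    msg <- c(msg, "mixture weights must sum to 1")
  for (cmp in object@components) {
    if (any(abs(rowSums(cmp$transition) - 1) > 1e-9))
      msg <- c(msg, "transition rows must sum to 1")
    if (abs(sum(cmp$initial) - 1) > 1e-9)
      msg <- c(msg, "initial probabilities must sum to 1")
  }
  if (length(msg)) unique(msg) else TRUE
})
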