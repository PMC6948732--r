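#' Intensity matrix of a FeatureMatrix
#' @param x a [FeatureMatrix-class]
#' @return numeric matrix (features x samples), `NA` = missing.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Sample group labels
#' @param x a [FeatureMatrix-class]
#' @return character vector named by sample id.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Declared scale of a FeatureMatrix
#' @param x a [FeatureMatrix-class]
#' @return `"raw"` or `"log2"`.
#' @export
setGeneric("scaleFlag", function(x) standardGeneric("scaleFlag"))

#' Logical mask of missing cells
#' @param x a [FeatureMatrix-class]
#' @return logical matrix, `TRUE` where the intensity is missing.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @describeIn intensities method for FeatureMatrix
setMethod("intensities", "FeatureMatrix", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @describeIn groupLabels method for FeatureMatrix
setMethod("groupLabels", "FeatureMatrix", function(x)
  setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @describeIn scaleFlag method for FeatureMatrix
setMethod("scaleFlag", "FeatureMatrix", function(x)
  S4Vectors::metadata(x)$scale)

#' @describeIn missingMask method for FeatureMatrix
setMethod("missingMask", "FeatureMatrix", function(x)
  is.na(SummarizedExperiment::assay(x, "intensity")))

setMethod("show", "FeatureMatrix", function(object) {
  v <- intensities(object)
  grp <- table(groupLabels(object))
  cat(sprintf("%s: %d features x %d samples [%s scale]\n",
              class(object), nrow(v), ncol(v), scaleFlag(object)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(grp), grp),
                       collapse = ", "), "\n")
  cat(sprintf("missing: %.1f%%\n", 100 * mean(is.na(v))))
})

setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork: %d reactions, %d metabolites (%d ubiquitous)\n",
              length(object@reactions), nrow(object@metabolites),
              sum(object@metabolites$ubiquitous)))
})

setMethod("show", "ReactionGraph", function(object) {
  cat(sprintf("ReactionGraph: %d reactions, %d directed edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
  if (length(object@groups))
    cat("weighted for groups:", paste(object@groups, collapse = ", "), "\n")
})

setMethod("show", "MetabolicPathSet", function(object) {
  cat(sprintf("MetabolicPathSet: %d paths\n", length(object@paths)))
  if (length(object@paths)) {
    cat(sprintf("score range [%.3f, %.3f], edge lengths %d-%d\n",
                min(object@score), max(object@score),
                min(object@length), max(object@length)))
  }
})

setMethod("length", "MetabolicPathSet", function(x) length(x@paths))

#' Coerce a MetabolicPathSet to a data.frame
#'
#' @param x a [MetabolicPathSet-class]
#' @param ... ignored
#' @return data.frame with `rank`, `condition`, `score`, `length`,
#'   `node_sequence` (reactions joined by `" -> "`).
#' @export
as.data.frame.MetabolicPathSet <- function(x, ...) {
  data.frame(rank = seq_along(x@paths),
             condition = x@condition,
             score = x@score,
             length = x@length,
             node_sequence = vapply(x@paths, paste, character(1),
                                    collapse = " -> "),
             stringsAsFactors = FALSE)
}

setMethod("show", "PathClassifierModel", function(object) {
  cat(sprintf("PathClassifierModel: 2 Markov components over %d reactions\n",
              length(object@alphabet)))
  cat(sprintf("mixture weights %.3f/%.3f; components -> conditions: %s\n",
              object@mixtureWeights[1], object@mixtureWeights[2],
              paste(sprintf("M%d=%s", 1:2, object@conditionOf),
                    collapse = ", ")))
})
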