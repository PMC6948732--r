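#' Collapse probe-level expression to target (UniProt) ids
#'
#' Many-to-one probe-to-protein mappings are resolved by keeping, per target,
#' the probe with the highest mean expression (the common microarray
#' collapse rule); unmapped probes are dropped and their count recorded in
#' `metadata(x)$unmapped_probes`.
#'
#' @param x a [FeatureMatrix-class] keyed by probe id.
#' @param mapping data.frame with columns `source_id`, `target_id` (no empty
#'   targets).
#' @return a [FeatureMatrix-class] keyed by target id.
#' @export
collapseProbes <- function(x, mapping) {
  stopifnot(is(x, "FeatureMatrix"))
  if (!nrow(mapping)) stop("empty id mapping")
  if (!all(c("source_id", "target_id") %in% colnames(mapping)))
    stop("mapping needs columns 'source_id' and 'target_id'")
  if (any(!nzchar(mapping$target_id)) || anyNA(mapping$target_id))
    stop("mapping contains empty target ids")
  v <- intensities(x)
  mapping <- mapping[mapping$source_id %in% rownames(v), , drop = FALSE]
  if (!nrow(mapping)) stop("no probe in the matrix maps to a target")
  nUnmapped <- sum(!rownames(v) %in% mapping$source_id)
  rowMean <- rowMeans(v, na.rm = TRUE)
  keep <- vapply(split(mapping$source_id, mapping$target_id), function(src) {
    src[which.max(rowMean[src])]
  }, character(1))
  out <- x[unname(keep), ]
  rownames(out) <- names(keep)
  S4Vectors::metadata(out)$unmapped_probes <- nUnmapped
  out
}

#' Gene- or pathway-level concordance of two significance lists
#'
#' Quantifies agreement between two differential analyses sharing an id
#' universe: the overlap of significant ids is tested with an upper-tail
#' hypergeometric probability (>= observed overlap when drawing `|sigA|`
#' ids from a universe containing `|sigB|` successes), and directional
#' agreement among overlapping ids with a one-sided binomial sign test at
#' probability 1/2.
#'
#' @param sigA,sigB data.frames with `feature_id` and `logFC` for the
#'   significant ids of each analysis (or character vectors of ids, in which
#'   case direction concordance is skipped).
#' @param universe character vector of ids tested in both analyses.
#' @return list of class `concordanceSummary`: `n_sig_A, n_sig_B, n_overlap,
#'   n_same_direction, p_overlap, p_direction, n_universe`.
#' @export
concordance <- function(sigA, sigB, universe) {
  if (!length(universe)) stop("empty universe")
  idsA <- if (is.data.frame(sigA)) sigA$feature_id else sigA
  idsB <- if (is.data.frame(sigB)) sigB$feature_id else sigB
  idsA <- intersect(idsA, universe)
  idsB <- intersect(idsB, universe)
  ov <- intersect(idsA, idsB)
  nU <- length(unique(universe))
  nA <- length(idsA); nB <- length(idsB); nOv <- length(ov)
  pOverlap <- phyper(nOv - 1, nB, nU - nB, nA, lower.tail = FALSE)
  nSame <- NA_integer_
  pDir <- NA_real_
  if (is.data.frame(sigA) && is.data.frame(sigB) && nOv > 0) {
    fcA <- setNames(sigA$logFC, sigA$feature_id)[ov]
    fcB <- setNames(sigB$logFC, sigB$feature_id)[ov]
    nSame <- sum(sign(fcA) == sign(fcB))
    pDir <- pbinom(nSame - 1, nOv, 0.5, lower.tail = FALSE)
  }
  structure(list(n_sig_A = nA, n_sig_B = nB, n_overlap = nOv,
                 n_same_direction = nSame, p_overlap = pOverlap,
                 p_direction = pDir, n_universe = nU),
            class = "concordanceSummary")
}

#' @export
print.concordanceSummary <- function(x, ...) {
  cat(sprintf(
    "concordance: |A|=%d, |B|=%d, overlap=%d (p=%.3g) in universe of %d\n",
    x$n_sig_A, x$n_sig_B, x$n_overlap, x$p_overlap, x$n_universe))
  if (!is.na(x$n_same_direction))
    cat(sprintf("same direction: %d/%d (p=%.3g)\n",
                x$n_same_direction, x$n_overlap, x$p_direction))
  invisible(x)
}

#' Grouped bar chart of cross-omics overlap
#'
#' Side-by-side bars: significant in analysis A, also significant in B, and
#' regulated in the same direction — for one or several levels (e.g. genes
#' and pathways).
#'
#' @param summaries named list of `concordanceSummary` objects.
#' @return a ggplot object.
#' @export
plotConcordance <- function(summaries) {
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(level = nm,
               category = factor(c("significant", "overlapping",
                                   "same direction"),
                                 levels = c("significant", "overlapping",
                                            "same direction")),
               count = c(s$n_sig_A, s$n_overlap,
                         ifelse(is.na(s$n_same_direction), 0,
                                s$n_same_direction)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = level, y = count, fill = category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("significant" = "#c0392b",
                                          "overlapping" = "#27ae60",
                                          "same direction" = "#2980b9")) +
    ggplot2::theme_bw() +
    ggplot2::labs(x = NULL, y = "count", fill = NULL)
}
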