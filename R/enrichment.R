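# Running-sum enrichment score from member positions in the sorted ranking.
# pos: sorted positions of set members in the decreasing ranking;
# absw: |stat|^exponent for all N positions (in ranking order).
.enrichmentScore <- function(pos, absw, N) {
  m <- length(pos)
  w <- absw[pos]
  NR <- sum(w)
  if (NR == 0) w <- rep(1, m) # all-zero stats: unweighted steps
  NR <- sum(w)
  q <- 1 / (N - m)
  W <- cumsum(w) / NR
  gaps <- (pos - seq_len(m)) * q        # non-member decrement before member j
  tops <- W - gaps                      # value just after each member step
  bottoms <- c(0, W[-m]) - gaps         # value just before each member step
  maxP <- max(0, tops)
  minP <- min(0, bottoms)
  # symmetric tie rule (to numerical tolerance): equal positive and
  # negative excursions cancel, so negating every statistic negates the
  # score
  if (abs(maxP + minP) < 1e-12) 0 else if (maxP > -minP) maxP else minP
}

#' Preranked set enrichment with a feature-label permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (GSEA-preranked style):
#' features are sorted by decreasing ranking statistic (ties broken by
#' feature id for determinism); the running sum increases by
#' `|stat|^weightExponent` (normalized) at member features and decreases by
#' `1/(N-m)` elsewhere; ES is the extreme deviation. The null distribution
#' permutes feature labels: when the number of distinct member-position
#' assignments `choose(N, m)` does not exceed `nPerm` the null is enumerated
#' exhaustively (exact p-values), otherwise `nPerm` random subsets are drawn.
#' NES divides ES by the mean |null ES| of the same sign; p-values are
#' sign-matched tail probabilities, BH-adjusted across sets.
#'
#' @param ranking named numeric vector (e.g. logFC per feature); no missing
#'   values allowed.
#' @param sets named list of sets as from [buildLipidSets()] or [readGmt()]
#'   (each with `members`; plain character vectors also accepted).
#' @param nPerm permutations, default 10000 (must be >= 100).
#' @param weightExponent weight on |stat|, default 1.
#' @param minSize minimum members-in-universe per set, default 3.
#' @param seed integer seed for the permutation draws.
#' @return data.frame `set_id, kind, size, ES, NES, p_value, adj_p_value,
#'   leading_edge` (comma-separated ids), one row per scored set.
#' @export
prerankedEnrichment <- function(ranking, sets, nPerm = 10000,
                                weightExponent = 1, minSize = 3, seed = 1L) {
  if (anyNA(ranking)) stop("ranking contains missing values")
  if (is.null(names(ranking))) stop("ranking must be named by feature id")
  if (nPerm < 100) stop("nPerm must be >= 100")
  N <- length(ranking)
  ord <- order(-ranking, names(ranking))
  stat <- ranking[ord]
  ids <- names(stat)
  absw <- abs(stat)^weightExponent

  rows <- list()
  set.seed(as.integer(seed))
  for (nm in names(sets)) {
    s <- sets[[nm]]
    members <- if (is.list(s)) s$members else s
    kind <- if (is.list(s) && !is.null(s$kind)) s$kind else "set"
    inSet <- ids %in% members
    m <- sum(inSet)
    if (m == 0) {
      warning("set '", nm, "' has no members in the ranking universe; skipped")
      next
    }
    if (m == N) {
      warning("set '", nm, "' spans the entire universe; skipped")
      next
    }
    if (m < minSize) next
    pos <- which(inSet)
    es <- .enrichmentScore(pos, absw, N)

    exhaustive <- choose(N, m) <= nPerm
    if (exhaustive) {
      combs <- combn(N, m)
      nullES <- apply(combs, 2, .enrichmentScore, absw = absw, N = N)
    } else {
      nullES <- vapply(seq_len(nPerm), function(i)
        .enrichmentScore(sort(sample.int(N, m)), absw, N), numeric(1))
    }
    sameSign <- if (es >= 0) nullES >= 0 else nullES < 0
    extreme <- abs(nullES) >= abs(es) - 1e-12
    if (exhaustive) {
      p <- sum(sameSign & extreme) / max(sum(sameSign), 1)
    } else {
      p <- (1 + sum(sameSign & extreme)) / (1 + sum(sameSign))
    }
    denom <- mean(abs(nullES[sameSign]))
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_

    # leading edge: members at or before (after, for negative ES) the extreme
    runSum <- cumsum(ifelse(inSet, absw * inSet / sum(absw[inSet]),
                            -1 / (N - m)))
    peak <- if (es >= 0) which.max(runSum) else which.min(runSum)
    le <- if (es >= 0) ids[seq_len(peak)][inSet[seq_len(peak)]]
          else ids[peak:N][inSet[peak:N]]
    rows[[nm]] <- data.frame(set_id = nm, kind = kind, size = m,
                             ES = es, NES = nes, p_value = p,
                             leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set_id = character(), kind = character(),
                      size = integer(), ES = numeric(), NES = numeric(),
                      p_value = numeric(), adj_p_value = numeric(),
                      leading_edge = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p_value <- p.adjust(out$p_value, method = "BH")
  out[, c("set_id", "kind", "size", "ES", "NES", "p_value",
          "adj_p_value", "leading_edge")]
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated format: set name, description, then member ids.
#'
#' @param path file path.
#' @return named list of sets, each `list(set_id, kind = "pathway",
#'   description, members)`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    sets[[f[1]]] <- list(set_id = f[1], kind = "pathway",
                         description = f[2],
                         members = unique(f[-(1:2)]))
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of sets (`members` element or character vectors).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    members <- if (is.list(s)) s$members else s
    desc <- if (is.list(s) && !is.null(s$description)) s$description else nm
    paste(c(nm, desc, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-class lipid regulation dot plot
#'
#' Fold changes of individual lipids grouped by class, with classes whose
#' set-enrichment adjusted p-value passes `alpha` highlighted — the standard
#' class-level summary view of a targeted panel.
#'
#' @param results differential results data.frame (needs `feature_id`,
#'   `logFC`).
#' @param enrichment output of [prerankedEnrichment()] on the class sets.
#' @param alpha significance threshold on `adj_p_value`, default 0.05.
#' @return a ggplot object.
#' @export
plotClassEnrichment <- function(results, enrichment, alpha = 0.05) {
  cat <- parseLipidCatalog(results$feature_id)
  df <- data.frame(class = cat$lipid_class, logFC = results$logFC)
  sig <- enrichment$set_id[enrichment$kind == "class" &
                           enrichment$adj_p_value < alpha]
  sig <- sub("^class:", "", sig)
  df$significant <- df$class %in% sig
  ggplot2::ggplot(df, ggplot2::aes(x = class, y = logFC,
                                   colour = significant)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "lipid class", y = "logFC",
                  colour = paste0("adj p < ", alpha)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
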