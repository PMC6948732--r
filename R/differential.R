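#' Per-feature two-group fits
#'
#' Computes, for every feature, the log2 fold change (numerator group mean
#' minus denominator group mean), the pooled residual variance and the
#' residual degrees of freedom, using only observed values. Features with
#' fewer than 2 observations in either group are flagged (`ok = FALSE`) and
#' carry missing statistics rather than being dropped silently.
#'
#' @param x a log2-scale [FeatureMatrix-class]
#' @param contrast character(2): `c(numerator, denominator)` group labels.
#' @return data.frame with `feature_id, logFC, s2, df, n1, n2, ok`.
#' @export
fitTwoGroup <- function(x, contrast) {
  stopifnot(is(x, "FeatureMatrix"), length(contrast) == 2)
  if (scaleFlag(x) != "log2")
    stop("fitTwoGroup expects log2-scale intensities")
  grp <- groupLabels(x)
  absent <- setdiff(contrast, unique(grp))
  if (length(absent))
    stop("group(s) absent from matrix: ", paste(absent, collapse = ", "))
  v <- intensities(x)
  c1 <- which(grp == contrast[1])
  c2 <- which(grp == contrast[2])
  v1 <- v[, c1, drop = FALSE]
  v2 <- v[, c2, drop = FALSE]
  n1 <- rowSums(!is.na(v1))
  n2 <- rowSums(!is.na(v2))
  m1 <- rowMeans(v1, na.rm = TRUE)
  m2 <- rowMeans(v2, na.rm = TRUE)
  ss1 <- rowSums((v1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((v2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  ok <- n1 >= 2 & n2 >= 2
  s2 <- ifelse(ok & df > 0, (ss1 + ss2) / pmax(df, 1), NA_real_)
  res <- data.frame(feature_id = rownames(v),
                    logFC = ifelse(ok, m1 - m2, NA_real_),
                    s2 = s2,
                    df = ifelse(ok, df, NA_integer_),
                    n1 = n1, n2 = n2, ok = ok,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  res
}

# Newton inversion of the trigamma function, y = trigamma(x) solved for x.
trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi)) return(NA_real_)
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks per-feature variances toward a common prior and computes
#' moderated t-statistics: the prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by method of moments on the log sample
#' variances (an `s^2 ~ s0^2 F(d, d0)` model, so
#' `E[log s2] = log s0^2 + psi(d/2) - log(d/2) - psi(d0/2) + log(d0/2)` and
#' `Var[log s2] = psi'(d/2) + psi'(d0/2)`); the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` and t is referred to a t-distribution on
#' `d0 + d` degrees of freedom. Benjamini-Hochberg adjustment is applied
#' across features.
#'
#' @param fits output of [fitTwoGroup()].
#' @param priorDf optional override of the estimated prior df; `0` gives
#'   ordinary pooled two-sample t-statistics.
#' @return data.frame with `feature_id, logFC, t, p_value, adj_p_value,
#'   direction` plus the fit columns; hyperparameters in attributes
#'   `prior_df` and `prior_var`.
#' @export
ebayesModerate <- function(fits, priorDf = NULL) {
  use <- fits$ok & !is.na(fits$s2) & fits$df > 0
  if (!any(use)) stop("no feature with enough observations to moderate")
  s2 <- fits$s2[use]
  d <- fits$df[use]
  if (all(s2 == 0)) stop("all residual variances are zero (degenerate input)")
  est <- s2 > 0
  if (is.null(priorDf)) {
    if (sum(est) < 10) {
      warning("fewer than 10 features with positive variance; ",
              "falling back to ordinary t-statistics")
      d0 <- 0
      s02 <- NA_real_
    } else {
      z <- log(s2[est])
      e <- z - digamma(d[est] / 2) + log(d[est] / 2)
      evar <- var(e) - mean(trigamma(d[est] / 2))
      if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s02 <- exp(mean(e))
      } else {
        d0 <- 2 * trigammaInverse(evar)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    d0 <- priorDf
    s02 <- if (d0 > 0) exp(mean(log(s2[est]))) else NA_real_
  }
  s2post <- rep(NA_real_, nrow(fits))
  if (d0 == 0) {
    s2post[use] <- s2
  } else if (is.infinite(d0)) {
    s2post[use] <- s02
  } else {
    s2post[use] <- (d0 * s02 + d * s2) / (d0 + d)
  }
  seFac <- sqrt(1 / fits$n1 + 1 / fits$n2)
  tstat <- fits$logFC / (sqrt(s2post) * seFac)
  dfTotal <- fits$df + d0
  p <- 2 * pt(-abs(tstat), df = dfTotal)
  padj <- rep(NA_real_, length(p))
  padj[use] <- p.adjust(p[use], method = "BH")
  out <- data.frame(feature_id = fits$feature_id,
                    logFC = fits$logFC,
                    t = tstat,
                    p_value = p,
                    adj_p_value = padj,
                    direction = ifelse(fits$logFC >= 0, "up", "down"),
                    s2 = fits$s2, s2_post = s2post, df = fits$df,
                    n1 = fits$n1, n2 = fits$n2, ok = fits$ok,
                    stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  attr(out, "contrast") <- attr(fits, "contrast")
  out
}

#' Significance calls and regulation tallies
#'
#' Adds two flags per feature (raw-significant `p_value < pThreshold`,
#' adjusted-significant `adj_p_value < pThreshold`) and summary counts in
#' which up-/down-regulated tallies additionally require
#' `|logFC| > lfcThreshold` (strict) under the raw rule — the reporting
#' convention of the source workflow's overview table.
#'
#' @param results output of [ebayesModerate()].
#' @param pThreshold default 0.05.
#' @param lfcThreshold default 1.5 (strict `>`).
#' @return `results` with `significant_raw`, `significant_adj` columns; a
#'   `summary` attribute lists `n_tested, sig_raw, sig_adj, up, down`.
#' @export
callSignificant <- function(results, pThreshold = 0.05, lfcThreshold = 1.5) {
  results$significant_raw <- !is.na(results$p_value) &
    results$p_value < pThreshold
  results$significant_adj <- !is.na(results$adj_p_value) &
    results$adj_p_value < pThreshold
  up <- results$significant_raw & results$logFC > lfcThreshold
  down <- results$significant_raw & results$logFC < -lfcThreshold
  attr(results, "summary") <- list(
    n_tested = sum(results$ok),
    sig_raw = sum(results$significant_raw),
    sig_adj = sum(results$significant_adj),
    up = sum(up, na.rm = TRUE),
    down = sum(down, na.rm = TRUE))
  results
}

#' One-call two-group differential analysis
#'
#' Convenience wrapper: [fitTwoGroup()] then [ebayesModerate()] then
#' [callSignificant()].
#'
#' @inheritParams fitTwoGroup
#' @inheritParams callSignificant
#' @return see [callSignificant()].
#' @export
runDifferential <- function(x, contrast, pThreshold = 0.05,
                            lfcThreshold = 1.5) {
  callSignificant(ebayesModerate(fitTwoGroup(x, contrast)),
                  pThreshold, lfcThreshold)
}
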