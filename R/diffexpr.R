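#' Log2 transform with pseudocount
#'
#' @param x TimecourseExperiment or numeric matrix of non-negative
#'   abundances.
#' @param pseudocount strictly positive offset, default 1.
#' @return matrix of \code{log2(value + pseudocount)} (for a
#'   TimecourseExperiment the design is preserved as attributes via
#'   [logAbundances()]; use that for pipeline code).
#' @export
logTransform <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (methods::is(x, "TimecourseExperiment")) abundances(x) else x
  log2(m + pseudocount)
}

#' @rdname logTransform
#' @details \code{logAbundances} returns the TimecourseExperiment with an
#'   extra \code{"log2"} assay.
#' @export
logAbundances <- function(x, pseudocount = 1) {
  SummarizedExperiment::assay(x, "log2") <- logTransform(x, pseudocount)
  x
}

trigammaInverse <- function(y) {
  # Newton iteration on x -> trigamma(x); y > 0
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits a per-gene two-group contrast on log-scale values, shrinking
#' gene-wise residual variances toward a common prior.  The prior
#' (scale \code{s0^2}, degrees of freedom \code{d0}) is estimated by a
#' method-of-moments fit of a scaled inverse-chi-square distribution on the
#' log residual variances; the moderated statistic uses the posterior
#' variance \code{(d0 s0^2 + d s^2) / (d0 + d)} with \code{d0 + d} degrees
#' of freedom.  \code{priorDf = 0} degenerates exactly to the classic
#' pooled-variance two-sample t-test.
#'
#' @param logMatrix genes x samples matrix of log2 abundances.
#' @param design design data.frame (sample, timepoint, replicate).
#' @param groupA,groupB timepoint labels; the fold-change is B over A.
#' @param priorDf optional fixed prior degrees of freedom (overrides the
#'   method-of-moments estimate; 0 disables moderation).
#' @return data.frame (one row per gene): \code{gene}, \code{mean_a},
#'   \code{mean_b}, \code{log2_fc}, \code{t_mod}, \code{df},
#'   \code{p_raw}, \code{p_adj} (Benjamini-Hochberg within this
#'   comparison), \code{comparison}.
#' @export
moderatedTTest <- function(logMatrix, design, groupA, groupB,
                           priorDf = NULL) {
  design <- validateDesign(design)
  sa <- design$sample[design$timepoint == groupA]
  sb <- design$sample[design$timepoint == groupB]
  sa <- intersect(sa, colnames(logMatrix))
  sb <- intersect(sb, colnames(logMatrix))
  nA <- length(sa); nB <- length(sb)
  if (nA < 2L || nB < 2L)
    stop("each group needs >= 2 samples (", groupA, ": ", nA, ", ",
         groupB, ": ", nB, ")")
  A <- logMatrix[, sa, drop = FALSE]
  B <- logMatrix[, sb, drop = FALSE]
  meanA <- rowMeans(A); meanB <- rowMeans(B)
  d <- nA + nB - 2L
  s2 <- (rowSums((A - meanA)^2) + rowSums((B - meanB)^2)) / d
  if (is.null(priorDf)) {
    pos <- s2 > 0
    if (sum(pos) >= 2L) {
      e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
      varE <- var(e)
      excess <- varE - trigamma(d / 2)
      if (is.finite(excess) && excess > 0) {
        d0 <- 2 * trigammaInverse(excess)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {   # no excess dispersion: complete shrinkage
        d0 <- Inf
        s02 <- exp(mean(e))
      }
    } else {
      d0 <- 0; s02 <- 0
    }
  } else {
    d0 <- priorDf
    s02 <- if (d0 > 0) {
      pos <- s2 > 0
      e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else 0
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  diff <- meanB - meanA
  se <- sqrt(s2post * (1 / nA + 1 / nB))
  tmod <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  dfTotal <- if (is.infinite(d0)) Inf else d + d0
  p <- ifelse(is.infinite(tmod), 0,
              2 * pt(-abs(tmod), df = if (is.infinite(dfTotal)) 1e8 else dfTotal))
  p[se == 0 & diff == 0] <- 1
  res <- data.frame(gene = rownames(logMatrix), mean_a = meanA,
                    mean_b = meanB, log2_fc = diff, t_mod = tmod,
                    df = dfTotal, p_raw = p,
                    p_adj = p.adjust(p, method = "BH"),
                    comparison = paste0(groupB, "_vs_", groupA),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "priorDf") <- d0
  attr(res, "priorVar") <- s02
  res
}

#' Filter differentially expressed genes
#'
#' Default thresholds: |log2FC| >= 1 (boundary inclusive) and raw
#' p < 0.05 (boundary exclusive).  Set \code{useAdjusted = TRUE} to gate on
#' the BH-adjusted p instead.
#'
#' @param result data.frame from [moderatedTTest()].
#' @param lfcMin minimum absolute log2 fold-change (inclusive).
#' @param pMax p-value ceiling (exclusive).
#' @param useAdjusted gate on \code{p_adj} instead of \code{p_raw}.
#' @return character vector of gene ids, in input order.
#' @export
filterDegs <- function(result, lfcMin = 1, pMax = 0.05,
                       useAdjusted = FALSE) {
  p <- if (useAdjusted) result$p_adj else result$p_raw
  result$gene[abs(result$log2_fc) >= lfcMin & p < pMax]
}

#' Union of DEG sets over comparisons
#'
#' @param degSets list of character vectors (or a list of result
#'   data.frames, filtered with the default thresholds).
#' @param ... passed to [filterDegs()] when data.frames are supplied.
#' @return stable-sorted character vector.
#' @export
unionDegs <- function(degSets, ...) {
  sets <- lapply(degSets, function(s)
    if (is.data.frame(s)) filterDegs(s, ...) else as.character(s))
  sort(unique(unlist(sets)))
}

#' Run all pairwise timepoint comparisons
#'
#' @param logMatrix genes x samples log2 matrix.
#' @param design design data.frame.
#' @param ... passed to [moderatedTTest()].
#' @return named list of result data.frames, one per ordered pair
#'   (later vs earlier), e.g. \code{"D4_vs_D0"}.
#' @export
allComparisons <- function(logMatrix, design, ...) {
  design <- validateDesign(design)
  tp <- levels(design$timepoint)
  prs <- combn(seq_along(tp), 2L)
  out <- list()
  for (k in seq_len(ncol(prs))) {
    a <- tp[prs[1L, k]]; b <- tp[prs[2L, k]]
    out[[paste0(b, "_vs_", a)]] <-
      moderatedTTest(logMatrix, design, a, b, ...)
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' \code{fold = 2^-((ctTarget - ctReference) -
#' (ctTargetCalibrator - ctReferenceCalibrator))}.
#'
#' @param ctTarget,ctReference Ct of target and reference gene in the
#'   sample of interest.
#' @param ctTargetCalibrator,ctReferenceCalibrator same in the calibrator
#'   sample.
#' @return fold-change relative to the calibrator.
#' @export
ddctRelativeExpression <- function(ctTarget, ctReference,
                                   ctTargetCalibrator,
                                   ctReferenceCalibrator) {
  ct <- c(ctTarget, ctReference, ctTargetCalibrator, ctReferenceCalibrator)
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  ddct <- (ctTarget - ctReference) -
    (ctTargetCalibrator - ctReferenceCalibrator)
  2^(-ddct)
}
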