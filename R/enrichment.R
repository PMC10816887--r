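#' Over-representation analysis
#'
#' Upper-tail hypergeometric test P(X >= k) of a query gene list against
#' each set of a collection, with BH adjustment across the tested sets.
#' Query genes outside the universe are dropped with a warning; sets are
#' intersected with the universe and skipped below \code{minSize} or above
#' \code{maxSize}.
#'
#' @param query character, query gene ids.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character, background gene ids.
#' @param minSize,maxSize set size bounds after universe intersection.
#' @return data.frame: set, k, K, n, N, p_hyper, p_adj, overlap
#'   (comma-joined ids), ordered by p_hyper.
#' @export
ora <- function(query, collection, universe, minSize = 3L, maxSize = 500L) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query id(s) outside the universe")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(setIds(collection), function(id) {
    members <- intersect(geneSets(collection)[[id]], universe)
    K <- length(members)
    if (K < minSize || K > maxSize) return(NULL)
    ov <- intersect(query, members)
    k <- length(ov)
    data.frame(set = id, k = k, K = K, n = n, N = N,
               p_hyper = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_hyper = numeric(),
                      p_adj = numeric(), overlap = character()))
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p_hyper, method = "BH")
  res <- res[order(res$p_hyper), c("set", "k", "K", "n", "N",
                                   "p_hyper", "p_adj", "overlap")]
  rownames(res) <- NULL
  res
}

# single-sample rank-weighted KS walk; expr: named numeric for one sample
ssWalkScore <- function(expr, members, tau) {
  N <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  inSet <- names(expr)[ord] %in% members
  K <- sum(inSet)
  if (K >= N || K < 2L) return(NA_real_)
  rankWeight <- (N:1)^tau            # top-ranked gene gets the largest weight
  wIn <- rankWeight * inSet
  steps <- ifelse(inSet, wIn / sum(wIn), -1 / (N - K))
  walk <- cumsum(steps)
  walk[which.max(abs(walk))]
}

#' Per-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by decreasing expression and a
#' weighted Kolmogorov-Smirnov random walk is run for every set: inside
#' steps are weighted by rank^tau (top gene = rank N) normalized to sum 1,
#' outside steps are -1/(N-K).  The score is the maximum-magnitude
#' deviation of the walk (signed).  Being rank-based, scores are invariant
#' under strictly monotone transforms of a sample's expression values.
#' Sets with fewer than two matrix genes, or covering the whole matrix,
#' are skipped with a warning.
#'
#' @param logMatrix genes x samples matrix.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param tau rank weight exponent >= 0, default 0.25.
#' @return set x sample score matrix (skipped sets absent), with
#'   \code{tau} attribute.
#' @export
sampleScores <- function(logMatrix, collection, tau = 0.25) {
  stopifnot(tau >= 0)
  genes <- rownames(logMatrix)
  sets <- lapply(geneSets(collection), intersect, genes)
  sizes <- vapply(sets, length, integer(1))
  skip <- sizes < 2L | sizes >= length(genes)
  if (any(skip))
    warning("skipping ", sum(skip), " set(s) with < 2 matrix genes or ",
            "covering all genes: ",
            paste(head(names(sets)[skip], 5L), collapse = ", "))
  sets <- sets[!skip]
  scores <- matrix(NA_real_, length(sets), ncol(logMatrix),
                   dimnames = list(names(sets), colnames(logMatrix)))
  for (s in colnames(logMatrix)) {
    expr <- setNames(logMatrix[, s], genes)
    for (id in names(sets))
      scores[id, s] <- ssWalkScore(expr, sets[[id]], tau)
  }
  attr(scores, "tau") <- tau
  scores
}

#' Significance of enrichment-score changes across timepoints
#'
#' Applies the moderated t-test (the same machinery as the expression
#' contrasts) to the per-sample score matrix for each requested timepoint
#' pair, with BH adjustment across sets within a comparison.  Significance
#' gate: adjusted p <= \code{alpha} (boundary inclusive).
#'
#' @param scores set x sample matrix from [sampleScores()].
#' @param design design data.frame.
#' @param contrasts list of c(groupA, groupB) pairs; default last vs
#'   first timepoint.
#' @param alpha adjusted-p ceiling (inclusive), default 0.05.
#' @return data.frame: set, comparison, delta (mean score change B-A),
#'   t_mod, p_raw, p_adj, significant.
#' @export
scoreSignificance <- function(scores, design, contrasts = NULL,
                              alpha = 0.05) {
  design <- validateDesign(design)
  tp <- levels(design$timepoint)
  if (is.null(contrasts))
    contrasts <- list(c(tp[1L], tp[length(tp)]))
  out <- list()
  for (ct in contrasts) {
    res <- moderatedTTest(scores, design, ct[1L], ct[2L])
    out[[length(out) + 1L]] <-
      data.frame(set = res$gene, comparison = res$comparison,
                 delta = res$log2_fc, t_mod = res$t_mod,
                 p_raw = res$p_raw, p_adj = res$p_adj,
                 significant = res$p_adj <= alpha,
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
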