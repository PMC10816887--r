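#' TF family enrichment
#'
#' For every family, tests over-representation of a differentially
#' expressed TF subset against the annotated TF universe: the upper-tail
#' cumulative hypergeometric P(X >= k) with the total annotated TFs as the
#' background, plus a two-sided Fisher exact p on the same 2x2 table; BH
#' adjustment of the hypergeometric p across families.
#'
#' @param tfSubset character, differentially expressed TF gene ids.
#' @param annotation named character gene -> family ([readTfAnnotation()]).
#' @param universe annotated TF universe (default: all annotated genes).
#' @return data.frame: family, k (overlap), K (family size), n (subset
#'   size), N (universe), p_hyper, p_fisher, p_adj.
#' @export
tfFamilyEnrichment <- function(tfSubset, annotation,
                               universe = names(annotation)) {
  universe <- unique(universe)
  annotation <- annotation[intersect(names(annotation), universe)]
  tfSubset <- intersect(unique(tfSubset), universe)
  N <- length(universe); n <- length(tfSubset)
  fams <- unique(annotation)
  rows <- lapply(fams, function(f) {
    members <- names(annotation)[annotation == f]
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(tfSubset, members))
    pHyper <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2L)
    pFisher <- fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(family = f, k = k, K = K, n = n, N = N,
               p_hyper = pHyper, p_fisher = pFisher)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p_hyper, method = "BH")
  res[order(res$p_hyper), , drop = FALSE]
}

# per-motif exact null score distribution under the background model,
# scores discretized to `bin` log2 units; returns list(breaks, tail)
# where tail[i] = P(score >= breaks[i])
pwmNullDistribution <- function(logOdds, background, bin = 1e-3) {
  intScores <- round(logOdds / bin)
  lo <- sum(apply(intScores, 2L, min))
  hi <- sum(apply(intScores, 2L, max))
  dist <- c(1)          # probability vector over offset (score - lo)
  offset <- 0L
  for (j in seq_len(ncol(intScores))) {
    colMin <- min(intScores[, j])
    span <- max(intScores[, j]) - colMin
    newDist <- numeric(length(dist) + span)
    for (b in 1:4) {
      sh <- intScores[b, j] - colMin
      idx <- seq_along(dist) + sh
      newDist[idx] <- newDist[idx] + dist * background[b]
    }
    dist <- newDist
    offset <- offset + colMin
  }
  tail <- rev(cumsum(rev(dist)))
  list(lo = lo, bin = bin, tail = tail)
}

pwmNullPvalue <- function(null, score) {
  idx <- round(score / null$bin) - null$lo + 1L
  idx <- pmin(pmax(idx, 1L), length(null$tail) + 1L)
  ifelse(idx > length(null$tail), 0, null$tail[idx])
}

BASES <- c("A", "C", "G", "T", "N")

seqCodes <- function(s) {
  match(strsplit(as.character(s), "")[[1L]], BASES)
}

revCompCodes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

scanOneStrand <- function(codes, lookup) {
  w <- ncol(lookup); L <- length(codes)
  if (w > L) return(numeric(0))
  nPos <- L - w + 1L
  scores <- numeric(nPos)
  for (j in seq_len(w))
    scores <- scores + lookup[codes[j:(j + nPos - 1L)], j]
  scores
}

#' Scan promoters with a PWM library
#'
#' Sliding-window log-odds score
#' \code{sum_i log2(pwm[base_i, i] / background[base_i])} on both strands,
#' with PWM probabilities floored at a pseudo-frequency before taking
#' logs.  Per-score p-values come from the exact null distribution of the
#' score under the background model, computed by dynamic programming over
#' motif positions with scores discretized to \code{bin} log2 units.  An N
#' base contributes the background probability, i.e. a log-odds term of
#' exactly 0.  Hits are windows with p <= \code{pThreshold}.  Offsets are
#' 0-based window starts on the forward sequence; minus-strand hits report
#' the forward-coordinate start of the reverse-complement window.
#'
#' @param promoters named DNAStringSet (or named character vector).
#' @param pwmLibrary a \linkS4class{PwmLibrary}.
#' @param pThreshold hit p-value ceiling, default 1e-4.
#' @param pseudoFreq probability floor before log-odds, default 1e-4.
#' @param bin score discretization for the null DP, default 1e-3.
#' @param bothStrands scan the reverse complement too.
#' @return data.frame: motif, gene, offset, strand, score, p_value.
#' @export
pwmScan <- function(promoters, pwmLibrary, pThreshold = 1e-4,
                    pseudoFreq = 1e-4, bin = 1e-3, bothStrands = TRUE) {
  bg <- pwmLibrary@background
  seqs <- setNames(as.character(promoters), names(promoters))
  if (is.null(names(seqs))) stop("promoters must be named")
  hits <- list()
  for (id in motifIds(pwmLibrary)) {
    pwm <- pmax(motifMatrix(pwmLibrary, id), pseudoFreq)
    pwm <- sweep(pwm, 2L, colSums(pwm), "/")
    logOdds <- log2(pwm / bg)
    null <- pwmNullDistribution(logOdds, bg, bin)
    lookup <- rbind(logOdds, N = 0)   # row 5: N scores 0
    w <- ncol(lookup)
    for (g in names(seqs)) {
      codes <- seqCodes(seqs[[g]])
      if (w > length(codes)) {
        warning(sprintf("motif %s (width %d) wider than promoter %s; skipped",
                        id, w, g))
        next
      }
      strands <- if (bothStrands) c("+", "-") else "+"
      for (st in strands) {
        sc <- if (st == "+") scanOneStrand(codes, lookup) else
          scanOneStrand(revCompCodes(codes), lookup)
        pv <- pwmNullPvalue(null, sc)
        keep <- which(pv <= pThreshold)
        if (!length(keep)) next
        off <- keep - 1L
        if (st == "-") off <- length(codes) - w - off   # forward coordinates
        hits[[length(hits) + 1L]] <-
          data.frame(motif = id, gene = g, offset = off, strand = st,
                     score = sc[keep], p_value = pv[keep],
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), gene = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$motif, out$gene, out$offset), , drop = FALSE]
}

#' Define transcriptional states from contiguous comparisons
#'
#' State s compares timepoint s+1 against timepoint s.  Each state carries
#' its DEG set with per-gene direction (sign of the log2 fold-change) and
#' the differentially expressed TF subset.
#'
#' @param comparisons named list from [allComparisons()].
#' @param design design data.frame (for the timepoint order).
#' @param tfAnnotation named character gene -> family.
#' @param ... thresholds passed to [filterDegs()].
#' @return list of states: label, comparison, degs (named character
#'   "up"/"down"), tfs (character).
#' @export
makeStates <- function(comparisons, design, tfAnnotation, ...) {
  design <- validateDesign(design)
  tp <- levels(design$timepoint)
  states <- list()
  for (s in seq_len(length(tp) - 1L)) {
    cmp <- paste0(tp[s + 1L], "_vs_", tp[s])
    res <- comparisons[[cmp]]
    if (is.null(res)) stop("missing comparison ", cmp)
    degs <- filterDegs(res, ...)
    dir <- setNames(ifelse(res$log2_fc[match(degs, res$gene)] > 0,
                           "up", "down"), degs)
    states[[s]] <- list(label = s, comparison = cmp, degs = dir,
                        tfs = intersect(degs, names(tfAnnotation)))
  }
  states
}

#' Build the directional regulatory network of one transcriptional state
#'
#' An edge TF -> target requires: the TF differentially expressed in the
#' state, the target in the state's DEG set, and a motif hit for one of
#' the TF's motifs in the target's promoter.  The sign is activation when
#' TF and target change in the same direction in the comparison,
#' inhibition otherwise.
#'
#' @param state one element of [makeStates()].
#' @param motifHits data.frame from [pwmScan()].
#' @param tfMotifMap data.frame with columns tf, motif.
#' @return data.frame: tf, target, state, sign, motif, offset, strand,
#'   score, p_value.  TFs without a mapped motif contribute no edges and
#'   are listed in the \code{"unmapped_tfs"} attribute.
#' @export
buildStateNetwork <- function(state, motifHits, tfMotifMap) {
  degs <- state$degs
  edges <- list()
  unmapped <- character()
  for (tf in state$tfs) {
    motifs <- tfMotifMap$motif[tfMotifMap$tf == tf]
    if (!length(motifs)) { unmapped <- c(unmapped, tf); next }
    h <- motifHits[motifHits$motif %in% motifs &
                     motifHits$gene %in% names(degs) &
                     motifHits$gene != tf, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[!duplicated(h$gene), , drop = FALSE]   # one supporting hit each
    sign <- ifelse(degs[h$gene] == degs[[tf]], "activation", "inhibition")
    edges[[length(edges) + 1L]] <-
      data.frame(tf = tf, target = h$gene, state = state$label,
                 sign = sign, motif = h$motif, offset = h$offset,
                 strand = h$strand, score = h$score, p_value = h$p_value,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf = character(), target = character(), state = integer(),
               sign = character(), motif = character(), offset = integer(),
               strand = character(), score = numeric(), p_value = numeric())
  rownames(out) <- NULL
  attr(out, "unmapped_tfs") <- unique(unmapped)
  out
}

#' Count regulatory pairs per state
#'
#' @param edges data.frame from [buildStateNetwork()] (states row-bound).
#' @return list: \code{counts} (data.frame state, activation, inhibition)
#'   and \code{multiStateTfs} (TFs active in more than one state).
#' @export
countPairs <- function(edges) {
  states <- sort(unique(edges$state))
  counts <- data.frame(
    state = states,
    activation = vapply(states, function(s)
      sum(edges$state == s & edges$sign == "activation"), integer(1)),
    inhibition = vapply(states, function(s)
      sum(edges$state == s & edges$sign == "inhibition"), integer(1)))
  tfStates <- unique(edges[c("tf", "state")])
  multi <- names(which(table(tfStates$tf) > 1L))
  list(counts = counts, multiStateTfs = multi)
}
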