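#' Candidate DNB modules at one timepoint
#'
#' Genes are clustered by average-linkage hierarchical clustering on the
#' distance \code{1 - |r|}, where r is the Pearson correlation over the
#' replicate values at the timepoint.  The tree is cut at a grid of
#' heights and every resulting cluster within the size bounds is returned
#' (deduplicated across heights).
#'
#' @param logMatrix genes x samples log2 matrix (rows = analyzed gene set,
#'   typically the union DEG set).
#' @param design design data.frame.
#' @param timepoint timepoint label.
#' @param minSize,maxSize module size bounds (defaults 5 and 100).
#' @param heights cut heights on 1 - |r| (defaults 0.2, 0.4, 0.6, 0.8).
#' @return list of character vectors (gene-id modules, sorted members).
#' @export
candidateModules <- function(logMatrix, design, timepoint, minSize = 5L,
                             maxSize = 100L,
                             heights = c(0.2, 0.4, 0.6, 0.8)) {
  design <- validateDesign(design)
  cols <- design$sample[design$timepoint == timepoint]
  if (length(cols) < 3L)
    stop("need >= 3 replicates at ", timepoint)
  sub <- logMatrix[, cols, drop = FALSE]
  keep <- apply(sub, 1L, sd) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < minSize)
    stop("fewer than minSize analyzable genes at ", timepoint)
  r <- cor(t(sub))
  d <- as.dist(1 - abs(r))
  hc <- hclust(d, method = "average")
  mods <- list()
  seen <- character()
  for (h in heights) {
    ct <- cutree(hc, h = h)
    for (cl in unique(ct)) {
      members <- sort(names(ct)[ct == cl])
      if (length(members) < minSize || length(members) > maxSize) next
      key <- paste(members, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      mods[[length(mods) + 1L]] <- members
    }
  }
  mods
}

#' DNB statistics of one module at one timepoint
#'
#' SDin: mean within-timepoint sample standard deviation (n-1 denominator)
#' of member genes across replicates.  PCCin: mean absolute Pearson
#' correlation over all member pairs.  PCCout: mean absolute Pearson
#' correlation between members and all non-member analyzed genes.
#' CI = SDin * PCCin / max(PCCout, epsilon).  Correlations involving a
#' zero-variance gene are defined as 0 and flagged.
#'
#' @param module character, member gene ids (>= 2).
#' @param logMatrix genes x samples log2 matrix (rows = analyzed set).
#' @param design design data.frame.
#' @param timepoint timepoint label.
#' @param epsilon denominator floor on PCCout, default 0.05.
#' @return one-row data.frame: timepoint, size, SDin, PCCin, PCCout, CI,
#'   plus a \code{"flagged"} attribute with zero-variance member ids.
#' @export
moduleStats <- function(module, logMatrix, design, timepoint,
                        epsilon = 0.05) {
  if (length(module) < 2L) stop("module needs >= 2 members")
  design <- validateDesign(design)
  cols <- design$sample[design$timepoint == timepoint]
  sub <- logMatrix[, cols, drop = FALSE]
  members <- intersect(module, rownames(sub))
  outside <- setdiff(rownames(sub), members)
  M <- sub[members, , drop = FALSE]
  sds <- apply(M, 1L, sd)
  SDin <- mean(sds)
  flagged <- members[sds == 0]
  safeCor <- function(X, Y = NULL) {
    suppressWarnings(r <- cor(t(X), if (is.null(Y)) NULL else t(Y)))
    r[is.na(r)] <- 0
    r
  }
  rIn <- safeCor(M)
  PCCin <- if (length(members) > 1L)
    mean(abs(rIn[upper.tri(rIn)])) else 0
  PCCout <- if (length(outside)) {
    rOut <- safeCor(M, sub[outside, , drop = FALSE])
    mean(abs(rOut))
  } else 0
  CI <- SDin * PCCin / max(PCCout, epsilon)
  out <- data.frame(timepoint = timepoint, size = length(members),
                    SDin = SDin, PCCin = PCCin, PCCout = PCCout, CI = CI,
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  out
}

#' Criticality-index curve and tipping point
#'
#' For every timepoint, the best candidate module is the one maximizing CI
#' (ties: larger module, then lexicographically smallest member list); the
#' tipping point is the timepoint whose best CI is maximal, and the best
#' module there is the DNB member set.
#'
#' @param logMatrix genes x samples log2 matrix over the analyzed gene set.
#' @param design design data.frame.
#' @param minSize,maxSize,heights passed to [candidateModules()].
#' @param epsilon passed to [moduleStats()].
#' @return a \linkS4class{DnbResult}.
#' @export
criticalityCurve <- function(logMatrix, design, minSize = 5L,
                             maxSize = 100L,
                             heights = c(0.2, 0.4, 0.6, 0.8),
                             epsilon = 0.05) {
  design <- validateDesign(design)
  tp <- levels(design$timepoint)
  rows <- list(); best <- list()
  for (t in tp) {
    mods <- candidateModules(logMatrix, design, t, minSize, maxSize,
                             heights)
    if (!length(mods))
      stop("no candidate module at ", t,
           " within the size bounds; widen heights or sizes")
    stats <- lapply(mods, moduleStats, logMatrix = logMatrix,
                    design = design, timepoint = t, epsilon = epsilon)
    ci <- vapply(stats, function(s) s$CI, numeric(1))
    sz <- vapply(stats, function(s) s$size, numeric(1))
    key <- vapply(mods, paste, character(1), collapse = ",")
    ord <- order(-ci, -sz, key)
    pick <- ord[1L]
    rows[[t]] <- stats[[pick]]
    best[[t]] <- mods[[pick]]
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  ciBest <- curve$CI
  if (all(ciBest == ciBest[1L]) && length(ciBest) > 1L)
    warning("all timepoints have equal CI; earliest chosen as tip")
  tip <- tp[which.max(ciBest)]
  methods::new("DnbResult", curve = curve, tip = tip,
               members = best[[tip]], modules = best)
}

#' DNB member-centered neighborhood network
#'
#' Induced subnetwork on the DNB members plus their first neighbors that
#' are differential genes; isolated members are retained as nodes.
#' Members absent from the interaction network are reported via the
#' \code{"dropped"} attribute (with their count), mirroring the situation
#' where some members have no protein-level interactions.
#'
#' @param members DNB member gene ids.
#' @param network data.frame from, to, weight ([readEdges()]).
#' @param degSet differential gene ids eligible as neighbors.
#' @return list: \code{nodes} (character), \code{edges} (data.frame
#'   from, to, weight); attribute \code{"dropped"} lists members not in
#'   the network.
#' @export
dnbNeighborhood <- function(members, network, degSet) {
  g <- igraph::graph_from_data_frame(network[c("from", "to")],
                                     directed = FALSE)
  present <- intersect(members, igraph::V(g)$name)
  dropped <- setdiff(members, present)
  neigh <- character()
  if (length(present)) {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                               names)))
    neigh <- intersect(setdiff(nb, members), degSet)
  }
  nodes <- union(members, neigh)
  keep <- network$from %in% nodes & network$to %in% nodes
  edges <- network[keep, , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  attr(out, "dropped") <- dropped
  out
}
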