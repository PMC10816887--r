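#' Joint gene-metabolite pathway enrichment
#'
#' Runs over-representation separately on the gene side (DEGs vs the gene
#' members of each pathway) and the metabolite side (DRMs vs the
#' metabolite members), BH-adjusts within each side across pathways, and
#' flags pathways where both sides are significant at \code{alpha}.  A
#' Fisher combination chi-square = -2(ln p_g + ln p_m) with 4 df is also
#' reported.  A pathway with an empty side gets p = 1 on that side and can
#' never be joint.
#'
#' @param degSet differential gene ids.
#' @param drmSet differential metabolite ids.
#' @param pathwayMap data.frame pathway, member, type
#'   ([readPathwayMap()]).
#' @param geneUniverse,metUniverse background id sets.
#' @param alpha per-side adjusted-p ceiling (inclusive), default 0.05.
#' @param minSize minimum members per tested side, default 1.
#' @return data.frame: pathway, k_gene, K_gene, p_gene, p_gene_adj,
#'   k_met, K_met, p_met, p_met_adj, joint, chisq, p_combined.
#' @export
jointEnrichment <- function(degSet, drmSet, pathwayMap, geneUniverse,
                            metUniverse, alpha = 0.05, minSize = 1L) {
  pws <- unique(pathwayMap$pathway)
  degSet <- intersect(unique(degSet), geneUniverse)
  drmSet <- intersect(unique(drmSet), metUniverse)
  sideP <- function(query, members, universe) {
    members <- intersect(members, universe)
    K <- length(members)
    if (K < minSize)
      return(c(k = 0, K = K, p = 1))
    k <- length(intersect(query, members))
    c(k = k, K = K,
      p = phyper(k - 1L, K, length(universe) - K, length(query),
                 lower.tail = FALSE))
  }
  rows <- lapply(pws, function(pw) {
    sub <- pathwayMap[pathwayMap$pathway == pw, , drop = FALSE]
    g <- sideP(degSet, sub$member[sub$type == "gene"], geneUniverse)
    m <- sideP(drmSet, sub$member[sub$type == "metabolite"], metUniverse)
    data.frame(pathway = pw, k_gene = g["k"], K_gene = g["K"],
               p_gene = g["p"], k_met = m["k"], K_met = m["K"],
               p_met = m["p"], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_gene_adj <- p.adjust(res$p_gene, method = "BH")
  res$p_met_adj <- p.adjust(res$p_met, method = "BH")
  res$joint <- res$p_gene_adj <= alpha & res$p_met_adj <= alpha
  res$chisq <- -2 * (log(res$p_gene) + log(res$p_met))
  res$p_combined <- pchisq(res$chisq, df = 4, lower.tail = FALSE)
  res[order(res$p_combined),
      c("pathway", "k_gene", "K_gene", "p_gene", "p_gene_adj",
        "k_met", "K_met", "p_met", "p_met_adj", "joint", "chisq",
        "p_combined")]
}

#' Long-format projection of one pathway's members onto the screens
#'
#' Emits one row per pathway member per comparison: genes with their
#' log2 fold-change and metabolites with their fold-change and direction.
#' Members absent from the data get NA markers.
#'
#' @param degStats named list of [moderatedTTest()] results per
#'   comparison.
#' @param metScreens named list of [pairwiseDrm()] results per
#'   comparison.
#' @param pathwayMap data.frame pathway, member, type.
#' @param pathwayId pathway to project.
#' @return data.frame: pathway, member, type, comparison, log2_fc,
#'   fold_change, direction.
#' @export
pathwayProjectionTable <- function(degStats, metScreens, pathwayMap,
                                   pathwayId) {
  sub <- pathwayMap[pathwayMap$pathway == pathwayId, , drop = FALSE]
  if (!nrow(sub)) stop("unknown pathway: ", pathwayId)
  comparisons <- union(names(degStats), names(metScreens))
  rows <- list()
  for (cmp in comparisons) {
    dg <- degStats[[cmp]]; ms <- metScreens[[cmp]]
    for (i in seq_len(nrow(sub))) {
      member <- sub$member[i]; type <- sub$type[i]
      lfc <- NA_real_; fc <- NA_real_; dir <- NA_character_
      if (type == "gene" && !is.null(dg)) {
        j <- match(member, dg$gene)
        if (!is.na(j)) lfc <- dg$log2_fc[j]
      } else if (type == "metabolite" && !is.null(ms)) {
        j <- match(member, ms$metabolite)
        if (!is.na(j)) { fc <- ms$fold_change[j]; dir <- ms$direction[j] }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(pathway = pathwayId, member = member, type = type,
                   comparison = cmp, log2_fc = lfc, fold_change = fc,
                   direction = dir, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign concordance between gene and metabolite changes in a pathway
#'
#' Fraction of (gene, metabolite) member pairs within one pathway and one
#' comparison whose changes share a sign.  A descriptive summary only.
#'
#' @param projection output of [pathwayProjectionTable()].
#' @return data.frame: comparison, concordance.
#' @export
signConcordance <- function(projection) {
  out <- lapply(split(projection, projection$comparison), function(d) {
    gs <- sign(d$log2_fc[d$type == "gene"])
    msDir <- d$direction[d$type == "metabolite"]
    ms <- ifelse(msDir == "increased", 1, ifelse(msDir == "decreased", -1, 0))
    gs <- gs[is.finite(gs)]; ms <- ms[!is.na(ms)]
    conc <- if (length(gs) && length(ms))
      mean(outer(gs, ms, "==")) else NA_real_
    data.frame(comparison = d$comparison[1L], concordance = conc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
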