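#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: a 4-timepoint,
#' replicated time-course expression matrix with archetype clusters and one
#' planted DNB module, promoters with planted TF binding motifs, an
#' interaction network and a targeted metabolite panel with planted
#' fold-changes.  All generators are pure functions of this config (the
#' seed lives inside it).
#'
#' @param seed integer master seed.
#' @param nGenes total gene count (>= cluster members + DNB module size).
#' @param timepoints ordered timepoint labels.
#' @param nReplicates replicates per timepoint (expression).
#' @param clusterSpec list of archetypes, each
#'   \code{list(profile = <log2 offsets per timepoint>, n = <members>,
#'   sd = <log2 noise sd>)}.
#' @param dnbSpec \code{list(size, tip, rhoInPre, rhoInTip, rhoOut, sdMult,
#'   sd)}: module size, tipping timepoint index, within-module correlation
#'   before/at the tip, member-to-outside correlation, the factor by which
#'   member sd is scaled at the tip, and the baseline member sd.
#' @param tfSpec \code{list(nTfs, targetsPerTf, motifWidth, promoterLength,
#'   insertionRate, background)}.
#' @param metSpec \code{list(nMetabolites, nPlanted, plantedLfc, cv,
#'   nReplicates)}; planted metabolites shift all post-baseline timepoints
#'   by \code{plantedLfc} log2 units.
#' @param netSpec \code{list(avgDegree)}.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 600L,
                      timepoints = c("D0", "D4", "D8", "D12"),
                      nReplicates = 3L,
                      clusterSpec = list(
                        C1 = list(profile = c(1.5, -1.5, -0.7, 1.5), n = 60L, sd = 0.2),
                        C2 = list(profile = c(-1.5, -0.5, 0.6, 1.5), n = 60L, sd = 0.2),
                        C3 = list(profile = c(1.5, 0.6, -0.5, -1.5), n = 60L, sd = 0.2),
                        C4 = list(profile = c(-1.5, 1.5, 0.7, -1.5), n = 60L, sd = 0.2)),
                      dnbSpec = list(size = 20L, tip = 2L, rhoInPre = 0.25,
                                     rhoInTip = 0.9, rhoOut = 0.1,
                                     sdMult = 3, sd = 0.5,
                                     profile = c(0, 1.5, 2, 2)),
                      tfSpec = list(nTfs = 6L, targetsPerTf = 10L,
                                    motifWidth = 8L, promoterLength = 1000L,
                                    insertionRate = 1.0,
                                    background = c(A = .25, C = .25,
                                                   G = .25, T = .25)),
                      metSpec = list(nMetabolites = 50L, nPlanted = 16L,
                                     plantedLfc = 2, cv = 0.1,
                                     nReplicates = 5L),
                      netSpec = list(avgDegree = 4)) {
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              timepoints = timepoints, nReplicates = as.integer(nReplicates),
              clusterSpec = clusterSpec, dnbSpec = dnbSpec, tfSpec = tfSpec,
              metSpec = metSpec, netSpec = netSpec)
  nClust <- sum(vapply(clusterSpec, function(s) s$n, numeric(1)))
  if (nGenes < nClust + dnbSpec$size)
    stop("nGenes must cover cluster members plus the DNB module")
  if (dnbSpec$tip < 1L || dnbSpec$tip > length(timepoints))
    stop("dnbSpec$tip out of timepoint range")
  with(dnbSpec, {
    if (!(rhoOut >= 0 && rhoOut < rhoInTip && rhoInTip <= 1))
      stop("need 0 <= rhoOut < rhoInTip <= 1")
  })
  if (!is.null(dnbSpec$profile) &&
      length(dnbSpec$profile) != length(timepoints))
    stop("dnbSpec$profile length must match timepoints")
  bad <- vapply(clusterSpec, function(s)
    length(s$profile) != length(timepoints), logical(1))
  if (any(bad))
    stop("archetype profile length must match timepoints: ",
         names(clusterSpec)[bad][1L])
  structure(cfg, class = c("SimulationConfig", "list"))
}

subSeed <- function(seed, k) as.integer((seed + k * 7919L) %% 2147483629L)

#' Simulate a time-course expression matrix with planted structure
#'
#' Values are multivariate log-normal: normal on the log2 scale, then
#' exponentiated.  Archetype cluster members follow their profile means
#' plus independent noise.  DNB module members share a per-timepoint common
#' factor giving pairwise correlation \code{rhoInPre} (or \code{rhoInTip}
#' at the tipping timepoint) and sd scaled by \code{sdMult} there;
#' non-members load on the same factor so that the member-to-outside
#' correlation equals \code{rhoOut}.  This one-factor construction requires
#' \code{rhoOut^2 <= rhoIn}; violations mean the requested correlation
#' matrix is not positive semi-definite and raise an error naming the DNB
#' block.
#'
#' @param config a [simConfig()].
#' @return list with elements \code{tce} (a
#'   \linkS4class{TimecourseExperiment}), \code{clusters} (named character,
#'   gene -> archetype label, \code{"DNB"} or \code{"null"}) and
#'   \code{dnbMembers}.
#' @export
simulateTimecourse <- function(config) {
  set.seed(subSeed(config$seed, 0L))
  tp <- config$timepoints
  nT <- length(tp); nR <- config$nReplicates
  baseMean <- 6
  geneIds <- sprintf("G%04d", seq_len(config$nGenes))
  sampleIds <- paste0(rep(tp, each = nR), "_R", rep(seq_len(nR), nT))
  design <- data.frame(sample = sampleIds,
                       timepoint = factor(rep(tp, each = nR), levels = tp),
                       replicate = rep(seq_len(nR), nT))

  labels <- rep("null", config$nGenes)
  idx <- 1L
  for (nm in names(config$clusterSpec)) {
    n <- config$clusterSpec[[nm]]$n
    labels[idx:(idx + n - 1L)] <- nm
    idx <- idx + n
  }
  dnbIdx <- idx:(idx + config$dnbSpec$size - 1L)
  labels[dnbIdx] <- "DNB"
  names(labels) <- geneIds

  logm <- matrix(NA_real_, config$nGenes, nT * nR,
                 dimnames = list(geneIds, sampleIds))
  ds <- config$dnbSpec
  for (t in seq_len(nT)) {
    cols <- (t - 1L) * nR + seq_len(nR)
    rhoIn <- if (t == ds$tip) ds$rhoInTip else ds$rhoInPre
    if (ds$rhoOut^2 > rhoIn)
      stop(sprintf(paste0("DNB block correlation not positive semi-definite",
                          " at timepoint %s: rhoOut^2 (%.3g) > rhoIn (%.3g)"),
                   tp[t], ds$rhoOut^2, rhoIn))
    a <- sqrt(rhoIn)
    b <- if (a > 0) ds$rhoOut / a else 0
    sdDnb <- ds$sd * if (t == ds$tip) ds$sdMult else 1
    f <- rnorm(nR)   # shared factor, one draw per replicate sample
    for (g in seq_len(config$nGenes)) {
      lab <- labels[g]
      if (lab == "DNB") {
        z <- a * f + sqrt(1 - a^2) * rnorm(nR)
        dnbMean <- baseMean + if (is.null(ds$profile)) 0 else ds$profile[t]
        logm[g, cols] <- dnbMean + sdDnb * z
      } else if (lab == "null") {
        z <- b * f + sqrt(1 - b^2) * rnorm(nR)
        logm[g, cols] <- baseMean + 0.3 * z
      } else {
        sp <- config$clusterSpec[[lab]]
        z <- b * f + sqrt(1 - b^2) * rnorm(nR)
        logm[g, cols] <- baseMean + sp$profile[t] + sp$sd * z
      }
    }
  }
  tce <- TimecourseExperiment(2^logm, design)
  list(tce = tce, clusters = labels,
       dnbMembers = geneIds[dnbIdx], logMatrix = logm)
}

randomSeq <- function(n, bg) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

sharpPwm <- function(consensus, major = 0.97) {
  w <- nchar(consensus)
  m <- matrix((1 - major) / 3, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  cc <- strsplit(consensus, "")[[1L]]
  for (j in seq_len(w)) m[cc[j], j] <- major
  m
}

consensusOf <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
}

#' Simulate promoters with planted TF binding motifs
#'
#' Background sequences are i.i.d. draws from the background nucleotide
#' frequencies.  Each TF gets a sharp random-consensus PWM; for every
#' planted TF -> target pair (with probability \code{insertionRate}) one
#' exact-consensus instance is written into the target promoter at a
#' recorded position on the + strand.
#'
#' @param config a [simConfig()].
#' @param tfTargets data.frame with columns \code{tf}, \code{target}.
#' @param genes ids needing a promoter (defaults to all genes in
#'   \code{tfTargets}).
#' @return list: \code{promoters} (DNAStringSet), \code{pwms}
#'   (\linkS4class{PwmLibrary}), \code{tfMotifMap} (data.frame tf, motif),
#'   \code{truth} (data.frame tf, motif, gene, offset).
#' @export
simulatePromoters <- function(config, tfTargets,
                              genes = unique(c(tfTargets$tf, tfTargets$target))) {
  set.seed(subSeed(config$seed, 1L))
  ts <- config$tfSpec
  bg <- ts$background
  L <- ts$promoterLength; w <- ts$motifWidth
  if (w > L) stop("motif width exceeds promoter length")
  seqs <- vapply(genes, function(g) randomSeq(L, bg), character(1))
  tfs <- unique(tfTargets$tf)
  motifs <- list(); map <- data.frame(tf = character(), motif = character())
  for (tf in tfs) {
    cons <- randomSeq(w, bg)
    id <- paste0("M_", tf)
    motifs[[id]] <- sharpPwm(cons)
    map <- rbind(map, data.frame(tf = tf, motif = id))
  }
  truth <- data.frame(tf = character(), motif = character(),
                      gene = character(), offset = integer())
  for (i in seq_len(nrow(tfTargets))) {
    if (runif(1) > ts$insertionRate) next
    tf <- tfTargets$tf[i]; tgt <- tfTargets$target[i]
    cons <- consensusOf(motifs[[paste0("M_", tf)]])
    off <- sample.int(L - w + 1L, 1L) - 1L   # 0-based
    substr(seqs[tgt], off + 1L, off + w) <- cons
    truth <- rbind(truth, data.frame(tf = tf, motif = paste0("M_", tf),
                                     gene = tgt, offset = off))
  }
  proms <- Biostrings::DNAStringSet(seqs)
  names(proms) <- genes
  list(promoters = proms, pwms = PwmLibrary(motifs, bg),
       tfMotifMap = map, truth = truth)
}

#' Simulate a targeted metabolite panel with planted fold-changes
#'
#' Log-normal concentrations; the first \code{nPlanted} metabolites shift
#' their group means at every post-baseline timepoint by \code{plantedLfc}
#' log2 units.  The truth lists, per pairwise comparison, every metabolite
#' whose planted |log2FC| between the two groups is >= 1.
#'
#' @param config a [simConfig()].
#' @return list: \code{tce} (metabolite TimecourseExperiment),
#'   \code{plantedLfc} (metabolite x timepoint log2 offsets), \code{truth}
#'   (named list per comparison "B_vs_A" of metabolite ids).
#' @export
simulateMetabolome <- function(config) {
  set.seed(subSeed(config$seed, 2L))
  ms <- config$metSpec
  tp <- config$timepoints; nT <- length(tp); nR <- ms$nReplicates
  ids <- sprintf("M%03d", seq_len(ms$nMetabolites))
  lfc <- matrix(0, ms$nMetabolites, nT, dimnames = list(ids, tp))
  if (ms$nPlanted > 0L)
    lfc[seq_len(ms$nPlanted), -1L] <- rep(ms$plantedLfc,
                                          length.out = ms$nPlanted)
  base <- exp(rnorm(ms$nMetabolites, log(100), 0.5))
  sigma <- sqrt(log(1 + ms$cv^2))
  sampleIds <- paste0(rep(tp, each = nR), "_M", rep(seq_len(nR), nT))
  vals <- matrix(NA_real_, ms$nMetabolites, nT * nR,
                 dimnames = list(ids, sampleIds))
  for (t in seq_len(nT)) {
    cols <- (t - 1L) * nR + seq_len(nR)
    mu <- base * 2^lfc[, t]
    vals[, cols] <- mu * exp(matrix(rnorm(length(ids) * nR, 0, sigma),
                                    ncol = nR))
  }
  design <- data.frame(sample = sampleIds,
                       timepoint = factor(rep(tp, each = nR), levels = tp),
                       replicate = rep(seq_len(nR), nT))
  pairs <- combn(seq_len(nT), 2L)
  truth <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    nm <- paste0(tp[b], "_vs_", tp[a])
    truth[[nm]] <- ids[abs(lfc[, b] - lfc[, a]) >= 1]
  }
  list(tce = TimecourseExperiment(vals, design), plantedLfc = lfc,
       truth = truth)
}

#' Simulate an undirected interaction network
#'
#' Erdos-Renyi background edges at the configured average degree, plus
#' three guaranteed edges from every DNB member to sampled cluster genes so
#' the neighborhood expansion has signal to find.
#'
#' @param config a [simConfig()].
#' @param genes all gene ids.
#' @param dnbMembers DNB member ids.
#' @param clusterGenes pool of differential genes to wire members to.
#' @return data.frame from, to, weight.
#' @export
simulateNetwork <- function(config, genes, dnbMembers, clusterGenes) {
  set.seed(subSeed(config$seed, 3L))
  n <- length(genes)
  nEdges <- round(config$netSpec$avgDegree * n / 2)
  from <- sample(genes, nEdges, replace = TRUE)
  to <- sample(genes, nEdges, replace = TRUE)
  keep <- from != to
  edges <- data.frame(from = from[keep], to = to[keep],
                      weight = round(runif(sum(keep), 0.4, 1), 3))
  pool <- setdiff(clusterGenes, dnbMembers)
  for (m in dnbMembers) {
    tgt <- sample(pool, 3L)
    edges <- rbind(edges, data.frame(from = m, to = tgt, weight = 0.9))
  }
  dedupEdges(edges)
}

#' Simulate a gene-set collection from planted cluster truth
#'
#' One set per planted archetype cluster (its true members) plus random
#' decoy sets drawn from all genes.
#'
#' @param config a [simConfig()].
#' @param clusters named character gene -> label, from
#'   [simulateTimecourse()].
#' @param nRandom decoy set count.
#' @param randomSize decoy set size.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
simulateGeneSets <- function(config, clusters, nRandom = 10L,
                             randomSize = 30L) {
  set.seed(subSeed(config$seed, 4L))
  genes <- names(clusters)
  sets <- list()
  for (nm in names(config$clusterSpec))
    sets[[paste0("SET_", nm)]] <- genes[clusters == nm]
  for (i in seq_len(nRandom))
    sets[[sprintf("SET_RND%02d", i)]] <- sample(genes, randomSize)
  GeneSetCollection(sets)
}

#' Simulate a joint gene/metabolite pathway map
#'
#' One "signal" pathway loaded with planted differential genes and planted
#' metabolites, plus decoy pathways with random members.
#'
#' @param config a [simConfig()].
#' @param clusters gene truth labels.
#' @param metIds metabolite ids (planted ones first).
#' @param nDecoys decoy pathway count.
#' @return data.frame pathway, member, type.
#' @export
simulatePathwayMap <- function(config, clusters, metIds, nDecoys = 5L) {
  set.seed(subSeed(config$seed, 5L))
  genes <- names(clusters)
  sigGenes <- sample(genes[clusters %in% names(config$clusterSpec)], 25L)
  sigMets <- metIds[seq_len(min(10L, config$metSpec$nPlanted))]
  map <- rbind(
    data.frame(pathway = "PW_SIGNAL", member = sigGenes, type = "gene"),
    data.frame(pathway = "PW_SIGNAL", member = sigMets, type = "metabolite"))
  for (i in seq_len(nDecoys)) {
    nm <- sprintf("PW_DECOY%02d", i)
    map <- rbind(map,
                 data.frame(pathway = nm, member = sample(genes, 15L),
                            type = "gene"),
                 data.frame(pathway = nm,
                            member = sample(metIds, 5L),
                            type = "metabolite"))
  }
  map
}

#' Generate every pipeline input with planted ground truth
#'
#' Runs all generators from one config and (optionally) writes the full
#' input file set plus a \code{truth.json} to a directory.
#'
#' @param config a [simConfig()].
#' @param dir output directory, or NULL to skip writing.
#' @return named list of all simulated objects and truths.
#' @export
simulateAll <- function(config, dir = NULL) {
  tc <- simulateTimecourse(config)
  # TFs and targets drawn from archetype-cluster (differential) genes
  set.seed(subSeed(config$seed, 6L))
  clustered <- names(tc$clusters)[tc$clusters %in% names(config$clusterSpec)]
  ts <- config$tfSpec
  tfs <- sample(clustered, ts$nTfs)
  pool <- setdiff(clustered, tfs)
  tfTargets <- do.call(rbind, lapply(tfs, function(tf)
    data.frame(tf = tf, target = sample(pool, ts$targetsPerTf))))
  tfFamilies <- c("zf-C2H2", "Homeobox", "TF_bZIP", "RHD", "bHLH", "HSF")
  tfAnnot <- setNames(rep(tfFamilies, length.out = length(tfs)), tfs)
  prom <- simulatePromoters(config, tfTargets)
  met <- simulateMetabolome(config)
  net <- simulateNetwork(config, names(tc$clusters), tc$dnbMembers, clustered)
  gsc <- simulateGeneSets(config, tc$clusters)
  pmap <- simulatePathwayMap(config, tc$clusters, rownames(met$tce))
  out <- list(config = config, tce = tc$tce, clusters = tc$clusters,
              dnbMembers = tc$dnbMembers, tfTargets = tfTargets,
              tfAnnotation = tfAnnot, promoters = prom$promoters,
              pwms = prom$pwms, tfMotifMap = prom$tfMotifMap,
              motifTruth = prom$truth, metabolites = met$tce,
              metTruth = met$truth, network = net, geneSets = gsc,
              pathwayMap = pmap)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpression(tc$tce, file.path(dir, "expression.tsv"),
                    file.path(dir, "design.tsv"))
    writeExpression(met$tce, file.path(dir, "metabolites.tsv"),
                    file.path(dir, "met_design.tsv"))
    writePromoters(prom$promoters, file.path(dir, "promoters.fa"))
    writeMeme(prom$pwms, file.path(dir, "motifs.meme"))
    write.table(data.frame(gene = names(tfAnnot), family = tfAnnot),
                file.path(dir, "tf_annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(prom$tfMotifMap, file.path(dir, "tf_motif_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeEdges(net, file.path(dir, "network.tsv"))
    writeGmt(gsc, file.path(dir, "genesets.gmt"))
    writePathwayMap(pmap, file.path(dir, "pathways.tsv"))
    jsonlite::write_json(
      list(clusters = as.list(tc$clusters), dnbMembers = tc$dnbMembers,
           motifTruth = prom$truth, metTruth = met$truth),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
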