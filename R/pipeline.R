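#' Pipeline run configuration
#'
#' Validates a configuration (an R list or a YAML file path) for
#' [runPipeline()]: input paths, per-stage parameters and the global
#' seed.  Referenced files must exist at validation time; out-of-range
#' thresholds are rejected before any stage runs.
#'
#' @param config list or YAML path with elements \code{inputs} (paths:
#'   expression, design, metabolites, met_design, promoters, motifs,
#'   tf_annotation, tf_motif_map, network, genesets, pathways),
#'   \code{params} (lfc_min, p_max, clusters, fuzzifier, epsilon,
#'   p_threshold, n_orth, alpha, fc_low, fc_high, vip_min, tau) and
#'   \code{seed}.
#' @param stages stages to run (subset of the canonical seven).
#' @return validated config list (class \code{RunConfig}).
#' @export
runConfig <- function(config, stages = c("diffexpr", "timeclust", "grn",
                                         "dnb", "enrichment",
                                         "metabolomics", "integration")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(lfc_min = 1, p_max = 0.05, clusters = 4L,
                   fuzzifier = 1.25, epsilon = 0.05, p_threshold = 1e-4,
                   n_orth = 1L, alpha = 0.05, fc_low = 0.5, fc_high = 2,
                   vip_min = 1, tau = 0.25, min_module = 5L,
                   max_module = 100L)
  config$params <- utils::modifyList(defaults,
                                     as.list(config$params %||% list()))
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- match.arg(stages, several.ok = TRUE)
  p <- config$params
  if (p$p_max <= 0 || p$p_max > 1 || p$alpha <= 0 || p$alpha > 1 ||
      p$p_threshold <= 0 || p$p_threshold > 1)
    stop("p-value thresholds must lie in (0, 1]")
  if (p$fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (p$fc_low >= p$fc_high) stop("fc_low must be below fc_high")
  need <- c("expression", "design")
  if ("metabolomics" %in% config$stages)
    need <- c(need, "metabolites", "met_design")
  if ("grn" %in% config$stages)
    need <- c(need, "promoters", "motifs", "tf_annotation", "tf_motif_map")
  if ("dnb" %in% config$stages) need <- c(need, "network")
  if ("enrichment" %in% config$stages) need <- c(need, "genesets")
  if ("integration" %in% config$stages) need <- c(need, "pathways")
  for (k in unique(need)) {
    path <- config$inputs[[k]]
    if (is.null(path) || !file.exists(path))
      stop("missing input file for '", k, "': ",
           if (is.null(path)) "(not configured)" else path)
  }
  structure(config, class = c("RunConfig", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeStage <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes differential expression, temporal clustering, regulatory-state
#' network construction, DNB tipping-point analysis, enrichment (ORA plus
#' per-sample scores), metabolite screening and joint pathway integration
#' from one validated config, writing per-stage TSV outputs, a JSON run
#' manifest (parameters, seed, input checksums, stage output checksums)
#' and a log.  A stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config a [runConfig()] (or list/YAML path accepted by it).
#' @param outDir output directory.
#' @return the manifest (invisibly), also written to
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, outDir) {
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  logFile <- file.path(outDir, "pipeline.log")
  logMsg <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                              "\n", file = logFile, append = TRUE)
  outputs <- character()
  stageRuns <- character()
  runStage <- function(name, fn) {
    logMsg("stage", name, "start")
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (completed outputs kept in ", outDir, ")", call. = FALSE))
    stageRuns <<- c(stageRuns, name)
    logMsg("stage", name, "done")
    res
  }

  tce <- readExpression(config$inputs$expression, config$inputs$design)
  design <- designTable(tce)
  logm <- logTransform(tce)
  results <- list()

  if ("diffexpr" %in% config$stages) {
    results$comparisons <- runStage("diffexpr", function() {
      cmp <- allComparisons(logm, design)
      for (nm in names(cmp)) {
        tab <- cmp[[nm]]
        tab$deg_flag <- tab$gene %in% filterDegs(tab, p$lfc_min, p$p_max)
        outputs[[paste0("diffexpr_", nm)]] <<-
          writeStage(tab, outDir, paste0("diffexpr_", nm, ".tsv"))
      }
      cmp
    })
    results$degs <- unionDegs(results$comparisons,
                              lfcMin = p$lfc_min, pMax = p$p_max)
    writeLines(results$degs, file.path(outDir, "degs.txt"))
    outputs[["degs"]] <- file.path(outDir, "degs.txt")
  }

  if ("timeclust" %in% config$stages) {
    results$clustering <- runStage("timeclust", function() {
      prof <- suppressWarnings(buildProfiles(logm, design, results$degs))
      fc <- fuzzyCMeans(prof, c = p$clusters, m = p$fuzzifier,
                        seed = config$seed)
      lab <- assignClusters(fc)
      outputs[["memberships"]] <<- writeStage(
        data.frame(gene = rownames(memberships(fc)), memberships(fc),
                   cluster = lab, check.names = FALSE),
        outDir, "cluster_memberships.tsv")
      outputs[["centers"]] <<- writeStage(
        data.frame(cluster = rownames(clusterCenters(fc)),
                   clusterCenters(fc), check.names = FALSE),
        outDir, "cluster_centers.tsv")
      fc
    })
  }

  if ("grn" %in% config$stages) {
    results$grn <- runStage("grn", function() {
      tfAnnot <- readTfAnnotation(config$inputs$tf_annotation)
      proms <- readPromoters(config$inputs$promoters)
      pwms <- readMeme(config$inputs$motifs)
      tfMap <- read.delim(config$inputs$tf_motif_map,
                          stringsAsFactors = FALSE)
      states <- makeStates(results$comparisons, design, tfAnnot,
                           lfcMin = p$lfc_min, pMax = p$p_max)
      hits <- pwmScan(proms, pwms, pThreshold = p$p_threshold)
      edges <- do.call(rbind, lapply(states, buildStateNetwork,
                                     motifHits = hits,
                                     tfMotifMap = tfMap))
      enr <- lapply(states, function(s)
        tfFamilyEnrichment(s$tfs, tfAnnot))
      outputs[["grn_edges"]] <<- writeStage(edges, outDir,
                                            "grn_edges.tsv")
      outputs[["tf_enrichment"]] <<- writeStage(
        do.call(rbind, Map(function(e, s) cbind(state = s$label, e),
                           enr, states)),
        outDir, "tf_family_enrichment.tsv")
      list(states = states, hits = hits, edges = edges,
           pairCounts = countPairs(edges), enrichment = enr)
    })
  }

  if ("dnb" %in% config$stages) {
    results$dnb <- runStage("dnb", function() {
      net <- readEdges(config$inputs$network)
      analyzed <- intersect(results$degs, rownames(logm))
      dnb <- criticalityCurve(logm[analyzed, , drop = FALSE], design,
                              minSize = p$min_module,
                              maxSize = p$max_module,
                              epsilon = p$epsilon)
      nb <- dnbNeighborhood(dnbMembers(dnb), net, results$degs)
      outputs[["ci_curve"]] <<- writeStage(ciCurve(dnb), outDir,
                                           "dnb_ci_curve.tsv")
      writeLines(dnbMembers(dnb), file.path(outDir, "dnb_members.txt"))
      outputs[["dnb_members"]] <<- file.path(outDir, "dnb_members.txt")
      outputs[["dnb_network"]] <<- writeStage(nb$edges, outDir,
                                              "dnb_neighborhood.tsv")
      list(result = dnb, neighborhood = nb)
    })
  }

  if ("enrichment" %in% config$stages) {
    results$enrichment <- runStage("enrichment", function() {
      gsc <- readGmt(config$inputs$genesets)
      oraRes <- ora(results$degs, gsc, rownames(logm))
      scores <- suppressWarnings(sampleScores(logm, gsc, tau = p$tau))
      sig <- scoreSignificance(scores, design, alpha = p$alpha)
      outputs[["ora"]] <<- writeStage(oraRes, outDir, "ora_degs.tsv")
      outputs[["scores"]] <<- writeStage(
        data.frame(set = rownames(scores), scores, check.names = FALSE),
        outDir, "sample_scores.tsv")
      outputs[["score_sig"]] <<- writeStage(sig, outDir,
                                            "score_significance.tsv")
      list(ora = oraRes, scores = scores, significance = sig)
    })
  }

  if ("metabolomics" %in% config$stages) {
    results$metabolomics <- runStage("metabolomics", function() {
      met <- readMetabolites(config$inputs$metabolites,
                             config$inputs$met_design)
      mdesign <- designTable(met)
      tp <- timepointLevels(met)
      prs <- combn(seq_along(tp), 2L)
      screens <- list()
      for (k in seq_len(ncol(prs))) {
        a <- tp[prs[1L, k]]; b <- tp[prs[2L, k]]
        nm <- paste0(b, "_vs_", a)
        screens[[nm]] <- pairwiseDrm(abundances(met), mdesign, a, b,
                                     low = p$fc_low, high = p$fc_high,
                                     vipMin = p$vip_min)
        outputs[[paste0("drm_", nm)]] <<-
          writeStage(screens[[nm]], outDir, paste0("drm_", nm, ".tsv"))
      }
      multi <- multigroupDrm(abundances(met), mdesign,
                             vipMin = p$vip_min)
      sets <- drmSets(screens)
      outputs[["drm_multigroup"]] <<- writeStage(multi, outDir,
                                                 "drm_multigroup.tsv")
      jsonlite::write_json(
        list(exclusive = as.list(sets$exclusive),
             consistent = sets$consistent,
             fraction_increased = sets$fractionIncreased),
        file.path(outDir, "drm_sets.json"), auto_unbox = TRUE,
        digits = NA)
      outputs[["drm_sets"]] <<- file.path(outDir, "drm_sets.json")
      list(screens = screens, multigroup = multi, sets = sets)
    })
  }

  if ("integration" %in% config$stages) {
    results$integration <- runStage("integration", function() {
      pmap <- readPathwayMap(config$inputs$pathways)
      screens <- results$metabolomics$screens
      drms <- unique(unlist(lapply(screens, function(s)
        s$metabolite[s$drm_flag])))
      metIds <- unique(screens[[1L]]$metabolite)
      joint <- jointEnrichment(results$degs, drms, pmap,
                               geneUniverse = rownames(logm),
                               metUniverse = metIds, alpha = p$alpha)
      outputs[["joint"]] <<- writeStage(joint, outDir,
                                        "joint_pathways.tsv")
      proj <- lapply(unique(pmap$pathway), function(pw)
        pathwayProjectionTable(results$comparisons, screens, pmap, pw))
      projAll <- do.call(rbind, proj)
      outputs[["projection"]] <<- writeStage(projAll, outDir,
                                             "pathway_projection.tsv")
      list(joint = joint, projection = projAll)
    })
  }

  inputsUsed <- unlist(config$inputs[vapply(config$inputs, is.character,
                                            logical(1))])
  manifest <- list(
    package = "tipomics",
    version = as.character(utils::packageVersion("tipomics")),
    seed = config$seed,
    parameters = p,
    stages = stageRuns,
    input_checksums = as.list(tools::md5sum(inputsUsed)),
    output_checksums = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
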