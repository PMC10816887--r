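#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd var phyper fisher.test p.adjust pt pchisq
#'   hclust cutree as.dist rnorm runif setNames aov anova lm aggregate
#'   complete.cases quantile median
#' @importFrom utils read.delim write.table head combn
NULL

#' Time-course omics experiment
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding a
#' features x samples abundance matrix (gene expression or metabolite
#' concentrations) together with a sample design binding every sample to an
#' ordered timepoint and a replicate index.  Timepoint order is taken from
#' the design declaration, never from string sorting, so \code{"D12"} sorts
#' after \code{"D4"}.
#'
#' @slot .placeholder none; all data live in the parent class.
#' @seealso [TimecourseExperiment()], [readExpression()]
#' @export
setClass("TimecourseExperiment",
         contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
  msg <- character()
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate or missing feature ids (first duplicate: %s)",
                          rownames(object)[duplicated(rownames(object))][1]))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate or missing sample ids (first duplicate: %s)",
                          colnames(object)[duplicated(colnames(object))][1]))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("timepoint", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'timepoint' and 'replicate'")
  else {
    if (!is.factor(cd$timepoint))
      msg <- c(msg, "timepoint must be a factor with explicitly ordered levels")
    if (!is.numeric(cd$replicate) || any(cd$replicate < 1))
      msg <- c(msg, "replicate must be a positive integer index")
  }
  if (length(SummarizedExperiment::assays(object)) >= 1) {
    a <- SummarizedExperiment::assay(object, 1L)
    if (any(!is.finite(a))) {
      bad <- which(!is.finite(a), arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf("non-finite value at (%s, %s)",
                            rownames(object)[bad[1L]], colnames(object)[bad[2L]]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TimecourseExperiment
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   abundances must be finite and non-negative.
#' @param design data.frame with columns \code{sample}, \code{timepoint},
#'   \code{replicate}.  Timepoint level order is the order of first
#'   appearance in the design.
#' @param assayName name for the abundance assay.
#' @return A \linkS4class{TimecourseExperiment}.
#' @examples
#' m <- matrix(1:12, 3, 4, dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' d <- data.frame(sample = paste0("S", 1:4),
#'                 timepoint = rep(c("D0", "D4"), each = 2),
#'                 replicate = rep(1:2, 2))
#' TimecourseExperiment(m, d)
#' @export
TimecourseExperiment <- function(values, design, assayName = "abund") {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)))
    stop("values must have feature ids as rownames")
  if (is.null(colnames(values)))
    stop("values must have sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  design <- validateDesign(design)
  missing <- setdiff(colnames(values), design$sample)
  if (length(missing))
    stop("sample(s) in matrix absent from design: ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite abundance at (%s, %s)",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at (%s, %s)",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  cd <- S4Vectors::DataFrame(timepoint = design$timepoint,
                             replicate = as.integer(design$replicate),
                             row.names = design$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(values), assayName), colData = cd)
  methods::new("TimecourseExperiment", se)
}

validateDesign <- function(design) {
  design <- as.data.frame(design)
  need <- c("sample", "timepoint", "replicate")
  if (!all(need %in% colnames(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("duplicate sample id in design: ",
         design$sample[duplicated(design$sample)][1L])
  if (!is.factor(design$timepoint))
    design$timepoint <- factor(design$timepoint,
                               levels = unique(as.character(design$timepoint)))
  design
}

#' @describeIn TimecourseExperiment timepoint factor per sample
#' @param x a TimecourseExperiment
#' @export
timepoints <- function(x) SummarizedExperiment::colData(x)$timepoint

#' @describeIn TimecourseExperiment ordered timepoint labels
#' @export
timepointLevels <- function(x) levels(timepoints(x))

#' @describeIn TimecourseExperiment replicate index per sample
#' @export
replicates <- function(x) SummarizedExperiment::colData(x)$replicate

#' @describeIn TimecourseExperiment abundance matrix (first assay)
#' @param assay assay name or index
#' @export
abundances <- function(x, assay = 1L) SummarizedExperiment::assay(x, assay)

#' @describeIn TimecourseExperiment design as a plain data.frame
#' @export
designTable <- function(x) {
  data.frame(sample = colnames(x),
             timepoint = as.character(timepoints(x)),
             replicate = replicates(x),
             stringsAsFactors = FALSE)
}

setMethod("show", "TimecourseExperiment", function(object) {
  cat(sprintf("TimecourseExperiment: %d features x %d samples\n",
              nrow(object), ncol(object)))
  cat("  timepoints:",
      paste(sprintf("%s(n=%d)", timepointLevels(object),
                    tabulate(timepoints(object))), collapse = " "), "\n")
  cat("  assays:",
      paste(names(SummarizedExperiment::assays(object)), collapse = ", "), "\n")
})

#' Position weight matrix library
#'
#' Holds a set of nucleotide motifs as per-position probability matrices
#' (rows A, C, G, T) plus a shared background frequency vector.  Every
#' column of every motif must sum to one; the background must be strictly
#' positive and sum to one.
#'
#' @slot motifs named list of 4 x width probability matrices.
#' @slot background numeric(4), named A,C,G,T, summing to 1.
#' @export
setClass("PwmLibrary",
         representation(motifs = "list", background = "numeric"))

setValidity("PwmLibrary", function(object) {
  msg <- character()
  bg <- object@background
  if (length(bg) != 4L || is.null(names(bg)) ||
      !identical(names(bg), c("A", "C", "G", "T")))
    msg <- c(msg, "background must be named A,C,G,T")
  else {
    if (any(bg <= 0)) msg <- c(msg, "background frequencies must be > 0")
    if (abs(sum(bg) - 1) > 1e-6) msg <- c(msg, "background must sum to 1")
  }
  for (id in names(object@motifs)) {
    m <- object@motifs[[id]]
    if (!is.matrix(m) || nrow(m) != 4L || ncol(m) < 1L) {
      msg <- c(msg, sprintf("motif %s: must be a 4 x width matrix", id))
      next
    }
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, sprintf("motif %s: column %d sums to %.6g, not 1",
                            id, which(abs(cs - 1) > 1e-9)[1L],
                            cs[which(abs(cs - 1) > 1e-9)[1L]]))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PwmLibrary constructor
#' @param motifs named list of probability matrices (rows A,C,G,T).
#' @param background nucleotide frequencies, default uniform.
#' @export
PwmLibrary <- function(motifs,
                       background = c(A = .25, C = .25, G = .25, T = .25)) {
  motifs <- lapply(motifs, function(m) {
    m <- as.matrix(m)
    rownames(m) <- c("A", "C", "G", "T")
    m
  })
  methods::new("PwmLibrary", motifs = motifs,
               background = background[c("A", "C", "G", "T")])
}

#' @describeIn PwmLibrary motif ids
#' @param x a PwmLibrary
#' @export
motifIds <- function(x) names(x@motifs)

#' @describeIn PwmLibrary extract one motif matrix
#' @param id motif id
#' @export
motifMatrix <- function(x, id) x@motifs[[id]]

#' @describeIn PwmLibrary motif widths
#' @export
motifWidths <- function(x) vapply(x@motifs, ncol, integer(1))

setMethod("show", "PwmLibrary", function(object) {
  cat(sprintf("PwmLibrary: %d motif(s), widths %s\n", length(object@motifs),
              paste(motifWidths(object), collapse = ",")))
  cat("  background:",
      paste(sprintf("%s=%.3f", names(object@background), object@background),
            collapse = " "), "\n")
})

#' Gene set collection
#'
#' Flat named gene sets (GMT semantics): each set has an id, a free-text
#' description and a deduplicated, non-empty member list.
#'
#' @slot sets named list of character vectors.
#' @slot description named character, one per set.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set ids must be unique and named")
  empty <- vapply(object@sets, length, integer(1)) == 0L
  if (any(empty))
    msg <- c(msg, sprintf("empty gene set: %s", names(object@sets)[empty][1L]))
  dup <- vapply(object@sets, anyDuplicated, integer(1)) > 0L
  if (any(dup))
    msg <- c(msg, sprintf("duplicated members in set: %s",
                          names(object@sets)[dup][1L]))
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSetCollection constructor
#' @param sets named list of member id vectors.
#' @param description optional named descriptions.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(description))
    description <- setNames(rep("", length(sets)), names(sets))
  methods::new("GeneSetCollection", sets = sets,
               description = description[names(sets)])
}

#' @describeIn GeneSetCollection member lists
#' @param x a GeneSetCollection
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection set ids
#' @export
setIds <- function(x) names(x@sets)

setMethod("show", "GeneSetCollection", function(object) {
  sz <- vapply(object@sets, length, integer(1))
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(sz), min(sz), max(sz)))
})

#' Fuzzy clustering result
#'
#' Soft clustering of standardized temporal profiles: a gene x cluster
#' membership matrix (rows sum to one), cluster centers over timepoints,
#' the fuzzifier, and the per-iteration objective trace.
#'
#' @slot membership gene x cluster matrix in [0,1], rows sum to 1.
#' @slot centers cluster x timepoint matrix.
#' @slot m fuzzifier (> 1).
#' @slot objective numeric, objective value per iteration.
#' @slot iterations number of iterations run.
#' @export
setClass("FuzzyClustering",
         representation(membership = "matrix", centers = "matrix",
                        m = "numeric", objective = "numeric",
                        iterations = "integer"))

setValidity("FuzzyClustering", function(object) {
  rs <- rowSums(object@membership)
  if (any(abs(rs - 1) > 1e-9))
    return(sprintf("membership rows must sum to 1 (gene %s: %.6g)",
                   rownames(object@membership)[which.max(abs(rs - 1))],
                   rs[which.max(abs(rs - 1))]))
  if (any(!is.finite(object@centers))) return("non-finite cluster center")
  TRUE
})

#' @describeIn FuzzyClustering membership matrix
#' @param x a FuzzyClustering
#' @export
memberships <- function(x) x@membership

#' @describeIn FuzzyClustering cluster center profiles
#' @export
clusterCenters <- function(x) x@centers

setMethod("show", "FuzzyClustering", function(object) {
  cat(sprintf("FuzzyClustering: %d genes, %d clusters, m=%.3g, %d iterations\n",
              nrow(object@membership), ncol(object@membership), object@m,
              object@iterations))
})

#' Dynamic network biomarker result
#'
#' Per-timepoint best candidate module with its criticality index
#' CI = SDin * PCCin / max(PCCout, eps); the tipping point is the timepoint
#' attaining the maximal CI and the DNB member set is the best module there.
#'
#' @slot curve data.frame: timepoint, SDin, PCCin, PCCout, CI, module_size.
#' @slot tip character, tipping timepoint label.
#' @slot members character, DNB member gene ids at the tip.
#' @slot modules list of best-module member vectors per timepoint.
#' @export
setClass("DnbResult",
         representation(curve = "data.frame", tip = "character",
                        members = "character", modules = "list"))

setValidity("DnbResult", function(object) {
  cv <- object@curve
  if (!all(c("timepoint", "SDin", "PCCin", "PCCout", "CI") %in% colnames(cv)))
    return("curve must have columns timepoint, SDin, PCCin, PCCout, CI")
  if (length(object@tip) == 1L &&
      !isTRUE(all.equal(max(cv$CI), cv$CI[cv$timepoint == object@tip])))
    return("tipping timepoint must attain the maximal CI")
  TRUE
})

#' @describeIn DnbResult CI curve over timepoints
#' @param x a DnbResult
#' @export
ciCurve <- function(x) x@curve

#' @describeIn DnbResult tipping timepoint label
#' @export
tippingPoint <- function(x) x@tip

#' @describeIn DnbResult DNB member ids at the tip
#' @export
dnbMembers <- function(x) x@members

setMethod("show", "DnbResult", function(object) {
  cat("DnbResult\n")
  print(object@curve, row.names = FALSE)
  cat(sprintf("  tipping point: %s (%d members)\n", object@tip,
              length(object@members)))
})

#' Fitted OPLS-DA model
#'
#' One predictive component plus k orthogonal components fitted by NIPALS
#' with orthogonal signal correction.  Variables are mean-centered and
#' unit-variance scaled before fitting; the class vector is +/-1 coded and
#' centered.
#'
#' @slot weights numeric p, unit-norm predictive weights (on scaled data).
#' @slot scores numeric n, predictive scores.
#' @slot loadings numeric p, predictive loadings.
#' @slot orthoScores matrix n x k of orthogonal scores.
#' @slot orthoLoadings matrix p x k of orthogonal loadings.
#' @slot orthoWeights matrix p x k of orthogonal weights.
#' @slot center,scale numeric p, the scaling applied to X.
#' @slot y numeric n, centered class vector.
#' @slot q numeric, y-loading of the predictive component.
#' @slot variables character, variable names (after dropping constants).
#' @slot dropped character, constant variables removed before fitting.
#' @export
setClass("OplsModel",
         representation(weights = "numeric", scores = "numeric",
                        loadings = "numeric", orthoScores = "matrix",
                        orthoLoadings = "matrix", orthoWeights = "matrix",
                        center = "numeric", scale = "numeric",
                        y = "numeric", q = "numeric",
                        variables = "character", dropped = "character"))

setValidity("OplsModel", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@weights^2)) - 1) > 1e-8)
    msg <- c(msg, "predictive weight vector must have unit norm")
  if (ncol(object@orthoScores) > 0) {
    dots <- abs(crossprod(object@orthoScores, object@scores))
    if (any(dots > 1e-6 * sqrt(sum(object@scores^2)) *
              sqrt(colSums(object@orthoScores^2))))
      msg <- c(msg, "orthogonal scores must be orthogonal to predictive scores")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OplsModel", function(object) {
  cat(sprintf("OplsModel: %d variables, 1 predictive + %d orthogonal component(s)\n",
              length(object@weights), ncol(object@orthoScores)))
  if (length(object@dropped))
    cat("  dropped constant variables:",
        paste(object@dropped, collapse = ", "), "\n")
})
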