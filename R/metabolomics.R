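#' Fit an OPLS-DA model for a two-group contrast
#'
#' NIPALS-style orthogonal projections to latent structures discriminant
#' analysis: variables are mean-centered and unit-variance scaled
#' (constant variables dropped with a warning); the class vector is +/-1
#' coded and centered.  Each orthogonal component removes the part of the
#' X loading orthogonal to the predictive direction; the final predictive
#' component is refitted on the filtered matrix.  Deterministic (no random
#' initialization).
#'
#' @param table metabolites x samples concentration matrix or a
#'   TimecourseExperiment.
#' @param design design data.frame (ignored when \code{table} is a
#'   TimecourseExperiment).
#' @param groupA,groupB timepoint labels (A coded -1, B coded +1).
#' @param nOrth number of orthogonal components, default 1.
#' @return an \linkS4class{OplsModel}.
#' @export
fitOplsda <- function(table, design = NULL, groupA, groupB, nOrth = 1L) {
  if (methods::is(table, "TimecourseExperiment")) {
    design <- designTable(table)
    table <- abundances(table)
  }
  design <- validateDesign(design)
  sa <- intersect(design$sample[design$timepoint == groupA], colnames(table))
  sb <- intersect(design$sample[design$timepoint == groupB], colnames(table))
  if (length(sa) < 3L || length(sb) < 3L)
    stop("each group needs >= 3 samples")
  X <- t(table[, c(sa, sb), drop = FALSE])   # samples x variables
  y <- c(rep(-1, length(sa)), rep(1, length(sb)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  dropped <- colnames(X)[scl == 0]
  if (length(dropped)) {
    warning("dropping constant variable(s): ",
            paste(dropped, collapse = ", "))
    keep <- scl > 0
    X <- X[, keep, drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
  }
  if (!ncol(X)) stop("all variables constant")
  X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  yc <- y - mean(y)
  Xf <- X
  oW <- oP <- matrix(0, ncol(X), 0L)
  oT <- matrix(0, nrow(X), 0L)
  for (k in seq_len(nOrth)) {
    w <- crossprod(Xf, yc); w <- w / sqrt(sum(w^2))
    tt <- Xf %*% w
    p <- crossprod(Xf, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break   # no orthogonal variation left
    wo <- wo / nwo
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    oW <- cbind(oW, wo); oP <- cbind(oP, po); oT <- cbind(oT, to)
  }
  w <- crossprod(Xf, yc); w <- as.numeric(w / sqrt(sum(w^2)))
  tt <- as.numeric(Xf %*% w)
  p <- as.numeric(crossprod(Xf, tt) / sum(tt^2))
  q <- sum(yc * tt) / sum(tt^2)
  methods::new("OplsModel", weights = setNames(w, colnames(X)),
               scores = tt, loadings = p, orthoScores = oT,
               orthoLoadings = oP, orthoWeights = oW,
               center = ctr, scale = scl, y = yc, q = q,
               variables = colnames(X), dropped = dropped)
}

#' Variable importance in projection
#'
#' \code{VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a SSY_a)} over the
#' predictive component(s); with unit-norm weights this satisfies the
#' identity \code{sum_j VIP_j^2 = p} exactly.
#'
#' @param model an \linkS4class{OplsModel}.
#' @return named numeric VIP per variable.
#' @export
vipScores <- function(model) {
  w <- model@weights
  p <- length(w)
  # single predictive component: SSY weights cancel
  setNames(sqrt(p * w^2), names(w))
}

#' Cross-validated Q2 of an OPLS-DA contrast
#'
#' Leave-one-out (or k-fold) predictive Q2 = 1 - PRESS/SSY on the +/-1
#' class coding, refitting scaling and all components inside each fold.
#'
#' @param table metabolites x samples matrix or TimecourseExperiment.
#' @param design design data.frame.
#' @param groupA,groupB timepoint labels.
#' @param nOrth orthogonal components.
#' @param folds number of CV folds (default: leave-one-out).
#' @param labels optional replacement class labels (same length/order as
#'   the concatenated groupA, groupB samples) for permutation tests.
#' @return numeric Q2.
#' @export
oplsQ2 <- function(table, design = NULL, groupA, groupB, nOrth = 1L,
                   folds = NULL, labels = NULL) {
  if (methods::is(table, "TimecourseExperiment")) {
    design <- designTable(table)
    table <- abundances(table)
  }
  design <- validateDesign(design)
  sa <- intersect(design$sample[design$timepoint == groupA], colnames(table))
  sb <- intersect(design$sample[design$timepoint == groupB], colnames(table))
  samples <- c(sa, sb)
  y <- if (is.null(labels)) c(rep(-1, length(sa)), rep(1, length(sb))) else
    labels
  X0 <- t(table[, samples, drop = FALSE])
  n <- length(y)
  if (is.null(folds)) folds <- n
  foldId <- rep(seq_len(folds), length.out = n)
  press <- 0
  for (f in seq_len(folds)) {
    test <- foldId == f
    Xtr <- X0[!test, , drop = FALSE]; ytr <- y[!test]
    if (length(unique(ytr)) < 2L) next
    ctr <- colMeans(Xtr); scl <- apply(Xtr, 2L, sd)
    keep <- scl > 0
    Xs <- sweep(sweep(Xtr[, keep, drop = FALSE], 2L, ctr[keep]), 2L,
                scl[keep], "/")
    yc <- ytr - mean(ytr)
    Xts <- sweep(sweep(X0[test, keep, drop = FALSE], 2L, ctr[keep]), 2L,
                 scl[keep], "/")
    Xf <- Xs
    for (k in seq_len(nOrth)) {
      w <- crossprod(Xf, yc); w <- w / sqrt(sum(w^2))
      tt <- Xf %*% w
      p <- crossprod(Xf, tt) / sum(tt^2)
      wo <- p - as.numeric(crossprod(w, p)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) break
      wo <- wo / nwo
      to <- Xf %*% wo
      po <- crossprod(Xf, to) / sum(to^2)
      Xf <- Xf - to %*% t(po)
      tos <- Xts %*% wo
      Xts <- Xts - tos %*% t(po)
    }
    w <- crossprod(Xf, yc); w <- w / sqrt(sum(w^2))
    tt <- Xf %*% w
    q <- sum(yc * tt) / sum(tt^2)
    pred <- as.numeric(Xts %*% w) * q + mean(ytr)
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Pairwise differentially-regulated-metabolite screen
#'
#' Fold change is the ratio of raw-concentration group means (B over A);
#' a metabolite is called a DRM when (FC >= \code{high} OR FC <=
#' \code{low}) AND VIP > 1.  Boundary semantics: FC thresholds inclusive,
#' VIP threshold exclusive.
#'
#' @param table metabolites x samples matrix or TimecourseExperiment.
#' @param design design data.frame.
#' @param groupA,groupB timepoint labels.
#' @param model optional pre-fitted \linkS4class{OplsModel} for this pair.
#' @param low,high fold-change thresholds (defaults 0.5 and 2; the
#'   conventional reciprocal pair).
#' @param vipMin VIP threshold (exclusive), default 1.
#' @return data.frame: metabolite, mean_a, mean_b, fold_change, vip,
#'   drm_flag, direction, comparison.
#' @export
pairwiseDrm <- function(table, design = NULL, groupA, groupB,
                        model = NULL, low = 0.5, high = 2, vipMin = 1) {
  if (methods::is(table, "TimecourseExperiment")) {
    design <- designTable(table)
    table <- abundances(table)
  }
  design <- validateDesign(design)
  if (is.null(model))
    model <- fitOplsda(table, design, groupA, groupB)
  vip <- vipScores(model)
  sa <- intersect(design$sample[design$timepoint == groupA], colnames(table))
  sb <- intersect(design$sample[design$timepoint == groupB], colnames(table))
  meanA <- rowMeans(table[, sa, drop = FALSE])
  meanB <- rowMeans(table[, sb, drop = FALSE])
  fc <- meanB / meanA
  ids <- rownames(table)
  v <- vip[ids]; v[is.na(v)] <- 0   # dropped-constant variables: VIP 0
  flag <- (fc >= high | fc <= low) & v > vipMin
  data.frame(metabolite = ids, mean_a = meanA, mean_b = meanB,
             fold_change = fc, vip = as.numeric(v), drm_flag = flag,
             direction = ifelse(fc > 1, "increased",
                                ifelse(fc < 1, "decreased", "unchanged")),
             comparison = paste0(groupB, "_vs_", groupA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-group differentially-regulated-metabolite screen
#'
#' One-way ANOVA across all timepoints per metabolite (raw p) combined
#' with the VIP from an OPLS-DA of the first-vs-last timepoint contrast
#' (configurable): DRM when p < 0.05 AND VIP > 1.
#'
#' @param table metabolites x samples matrix or TimecourseExperiment.
#' @param design design data.frame.
#' @param vipPair c(groupA, groupB) supplying the VIP model; default
#'   first and last timepoint.
#' @param pMax ANOVA p ceiling (exclusive), default 0.05.
#' @param vipMin VIP threshold (exclusive), default 1.
#' @return data.frame: metabolite, anova_p, vip, drm_flag.
#' @export
multigroupDrm <- function(table, design = NULL, vipPair = NULL,
                          pMax = 0.05, vipMin = 1) {
  if (methods::is(table, "TimecourseExperiment")) {
    design <- designTable(table)
    table <- abundances(table)
  }
  design <- validateDesign(design)
  tp <- levels(design$timepoint)
  if (is.null(vipPair)) vipPair <- c(tp[1L], tp[length(tp)])
  model <- fitOplsda(table, design, vipPair[1L], vipPair[2L])
  vip <- vipScores(model)
  grp <- design$timepoint[match(colnames(table), design$sample)]
  pvals <- apply(table, 1L, function(v) {
    if (sd(v) == 0) return(1)
    anova(lm(v ~ grp))[["Pr(>F)"]][1L]
  })
  ids <- rownames(table)
  v <- vip[ids]; v[is.na(v)] <- 0
  data.frame(metabolite = ids, anova_p = as.numeric(pvals),
             vip = as.numeric(v),
             drm_flag = pvals < pMax & v > vipMin,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DRM set accounting across comparisons
#'
#' UpSet-style exclusive intersection counts over the pairwise DRM sets,
#' the subset of metabolites consistently called (same direction) in every
#' comparison against the baseline group, and the fraction of increased
#' calls among all DRM calls.
#'
#' @param screens named list of [pairwiseDrm()] results (names like
#'   \code{"D4_vs_D0"}).
#' @param baseline baseline group label, default the common suffix group.
#' @return list: \code{exclusive} (named integer, keys like
#'   \code{"D4_vs_D0&D8_vs_D0"}), \code{consistent} (data.frame
#'   metabolite, direction for metabolites DRM in every baseline
#'   comparison with one direction), \code{fractionIncreased}.
#' @export
drmSets <- function(screens, baseline = NULL) {
  sets <- lapply(screens, function(s) s$metabolite[s$drm_flag])
  allIds <- unique(unlist(sets))
  memb <- vapply(sets, function(s) allIds %in% s,
                 logical(length(allIds)))
  if (length(allIds) == 1L) memb <- matrix(memb, nrow = 1L,
                                           dimnames = list(allIds,
                                                           names(sets)))
  rownames(memb) <- allIds
  pattern <- apply(memb, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  exclusive <- table(pattern)
  exclusive <- setNames(as.integer(exclusive), names(exclusive))
  # consistent-direction subset vs the baseline group
  if (is.null(baseline)) {
    suffix <- sub(".*_vs_", "", names(screens))
    baseline <- names(sort(table(suffix), decreasing = TRUE))[1L]
  }
  base <- screens[grepl(paste0("_vs_", baseline, "$"), names(screens))]
  consistent <- data.frame(metabolite = character(),
                           direction = character())
  if (length(base)) {
    flags <- lapply(base, function(s)
      setNames(s$drm_flag, s$metabolite))
    dirs <- lapply(base, function(s)
      setNames(s$direction, s$metabolite))
    ids <- Reduce(intersect, lapply(flags, function(f) names(f)[f]))
    if (length(ids)) {
      sameDir <- vapply(ids, function(m) {
        d <- vapply(dirs, function(dd) dd[[m]], character(1))
        length(unique(d)) == 1L
      }, logical(1))
      ids <- ids[sameDir]
      consistent <- data.frame(
        metabolite = ids,
        direction = vapply(ids, function(m) dirs[[1L]][[m]], character(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, lapply(screens, function(s)
    s[s$drm_flag, c("metabolite", "direction")]))
  fractionIncreased <- if (nrow(calls))
    mean(calls$direction == "increased") else NA_real_
  list(exclusive = exclusive, consistent = consistent,
       fractionIncreased = fractionIncreased)
}
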