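#' Build standardized temporal profiles
#'
#' Replicate values are averaged per timepoint, then each gene's profile is
#' z-standardized (mean 0, sample sd 1 with the n-1 denominator) across
#' timepoints.  Genes with zero temporal variance cannot be standardized
#' and are dropped with a warning listing their ids.
#'
#' @param logMatrix genes x samples log2 matrix.
#' @param design design data.frame.
#' @param degSet gene ids to profile (default: all rows).
#' @return genes x timepoints matrix of standardized profiles.
#' @export
buildProfiles <- function(logMatrix, design, degSet = rownames(logMatrix)) {
  design <- validateDesign(design)
  degSet <- intersect(degSet, rownames(logMatrix))
  tp <- levels(design$timepoint)
  means <- sapply(tp, function(t) {
    cols <- design$sample[design$timepoint == t]
    rowMeans(logMatrix[degSet, cols, drop = FALSE])
  })
  means <- matrix(means, nrow = length(degSet),
                  dimnames = list(degSet, tp))
  sds <- apply(means, 1L, sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning("dropping ", sum(flat), " constant-profile gene(s): ",
            paste(head(degSet[flat], 10L), collapse = ", "))
    means <- means[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  (means - rowMeans(means)) / sds
}

#' Fuzzy c-means clustering
#'
#' Standard alternating optimisation: memberships
#' \code{u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))} and centers as
#' membership^m-weighted means, Euclidean distance.  Centers are
#' initialized by seeded sampling of data rows.  A profile at zero
#' distance from a center receives membership 1 there (0 elsewhere).
#' Convergence when the maximum membership change drops below \code{tol}.
#'
#' @param profiles genes x timepoints matrix (standardized).
#' @param c number of clusters (>= 1).
#' @param m fuzzifier (> 1).
#' @param tol convergence tolerance on memberships.
#' @param maxIter iteration cap.
#' @param seed RNG seed for the initialization.
#' @return a \linkS4class{FuzzyClustering}.
#' @export
fuzzyCMeans <- function(profiles, c = 4L, m = 1.25, tol = 1e-6,
                        maxIter = 200L, seed = 1L) {
  stopifnot(c >= 1L, m > 1)
  n <- nrow(profiles)
  if (n < c) stop("fewer profiles than clusters")
  set.seed(seed)
  # seeded farthest-point initialization: reproducible and duplicate-free
  idx <- sample.int(n, 1L)
  while (length(idx) < c) {
    d2min <- apply(vapply(idx, function(i)
      rowSums(sweep(profiles, 2L, profiles[i, ])^2), numeric(n)), 1L, min)
    cand <- which.max(d2min)
    if (d2min[cand] == 0)
      cand <- sample(setdiff(seq_len(n), idx), 1L)
    idx <- c(idx, cand)
  }
  centers <- profiles[idx, , drop = FALSE]
  rownames(centers) <- paste0("C", seq_len(c))
  u <- matrix(1 / c, n, c, dimnames = list(rownames(profiles),
                                           rownames(centers)))
  objective <- numeric()
  expo <- 2 / (m - 1)
  for (iter in seq_len(maxIter)) {
    d2 <- outer(rowSums(profiles^2), rep(1, c)) -
      2 * profiles %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    uNew <- matrix(0, n, c, dimnames = dimnames(u))
    zero <- d2 == 0
    hasZero <- rowSums(zero) > 0
    if (any(hasZero)) {
      for (i in which(hasZero))
        uNew[i, which(zero[i, ])[1L]] <- 1
    }
    ok <- !hasZero
    if (any(ok)) {
      dpow <- d2[ok, , drop = FALSE]^(expo / 2)
      uNew[ok, ] <- (1 / dpow) / rowSums(1 / dpow)
    }
    objective <- c(objective, sum(uNew^m * d2))
    um <- uNew^m
    centers <- (t(um) %*% profiles) / colSums(um)
    delta <- max(abs(uNew - u))
    u <- uNew
    if (delta < tol) break
  }
  methods::new("FuzzyClustering", membership = u, centers = centers,
               m = m, objective = objective, iterations = as.integer(iter))
}

#' Harden a fuzzy clustering into labels
#'
#' Argmax membership per gene; ties resolved toward the lowest cluster
#' index; genes whose maximum membership falls below \code{minMembership}
#' are labelled \code{NA} (unassigned).
#'
#' @param clustering a \linkS4class{FuzzyClustering}.
#' @param minMembership assignment floor, default 0.3.
#' @return named character vector gene -> cluster label (NA = unassigned).
#' @export
assignClusters <- function(clustering, minMembership = 0.3) {
  u <- memberships(clustering)
  idx <- apply(u, 1L, which.max)   # which.max takes the first (lowest) tie
  lab <- colnames(u)[idx]
  lab[u[cbind(seq_len(nrow(u)), idx)] < minMembership] <- NA_character_
  setNames(lab, rownames(u))
}
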