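makeMetMatrix <- function(nMet = 15L, reps = 5L, seed = 1L,
                          tp = c("D0", "D4"), shift = NULL) {
  set.seed(seed)
  d <- toyDesign(tp = tp, reps = reps, prefix = "Q")
  m <- matrix(exp(rnorm(nMet * nrow(d), log(50), 0.1)), nMet,
              dimnames = list(sprintf("M%02d", seq_len(nMet)), d$sample))
  if (!is.null(shift))
    for (i in seq_along(shift))
      m[i, d$timepoint == tp[2L]] <- m[i, d$timepoint == tp[2L]] * 2^shift[i]
  list(m = m, d = d)
}

test_that("OPLS-DA concentrates weight on a perfectly class-aligned variable", {
  set.seed(61)
  d <- toyDesign(tp = c("D0", "D4"), reps = 20L, prefix = "Q")
  cls <- ifelse(d$timepoint == "D4", 1, -1)
  m <- rbind(x1 = 50 + 5 * cls,
             matrix(rnorm(3 * 40, 50, 1), 3, 40,
                    dimnames = list(paste0("x", 2:4), NULL)))
  colnames(m) <- d$sample
  fit <- fitOplsda(m, d, "D0", "D4")
  expect_gt(abs(fit@weights[["x1"]]), 0.95)
  expect_true(validObject(fit))
})

test_that("orthogonal scores stay orthogonal to predictive scores", {
  for (s in 1:5) {
    mm <- makeMetMatrix(seed = s, shift = c(1, -1))
    fit <- fitOplsda(mm$m, mm$d, "D0", "D4", nOrth = 2L)
    if (ncol(fit@orthoScores))
      expect_lt(max(abs(crossprod(fit@orthoScores, fit@scores))), 1e-8)
  }
})

test_that("VIP satisfies its algebraic identity and the equal-weight case", {
  mm <- makeMetMatrix(seed = 3, shift = c(2, -2, 1))
  fit <- fitOplsda(mm$m, mm$d, "D0", "D4")
  vip <- vipScores(fit)
  expect_equal(sum(vip^2), length(vip), tolerance = 1e-8)
  expect_equal(mean(vip^2), 1, tolerance = 1e-8)
  # equal |weights| -> all VIP exactly 1 (constructed model)
  fitEq <- fit
  p <- length(fit@weights)
  fitEq@weights <- setNames(rep(1 / sqrt(p), p), names(fit@weights))
  expect_equal(unname(vipScores(fitEq)), rep(1, p), tolerance = 1e-12)
})

test_that("VIP matches the single-component closed form on a 3-variable fixture", {
  set.seed(67)
  d <- toyDesign(tp = c("D0", "D4"), reps = 4L, prefix = "Q")
  m <- matrix(exp(rnorm(24, log(30), 0.3)), 3,
              dimnames = list(c("a", "b", "c"), d$sample))
  fit <- fitOplsda(m, d, "D0", "D4")
  w <- fit@weights                       # unit norm by model invariant
  want <- sqrt(3 * w^2 / sum(w^2))       # formula with one component
  expect_equal(vipScores(fit), want, tolerance = 1e-10)
})

test_that("permuted class labels give non-positive cross-validated Q2 on average", {
  mm <- makeMetMatrix(nMet = 20L, reps = 6L, seed = 5, shift = c(2, 2, -2))
  set.seed(71)
  q2s <- replicate(20, {
    oplsQ2(mm$m, mm$d, "D0", "D4", labels = sample(rep(c(-1, 1), 6)))
  })
  expect_lte(mean(q2s), 0)
  # the true labeling is predictive
  expect_gt(oplsQ2(mm$m, mm$d, "D0", "D4"), 0.3)
})

test_that("pairwise DRM screen boundary semantics match a brute-force refilter", {
  mm <- makeMetMatrix(seed = 7, shift = c(2, 1.2, -2, 0.2))
  scr <- pairwiseDrm(mm$m, mm$d, "D0", "D4")
  brute <- with(scr, (fold_change >= 2 | fold_change <= 0.5) & vip > 1)
  expect_identical(scr$drm_flag, brute)
  # hand-held boundary cases on a synthetic screen row
  row <- data.frame(fold_change = 2.0, vip = 1.01)
  expect_true(with(row, (fold_change >= 2 | fold_change <= 0.5) & vip > 1))
  expect_identical(scr$direction[scr$fold_change > 1][1L], "increased")
  # FC at exactly the boundary is included; VIP exactly 1 is excluded
  scr2 <- scr
  scr2$fold_change[1L] <- 2.0; scr2$vip[1L] <- 1.0
  flag <- with(scr2[1L, ], (fold_change >= 2 | fold_change <= 0.5) & vip > 1)
  expect_false(flag)
  expect_false(with(data.frame(fold_change = 1.9, vip = 5),
                    (fold_change >= 2 | fold_change <= 0.5) & vip > 1))
})

test_that("screening is label-antisymmetric", {
  mm <- makeMetMatrix(seed = 9, shift = c(2, -1.5))
  ab <- pairwiseDrm(mm$m, mm$d, "D0", "D4")
  ba <- pairwiseDrm(mm$m, mm$d, "D4", "D0")
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_identical(ab$drm_flag, ba$drm_flag)
  expect_equal(ab$vip, ba$vip, tolerance = 1e-8)
})

test_that("multi-group ANOVA p matches the textbook F computation", {
  d <- toyDesign(tp = c("D0", "D4", "D8", "D12"), reps = 3L, prefix = "Q")
  v <- c(5.1, 4.9, 5.3,  6.2, 6.0, 6.4,  7.1, 6.8, 7.2,  7.0, 7.3, 6.9)
  m <- matrix(rep(v, 2), 2, byrow = TRUE,
              dimnames = list(c("Ma", "Mb"), d$sample))
  res <- multigroupDrm(m + matrix(c(0, 0.001), 2, 12), d)
  # textbook one-way F on the first row
  groups <- split(v, rep(1:4, each = 3))
  grand <- mean(v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / 3) / (ssw / 8)
  pHand <- pf(f, 3, 8, lower.tail = FALSE)
  expect_equal(res$anova_p[1L], pHand, tolerance = 1e-10)
})

test_that("a planted monotone trend is called as a multi-group DRM", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(200 + s)
    d <- toyDesign(tp = c("D0", "D4", "D8", "D12"), reps = 5L,
                   prefix = "Q")
    trend <- rep(c(1, 2, 3, 4), each = 5)
    m <- rbind(T1 = trend * exp(rnorm(20, 0, sqrt(log(1 + 0.01)))),
               matrix(exp(rnorm(10 * 20, log(2), 0.1)), 10, 20,
                      dimnames = list(paste0("N", 1:10), NULL)))
    colnames(m) <- d$sample
    res <- multigroupDrm(m, d)
    if (res$drm_flag[res$metabolite == "T1"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("DRM set accounting: exclusive regions, consistency, fraction increased", {
  mkScreen <- function(ids, dirs, cmp)
    data.frame(metabolite = ids, fold_change = ifelse(dirs == "increased",
                                                      3, 0.3),
               vip = 2, drm_flag = TRUE, direction = dirs,
               comparison = cmp)
  s1 <- mkScreen(c("A", "B"), c("increased", "increased"), "D4_vs_D0")
  s2 <- mkScreen(c("B", "C"), c("increased", "increased"), "D8_vs_D0")
  sets <- drmSets(list(D4_vs_D0 = s1, D8_vs_D0 = s2))
  expect_identical(unname(sets$exclusive[order(names(sets$exclusive))]),
                   c(1L, 1L, 1L))
  expect_identical(sets$consistent$metabolite, "B")
  expect_equal(sets$fractionIncreased, 1.0)
  # a decreased call lowers the increased fraction; direction conflict
  s2b <- mkScreen(c("B", "C"), c("decreased", "increased"), "D8_vs_D0")
  sets2 <- drmSets(list(D4_vs_D0 = s1, D8_vs_D0 = s2b))
  expect_identical(nrow(sets2$consistent), 0L)
  expect_equal(sets2$fractionIncreased, 3 / 4)
})

test_that("planted metabolome screen recovers truth with few false calls", {
  sens <- fcr <- numeric()
  for (s in 1:20) {
    cfg <- simConfig(seed = 300 + s,
                     metSpec = list(nMetabolites = 40L, nPlanted = 12L,
                                    plantedLfc = 2, cv = 0.1,
                                    nReplicates = 5L))
    sim <- simulateMetabolome(cfg)
    d <- designTable(sim$tce)
    scr <- pairwiseDrm(abundances(sim$tce), d, "D0", "D4")
    called <- scr$metabolite[scr$drm_flag]
    truth <- sim$truth$D4_vs_D0
    nulls <- setdiff(scr$metabolite, truth)
    sens <- c(sens, length(intersect(called, truth)) / length(truth))
    fcr <- c(fcr, length(setdiff(called, truth)) / length(nulls))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fcr), 0.1)
})
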