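test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 42)
  a <- simulateTimecourse(cfg)
  b <- simulateTimecourse(cfg)
  expect_identical(abundances(a$tce), abundances(b$tce))
  tfT <- data.frame(tf = "G0001", target = c("G0002", "G0003"))
  pa <- simulatePromoters(cfg, tfT)
  pb <- simulatePromoters(cfg, tfT)
  expect_identical(as.character(pa$promoters), as.character(pb$promoters))
  ma <- simulateMetabolome(cfg)
  mb <- simulateMetabolome(cfg)
  expect_identical(abundances(ma$tce), abundances(mb$tce))
})

test_that("planted DNB correlation peaks at the tipping timepoint", {
  cfg <- simConfig(seed = 3, nReplicates = 30L,
                   dnbSpec = list(size = 20L, tip = 2L, rhoInPre = 0.2,
                                  rhoInTip = 0.95, rhoOut = 0.1,
                                  sdMult = 3, sd = 0.5,
                                  profile = c(0, 0, 0, 0)))
  sim <- simulateTimecourse(cfg)
  logm <- logTransform(sim$tce)
  d <- designTable(sim$tce)
  meanCor <- vapply(timepointLevels(sim$tce), function(t) {
    cols <- d$sample[d$timepoint == t]
    r <- cor(t(logm[sim$dnbMembers, cols]))
    mean(abs(r[upper.tri(r)]))
  }, numeric(1))
  expect_gt(meanCor[["D4"]], max(meanCor[c("D0", "D8", "D12")]))
  expect_equal(meanCor[["D4"]], 0.95, tolerance = 0.05)
})

test_that("monotone archetype members have positive fitted slopes", {
  cfg <- simConfig(seed = 5)
  sim <- simulateTimecourse(cfg)
  logm <- logTransform(sim$tce)
  prof <- buildProfiles(logm, designTable(sim$tce),
                        names(sim$clusters)[sim$clusters == "C2"])
  slopes <- apply(prof, 1L, function(v) coef(lm(v ~ seq_along(v)))[2L])
  expect_gte(mean(slopes > 0), 0.95)
})

test_that("insertion rate 1 plants the exact consensus at the recorded offset", {
  cfg <- simConfig(seed = 11)
  tfT <- data.frame(tf = rep("G0001", 5L),
                    target = paste0("G000", 2:6))
  sim <- simulatePromoters(cfg, tfT)
  expect_identical(nrow(sim$truth), 5L)
  cons <- vapply(seq_len(nrow(sim$truth)), function(i) {
    with(sim$truth[i, ], substr(as.character(sim$promoters[[gene]]),
                                offset + 1L,
                                offset + ncol(motifMatrix(sim$pwms, motif))))
  }, character(1))
  consensus <- paste(rownames(motifMatrix(sim$pwms, "M_G0001"))[
    apply(motifMatrix(sim$pwms, "M_G0001"), 2L, which.max)], collapse = "")
  expect_true(all(cons == consensus))
})

test_that("at insertion rate 0 consensus occurrences match the background expectation", {
  cfg <- simConfig(seed = 13,
                   tfSpec = list(nTfs = 1L, targetsPerTf = 1L,
                                 motifWidth = 4L, promoterLength = 1000L,
                                 insertionRate = 0,
                                 background = c(A = .25, C = .25,
                                                G = .25, T = .25)))
  genes <- sprintf("P%03d", 1:500)
  tfT <- data.frame(tf = "TF1", target = "P001")
  sim <- simulatePromoters(cfg, tfT, genes = genes)
  expect_identical(nrow(sim$truth), 0L)
  cons <- consensus <- paste(rownames(motifMatrix(sim$pwms, "M_TF1"))[
    apply(motifMatrix(sim$pwms, "M_TF1"), 2L, which.max)], collapse = "")
  counts <- vapply(as.character(sim$promoters), function(s) {
    hits <- gregexpr(cons, s, fixed = TRUE)[[1L]]
    sum(hits > 0)
  }, numeric(1))
  lambda <- (1000 - 4 + 1) * 0.25^4   # per-promoter expectation
  total <- sum(counts)
  expect_lt(abs(total - 500 * lambda), 4 * sqrt(500 * lambda))
})

test_that("planted metabolite fold-changes are realized and truth is consistent", {
  cfg0 <- simConfig(seed = 17,
                    metSpec = list(nMetabolites = 30L, nPlanted = 0L,
                                   plantedLfc = 0, cv = 0.1,
                                   nReplicates = 5L))
  m0 <- simulateMetabolome(cfg0)
  expect_true(all(lengths(m0$truth) == 0L))
  cfg <- simConfig(seed = 19,
                   metSpec = list(nMetabolites = 30L, nPlanted = 10L,
                                  plantedLfc = 2, cv = 0.05,
                                  nReplicates = 5L))
  m <- simulateMetabolome(cfg)
  vals <- abundances(m$tce)
  d <- designTable(m$tce)
  fc <- rowMeans(vals[1:10, d$sample[d$timepoint == "D4"]]) /
    rowMeans(vals[1:10, d$sample[d$timepoint == "D0"]])
  expect_gt(median(fc), 3.5)
  expect_lt(median(fc), 4.5)
  expect_setequal(m$truth$D4_vs_D0, sprintf("M%03d", 1:10))
})

test_that("impossible correlation structure errors naming the DNB block", {
  cfg <- simConfig(seed = 1)
  cfg$dnbSpec$rhoInPre <- 0.01
  cfg$dnbSpec$rhoOut <- 0.3
  expect_error(simulateTimecourse(cfg), "positive semi-definite")
})

test_that("planted statistics converge at large replicate counts", {
  cfg <- simConfig(seed = 23, nReplicates = 100L,
                   dnbSpec = list(size = 10L, tip = 2L, rhoInPre = 0.3,
                                  rhoInTip = 0.8, rhoOut = 0.1,
                                  sdMult = 2, sd = 0.5,
                                  profile = c(0, 0, 0, 0)))
  sim <- simulateTimecourse(cfg)
  logm <- log2(abundances(sim$tce))
  d <- designTable(sim$tce)
  colsTip <- d$sample[d$timepoint == "D4"]
  M <- logm[sim$dnbMembers, colsTip]
  r <- cor(t(M))
  rBar <- mean(r[upper.tri(r)])
  # Fisher-z standard error at n=100, ~3 se band
  expect_lt(abs(atanh(rBar) - atanh(0.8)), 3 / sqrt(97) * 3)
  sdBar <- mean(apply(M, 1L, sd))
  # member sds co-vary at rho = 0.8, so the mean-sd se is close to one
  # gene's se, sd/sqrt(2n) ~ 0.07; allow a 3-se band
  expect_equal(sdBar, 1.0, tolerance = 0.22)  # sd * sdMult = 0.5 * 2
})
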