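test_that("module statistics follow the sample-sd worked example", {
  d <- toyDesign(tp = "D0", reps = 3L)
  logm <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), out = c(1, 3, 2))
  colnames(logm) <- d$sample
  st <- moduleStats(c("g1", "g2"), logm, d, "D0", epsilon = 0.05)
  expect_equal(st$PCCin, 1)
  expect_equal(st$SDin, 1.5)          # (sd(1,2,3) + sd(2,4,6)) / 2
  expect_equal(st$PCCout, 0.5)        # cor((1,2,3),(1,3,2)) = 0.5
  expect_equal(st$CI, 1.5 * 1 / 0.5)
})

test_that("module statistics equal brute force on every module of a 6-gene toy", {
  set.seed(41)
  d <- toyDesign(tp = c("D0", "D4"), reps = 5L)
  logm <- matrix(rnorm(60, 5), 6, 10,
                 dimnames = list(paste0("g", 1:6), d$sample))
  genes <- rownames(logm)
  for (sz in 2:4) {
    mods <- combn(genes, sz, simplify = FALSE)
    for (mod in mods) {
      for (tpt in c("D0", "D4")) {
        got <- moduleStats(mod, logm, d, tpt)
        want <- bruteStats(mod, logm, d, tpt)
        expect_equal(got$SDin, want[["SDin"]], tolerance = 1e-12)
        expect_equal(got$PCCin, want[["PCCin"]], tolerance = 1e-12)
        expect_equal(got$PCCout, want[["PCCout"]], tolerance = 1e-12)
        expect_equal(got$CI, want[["CI"]], tolerance = 1e-12)
      }
    }
  }
})

test_that("zero-variance members get zero correlations and are flagged", {
  d <- toyDesign(tp = "D0", reps = 3L)
  logm <- rbind(g1 = c(1, 1, 1), g2 = c(2, 4, 6), g3 = c(5, 4, 7))
  colnames(logm) <- d$sample
  st <- moduleStats(c("g1", "g2"), logm, d, "D0")
  expect_identical(attr(st, "flagged"), "g1")
  expect_equal(st$PCCin, 0)
})

test_that("CI responds monotonically to its three inputs above the floor", {
  ci <- function(sdin, pccin, pccout, eps = 0.05)
    sdin * pccin / max(pccout, eps)
  expect_gt(ci(1.1, .5, .3), ci(1.0, .5, .3))
  expect_gt(ci(1, .6, .3), ci(1, .5, .3))
  expect_lt(ci(1, .5, .4), ci(1, .5, .3))
  # below the floor the denominator saturates
  expect_equal(ci(1, .5, .01), ci(1, .5, .04))
})

test_that("a perfectly correlated planted pair appears among candidates", {
  set.seed(43)
  d <- toyDesign(tp = "D0", reps = 30L)
  base <- rnorm(30)
  logm <- rbind(g1 = base, g2 = 2 * base + 1,
                matrix(rnorm(28 * 30), 28, 30,
                       dimnames = list(paste0("n", 1:28), NULL)))
  colnames(logm) <- d$sample
  mods <- candidateModules(logm, d, "D0", minSize = 2L, maxSize = 10L,
                           heights = c(0.05, 0.2))
  expect_true(any(vapply(mods, function(m)
    identical(sort(m), c("g1", "g2")), logical(1))))
})

test_that("independent genes form no tight module", {
  hit <- 0L
  for (s in 1:5) {
    set.seed(s)
    d <- toyDesign(tp = "D0", reps = 50L)
    logm <- matrix(rnorm(100 * 50), 100, 50,
                   dimnames = list(sprintf("g%03d", 1:100), d$sample))
    mods <- candidateModules(logm, d, "D0", minSize = 5L, maxSize = 50L)
    tight <- vapply(mods, function(m) {
      r <- cor(t(logm[m, d$sample]))
      mean(abs(r[upper.tri(r)])) > 0.8
    }, logical(1))
    if (any(tight)) hit <- hit + 1L
  }
  expect_lte(hit, 1L)   # >= 95% of seeds clean, allow one failure in five
})

test_that("without a planted module the detected tip is uniform over timepoints", {
  tp <- c("D0", "D4", "D8", "D12")
  d <- toyDesign(tp = tp, reps = 6L)
  tips <- vapply(1:60, function(s) {
    set.seed(s)
    m <- matrix(rnorm(80 * 24, 6, 0.5), 80, 24,
                dimnames = list(sprintf("g%02d", 1:80), d$sample))
    tippingPoint(criticalityCurve(m, d))
  }, character(1))
  counts <- table(factor(tips, levels = tp))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("the criticality curve peaks at the planted tipping point", {
  cfg <- simConfig(seed = 47, nReplicates = 10L)
  sim <- simulateTimecourse(cfg)
  logm <- logTransform(sim$tce)
  dnb <- criticalityCurve(logm, designTable(sim$tce))
  expect_identical(tippingPoint(dnb), "D4")
  cv <- ciCurve(dnb)
  expect_identical(cv$timepoint[which.max(cv$CI)], "D4")
  expect_gt(length(intersect(dnbMembers(dnb), sim$dnbMembers)) /
              length(sim$dnbMembers), 0.8)
})

test_that("neighborhood expansion keeps members, adds only DEG neighbors", {
  net <- data.frame(from = c("m1", "m1", "m1", "m1", "m1"),
                    to = c("d1", "d2", "d3", "x1", "x2"), weight = 1)
  nb <- dnbNeighborhood("m1", net, degSet = c("d1", "d2", "d3"))
  expect_identical(nrow(nb$edges), 3L)
  expect_setequal(nb$nodes, c("m1", "d1", "d2", "d3"))
  # empty network: members survive as isolated nodes
  nb0 <- dnbNeighborhood(c("m1", "m2"),
                         data.frame(from = character(), to = character(),
                                    weight = numeric()),
                         degSet = "d1")
  expect_setequal(nb0$nodes, c("m1", "m2"))
  expect_identical(nrow(nb0$edges), 0L)
  expect_setequal(attr(nb0, "dropped"), c("m1", "m2"))
})

test_that("neighborhood is monotone in the DEG set", {
  set.seed(49)
  genes <- paste0("g", 1:30)
  net <- data.frame(from = sample(genes, 60, TRUE),
                    to = sample(genes, 60, TRUE), weight = 1)
  net <- net[net$from != net$to, ]
  members <- genes[1:3]
  degA <- genes[4:10]
  degB <- c(degA, genes[11:15])
  a <- dnbNeighborhood(members, net, degA)
  b <- dnbNeighborhood(members, net, degB)
  expect_true(all(a$nodes %in% b$nodes))
  expect_gte(nrow(b$edges), nrow(a$edges))
})
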