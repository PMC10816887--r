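test_that("TF family enrichment equals exhaustive hypergeometric enumeration", {
  annot <- setNames(c(rep("famA", 5), rep("famB", 5)), paste0("T", 1:10))
  sub <- paste0("T", 1:4)               # four famA members
  res <- tfFamilyEnrichment(sub, annot)
  pA <- res$p_hyper[res$family == "famA"]
  expect_equal(pA, 5 / 210, tolerance = 1e-12)
  expect_equal(pA, enumHyperTail(10, 5, 4, 4), tolerance = 1e-12)
  # k = 0 on famB is certain
  expect_equal(res$p_hyper[res$family == "famB"],
               enumHyperTail(10, 5, 4, 0), tolerance = 1e-12)
  expect_equal(res$p_hyper[res$family == "famB"], 1, tolerance = 1e-12)
  # subset = universe: every family has k = K, p = 1
  resAll <- tfFamilyEnrichment(names(annot), annot)
  expect_true(all(resAll$p_hyper == 1))
})

test_that("cumulative hypergeometric p equals one-sided Fisher exact p", {
  annot <- setNames(rep(c("f1", "f2", "f3"), times = c(6, 9, 5)),
                    paste0("T", 1:20))
  set.seed(21)
  sub <- sample(names(annot), 7)
  res <- tfFamilyEnrichment(sub, annot)
  for (i in seq_len(nrow(res))) {
    tab <- with(res[i, ], matrix(c(k, K - k, n - k, N - K - (n - k)), 2L))
    expect_equal(res$p_hyper[i],
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("consensus PWM scan reproduces the exact trimer null", {
  pwm <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", 1] <- pwm["C", 2] <- pwm["G", 3] <- 1
  lib <- PwmLibrary(list(CONS = pwm))
  hits <- pwmScan(c(P1 = "TTTTACGTTTT"), lib, pThreshold = 0.02,
                  bothStrands = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset, 4L)
  expect_equal(hits$score, 3 * log2(1 / 0.25), tolerance = 0.01)
  expect_equal(hits$p_value, 1 / 64, tolerance = 1e-9)
})

test_that("a uniform PWM produces no hits at any threshold below 1", {
  pwm <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  lib <- PwmLibrary(list(U = pwm))
  hits <- pwmScan(c(P1 = paste(rep("ACGT", 20), collapse = "")), lib,
                  pThreshold = 0.999)
  expect_identical(nrow(hits), 0L)
  # at threshold 1 every window is a (score 0, p 1) hit
  all <- pwmScan(c(P1 = "ACGTACGT"), lib, pThreshold = 1,
                 bothStrands = FALSE)
  expect_true(all(all$score == 0) && all(all$p_value == 1))
})

test_that("scan p-values match exhaustive k-mer enumeration within a bin", {
  set.seed(31)
  bg <- c(A = .3, C = .2, G = .2, T = .3)
  for (w in c(3L, 5L)) {
    raw <- matrix(rexp(4 * w), 4)
    pwm <- sweep(raw, 2L, colSums(raw), "/")
    rownames(pwm) <- c("A", "C", "G", "T")
    lib <- PwmLibrary(list(M = pwm), background = bg)
    enum <- enumKmerTail(pwm, bg)
    null <- tipomics:::pwmNullDistribution(
      log2(sweep(pmax(pwm, 1e-4), 2L, colSums(pmax(pwm, 1e-4)), "/") / bg),
      bg)
    for (s in quantile(enum$scores, c(.05, .5, .9, .99))) {
      pDp <- tipomics:::pwmNullPvalue(null, s)
      tol <- (w + 1) * 1e-3
      pHi <- sum(enum$probs[enum$scores >= s - tol])
      pLo <- sum(enum$probs[enum$scores >= s + tol])
      expect_gte(pDp, pLo - 1e-12)
      expect_lte(pDp, pHi + 1e-12)
    }
  }
})

test_that("planted consensus is found at its offset and strand symmetry holds", {
  cfg <- simConfig(seed = 37)
  tfT <- data.frame(tf = "G0001", target = "G0002")
  sim <- simulatePromoters(cfg, tfT)
  hits <- pwmScan(sim$promoters, sim$pwms, pThreshold = 1e-4)
  planted <- hits[hits$gene == sim$truth$gene[1L] & hits$strand == "+", ]
  expect_true(sim$truth$offset[1L] %in% planted$offset)
  # strand symmetry: scanning the reverse complement mirrors the hits
  rc <- Biostrings::reverseComplement(sim$promoters)
  hitsRc <- pwmScan(rc, sim$pwms, pThreshold = 1e-4)
  L <- Biostrings::width(sim$promoters)[1L]
  w <- motifWidths(sim$pwms)[[1L]]
  fwd <- hits[order(hits$gene, hits$offset, hits$strand), ]
  mir <- hitsRc
  mir$offset <- L - w - mir$offset
  mir$strand <- ifelse(mir$strand == "+", "-", "+")
  mir <- mir[order(mir$gene, mir$offset, mir$strand), ]
  expect_equal(fwd$offset, mir$offset)
  expect_equal(fwd$strand, mir$strand)
  expect_equal(fwd$score, mir$score, tolerance = 1e-9)
})

test_that("a motif wider than the promoter yields a warning and no hits", {
  pwm <- matrix(0.25, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  lib <- PwmLibrary(list(WIDE = pwm))
  expect_warning(hits <- pwmScan(c(P1 = "ACGT"), lib, pThreshold = 1),
                 "wider")
  expect_identical(nrow(hits), 0L)
})

test_that("direction rule: activation iff TF and target move together", {
  state <- list(label = 1L, comparison = "D4_vs_D0",
                degs = c(TF1 = "up", TF2 = "down", A = "up", B = "down",
                         C = "up", D = "down"),
                tfs = c("TF1", "TF2"))
  hits <- data.frame(motif = c("M1", "M1", "M2", "M2", "M1"),
                     gene = c("A", "B", "C", "D", "TF2"),
                     offset = c(10L, 20L, 30L, 40L, 50L),
                     strand = "+", score = 5, p_value = 1e-5)
  map <- data.frame(tf = c("TF1", "TF2"), motif = c("M1", "M2"))
  edges <- buildStateNetwork(state, hits, map)
  sgn <- setNames(edges$sign, paste(edges$tf, edges$target))
  expect_identical(sgn[["TF1 A"]], "activation")   # up/up
  expect_identical(sgn[["TF1 B"]], "inhibition")   # up/down
  expect_identical(sgn[["TF2 C"]], "inhibition")   # down/up
  expect_identical(sgn[["TF2 D"]], "activation")   # down/down
  expect_identical(sgn[["TF1 TF2"]], "inhibition") # TF regulating a TF
  expect_identical(nrow(edges), 5L)
  # no hit -> no edge even when both are DEGs
  expect_false("TF2 A" %in% names(sgn))
})

test_that("TFs without motif mapping contribute no edges but are reported", {
  state <- list(label = 2L, comparison = "D8_vs_D4",
                degs = c(TFX = "up", A = "up"), tfs = "TFX")
  hits <- data.frame(motif = "M9", gene = "A", offset = 1L, strand = "+",
                     score = 3, p_value = 1e-5)
  edges <- buildStateNetwork(state, hits,
                             data.frame(tf = character(),
                                        motif = character()))
  expect_identical(nrow(edges), 0L)
  expect_identical(attr(edges, "unmapped_tfs"), "TFX")
})

test_that("pair counting tallies signs per state and flags multi-state TFs", {
  empty <- data.frame(tf = character(), target = character(),
                      state = integer(), sign = character())
  expect_identical(sum(unlist(countPairs(empty)$counts[-1])), 0L)
  edges <- data.frame(
    tf = c("T1", "T1", "T2", "T1", "T3"),
    target = paste0("G", 1:5),
    state = c(1L, 1L, 1L, 2L, 2L),
    sign = c("activation", "inhibition", "activation", "activation",
             "inhibition"))
  cp <- countPairs(edges)
  expect_identical(cp$counts$activation[cp$counts$state == 1L], 2L)
  expect_identical(cp$counts$inhibition[cp$counts$state == 1L], 1L)
  expect_identical(cp$counts$activation[cp$counts$state == 2L], 1L)
  expect_identical(cp$multiStateTfs, "T1")
})
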