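# shared fixtures built in code

toyDesign <- function(tp = c("D0", "D4"), reps = 3L, prefix = "S") {
  data.frame(sample = paste0(prefix, seq_len(length(tp) * reps)),
             timepoint = rep(tp, each = reps),
             replicate = rep(seq_len(reps), length(tp)),
             stringsAsFactors = FALSE)
}

toyTce <- function(nGenes = 3L, tp = c("D0", "D4"), reps = 3L, seed = 1L) {
  set.seed(seed)
  d <- toyDesign(tp, reps)
  m <- matrix(round(runif(nGenes * nrow(d), 1, 100), 3), nGenes,
              dimnames = list(paste0("G", seq_len(nGenes)), d$sample))
  TimecourseExperiment(m, d)
}

# exhaustive hypergeometric upper tail by enumerating all draws
enumHyperTail <- function(N, K, n, k) {
  draws <- combn(N, n)
  inK <- draws <= K          # treat 1..K as the set members
  mean(colSums(inK) >= k)
}

# naive weighted KS walk, independent of the package implementation
naiveWalk <- function(expr, members, tau) {
  ord <- order(expr, decreasing = TRUE)
  genes <- names(expr)[ord]
  N <- length(genes)
  inSet <- genes %in% members
  K <- sum(inSet)
  w <- (N:1)^tau
  cum <- 0; best <- 0
  for (i in seq_len(N)) {
    cum <- cum + if (inSet[i]) w[i] / sum(w[inSet]) else -1 / (N - K)
    if (abs(cum) > abs(best)) best <- cum
  }
  best
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# weighted exhaustive k-mer tail probabilities for a floored PWM
enumKmerTail <- function(pwm, bg, pseudoFreq = 1e-4) {
  pwm <- pmax(pwm, pseudoFreq)
  pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  lo <- log2(pwm / bg)
  w <- ncol(pwm)
  kmers <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(vapply(seq_len(w), function(j) lo[kmers[, j], j],
                           numeric(nrow(kmers))))
  probs <- apply(matrix(bg[kmers], ncol = w), 1L, prod)
  list(scores = scores, probs = probs)
}

# independent brute-force DNB statistics
bruteStats <- function(module, logm, design, timepoint, epsilon = 0.05) {
  cols <- design$sample[design$timepoint == timepoint]
  M <- logm[module, cols, drop = FALSE]
  sdin <- mean(apply(M, 1L, sd))
  prs <- combn(length(module), 2L)
  pccin <- mean(vapply(seq_len(ncol(prs)), function(i) {
    r <- suppressWarnings(cor(M[prs[1L, i], ], M[prs[2L, i], ]))
    if (is.na(r)) 0 else abs(r)
  }, numeric(1)))
  outside <- setdiff(rownames(logm), module)
  pccout <- mean(vapply(outside, function(o) {
    mean(vapply(module, function(g) {
      r <- suppressWarnings(cor(logm[g, cols], logm[o, cols]))
      if (is.na(r)) 0 else abs(r)
    }, numeric(1)))
  }, numeric(1)))
  ci <- sdin * pccin / max(pccout, epsilon)
  c(SDin = sdin, PCCin = pccin, PCCout = pccout, CI = ci)
}

# simulate a full input file set and return a pipeline config pointing at it
pipelineInputs <- function(dir, seed = 7L) {
  cfg <- simConfig(seed = seed)
  simulateAll(cfg, dir = dir)
  list(inputs = list(
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    met_design = file.path(dir, "met_design.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    motifs = file.path(dir, "motifs.meme"),
    tf_annotation = file.path(dir, "tf_annotation.tsv"),
    tf_motif_map = file.path(dir, "tf_motif_map.tsv"),
    network = file.path(dir, "network.tsv"),
    genesets = file.path(dir, "genesets.gmt"),
    pathways = file.path(dir, "pathways.tsv")), seed = seed)
}
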