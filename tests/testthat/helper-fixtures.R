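# Small in-code fixture builders shared across test files.

makeOmics <- function(values, kind = "mrna_counts",
                      features = sprintf("f%02d", seq_len(nrow(values))),
                      samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  OmicsMatrix(values, kind)
}

# random small transform instance: <= maxGenes genes, <= maxSamples samples,
# random bipartite wiring with moderate value ranges
randomInstance <- function(maxGenes = 10, maxSamples = 5) {
  nG <- sample(1:maxGenes, 1)
  nS <- sample(1:maxSamples, 1)
  nM <- sample(1:6, 1)
  nC <- sample(1:6, 1)
  genes <- paste0("g", seq_len(nG))
  mirnas <- paste0("m", seq_len(nM))
  cpgs <- paste0("c", seq_len(nC))
  mrna <- makeOmics(matrix(round(runif(nG * nS, 0, 100), 2), nG, nS),
                    "mrna_counts", genes)
  mirna <- makeOmics(matrix(round(runif(nM * nS, 0, 100), 2), nM, nS),
                     "mirna_counts", mirnas)
  meth <- makeOmics(matrix(round(runif(nC * nS, 0.2, 1), 3), nC, nS),
                    "methylation_beta", cpgs)
  pairs <- expand.grid(mirna_id = mirnas, gene_id = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE]
  pairs$raw_score <- -round(runif(nrow(pairs), 0.1, 1), 3)
  pm <- expand.grid(cpg_id = cpgs, gene_id = genes,
                    stringsAsFactors = FALSE)
  pm <- pm[runif(nrow(pm)) < 0.5, , drop = FALSE]
  pm$tss_distance_bp <- sample(0:1500, nrow(pm), replace = TRUE)
  list(mrna = mrna, mirna = mirna, meth = meth, pairs = pairs, pm = pm)
}

# run the transform both ways (fast path and naive oracle) on an instance
bothRoutes <- function(inst, cfg = TransformConfig()) {
  ints <- if (nrow(inst$pairs)) {
    normalizeInteractionScores(inst$pairs, cfg@isFloor)
  } else {
    cbind(inst$pairs, is = numeric(0))
  }
  oracle <- deltaOracle(inst$mrna, inst$mirna, inst$meth, ints, inst$pm, cfg)
  fast <- tryCatch({
    g <- buildGraphs(ints, inst$pm, inst$mrna, inst$mirna, inst$meth)
    transformMatrix(inst$mrna, inst$mirna, inst$meth, g, cfg)
  }, error = function(e) NULL)
  list(oracle = oracle, fast = fast)
}

# easy-mode classification data: well-separated class means
easyClassData <- function(n = 80, p = 6, classes = c("a", "b", "c", "d"),
                          sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(classes, length.out = n)
  mu <- matrix(rnorm(length(classes) * p, sd = sep),
               length(classes), p)
  X <- mu[match(y, classes), ] + matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, y = y)
}
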