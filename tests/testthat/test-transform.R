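test_that("interaction-score normalisation maps |raw| onto [floor, 1]", {
  t <- data.frame(mirna_id = paste0("m", 1:3), gene_id = "g1",
                  raw_score = c(-0.2, -0.6, -1.0))
  out <- normalizeInteractionScores(t, 0.01)
  expect_equal(out$is, c(0.01, 0.505, 1.0), tolerance = 1e-12)

  one <- normalizeInteractionScores(t[1, ], 0.01)
  expect_equal(one$is, 1)

  const <- t; const$raw_score <- -0.5
  expect_equal(normalizeInteractionScores(const, 0.01)$is, rep(1, 3))

  expect_error(normalizeInteractionScores(t[0, ]), "empty")
})

test_that("modulating factors match their closed forms", {
  expect_equal(delta1GeneSample(0, 1.0, 1.5, 1), 1, tolerance = 1e-12)
  expect_equal(delta1GeneSample(c(1, 1), c(1, 1), 1.5, 1), exp(-1.5),
               tolerance = 1e-12)
  expect_equal(delta1GeneSample(3, 0.5, 1.5, 1), 2 * exp(-3),
               tolerance = 1e-12)
  expect_equal(delta2GeneSample(1.0, 1.5), 1, tolerance = 1e-12)
  expect_equal(delta2GeneSample(0.5, 1.5), exp(1.5), tolerance = 1e-12)
  expect_equal(delta2GeneSample(c(0.5, 1.0), 1.5), (exp(1.5) + 1) / 2,
               tolerance = 1e-12)
  # single partner closed form on a grid: IS^-1 * (e+1)^(-alpha/ln 2)
  for (e in c(0, 0.5, 2, 10, 100)) {
    for (is in c(0.05, 0.4, 1)) {
      expect_equal(delta1GeneSample(e, is, 1.5, 1),
                   (1 / is) * (e + 1)^(-1.5 / log(2)), tolerance = 1e-9)
    }
  }
  expect_true(is.na(delta1GeneSample(numeric(0), numeric(0))))
  expect_true(is.na(delta2GeneSample(numeric(0))))
})

test_that("factor combination honours weights and the missing-partner policy", {
  expect_equal(combineDelta(1, 1, 1, 1), 1)
  expect_equal(combineDelta(0.2, 4.0, 1, 1), 2.1, tolerance = 1e-12)
  expect_equal(combineDelta(0.2, 4.0, 3, 1), 1.15, tolerance = 1e-12)
  expect_equal(combineDelta(NA, 4.0, 1, 1, "fallback"), 4.0)
  expect_equal(combineDelta(NA, 4.0, 1, 1, "neutral_one"), 2.5)
  expect_equal(combineDelta(NA, NA, 1, 1), 1)
})

test_that("graph construction drops unmatched edges and deduplicates", {
  inst <- list(
    mrna = makeOmics(matrix(1, 2, 2), "mrna_counts", c("g1", "g2")),
    mirna = makeOmics(matrix(1, 1, 2), "mirna_counts", "m1"),
    meth = makeOmics(matrix(0.5, 1, 2), "methylation_beta", "c1")
  )
  pairs <- data.frame(mirna_id = c("m1", "m1", "mAbsent"),
                      gene_id = c("g1", "g2", "g1"),
                      raw_score = c(-0.3, -0.6, -0.9))
  pm <- data.frame(cpg_id = c("c1", "c1", "cAbsent"),
                   gene_id = c("g1", "g1", "g2"),
                   tss_distance_bp = c(10L, 10L, 5L))
  g <- buildGraphs(normalizeInteractionScores(pairs), pm,
                   inst$mrna, inst$mirna, inst$meth)
  expect_equal(unname(g@edgeStats["mirna_edges"]), 2)
  expect_equal(unname(g@edgeStats["mirna_dropped"]), 1)
  expect_equal(unname(g@edgeStats["cpg_edges"]), 1)   # duplicate collapsed
  expect_equal(unname(g@edgeStats["cpg_dropped"]), 1)
})

test_that("genes without partners pass through the transform unchanged", {
  fx <- generateDegenerateCases()$transform
  ints <- normalizeInteractionScores(fx$interactions)
  g <- buildGraphs(ints, fx$promoterMap, fx$mrna, fx$mirna, fx$meth)
  res <- transformMatrix(fx$mrna, fx$mirna, fx$meth, g)
  gene <- fx$planted$partnerlessGene
  expect_identical(transformedMatrix(res)[gene, ],
                   omicsValues(fx$mrna)[gene, ])
  expect_true(all(deltaMatrix(res)[gene, ] == 1))
})

test_that("all-neutral partners give a combined factor of exactly 1", {
  mrna <- makeOmics(matrix(c(10, 20, 30, 40), 2, 2), "mrna_counts",
                    c("g1", "g2"))
  mirna <- makeOmics(matrix(0, 1, 2), "mirna_counts", "m1")
  meth <- makeOmics(matrix(1, 1, 2), "methylation_beta", "c1")
  pairs <- data.frame(mirna_id = "m1", gene_id = "g1", raw_score = -0.5)
  pm <- data.frame(cpg_id = "c1", gene_id = "g1", tss_distance_bp = 0L)
  g <- buildGraphs(normalizeInteractionScores(pairs), pm, mrna, mirna, meth)
  res <- transformMatrix(mrna, mirna, meth, g)
  expect_identical(transformedMatrix(res), omicsValues(mrna))
})

test_that("fast transform agrees with the naive edge-loop oracle", {
  set.seed(2024)
  checked <- 0
  for (i in 1:200) {
    inst <- randomInstance()
    routes <- bothRoutes(inst)
    if (is.null(routes$fast)) next   # no usable edges in either graph
    checked <- checked + 1
    expect_lt(max(abs(routes$fast@transformed -
                        routes$oracle$transformed)), 1e-9)
    expect_lt(max(abs(routes$fast@delta - routes$oracle$delta)), 1e-9)
  }
  expect_gt(checked, 150)
})

test_that("factors are strictly decreasing in expression, score and beta", {
  exprGrid <- seq(0, 90, length.out = 10)
  isGrid <- seq(0.1, 1, length.out = 10)
  for (is in isGrid) {
    d <- vapply(exprGrid, function(e) delta1GeneSample(e, is, 1.5, 1), 0)
    expect_true(all(diff(d) < 0))
  }
  for (e in exprGrid) {
    d <- vapply(isGrid, function(is) delta1GeneSample(e, is, 1.5, 1), 0)
    expect_true(all(diff(d) < 0))
  }
  betaGrid <- seq(0.05, 1, length.out = 10)
  d2 <- vapply(betaGrid, function(b) delta2GeneSample(b, 1.5), 0)
  expect_true(all(diff(d2) < 0))
  # also with a fixed second partner
  d2b <- vapply(betaGrid, function(b) delta2GeneSample(c(b, 0.5), 1.5), 0)
  expect_true(all(diff(d2b) < 0))
})

test_that("permuting sample order permutes output columns identically", {
  set.seed(5)
  inst <- randomInstance(maxGenes = 6, maxSamples = 5)
  while (is.null(bothRoutes(inst)$fast)) inst <- randomInstance(6, 5)
  routes <- bothRoutes(inst)
  nS <- ncol(omicsValues(inst$mrna))
  perm <- sample(nS)
  permInst <- inst
  for (nm in c("mrna", "mirna", "meth")) {
    v <- omicsValues(inst[[nm]])[, perm, drop = FALSE]
    permInst[[nm]] <- OmicsMatrix(v, omicsKind(inst[[nm]]))
  }
  permuted <- bothRoutes(permInst)
  expect_identical(permuted$fast@transformed,
                   routes$fast@transformed[, perm, drop = FALSE])
})

test_that("misaligned samples are rejected rather than reindexed", {
  mrna <- makeOmics(matrix(1, 1, 2), "mrna_counts", "g1", c("s1", "s2"))
  mirna <- makeOmics(matrix(1, 1, 2), "mirna_counts", "m1", c("s2", "s1"))
  meth <- makeOmics(matrix(0.5, 1, 2), "methylation_beta", "c1",
                    c("s1", "s2"))
  pairs <- data.frame(mirna_id = "m1", gene_id = "g1", raw_score = -0.5)
  pm <- data.frame(cpg_id = "c1", gene_id = "g1", tss_distance_bp = 0L)
  g <- buildGraphs(normalizeInteractionScores(pairs), pm, mrna,
                   makeOmics(matrix(1, 1, 2), "mirna_counts", "m1"),
                   meth)
  expect_error(transformMatrix(mrna, mirna, meth, g), "sample-aligned")
})
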