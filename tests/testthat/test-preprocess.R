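test_that("feature filter removes strictly above the bad-fraction threshold", {
  v <- matrix(5, 4, 10)
  v[1, 1:3] <- 0                  # 30% zeros: removed
  v[2, 1:2] <- 0                  # exactly 20%: kept (strict inequality)
  v[3, 1] <- 0; v[3, 2:3] <- NA   # 1 zero + 2 missing = 30%: removed
  m <- makeOmics(v)
  res <- filterFeatures(m, 0.2)
  expect_identical(res$removed, c("f01", "f03"))
  expect_identical(featureIds(res$matrix), c("f02", "f04"))
})

test_that("sample filter applies the same rule column-wise", {
  v <- matrix(5, 4, 4)
  v[1:1, 1] <- NA                 # 25% missing: removed
  v[1:2, 2] <- 0                  # 50% zeros: removed
  m <- makeOmics(v)
  res <- filterSamples(m, 0.2)
  expect_identical(res$removed, c("s01", "s02"))
  expect_identical(sampleIds(res$matrix), c("s03", "s04"))
  expect_error(filterSamples(makeOmics(matrix(0, 2, 2))), "all samples")
})

test_that("filtering is idempotent", {
  set.seed(42)
  for (i in 1:20) {
    v <- matrix(rpois(60, 20) + 1, 6, 10)
    v[runif(60) < 0.15] <- NA
    v[1, ] <- 5   # one always-clean feature
    m <- makeOmics(v)
    once <- filterFeatures(m, 0.2)$matrix
    twice <- filterFeatures(once, 0.2)$matrix
    expect_identical(omicsValues(twice), omicsValues(once))
  }
})

test_that("sample intersection keeps the first matrix's order", {
  m1 <- makeOmics(matrix(1, 2, 3), samples = c("A", "B", "C"))
  m2 <- makeOmics(matrix(1, 2, 3), samples = c("B", "C", "D"))
  m3 <- makeOmics(matrix(1, 2, 2), samples = c("C", "B"))
  out <- intersectSamples(list(m1, m2, m3))
  for (m in out) expect_identical(sampleIds(m), c("B", "C"))

  same <- intersectSamples(list(m1, m1))
  expect_identical(omicsValues(same[[1]]), omicsValues(m1))

  m4 <- makeOmics(matrix(1, 2, 2), samples = c("X", "Y"))
  expect_error(intersectSamples(list(m1, m4)), "no samples")
})

test_that("median-of-ratios size factors match hand computation", {
  v <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2)
  res <- sizeFactorNormalize(makeOmics(v))
  sf <- unname(res$sizeFactors)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  expect_equal(omicsValues(res$matrix)[, 1], omicsValues(res$matrix)[, 2],
               tolerance = 1e-12)

  # identical columns: all size factors 1
  v2 <- matrix(c(3, 7, 11), 3, 4)
  res2 <- sizeFactorNormalize(makeOmics(v2))
  expect_equal(unname(res2$sizeFactors), rep(1, 4), tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  v <- matrix(rnbinom(200, mu = 100, size = 5) + 1, 20, 10)
  m <- makeOmics(v)
  ours <- sizeFactorNormalize(m)$sizeFactors
  ref <- DESeq2::estimateSizeFactorsForMatrix(v)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("normalisation absorbs per-sample scaling and sample order", {
  set.seed(11)
  v <- matrix(rnbinom(50, mu = 50, size = 10) + 1, 10, 5)
  m <- makeOmics(v)
  base <- sizeFactorNormalize(m)

  # scaling one column by c shifts the geometric-mean reference by c^(1/m),
  # so normalised matrices agree up to that common factor
  v2 <- v; v2[, 3] <- v2[, 3] * 5
  scaled <- sizeFactorNormalize(makeOmics(v2))
  ratio <- omicsValues(scaled$matrix) / omicsValues(base$matrix)
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  expect_equal(unname(scaled$sizeFactors[3] / base$sizeFactors[3]),
               5 * 5^(-1 / 5), tolerance = 1e-12)

  perm <- c(4, 2, 5, 1, 3)
  permuted <- sizeFactorNormalize(makeOmics(v[, perm],
                                            samples = sprintf("s%02d", perm)))
  expect_equal(unname(permuted$sizeFactors), unname(base$sizeFactors[perm]),
               tolerance = 1e-12)
})

test_that("beta imputation uses the feature median, then clamps", {
  v <- matrix(c(0.2, NA, 0.4,
                0, 0.5, 0.9,
                NA, 0.5, NA), 3, 3, byrow = TRUE)
  m <- makeOmics(v, "methylation_beta")
  out <- omicsValues(imputeAndClampBeta(m, 1e-3))
  expect_equal(unname(out[1, ]), c(0.2, 0.3, 0.4))
  expect_equal(out[2, 1], 1e-3)          # zero clamped to the floor
  expect_equal(unname(out[3, ]), c(0.5, 0.5, 0.5))
  expect_true(all(out >= 1e-3 & out <= 1))

  v[3, ] <- NA
  expect_error(imputeAndClampBeta(makeOmics(v, "methylation_beta")),
               "no non-missing")
})

test_that("promoter window is inclusive at both ends", {
  p <- data.frame(cpg_id = paste0("cg", 1:5), gene_id = "g1",
                  tss_distance_bp = c(0L, 700L, 1500L, 1501L, 4000L))
  out <- restrictPromoterMap(p, 1500)
  expect_identical(out$cpg_id, c("cg1", "cg2", "cg3"))
})

test_that("degenerate fixtures produce exactly the planted filter outcomes", {
  fx <- generateDegenerateCases()
  res <- filterFeatures(fx$features$matrix, 0.2)
  expect_identical(sort(res$removed), sort(fx$features$planted$removedFeatures))
  expect_identical(featureIds(res$matrix), fx$features$planted$keptFeatures)

  res2 <- filterSamples(fx$samples$matrix, 0.2)
  expect_identical(res2$removed, fx$samples$planted$removedSamples)

  bm <- fx$beta$matrix
  expect_error(imputeAndClampBeta(bm), "no non-missing")
  keepRows <- setdiff(rownames(omicsValues(bm)),
                      fx$beta$planted$allMissingFeature)
  ok <- OmicsMatrix(omicsValues(bm)[keepRows, , drop = FALSE],
                    "methylation_beta")
  out <- omicsValues(imputeAndClampBeta(ok, 1e-3))
  expect_equal(out[fx$beta$planted$zeroCell[1], fx$beta$planted$zeroCell[2]],
               1e-3)
})

test_that("the preprocessing cascade reports consistent counts", {
  b <- generateBundle(syntheticConfig(seed = 3))
  pre <- preprocessOmics(b$mrna, b$mirna, b$meth)
  rep <- pre$report
  for (nm in c("mrna", "mirna", "meth")) {
    expect_equal(rep$counts_before[[nm]][1] - length(rep$features_removed[[nm]]),
                 rep$counts_after[[nm]][1])
  }
  expect_identical(sampleIds(pre$mrna), sampleIds(pre$meth))
  expect_false(anyNA(omicsValues(pre$meth)))
})
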