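test_that("stratified split is proportional, disjoint and deterministic", {
  labels <- data.frame(sample_id = sprintf("s%03d", 1:100),
                       class_label = rep(c("a", "b", "c", "d"), each = 25))
  sp <- stratifiedSplit(labels, 0.2, 9)
  expect_length(sp$test, 20)
  tab <- table(labels$class_label[labels$sample_id %in% sp$test])
  expect_true(all(tab == 5))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), labels$sample_id)
  expect_identical(sp, stratifiedSplit(labels, 0.2, 9))

  # per-class test counts within 1 of the exact proportion, uneven sizes
  lab2 <- data.frame(sample_id = sprintf("t%03d", 1:37),
                     class_label = rep(c("x", "y", "z"), c(19, 11, 7)))
  sp2 <- stratifiedSplit(lab2, 0.3, 4)
  tab2 <- table(lab2$class_label[lab2$sample_id %in% sp2$test])
  expect_true(all(abs(tab2 - c(19, 11, 7) * 0.3) <= 1))

  bad <- data.frame(sample_id = c("a1", "a2", "b1"),
                    class_label = c("a", "a", "b"))
  expect_error(stratifiedSplit(bad, 0.2, 1), "fewer than 2")
})

test_that("minority augmentation balances classes with convex combinations", {
  set.seed(30)
  y <- rep(c("maj", "m1", "m2", "m3"), c(40, 10, 10, 10))
  X <- matrix(rnorm(70 * 3), 70, 3) +
    matrix(rep(c(0, 4, 8, 12), c(40, 10, 10, 10)), 70, 3)
  aug <- augmentMinority(X, y, seed = 5)
  tab <- table(aug$y)
  expect_true(all(abs(tab - 40) <= 4))          # within 10% of the majority
  # originals preserved bit-identically, first
  expect_identical(aug$X[1:70, ], unname(X))
  # every synthetic point lies on a segment between two same-class originals
  synIdx <- which(aug$synthetic)
  for (i in synIdx) {
    cl <- aug$y[i]
    orig <- X[y == cl, , drop = FALSE]
    onSegment <- FALSE
    for (a in seq_len(nrow(orig))) {
      d <- sweep(orig, 2, aug$X[i, ])           # candidates for endpoint 2
      v <- aug$X[i, ] - orig[a, ]
      for (b in seq_len(nrow(orig))) {
        ab <- orig[b, ] - orig[a, ]
        den <- sum(ab^2)
        if (den == 0) next
        lam <- sum(v * ab) / den
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sqrt(sum((orig[a, ] + lam * ab - aug$X[i, ])^2)) < 1e-8) {
          onSegment <- TRUE
          break
        }
      }
      if (onSegment) break
    }
    expect_true(onSegment)
  }
  expect_identical(aug, augmentMinority(X, y, seed = 5))
})

test_that("augmentation leaves balanced input unchanged and warns on tiny classes", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), each = 10)
  out <- augmentMinority(X, y, seed = 1)
  expect_identical(out$X, X)
  expect_identical(out$y, y)

  y2 <- rep(c("a", "b"), c(17, 3))
  expect_warning(augmentMinority(X[1:20, ], y2, seed = 1), "duplicating")
})

test_that("feature concatenation stacks layers with kind-prefixed ids", {
  m1 <- makeOmics(matrix(1, 5, 3))
  m2 <- makeOmics(matrix(2, 2, 3), "mirna_counts")
  m3 <- makeOmics(matrix(0.5, 4, 3), "methylation_beta")
  X <- concatenateFeatures(list(m1, m2, m3))
  expect_equal(dim(X), c(3L, 11L))
  expect_true(all(startsWith(colnames(X)[6:7], "mirna_counts:")))
  expect_identical(concatenateFeatures(list(m1)), {
    b <- t(omicsValues(m1)); colnames(b) <- paste0("mrna_counts:",
                                                   colnames(b)); b
  })
  m4 <- makeOmics(matrix(1, 2, 3), samples = c("x", "y", "z"))
  expect_error(concatenateFeatures(list(m1, m4)), "aligned")
})

test_that("model families fit separable data and are seed-deterministic", {
  d <- easyClassData(n = 80, p = 6, sep = 5, seed = 2)
  for (fam in c("logistic_ovr", "knn", "random_forest", "feedforward_net")) {
    spec <- if (fam == "feedforward_net") {
      modelSpec(fam, hiddenSizes = c(32L, 16L, 8L), epochs = 40L, seed = 7)
    } else modelSpec(fam, seed = 7)
    pred <- fitPredict(spec, d$X, d$y, d$X)
    expect_gte(mean(pred$labels == d$y), 0.9)
    expect_equal(unname(rowSums(pred$scores)), rep(1, nrow(d$X)),
                 tolerance = 1e-6)
    pred2 <- fitPredict(spec, d$X, d$y, d$X)
    expect_identical(pred$labels, pred2$labels)
  }
  expect_error(modelSpec("knn", neighbours = 3), "unknown hyperparameter")
})

test_that("1-nearest-neighbour memorises its training set", {
  d <- easyClassData(n = 40, p = 4, sep = 2, seed = 3)
  pred <- fitPredict(modelSpec("knn", k = 1L), d$X, d$y, d$X)
  expect_identical(pred$labels, d$y)
})

test_that("evaluation metrics match hand computation and the 0 convention", {
  perfect <- evaluateClassifier(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect@accuracy, 1)
  expect_true(all(perfect@perClass$f1 == 1))

  # confusion [[3,1],[2,4]]: true a: 3 a's, 1 b; true b: 2 a's, 4 b's
  yT <- rep(c("a", "b"), c(4, 6))
  yP <- c("a", "a", "a", "b", "a", "a", "b", "b", "b", "b")
  ev <- evaluateClassifier(yT, yP)
  expect_equal(ev@perClass$precision, c(3 / 5, 4 / 5))
  expect_equal(ev@perClass$recall, c(3 / 4, 4 / 6))
  expect_equal(ev@perClass$f1,
               c(2 * 0.6 * 0.75 / 1.35, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3)))
  expect_equal(unname(rowSums(ev@confusion)), c(4, 6))

  # class never predicted: precision 0, F1 0
  ev2 <- evaluateClassifier(c("a", "a", "b"), c("a", "a", "a"))
  expect_equal(ev2@perClass$precision[ev2@perClass$class == "b"], 0)
  expect_equal(ev2@perClass$f1[ev2@perClass$class == "b"], 0)
})

test_that("macro AUROC of random scores on balanced two-class data is ~0.5", {
  aucs <- vapply(1:30, function(s) {
    set.seed(s)
    y <- rep(c("a", "b"), each = 30)
    sc <- matrix(runif(120), 60, 2, dimnames = list(NULL, c("a", "b")))
    evaluateClassifier(y, ifelse(sc[, 1] > sc[, 2], "a", "b"), sc)@macroAuroc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("cross-validation folds are stratified, disjoint and seeded", {
  d <- easyClassData(n = 25, p = 4, classes = c("a", "b", "c", "d", "e"),
                     seed = 4)
  cv <- crossValidate(modelSpec("knn", k = 3L), d$X, d$y, nFolds = 5,
                      seed = 6)
  expect_equal(as.vector(table(cv$folds)), rep(5L, 5))
  for (f in 1:5) {
    expect_equal(as.vector(table(d$y[cv$folds == f])), rep(1L, 5))
  }
  cv2 <- crossValidate(modelSpec("knn", k = 3L), d$X, d$y, nFolds = 5,
                       seed = 6)
  expect_identical(cv$folds, cv2$folds)
})

test_that("scaling statistics come from the training partition only", {
  d <- easyClassData(n = 60, p = 5, seed = 8)
  testX <- d$X[41:60, ]
  before <- testX + 0
  m <- fitModel(modelSpec("logistic_ovr"), d$X[1:40, ], d$y[1:40])
  predictModel(m, testX)
  expect_identical(testX, before)
  expect_equal(unname(m$scaler$mu), unname(colMeans(d$X[1:40, ])))
})
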