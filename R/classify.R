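## Stratified splitting, adaptive minority oversampling, the four model
## families and the evaluation metrics (per-class precision/recall/F1,
## accuracy, macro one-vs-rest AUROC).
##
## All fitting is done on matrices with samples in rows and features in
## columns. Features are standardised with training-set statistics only;
## test rows are never touched before prediction.

.MODELS <- c("logistic_ovr", "knn", "random_forest", "feedforward_net")

#' Specify a classification model and its hyperparameters
#'
#' Only documented hyperparameter keys are accepted per family:
#' \describe{
#'   \item{logistic_ovr}{\code{lambda} ridge penalty of each one-vs-rest
#'     logistic fit (default 1e-3).}
#'   \item{knn}{\code{k} number of neighbours (default 4).}
#'   \item{random_forest}{\code{ntree} (default 500).}
#'   \item{feedforward_net}{\code{hiddenSizes} (default c(256, 128, 64),
#'     three ReLU hidden layers, softmax output), \code{epochs} (default
#'     80), \code{batchSize} (default 16), \code{learningRate} (default
#'     1e-3, adaptive-moment updates), trained with the multiclass
#'     cross-entropy loss on integer-coded labels.}
#' }
#'
#' @param model one of \code{"logistic_ovr"}, \code{"knn"},
#'   \code{"random_forest"}, \code{"feedforward_net"}.
#' @param ... hyperparameter overrides (documented keys only).
#' @param seed integer seed used wherever the family is stochastic.
#' @return a \code{ModelSpec} list.
#' @export
modelSpec <- function(model = .MODELS, ..., seed = 1L) {
  model <- match.arg(model)
  defaults <- switch(model,
    logistic_ovr = list(lambda = 1e-3),
    knn = list(k = 4L),
    random_forest = list(ntree = 500L),
    feedforward_net = list(hiddenSizes = c(256L, 128L, 64L), epochs = 80L,
                           batchSize = 16L, learningRate = 1e-3)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", model,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(model = model, hyper = defaults, seed = as.integer(seed)),
            class = "ModelSpec")
}

#' Stratified train/test split
#'
#' Per-class sampling so that each class's test count equals
#' round(class size * testFraction) (always within 1 of the exact
#' proportion). Deterministic given the seed.
#'
#' @param labels label data.frame (\code{sample_id}, \code{class_label}).
#' @param testFraction fraction of each class assigned to the test set,
#'   default 0.2.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} sample id vectors.
#' @export
stratifiedSplit <- function(labels, testFraction = 0.2, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1)
  sizes <- table(labels$class_label)
  if (any(sizes < 2L)) {
    stop(sprintf("class '%s' has fewer than 2 samples",
                 names(sizes)[sizes < 2L][1]), call. = FALSE)
  }
  test <- character()
  set.seed(seed)
  for (cl in sort(names(sizes))) {
    ids <- labels$sample_id[labels$class_label == cl]
    nTest <- max(1L, min(length(ids) - 1L,
                         as.integer(round(length(ids) * testFraction))))
    test <- c(test, sample(ids, nTest))
  }
  list(train = setdiff(labels$sample_id, test), test = test)
}

# k nearest neighbours of each row of x among rows of pool (excluding an
# identical index when self = TRUE); returns an index matrix.
.knnIndex <- function(x, pool, k, self = FALSE) {
  d2 <- outer(rowSums(x^2), rowSums(pool^2), "+") - 2 * tcrossprod(x, pool)
  idx <- vapply(seq_len(nrow(x)), function(i) {
    di <- d2[i, ]
    if (self) di[i] <- Inf
    order(di)[seq_len(k)]
  }, integer(k))
  matrix(idx, nrow = nrow(x), ncol = k, byrow = TRUE)
}

#' Adaptive synthetic oversampling of minority classes
#'
#' Brings every minority class up to the majority class size by adding
#' synthetic rows that are convex combinations of same-class neighbour
#' pairs. Generation is density-weighted: minority points whose
#' k-nearest-neighbour sets (over all classes) contain many other-class
#' points spawn more synthetic neighbours, focusing augmentation near class
#' boundaries. Original rows are preserved unchanged. Apply to the training
#' partition only.
#'
#' @param X samples-by-features numeric matrix.
#' @param y class labels (one per row of X).
#' @param seed integer seed; output is deterministic given it.
#' @param k neighbour count of the density estimate (default 5). A minority
#'   class with fewer than k + 1 members falls back to plain duplication
#'   with a warning.
#' @return list with \code{X}, \code{y} (originals first, synthetic rows
#'   appended) and \code{synthetic} (logical marker per row).
#' @export
augmentMinority <- function(X, y, seed = 1L, k = 5L) {
  stopifnot(nrow(X) == length(y))
  y <- as.character(y)
  sizes <- table(y)
  if (length(sizes) < 2L) stop("need at least two classes", call. = FALSE)
  nMaj <- max(sizes)
  set.seed(seed)
  newX <- list(); newY <- character()
  for (cl in sort(names(sizes))) {
    need <- nMaj - sizes[[cl]]
    if (need == 0L) next
    idx <- which(y == cl)
    nc <- length(idx)
    if (nc < k + 1L) {
      warning(sprintf(
        "class '%s' has %d members (< k + 1 = %d); duplicating instead of interpolating",
        cl, nc, k + 1L))
      pick <- idx[(seq_len(need) - 1L) %% nc + 1L]
      newX[[cl]] <- X[pick, , drop = FALSE]
      newY <- c(newY, rep(cl, need))
      next
    }
    nnAll <- .knnIndex(X[idx, , drop = FALSE], X, k, self = FALSE)
    # exclude the point itself if it appears among its own neighbours
    r <- vapply(seq_len(nc), function(i) {
      nb <- nnAll[i, ]
      nb <- nb[nb != idx[i]]
      mean(y[nb] != cl)
    }, 0)
    w <- if (sum(r) == 0) rep(1 / nc, nc) else r / sum(r)
    g <- floor(w * need)
    rem <- need - sum(g)
    if (rem > 0L) {
      extra <- order(w * need - g, decreasing = TRUE)[seq_len(rem)]
      g[extra] <- g[extra] + 1L
    }
    nnSame <- .knnIndex(X[idx, , drop = FALSE], X[idx, , drop = FALSE],
                        min(k, nc - 1L), self = TRUE)
    rows <- matrix(0, need, ncol(X))
    pos <- 1L
    for (i in seq_len(nc)) {
      if (g[i] == 0L) next
      for (j in seq_len(g[i])) {
        z <- nnSame[i, sample.int(ncol(nnSame), 1L)]
        lam <- stats::runif(1)
        rows[pos, ] <- X[idx[i], ] + lam * (X[idx[z], ] - X[idx[i], ])
        pos <- pos + 1L
      }
    }
    colnames(rows) <- colnames(X)
    newX[[cl]] <- rows
    newY <- c(newY, rep(cl, need))
  }
  if (length(newX)) {
    Xout <- rbind(X, do.call(rbind, newX))
    rownames(Xout) <- NULL
    list(X = Xout, y = c(y, newY),
         synthetic = c(rep(FALSE, length(y)), rep(TRUE, length(newY))))
  } else {
    list(X = X, y = y, synthetic = rep(FALSE, length(y)))
  }
}

#' Concatenate sample-aligned omics matrices into one feature matrix
#'
#' The baseline integration: features of all layers stacked side by side,
#' ids prefixed with the omics kind, samples in rows in their (shared)
#' order.
#'
#' @param ms list of sample-aligned \linkS4class{OmicsMatrix} objects.
#' @return samples-by-features numeric matrix.
#' @export
concatenateFeatures <- function(ms) {
  stopifnot(length(ms) >= 1L)
  sids <- sampleIds(ms[[1]])
  blocks <- lapply(ms, function(m) {
    if (!identical(sampleIds(m), sids)) {
      stop("matrices are not sample-aligned", call. = FALSE)
    }
    b <- t(omicsValues(m))
    colnames(b) <- paste(omicsKind(m), colnames(b), sep = ":")
    b
  })
  do.call(cbind, blocks)
}

.scaleFit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

.scaleApply <- function(X, sc) sweep(sweep(X, 2L, sc$mu, "-"), 2L, sc$sd, "/")

#' Fit a classification model
#'
#' Standardises features with training statistics (kept inside the returned
#' object and re-applied at prediction time) and fits the requested family.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param X training samples-by-features matrix.
#' @param y training labels.
#' @return a \code{GainModel} object usable with \code{\link{predictModel}}.
#' @export
fitModel <- function(spec, X, y) {
  stopifnot(inherits(spec, "ModelSpec"), nrow(X) == length(y))
  y <- as.character(y)
  classes <- sort(unique(y))
  sc <- .scaleFit(X)
  Xs <- .scaleApply(X, sc)
  h <- spec$hyper
  fit <- switch(spec$model,
    logistic_ovr = lapply(stats::setNames(classes, classes), function(cl) {
      glmnet::glmnet(Xs, as.integer(y == cl), family = "binomial",
                     alpha = 0, lambda = h$lambda, standardize = FALSE)
    }),
    knn = list(X = Xs, y = y, k = h$k),
    random_forest = {
      set.seed(spec$seed)
      randomForest::randomForest(Xs, factor(y, levels = classes),
                                 ntree = h$ntree)
    },
    feedforward_net = .mlpFit(Xs, match(y, classes), length(classes),
                              h$hiddenSizes, h$epochs, h$batchSize,
                              h$learningRate, spec$seed)
  )
  structure(list(spec = spec, scaler = sc, classes = classes, fit = fit),
            class = "GainModel")
}

#' Predict labels and class scores from a fitted model
#'
#' @param model a \code{GainModel} from \code{\link{fitModel}}.
#' @param X samples-by-features matrix.
#' @return list with \code{labels} (character) and \code{scores}
#'   (samples-by-classes matrix; rows sum to 1 for probabilistic families).
#' @export
predictModel <- function(model, X) {
  stopifnot(inherits(model, "GainModel"))
  Xs <- .scaleApply(X, model$scaler)
  classes <- model$classes
  scores <- switch(model$spec$model,
    logistic_ovr = {
      s <- vapply(classes, function(cl) {
        as.numeric(stats::predict(model$fit[[cl]], Xs, type = "response"))
      }, numeric(nrow(Xs)))
      s <- matrix(s, nrow(Xs), length(classes),
                  dimnames = list(NULL, classes))
      s / rowSums(s)
    },
    knn = .knnScores(model$fit, Xs, classes),
    random_forest = {
      p <- stats::predict(model$fit, Xs, type = "prob")
      p[, classes, drop = FALSE]
    },
    feedforward_net = {
      p <- .mlpPredict(model$fit, Xs)
      colnames(p) <- classes
      p
    }
  )
  labels <- classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}

#' Fit on a training set and predict a test set
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param trainX,trainY training data.
#' @param testX test features.
#' @return as \code{\link{predictModel}}.
#' @export
fitPredict <- function(spec, trainX, trainY, testX) {
  predictModel(fitModel(spec, trainX, trainY), testX)
}

# Vote-fraction kNN scores with deterministic distance/index tie-breaking.
.knnScores <- function(fit, Xs, classes) {
  k <- min(fit$k, nrow(fit$X))
  nn <- .knnIndex(Xs, fit$X, k, self = FALSE)
  s <- matrix(0, nrow(Xs), length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xs))) {
    v <- table(factor(fit$y[nn[i, ]], levels = classes))
    s[i, ] <- as.numeric(v) / k
  }
  s
}

#' Evaluate multiclass predictions
#'
#' Per-class precision, recall and F1 use the 0 convention for empty
#' denominators (a class never predicted gets precision and F1 of 0).
#' Per-class AUROC is one-vs-rest on the class's score column; the overall
#' AUROC is their unweighted mean (classes absent from the truth are
#' skipped).
#'
#' @param yTrue,yPred label vectors.
#' @param scores optional samples-by-classes score matrix (for AUROC).
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateClassifier <- function(yTrue, yPred, scores = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  classes <- sort(unique(c(yTrue, yPred,
                           if (!is.null(scores)) colnames(scores))))
  cm <- table(factor(yTrue, classes), factor(yPred, classes))
  prec <- rec <- f1 <- auc <- rep(NA_real_, length(classes))
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    predP <- sum(cm[, i]); trueP <- sum(cm[i, ])
    prec[i] <- if (predP == 0) 0 else tp / predP
    rec[i] <- if (trueP == 0) 0 else tp / trueP
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    if (!is.null(scores) && classes[i] %in% colnames(scores)) {
      isPos <- yTrue == classes[i]
      if (any(isPos) && any(!isPos)) {
        r <- pROC::roc(response = isPos, predictor = scores[, classes[i]],
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
        auc[i] <- as.numeric(pROC::auc(r))
      }
    }
  }
  perClass <- data.frame(class = classes, precision = prec, recall = rec,
                         f1 = f1, auroc = auc,
                         support = as.integer(rowSums(cm)),
                         stringsAsFactors = FALSE)
  new("EvalReport", perClass = perClass,
      accuracy = mean(yTrue == yPred),
      macroAuroc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE),
      confusion = unclass(as.matrix(cm)))
}

#' Macro F1 of an EvalReport
#' @param report an \linkS4class{EvalReport}.
#' @return unweighted mean of per-class F1 scores.
#' @export
macroF1 <- function(report) mean(report@perClass$f1)

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and disjoint, their union is the full
#' sample set, and fold membership is deterministic given the seed. When
#' \code{augment} is TRUE, minority oversampling is applied inside each
#' training fold only.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param X samples-by-features matrix.
#' @param y labels.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed.
#' @param augment apply \code{\link{augmentMinority}} to each training fold.
#' @return list with \code{reports} (one \linkS4class{EvalReport} per fold)
#'   and \code{folds} (fold index per sample).
#' @export
crossValidate <- function(spec, X, y, nFolds = 5L, seed = 1L,
                          augment = FALSE) {
  y <- as.character(y)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  reports <- lapply(seq_len(nFolds), function(f) {
    tr <- fold != f
    trX <- X[tr, , drop = FALSE]; trY <- y[tr]
    if (augment) {
      aug <- augmentMinority(trX, trY, seed = seed + f)
      trX <- aug$X; trY <- aug$y
    }
    pred <- fitPredict(spec, trX, trY, X[!tr, , drop = FALSE])
    evaluateClassifier(y[!tr], pred$labels, pred$scores)
  })
  list(reports = reports, folds = fold)
}

## ---- minimal feed-forward network (ReLU hidden layers, softmax output,
## adaptive-moment updates, multiclass cross-entropy) ----

.mlpFit <- function(X, yInt, nClasses, hiddenSizes, epochs, batchSize,
                    lr, seed) {
  set.seed(seed)
  sizes <- c(ncol(X), hiddenSizes, nClasses)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l) {
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1])
  })
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X); step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1, n)]
      xb <- X[idx, , drop = FALSE]
      # forward
      acts <- vector("list", L + 1); acts[[1]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2L, b[[l]], "+")
        acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      logits <- acts[[L + 1]]
      mx <- apply(logits, 1L, max)
      p <- exp(logits - mx)
      p <- p / rowSums(p)
      # backward: dL/dlogits for cross-entropy with softmax
      grad <- p
      grad[cbind(seq_along(idx), yInt[idx])] <-
        grad[cbind(seq_along(idx), yInt[idx])] - 1
      grad <- grad / length(idx)
      step <- step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], grad)
        gb <- colSums(grad)
        if (l > 1) {
          grad <- (grad %*% t(W[[l]])) * (acts[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  list(W = W, b = b)
}

.mlpPredict <- function(fit, X) {
  L <- length(fit$W)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  mx <- apply(a, 1L, max)
  p <- exp(a - mx)
  p / rowSums(p)
}
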