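## Feature-importance ranking on the transformed matrix and the annotation
## filter cascade (deleteriousness windows + haploinsufficiency) with
## subtype-unique set logic.

#' Fit a gradient-boosted tree ensemble for importance analysis
#'
#' Multiclass boosted trees whose exact per-feature Shapley contributions
#' can be extracted directly (tree-path attribution), used as the
#' importance backend for the transformed feature matrix.
#'
#' @param X samples-by-features matrix.
#' @param y class labels.
#' @param nrounds boosting rounds (default 50).
#' @param maxDepth tree depth (default 4).
#' @param seed integer seed.
#' @return list of class \code{TreeEnsemble} with the booster and the class
#'   level order.
#' @export
fitTreeEnsemble <- function(X, y, nrounds = 50L, maxDepth = 4L, seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  d <- xgboost::xgb.DMatrix(as.matrix(X), label = match(y, classes) - 1L,
                            nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = maxDepth, eta = 0.3, nthread = 1, seed = seed),
    data = d, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, classes = classes,
                 featureNames = colnames(X)),
            class = "TreeEnsemble")
}

#' Rank features by importance
#'
#' Backend \code{"shapley_tree"} requires a tree ensemble from
#' \code{\link{fitTreeEnsemble}} and scores each feature by the mean
#' absolute Shapley contribution over samples, globally (mean over classes)
#' and per class. Backend \code{"permutation"} works with any fitted
#' \code{GainModel}: each feature column is permuted (seeded,
#' \code{nRepeats} times) and the mean drop in accuracy on \code{(X, y)} is
#' the importance.
#'
#' @param model a \code{TreeEnsemble} (shapley_tree) or \code{GainModel}
#'   (permutation).
#' @param X samples-by-features matrix (training partition).
#' @param y labels for \code{X}.
#' @param backend \code{"shapley_tree"} or \code{"permutation"}.
#' @param topK number of features to return (full ranking if larger than
#'   the feature count).
#' @param nRepeats permutation repeats (permutation backend only).
#' @param seed integer seed (permutation backend only).
#' @return data.frame sorted by decreasing importance with columns
#'   \code{feature}, \code{importance}, per-class columns for the Shapley
#'   backend, and a \code{backend} attribute.
#' @export
rankFeatures <- function(model, X, y,
                         backend = c("shapley_tree", "permutation"),
                         topK = Inf, nRepeats = 5L, seed = 1L) {
  backend <- match.arg(backend)
  X <- as.matrix(X)
  if (backend == "shapley_tree") {
    if (!inherits(model, "TreeEnsemble")) {
      stop("backend 'shapley_tree' needs a tree ensemble from ",
           "fitTreeEnsemble()", call. = FALSE)
    }
    contrib <- stats::predict(model$booster,
                              xgboost::xgb.DMatrix(X, nthread = 1),
                              predcontrib = TRUE)
    # n x classes x (features + bias); drop the bias column
    contrib <- contrib[, , -dim(contrib)[3], drop = FALSE]
    perClass <- apply(abs(contrib), c(3, 2), mean)
    colnames(perClass) <- paste0("importance_", model$classes)
    imp <- rowMeans(perClass)
    out <- data.frame(feature = colnames(X), importance = imp, perClass,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    if (!inherits(model, "GainModel")) {
      stop("backend 'permutation' needs a fitted GainModel", call. = FALSE)
    }
    y <- as.character(y)
    base <- mean(predictModel(model, X)$labels == y)
    set.seed(seed)
    imp <- vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(nRepeats), function(r) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        base - mean(predictModel(model, Xp)$labels == y)
      }, 0)
      mean(drops)
    }, 0)
    out <- data.frame(feature = colnames(X), importance = imp,
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (is.finite(topK)) out <- utils::head(out, topK)
  attr(out, "backend") <- backend
  out
}

#' Per-class top-k gene lists from a Shapley ranking
#'
#' Each class's list is the k features with the largest per-class mean
#' absolute Shapley contribution.
#'
#' @param ranking output of \code{\link{rankFeatures}} with per-class
#'   columns.
#' @param k list length per class.
#' @return named list of character vectors, one per class.
#' @export
topGenesPerClass <- function(ranking, k = 25L) {
  cols <- grep("^importance_", names(ranking), value = TRUE)
  if (!length(cols)) {
    stop("ranking has no per-class importance columns", call. = FALSE)
  }
  out <- lapply(cols, function(cc) {
    ranking$feature[order(-ranking[[cc]], ranking$feature)][
      seq_len(min(k, nrow(ranking)))]
  })
  names(out) <- sub("^importance_", "", cols)
  out
}

#' Filter genes by deleteriousness and haploinsufficiency annotation
#'
#' A gene passes iff (its SIFT score is present and inside
#' \code{siftWindow}, boundaries inclusive) OR (its PolyPhen score is
#' present and inside \code{polyphenWindow}) -- AND its haploinsufficiency
#' score is present and strictly positive. With \code{conjunctive = TRUE}
#' the OR becomes an AND. Genes with no scores at all are dropped and
#' counted separately.
#'
#' @param genes character vector of candidate gene ids.
#' @param ann annotation table (see \code{\link{readAnnotationTable}}).
#' @param siftWindow inclusive SIFT window, default c(0, 0.05)
#'   (deleterious).
#' @param polyphenWindow inclusive PolyPhen window, default c(0.85, 1)
#'   (probably damaging).
#' @param conjunctive require both windows instead of either.
#' @return list with \code{kept} (gene ids, input order preserved),
#'   \code{droppedNoScores} (genes absent from the table or with all scores
#'   missing), and \code{droppedByRule}.
#' @export
filterByAnnotation <- function(genes, ann, siftWindow = c(0, 0.05),
                               polyphenWindow = c(0.85, 1),
                               conjunctive = FALSE) {
  idx <- match(genes, ann$gene_id)
  sift <- ann$sift[idx]; poly <- ann$polyphen[idx]
  hi <- ann$haploinsufficiency[idx]
  noScores <- is.na(idx) | (is.na(sift) & is.na(poly) & is.na(hi))
  inSift <- !is.na(sift) & sift >= siftWindow[1] & sift <= siftWindow[2]
  inPoly <- !is.na(poly) & poly >= polyphenWindow[1] &
    poly <= polyphenWindow[2]
  damaging <- if (conjunctive) inSift & inPoly else inSift | inPoly
  pass <- !noScores & damaging & !is.na(hi) & hi > 0
  list(kept = genes[pass],
       droppedNoScores = genes[noScores],
       droppedByRule = genes[!pass & !noScores])
}

#' Subtype-unique and shared gene sets
#'
#' Exact set algebra over per-class gene lists: for each class the genes
#' found in that class and no other, plus every pairwise intersection and
#' the intersection across all classes.
#'
#' @param perClass named list of character vectors (one per class).
#' @return list with \code{unique} (named list), \code{sharedAll}
#'   (intersection of all lists), \code{pairwise} (named list of pairwise
#'   intersections, names "A&B"), \code{union}, and \code{multiClass}
#'   (genes in two or more lists).
#' @export
subtypeUniqueSets <- function(perClass) {
  stopifnot(length(perClass) >= 2L, !is.null(names(perClass)))
  perClass <- lapply(perClass, unique)
  allGenes <- unique(unlist(perClass))
  member <- vapply(perClass, function(g) allGenes %in% g,
                   logical(length(allGenes)))
  nClasses <- rowSums(member)
  uniq <- lapply(seq_along(perClass), function(i) {
    allGenes[member[, i] & nClasses == 1L]
  })
  names(uniq) <- names(perClass)
  prs <- utils::combn(names(perClass), 2, simplify = FALSE)
  pairwise <- lapply(prs, function(p) {
    intersect(perClass[[p[1]]], perClass[[p[2]]])
  })
  names(pairwise) <- vapply(prs, paste, "", collapse = "&")
  list(unique = uniq,
       sharedAll = Reduce(intersect, perClass),
       pairwise = pairwise,
       union = allGenes,
       multiClass = allGenes[nClasses >= 2L])
}
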