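## Missingness filtering, cross-omics sample intersection, count
## normalisation and methylation imputation.
##
## A cell is "bad" when it is zero OR missing; a feature (or sample) is
## removed when its bad fraction strictly exceeds the threshold, so a
## feature sitting exactly on the 20% boundary survives. Zeros count toward
## the bad fraction for every omics kind, including methylation.

.badFraction <- function(v) {
  (sum(is.na(v)) + sum(v == 0, na.rm = TRUE)) / length(v)
}

#' Remove features with too many zero or missing entries
#'
#' A feature is removed iff (number of entries that are zero or missing) /
#' (number of samples) is strictly greater than \code{maxBadFraction}.
#' Surviving features keep their original order.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param maxBadFraction threshold in [0, 1); default 0.2.
#' @return list with \code{matrix} (filtered \linkS4class{OmicsMatrix}) and
#'   \code{removed} (character vector of removed feature ids).
#' @export
filterFeatures <- function(m, maxBadFraction = 0.2) {
  stopifnot(maxBadFraction >= 0, maxBadFraction < 1)
  v <- omicsValues(m)
  bad <- apply(v, 1L, .badFraction)
  drop <- bad > maxBadFraction
  if (all(drop)) {
    stop("all features removed by the bad-fraction filter", call. = FALSE)
  }
  list(matrix = OmicsMatrix(v[!drop, , drop = FALSE], omicsKind(m)),
       removed = rownames(v)[drop])
}

#' Remove samples with too many zero or missing entries
#'
#' Column-wise analogue of \code{\link{filterFeatures}}.
#'
#' @inheritParams filterFeatures
#' @return list with \code{matrix} and \code{removed} (sample ids).
#' @export
filterSamples <- function(m, maxBadFraction = 0.2) {
  stopifnot(maxBadFraction >= 0, maxBadFraction < 1)
  v <- omicsValues(m)
  bad <- apply(v, 2L, .badFraction)
  drop <- bad > maxBadFraction
  if (all(drop)) {
    stop("all samples removed by the bad-fraction filter", call. = FALSE)
  }
  list(matrix = OmicsMatrix(v[, !drop, drop = FALSE], omicsKind(m)),
       removed = colnames(v)[drop])
}

#' Restrict several omics matrices to their common samples
#'
#' Keeps only samples present in every matrix, ordered by their appearance
#' in the first matrix, and returns all matrices with that identical sample
#' order.
#'
#' @param ms list of \linkS4class{OmicsMatrix} objects.
#' @return list of \linkS4class{OmicsMatrix} objects sharing an identical
#'   ordered sample id vector.
#' @export
intersectSamples <- function(ms) {
  stopifnot(length(ms) >= 1L)
  common <- Reduce(intersect, lapply(ms, sampleIds))
  if (length(common) == 0L) {
    stop("no samples are shared by all omics matrices", call. = FALSE)
  }
  common <- sampleIds(ms[[1]])[sampleIds(ms[[1]]) %in% common]
  lapply(ms, function(m) {
    OmicsMatrix(omicsValues(m)[, common, drop = FALSE], omicsKind(m))
  })
}

#' Median-of-ratios size-factor normalisation for count matrices
#'
#' Per-feature geometric means are computed over samples using only features
#' with all-positive counts as the reference; each sample's size factor is
#' the median over those features of count / geometric mean, and normalised
#' values are counts divided by the sample's size factor.
#'
#' @param m an \linkS4class{OmicsMatrix} of kind \code{mrna_counts} or
#'   \code{mirna_counts}, without missing values.
#' @return list with \code{matrix} (normalised \linkS4class{OmicsMatrix})
#'   and \code{sizeFactors} (named numeric vector).
#' @export
sizeFactorNormalize <- function(m) {
  if (!omicsKind(m) %in% c("mrna_counts", "mirna_counts")) {
    stop("size-factor normalisation applies to count matrices only",
         call. = FALSE)
  }
  v <- omicsValues(m)
  if (anyNA(v)) {
    stop("count matrix contains missing values; filter or impute first",
         call. = FALSE)
  }
  ref <- rowSums(v > 0) == ncol(v)
  if (!any(ref)) {
    stop(paste("no feature has all-positive counts; cannot form the",
               "median-of-ratios reference (consider adding a pseudocount)"),
         call. = FALSE)
  }
  logGeo <- rowMeans(log(v[ref, , drop = FALSE]))
  sf <- apply(log(v[ref, , drop = FALSE]) - logGeo, 2L,
              stats::median)
  sf <- exp(sf)
  out <- sweep(v, 2L, sf, "/")
  list(matrix = OmicsMatrix(out, omicsKind(m)),
       sizeFactors = stats::setNames(sf, colnames(v)))
}

#' Impute missing methylation beta values and clamp to a positive floor
#'
#' Missing entries are replaced by the feature's median over its non-missing
#' values; all values are then clamped into [\code{betaFloor}, 1]. The floor
#' keeps the downstream methylation factor finite (it diverges as beta
#' approaches 0).
#'
#' @param m an \linkS4class{OmicsMatrix} of kind \code{methylation_beta}.
#' @param betaFloor lower clamp, default 1e-3.
#' @return an \linkS4class{OmicsMatrix} with no missing entries and all
#'   values in [betaFloor, 1].
#' @export
imputeAndClampBeta <- function(m, betaFloor = 1e-3) {
  if (omicsKind(m) != "methylation_beta") {
    stop("imputeAndClampBeta applies to methylation matrices only",
         call. = FALSE)
  }
  stopifnot(betaFloor > 0, betaFloor < 1)
  v <- omicsValues(m)
  allMiss <- rowSums(!is.na(v)) == 0L
  if (any(allMiss)) {
    stop(sprintf(
      "feature '%s' has no non-missing beta values; filter it out first",
      rownames(v)[allMiss][1]), call. = FALSE)
  }
  if (anyNA(v)) {
    med <- apply(v, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 1L]]
  }
  v <- pmin(pmax(v, betaFloor), 1)
  OmicsMatrix(v, "methylation_beta")
}

#' Restrict a promoter map to a TSS distance window
#'
#' Keeps CpG-gene rows with 0 <= tss_distance_bp <= \code{maxDistanceBp},
#' both boundaries inclusive.
#'
#' @param p promoter map data.frame (see \code{\link{readPromoterMap}}).
#' @param maxDistanceBp window upper end in bp, default 1500.
#' @return the restricted promoter map.
#' @export
restrictPromoterMap <- function(p, maxDistanceBp = 1500) {
  stopifnot(maxDistanceBp >= 0)
  p[p$tss_distance_bp >= 0 & p$tss_distance_bp <= maxDistanceBp, ,
    drop = FALSE]
}

#' Run the full per-omic preprocessing cascade
#'
#' Applies, in this fixed order: feature filtering, sample filtering,
#' cross-omic sample intersection, size-factor normalisation of the two
#' count matrices, and methylation imputation/clamping. The order is fixed
#' because results depend on it.
#'
#' @param mrna,mirna,meth the three \linkS4class{OmicsMatrix} inputs.
#' @param maxBadFraction zero/missing threshold, default 0.2.
#' @param betaFloor methylation clamp floor, default 1e-3.
#' @return list with elements \code{mrna}, \code{mirna}, \code{meth}
#'   (processed matrices), \code{sizeFactors} (list for the two count
#'   layers), and \code{report} (a FilterReport list: per-omic removed
#'   feature/sample ids, retained sample ids, before/after counts).
#' @export
preprocessOmics <- function(mrna, mirna, meth, maxBadFraction = 0.2,
                            betaFloor = 1e-3) {
  ms <- list(mrna = mrna, mirna = mirna, meth = meth)
  featRemoved <- sampRemoved <- list()
  before <- lapply(ms, function(m) dim(omicsValues(m)))
  for (nm in names(ms)) {
    ff <- filterFeatures(ms[[nm]], maxBadFraction)
    fs <- filterSamples(ff$matrix, maxBadFraction)
    featRemoved[[nm]] <- ff$removed
    sampRemoved[[nm]] <- fs$removed
    ms[[nm]] <- fs$matrix
  }
  ms <- intersectSamples(ms)
  names(ms) <- c("mrna", "mirna", "meth")
  sfs <- list()
  for (nm in c("mrna", "mirna")) {
    sf <- sizeFactorNormalize(ms[[nm]])
    ms[[nm]] <- sf$matrix
    sfs[[nm]] <- sf$sizeFactors
  }
  ms$meth <- imputeAndClampBeta(ms$meth, betaFloor)
  after <- lapply(ms, function(m) dim(omicsValues(m)))
  report <- list(
    features_removed = featRemoved,
    samples_removed = sampRemoved,
    samples_retained = sampleIds(ms$mrna),
    counts_before = before,
    counts_after = after
  )
  list(mrna = ms$mrna, mirna = ms$mirna, meth = ms$meth,
       sizeFactors = sfs, report = report)
}
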