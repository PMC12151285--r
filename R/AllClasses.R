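#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors SimpleList metadata metadata<-
NULL

.OMICS_KINDS <- c("mrna_counts", "mirna_counts", "methylation_beta")

#' OmicsMatrix: a features-by-samples omics data matrix
#'
#' Thin extension of \linkS4class{SummarizedExperiment} carrying a single
#' numeric assay (features in rows, samples in columns) plus a tag saying
#' which omics layer the values belong to. The tag drives validity checks:
#' methylation beta values must lie in [0, 1]; count matrices must be
#' non-negative. Missing entries are represented as \code{NA}.
#'
#' @slot kind one of \code{"mrna_counts"}, \code{"mirna_counts"},
#'   \code{"methylation_beta"}.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(kind = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .OMICS_KINDS) {
    msg <- c(msg, sprintf(
      "kind must be one of: %s", paste(.OMICS_KINDS, collapse = ", ")
    ))
  }
  if (length(assays(object)) != 1L) {
    msg <- c(msg, "OmicsMatrix must carry exactly one assay")
  } else {
    v <- assay(object)
    if (!is.numeric(v)) msg <- c(msg, "assay values must be numeric")
    fid <- rownames(v)
    sid <- colnames(v)
    if (is.null(fid) || is.null(sid)) {
      msg <- c(msg, "assay must have feature (row) and sample (column) names")
    } else {
      if (anyDuplicated(fid)) {
        msg <- c(msg, "duplicate feature ids")
      }
      if (anyDuplicated(sid)) {
        msg <- c(msg, "duplicate sample ids")
      }
    }
    if (is.numeric(v) && length(object@kind) == 1L &&
        object@kind %in% .OMICS_KINDS) {
      bad <- .rangeViolations(v, object@kind)
      if (!is.null(bad)) msg <- c(msg, bad)
    }
  }
  if (length(msg)) msg else TRUE
})

# First offending cell named in the message so users can find it in the file.
.rangeViolations <- function(v, kind) {
  if (kind == "methylation_beta") {
    off <- which(!is.na(v) & (v < 0 | v > 1), arr.ind = TRUE)
    if (nrow(off)) {
      return(sprintf(
        "methylation beta value %g outside [0, 1] at feature '%s', sample '%s'",
        v[off[1, 1], off[1, 2]], rownames(v)[off[1, 1]], colnames(v)[off[1, 2]]
      ))
    }
  } else {
    off <- which(!is.na(v) & v < 0, arr.ind = TRUE)
    if (nrow(off)) {
      return(sprintf(
        "negative count %g at feature '%s', sample '%s'",
        v[off[1, 1], off[1, 2]], rownames(v)[off[1, 1]], colnames(v)[off[1, 2]]
      ))
    }
  }
  NULL
}

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). \code{NA} marks missing.
#' @param kind omics kind tag; one of \code{"mrna_counts"},
#'   \code{"mirna_counts"}, \code{"methylation_beta"}.
#' @return a validated \linkS4class{OmicsMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' OmicsMatrix(m, "mrna_counts")
#' @export
OmicsMatrix <- function(values, kind = c("mrna_counts", "mirna_counts",
                                         "methylation_beta")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = SimpleList(values = values))
  new("OmicsMatrix", se, kind = kind)
}

#' TransformConfig: free parameters of the graph transform
#'
#' Holds every tunable of the modulating-factor computation: the exponential
#' decay rates for the miRNA and methylation factors, the weight ratio used
#' when the two factors are averaged, the expression pseudocount entering the
#' log2, the floor applied to normalised interaction scores, and the policy
#' for genes lacking partners in one (or both) graphs.
#'
#' @slot alpha decay exponent for the miRNA factor (> 0, default 1.5).
#' @slot betaExp decay exponent for the methylation factor (> 0, default 1.5).
#' @slot w1,w2 non-negative weights of the miRNA and methylation factors in
#'   the combined factor; not both zero. Default 1:1.
#' @slot exprPseudocount added to miRNA expression before log2 (> 0,
#'   default 1).
#' @slot isFloor lower bound of the normalised interaction score, in (0, 1);
#'   default 0.01.
#' @slot missingPartnerPolicy \code{"fallback"} uses the available factor
#'   alone when a gene has partners in only one graph; \code{"neutral_one"}
#'   replaces the absent factor by 1 in the weighted mean. Genes with no
#'   partners at all always get a combined factor of 1.
#' @slot log2Mrna if TRUE, mRNA expression is log2(x + 1) transformed before
#'   the factor is applied.
#' @export
setClass("TransformConfig", slots = c(
  alpha = "numeric", betaExp = "numeric",
  w1 = "numeric", w2 = "numeric",
  exprPseudocount = "numeric", isFloor = "numeric",
  missingPartnerPolicy = "character", log2Mrna = "logical"
))

setValidity("TransformConfig", function(object) {
  msg <- character()
  if (!is.finite(object@alpha) || object@alpha <= 0) {
    msg <- c(msg, "alpha must be finite and > 0")
  }
  if (!is.finite(object@betaExp) || object@betaExp <= 0) {
    msg <- c(msg, "betaExp must be finite and > 0")
  }
  if (object@w1 < 0 || object@w2 < 0) msg <- c(msg, "weights must be >= 0")
  if (object@w1 + object@w2 <= 0) msg <- c(msg, "w1 + w2 must be > 0")
  if (object@exprPseudocount <= 0) msg <- c(msg, "exprPseudocount must be > 0")
  if (object@isFloor <= 0 || object@isFloor >= 1) {
    msg <- c(msg, "isFloor must lie in (0, 1)")
  }
  if (!object@missingPartnerPolicy %in% c("fallback", "neutral_one")) {
    msg <- c(msg, "missingPartnerPolicy must be 'fallback' or 'neutral_one'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TransformConfig
#'
#' @param alpha,betaExp decay exponents (defaults 1.5).
#' @param w1,w2 weights of the miRNA and methylation factors (defaults 1, 1).
#' @param exprPseudocount pseudocount added before log2 (default 1).
#' @param isFloor interaction-score floor (default 0.01).
#' @param missingPartnerPolicy "fallback" or "neutral_one".
#' @param log2Mrna log2(x+1)-transform mRNA before applying the factor.
#' @return a validated \linkS4class{TransformConfig}.
#' @export
TransformConfig <- function(alpha = 1.5, betaExp = 1.5, w1 = 1, w2 = 1,
                            exprPseudocount = 1, isFloor = 0.01,
                            missingPartnerPolicy = c("fallback", "neutral_one"),
                            log2Mrna = FALSE) {
  missingPartnerPolicy <- match.arg(missingPartnerPolicy)
  new("TransformConfig", alpha = alpha, betaExp = betaExp, w1 = w1, w2 = w2,
      exprPseudocount = exprPseudocount, isFloor = isFloor,
      missingPartnerPolicy = missingPartnerPolicy, log2Mrna = log2Mrna)
}

#' RegulatoryGraphs: the two weighted bipartite edge sets
#'
#' Per-gene adjacency of the two regulatory graphs after alignment with the
#' data matrices: for each gene, the interacting miRNAs with their normalised
#' interaction scores, and the promoter CpGs. Genes absent from an edge set
#' are simply missing from the corresponding list; the missing-partner policy
#' of \linkS4class{TransformConfig} decides how they are treated.
#'
#' @slot mirnaEdges named list (by gene id) of data.frames with columns
#'   \code{mirna_id}, \code{is}.
#' @slot cpgEdges named list (by gene id) of character vectors of CpG ids.
#' @slot edgeStats named numeric vector of bookkeeping counts (usable and
#'   dropped edges per graph).
#' @export
setClass("RegulatoryGraphs", slots = c(
  mirnaEdges = "list", cpgEdges = "list", edgeStats = "numeric"
))

#' DeltaResult: modulating factors and the transformed mRNA matrix
#'
#' @slot delta1,delta2 gene-by-sample matrices of the miRNA- and
#'   methylation-derived modulating factors (\code{NA} where a gene has no
#'   partners in that graph).
#' @slot delta combined gene-by-sample factor (never \code{NA}; 1 for genes
#'   with no partners).
#' @slot transformed gene-by-sample transformed mRNA matrix.
#' @slot config the \linkS4class{TransformConfig} used.
#' @export
setClass("DeltaResult", slots = c(
  delta1 = "matrix", delta2 = "matrix", delta = "matrix",
  transformed = "matrix", config = "TransformConfig"
))

setValidity("DeltaResult", function(object) {
  dims <- list(dim(object@delta1), dim(object@delta2), dim(object@delta),
               dim(object@transformed))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    return("delta1, delta2, delta and transformed must share dimensions")
  }
  if (anyNA(object@delta)) return("combined delta must have no NA entries")
  TRUE
})

#' EvalReport: multiclass classification metrics
#'
#' @slot perClass data.frame with one row per class: precision, recall, f1,
#'   auroc, support.
#' @slot accuracy overall accuracy.
#' @slot macroAuroc unweighted mean of the one-vs-rest per-class AUROCs.
#' @slot confusion confusion matrix (true classes in rows).
#' @export
setClass("EvalReport", slots = c(
  perClass = "data.frame", accuracy = "numeric",
  macroAuroc = "numeric", confusion = "matrix"
))
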