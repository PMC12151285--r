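#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("omicsKind", function(x) standardGeneric("omicsKind"))

#' @rdname OmicsMatrix-accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' Accessors for OmicsMatrix
#'
#' \code{featureIds} and \code{sampleIds} return the row and column ids,
#' \code{omicsKind} the omics layer tag, and \code{omicsValues} the plain
#' numeric matrix.
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @name OmicsMatrix-accessors
#' @aliases featureIds,OmicsMatrix-method sampleIds,OmicsMatrix-method
#'   omicsKind,OmicsMatrix-method omicsValues,OmicsMatrix-method
NULL

setMethod("featureIds", "OmicsMatrix", function(x) rownames(x))
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))
setMethod("omicsKind", "OmicsMatrix", function(x) x@kind)
setMethod("omicsValues", "OmicsMatrix", function(x) assay(x))

setMethod("show", "OmicsMatrix", function(object) {
  v <- assay(object)
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples (%d missing)\n",
              object@kind, nrow(v), ncol(v), sum(is.na(v))))
})

setMethod("show", "TransformConfig", function(object) {
  cat(sprintf(
    paste0("TransformConfig: alpha=%g betaExp=%g weights=%g:%g ",
           "pseudocount=%g isFloor=%g policy=%s log2Mrna=%s\n"),
    object@alpha, object@betaExp, object@w1, object@w2,
    object@exprPseudocount, object@isFloor, object@missingPartnerPolicy,
    object@log2Mrna
  ))
})

setMethod("show", "RegulatoryGraphs", function(object) {
  cat(sprintf(
    "RegulatoryGraphs: %d genes with miRNA partners, %d genes with CpG partners\n",
    length(object@mirnaEdges), length(object@cpgEdges)
  ))
  st <- object@edgeStats
  cat(sprintf("  usable edges: %d miRNA-gene, %d CpG-gene (dropped: %d, %d)\n",
              st[["mirna_edges"]], st[["cpg_edges"]],
              st[["mirna_dropped"]], st[["cpg_dropped"]]))
})

setMethod("show", "DeltaResult", function(object) {
  cat(sprintf("DeltaResult: %d genes x %d samples\n",
              nrow(object@delta), ncol(object@delta)))
  cat(sprintf("  genes with miRNA factor: %d, with CpG factor: %d\n",
              sum(rowSums(!is.na(object@delta1)) > 0),
              sum(rowSums(!is.na(object@delta2)) > 0)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f, macro one-vs-rest AUROC %.4f\n",
              object@accuracy, object@macroAuroc))
  pc <- object@perClass
  num <- vapply(pc, is.numeric, TRUE)
  pc[num] <- lapply(pc[num], round, 4)
  print(pc)
})

#' @rdname DeltaResult-accessors
#' @export
setGeneric("transformedMatrix", function(x) standardGeneric("transformedMatrix"))

#' @rdname DeltaResult-accessors
#' @export
setGeneric("deltaMatrix", function(x, which = "delta") {
  standardGeneric("deltaMatrix")
})

#' Accessors for DeltaResult
#'
#' @param x a \linkS4class{DeltaResult}.
#' @param which one of "delta", "delta1", "delta2".
#' @name DeltaResult-accessors
#' @aliases transformedMatrix,DeltaResult-method deltaMatrix,DeltaResult-method
NULL

setMethod("transformedMatrix", "DeltaResult", function(x) x@transformed)
setMethod("deltaMatrix", "DeltaResult", function(x, which = "delta") {
  switch(match.arg(which, c("delta", "delta1", "delta2")),
         delta = x@delta, delta1 = x@delta1, delta2 = x@delta2)
})
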