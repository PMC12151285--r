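## The method core: weighted bipartite regulatory graphs and the per-gene,
## per-sample modulating factors.
##
## For a gene g and sample s with n interacting miRNAs,
##   delta1[g,s] = (1/n) * sum_i 1 / (IS_i * exp(alpha * log2(e_i + pc)))
## where e_i is miRNA i's expression in sample s and IS_i its normalised
## interaction score. For m promoter CpGs with beta values b_i,
##   delta2[g,s] = (1/m) * sum_i 1 / exp(betaExp * log2(b_i)).
## The combined factor is the weighted mean (w1*delta1 + w2*delta2)/(w1+w2)
## and the transformed expression is delta * expr(mRNA).
##
## Terms are accumulated in log space (log-sum-exp) so that very strong
## repression (tiny IS, large normalised counts) cannot overflow.

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise log-sum-exp of a matrix (partners in rows, samples in columns).
.colLogSumExp <- function(x) {
  m <- apply(x, 2L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    xs <- sweep(x[, ok, drop = FALSE], 2L, m[ok], "-")
    out[ok] <- m[ok] + log(colSums(exp(xs)))
  }
  out
}

#' Normalise raw miRNA-mRNA interaction scores
#'
#' Raw scores follow the TargetScan weighted-context-score convention
#' (non-positive, more negative = stronger repression). Their absolute
#' values are min-max rescaled onto [\code{isFloor}, 1], preserving the
#' "stronger score, stronger downregulation" ordering while keeping the
#' reciprocal 1/IS bounded. If all raw scores are equal the normalised score
#' is 1 for every pair.
#'
#' @param t interaction table (see \code{\link{readInteractionTable}}).
#' @param isFloor lower end of the normalised range, in (0, 1); default 0.01.
#' @return the table with an added \code{is} column in [isFloor, 1].
#' @export
normalizeInteractionScores <- function(t, isFloor = 0.01) {
  if (nrow(t) == 0L) stop("interaction table is empty", call. = FALSE)
  stopifnot(isFloor > 0, isFloor < 1)
  a <- abs(t$raw_score)
  rng <- range(a)
  if (rng[1] == rng[2]) {
    t$is <- rep(1, nrow(t))
  } else {
    t$is <- isFloor + (a - rng[1]) / (rng[2] - rng[1]) * (1 - isFloor)
  }
  t
}

#' Build the two regulatory graphs aligned to the data matrices
#'
#' Edges referencing miRNAs, CpGs or genes absent from the corresponding
#' matrices are dropped and counted; duplicate promoter-map rows collapse to
#' a single edge. Genes of the mRNA matrix missing from an edge set simply
#' have no entry there (the missing-partner policy handles them at
#' transform time).
#'
#' @param t interaction table carrying an \code{is} column (run
#'   \code{\link{normalizeInteractionScores}} first).
#' @param p promoter map (ideally already windowed via
#'   \code{\link{restrictPromoterMap}}).
#' @param mrna,mirna,meth the three aligned \linkS4class{OmicsMatrix}
#'   objects.
#' @return a \linkS4class{RegulatoryGraphs} object.
#' @export
buildGraphs <- function(t, p, mrna, mirna, meth) {
  if (is.null(t$is)) {
    stop("interaction table has no 'is' column; run ",
         "normalizeInteractionScores() first", call. = FALSE)
  }
  genes <- featureIds(mrna)
  keepM <- t$gene_id %in% genes & t$mirna_id %in% featureIds(mirna)
  tm <- t[keepM, , drop = FALSE]
  p <- p[!duplicated(p[c("cpg_id", "gene_id")]), , drop = FALSE]
  keepC <- p$gene_id %in% genes & p$cpg_id %in% featureIds(meth)
  pc <- p[keepC, , drop = FALSE]
  if (nrow(tm) == 0L && nrow(pc) == 0L) {
    stop("no usable edges in either regulatory graph after alignment",
         call. = FALSE)
  }
  mirnaEdges <- lapply(
    split(tm[c("mirna_id", "is")], tm$gene_id),
    function(df) df[!duplicated(df$mirna_id), , drop = FALSE]
  )
  cpgEdges <- lapply(split(pc$cpg_id, pc$gene_id), unique)
  new("RegulatoryGraphs",
      mirnaEdges = mirnaEdges, cpgEdges = cpgEdges,
      edgeStats = c(
        mirna_edges = sum(vapply(mirnaEdges, nrow, 0L)),
        cpg_edges = sum(lengths(cpgEdges)),
        mirna_dropped = sum(!keepM),
        cpg_dropped = sum(!keepC)
      ))
}

#' miRNA-derived modulating factor for one gene in one sample
#'
#' Average over the gene's interacting miRNAs of
#' 1 / (IS * exp(alpha * log2(expr + pseudocount))); strictly decreasing in
#' every partner expression and every interaction score.
#'
#' @param exprs non-negative miRNA expression values, one per partner.
#' @param iss matching normalised interaction scores in (0, 1].
#' @param alpha decay exponent (> 0).
#' @param pseudocount added before log2 (> 0).
#' @return a positive scalar, or \code{NA_real_} when there are no partners.
#' @export
delta1GeneSample <- function(exprs, iss, alpha = 1.5, pseudocount = 1) {
  n <- length(exprs)
  if (n == 0L) return(NA_real_)
  stopifnot(length(iss) == n, all(exprs >= 0), all(iss > 0), all(iss <= 1))
  logTerms <- -log(iss) - alpha * log2(exprs + pseudocount)
  exp(.logSumExp(logTerms) - log(n))
}

#' Methylation-derived modulating factor for one gene in one sample
#'
#' Average over the gene's promoter CpGs of 1 / exp(betaExp * log2(beta)),
#' i.e. beta^(-betaExp / ln 2); strictly decreasing in every beta.
#'
#' @param betas beta values in (0, 1], one per promoter CpG.
#' @param betaExp decay exponent (> 0).
#' @return a positive scalar, or \code{NA_real_} when there are no partners.
#' @export
delta2GeneSample <- function(betas, betaExp = 1.5) {
  n <- length(betas)
  if (n == 0L) return(NA_real_)
  stopifnot(all(betas > 0), all(betas <= 1))
  logTerms <- -betaExp * log2(betas)
  exp(.logSumExp(logTerms) - log(n))
}

#' Combine the two modulating factors into the final factor
#'
#' Both present: weighted mean (w1*d1 + w2*d2)/(w1+w2). Exactly one present:
#' under policy \code{"fallback"} the present factor is used alone, under
#' \code{"neutral_one"} the absent one is replaced by 1 in the weighted
#' mean. Both absent: 1, so the transform is the identity for that gene.
#'
#' @param d1,d2 factors or \code{NA} (absent).
#' @param w1,w2 non-negative weights, not both zero.
#' @param policy "fallback" or "neutral_one".
#' @return the combined factor.
#' @export
combineDelta <- function(d1, d2, w1 = 1, w2 = 1,
                         policy = c("fallback", "neutral_one")) {
  policy <- match.arg(policy)
  stopifnot(w1 >= 0, w2 >= 0, w1 + w2 > 0)
  if (is.na(d1) && is.na(d2)) return(1)
  if (policy == "fallback") {
    if (is.na(d1)) return(d2)
    if (is.na(d2)) return(d1)
  } else {
    if (is.na(d1)) d1 <- 1
    if (is.na(d2)) d2 <- 1
  }
  (w1 * d1 + w2 * d2) / (w1 + w2)
}

#' Compute modulating factors and the transformed mRNA matrix
#'
#' For every gene and sample, the miRNA factor is computed from that
#' sample's partner-miRNA expression values, the methylation factor from
#' that sample's partner-CpG beta values, the combined factor via
#' \code{\link{combineDelta}}, and the transformed value as combined factor
#' times the sample's mRNA expression. Deterministic: identical inputs give
#' bit-identical outputs.
#'
#' @param mrna,mirna,meth sample-aligned \linkS4class{OmicsMatrix} objects
#'   (identical ordered sample ids; no missing values; methylation already
#'   clamped into (0, 1]).
#' @param g a \linkS4class{RegulatoryGraphs} object.
#' @param cfg a \linkS4class{TransformConfig}.
#' @return a \linkS4class{DeltaResult}.
#' @export
transformMatrix <- function(mrna, mirna, meth, g, cfg = TransformConfig()) {
  sids <- sampleIds(mrna)
  if (!identical(sids, sampleIds(mirna)) ||
      !identical(sids, sampleIds(meth))) {
    stop("matrices are not sample-aligned; run intersectSamples() first",
         call. = FALSE)
  }
  ev <- omicsValues(mrna)
  if (anyNA(ev) || anyNA(omicsValues(mirna)) || anyNA(omicsValues(meth))) {
    stop("matrices must have no missing values at transform time",
         call. = FALSE)
  }
  if (cfg@log2Mrna) ev <- log2(ev + 1)
  genes <- featureIds(mrna)
  nS <- length(sids)
  miV <- omicsValues(mirna)
  beV <- omicsValues(meth)
  d1 <- d2 <- matrix(NA_real_, length(genes), nS,
                     dimnames = list(genes, sids))
  for (gene in intersect(genes, names(g@mirnaEdges))) {
    e <- g@mirnaEdges[[gene]]
    # partners x samples matrix of per-term logs, collapsed per column
    lt <- -log(e$is) -
      cfg@alpha * log2(miV[e$mirna_id, , drop = FALSE] + cfg@exprPseudocount)
    d1[gene, ] <- exp(.colLogSumExp(lt) - log(nrow(e)))
  }
  for (gene in intersect(genes, names(g@cpgEdges))) {
    cp <- g@cpgEdges[[gene]]
    lt <- -cfg@betaExp * log2(beV[cp, , drop = FALSE])
    d2[gene, ] <- exp(.colLogSumExp(lt) - log(length(cp)))
  }
  w1 <- cfg@w1; w2 <- cfg@w2
  dd <- matrix(1, length(genes), nS, dimnames = list(genes, sids))
  both <- !is.na(d1) & !is.na(d2)
  dd[both] <- (w1 * d1[both] + w2 * d2[both]) / (w1 + w2)
  only1 <- !is.na(d1) & is.na(d2)
  only2 <- is.na(d1) & !is.na(d2)
  if (cfg@missingPartnerPolicy == "fallback") {
    dd[only1] <- d1[only1]
    dd[only2] <- d2[only2]
  } else {
    dd[only1] <- (w1 * d1[only1] + w2) / (w1 + w2)
    dd[only2] <- (w1 + w2 * d2[only2]) / (w1 + w2)
  }
  new("DeltaResult", delta1 = d1, delta2 = d2, delta = dd,
      transformed = dd * ev, config = cfg)
}
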