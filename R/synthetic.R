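## Self-contained synthetic multi-omics generator. Counts are
## negative-binomial (overdispersed, like RNA-seq), methylation values are
## Beta-distributed, and class signal is planted ONLY in the regulators
## (partner miRNA levels on the log2 scale, partner CpG beta values on the
## logit scale) of a designated subset of genes. Baseline mRNA means are
## suppressed by the sampled regulator levels, so mRNA carries class signal
## only through the regulatory structure -- the situation in which the
## graph transform is expected to concentrate signal into gene features.

#' Configuration of the synthetic data generator
#'
#' @param classSizes named integer vector of per-class sample counts.
#' @param nGenes,nMirnas,nCpgs feature counts per layer.
#' @param mirnaEdgeRange,cpgEdgeRange inclusive ranges of partners per gene.
#' @param nSignalGenes number of genes whose regulators carry class signal
#'   (assigned round-robin to classes).
#' @param mirnaShift class effect on a signal gene's partner miRNAs,
#'   in log2 units (default 1.5, i.e. about 2.8-fold).
#' @param betaShift class effect on a signal gene's partner CpG beta
#'   values, on the logit scale (default 1.5).
#' @param mirnaSuppression,methSuppression exponents tying the mRNA
#'   baseline mean to its regulators' sampled levels.
#' @param countMeanlog,countSdlog log-normal baseline for feature mean
#'   counts.
#' @param dispersion negative-binomial size parameter (default 10).
#' @param baselineHazard exponential event rate per time unit per class
#'   (recycled across classes).
#' @param hazardRatio multiplicative hazard for samples with
#'   above-median expression of the planted prognostic gene (default 3).
#' @param censorMax upper end of the uniform censoring window.
#' @param seed mandatory integer seed.
#' @return a \code{SyntheticConfig} list.
#' @export
syntheticConfig <- function(classSizes = c(C1 = 60L, C2 = 30L, C3 = 20L,
                                           C4 = 40L),
                            nGenes = 60L, nMirnas = 40L, nCpgs = 80L,
                            mirnaEdgeRange = c(2L, 5L),
                            cpgEdgeRange = c(2L, 5L),
                            nSignalGenes = 16L,
                            mirnaShift = 2, betaShift = 2,
                            mirnaSuppression = 0.4, methSuppression = 1.0,
                            countMeanlog = log(500), countSdlog = 0.6,
                            dispersion = 10,
                            baselineHazard = 0.05, hazardRatio = 3,
                            censorMax = 60, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(classSizes >= 1L), length(classSizes) >= 2L,
            nGenes >= 1L, nMirnas >= 1L, nCpgs >= 1L,
            nSignalGenes <= nGenes)
  if (mirnaEdgeRange[2] > nMirnas || cpgEdgeRange[2] > nCpgs) {
    stop("edges per gene exceed available regulator nodes", call. = FALSE)
  }
  structure(as.list(environment()), class = "SyntheticConfig")
}

.rbetaMean <- function(n, mean, precision = 20) {
  stats::rbeta(n, mean * precision, (1 - mean) * precision)
}

#' Generate a synthetic multi-omics fixture bundle
#'
#' Produces three aligned omics matrices with planted regulatory structure,
#' the interaction and promoter tables, class labels, gene annotations,
#' survival records, and ground-truth metadata (true regulator sets, the
#' planted prognostic gene, and modulating-factor matrices computed with
#' the naive edge-loop evaluator \code{\link{deltaOracle}}). Deterministic:
#' the same config (including seed) gives a bit-identical bundle.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return a \code{FixtureBundle} list; see Details.
#' @details Elements: \code{mrna}, \code{mirna}, \code{meth}
#'   (\linkS4class{OmicsMatrix}), \code{interactions}, \code{promoterMap},
#'   \code{labels}, \code{annotations}, \code{survival} (data.frames), and
#'   \code{truth} (signal genes, per-gene regulator sets, prognostic gene,
#'   oracle delta matrices on the emitted data under the default
#'   \linkS4class{TransformConfig}).
#' @export
generateBundle <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("g%03d", seq_len(cfg$nGenes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$nMirnas))
  cpgs <- sprintf("cg%03d", seq_len(cfg$nCpgs))
  classes <- names(cfg$classSizes)
  sids <- sprintf("s%03d", seq_len(sum(cfg$classSizes)))
  labels <- data.frame(
    sample_id = sids,
    class_label = rep(classes, times = cfg$classSizes),
    stringsAsFactors = FALSE
  )

  # regulatory wiring
  mirnaPartners <- lapply(genes, function(g) {
    sort(sample(mirnas, sample(cfg$mirnaEdgeRange[1]:cfg$mirnaEdgeRange[2], 1)))
  })
  names(mirnaPartners) <- genes
  cpgPartners <- lapply(genes, function(g) {
    sort(sample(cpgs, sample(cfg$cpgEdgeRange[1]:cfg$cpgEdgeRange[2], 1)))
  })
  names(cpgPartners) <- genes
  interactions <- do.call(rbind, lapply(genes, function(g) {
    data.frame(mirna_id = mirnaPartners[[g]], gene_id = g,
               raw_score = -round(stats::runif(length(mirnaPartners[[g]]),
                                               0.2, 1.0), 4),
               stringsAsFactors = FALSE)
  }))
  promoterMap <- do.call(rbind, lapply(genes, function(g) {
    data.frame(cpg_id = cpgPartners[[g]], gene_id = g,
               tss_distance_bp = sample(0:1500, length(cpgPartners[[g]]),
                                        replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  signalGenes <- genes[seq_len(cfg$nSignalGenes)]
  signalClass <- stats::setNames(
    rep(classes, length.out = cfg$nSignalGenes), signalGenes)

  # miRNA layer: NB counts around per-miRNA baselines, shifted (log2 scale)
  # in the class assigned to each signal gene the miRNA regulates
  nS <- length(sids)
  muMir <- exp(stats::rnorm(cfg$nMirnas, cfg$countMeanlog, cfg$countSdlog))
  names(muMir) <- mirnas
  shiftMir <- matrix(0, cfg$nMirnas, nS, dimnames = list(mirnas, sids))
  for (g in signalGenes) {
    inClass <- labels$class_label == signalClass[[g]]
    shiftMir[mirnaPartners[[g]], inClass] <-
      shiftMir[mirnaPartners[[g]], inClass] + cfg$mirnaShift
  }
  muMirMat <- muMir * 2^shiftMir
  mirnaVals <- matrix(
    stats::rnbinom(length(muMirMat), mu = as.numeric(muMirMat),
                   size = cfg$dispersion),
    cfg$nMirnas, nS, dimnames = list(mirnas, sids))

  # methylation layer: Beta draws around per-CpG baselines, shifted on the
  # logit scale in the signal class
  baseBeta <- .rbetaMean(cfg$nCpgs, 0.4, 8)
  baseBeta <- pmin(pmax(baseBeta, 0.05), 0.95)
  names(baseBeta) <- cpgs
  logit <- function(p) log(p / (1 - p))
  invlogit <- function(x) 1 / (1 + exp(-x))
  shiftCpg <- matrix(0, cfg$nCpgs, nS, dimnames = list(cpgs, sids))
  for (g in signalGenes) {
    inClass <- labels$class_label == signalClass[[g]]
    shiftCpg[cpgPartners[[g]], inClass] <-
      shiftCpg[cpgPartners[[g]], inClass] + cfg$betaShift
  }
  meanBeta <- invlogit(logit(baseBeta) + shiftCpg)
  methVals <- matrix(
    .rbetaMean(length(meanBeta), as.numeric(meanBeta), 40),
    cfg$nCpgs, nS, dimnames = list(cpgs, sids))
  methVals <- round(pmin(pmax(methVals, 0.001), 0.999), 4)

  # mRNA layer: baseline suppressed by the gene's sampled regulator levels;
  # class signal enters only through those regulators
  muGene <- exp(stats::rnorm(cfg$nGenes, cfg$countMeanlog, cfg$countSdlog))
  names(muGene) <- genes
  mrnaVals <- matrix(0, cfg$nGenes, nS, dimnames = list(genes, sids))
  for (g in genes) {
    mirMean <- colMeans(mirnaVals[mirnaPartners[[g]], , drop = FALSE])
    betaMean <- colMeans(methVals[cpgPartners[[g]], , drop = FALSE])
    mu <- muGene[[g]] *
      ((mirMean + 1) / (muMir[mirnaPartners[[g]]] |> mean() + 1))^
        (-cfg$mirnaSuppression) *
      2^(-cfg$methSuppression * (betaMean - mean(baseBeta[cpgPartners[[g]]])))
    mrnaVals[g, ] <- stats::rnbinom(nS, mu = mu, size = cfg$dispersion)
  }

  annotations <- data.frame(
    gene_id = genes,
    sift = round(stats::runif(cfg$nGenes), 3),
    polyphen = round(stats::runif(cfg$nGenes), 3),
    haploinsufficiency = round(stats::runif(cfg$nGenes), 3),
    stringsAsFactors = FALSE
  )

  # survival: exponential times; the planted prognostic gene multiplies the
  # hazard for samples expressing it above its median
  progGene <- signalGenes[1]
  high <- mrnaVals[progGene, ] > stats::median(mrnaVals[progGene, ])
  haz <- rep_len(cfg$baselineHazard, length(classes))[
    match(labels$class_label, classes)]
  rate <- haz * ifelse(high, cfg$hazardRatio, 1)
  evTime <- stats::rexp(nS, rate)
  cens <- stats::runif(nS, 0, cfg$censorMax)
  survivalRecords <- data.frame(
    sample_id = sids,
    time = round(pmin(evTime, cens), 3),
    event = as.integer(evTime <= cens),
    stringsAsFactors = FALSE
  )

  mrna <- OmicsMatrix(mrnaVals, "mrna_counts")
  mirna <- OmicsMatrix(mirnaVals, "mirna_counts")
  meth <- OmicsMatrix(methVals, "methylation_beta")
  oracle <- deltaOracle(mrna, mirna, meth,
                        normalizeInteractionScores(interactions),
                        promoterMap, TransformConfig())
  structure(list(
    mrna = mrna, mirna = mirna, meth = meth,
    interactions = interactions, promoterMap = promoterMap,
    labels = labels, annotations = annotations,
    survival = survivalRecords,
    truth = list(signalGenes = signalGenes, signalClass = signalClass,
                 mirnaPartners = mirnaPartners, cpgPartners = cpgPartners,
                 prognosticGene = progGene, oracleDelta = oracle),
    config = cfg
  ), class = "FixtureBundle")
}

#' Naive edge-loop evaluator of the modulating factors
#'
#' Direct, loop-based application of the factor definitions from the raw
#' edge tables: for every gene and sample the miRNA terms
#' 1/(IS * e^(alpha*log2(expr+pc))) and methylation terms
#' 1/e^(betaExp*log2(beta)) are averaged, combined by weighted mean under
#' the missing-partner policy, and multiplied into the mRNA value. Written
#' independently of \code{\link{transformMatrix}} (no shared code path, no
#' log-space tricks) to serve as its cross-check.
#'
#' @param mrna,mirna,meth aligned \linkS4class{OmicsMatrix} objects.
#' @param interactions interaction table with an \code{is} column.
#' @param promoterMap promoter map data.frame.
#' @param cfg a \linkS4class{TransformConfig}.
#' @return list of matrices \code{delta1}, \code{delta2}, \code{delta},
#'   \code{transformed}.
#' @export
deltaOracle <- function(mrna, mirna, meth, interactions, promoterMap, cfg) {
  genes <- featureIds(mrna); sids <- sampleIds(mrna)
  ev <- omicsValues(mrna)
  if (cfg@log2Mrna) ev <- log2(ev + 1)
  miV <- omicsValues(mirna); beV <- omicsValues(meth)
  d1 <- d2 <- matrix(NA_real_, length(genes), length(sids),
                     dimnames = list(genes, sids))
  dd <- tr <- matrix(0, length(genes), length(sids),
                     dimnames = list(genes, sids))
  pm <- promoterMap[!duplicated(promoterMap[c("cpg_id", "gene_id")]), ]
  for (g in genes) {
    edgesM <- interactions[interactions$gene_id == g &
                             interactions$mirna_id %in% rownames(miV), ]
    edgesM <- edgesM[!duplicated(edgesM$mirna_id), ]
    edgesC <- unique(pm$cpg_id[pm$gene_id == g & pm$cpg_id %in% rownames(beV)])
    for (s in sids) {
      v1 <- if (nrow(edgesM) > 0) {
        terms <- numeric(nrow(edgesM))
        for (i in seq_len(nrow(edgesM))) {
          e <- miV[edgesM$mirna_id[i], s]
          terms[i] <- 1 / (edgesM$is[i] *
                             exp(cfg@alpha * log2(e + cfg@exprPseudocount)))
        }
        mean(terms)
      } else NA_real_
      v2 <- if (length(edgesC) > 0) {
        terms <- numeric(length(edgesC))
        for (i in seq_along(edgesC)) {
          terms[i] <- 1 / exp(cfg@betaExp * log2(beV[edgesC[i], s]))
        }
        mean(terms)
      } else NA_real_
      d1[g, s] <- v1
      d2[g, s] <- v2
      dd[g, s] <- combineDelta(v1, v2, cfg@w1, cfg@w2,
                               cfg@missingPartnerPolicy)
      tr[g, s] <- dd[g, s] * ev[g, s]
    }
  }
  list(delta1 = d1, delta2 = d2, delta = dd, transformed = tr)
}

#' Edge-case fixture bundles for filter and transform tests
#'
#' Small hand-planted matrices with known violation counts: an all-zero
#' feature, a feature exactly on the 20\% zero boundary (survives), a
#' feature above it (removed), a sample with more than 20\% missing, a gene
#' with no regulatory partners, a constant-expression gene, beta values of
#' 0 (clamp target) and an all-missing beta feature (error target).
#'
#' @return named list of fixtures, each a list with the relevant objects
#'   and a \code{planted} list of expected outcomes.
#' @export
generateDegenerateCases <- function() {
  # 10 samples so the 20% boundary is exactly 2 bad cells
  sids <- sprintf("s%02d", 1:10)
  counts <- matrix(100, 5, 10, dimnames = list(
    c("ok", "boundary20", "over20", "allzero", "forSample"), sids))
  counts["boundary20", 1:2] <- 0          # 2/10 = 20%: survives (strict >)
  counts["over20", 1:3] <- 0              # 30%: removed
  counts["allzero", ] <- 0                # removed
  filterFixture <- list(
    matrix = OmicsMatrix(counts, "mrna_counts"),
    planted = list(removedFeatures = c("over20", "allzero"),
                   keptFeatures = c("ok", "boundary20", "forSample"))
  )

  sampleCounts <- matrix(50, 4, 5, dimnames = list(
    paste0("g", 1:4), paste0("s", 1:5)))
  sampleCounts[1, "s5"] <- NA             # 1/4 = 25% missing: removed
  sampleFixture <- list(
    matrix = OmicsMatrix(sampleCounts, "mrna_counts"),
    planted = list(removedSamples = "s5", keptSamples = paste0("s", 1:4))
  )

  beta <- matrix(0.5, 3, 4, dimnames = list(
    c("normal", "haszero", "allmissing"), paste0("s", 1:4)))
  beta["haszero", 1] <- 0                 # clamp target
  beta["allmissing", ] <- NA              # impute error target
  betaFixture <- list(matrix = OmicsMatrix(beta, "methylation_beta"),
                      planted = list(allMissingFeature = "allmissing",
                                     zeroCell = c("haszero", "s1")))

  # transform fixture: g2 has no partners in either graph
  m <- matrix(c(10, 20, 30, 40, 5, 5, 5, 5), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  mi <- matrix(c(3, 1, 4, 1), 1, 4, dimnames = list("mir1", paste0("s", 1:4)))
  me <- matrix(0.5, 1, 4, dimnames = list("cg1", paste0("s", 1:4)))
  transformFixture <- list(
    mrna = OmicsMatrix(m, "mrna_counts"),
    mirna = OmicsMatrix(mi, "mirna_counts"),
    meth = OmicsMatrix(me, "methylation_beta"),
    interactions = data.frame(mirna_id = "mir1", gene_id = "g1",
                              raw_score = -0.5, stringsAsFactors = FALSE),
    promoterMap = data.frame(cpg_id = "cg1", gene_id = "g1",
                             tss_distance_bp = 100L,
                             stringsAsFactors = FALSE),
    planted = list(partnerlessGene = "g2")
  )

  constExpr <- stats::setNames(rep(7, 6), paste0("s", 1:6))
  list(features = filterFixture, samples = sampleFixture,
       beta = betaFixture, transform = transformFixture,
       constantExpression = constExpr)
}
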