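## Kaplan-Meier estimation, median-expression dichotomisation and log-rank
## screening of candidate prognostic genes. The estimator and test are
## delegated to the survival package; this module adds the grouping rule,
## degenerate-case handling and the per-gene screening loop.

#' Split samples into high/low expression groups
#'
#' High = strictly above the expression quantile (median by default),
#' low = at or below it, so ties at the cut point go to the low group.
#'
#' @param expr named numeric vector (one gene's expression per sample).
#' @param quantile cut quantile, default 0.5 (median).
#' @return character vector of \code{"high"}/\code{"low"} labels, named by
#'   sample.
#' @export
dichotomizeByExpression <- function(expr, quantile = 0.5) {
  cut <- stats::quantile(expr, quantile, names = FALSE, type = 7)
  grp <- ifelse(expr > cut, "high", "low")
  if (length(unique(grp)) < 2L) {
    stop("expression split produced an empty group (constant expression?)",
         call. = FALSE)
  }
  stats::setNames(grp, names(expr))
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over distinct event times t_i <= t of (1 - d_i / n_i);
#' subjects censored at an event time still count as at risk there.
#'
#' @param records survival data.frame (\code{sample_id}, \code{time},
#'   \code{event}).
#' @return data.frame step function with columns \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival} (event times only).
#' @export
kmEstimate <- function(records) {
  stopifnot(nrow(records) >= 1L)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = records, conf.type = "none"
  )
  s <- summary(fit, censored = FALSE)
  data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
             survival = s$surv)
}

#' Two-group log-rank test
#'
#' Standard chi-square statistic with one degree of freedom:
#' U = sum over event times of (observed - expected deaths in group 1),
#' V the summed hypergeometric variances, statistic U^2/V, p from the
#' upper chi-square tail. With no events in either group the statistic is
#' undefined and reported as \code{NA}, never 0.
#'
#' @param records survival data.frame.
#' @param group two-level factor/character, one entry per record.
#' @return list with \code{statistic}, \code{p}, and \code{groupSizes}.
#' @export
logrankTest <- function(records, group) {
  group <- as.character(group)
  stopifnot(nrow(records) == length(group))
  if (length(unique(group)) != 2L) {
    stop("log-rank test needs exactly two groups", call. = FALSE)
  }
  if (sum(records$event) == 0) {
    return(list(statistic = NA_real_, p = NA_real_,
                groupSizes = table(group)))
  }
  d <- data.frame(time = records$time, event = records$event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  stat <- sd$chisq
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       groupSizes = table(group))
}

#' Log-rank screen of a gene list within a sample subset
#'
#' For each gene: dichotomise its expression at the quantile, run the
#' two-group log-rank test against the survival records, and flag p < alpha
#' (strictly). No multiplicity correction is applied by default; set
#' \code{adjust = TRUE} for Benjamini-Hochberg adjusted significance.
#'
#' @param expr features-by-samples expression matrix (raw or transformed).
#' @param records survival data.frame; only samples present in both the
#'   matrix and the records are used.
#' @param genes character vector of gene ids to screen (rows of expr).
#' @param alphaLevel significance threshold (default 0.05).
#' @param quantile expression cut quantile (default 0.5).
#' @param adjust add Benjamini-Hochberg adjusted p-values and flag on them.
#' @return data.frame with columns \code{gene}, \code{statistic}, \code{p},
#'   \code{significant} (and \code{p_adj} when \code{adjust}).
#' @export
screenGenes <- function(expr, records, genes, alphaLevel = 0.05,
                        quantile = 0.5, adjust = FALSE) {
  common <- intersect(colnames(expr), records$sample_id)
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), statistic = numeric(),
                      p = numeric(), significant = logical()))
  }
  if (length(common) < 4L) {
    stop("too few samples shared between expression matrix and survival ",
         "records", call. = FALSE)
  }
  rec <- records[match(common, records$sample_id), , drop = FALSE]
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(expr)) {
      return(data.frame(gene = g, statistic = NA_real_, p = NA_real_))
    }
    e <- stats::setNames(expr[g, common], common)
    grp <- tryCatch(dichotomizeByExpression(e, quantile),
                    error = function(e) NULL)
    if (is.null(grp)) {
      return(data.frame(gene = g, statistic = NA_real_, p = NA_real_))
    }
    lr <- logrankTest(rec, grp[common])
    data.frame(gene = g, statistic = lr$statistic, p = lr$p)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alphaLevel
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alphaLevel
  }
  rownames(out) <- NULL
  out
}
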