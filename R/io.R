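## Delimited-text readers and writers for the tool's tabular inputs.
## Contract: tab-separated with a header row by default, comma via `sep`;
## "NA", "NaN" and empty cells mean missing; zero is a value, never missing.

.MISSING_MARKERS <- c("NA", "NaN", "")

.readDelim <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    na.strings = .MISSING_MARKERS,
                    stringsAsFactors = FALSE, comment.char = "")
}

.requireColumns <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' is missing required column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read a features-by-samples omics matrix from delimited text
#'
#' The first column holds feature ids, the header row sample ids. Cells equal
#' to \code{NA}, \code{NaN} or empty are read as missing. Row and column
#' order are preserved exactly as on disk; no rows are ever silently dropped.
#'
#' @param path path to a TSV (or CSV, with \code{sep = ","}) file.
#' @param kind omics kind tag (drives range validation).
#' @param sep field delimiter, tab by default.
#' @return an \linkS4class{OmicsMatrix}.
#' @export
readOmicsMatrix <- function(path, kind, sep = "\t") {
  df <- .readDelim(path, sep)
  if (ncol(df) < 2L) {
    stop("omics matrix file must have a feature-id column plus >= 1 sample",
         call. = FALSE)
  }
  fid <- as.character(df[[1]])
  if (anyDuplicated(fid)) {
    stop(sprintf("duplicate feature id '%s' in %s",
                 fid[duplicated(fid)][1], path), call. = FALSE)
  }
  sid <- names(df)[-1]
  if (anyDuplicated(sid)) {
    stop(sprintf("duplicate sample id '%s' in %s",
                 sid[duplicated(sid)][1], path), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("non-numeric values in omics matrix ", path, call. = FALSE)
  }
  dimnames(vals) <- list(fid, sid)
  OmicsMatrix(vals, kind)
}

#' Write an OmicsMatrix to delimited text
#'
#' Inverse of \code{\link{readOmicsMatrix}}: a write/read round trip
#' reproduces ids, kind (caller-supplied), values and missingness exactly.
#'
#' @param m an \linkS4class{OmicsMatrix}.
#' @param path output path.
#' @param sep field delimiter.
#' @export
writeOmicsMatrix <- function(m, path, sep = "\t") {
  v <- omicsValues(m)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.checkNoDuplicatePairs <- function(df, keyCols, what, path) {
  key <- do.call(paste, c(df[keyCols], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), keyCols, drop = FALSE][1, ]
    stop(sprintf("duplicate (%s) pair in %s file '%s': %s",
                 paste(keyCols, collapse = ", "), what, path,
                 paste(unlist(d), collapse = " / ")), call. = FALSE)
  }
}

#' Read a miRNA-to-gene interaction table
#'
#' Required columns: \code{mirna_id}, \code{gene_id}, \code{raw_score}.
#' Raw scores follow the TargetScan weighted-context-score convention
#' (non-positive; more negative = stronger repression). Pairs must be unique.
#'
#' @param path,sep file path and delimiter.
#' @return data.frame with the three columns, classed for validation.
#' @export
readInteractionTable <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  .requireColumns(df, c("mirna_id", "gene_id", "raw_score"),
                  "interaction table", path)
  df <- df[c("mirna_id", "gene_id", "raw_score")]
  df$mirna_id <- as.character(df$mirna_id)
  df$gene_id <- as.character(df$gene_id)
  .checkNoDuplicatePairs(df, c("mirna_id", "gene_id"), "interaction", path)
  if (!is.numeric(df$raw_score) || anyNA(df$raw_score) ||
      any(!is.finite(df$raw_score))) {
    stop("raw_score must be finite and non-missing in ", path, call. = FALSE)
  }
  df
}

#' Read a CpG-to-gene promoter map
#'
#' Required columns: \code{cpg_id}, \code{gene_id}, \code{tss_distance_bp}
#' (non-negative integer distance upstream of the transcription start site).
#'
#' @param path,sep file path and delimiter.
#' @return data.frame with the three columns.
#' @export
readPromoterMap <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  .requireColumns(df, c("cpg_id", "gene_id", "tss_distance_bp"),
                  "promoter map", path)
  df <- df[c("cpg_id", "gene_id", "tss_distance_bp")]
  df$cpg_id <- as.character(df$cpg_id)
  df$gene_id <- as.character(df$gene_id)
  .checkNoDuplicatePairs(df, c("cpg_id", "gene_id"), "promoter map", path)
  if (anyNA(df$tss_distance_bp) || any(df$tss_distance_bp < 0)) {
    stop("tss_distance_bp must be non-negative and non-missing in ", path,
         call. = FALSE)
  }
  df
}

#' Read per-sample class labels
#'
#' Required columns: \code{sample_id}, \code{class_label}; one row per
#' sample; at least two distinct labels.
#'
#' @param path,sep file path and delimiter.
#' @return data.frame with the two columns.
#' @export
readLabels <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  .requireColumns(df, c("sample_id", "class_label"), "label", path)
  df <- df[c("sample_id", "class_label")]
  df$sample_id <- as.character(df$sample_id)
  df$class_label <- as.character(df$class_label)
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample id '%s' in label file %s",
                 df$sample_id[duplicated(df$sample_id)][1], path),
         call. = FALSE)
  }
  if (length(unique(df$class_label)) < 2L) {
    stop("label file must contain at least two distinct class labels",
         call. = FALSE)
  }
  df
}

#' Read a gene-level annotation table
#'
#' Required columns: \code{gene_id}, \code{sift}, \code{polyphen},
#' \code{haploinsufficiency}; score columns may contain missing values but
#' present values must lie in [0, 1]. One row per gene.
#'
#' @param path,sep file path and delimiter.
#' @return data.frame with the four columns.
#' @export
readAnnotationTable <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  cols <- c("gene_id", "sift", "polyphen", "haploinsufficiency")
  .requireColumns(df, cols, "annotation", path)
  df <- df[cols]
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id in annotation file ", path, call. = FALSE)
  }
  for (sc in cols[-1]) {
    v <- df[[sc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf("%s scores must lie in [0, 1] in %s", sc, path),
           call. = FALSE)
    }
  }
  df
}

#' Read per-sample survival records
#'
#' Required columns: \code{sample_id}, \code{time} (non-negative, one unit
#' throughout), \code{event} (1 = death observed, 0 = censored).
#'
#' @param path,sep file path and delimiter.
#' @return data.frame with the three columns.
#' @export
readSurvivalRecords <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  .requireColumns(df, c("sample_id", "time", "event"), "survival", path)
  df <- df[c("sample_id", "time", "event")]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in survival file ", path, call. = FALSE)
  }
  if (anyNA(df$time) || any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("survival time must be finite and >= 0 in ", path, call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death) in ", path, call. = FALSE)
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @param sep field delimiter.
#' @export
writeTable <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
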