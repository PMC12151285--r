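## End-to-end orchestration: preprocess -> transform -> split/augment ->
## train/evaluate -> explain -> survival, as one reproducible run with a
## machine-readable manifest. A single global seed fans out to per-stage
## seeds as seed + stage index, so any stage can be re-run in isolation.

.CONFIG_DEFAULTS <- list(
  seed = 1L,
  max_bad_fraction = 0.2,
  beta_floor = 1e-3,
  tss_window = 1500L,
  alpha = 1.5,
  beta_exp = 1.5,
  w1 = 1,
  w2 = 1,
  expr_pseudocount = 1,
  is_floor = 0.01,
  missing_partner_policy = "fallback",
  log2_mrna = FALSE,
  test_fraction = 0.2,
  model = "logistic_ovr",
  augment = FALSE,
  knn_neighbors = 4L,
  top_k = 357L,
  per_class_k = 25L,
  alpha_level = 0.05,
  mrna = "", mirna = "", meth = "", pairs = "", promoter_map = "",
  labels = "", annotations = "", survival = ""
)

#' Default run configuration
#'
#' Every tunable of every pipeline stage with its documented default.
#' @return named list.
#' @export
gainDefaultConfig <- function() .CONFIG_DEFAULTS

#' Read a flat key = value run configuration file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting
#' with \code{#} are ignored. Unknown keys are rejected; values are coerced
#' to the type of the corresponding default.
#'
#' @param path config file path.
#' @return full config list (defaults overridden by the file).
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- .CONFIG_DEFAULTS
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) {
      stop("malformed config line (expected key = value): ", ln,
           call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    proto <- .CONFIG_DEFAULTS[[key]]
    cfg[[key]] <- if (is.logical(proto)) {
      toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else if (is.integer(proto)) {
      as.integer(val)
    } else if (is.numeric(proto)) {
      as.numeric(val)
    } else val
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, the graph transform, stratified splitting with
#' optional minority augmentation, model training and evaluation, Shapley
#' importance with the annotation filter cascade and subtype-unique sets,
#' and per-subtype log-rank survival screening. Inputs come either from a
#' synthetic \code{FixtureBundle} or from the file paths in the config.
#' All stage outputs are written as TSV under \code{outDir} together with a
#' JSON run manifest; outputs are pure functions of (inputs, config, seed).
#'
#' @param config run configuration list (see \code{\link{gainDefaultConfig}}
#'   / \code{\link{readRunConfig}}).
#' @param bundle optional \code{FixtureBundle} from
#'   \code{\link{generateBundle}}; when NULL, inputs are read from the
#'   paths in \code{config}.
#' @param outDir output directory (created if absent).
#' @return the run manifest (list), invisibly written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, bundle = NULL, outDir) {
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- .CONFIG_DEFAULTS
  cfg[names(config)] <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  inputs <- .stage("load", {
    if (is.null(bundle)) {
      paths <- cfg[c("mrna", "mirna", "meth", "pairs", "promoter_map",
                     "labels")]
      missing <- names(paths)[!vapply(paths, function(p) {
        nzchar(p) && file.exists(p)
      }, TRUE)]
      if (length(missing)) {
        stop("missing required input(s): ", paste(missing, collapse = ", "))
      }
      list(
        mrna = readOmicsMatrix(cfg$mrna, "mrna_counts"),
        mirna = readOmicsMatrix(cfg$mirna, "mirna_counts"),
        meth = readOmicsMatrix(cfg$meth, "methylation_beta"),
        interactions = readInteractionTable(cfg$pairs),
        promoterMap = readPromoterMap(cfg$promoter_map),
        labels = readLabels(cfg$labels),
        annotations = if (nzchar(cfg$annotations)) {
          readAnnotationTable(cfg$annotations)
        },
        survival = if (nzchar(cfg$survival)) {
          readSurvivalRecords(cfg$survival)
        }
      )
    } else {
      bundle[c("mrna", "mirna", "meth", "interactions", "promoterMap",
               "labels", "annotations", "survival")]
    }
  })

  pre <- .stage("preprocess", {
    out <- preprocessOmics(inputs$mrna, inputs$mirna, inputs$meth,
                           maxBadFraction = cfg$max_bad_fraction,
                           betaFloor = cfg$beta_floor)
    out$promoterMap <- restrictPromoterMap(inputs$promoterMap,
                                           cfg$tss_window)
    out
  })

  trans <- .stage("transform", {
    ints <- normalizeInteractionScores(inputs$interactions, cfg$is_floor)
    graphs <- buildGraphs(ints, pre$promoterMap, pre$mrna, pre$mirna,
                          pre$meth)
    tcfg <- TransformConfig(
      alpha = cfg$alpha, betaExp = cfg$beta_exp, w1 = cfg$w1, w2 = cfg$w2,
      exprPseudocount = cfg$expr_pseudocount, isFloor = cfg$is_floor,
      missingPartnerPolicy = cfg$missing_partner_policy,
      log2Mrna = cfg$log2_mrna
    )
    list(graphs = graphs,
         delta = transformMatrix(pre$mrna, pre$mirna, pre$meth, graphs,
                                 tcfg))
  })
  writeOmicsMatrix(OmicsMatrix(transformedMatrix(trans$delta),
                               "mrna_counts"),
                   file.path(outDir, "transformed.tsv"))

  labels <- inputs$labels[inputs$labels$sample_id %in%
                            sampleIds(pre$mrna), , drop = FALSE]
  split <- .stage("split", {
    stratifiedSplit(labels, cfg$test_fraction, seed + 3L)
  })

  feat <- t(transformedMatrix(trans$delta))
  yAll <- stats::setNames(labels$class_label, labels$sample_id)
  trainX <- feat[split$train, , drop = FALSE]
  trainY <- yAll[split$train]
  if (isTRUE(cfg$augment)) {
    aug <- .stage("augment", augmentMinority(trainX, trainY, seed + 4L))
    trainX <- aug$X; trainY <- aug$y
  }

  eval <- .stage("train", {
    spec <- if (cfg$model == "knn") {
      modelSpec("knn", k = cfg$knn_neighbors, seed = seed + 5L)
    } else {
      modelSpec(cfg$model, seed = seed + 5L)
    }
    pred <- fitPredict(spec, trainX, trainY,
                       feat[split$test, , drop = FALSE])
    evaluateClassifier(yAll[split$test], pred$labels, pred$scores)
  })
  writeTable(eval@perClass, file.path(outDir, "eval_per_class.tsv"))
  writeTable(as.data.frame(eval@confusion),
             file.path(outDir, "confusion.tsv"))

  explain <- .stage("explain", {
    ens <- fitTreeEnsemble(trainX, trainY, seed = seed + 6L)
    ranking <- rankFeatures(ens, trainX, trainY, backend = "shapley_tree",
                            topK = cfg$top_k)
    perClass <- topGenesPerClass(ranking, cfg$per_class_k)
    if (!is.null(inputs$annotations)) {
      perClass <- lapply(perClass, function(g) {
        filterByAnnotation(g, inputs$annotations)$kept
      })
    }
    list(ranking = ranking, perClass = perClass,
         sets = subtypeUniqueSets(perClass))
  })
  writeTable(explain$ranking, file.path(outDir, "importance.tsv"))
  membership <- data.frame(
    gene = explain$sets$union,
    classes = vapply(explain$sets$union, function(g) {
      paste(names(explain$perClass)[vapply(explain$perClass, function(v) {
        g %in% v
      }, TRUE)], collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  writeTable(membership, file.path(outDir, "gene_sets.tsv"))

  survOut <- NULL
  if (!is.null(inputs$survival)) {
    survOut <- .stage("survival", {
      tr <- transformedMatrix(trans$delta)
      res <- lapply(names(explain$perClass), function(cl) {
        inClass <- labels$sample_id[labels$class_label == cl]
        genes <- explain$sets$unique[[cl]]
        if (length(genes) == 0L || length(inClass) < 4L) return(NULL)
        scr <- screenGenes(tr[, inClass, drop = FALSE],
                           inputs$survival, genes,
                           alphaLevel = cfg$alpha_level)
        if (nrow(scr)) cbind(subtype = cl, scr) else NULL
      })
      do.call(rbind, res)
    })
    if (!is.null(survOut)) {
      writeTable(survOut, file.path(outDir, "survival_screen.tsv"))
    }
  }

  outFiles <- list.files(outDir, full.names = TRUE)
  outFiles <- outFiles[basename(outFiles) != "manifest.json"]
  manifest <- list(
    tool_version = as.character(utils::packageVersion("gainet")),
    config = cfg[order(names(cfg))],
    seed = seed,
    stage_seeds = list(split = seed + 3L, augment = seed + 4L,
                       train = seed + 5L, explain = seed + 6L),
    counts = list(
      samples_retained = length(pre$report$samples_retained),
      features = lapply(pre$report$counts_after, function(d) d[1]),
      usable_edges = as.list(trans$graphs@edgeStats),
      train = length(trainY), test = length(split$test),
      accuracy = eval@accuracy, macro_f1 = macroF1(eval)
    ),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(sort(outFiles)))),
      basename(sort(outFiles)))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
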