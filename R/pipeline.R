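#' Pipeline configuration
#'
#' A flat list of paths, stage toggles and thresholds mirroring the printed
#' defaults of the emulated analysis: Bonferroni family-wise alpha 0.05, FDR
#' 5\%, top 300 transcripts by selection score (threshold alternative 1.8),
#' per-drug regulated-transcript threshold 10, walk-length cutoff 4 for
#' network dissection, and 50 most sensitive transcripts per mechanism for
#' target inference.
#'
#' @param outdir run directory (created by \code{\link{runPipeline}})
#' @param synthetic a \linkS4class{SyntheticConfig} for synthetic generation,
#'   or NULL when \code{matrixPath}/\code{sampleSheetPath} point at real data
#' @param matrixPath,sampleSheetPath input TSVs (ignored when synthetic)
#' @param gmtPath optional GMT file for the enrichment stage; for synthetic
#'   runs, gene sets are derived from the planted truth when absent
#' @param stages named logical vector toggling the stages
#' @param log2Input input is linear scale and needs a log2 transform
#' @param bonferroniAlpha,fdr,topK,scoreThreshold,perDrugThreshold,cutoff,
#'   minNetworkSize,topKSensitive analysis thresholds
#' @param seed integer seed controlling all randomness of the run
#' @return a config list for \code{\link{runPipeline}}
#' @export
pipelineConfig <- function(outdir,
                           synthetic = syntheticConfig(),
                           matrixPath = NULL, sampleSheetPath = NULL,
                           gmtPath = NULL,
                           stages = c(normalize = TRUE, screen = TRUE,
                                      score = TRUE, classify = TRUE,
                                      network = TRUE, enrich = TRUE,
                                      infer = TRUE),
                           log2Input = FALSE,
                           bonferroniAlpha = 0.05, fdr = 0.05,
                           topK = 300, scoreThreshold = 1.8,
                           perDrugThreshold = 10,
                           cutoff = 4, minNetworkSize = 10,
                           topKSensitive = 50,
                           seed = 1L) {
  stopifnot(bonferroniAlpha > 0, fdr > 0, topK > 0, scoreThreshold > 0,
            perDrugThreshold > 0, cutoff > 0, topKSensitive > 0)
  if (!is.null(synthetic)) synthetic@seed <- as.integer(seed)
  list(outdir = outdir, synthetic = synthetic, matrixPath = matrixPath,
       sampleSheetPath = sampleSheetPath, gmtPath = gmtPath, stages = stages,
       log2Input = log2Input, bonferroniAlpha = bonferroniAlpha, fdr = fdr,
       topK = topK, scoreThreshold = scoreThreshold,
       perDrugThreshold = perDrugThreshold, cutoff = cutoff,
       minNetworkSize = minNetworkSize, topKSensitive = topKSensitive,
       seed = as.integer(seed))
}

.stage_msg <- function(log, stage, ...) {
  msg <- paste0("[", stage, "] ", ...)
  message(msg)
  c(log, msg)
}

.stage_on <- function(config, stage) {
  isTRUE(config$stages[[stage]])
}

.stage_require <- function(obj, stage, needed_by) {
  if (is.null(obj))
    stop("stage '", needed_by, "' needs the output of disabled stage '",
         stage, "'", call. = FALSE)
  obj
}

#' Run the full analysis pipeline
#'
#' Executes, in order: generate (or load) -> normalize -> screen -> score ->
#' classify -> network -> enrich -> infer, writing each stage's tables into
#' the run directory plus a machine-readable \code{summary.json}. Identical
#' configuration and seed give byte-identical summaries. Any stage error
#' aborts with a message naming the stage; a stage consuming a disabled
#' stage's output fails fast.
#'
#' @param config list from \code{\link{pipelineConfig}}
#' @return invisibly, the summary list
#' @export
runPipeline <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  summary <- list(seed = config$seed)
  truth <- NULL

  ## ---- generate / load ----
  if (!is.null(config$synthetic)) {
    sim <- generateExperiment(config$synthetic)
    x <- sim$experiment
    truth <- sim$truth
    writeSyntheticExperiment(sim, config$synthetic, outdir)
    log <- .stage_msg(log, "generate", nrow(x), " probes x ", ncol(x),
                      " samples (synthetic)")
  } else {
    if (is.null(config$matrixPath) || is.null(config$sampleSheetPath))
      stop("[load] no synthetic config and no input paths")
    x <- readExpression(config$matrixPath, config$sampleSheetPath)
    log <- .stage_msg(log, "load", nrow(x), " probes x ", ncol(x), " samples")
  }
  sheet <- sampleSheet(x)
  per_drug <- table(sheet$drug[!sheet$is_vehicle & sheet$drug != "NAIVE"])
  summary$n_probes <- nrow(x)
  summary$n_samples <- ncol(x)
  summary$arrays_per_drug <- if (length(unique(per_drug)) == 1L)
    as.integer(per_drug[1]) else as.list(per_drug)

  ## ---- normalize ----
  norm <- NULL
  if (.stage_on(config, "normalize")) {
    norm <- suppressWarnings(
      normalizeExpression(x, log2Input = config$log2Input))
    writeExpression(norm, file.path(outdir, "normalized.tsv"),
                    file.path(outdir, "sample_sheet_norm.tsv"))
    log <- .stage_msg(log, "normalize", "quantile + per-batch z-score")
  }

  ## ---- screen ----
  screen <- NULL
  if (.stage_on(config, "screen")) {
    screen <- twowayAnova(.stage_require(norm, "normalize", "screen"))
    writeScreenResult(screen, file.path(outdir, "screen.tsv"))
    n_bonf <- sum(screen$p_bonf < config$bonferroniAlpha)
    n_fdr <- sum(screen$p_bh <= config$fdr)
    tp <- estimateTruePositives(screen$p_drug)
    summary$screen <- list(df = as.list(attr(screen, "df")),
                           bonferroni_significant = n_bonf,
                           fdr_significant = n_fdr,
                           estimated_true_positives = tp$plateau)
    log <- .stage_msg(log, "screen", n_bonf, " Bonferroni / ", n_fdr,
                      " FDR significant probes")
  }

  ## ---- score ----
  scores <- NULL
  selected <- NULL
  fct <- NULL
  if (.stage_on(config, "score")) {
    fct <- foldChanges(.stage_require(norm, "normalize", "score"))
    scores <- suppressWarnings(g2mScore(fct))
    writeScoreTable(scores, file.path(outdir, "scores.tsv"))
    k <- min(config$topK, nrow(globalScores(scores)))
    selected <- selectTranscripts(scores, "top_k", k)
    .writeTsv(selected, file.path(outdir, "selected.tsv"))
    counts <- countRegulated(scores, config$perDrugThreshold)
    .writeTsv(counts, file.path(outdir, "regulated_per_drug.tsv"))
    summary$score <- list(
      selected = nrow(selected),
      above_threshold = nrow(selectTranscripts(scores, "threshold",
                                               config$scoreThreshold)),
      regulated_per_drug = stats::setNames(as.list(counts$n_regulated),
                                           counts$drug))
    log <- .stage_msg(log, "score", nrow(selected), " transcripts selected")
  }

  ## ---- classify ----
  if (.stage_on(config, "classify")) {
    sel <- .stage_require(selected, "score", "classify")
    profiles <- buildDrugProfiles(.stage_require(fct, "score", "classify"),
                                  sel$probe_id)
    hc <- clusterDrugs(profiles)
    writeDendrogramNewick(hc, file.path(outdir, "dendrogram.nwk"))
    nc <- min(3L, nrow(profiles) - 1L, ncol(profiles))
    pca <- pcaDrugs(profiles, nc)
    .writeMatrixTsv(pca@scores, "drug", file.path(outdir, "pca_scores.tsv"))
    comp_cor <- suppressWarnings(correlateComponents(pca, fct, sel$probe_id))
    .writeMatrixTsv(comp_cor, "probe_id",
                    file.path(outdir, "component_correlations.tsv"))
    summary$classify <- list(
      n_components = nc,
      variance_explained = round(sum(pca@varFrac), 4))
    log <- .stage_msg(log, "classify",
                      sprintf("%d PCA components explain %.1f%% of variance",
                              nc, 100 * sum(pca@varFrac)))
  }

  ## ---- network ----
  networks <- NULL
  if (.stage_on(config, "network")) {
    sel <- .stage_require(selected, "score", "network")
    prof <- transcriptProfiles(.stage_require(fct, "score", "network"))
    dmat <- suppressWarnings(spearmanDistance(prof))
    tree <- buildMST(dmat)
    writeTree(tree, file.path(outdir, "tree_edges.tsv"),
              file.path(outdir, "tree.graphml"))
    networks <- extractNetworks(tree, sel$probe_id, cutoff = config$cutoff,
                                minNetworkSize = config$minNetworkSize)
    .writeTsv(networks, file.path(outdir, "networks.tsv"))
    sizes <- attr(networks, "sizes")
    summary$network <- list(n_networks = length(sizes),
                            sizes = as.list(sizes))
    log <- .stage_msg(log, "network", length(sizes), " networks (",
                      paste(sizes, collapse = "/"), ")")
  }

  ## ---- enrich ----
  if (.stage_on(config, "enrich")) {
    sel <- .stage_require(selected, "score", "enrich")
    collection <- NULL
    if (!is.null(config$gmtPath)) {
      collection <- readGMT(config$gmtPath, universe = rownames(x))
    } else if (!is.null(truth)) {
      membership <- trueMembership(truth)
      mods <- split(names(membership), membership)
      mods <- mods[names(mods) != "background"]
      if (length(mods))
        collection <- geneSetCollection(mods, names(membership))
    }
    if (is.null(collection)) {
      log <- .stage_msg(log, "enrich", "no gene sets available; skipped")
    } else {
      enr <- setEnrichment(sel$probe_id, collection)
      .writeTsv(enr, file.path(outdir, "enrichment.tsv"))
      summary$enrich <- list(n_sets_tested = nrow(enr),
                             n_significant = sum(enr$significant))
      log <- .stage_msg(log, "enrich", sum(enr$significant),
                        " significant sets of ", nrow(enr))
    }
  }

  ## ---- infer ----
  if (.stage_on(config, "infer")) {
    fct_ok <- .stage_require(fct, "score", "infer")
    B <- if (!is.null(config$synthetic))
      generateBindingMatrix(config$synthetic) else NULL
    if (is.null(B)) {
      log <- .stage_msg(log, "infer", "no binding matrix available; skipped")
    } else {
      B <- B[rowSums(B > 0) > 0, , drop = FALSE]
      E <- drugResponseMatrix(fct_ok)[, rownames(B), drop = FALSE]
      A <- fitSensitivity(E, B)
      red <- reduceSensitive(A, topK = min(config$topKSensitive, ncol(A)))
      .writeMatrixTsv(red$A, "mechanism",
                      file.path(outdir, "sensitivity_reduced.tsv"))
      loo <- looValidate(E, B, topK = min(config$topKSensitive, ncol(A)))
      .writeTsv(loo, file.path(outdir, "loo_validation.tsv"))
      summary$infer <- list(
        reduced_transcripts = red$unionSize,
        median_loo_cosine = round(stats::median(loo$cosine, na.rm = TRUE), 4),
        top1_accuracy = round(mean(loo$rank_of_true == 1, na.rm = TRUE), 4))
      log <- .stage_msg(log, "infer", red$unionSize,
                        " reduced transcripts; median LOO cosine ",
                        summary$infer$median_loo_cosine)
    }
  }

  writeLines(log, file.path(outdir, "run.log"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
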