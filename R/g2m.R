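#' Fold changes and t tests against the matched vehicle
#'
#' For every (probe, drug, time-point): log2 fold change = mean of the treated
#' replicates minus mean of the matched vehicle replicates (both on the
#' normalized log2 scale), and a two-sided equal-variance two-sample t-test
#' P value on the replicate values. Per (probe, drug), the cross-time
#' consistency summaries \code{foldmean} (mean signed log2 fold change over
#' the time course) and \code{foldsd} (sample sd, n - 1) are added.
#'
#' @param x a normalized \linkS4class{DrugExpressionSet}
#' @param vehiclePolicy \code{"matched"} compares each drug with the vehicle
#'   named in its sample-sheet \code{control} column (e.g. Tween for drugs
#'   dissolved in Tween 80); \code{"always_saline"} compares everything with
#'   \code{salineLabel}
#' @param salineLabel the saline vehicle's drug label
#' @return a \linkS4class{FoldChangeTable}
#' @export
foldChanges <- function(x, vehiclePolicy = c("matched", "always_saline"),
                        salineLabel = "SAL") {
  vehiclePolicy <- match.arg(vehiclePolicy)
  stopifnot(is(x, "DrugExpressionSet"))
  sheet <- sampleSheet(x)
  m <- exprValues(x)
  if (!"role" %in% colnames(sheet))
    sheet$role <- ifelse(sheet$is_vehicle, "vehicle",
                         ifelse(sheet$drug == "NAIVE", "naive", "treatment"))
  drugs <- unique(sheet$drug[sheet$role == "treatment"])
  times <- sort(unique(sheet$time_h[sheet$role == "treatment"]))
  probes <- rownames(m)

  blocks <- vector("list", length(drugs) * length(times))
  summ <- vector("list", length(drugs))
  bi <- 0L
  for (di in seq_along(drugs)) {
    d <- drugs[di]
    veh <- salineLabel
    if (vehiclePolicy == "matched" && "control" %in% colnames(sheet)) {
      ctl <- sheet$control[sheet$drug == d][1]
      if (!is.na(ctl)) veh <- ctl
    }
    lfc_mat <- matrix(NA_real_, length(probes), length(times))
    tp_mat <- matrix(NA_real_, length(probes), length(times))
    for (ti in seq_along(times)) {
      t_h <- times[ti]
      i1 <- which(sheet$drug == d & sheet$time_h == t_h)
      i0 <- which(sheet$drug == veh & sheet$time_h == t_h)
      if (!length(i0))
        stop("no vehicle group '", veh, "' at time ", t_h, " for drug ", d)
      n1 <- length(i1); n0 <- length(i0)
      if (n1 < 2 || n0 < 2)
        stop("need >= 2 replicates per group (drug ", d, ", time ", t_h, ")")
      x1 <- m[, i1, drop = FALSE]; x0 <- m[, i0, drop = FALSE]
      m1 <- rowMeans(x1); m0 <- rowMeans(x0)
      v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
      v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
      sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n0))
      diff <- m1 - m0
      tstat <- diff / se
      tstat[se == 0 & diff == 0] <- 0
      p <- 2 * stats::pt(abs(tstat), df = n1 + n0 - 2, lower.tail = FALSE)
      p[se == 0 & diff != 0] <- 0
      lfc_mat[, ti] <- diff
      tp_mat[, ti] <- p
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(probe_id = probes, drug = d, time_h = t_h,
                                 log2fc = diff, fold = 2^diff, t_p = p,
                                 row.names = NULL)
    }
    foldmean <- rowMeans(lfc_mat)
    foldsd <- apply(lfc_mat, 1, stats::sd)
    summ[[di]] <- data.frame(probe_id = probes, drug = d,
                             foldmean = foldmean, foldsd = foldsd,
                             row.names = NULL)
  }
  new("FoldChangeTable", table = do.call(rbind, blocks),
      summary = do.call(rbind, summ), probes = probes, drugs = drugs,
      times = times)
}

#' The selection-score kernel
#'
#' \deqn{score = 10 \cdot (-\log_2 p) \cdot \log_2(f + 1) \cdot
#'   foldmean/foldsd}
#' with \eqn{f = 2^{|log2fc|} - 1} the magnitude-of-change term (the fold
#' ratio folded onto the amplification side, so a 2-fold induction and a
#' 2-fold repression contribute identically and the score magnitude is
#' invariant to swapping the drug and vehicle labels). The first
#' factor rewards per-time significance, the second the magnitude of change,
#' and the signed consistency ratio \eqn{foldmean/foldsd} rewards a response
#' sustained across the time course and carries the direction (consistently
#' down-regulated transcripts get negative scores of symmetric magnitude).
#' \code{p = 1} or \code{log2fc = 0} gives a score of exactly 0; \code{p} is
#' clamped away from 0 so the score stays finite.
#'
#' @param t_p per-time t-test P value
#' @param log2fc per-time signed log2 fold change
#' @param consistency the signed ratio foldmean/foldsd
#' @return numeric score
#' @examples
#' g2mFormula(0.25, 1, 2)  # 10 * 2 * 1 * 2 = 40
#' g2mFormula(1, 3, 5)     # 0
#' @export
g2mFormula <- function(t_p, log2fc, consistency) {
  p <- pmax(t_p, .Machine$double.xmin)
  f <- 2^abs(log2fc) - 1
  10 * (-log2(p)) * log2(f + 1) * consistency
}

#' Composite selection score per (probe, drug, time)
#'
#' Applies \code{\link{g2mFormula}} to a \linkS4class{FoldChangeTable} and
#' aggregates: the drug-level score is the per-time score of maximal absolute
#' value (sign retained; ties broken by earliest time), and the per-probe
#' global score is the drug-level score of maximal absolute value (ties by
#' drug label). (probe, drug) pairs with \code{foldsd = 0} have an undefined
#' consistency ratio; their scores are reported as NA, excluded from the
#' aggregates, and counted in a warning.
#'
#' @param fct a \linkS4class{FoldChangeTable}
#' @return a \linkS4class{G2MScoreTable}
#' @export
g2mScore <- function(fct) {
  stopifnot(is(fct, "FoldChangeTable"))
  tb <- fcTable(fct)
  sm <- fcSummary(fct)
  key <- paste(tb$probe_id, tb$drug, sep = "\r")
  skey <- paste(sm$probe_id, sm$drug, sep = "\r")
  undef <- is.na(sm$foldsd) | sm$foldsd == 0
  ratio <- ifelse(undef, NA_real_, sm$foldmean / sm$foldsd)
  cons <- ratio[match(key, skey)]
  tb$score <- g2mFormula(tb$t_p, tb$log2fc, cons)
  excluded <- sm[undef, c("probe_id", "drug"), drop = FALSE]
  if (nrow(excluded))
    warning(nrow(excluded),
            " (probe, drug) pair(s) with zero cross-time sd: ",
            "score undefined, excluded from ranking")
  ok <- tb[!is.na(tb$score), , drop = FALSE]
  ord <- order(ok$probe_id, ok$drug, -abs(ok$score), ok$time_h)
  ok <- ok[ord, ]
  dkey <- paste(ok$probe_id, ok$drug, sep = "\r")
  drug_scores <- ok[!duplicated(dkey), c("probe_id", "drug", "score")]
  ord2 <- order(drug_scores$probe_id, -abs(drug_scores$score),
                drug_scores$drug)
  ds <- drug_scores[ord2, ]
  global <- ds[!duplicated(ds$probe_id), c("probe_id", "score")]
  rownames(drug_scores) <- rownames(global) <- NULL
  new("G2MScoreTable", table = tb, drugScores = drug_scores,
      globalScores = global, excluded = excluded)
}

#' Rank and select transcripts by global score
#'
#' Deterministic ranking by absolute global score, descending, with ties
#' broken by probe id. \code{top_k} returns the k best; \code{threshold}
#' returns every probe with |score| above the value.
#'
#' @param scores a \linkS4class{G2MScoreTable}
#' @param mode \code{"top_k"} or \code{"threshold"}
#' @param value k, or the score threshold
#' @return data.frame(probe_id, score, rank), in rank order
#' @export
selectTranscripts <- function(scores, mode = c("top_k", "threshold"), value) {
  mode <- match.arg(mode)
  stopifnot(is(scores, "G2MScoreTable"))
  g <- globalScores(scores)
  ord <- order(-abs(g$score), g$probe_id)
  ranked <- data.frame(probe_id = g$probe_id[ord], score = g$score[ord],
                       rank = seq_along(ord), row.names = NULL)
  if (mode == "top_k") {
    k <- as.integer(value)
    if (k > nrow(ranked))
      stop("k = ", k, " exceeds the ", nrow(ranked), " scored probes")
    ranked[seq_len(k), , drop = FALSE]
  } else {
    ranked[abs(ranked$score) > value, , drop = FALSE]
  }
}

#' Per-drug counts of regulated transcripts at a score threshold
#'
#' @param scores a \linkS4class{G2MScoreTable}
#' @param threshold drug-level |score| cutoff (default 10)
#' @return data.frame(drug, n_regulated)
#' @export
countRegulated <- function(scores, threshold = 10) {
  stopifnot(is(scores, "G2MScoreTable"))
  ds <- drugScores(scores)
  agg <- stats::aggregate(list(n_regulated = abs(ds$score) > threshold),
                          by = list(drug = ds$drug), FUN = sum)
  agg[order(agg$drug), , drop = FALSE]
}

#' Write the score table to TSV
#'
#' Columns: probe_id, drug, time_h, log2fc, t_p, score, drug_score,
#' global_score.
#'
#' @param scores a \linkS4class{G2MScoreTable}
#' @param path output path
#' @return invisibly, the path
#' @export
writeScoreTable <- function(scores, path) {
  tb <- scoreTable(scores)
  ds <- drugScores(scores)
  gs <- globalScores(scores)
  tb$drug_score <- ds$score[match(paste(tb$probe_id, tb$drug),
                                  paste(ds$probe_id, ds$drug))]
  tb$global_score <- gs$score[match(tb$probe_id, gs$probe_id)]
  .writeTsv(tb[, c("probe_id", "drug", "time_h", "log2fc", "t_p", "score",
                   "drug_score", "global_score")], path)
  invisible(path)
}
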