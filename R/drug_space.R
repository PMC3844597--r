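#' Per-drug expression profiles over a transcript set
#'
#' Rows are drugs, columns the signed log2 fold changes of the selected
#' transcripts at every time-point (transcript-major, time-minor column
#' order; column names \code{probe@time}).
#'
#' @param fct a \linkS4class{FoldChangeTable}
#' @param transcripts probe ids to include (must be scored probes)
#' @return drugs x (transcripts * times) numeric matrix
#' @export
buildDrugProfiles <- function(fct, transcripts) {
  stopifnot(is(fct, "FoldChangeTable"))
  unknown <- setdiff(transcripts, fct@probes)
  if (length(unknown))
    stop("unknown transcript id(s): ", paste(utils::head(unknown, 5),
                                             collapse = ", "))
  tb <- fcTable(fct)
  tb <- tb[tb$probe_id %in% transcripts, , drop = FALSE]
  drugs <- fct@drugs
  times <- fct@times
  feat <- as.vector(t(outer(transcripts, times,
                            function(p, t) paste0(p, "@", t))))
  out <- matrix(NA_real_, length(drugs), length(feat),
                dimnames = list(drugs, feat))
  idx <- cbind(match(tb$drug, drugs),
               match(paste0(tb$probe_id, "@", tb$time_h), feat))
  out[idx] <- tb$log2fc
  if (anyNA(out)) stop("incomplete fold-change table")
  out
}

#' Transcript co-expression profiles
#'
#' One row per transcript: the group-mean log2 fold change over every
#' (drug, time) condition -- the drug-response curve used to correlate
#' transcripts with each other on the co-expression map.
#'
#' @param fct a \linkS4class{FoldChangeTable}
#' @param transcripts probe ids (default: all scored probes)
#' @return transcripts x (drugs * times) numeric matrix
#' @export
transcriptProfiles <- function(fct, transcripts = NULL) {
  stopifnot(is(fct, "FoldChangeTable"))
  if (is.null(transcripts)) transcripts <- fct@probes
  unknown <- setdiff(transcripts, fct@probes)
  if (length(unknown))
    stop("unknown transcript id(s): ", paste(utils::head(unknown, 5),
                                             collapse = ", "))
  tb <- fcTable(fct)
  tb <- tb[tb$probe_id %in% transcripts, , drop = FALSE]
  drugs <- fct@drugs
  times <- fct@times
  feat <- as.vector(t(outer(drugs, times, paste, sep = "@")))
  out <- matrix(NA_real_, length(transcripts), length(feat),
                dimnames = list(transcripts, feat))
  out[cbind(match(tb$probe_id, transcripts),
            match(paste0(tb$drug, "@", tb$time_h), feat))] <- tb$log2fc
  if (anyNA(out)) stop("incomplete fold-change table")
  out
}

#' Per-drug scalar transcript response
#'
#' Summarises each transcript's response to each drug by the signed log2 fold
#' change at the time-point of maximal absolute change.
#'
#' @param fct a \linkS4class{FoldChangeTable}
#' @param transcripts probe ids (default: all)
#' @return transcripts x drugs numeric matrix
#' @export
drugResponseMatrix <- function(fct, transcripts = NULL) {
  stopifnot(is(fct, "FoldChangeTable"))
  if (is.null(transcripts)) transcripts <- fct@probes
  tb <- fcTable(fct)
  tb <- tb[tb$probe_id %in% transcripts, , drop = FALSE]
  ord <- order(tb$probe_id, tb$drug, -abs(tb$log2fc), tb$time_h)
  tb <- tb[ord, ]
  key <- paste(tb$probe_id, tb$drug, sep = "\r")
  best <- tb[!duplicated(key), , drop = FALSE]
  out <- matrix(NA_real_, length(transcripts), length(fct@drugs),
                dimnames = list(transcripts, fct@drugs))
  out[cbind(match(best$probe_id, transcripts),
            match(best$drug, fct@drugs))] <- best$log2fc
  out
}

#' Hierarchical clustering of drugs by expression profile
#'
#' Agglomerative clustering of the drug profile matrix with Euclidean
#' distance and complete linkage. Deterministic for a fixed input (ties
#' resolved by the stable ordering of \code{stats::hclust}).
#'
#' @param profiles matrix from \code{\link{buildDrugProfiles}}
#' @return an \code{hclust} object with drug labels
#' @export
clusterDrugs <- function(profiles) {
  if (nrow(profiles) < 2) stop("need >= 2 drugs to cluster")
  if (anyNA(profiles) || any(!is.finite(profiles)))
    stop("profiles contain non-finite values")
  stats::hclust(stats::dist(profiles, method = "euclidean"),
                method = "complete")
}

#' Export a drug dendrogram in Newick format
#'
#' Leaf names are drug labels; branch lengths are merge-height differences.
#'
#' @param hc an \code{hclust} from \code{\link{clusterDrugs}}
#' @param path output path
#' @return invisibly, the path
#' @export
writeDendrogramNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component analysis of drug profiles
#'
#' PCA of the column-centered (unscaled -- fold changes share units) profile
#' matrix with drugs as observations. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so scores are
#' reproducible.
#'
#' @param profiles drugs x features matrix
#' @param nComponents components to retain (default 3); must not exceed
#'   min(drugs - 1, features)
#' @return a \linkS4class{DrugPCA}
#' @export
pcaDrugs <- function(profiles, nComponents = 3) {
  maxc <- min(nrow(profiles) - 1L, ncol(profiles))
  if (nComponents > maxc)
    stop("nComponents exceeds min(n_drugs - 1, n_features) = ", maxc)
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total_frac <- (vars / sum(vars))[seq_len(maxc)]
  keep <- seq_len(nComponents)
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  flip <- vapply(keep, function(j) {
    v <- load[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  new("DrugPCA", scores = scores, loadings = load,
      varFrac = (vars / sum(vars))[keep], totalVarFrac = total_frac)
}

#' Correlation of transcript responses with PCA components
#'
#' Pearson correlation between each transcript's per-drug response vector
#' (signed log2 fold change at the time of maximal absolute change) and the
#' drug scores of each retained component. Transcripts with zero response
#' variance get NA with a warning.
#'
#' @param pca a \linkS4class{DrugPCA}
#' @param fct the \linkS4class{FoldChangeTable} the PCA was built from
#' @param transcripts probe ids to correlate
#' @return transcripts x components matrix of correlations in [-1, 1]
#' @export
correlateComponents <- function(pca, fct, transcripts) {
  stopifnot(is(pca, "DrugPCA"))
  resp <- drugResponseMatrix(fct, transcripts)
  drugs <- rownames(pca@scores)
  resp <- resp[, drugs, drop = FALSE]
  sds <- apply(resp, 1, stats::sd)
  out <- matrix(NA_real_, nrow(resp), ncol(pca@scores),
                dimnames = list(rownames(resp), colnames(pca@scores)))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance transcript(s): correlation undefined")
  if (any(ok))
    out[ok, ] <- stats::cor(t(resp[ok, , drop = FALSE]), pca@scores)
  out
}
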