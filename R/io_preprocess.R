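.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.writeMatrixTsv <- function(m, idcol, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- idcol
  .writeTsv(df, path)
}

#' Read an expression matrix and sample sheet from TSV files
#'
#' The matrix file has probe ids in the first column and one column per
#' sample; the sample sheet has one row per sample with at least
#' \code{sample_id, drug, time_h, replicate, batch, is_vehicle}. Probe and
#' sample order is preserved from the files. Missing or unparseable cells are
#' an error (reported with their row and column), not imputed.
#'
#' @param matrixPath path to the expression TSV
#' @param sampleSheetPath path to the sample sheet TSV
#' @return a \linkS4class{DrugExpressionSet}
#' @seealso \code{\link{writeExpression}} for the inverse; the round trip is
#'   lossless.
#' @export
readExpression <- function(matrixPath, sampleSheetPath) {
  raw <- utils::read.delim(matrixPath, check.names = FALSE,
                           colClasses = "character")
  if (anyDuplicated(raw[[1]]))
    stop("duplicate probe ids in ", matrixPath)
  probe_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unparseable or missing value at probe '%s', sample '%s'",
                 probe_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(probe_ids, colnames(vals))
  sheet <- utils::read.delim(sampleSheetPath, check.names = FALSE)
  sheet$is_vehicle <- as.logical(sheet$is_vehicle)
  DrugExpressionSet(num, sheet)
}

#' Write a DrugExpressionSet to TSV files
#'
#' @param x a \linkS4class{DrugExpressionSet}
#' @param matrixPath,sampleSheetPath output paths
#' @return invisibly, \code{x}
#' @export
writeExpression <- function(x, matrixPath, sampleSheetPath) {
  m <- exprValues(x)
  fmt <- matrix(formatC(m, digits = 17, format = "g"), nrow(m),
                dimnames = dimnames(m))
  df <- data.frame(probe_id = rownames(m), fmt, check.names = FALSE)
  .writeTsv(df, matrixPath)
  .writeTsv(sampleSheet(x), sampleSheetPath)
  invisible(x)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the identical value distribution: the
#' vector of row-rank means. Ties are resolved by averaging the reference
#' values of the tied ranks. Idempotent. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param x numeric matrix (probes x samples) or a
#'   \linkS4class{DrugExpressionSet}
#' @return object of the same kind with normalized values
#' @examples
#' quantileNormalize(cbind(a = c(1, 2), b = c(3, 2)))
#' @export
quantileNormalize <- function(x) {
  if (is(x, "DrugExpressionSet")) {
    se <- x
    m <- exprValues(x)
  } else {
    se <- NULL
    m <- as.matrix(x)
  }
  if (!is.numeric(m)) stop("expression values must be numeric")
  if (ncol(m) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(x)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (is.null(se)) return(out)
  DrugExpressionSet(out, sampleSheet(se))
}

#' Log2 transform with a floor
#'
#' For linear-scale input: values are floored at \code{floor} (default 1.0)
#' before taking log2, so non-positive intensities cannot produce -Inf/NaN.
#'
#' @param x matrix or \linkS4class{DrugExpressionSet} of linear-scale values
#' @param floor lower clamp applied before the logarithm
#' @return log2-scale object of the same kind
#' @export
log2Transform <- function(x, floor = 1.0) {
  if (is(x, "DrugExpressionSet"))
    return(DrugExpressionSet(log2(pmax(exprValues(x), floor)),
                             sampleSheet(x)))
  log2(pmax(as.matrix(x), floor))
}

#' Per-batch z-score standardization
#'
#' Within each hybridization batch, each probe's values are centered and
#' scaled to mean 0 and (population, i.e. divide-by-n) standard deviation 1,
#' removing any per-batch affine distortion \eqn{a x + b} (a > 0). Probes
#' constant within a batch are mapped to 0 with a warning.
#'
#' @param x numeric matrix (probes x samples) or a
#'   \linkS4class{DrugExpressionSet} (batch labels then come from the sample
#'   sheet)
#' @param batches batch label per sample; ignored for a DrugExpressionSet
#' @return object of the same kind, standardized
#' @export
standardizeBatches <- function(x, batches = NULL) {
  if (is(x, "DrugExpressionSet")) {
    se <- x
    m <- exprValues(x)
    batches <- sampleSheet(x)$batch
  } else {
    se <- NULL
    m <- as.matrix(x)
  }
  if (is.null(batches) || length(batches) != ncol(m))
    stop("every sample needs a batch label")
  tab <- table(batches)
  if (any(tab < 2))
    stop("batch(es) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  out <- m
  n_const <- 0L
  for (b in unique(batches)) {
    cols <- which(batches == b)
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    centered <- sub - mu
    sd_pop <- sqrt(rowMeans(centered^2))
    const <- sd_pop == 0
    n_const <- n_const + sum(const)
    sd_pop[const] <- 1
    out[, cols] <- centered / sd_pop
  }
  if (n_const > 0)
    warning(n_const, " probe/batch combination(s) constant; set to 0")
  if (is.null(se)) return(out)
  DrugExpressionSet(out, sampleSheet(se))
}

#' Full normalization chain
#'
#' Applies, in order: an optional background hook (default pass-through),
#' quantile normalization, an optional log2 transform (for linear-scale
#' input), and per-batch z-score standardization.
#'
#' @param x a \linkS4class{DrugExpressionSet}
#' @param background function applied to the raw matrix first (default
#'   \code{identity}; background subtraction is upstream of this package)
#' @param log2Input set TRUE when the input is linear-scale intensity
#' @param floor floor for the log2 transform
#' @param quantile,batch stage toggles
#' @return normalized \linkS4class{DrugExpressionSet}
#' @export
normalizeExpression <- function(x, background = identity, log2Input = FALSE,
                                floor = 1.0, quantile = TRUE, batch = TRUE) {
  stopifnot(is(x, "DrugExpressionSet"))
  m <- background(exprValues(x))
  x <- DrugExpressionSet(m, sampleSheet(x))
  if (quantile) x <- quantileNormalize(x)
  if (log2Input) x <- log2Transform(x, floor)
  if (batch) x <- standardizeBatches(x)
  x
}
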